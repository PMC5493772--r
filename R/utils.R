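# Shared validators and small helpers.

#' Check that a data frame has the given columns
#'
#' @param df data frame to check.
#' @param cols required column names.
#' @param what label used in the error message.
#' @noRd
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate an array manifest
#'
#' Checks columns, roles, duplicate array ids, and that every
#' collection x media set with treatment arrays also has a control.
#' @noRd
validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  check_columns(manifest, .manifest_cols, "manifest")
  bad_roles <- setdiff(unique(manifest$role), .roles)
  if (length(bad_roles) > 0) {
    abort(sprintf("manifest contains unknown role(s) %s; allowed roles are: %s",
                  paste(sQuote(bad_roles), collapse = ", "),
                  paste(.roles, collapse = ", ")))
  }
  dup <- manifest$array_id[duplicated(manifest$array_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate array_id in manifest: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  no_ctl <- manifest |>
    group_by(.data$collection, .data$media) |>
    summarise(has_control = any(.data$role == "control"), .groups = "drop") |>
    filter(!.data$has_control)
  if (nrow(no_ctl) > 0) {
    abort(sprintf("set(s) with no control array: %s",
                  paste(paste(no_ctl$collection, no_ctl$media, sep = "/"),
                        collapse = ", ")))
  }
  manifest
}

# Derive a stream-specific child seed from the user seed; kept < 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483647L
}

# Tag id convention: "<strain>|up" / "<strain>|dn".
tag_id <- function(strain_id, tag_class) {
  paste0(strain_id, "|", if_else(tag_class == "uptag", "up", "dn"))
}

tag_strain <- function(tag_id) sub("\\|(up|dn)$", "", tag_id)

tag_class_of <- function(tag_id) {
  if_else(grepl("\\|up$", tag_id), "uptag", "downtag")
}

#' Write a tibble as TSV (deterministic, no quoting surprises)
#' @noRd
write_tsv_file <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

read_tsv_file <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}
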