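# Feature-level intensity handling: loading, artifact masking, and
# summarization to one log2 value per tag per array.

#' Construct a tag-level intensity matrix
#'
#' The pipeline's central array container: one log2 intensity per tag per
#' array in long form, the array manifest, and a log of masked features.
#'
#' @param values tibble `tag_id`, `array_id`, `value` (log2 scale).
#' @param manifest array manifest (validated).
#' @param mask_log tibble of removed features (`tag_id`, `array_id`,
#'   `feature`, `reason`).
#' @return An object of class `tag_matrix`.
#' @export
new_tag_matrix <- function(values, manifest,
                           mask_log = tibble(tag_id = character(),
                                             array_id = character(),
                                             feature = integer(),
                                             reason = character())) {
  manifest <- validate_manifest(manifest)
  check_columns(values, c("tag_id", "array_id", "value"), "values")
  extra <- setdiff(unique(values$array_id), manifest$array_id)
  if (length(extra) > 0) {
    abort(sprintf("array(s) in values missing from manifest: %s",
                  paste(extra, collapse = ", ")))
  }
  structure(list(values = as_tibble(values), manifest = manifest,
                 mask_log = as_tibble(mask_log)),
            class = "tag_matrix")
}

#' @export
print.tag_matrix <- function(x, ...) {
  cat("<tag_matrix> ", dplyr::n_distinct(x$values$tag_id), " tags x ",
      nrow(x$manifest), " arrays (", nrow(x$mask_log),
      " masked features)\n", sep = "")
  invisible(x)
}

#' Load a feature-level intensity table and its manifest
#'
#' Expects the TSV dialects written by [write_fixture_bundle()]: an
#' intensity table with `tag_id`, `array_id` and `feature_*` columns (log2
#' scale), and a manifest with `array_id`, `collection`, `media`,
#' `condition`, `batch`, `replicate`, `role`. Roles are validated and any
#' set without a control array is rejected.
#'
#' @param path intensity TSV path.
#' @param manifest_path manifest TSV path.
#' @return list with `features` tibble and validated `manifest`.
#' @export
load_intensity_table <- function(path, manifest_path) {
  features <- read_tsv_file(path)
  check_columns(features, c("tag_id", "array_id"), "intensity table")
  fcols <- grep("^feature_", names(features), value = TRUE)
  if (length(fcols) == 0) abort("intensity table has no feature_* columns")
  manifest <- validate_manifest(read_tsv_file(manifest_path))
  extra <- setdiff(unique(features$array_id), manifest$array_id)
  if (length(extra) > 0) {
    abort(sprintf("array(s) in intensity table missing from manifest: %s",
                  paste(extra, collapse = ", ")))
  }
  list(features = features, manifest = manifest)
}

#' Mask outlier replicate features for one tag on one array
#'
#' Robust trim: features farther than `mad_k` scaled MADs from the feature
#' median are flagged as artifacts and the summary is the mean of the
#' remainder. When the MAD is zero (replicates essentially identical) a
#' feature is flagged if it lies more than 3 sd from the mean of the other
#' features. If flagging would leave fewer than `min_keep` features, the
#' `min_keep` features closest to the median are kept instead.
#'
#' @param features numeric vector of replicate log2 intensities (>= 3
#'   finite values expected).
#' @param mad_k MAD multiplier (default 4).
#' @param min_keep minimum features that must survive (default 3).
#' @return list with `summary` (mean of kept features, `NA` if fewer than
#'   `min_keep` finite inputs) and `flags` (logical, `TRUE` = masked).
#' @export
#' @examples
#' mask_replicate_features(c(10, 10, 10, 10, 16))
mask_replicate_features <- function(features, mad_k = 4, min_keep = 3) {
  flags <- rep(FALSE, length(features))
  finite <- is.finite(features)
  if (sum(finite) < min_keep) {
    return(list(summary = NA_real_, flags = !finite))
  }
  x <- features
  med <- median(x[finite])
  m <- mad(x[finite])  # 1.4826 scaling is mad()'s default
  if (m > 0) {
    flags <- finite & abs(x - med) > mad_k * m
  } else {
    # Degenerate spread: flag features > 3 sd from the mean of the others.
    for (i in which(finite)) {
      others <- x[finite][setdiff(seq_len(sum(finite)), match(i, which(finite)))]
      s <- sd(others)
      if (is.finite(s) && s > 0 && abs(x[i] - mean(others)) > 3 * s) {
        flags[i] <- TRUE
      } else if ((!is.finite(s) || s == 0) && length(others) > 0 &&
                 x[i] != others[1] && all(others == others[1])) {
        flags[i] <- TRUE
      }
    }
  }
  flags[!finite] <- TRUE
  if (sum(finite & !flags) < min_keep) {
    keep <- order(abs(x - med))[seq_len(min_keep)]
    flags <- rep(TRUE, length(x))
    flags[keep] <- FALSE
    flags[!finite] <- TRUE
  }
  list(summary = mean(x[!flags & finite]), flags = flags)
}

#' Summarize replicate features to one value per tag per array
#'
#' Applies [mask_replicate_features()] to every (tag, array) row of a
#' feature-level table and records every removed feature in the mask log.
#' Tags with fewer than `min_keep` finite features on an array are marked
#' missing there (dropped from the value table, logged).
#'
#' @param features feature-level tibble (`tag_id`, `array_id`,
#'   `feature_*`).
#' @param manifest validated array manifest.
#' @param mad_k,min_keep masking parameters.
#' @return A [new_tag_matrix()] object.
#' @export
summarize_to_tags <- function(features, manifest, mad_k = 4, min_keep = 3) {
  check_columns(features, c("tag_id", "array_id"), "features")
  fcols <- grep("^feature_", names(features), value = TRUE)
  if (length(fcols) == 0) abort("no feature_* columns to summarize")
  fm <- as.matrix(features[, fcols])
  n <- nrow(fm)
  nf <- length(fcols)

  if (nf == 1) {
    values <- tibble(tag_id = features$tag_id, array_id = features$array_id,
                     value = fm[, 1])
    return(new_tag_matrix(values[is.finite(values$value), ], manifest))
  }

  # Vectorized fast path: rows whose spread is within tolerance need no
  # masking; the remainder go through the per-row rule.
  med <- apply(fm, 1, median, na.rm = TRUE)
  dev <- abs(fm - med)
  madv <- apply(dev, 1, median, na.rm = TRUE) * 1.4826
  n_finite <- rowSums(is.finite(fm))
  all_in <- madv > 0 & apply(dev <= mad_k * madv, 1, all) & n_finite == nf
  summary <- rep(NA_real_, n)
  summary[all_in] <- rowMeans(fm[all_in, , drop = FALSE])

  mask_rows <- list()
  slow <- which(!all_in)
  for (i in slow) {
    res <- mask_replicate_features(fm[i, ], mad_k = mad_k, min_keep = min_keep)
    summary[i] <- res$summary
    if (any(res$flags)) {
      mask_rows[[length(mask_rows) + 1L]] <- tibble(
        tag_id = features$tag_id[i], array_id = features$array_id[i],
        feature = which(res$flags),
        reason = if_else(is.finite(fm[i, which(res$flags)]),
                         "outlier", "nonfinite"))
    }
    if (is.na(res$summary)) {
      mask_rows[[length(mask_rows) + 1L]] <- tibble(
        tag_id = features$tag_id[i], array_id = features$array_id[i],
        feature = NA_integer_, reason = "too_few_features")
    }
  }
  mask_log <- if (length(mask_rows) > 0) bind_rows(mask_rows) else
    tibble(tag_id = character(), array_id = character(),
           feature = integer(), reason = character())
  values <- tibble(tag_id = features$tag_id, array_id = features$array_id,
                   value = summary)
  new_tag_matrix(values[!is.na(values$value), ], manifest, mask_log)
}
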