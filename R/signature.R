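# Shared fitness signatures across condition groups (e.g. the HLU
# signature of the plasmid-complemented prototroph collection) and their
# subtraction to reveal condition-specific effects.

#' Define a shared fitness signature across a condition group
#'
#' The signature profile is the per-strain median of the per-condition
#' median FDs across the group. Members are strains whose `fd_median`
#' meets `threshold` in every group condition (`rule = "all"`, default) or
#' in at least one (`rule = "any"`).
#'
#' @param stats tibble with `strain_id`, `condition`, `fd_median` (the
#'   `stats` element of a `fitness_table`, or any compatible table).
#' @param group conditions forming the signature group.
#' @param threshold FD cutoff for membership (default 1.0).
#' @param rule `"all"` or `"any"`.
#' @return An object of class `fd_signature`: list with `profile` (tibble
#'   `strain_id`, `profile_fd`), `members`, `group`, `threshold`, `rule`.
#' @export
#' @examples
#' stats <- tibble::tibble(strain_id = rep(c("s1", "s2"), each = 3),
#'                         condition = rep(c("H", "L", "U"), 2),
#'                         fd_median = c(2, 2, 2, 2, 2, 0.5))
#' define_shared_signature(stats, c("H", "L", "U"))$members
define_shared_signature <- function(stats, group, threshold = 1.0,
                                    rule = c("all", "any")) {
  rule <- match.arg(rule)
  if (inherits(stats, "fitness_table")) stats <- stats$stats
  check_columns(stats, c("strain_id", "condition", "fd_median"), "stats")
  missing_cond <- setdiff(group, unique(stats$condition))
  if (length(missing_cond) > 0) {
    abort(sprintf("condition(s) not in the FD table: %s",
                  paste(missing_cond, collapse = ", ")))
  }
  if (length(group) == 1) {
    warn("signature group of size 1: the signature equals the condition")
  }
  sub <- filter(stats, .data$condition %in% group)
  prof <- sub |>
    group_by(.data$strain_id) |>
    summarise(profile_fd = median(.data$fd_median),
              n_cond = dplyr::n(),
              n_pass = sum(.data$fd_median >= threshold),
              .groups = "drop")
  members <- switch(rule,
    all = prof$strain_id[prof$n_pass == length(group) &
                           prof$n_cond == length(group)],
    any = prof$strain_id[prof$n_pass >= 1])
  structure(list(profile = select(prof, "strain_id", "profile_fd"),
                 members = sort(members), group = group,
                 threshold = threshold, rule = rule),
            class = "fd_signature")
}

#' @export
print.fd_signature <- function(x, ...) {
  cat("<fd_signature> group {", paste(x$group, collapse = ", "), "}: ",
      length(x$members), " member strains (FD >= ", x$threshold,
      ", rule = ", x$rule, ")\n", sep = "")
  invisible(x)
}

#' Subtract a shared signature from one condition's FD profile
#'
#' Recomputes fitness relative to the shared signature as reference:
#' `fd_corrected = fd_median - profile_fd`. Strains without a profile
#' value pass through unchanged and are flagged.
#'
#' @param stats FD table for one condition (`strain_id`, `condition`,
#'   `fd_median`), or a `fitness_table` (its `stats` are filtered to
#'   `condition`).
#' @param signature an `fd_signature`.
#' @param condition the condition being corrected; must belong to the
#'   signature's group.
#' @return tibble `strain_id`, `condition`, `fd_median`, `profile_fd`,
#'   `fd_corrected`, `profiled` (FALSE where no profile existed).
#' @export
subtract_signature <- function(stats, signature, condition = NULL) {
  stopifnot(inherits(signature, "fd_signature"))
  if (inherits(stats, "fitness_table")) stats <- stats$stats
  check_columns(stats, c("strain_id", "condition", "fd_median"), "stats")
  condition <- condition %||% unique(stats$condition)
  if (length(condition) != 1) {
    abort("subtract_signature corrects one condition at a time")
  }
  if (!condition %in% signature$group) {
    abort(sprintf("condition %s is outside the signature group {%s}: correction undefined",
                  condition, paste(signature$group, collapse = ", ")))
  }
  stats |>
    filter(.data$condition == !!condition) |>
    left_join(signature$profile, by = "strain_id") |>
    mutate(profiled = !is.na(.data$profile_fd),
           fd_corrected = if_else(.data$profiled,
                                  .data$fd_median - .data$profile_fd,
                                  .data$fd_median)) |>
    select("strain_id", "condition", "fd_median", "profile_fd",
           "fd_corrected", "profiled")
}

#' Pearson correlation of fitness profiles between collections
#'
#' Computed per shared condition over the strains measured in both tables
#' whose `fd_median` exceeds `threshold` in at least one shared condition
#' (in either collection).
#'
#' @param stats_a,stats_b FD tables (`strain_id`, `condition`,
#'   `fd_median`) or `fitness_table`s.
#' @param threshold FD inclusion cutoff (default 1.0).
#' @param min_strains minimum qualifying strains (default 3); below it the
#'   correlation is reported as `NA`.
#' @return tibble `condition`, `n_strains`, `r`.
#' @export
profile_correlation <- function(stats_a, stats_b, threshold = 1.0,
                                min_strains = 3) {
  if (inherits(stats_a, "fitness_table")) stats_a <- stats_a$stats
  if (inherits(stats_b, "fitness_table")) stats_b <- stats_b$stats
  shared <- intersect(unique(stats_a$condition), unique(stats_b$condition))
  if (length(shared) == 0) abort("no shared conditions between the tables")
  joined <- inner_join(
    select(stats_a, "strain_id", "condition", fd_a = "fd_median"),
    select(stats_b, "strain_id", "condition", fd_b = "fd_median"),
    by = c("strain_id", "condition")) |>
    filter(.data$condition %in% shared)
  qualifying <- joined |>
    group_by(.data$strain_id) |>
    summarise(pass = any(.data$fd_a > threshold | .data$fd_b > threshold),
              .groups = "drop") |>
    filter(.data$pass) |>
    pull("strain_id")
  joined |>
    filter(.data$strain_id %in% qualifying) |>
    group_by(.data$condition) |>
    summarise(n_strains = dplyr::n(),
              r = if (dplyr::n() >= min_strains)
                cor(.data$fd_a, .data$fd_b) else NA_real_,
              .groups = "drop")
}
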