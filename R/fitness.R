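# Fitness-defect scoring: tag-class normalization, best-tag selection,
# batch standardization, FD scores against control medians, and
# t-test / Benjamini-Hochberg significance.

#' Normalize uptags and downtags to their set medians
#'
#' Within each collection x media set, each array's uptag values are
#' shifted so the array's uptag median equals the set's overall uptag
#' median (the median over arrays of per-array uptag medians); downtags
#' likewise. The choice of the median-of-medians target makes the
#' operation exactly idempotent. Shifts are recorded in
#' `attr(, "shift_log")`.
#'
#' @param tm a `tag_matrix`.
#' @return A normalized `tag_matrix`.
#' @export
normalize_by_tag_class_median <- function(tm) {
  stopifnot(inherits(tm, "tag_matrix"))
  v <- tm$values |>
    mutate(tag_class = tag_class_of(.data$tag_id)) |>
    left_join(select(tm$manifest, "array_id", "collection", "media"),
              by = "array_id")
  if (!all(c("uptag", "downtag") %in% unique(v$tag_class))) {
    abort("matrix must contain both uptag and downtag rows")
  }
  single <- v |>
    distinct(.data$collection, .data$media, .data$array_id) |>
    dplyr::count(.data$collection, .data$media) |>
    filter(.data$n < 2)
  if (nrow(single) > 0) {
    warn("set(s) with a single array: normalization is the identity there")
  }
  per_array <- v |>
    group_by(.data$collection, .data$media, .data$tag_class,
             .data$array_id) |>
    summarise(array_median = median(.data$value), .groups = "drop_last") |>
    mutate(target = median(.data$array_median),
           shift = .data$target - .data$array_median) |>
    ungroup()
  shifted <- v |>
    left_join(select(per_array, "collection", "media", "tag_class",
                     "array_id", "shift"),
              by = c("collection", "media", "tag_class", "array_id")) |>
    mutate(value = .data$value + .data$shift)
  out <- new_tag_matrix(select(shifted, "tag_id", "array_id", "value"),
                        tm$manifest, tm$mask_log)
  attr(out, "shift_log") <- select(per_array, "collection", "media",
                                   "tag_class", "array_id", "shift")
  out
}

#' Select the best tag per strain and collapse to a strain matrix
#'
#' Per strain and set, the representing tag is the one with the lowest
#' coefficient of variation (sd/mean of linear-scale `2^log2` intensities)
#' across the set's control replicates; ties go to the uptag. The chosen
#' tag's values represent the strain on every array of the set.
#'
#' @param tm a (normalized) `tag_matrix`.
#' @param strains optional character vector restricting to these strains
#'   (e.g. those passing presence calling). Strains with no measured tag
#'   are excluded.
#' @return list with `values` (tibble `strain_id`, `array_id`, `value`),
#'   `best_tags` (tibble `collection`, `media`, `strain_id`, `tag_class`,
#'   `cv`), and `manifest`.
#' @export
select_best_tag <- function(tm, strains = NULL) {
  stopifnot(inherits(tm, "tag_matrix"))
  v <- tm$values |>
    mutate(strain_id = tag_strain(.data$tag_id),
           tag_class = tag_class_of(.data$tag_id)) |>
    left_join(select(tm$manifest, "array_id", "collection", "media",
                     "role"),
              by = "array_id")
  if (!is.null(strains)) v <- filter(v, .data$strain_id %in% strains)
  n_ctl <- v |>
    filter(.data$role == "control") |>
    distinct(.data$collection, .data$media, .data$array_id) |>
    dplyr::count(.data$collection, .data$media)
  if (any(n_ctl$n < 2)) {
    abort("best-tag selection needs >= 2 control replicates per set")
  }
  cv_tab <- v |>
    filter(.data$role == "control") |>
    group_by(.data$collection, .data$media, .data$strain_id,
             .data$tag_class) |>
    summarise(cv = sd(2^.data$value) / mean(2^.data$value),
              n = dplyr::n(), .groups = "drop")
  best <- cv_tab |>
    group_by(.data$collection, .data$media, .data$strain_id) |>
    arrange(.data$cv, .data$tag_class == "downtag", .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("collection", "media", "strain_id", "tag_class", "cv")
  values <- v |>
    inner_join(best, by = c("collection", "media", "strain_id",
                            "tag_class")) |>
    select("strain_id", "array_id", "value")
  list(values = values, best_tags = best, manifest = tm$manifest)
}

#' Location-scale batch standardization
#'
#' Per strain and set: values of each batch are centred and scaled to the
#' batch mean and sd, then rescaled to the strain's pooled mean and sd
#' across the set's arrays. Batches with a single array (or zero spread)
#' receive a location-only correction. Single-batch sets are returned
#' unchanged (the transform is the identity there).
#'
#' @param collapsed list from [select_best_tag()] (or any list with
#'   `values` and `manifest`).
#' @return the same list with corrected `values`.
#' @export
batch_correct <- function(collapsed) {
  v <- collapsed$values |>
    left_join(select(collapsed$manifest, "array_id", "collection",
                     "media", "batch"),
              by = "array_id")
  batch_sizes <- collapsed$manifest |>
    dplyr::count(.data$collection, .data$media, .data$batch)
  if (any(batch_sizes$n < 2) && dplyr::n_distinct(batch_sizes$batch) > 1) {
    warn("batch(es) with a single array: location-only correction applied")
  }
  corrected <- v |>
    group_by(.data$collection, .data$media, .data$strain_id) |>
    mutate(pooled_mean = mean(.data$value), pooled_sd = sd(.data$value)) |>
    group_by(.data$collection, .data$media, .data$strain_id,
             .data$batch) |>
    mutate(b_mean = mean(.data$value),
           b_sd = if (dplyr::n() >= 2) sd(.data$value) else NA_real_) |>
    ungroup() |>
    mutate(value = case_when(
      is.na(.data$pooled_sd) | .data$pooled_sd == 0 ~ .data$value,
      is.na(.data$b_sd) | .data$b_sd == 0 ~
        .data$value - .data$b_mean + .data$pooled_mean,
      TRUE ~ (.data$value - .data$b_mean) / .data$b_sd * .data$pooled_sd +
        .data$pooled_mean))
  # single-batch sets: transform above equals identity only in location;
  # restore exact identity by construction
  n_batches <- v |>
    distinct(.data$collection, .data$media, .data$batch) |>
    dplyr::count(.data$collection, .data$media, name = "n_batches")
  corrected <- corrected |>
    left_join(n_batches, by = c("collection", "media")) |>
    mutate(value = if_else(.data$n_batches == 1,
                           v$value, .data$value))
  collapsed$values <- select(corrected, "strain_id", "array_id", "value")
  collapsed
}

#' Compute fitness-defect scores against control medians
#'
#' `FD(strain, treatment array) = median over the set's control arrays -
#' treatment value`, so positive FD means depletion (a fitness defect).
#' Per-condition profiles are summarized as the median FD across that
#' condition's replicates.
#'
#' @param collapsed list with `values` (`strain_id`, `array_id`, `value`)
#'   and `manifest`.
#' @return An object of class `fitness_table`: list with `fd` (per
#'   replicate: `strain_id`, `collection`, `media`, `condition`,
#'   `replicate`, `array_id`, `fd`), `stats` (per strain x condition:
#'   `fd_median`, `n_reps`; `p`/`q` filled by [test_significance()]), and
#'   `manifest`.
#' @export
compute_fd_scores <- function(collapsed) {
  v <- collapsed$values |>
    left_join(collapsed$manifest, by = "array_id")
  ctl <- v |>
    filter(.data$role == "control") |>
    group_by(.data$collection, .data$media, .data$strain_id) |>
    summarise(ctl_median = median(.data$value),
              n_ctl = dplyr::n(), .groups = "drop")
  if (nrow(ctl) == 0) abort("no control arrays in the set")
  fd <- v |>
    filter(.data$role == "treatment") |>
    inner_join(ctl, by = c("collection", "media", "strain_id")) |>
    mutate(fd = .data$ctl_median - .data$value) |>
    select("strain_id", "collection", "media", "condition",
           "replicate", "array_id", "fd", "n_ctl")
  if (nrow(fd) == 0) abort("no treatment arrays: nothing to score")
  stats <- fd |>
    group_by(.data$strain_id, .data$collection, .data$condition) |>
    summarise(fd_median = median(.data$fd), n_reps = dplyr::n(),
              .groups = "drop")
  structure(list(fd = fd, stats = stats, manifest = collapsed$manifest,
                 best_tags = collapsed$best_tags %||% NULL),
            class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("<fitness_table> ", dplyr::n_distinct(x$stats$strain_id),
      " strains x ", dplyr::n_distinct(x$stats$condition),
      " condition(s)", if (!is.null(x$stats$q)) " (with p/q)", "\n",
      sep = "")
  invisible(x)
}

#' Variance factor of the median of n standard normal draws
#'
#' Used to propagate the uncertainty of the shared control-median
#' reference into FD significance. Exact for n <= 2 and for odd n
#' (numerical integration of the central order statistic); even n >= 4
#' is approximated by the mean of the neighbouring odd values (slightly
#' conservative).
#'
#' @param n number of control replicates.
#' @return `Var(median(x_1..x_n))` for iid standard normal x.
#' @export
median_var_factor <- function(n) {
  stopifnot(n >= 1)
  if (n <= 2) return(1 / n)
  if (n %% 2 == 0) {
    return(mean(c(median_var_factor(n - 1), median_var_factor(n + 1))))
  }
  k <- (n + 1) / 2
  dens <- function(x) {
    exp(lchoose(n, k - 1) + log(k) + (k - 1) * stats::pnorm(x, log.p = TRUE) +
          (n - k) * stats::pnorm(x, lower.tail = FALSE, log.p = TRUE) +
          dnorm(x, log = TRUE)) * x^2
  }
  stats::integrate(dens, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Per-strain significance of replicate FD scores
#'
#' Replicate FDs are fit to a linear model with one mean per strain and
#' tested two-sided against zero. With `var_pool = "condition"` (default)
#' the model is fit jointly per condition — one coefficient per strain,
#' residual variance pooled across strains (`df = n_obs - n_strains`) —
#' and the standard error also propagates the uncertainty of the shared
#' control-median reference:
#' `se = sigma * sqrt(1/n_reps + c_med(n_ctl))` with `c_med` from
#' [median_var_factor()] (the reference is the same draw for every
#' replicate, so its noise shifts a strain's mean FD without appearing in
#' the replicate variance; ignoring it makes the null anticonservative).
#' With `var_pool = "none"` each strain is tested on its own replicate
#' variance (a plain one-sample t-test, `df = n - 1`). p-values are
#' adjusted to q-values by Benjamini-Hochberg step-up across strains
#' within each condition. Replicate sets with zero variance and a
#' nonzero mean get the smallest representable p (logged in
#' `attr(, "degenerate")`).
#'
#' @param ft a `fitness_table`.
#' @param var_pool `"condition"` (pooled residual variance with
#'   reference-uncertainty propagation) or `"none"` (per-strain
#'   variance).
#' @return the `fitness_table` with `t`, `p`, `q` columns added to
#'   `stats`.
#' @export
test_significance <- function(ft, var_pool = c("condition", "none")) {
  stopifnot(inherits(ft, "fitness_table"))
  var_pool <- match.arg(var_pool)
  per <- ft$fd |>
    group_by(.data$strain_id, .data$collection, .data$condition) |>
    summarise(mean_fd = mean(.data$fd), sd_fd = sd(.data$fd),
              n = dplyr::n(),
              n_ctl = if ("n_ctl" %in% names(ft$fd)) first(.data$n_ctl)
                      else NA_integer_,
              .groups = "drop")
  if (any(per$n < 2)) abort("significance testing needs >= 2 replicates")
  if (var_pool == "condition") {
    # pooled residual sd of the one-mean-per-strain linear model, with the
    # control-reference variance term added to the standard error
    c_med_of <- vapply(sort(unique(per$n_ctl[!is.na(per$n_ctl)])),
                       median_var_factor, numeric(1))
    names(c_med_of) <- sort(unique(per$n_ctl[!is.na(per$n_ctl)]))
    per <- per |>
      group_by(.data$collection, .data$condition) |>
      mutate(df = sum(.data$n) - dplyr::n(),
             se_sd = sqrt(sum(.data$sd_fd^2 * (.data$n - 1)) / .data$df)) |>
      ungroup() |>
      mutate(c_med = if_else(is.na(.data$n_ctl), 0,
                             unname(c_med_of[as.character(.data$n_ctl)])),
             se = .data$se_sd * sqrt(1 / .data$n + .data$c_med))
  } else {
    per <- mutate(per, df = .data$n - 1, se_sd = .data$sd_fd,
                  se = .data$se_sd / sqrt(.data$n))
  }
  per <- per |>
    mutate(t = .data$mean_fd / .data$se,
           p = case_when(
             .data$se_sd == 0 & .data$mean_fd == 0 ~ 1,
             .data$se_sd == 0 ~ .Machine$double.xmin,
             TRUE ~ 2 * pt(-abs(.data$t), .data$df))) |>
    group_by(.data$collection, .data$condition) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup()
  degenerate <- filter(per, .data$se_sd == 0 & .data$mean_fd != 0)
  ft$stats <- ft$stats |>
    left_join(select(per, "strain_id", "collection", "condition",
                     "t", "p", "q"),
              by = c("strain_id", "collection", "condition"))
  attr(ft, "degenerate") <- degenerate
  ft
}
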