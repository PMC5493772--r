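man4 <- function() {
  tibble::tibble(
    array_id = c("c1", "c2", "c3", "t1"),
    collection = "YKO", media = "SC",
    condition = c("SC", "SC", "SC", "drug"),
    batch = "b1", replicate = c(1:3, 1),
    role = c("control", "control", "control", "treatment"))
}

test_that("tag-class normalization shifts arrays to the set median and is idempotent", {
  man <- man4()
  base <- tidyr::crossing(
    tibble::tibble(tag_id = tag_id(rep(sprintf("s%02d", 1:10), 2),
                                   rep(c("uptag", "downtag"), each = 10)),
                   level = rep(seq(9, 11, length.out = 10), 2)),
    array_id = man$array_id) |>
    dplyr::mutate(value = level)
  tm <- new_tag_matrix(dplyr::select(base, tag_id, array_id, value), man)

  # identical arrays: no change
  n1 <- normalize_by_tag_class_median(tm)
  expect_equal(dplyr::arrange(n1$values, tag_id, array_id),
               dplyr::arrange(tm$values, tag_id, array_id))

  # +1 on one array's uptags is removed; downtags untouched
  skew <- tm$values |>
    dplyr::mutate(value = value + (array_id == "t1" &
                                     grepl("\\|up$", tag_id)))
  tm2 <- new_tag_matrix(skew, man)
  n2 <- normalize_by_tag_class_median(tm2)
  expect_equal(dplyr::arrange(n2$values, tag_id, array_id),
               dplyr::arrange(tm$values, tag_id, array_id))
  shifts <- attr(n2, "shift_log")
  expect_equal(shifts$shift[shifts$array_id == "t1" &
                              shifts$tag_class == "uptag"], -1)
  expect_equal(shifts$shift[shifts$tag_class == "downtag"], rep(0, 4))

  # idempotence
  set.seed(41)
  noisy <- tm$values |> dplyr::mutate(value = value + rnorm(dplyr::n(), 0, 1))
  tm3 <- new_tag_matrix(noisy, man)
  once <- normalize_by_tag_class_median(tm3)
  twice <- normalize_by_tag_class_median(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("best tag is the lowest linear-scale CV, ties to the uptag", {
  man <- man4()
  # uptag steady, downtag noisy across controls
  vals <- tibble::tibble(
    tag_id = rep(tag_id(c("s1", "s1"), c("uptag", "downtag")), each = 4),
    array_id = rep(man$array_id, 2),
    value = c(10, 10.02, 9.98, 8, 10, 11, 9, 8))
  sel <- select_best_tag(new_tag_matrix(vals, man))
  expect_equal(sel$best_tags$tag_class, "uptag")
  expect_equal(sel$values$value[sel$values$array_id == "t1"], 8)

  # exact tie -> uptag
  tie <- vals |> dplyr::mutate(value = rep(c(10, 10.1, 9.9, 8), 2))
  sel2 <- select_best_tag(new_tag_matrix(tie, man))
  expect_equal(sel2$best_tags$tag_class, "uptag")

  # noiseless fixture: collapsed values equal the generating means
  sc <- small_screen(n_strains = 40, n_hit = 5, fd = 1.5, noise_sd = 0,
                     seed = 44)
  tm <- summarize_to_tags(sc$screen$features, sc$screen$manifest)
  sel3 <- select_best_tag(tm)
  truth_vals <- sc$screen$tags$values |>
    dplyr::mutate(strain_id = sub("\\|(up|dn)$", "", tag_id))
  # every collapsed value equals one of the strain's generating tag
  # values on that array
  j <- dplyr::inner_join(
    sel3$values, truth_vals,
    by = c("strain_id", "array_id"),
    relationship = "many-to-many") |>
    dplyr::group_by(strain_id, array_id) |>
    dplyr::summarise(ok = any(abs(value.x - value.y) < 1e-9),
                     .groups = "drop")
  expect_true(all(j$ok))
})

test_that("batch standardization equalizes batch means and keeps pooled moments", {
  man <- tibble::tibble(
    array_id = sprintf("a%d", 1:6), collection = "YKO", media = "SC",
    condition = "SC", batch = rep(c("b1", "b2"), each = 3),
    replicate = rep(1:3, 2), role = "control")
  set.seed(42)
  vals <- tidyr::crossing(strain_id = sprintf("s%02d", 1:20),
                          array_id = man$array_id) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 10, 0.5) +
                    2 * (array_id %in% c("a4", "a5", "a6")))
  collapsed <- list(values = vals, manifest = man)
  corr <- batch_correct(collapsed)
  by_batch <- corr$values |>
    dplyr::left_join(man, by = "array_id") |>
    dplyr::group_by(strain_id, batch) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = batch, values_from = m)
  expect_lt(max(abs(by_batch$b1 - by_batch$b2)), 1e-9)
  # pooled mean per strain preserved
  pooled_in <- tapply(vals$value, vals$strain_id, mean)
  pooled_out <- tapply(corr$values$value, corr$values$strain_id, mean)
  expect_equal(pooled_out, pooled_in, tolerance = 1e-9)

  # single batch: identity
  man1 <- dplyr::mutate(man, batch = "b1")
  corr1 <- batch_correct(list(values = vals, manifest = man1))
  expect_equal(corr1$values$value, vals$value)
})

test_that("FD scores are control median minus treatment, zero on self-comparison", {
  man <- man4()
  vals <- tidyr::crossing(strain_id = sprintf("s%02d", 1:8),
                          array_id = man$array_id) |>
    dplyr::mutate(value = 10)
  ft <- compute_fd_scores(list(values = vals, manifest = man))
  expect_true(all(ft$fd$fd == 0))

  # planted depletion of exactly g*d = 2 on the treatment array
  vals2 <- vals |>
    dplyr::mutate(value = value - 2 * (strain_id == "s01" &
                                         array_id == "t1"))
  ft2 <- compute_fd_scores(list(values = vals2, manifest = man))
  expect_equal(ft2$stats$fd_median[ft2$stats$strain_id == "s01"], 2)
  expect_equal(ft2$stats$fd_median[ft2$stats$strain_id != "s01"],
               rep(0, 7))

  # FD linearity: +c on every treatment value shifts every FD by -c
  vals3 <- vals2 |>
    dplyr::mutate(value = value + 0.7 * (array_id == "t1"))
  ft3 <- compute_fd_scores(list(values = vals3, manifest = man))
  expect_equal(ft3$fd$fd, ft2$fd$fd - 0.7)
})

test_that("noiseless planted screen recovers FD = g*d exactly end to end", {
  sc <- small_screen(n_strains = 50, n_hit = 6, fd = 2, noise_sd = 0,
                     seed = 47)
  res <- quiet_fd(sc, normalize = FALSE)
  j <- dplyr::left_join(sc$truth$fitness, res$ft$stats,
                        by = c("strain_id", "condition"))
  expect_equal(j$fd_median, j$fd, tolerance = 1e-9)
})

test_that("the per-strain t matches the closed form and degenerate rules", {
  mk_ft <- function(fds) {
    n <- length(fds)
    structure(list(
      fd = tibble::tibble(strain_id = "s1", collection = "YKO",
                          media = "SC", condition = "drug",
                          replicate = seq_len(n),
                          array_id = sprintf("t%d", seq_len(n)),
                          fd = fds, n_ctl = 3L),
      stats = tibble::tibble(strain_id = "s1", collection = "YKO",
                             condition = "drug", fd_median = median(fds),
                             n_reps = n),
      manifest = NULL), class = "fitness_table")
  }
  # (2.0, 2.1, 1.9): mean 2, sd 0.1 -> t = 2/(0.1/sqrt(3)) = 34.64
  ft <- test_significance(mk_ft(c(2.0, 2.1, 1.9)), var_pool = "none")
  expect_equal(ft$stats$t, 2 / (0.1 / sqrt(3)), tolerance = 1e-6)

  # all-zero replicates: p = q = 1
  ft0 <- test_significance(mk_ft(c(0, 0, 0)), var_pool = "none")
  expect_equal(ft0$stats$p, 1)
  expect_equal(ft0$stats$q, 1)

  # zero variance, nonzero mean: smallest representable p, logged
  ftd <- test_significance(mk_ft(c(2, 2, 2)), var_pool = "none")
  expect_equal(ftd$stats$p, .Machine$double.xmin)
  expect_equal(nrow(attr(ftd, "degenerate")), 1)
})

test_that("q-values follow Benjamini-Hochberg step-up within a condition", {
  sc <- small_screen(n_strains = 120, n_hit = 10, fd = 2, seed = 48)
  res <- quiet_fd(sc)
  st <- dplyr::arrange(res$ft$stats, p)
  m <- nrow(st)
  # independent step-up oracle
  q_oracle <- rev(cummin(rev(st$p * m / seq_len(m))))
  expect_equal(st$q, pmin(q_oracle, 1), tolerance = 1e-12)
  expect_true(all(st$q >= st$p - 1e-15))
  expect_true(all(diff(st$q) >= -1e-15))
})

test_that("planted effects are recovered with high sensitivity and controlled FDR", {
  sc <- small_screen(n_strains = 800, n_hit = 60, fd = c(1, 2, 3),
                     noise_sd = 0.3, seed = 49)
  res <- quiet_fd(sc)
  j <- dplyr::left_join(sc$truth$fitness, res$ft$stats,
                        by = c("strain_id", "condition"))
  expect_lt(mean(abs(j$fd_median - j$fd)), 0.3)
  hits <- res$ft$stats$strain_id[res$ft$stats$q < 0.05]
  expect_gte(mean(sc$truth$fitness$strain_id %in% hits), 0.9)
  expect_lte(mean(!(hits %in% sc$truth$fitness$strain_id)), 0.15)
})

test_that("the median variance factor matches known constants", {
  expect_equal(median_var_factor(1), 1)
  expect_equal(median_var_factor(2), 0.5)
  expect_equal(median_var_factor(3), 0.4487, tolerance = 1e-3)
  expect_equal(median_var_factor(5), 0.2868, tolerance = 1e-3)
  # large-n asymptotic pi/(2n)
  expect_equal(median_var_factor(101), pi / 202, tolerance = 0.02)
})
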