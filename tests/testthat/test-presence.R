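test_that("EM recovers two well-separated components", {
  set.seed(21)
  x <- c(rnorm(1500, 10, 0.8), rnorm(300, 6.5, 0.7))
  fit <- fit_background_mixture(x)
  expect_true(fit$converged)
  expect_true(fit$separation_ok)
  expect_lt(abs(fit$means["present"] - 10), 0.15)
  expect_lt(abs(fit$means["absent"] - 6.5), 0.15)
  expect_lt(abs(fit$weights["present"] - 1500 / 1800), 0.03)
  # log-likelihood is monotone non-decreasing over EM iterations
  expect_true(all(diff(fit$loglik) >= -1e-8))
  # posteriors are probabilities and increase with intensity
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  grid <- posterior_present(fit, seq(4, 12, by = 0.1))
  expect_true(all(diff(grid) >= -1e-12))
})

test_that("EM agrees with an independent mixture fitter", {
  withr::local_package("mclust")
  set.seed(22)
  x <- c(rnorm(1200, 10, 0.8), rnorm(400, 6.5, 0.7))
  fit <- fit_background_mixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(unname(sort(fit$means)), unname(sort(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(unname(sort(fit$weights)), unname(sort(mc$parameters$pro)),
               tolerance = 0.02)
})

test_that("unimodal input triggers the no-separation fallback", {
  set.seed(23)
  x <- rnorm(1000, 10, 0.8)
  expect_warning(fit <- fit_background_mixture(x), "no separation")
  expect_false(fit$separation_ok)
  expect_error(fit_background_mixture(rep(5, 100)), "identical")
  expect_error(fit_background_mixture(rnorm(10)), ">= 20")
})

test_that("posterior is exactly one half at the midpoint of symmetric components", {
  fit <- structure(list(weights = c(absent = 0.5, present = 0.5),
                        means = c(absent = 6.5, present = 10),
                        sds = c(absent = 0.8, present = 0.8)),
                   class = "mixture_fit")
  expect_equal(posterior_present(fit, (6.5 + 10) / 2), 0.5)
})

test_that("tag and strain calling enforce the strict all-replicates rule", {
  # posterior exactly at the threshold counts as absent
  calls <- tibble::tibble(
    tag_id = tag_id(c("s1", "s1", "s1", "s1", "s1", "s1"),
                    rep(c("uptag", "downtag"), 3)),
    array_id = rep(c("a1", "a2", "a3"), each = 2),
    posterior = c(0.9, 0.5, 0.9, 0.9, 0.9, 0.9),
    present = posterior > 0.5)
  pc <- call_strain_presence(calls, "s1")
  expect_false(pc$present)  # downtag at exactly 0.5 on a1 fails the strain

  # 0.51 in two controls but 0.4 in one -> fails
  calls2 <- tibble::tibble(
    tag_id = tag_id(rep("s2", 3), rep("uptag", 3)),
    array_id = c("a1", "a2", "a3"),
    posterior = c(0.51, 0.51, 0.4),
    present = posterior > 0.5)
  expect_false(call_strain_presence(calls2, "s2")$present)

  # both tags pass everywhere -> present
  calls3 <- dplyr::mutate(calls, posterior = 0.9, present = TRUE)
  expect_true(call_strain_presence(calls3, "s1")$present)

  # strains with no measured tags are absent and logged
  pc4 <- suppressMessages(call_strain_presence(calls3, c("s1", "ghost")))
  expect_false(pc4$present[pc4$strain_id == "ghost"])
  expect_equal(attr(pc4, "no_tag_strains"), "ghost")
})

test_that("raising the posterior threshold never adds present strains", {
  sc <- small_screen(n_strains = 300, n_hit = 0, dropout = 0.2, seed = 31)
  tm <- summarize_to_tags(sc$screen$features, sc$screen$manifest)
  fits <- fit_control_mixtures(tm)
  prev <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    pc <- suppressMessages(
      call_strain_presence(call_tag_presence(fits, threshold = thr),
                           sc$library, threshold = thr))
    now <- pc$strain_id[pc$present]
    if (!is.null(prev)) expect_true(all(now %in% prev))
    prev <- now
  }
})

test_that("planted dropouts are recalled from the fixture", {
  sc <- small_screen(n_strains = 600, n_hit = 0, dropout = 0.18, seed = 33)
  tm <- summarize_to_tags(sc$screen$features, sc$screen$manifest)
  fits <- fit_control_mixtures(tm)
  pc <- suppressMessages(call_strain_presence(call_tag_presence(fits),
                                              sc$library))
  absent_truth <- setdiff(sc$truth$strains,
                          sc$truth$present_by_collection$YKO)
  called_absent <- pc$strain_id[!pc$present]
  expect_gte(mean(absent_truth %in% called_absent), 0.98)
})

test_that("roster comparison enumerates Venn regions correctly", {
  mk <- function(ids) tibble::tibble(strain_id = ids, present = TRUE)
  venn <- compare_rosters(list(A = mk(c("1", "2")), B = mk(c("2", "3")),
                               C = mk("2")))
  expect_equal(length(venn$universe), 3)
  expect_equal(venn$members[["A&B&C"]], "2")
  expect_equal(venn$members[["A"]], "1")
  expect_equal(venn$members[["B"]], "3")
  expect_equal(sum(venn$counts$count), length(venn$universe))

  same <- list(A = mk(c("x", "y")), B = mk(c("x", "y")),
               C = mk(c("x", "y")))
  v2 <- compare_rosters(same)
  expect_equal(v2$counts$count[v2$counts$region == "A&B&C"], 2L)
  expect_equal(sum(v2$counts$count), 2L)

  expect_error(compare_rosters(list(A = mk("1"))), ">= 2")
  expect_error(compare_rosters(list(A = mk(character()),
                                    B = mk(character()))),
               "empty")
})

test_that("missing-strain report fractions match hand counts", {
  mk <- function(ids) tibble::tibble(strain_id = ids, present = TRUE)
  u <- as.character(1:10)
  venn <- compare_rosters(list(A = mk(u), B = mk(u[1:6])))
  rep_none <- missing_strain_report(venn)
  expect_true(all(is.na(rep_none$frac_annotation_missing)))
  # annotation list of 5 with 3 missing from B -> 60%
  ann <- c("5", "6", "7", "8", "9")
  rep_ann <- missing_strain_report(venn, ann)
  expect_equal(rep_ann$frac_annotation_missing[rep_ann$collection == "B"],
               0.6)
  # annotation = universe -> fraction equals (universe - present)/universe
  rep_all <- missing_strain_report(venn, u)
  expect_equal(rep_all$frac_annotation_missing[rep_all$collection == "B"],
               4 / 10)
})
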