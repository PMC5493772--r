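# Strain-presence calling: two-component Gaussian mixture fit on control
# arrays, per-tag posteriors, the all-tags/all-replicates rule, and roster
# comparison across collections.

#' Fit a two-component Gaussian mixture to control-array intensities
#'
#' Models the log2 intensity distribution of tags on a control array as a
#' mixture of an absent (background) and a present (hybridized) Gaussian
#' component, fit by EM. Components are relabeled so the present component
#' has the larger mean. Initialization is deterministic: means at the 25th
#' and 75th percentiles, equal weights, pooled sd; `seed` is used only for
#' optional random restarts.
#'
#' @param x numeric vector of log2 intensities (>= 20 finite values with
#'   nonzero variance).
#' @param seed optional integer for `n_restarts > 0`.
#' @param tol relative log-likelihood convergence tolerance (1e-8).
#' @param max_iter maximum EM iterations (1000); non-convergence warns and
#'   returns the best fit.
#' @param n_restarts additional random restarts (default 0; the
#'   quantile-based start is deterministic).
#' @return An object of class `mixture_fit` with `weights`, `means`, `sds`
#'   (each named `absent`/`present`), `posterior` (per input value,
#'   P(present | x)), `loglik` (trace over iterations), `converged`, and
#'   `separation_ok` (`FALSE` when the two-component fit does not beat a
#'   single Gaussian on BIC or the component means are closer than half a
#'   pooled sd; downstream calling then treats every tag as present).
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(400, 10, 0.8), rnorm(80, 6.5, 0.7))
#' fit <- fit_background_mixture(x)
#' glance(fit)
fit_background_mixture <- function(x, seed = NULL, tol = 1e-8,
                                   max_iter = 1000, n_restarts = 0) {
  x <- x[is.finite(x)]
  if (length(x) < 20) abort("need >= 20 finite intensities to fit the mixture")
  if (sd(x) == 0) abort("degenerate input: all intensities identical")

  run_em <- function(mu, sigma, w) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E-step in log space for numerical stability
      la <- log(w[1]) + dnorm(x, mu[1], sigma[1], log = TRUE)
      lp <- log(w[2]) + dnorm(x, mu[2], sigma[2], log = TRUE)
      m <- pmax(la, lp)
      ll <- sum(m + log(exp(la - m) + exp(lp - m)))
      trace <- c(trace, ll)
      gamma <- 1 / (1 + exp(la - lp))   # P(component 2 | x)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      n2 <- sum(gamma); n1 <- length(x) - n2
      w <- c(n1, n2) / length(x)
      mu <- c(sum((1 - gamma) * x) / n1, sum(gamma * x) / n2)
      v1 <- sum((1 - gamma) * (x - mu[1])^2) / n1
      v2 <- sum(gamma * (x - mu[2])^2) / n2
      sigma <- sqrt(pmax(c(v1, v2), 1e-4))  # variance floor
    }
    list(mu = mu, sigma = sigma, w = w, gamma = gamma,
         loglik = trace, converged = converged)
  }

  s0 <- sd(x)
  best <- run_em(mu = as.numeric(quantile(x, c(0.25, 0.75))),
                 sigma = c(s0, s0), w = c(0.5, 0.5))
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(child_seed(seed, 4L))
    for (r in seq_len(n_restarts)) {
      mu_r <- sort(sample(x, 2))
      cand <- run_em(mu_r, c(s0, s0), c(0.5, 0.5))
      if (tail(cand$loglik, 1) > tail(best$loglik, 1)) best <- cand
    }
  }
  if (!best$converged) {
    warn(sprintf("EM did not converge in %d iterations; returning best fit",
                 max_iter))
  }

  ord <- order(best$mu)  # absent = lower mean, present = higher
  post_present <- if (ord[2] == 2) best$gamma else 1 - best$gamma
  weights <- setNames(best$w[ord], c("absent", "present"))
  means <- setNames(best$mu[ord], c("absent", "present"))
  sds <- setNames(best$sigma[ord], c("absent", "present"))
  # Guard against spurious splits of unimodal data: the two-component fit
  # must beat a single Gaussian on BIC, and the means must be at least half
  # a pooled sd apart.
  n <- length(x)
  ll1 <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * tail(best$loglik, 1) + 5 * log(n)
  pooled_sd <- sqrt(sum(weights * sds^2))
  separation_ok <- bic2 < bic1 &&
    (means["present"] - means["absent"]) >= 0.5 * pooled_sd
  if (!separation_ok) {
    warn("no separation between mixture components; downstream presence calling will treat all tags as present")
  }
  structure(list(weights = weights, means = means, sds = sds,
                 posterior = post_present, loglik = best$loglik,
                 converged = best$converged,
                 separation_ok = unname(separation_ok),
                 n = length(x), data = x),
            class = "mixture_fit")
}

#' Posterior probability of presence under a fitted mixture
#'
#' @param fit a `mixture_fit`.
#' @param x intensities to score (defaults to the fitted data).
#' @return numeric vector of P(present | x) in `[0, 1]`.
#' @export
posterior_present <- function(fit, x = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(x)) return(fit$posterior)
  la <- log(fit$weights["absent"]) +
    dnorm(x, fit$means["absent"], fit$sds["absent"], log = TRUE)
  lp <- log(fit$weights["present"]) +
    dnorm(x, fit$means["present"], fit$sds["present"], log = TRUE)
  unname(1 / (1 + exp(la - lp)))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> n = %d, absent: %.3f (%.3f) w=%.3f | present: %.3f (%.3f) w=%.3f%s\n",
    x$n, x$means["absent"], x$sds["absent"], x$weights["absent"],
    x$means["present"], x$sds["present"], x$weights["present"],
    if (!x$separation_ok) " [no separation]" else ""))
  invisible(x)
}

#' Fit background mixtures on every control array of a tag matrix
#'
#' One mixture per control array (optionally restricted to one collection),
#' with per-tag posteriors collected in long form.
#'
#' @param tm a `tag_matrix`.
#' @param collection optional collection filter.
#' @param ... passed to [fit_background_mixture()].
#' @return An object of class `control_fits`: list with `fits` (named list
#'   of `mixture_fit` per control array) and `posteriors` (tibble `tag_id`,
#'   `array_id`, `posterior`).
#' @export
fit_control_mixtures <- function(tm, collection = NULL, ...) {
  stopifnot(inherits(tm, "tag_matrix"))
  man <- tm$manifest
  if (!is.null(collection)) man <- filter(man, .data$collection == !!collection)
  ctl <- man$array_id[man$role == "control"]
  if (length(ctl) == 0) abort("no control arrays to fit")
  fits <- list()
  post <- list()
  for (a in ctl) {
    v <- filter(tm$values, .data$array_id == a)
    fits[[a]] <- fit_background_mixture(v$value, ...)
    post[[a]] <- tibble(tag_id = v$tag_id, array_id = a,
                        posterior = posterior_present(fits[[a]], v$value))
  }
  structure(list(fits = fits, posteriors = bind_rows(post),
                 control_arrays = ctl),
            class = "control_fits")
}

#' Call per-tag presence on every control array
#'
#' A tag passes on an array when its posterior probability of presence is
#' strictly greater than `threshold` (ties count as absent). When an
#' array's mixture has no component separation, every tag on that array is
#' called present (conservative fallback).
#'
#' @param fits a `control_fits` object.
#' @param threshold posterior cutoff (default 0.5).
#' @return tibble `tag_id`, `array_id`, `posterior`, `present`.
#' @export
call_tag_presence <- function(fits, threshold = 0.5) {
  stopifnot(inherits(fits, "control_fits"))
  missing_fit <- setdiff(fits$control_arrays, names(fits$fits))
  if (length(missing_fit) > 0) {
    abort(sprintf("no mixture fit for control array(s): %s",
                  paste(missing_fit, collapse = ", ")))
  }
  sep_ok <- map_chr(fits$fits, ~ if (.x$separation_ok) "ok" else "none")
  fits$posteriors |>
    mutate(present = .data$posterior > threshold |
             sep_ok[.data$array_id] == "none")
}

#' Collapse tag calls to strain presence
#'
#' A strain is present in a collection iff every one of its tags has a
#' passing posterior on every control replicate. Strains of the library
#' with no tags on the arrays are treated as absent and logged.
#'
#' @param tag_calls output of [call_tag_presence()].
#' @param library tag library tibble (`strain_id`, `uptag_seq`,
#'   `downtag_seq`) or a character vector of strain ids.
#' @param collection collection label to attach.
#' @param threshold recorded threshold.
#' @return A tibble of class `presence_call`: `strain_id`, `collection`,
#'   `present`, `min_posterior`, `n_tag_calls`. Strains with zero tag calls
#'   are listed in `attr(, "no_tag_strains")`.
#' @export
call_strain_presence <- function(tag_calls, library, collection = "YKO",
                                 threshold = 0.5) {
  strains <- if (is.character(library)) library else library$strain_id
  n_ctl <- dplyr::n_distinct(tag_calls$array_id)
  per_strain <- tag_calls |>
    mutate(strain_id = tag_strain(.data$tag_id)) |>
    filter(.data$strain_id %in% strains) |>
    group_by(.data$strain_id) |>
    summarise(present = all(.data$present),
              min_posterior = min(.data$posterior),
              n_tag_calls = dplyr::n(), .groups = "drop")
  no_tags <- setdiff(strains, per_strain$strain_id)
  if (length(no_tags) > 0) {
    inform(sprintf("%d strain(s) with no tag measurements treated as absent",
                   length(no_tags)))
    per_strain <- bind_rows(per_strain,
                            tibble(strain_id = no_tags, present = FALSE,
                                   min_posterior = NA_real_, n_tag_calls = 0L))
  }
  out <- per_strain |>
    mutate(collection = collection, threshold = threshold) |>
    select("strain_id", "collection", "present", "min_posterior",
           "n_tag_calls", "threshold") |>
    arrange(.data$strain_id)
  attr(out, "no_tag_strains") <- no_tags
  attr(out, "n_control_arrays") <- n_ctl
  class(out) <- c("presence_call", class(out))
  out
}

#' Compare presence rosters across collections
#'
#' Venn-style region counts over the universe of strains present in at
#' least one collection, with per-region strain lists for downstream
#' enrichment.
#'
#' @param calls named list, collection -> `presence_call` (or any tibble
#'   with `strain_id` and `present`).
#' @return An object of class `venn_counts`: list with `counts` (tibble
#'   `region`, `bitmask`, `count`), `members` (named list region ->
#'   strains), `present` (named list collection -> present strains), and
#'   `universe`.
#' @export
#' @examples
#' a <- tibble::tibble(strain_id = c("s1", "s2"), present = TRUE)
#' b <- tibble::tibble(strain_id = c("s2", "s3"), present = TRUE)
#' compare_rosters(list(A = a, B = b))$counts
compare_rosters <- function(calls) {
  if (length(calls) < 2) abort("need >= 2 collections to compare rosters")
  present <- lapply(calls, function(pc) pc$strain_id[pc$present])
  universe <- sort(unique(unlist(present)))
  if (length(universe) == 0) abort("empty union of present strains")
  k <- length(calls)
  cls <- names(calls)
  mask <- rep(0L, length(universe))
  for (i in seq_len(k)) {
    mask <- mask + bitwShiftL(as.integer(universe %in% present[[i]]), i - 1L)
  }
  all_masks <- seq_len(2^k - 1)
  region_name <- vapply(all_masks, function(m) {
    paste(cls[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0], collapse = "&")
  }, character(1))
  counts <- tibble(region = region_name, bitmask = all_masks,
                   count = vapply(all_masks, function(m) sum(mask == m),
                                  integer(1)))
  members <- setNames(lapply(all_masks, function(m) universe[mask == m]),
                      region_name)
  structure(list(counts = counts, members = members, present = present,
                 universe = universe),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("<venn_counts> universe =", length(x$universe), "strains\n")
  print(x$counts)
  invisible(x)
}

#' Per-collection missing-strain summary
#'
#' For each collection: strains missing relative to the universe and,
#' given an annotation list (e.g. known slow growers), the fraction of that
#' list missing from the collection.
#'
#' @param venn a `venn_counts` object.
#' @param annotations optional character vector of annotated strains.
#' @return tibble `collection`, `n_present`, `n_missing`,
#'   `frac_annotation_missing` (`NA` without annotations).
#' @export
missing_strain_report <- function(venn, annotations = NULL) {
  stopifnot(inherits(venn, "venn_counts"))
  purrr::imap_dfr(venn$present, function(p, cl) {
    missing <- setdiff(venn$universe, p)
    frac <- if (is.null(annotations) || length(annotations) == 0) {
      NA_real_
    } else {
      mean(annotations %in% missing)
    }
    tibble(collection = cl, n_present = length(p),
           n_missing = length(missing), frac_annotation_missing = frac)
  })
}
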