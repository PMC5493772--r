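# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a mixture fit
#'
#' @param x a `mixture_fit`.
#' @param ... unused.
#' @return tibble with one row per component (`component`, `weight`,
#'   `mean`, `sd`).
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = c("absent", "present"),
         weight = unname(x$weights),
         mean = unname(x$means),
         sd = unname(x$sds))
}

#' One-row summary of a mixture fit
#'
#' @param x a `mixture_fit`.
#' @param ... unused.
#' @return tibble with `n`, `loglik`, `iterations`, `converged`,
#'   `separation_ok`, `delta_mean`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(n = x$n, loglik = tail(x$loglik, 1),
         iterations = length(x$loglik), converged = x$converged,
         separation_ok = x$separation_ok,
         delta_mean = unname(x$means["present"] - x$means["absent"]))
}

#' Tidy a fitness table
#'
#' @param x a `fitness_table`.
#' @param ... unused.
#' @return the per-strain, per-condition statistics tibble (`fd_median`,
#'   and `p`/`q` when [test_significance()] has run).
#' @export
tidy.fitness_table <- function(x, ...) x$stats

#' One-row-per-condition summary of a fitness table
#'
#' @param x a `fitness_table`.
#' @param fd_threshold FD cutoff used for the `n_fd_hits` column.
#' @param q_threshold q cutoff for `n_significant` (ignored when q is
#'   absent).
#' @param ... unused.
#' @return tibble per condition: strain and hit counts.
#' @export
glance.fitness_table <- function(x, fd_threshold = 1.0,
                                 q_threshold = 0.05, ...) {
  x$stats |>
    group_by(.data$collection, .data$condition) |>
    summarise(
      n_strains = dplyr::n(),
      n_fd_hits = sum(.data$fd_median >= fd_threshold),
      n_significant = if ("q" %in% names(x$stats))
        sum(.data$q < q_threshold & .data$fd_median >= fd_threshold)
      else NA_integer_,
      .groups = "drop")
}

#' Tidy a shared-signature object
#'
#' @param x an `fd_signature`.
#' @param ... unused.
#' @return tibble `strain_id`, `profile_fd`, `member`.
#' @export
tidy.fd_signature <- function(x, ...) {
  x$profile |>
    mutate(member = .data$strain_id %in% x$members)
}

#' Plot a mixture fit over the intensity histogram
#'
#' @param object a `mixture_fit`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot: log2-intensity histogram with the two scaled
#'   component densities and their means.
#' @export
autoplot.mixture_fit <- function(object, bins = 60, ...) {
  df <- tibble(x = object$data)
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 400))
  comp <- bind_rows(
    mutate(grid, component = "absent",
           density = object$weights["absent"] *
             dnorm(.data$x, object$means["absent"], object$sds["absent"])),
    mutate(grid, component = "present",
           density = object$weights["present"] *
             dnorm(.data$x, object$means["present"], object$sds["present"])))
  ggplot(df, aes(x = .data$x)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   fill = "grey80", colour = "grey60") +
    geom_line(data = comp,
              aes(y = .data$density, colour = .data$component),
              linewidth = 0.8) +
    geom_vline(xintercept = unname(object$means), linetype = 2) +
    labs(x = "log2 intensity", y = "density",
         title = "Two-component background mixture") +
    theme_bw()
}

#' Ranked fitness-defect profile plot
#'
#' @param object a `fitness_table`.
#' @param fd_threshold horizontal reference line (default 1.0, the usual
#'   FD significance threshold).
#' @param ... unused.
#' @return a ggplot of per-strain median FDs ranked within each
#'   condition.
#' @export
autoplot.fitness_table <- function(object, fd_threshold = 1.0, ...) {
  df <- object$stats |>
    group_by(.data$condition) |>
    arrange(desc(.data$fd_median), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  ggplot(df, aes(x = .data$rank, y = .data$fd_median)) +
    geom_point(size = 0.6) +
    geom_hline(yintercept = fd_threshold, colour = "red", linetype = 2) +
    facet_wrap(~condition, scales = "free_x") +
    labs(x = "strain rank", y = "median FD (log2)",
         title = "Fitness-defect profiles") +
    theme_bw()
}

#' Signature profile plot
#'
#' @param object an `fd_signature`.
#' @param ... unused.
#' @return a ggplot of the ranked signature profile with members
#'   highlighted.
#' @export
autoplot.fd_signature <- function(object, ...) {
  df <- tidy(object) |>
    arrange(desc(.data$profile_fd)) |>
    mutate(rank = row_number())
  ggplot(df, aes(x = .data$rank, y = .data$profile_fd,
                 colour = .data$member)) +
    geom_point(size = 0.7) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = "strain rank", y = "median FD across group",
         title = paste("Shared signature:",
                       paste(object$group, collapse = ", "))) +
    theme_bw()
}
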