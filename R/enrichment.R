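# Right-sided hypergeometric gene-set enrichment with term-size filters
# and Holm (Bonferroni step-down) correction.

#' Hypergeometric gene-set enrichment
#'
#' For each annotation term, tests whether the query set contains more of
#' the term's genes than expected under sampling without replacement from
#' the universe: right-tail `p = P(X >= k)` with `X ~
#' Hypergeometric(N, K, n)` where `N` is the universe size, `K` the term
#' size within the universe, `n` the query size and `k` the observed
#' overlap. Terms with fewer than `min_size` or more than `max_size` genes
#' in the universe are excluded before testing; p-values are adjusted by
#' Bonferroni step-down (Holm) across the tested terms.
#'
#' @param query character vector of gene/strain ids; ids outside the
#'   universe are dropped with a warning.
#' @param universe character vector defining the background (e.g. strains
#'   present in at least one collection).
#' @param annotations tibble `term_id`, `term_name`, `gene_id` (one row
#'   per term-gene pair), or a named list term -> genes.
#' @param min_size,max_size term-size filters within the universe
#'   (defaults 5 and 300).
#' @param p_cut significance cutoff on the adjusted p (default 5e-4);
#'   sets the `passed` flag only.
#' @return tibble sorted by `p_adj`: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adj`, `passed`.
#' @export
#' @examples
#' ann <- tibble::tibble(term_id = "T1", term_name = "toy",
#'                       gene_id = paste0("g", 1:6))
#' hypergeometric_enrichment(paste0("g", 1:5), paste0("g", 1:20), ann,
#'                           min_size = 2)
hypergeometric_enrichment <- function(query, universe, annotations,
                                      min_size = 5, max_size = 300,
                                      p_cut = 5e-4) {
  if (length(query) == 0) abort("empty query set")
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) abort("no query genes inside the universe")

  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- purrr::imap_dfr(annotations, function(g, id) {
      tibble(term_id = id, term_name = id, gene_id = g)
    })
  }
  check_columns(annotations, c("term_id", "gene_id"), "annotations")
  if (!"term_name" %in% names(annotations)) {
    annotations$term_name <- annotations$term_id
  }
  ann <- annotations |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$term_id, .data$term_name, .data$gene_id)

  N <- length(universe)
  n <- length(query)
  res <- ann |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(K = dplyr::n(), k = sum(.data$gene_id %in% query),
              .groups = "drop") |>
    filter(.data$K >= min_size, .data$K <= max_size)
  if (nrow(res) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  k = integer(), K = integer(), n = integer(),
                  N = integer(), p_raw = numeric(), p_adj = numeric(),
                  passed = logical()))
  }
  res |>
    mutate(n = n, N = N,
           p_raw = phyper(.data$k - 1, .data$K, N - .data$K, n,
                          lower.tail = FALSE),
           p_adj = p.adjust(.data$p_raw, method = "holm"),
           passed = .data$p_adj <= p_cut) |>
    arrange(.data$p_adj, .data$p_raw) |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_raw",
           "p_adj", "passed")
}
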