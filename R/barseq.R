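# Bar-seq quantification: trim reads, locate and match 20-base barcodes by
# Hamming distance (unique-best-hit rule), filter and combine tag counts,
# and compute count-based fitness scores.

# Hamming distances from one 20-mer to every library barcode.
hamming_to_library <- function(candidate, lib_mat) {
  colSums(lib_mat != strsplit(candidate, "", fixed = TRUE)[[1]])
}

#' Count barcodes in Bar-seq reads
#'
#' Reads are trimmed to `trim_len` bases and scanned for a 20-base barcode:
#' first at the position following the uptag/downtag primer context (see
#' [barseq_anchors()]) with an exact index lookup, then — for reads not
#' resolved exactly — by best Hamming distance over the anchored window, or
#' over all 20-base windows when no anchor is found. A read is counted only
#' if its best hit has distance `<= max_mismatch` and beats the runner-up
#' tag by at least one mismatch (with integer distances this is a unique
#' best hit); equidistant reads are ambiguous and discarded.
#'
#' @param fastq named character vector of FASTQ paths (names are sample
#'   ids; `.gz` accepted).
#' @param library tag library tibble (`strain_id`, `uptag_seq`,
#'   `downtag_seq`); barcodes must be unique within each tag class.
#' @param manifest optional sample manifest (`sample_id`, `condition`,
#'   `replicate`, `role`); defaults to treating every sample as its own
#'   condition.
#' @param trim_len read trim length (default 50).
#' @param max_mismatch maximum Hamming distance for a counted hit
#'   (default 2).
#' @return An object of class `count_matrix`: list with `counts` (tibble
#'   `tag_id`, `sample_id`, `count`, complete over library tags), `stats`
#'   (per sample: `total`, `matched`, `ambiguous`, `unmatched`), and
#'   `manifest`.
#' @export
trim_and_match <- function(fastq, library, manifest = NULL, trim_len = 50,
                           max_mismatch = 2) {
  if (is.null(names(fastq)) || any(names(fastq) == "")) {
    names(fastq) <- sub("\\.fastq(\\.gz)?$", "", basename(fastq))
  }
  check_columns(library, c("strain_id", "uptag_seq", "downtag_seq"),
                "library")
  if (nrow(library) == 0) abort("empty barcode library")
  if (anyDuplicated(library$uptag_seq) || anyDuplicated(library$downtag_seq)) {
    abort("duplicate barcode sequences in library")
  }
  tags <- tibble(
    tag_id = c(tag_id(library$strain_id, "uptag"),
               tag_id(library$strain_id, "downtag")),
    barcode = c(library$uptag_seq, library$downtag_seq))
  bc_len <- nchar(tags$barcode[1])
  lib_mat <- matrix(unlist(strsplit(tags$barcode, "", fixed = TRUE)),
                    nrow = bc_len)
  exact_idx <- setNames(seq_len(nrow(tags)), tags$barcode)
  anchors <- c(.up_anchor, .dn_anchor)

  count_rows <- list()
  stat_rows <- list()
  for (smp in names(fastq)) {
    path <- fastq[[smp]]
    if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
    reads <- tryCatch(
      as.character(Biostrings::readBStringSet(path, format = "fastq")),
      error = function(e) abort(sprintf("cannot read FASTQ %s: %s",
                                        path, conditionMessage(e))))
    if (length(reads) == 0) abort(sprintf("empty FASTQ file: %s", path))
    trimmed <- substr(reads, 1, trim_len)
    n <- length(trimmed)
    assigned <- rep(NA_integer_, n)   # row in tags
    status <- rep("unmatched", n)

    # Anchored candidates (one per anchor when found).
    cand <- matrix(NA_character_, n, length(anchors))
    for (ai in seq_along(anchors)) {
      pos <- regexpr(anchors[ai], trimmed, fixed = TRUE)
      ok <- pos > 0 & pos + nchar(anchors[ai]) + bc_len - 1 <= nchar(trimmed)
      cand[ok, ai] <- substr(trimmed[ok], pos[ok] + nchar(anchors[ai]),
                             pos[ok] + nchar(anchors[ai]) + bc_len - 1)
    }
    has_anchor <- rowSums(!is.na(cand)) > 0

    # Fast path: exact hit on an anchored candidate.
    hit <- matrix(exact_idx[cand], n, length(anchors))
    n_hits <- rowSums(!is.na(hit))
    one_hit <- n_hits == 1
    assigned[one_hit] <- hit[cbind(which(one_hit),
                                   max.col(!is.na(hit[one_hit, , drop = FALSE]),
                                           ties.method = "first"))]
    status[one_hit] <- "matched"
    two_tags <- n_hits == 2 & hit[, 1] != hit[, 2]
    status[two_tags] <- "ambiguous"
    same_tag <- n_hits == 2 & hit[, 1] == hit[, 2]
    assigned[same_tag] <- hit[same_tag, 1]
    status[same_tag] <- "matched"

    # Slow path: Hamming search for the rest.
    todo <- which(status == "unmatched")
    n_win <- trim_len - bc_len + 1
    for (i in todo) {
      if (has_anchor[i]) {
        windows <- cand[i, !is.na(cand[i, ])]
      } else {
        r <- trimmed[i]
        if (nchar(r) < bc_len) next
        starts <- seq_len(min(n_win, nchar(r) - bc_len + 1))
        windows <- substring(r, starts, starts + bc_len - 1)
      }
      dist_tag <- rep(bc_len + 1L, nrow(tags))
      for (w in windows) {
        dist_tag <- pmin(dist_tag, hamming_to_library(w, lib_mat))
      }
      d1 <- min(dist_tag)
      if (d1 > max_mismatch) next
      best <- which(dist_tag == d1)
      if (length(best) == 1) {
        assigned[i] <- best
        status[i] <- "matched"
      } else {
        status[i] <- "ambiguous"
      }
    }

    cnt <- tabulate(assigned[status == "matched"], nbins = nrow(tags))
    count_rows[[smp]] <- tibble(tag_id = tags$tag_id, sample_id = smp,
                                count = cnt)
    stat_rows[[smp]] <- tibble(sample_id = smp, total = n,
                               matched = sum(status == "matched"),
                               ambiguous = sum(status == "ambiguous"),
                               unmatched = sum(status == "unmatched"))
  }
  manifest <- manifest %||%
    tibble(sample_id = names(fastq), condition = names(fastq),
           replicate = 1L, role = "treatment")
  structure(list(counts = bind_rows(count_rows),
                 stats = bind_rows(stat_rows),
                 manifest = as_tibble(manifest)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", dplyr::n_distinct(x$counts$tag_id), " tags x ",
      nrow(x$stats), " samples; ",
      sum(x$stats$matched), "/", sum(x$stats$total),
      " reads matched\n", sep = "")
  invisible(x)
}

#' Filter low-coverage tags and sum to strain counts
#'
#' Keeps tags whose count is at least `min_control_count` in every control
#' replicate, then sums the surviving uptag and downtag of each strain.
#' Strains losing all tags are dropped and listed in
#' `attr(, "dropped_strains")`.
#'
#' @param cm a `count_matrix`.
#' @param min_control_count minimum count required in all control samples
#'   (default 50).
#' @return list with `counts` (tibble `strain_id`, `sample_id`, `count`),
#'   `kept_tags`, `manifest`, `stats`.
#' @export
filter_and_combine <- function(cm, min_control_count = 50) {
  stopifnot(inherits(cm, "count_matrix"))
  ctl <- cm$manifest$sample_id[cm$manifest$role == "control"]
  if (length(ctl) == 0) abort("no control samples in manifest")
  keep <- cm$counts |>
    filter(.data$sample_id %in% ctl) |>
    group_by(.data$tag_id) |>
    summarise(ok = all(.data$count >= min_control_count), .groups = "drop") |>
    filter(.data$ok) |>
    pull("tag_id")
  if (length(keep) == 0) abort("no tag passes the control-count filter")
  all_strains <- unique(tag_strain(cm$counts$tag_id))
  combined <- cm$counts |>
    filter(.data$tag_id %in% keep) |>
    mutate(strain_id = tag_strain(.data$tag_id)) |>
    group_by(.data$strain_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  dropped <- setdiff(all_strains, unique(combined$strain_id))
  if (length(dropped) > 0) {
    inform(sprintf("%d strain(s) dropped: no tag passed the control-count filter",
                   length(dropped)))
  }
  out <- list(counts = combined, kept_tags = keep, manifest = cm$manifest,
              stats = cm$stats)
  attr(out, "dropped_strains") <- dropped
  out
}

#' Median-of-ratios size factors
#'
#' Each sample's size factor is the median, over strains with full
#' coverage, of its counts divided by the per-strain geometric-mean
#' reference (the standard median-of-ratios estimator for count data).
#'
#' @param counts strain x sample count matrix (strains in rows).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  log_ref <- rowMeans(log(counts))
  usable <- is.finite(log_ref)
  if (!any(usable)) abort("no strain has nonzero counts in every sample: cannot estimate size factors")
  apply(counts, 2, function(col) {
    exp(median(log(col[usable]) - log_ref[usable]))
  })
}

#' Count-based fitness-defect scores
#'
#' Counts are normalized by median-of-ratios size factors; the FD of a
#' strain in a treatment sample is
#' `log2(median normalized control count + 0.5) - log2(normalized count +
#' 0.5)`, so positive FD means depletion, on the same scale as the array
#' arm. Medians and t-test/BH significance follow the array fitness
#' machinery.
#'
#' @param combined list from [filter_and_combine()].
#' @param pseudo pseudo-count added inside the log (default 0.5).
#' @return A `fitness_table` (with `p`/`q` from [test_significance()]);
#'   `attr(, "size_factors")` holds the per-sample factors.
#' @export
count_fitness <- function(combined, pseudo = 0.5) {
  man <- combined$manifest
  ctl <- man$sample_id[man$role == "control"]
  trt <- man$sample_id[man$role == "treatment"]
  if (length(ctl) == 0 || length(trt) == 0) {
    abort("need >= 1 control and >= 1 treatment sample")
  }
  wide <- combined$counts |>
    pivot_wider(names_from = "sample_id", values_from = "count",
                values_fill = 0)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$strain_id
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  ctl_med <- apply(norm[, ctl, drop = FALSE], 1, median)
  fd_rows <- purrr::map_dfr(trt, function(smp) {
    mrow <- man[man$sample_id == smp, ]
    tibble(strain_id = rownames(norm),
           collection = "barseq", media = "pool",
           condition = mrow$condition, replicate = mrow$replicate,
           array_id = smp, n_ctl = length(ctl),
           fd = log2(ctl_med + pseudo) - log2(norm[, smp] + pseudo))
  })
  stats <- fd_rows |>
    group_by(.data$strain_id, .data$collection, .data$condition) |>
    summarise(fd_median = median(.data$fd), n_reps = dplyr::n(),
              .groups = "drop")
  ft <- structure(list(fd = fd_rows, stats = stats, manifest = man),
                  class = "fitness_table")
  if (min(stats$n_reps) >= 2) {
    ft <- test_significance(ft)
  }
  attr(ft, "size_factors") <- sf
  ft
}
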