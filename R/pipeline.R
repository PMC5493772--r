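# Orchestration of the two analysis tracks (array and Bar-seq) from a
# single declarative config, with structured run logs and reproducible
# text outputs.

#' Build and validate a pipeline run configuration
#'
#' Collects file paths, stage parameters and toggles. Defaults mirror the
#' analysis thresholds used throughout the package: posterior 0.5, FD 1.0,
#' q 0.05, Bar-seq control count 50, trim length 50, term sizes 5-300.
#'
#' @param intensities,manifest,library,annotations input TSV paths
#'   (annotations optional).
#' @param fastq named character vector of FASTQ paths (Bar-seq track).
#' @param barseq_manifest optional Bar-seq sample manifest TSV.
#' @param outdir output directory.
#' @param posterior_threshold,fd_threshold,q_threshold,mad_k,min_keep,
#'   trim_len,max_mismatch,min_control_count,min_term_size,max_term_size
#'   stage parameters.
#' @param signature_group optional condition group for signature
#'   definition/subtraction.
#' @param seed integer seed recorded in the log (the array track is
#'   deterministic; the seed feeds any optional EM restarts).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(intensities = NULL, manifest = NULL, library = NULL,
                       fastq = NULL, barseq_manifest = NULL,
                       annotations = NULL, outdir = tempfile("ykofit_run_"),
                       posterior_threshold = 0.5, fd_threshold = 1.0,
                       q_threshold = 0.05, mad_k = 4, min_keep = 3,
                       trim_len = 50, max_mismatch = 2,
                       min_control_count = 50, min_term_size = 5,
                       max_term_size = 300, signature_group = NULL,
                       seed = 1) {
  for (p in c(intensities, manifest, library, fastq, barseq_manifest,
              annotations)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configured path does not exist: %s", p))
    }
  }
  stopifnot(posterior_threshold > 0, posterior_threshold < 1,
            q_threshold > 0, q_threshold < 1, trim_len >= 20,
            max_mismatch >= 0, min_control_count >= 0)
  structure(
    list(intensities = intensities, manifest = manifest, library = library,
         fastq = fastq, barseq_manifest = barseq_manifest,
         annotations = annotations, outdir = outdir,
         posterior_threshold = posterior_threshold,
         fd_threshold = fd_threshold, q_threshold = q_threshold,
         mad_k = mad_k, min_keep = min_keep, trim_len = trim_len,
         max_mismatch = max_mismatch,
         min_control_count = min_control_count,
         min_term_size = min_term_size, max_term_size = max_term_size,
         signature_group = signature_group, seed = as.integer(seed)),
    class = "run_config")
}

log_stage <- function(log, stage, ...) {
  c(log, list(c(list(stage = stage), list(...))))
}

write_run_log <- function(log, config, path) {
  jsonlite::write_json(
    list(package = "ykofit",
         version = as.character(utils::packageVersion("ykofit")),
         seed = config$seed,
         parameters = config[!vapply(config, is.null, logical(1))],
         stages = log),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
}

#' Run the array analysis track
#'
#' Executes mask/summarize, per-control-array mixture fitting, presence
#' calling, tag-class normalization, best-tag selection, batch
#' standardization, FD scoring and significance testing; optionally
#' shared-signature definition/subtraction and enrichment of FD hits.
#' Writes `presence.tsv`, `fd.tsv` (and `signature.tsv`,
#' `fd_corrected.tsv`, `enrichment.tsv` when applicable), an
#' `exclusions.tsv` accounting for every dropped strain, and a
#' machine-readable `run_log.json`. Outputs are reproducible byte for
#' byte for a fixed config.
#'
#' @param config a `run_config` with `intensities`, `manifest`, `library`
#'   set.
#' @return invisibly, a list with the presence calls, fitness table,
#'   signature results and written paths.
#' @export
run_array_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$intensities) || is.null(config$manifest) ||
      is.null(config$library)) {
    abort("array track needs intensities, manifest and library paths")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  loaded <- load_intensity_table(config$intensities, config$manifest)
  library <- read_tsv_file(config$library)
  log <- log_stage(log, "load", n_feature_rows = nrow(loaded$features),
                   n_arrays = nrow(loaded$manifest))

  tm <- summarize_to_tags(loaded$features, loaded$manifest,
                          mad_k = config$mad_k, min_keep = config$min_keep)
  log <- log_stage(log, "summarize", n_tags = dplyr::n_distinct(tm$values$tag_id),
                   n_masked_features = nrow(tm$mask_log))

  collections <- unique(tm$manifest$collection)
  calls <- list()
  for (cl in collections) {
    fits <- fit_control_mixtures(tm, collection = cl)
    tag_calls <- call_tag_presence(fits, threshold = config$posterior_threshold)
    calls[[cl]] <- call_strain_presence(tag_calls, library, collection = cl,
                                        threshold = config$posterior_threshold)
  }
  presence <- bind_rows(calls)
  paths <- list(presence = file.path(config$outdir, "presence.tsv"))
  write_tsv_file(mutate(presence, present = as.integer(.data$present)),
                 paths$presence)
  log <- log_stage(log, "presence",
                   n_present = sum(presence$present),
                   n_absent = sum(!presence$present))

  venn <- if (length(collections) >= 2) compare_rosters(calls) else NULL
  if (!is.null(venn)) {
    paths$venn <- file.path(config$outdir, "venn.tsv")
    write_tsv_file(venn$counts, paths$venn)
    log <- log_stage(log, "rosters", universe = length(venn$universe))
  }

  normalized <- normalize_by_tag_class_median(tm)
  exclusions <- list()
  ft_all <- list()
  for (cl in collections) {
    present_strains <- calls[[cl]]$strain_id[calls[[cl]]$present]
    absent <- setdiff(library$strain_id, present_strains)
    if (length(absent) > 0) {
      exclusions[[cl]] <- tibble(strain_id = absent, collection = cl,
                                 stage = "presence", reason = "absent")
    }
    sub_man <- filter(normalized$manifest, .data$collection == cl)
    sub <- new_tag_matrix(
      filter(normalized$values, .data$array_id %in% sub_man$array_id),
      sub_man, normalized$mask_log)
    collapsed <- select_best_tag(sub, strains = present_strains)
    corrected <- batch_correct(collapsed)
    ft <- compute_fd_scores(corrected) |> test_significance()
    ft_all[[cl]] <- ft
  }
  stats <- bind_rows(lapply(ft_all, function(f) f$stats))
  fd <- bind_rows(lapply(ft_all, function(f) f$fd))
  paths$fd <- file.path(config$outdir, "fd.tsv")
  write_tsv_file(stats, paths$fd)
  log <- log_stage(log, "fitness", n_scores = nrow(stats))

  signature <- NULL; corrected_fd <- NULL
  if (!is.null(config$signature_group)) {
    signature <- define_shared_signature(stats, config$signature_group,
                                         threshold = config$fd_threshold)
    paths$signature <- file.path(config$outdir, "signature.tsv")
    write_tsv_file(mutate(tidy(signature),
                          member = as.integer(.data$member)),
                   paths$signature)
    corrected_fd <- purrr::map_dfr(config$signature_group, function(cond) {
      subtract_signature(stats, signature, condition = cond)
    })
    paths$fd_corrected <- file.path(config$outdir, "fd_corrected.tsv")
    write_tsv_file(corrected_fd, paths$fd_corrected)
    log <- log_stage(log, "signature", n_members = length(signature$members))
  }

  enrichment <- NULL
  if (!is.null(config$annotations)) {
    ann <- read_tsv_file(config$annotations)
    universe <- unique(presence$strain_id[presence$present])
    hits <- stats |>
      filter(.data$fd_median >= config$fd_threshold,
             is.na(.data$q) | .data$q < config$q_threshold) |>
      pull("strain_id") |> unique()
    if (length(hits) > 0) {
      enrichment <- hypergeometric_enrichment(
        hits, universe, ann, min_size = config$min_term_size,
        max_size = config$max_term_size)
      paths$enrichment <- file.path(config$outdir, "enrichment.tsv")
      write_tsv_file(enrichment, paths$enrichment)
      log <- log_stage(log, "enrichment", n_terms = nrow(enrichment),
                       n_passed = sum(enrichment$passed))
    }
  }

  exclusions <- if (length(exclusions) > 0) bind_rows(exclusions) else
    tibble(strain_id = character(), collection = character(),
           stage = character(), reason = character())
  paths$exclusions <- file.path(config$outdir, "exclusions.tsv")
  write_tsv_file(exclusions, paths$exclusions)
  paths$run_log <- file.path(config$outdir, "run_log.json")
  write_run_log(log, config, paths$run_log)

  invisible(list(presence = presence, venn = venn, fitness = ft_all,
                 stats = stats, fd = fd, signature = signature,
                 corrected_fd = corrected_fd, enrichment = enrichment,
                 exclusions = exclusions, paths = paths))
}

#' Run the Bar-seq analysis track
#'
#' Executes trim/match, control-count filtering with tag combination, and
#' count-based FD scoring with significance. Writes `counts.tsv`,
#' `strain_counts.tsv`, `barseq_fd.tsv` and `run_log.json`.
#'
#' @param config a `run_config` with `fastq` and `library` set (and
#'   optionally `barseq_manifest`).
#' @return invisibly, a list with the count matrix, combined counts,
#'   fitness table and written paths.
#' @export
run_barseq_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$fastq) || is.null(config$library)) {
    abort("barseq track needs fastq and library paths")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  library <- read_tsv_file(config$library)
  manifest <- if (!is.null(config$barseq_manifest)) {
    read_tsv_file(config$barseq_manifest)
  } else NULL
  cm <- trim_and_match(config$fastq, library, manifest = manifest,
                       trim_len = config$trim_len,
                       max_mismatch = config$max_mismatch)
  log <- log_stage(log, "match", total = sum(cm$stats$total),
                   matched = sum(cm$stats$matched),
                   ambiguous = sum(cm$stats$ambiguous),
                   unmatched = sum(cm$stats$unmatched))
  paths <- list(counts = file.path(config$outdir, "counts.tsv"))
  write_tsv_file(cm$counts, paths$counts)

  combined <- filter_and_combine(cm, min_control_count = config$min_control_count)
  log <- log_stage(log, "filter_combine",
                   n_tags_kept = length(combined$kept_tags),
                   n_strains = dplyr::n_distinct(combined$counts$strain_id),
                   n_dropped = length(attr(combined, "dropped_strains")))
  paths$strain_counts <- file.path(config$outdir, "strain_counts.tsv")
  write_tsv_file(combined$counts, paths$strain_counts)

  ft <- count_fitness(combined)
  paths$fd <- file.path(config$outdir, "barseq_fd.tsv")
  write_tsv_file(ft$stats, paths$fd)
  log <- log_stage(log, "count_fitness", n_scores = nrow(ft$stats))
  paths$run_log <- file.path(config$outdir, "run_log.json")
  write_run_log(log, config, paths$run_log)
  invisible(list(count_matrix = cm, combined = combined, fitness = ft,
                 paths = paths))
}
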