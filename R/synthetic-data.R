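# Synthetic pooled-screen generator: planted truth, array intensities,
# and Bar-seq reads with the statistical structure the pipeline assumes.

# Primer context flanking the 20-base barcodes in Bar-seq reads.
.up_anchor <- "GATGTCCACGAGGTCTCT"
.up_suffix <- "GTCGACCTGCAGCGTACG"
.dn_anchor <- "GAAAACGAGCTCGAATTCATCG"
.dn_suffix <- "CGGTGTCGGTCTCGTAG"

#' Primer-context anchors used in Bar-seq reads
#'
#' The generator emits reads as `<anchor><20-base barcode><suffix>` and the
#' matcher scans for these anchors to locate the barcode. Uptag and downtag
#' amplicons carry different gene-side primer sequences.
#'
#' @return A named list with `uptag` and `downtag` anchor strings.
#' @export
barseq_anchors <- function() {
  list(uptag = .up_anchor, downtag = .dn_anchor)
}

#' Planted ground truth for a synthetic pooled screen
#'
#' Defines which strains are present in each collection, the per-generation
#' relative growth deficit `d` of every (strain, condition) pair, and an
#' optional shared-signature group planted across several conditions. A
#' planted fitness defect of `fd` log2 units after `generations` doublings
#' corresponds to `d = fd / generations` per generation.
#'
#' @param n_strains number of deletion strains in the pool.
#' @param collections character vector of collection labels.
#' @param dropout_fracs named numeric vector/list, fraction of strains absent
#'   per collection (in `[0, 1)`). Dropouts are deterministic: the first
#'   `floor(f * n)` strains of a seeded shuffle are removed, so roster counts
#'   are exact.
#' @param effect_spec named list, `condition -> list(n_hit =, fd =)`: plant
#'   `n_hit` strains with fitness defect `fd` (recycled over hits) in that
#'   condition.
#' @param shared_spec optional `list(conditions =, n_members =, fd =)`: plant
#'   a shared signature of `n_members` strains with defect `fd` in every
#'   condition of the group.
#' @param generations number of pool doublings (default 5).
#' @param extra_conditions conditions with no planted effects to register as
#'   valid treatment conditions.
#' @param seed integer seed; identical inputs and seed give an identical
#'   bundle.
#'
#' @return An object of class `truth_bundle`: a list with `strains`,
#'   `present_by_collection`, `fitness` (tibble `strain_id`, `condition`,
#'   `d`, `fd`), `signature_members`, `conditions`, `generations`, `seed`.
#' @export
#' @examples
#' truth <- generate_truth(50, effect_spec = list(ARGdrop = list(n_hit = 5, fd = 2)),
#'                         seed = 1)
#' length(truth$strains)
generate_truth <- function(n_strains,
                           collections = "YKO",
                           dropout_fracs = NULL,
                           effect_spec = list(),
                           shared_spec = NULL,
                           generations = 5,
                           extra_conditions = character(),
                           seed = 1) {
  stopifnot(n_strains >= 1, generations > 0)
  dropout_fracs <- as.list(dropout_fracs %||% list())
  for (f in dropout_fracs) {
    if (f < 0 || f >= 1) abort("dropout fractions must lie in [0, 1)")
  }
  strains <- sprintf("S%05d", seq_len(n_strains))

  set.seed(child_seed(seed, 1L))
  present_by_collection <- lapply(setNames(collections, collections), function(cl) {
    f <- dropout_fracs[[cl]] %||% 0
    shuffled <- sample(strains)
    n_out <- floor(f * n_strains)
    sort(setdiff(strains, shuffled[seq_len(n_out)]))
  })

  set.seed(child_seed(seed, 2L))
  signature_members <- character()
  fit_rows <- list()
  if (!is.null(shared_spec)) {
    stopifnot(all(c("conditions", "n_members", "fd") %in% names(shared_spec)))
    if (shared_spec$n_members > n_strains) abort("n_members exceeds n_strains")
    signature_members <- sort(sample(strains, shared_spec$n_members))
    for (cond in shared_spec$conditions) {
      fit_rows[[length(fit_rows) + 1L]] <- tibble(
        strain_id = signature_members, condition = cond,
        fd = rep_len(shared_spec$fd, length(signature_members)))
    }
  }
  # condition-specific hits are disjoint across conditions (and from the
  # shared signature) so "specific to condition X" is true by construction
  eligible <- setdiff(strains, signature_members)
  for (cond in names(effect_spec)) {
    sp <- effect_spec[[cond]]
    if (sp$n_hit > length(eligible)) {
      abort(sprintf("effect_spec[%s]: n_hit (%d) exceeds available strains (%d)",
                    cond, sp$n_hit, length(eligible)))
    }
    if (any(sp$fd < 0)) abort("planted FD sizes must be >= 0")
    if (sp$n_hit == 0) next
    hits <- sort(sample(eligible, sp$n_hit))
    eligible <- setdiff(eligible, hits)
    fit_rows[[length(fit_rows) + 1L]] <- tibble(
      strain_id = hits, condition = cond, fd = rep_len(sp$fd, length(hits)))
  }
  fitness <- if (length(fit_rows) > 0) {
    bind_rows(fit_rows) |>
      group_by(.data$strain_id, .data$condition) |>
      summarise(fd = max(.data$fd), .groups = "drop") |>
      mutate(d = .data$fd / generations) |>
      select("strain_id", "condition", "d", "fd")
  } else {
    tibble(strain_id = character(), condition = character(),
           d = numeric(), fd = numeric())
  }

  conditions <- sort(unique(c(names(effect_spec),
                              if (!is.null(shared_spec)) shared_spec$conditions,
                              extra_conditions)))
  structure(
    list(strains = strains,
         collections = collections,
         present_by_collection = present_by_collection,
         fitness = fitness,
         signature_members = signature_members,
         conditions = conditions,
         generations = generations,
         seed = as.integer(seed)),
    class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle> ", length(x$strains), " strains, ",
      length(x$collections), " collection(s), ",
      length(x$conditions), " condition(s), generations = ",
      x$generations, "\n", sep = "")
  invisible(x)
}

#' Intensity-model parameters for the array simulator
#'
#' Log2 intensities are drawn from a two-component Gaussian mixture: tags of
#' present strains from `N(mu_present, sigma_present)` and tags of absent
#' strains from `N(mu_absent, sigma_absent)`. Each tag is printed as
#' `n_replicate_features` replicate features; a fraction `artifact_rate` of
#' features is hit by an additive `artifact_shift` (spatial artifact), and
#' every feature carries `N(0, noise_sd)` measurement noise. Arrays of the
#' same batch share an additive `N(0, batch_shift_sd)` offset.
#'
#' @param mu_present,sigma_present log2 mean/sd of hybridized (present) tags.
#' @param mu_absent,sigma_absent log2 mean/sd of background (absent) tags.
#' @param n_replicate_features replicate features per tag per array.
#' @param artifact_rate fraction of features hit by artifacts, in `[0, 1]`.
#' @param artifact_shift log2 offset added to artifact features.
#' @param batch_shift_sd sd of the per-batch additive offset.
#' @param noise_sd per-feature log2 noise sd.
#' @return A list of class `array_sim_params`.
#' @export
array_sim_params <- function(mu_present = 10, sigma_present = 0.8,
                             mu_absent = 6.5, sigma_absent = 0.7,
                             n_replicate_features = 5,
                             artifact_rate = 0, artifact_shift = 4,
                             batch_shift_sd = 0, noise_sd = 0.3) {
  if (mu_present <= mu_absent) abort("mu_present must exceed mu_absent")
  if (sigma_present <= 0 || sigma_absent <= 0) abort("sigmas must be > 0")
  if (artifact_rate < 0 || artifact_rate > 1) abort("artifact_rate must be in [0, 1]")
  if (noise_sd < 0 || batch_shift_sd < 0) abort("noise sds must be >= 0")
  structure(list(mu_present = mu_present, sigma_present = sigma_present,
                 mu_absent = mu_absent, sigma_absent = sigma_absent,
                 n_replicate_features = as.integer(n_replicate_features),
                 artifact_rate = artifact_rate, artifact_shift = artifact_shift,
                 batch_shift_sd = batch_shift_sd, noise_sd = noise_sd),
            class = "array_sim_params")
}

#' Build an array manifest for a simulated screen
#'
#' One control set plus `n_replicates` treatment arrays per condition, all in
#' one collection x media set.
#'
#' @param collection collection label.
#' @param media control media label (e.g. "SC").
#' @param conditions treatment condition labels.
#' @param n_replicates treatment replicates per condition.
#' @param n_controls number of control arrays.
#' @param batches optional batch labels recycled over arrays (default one
#'   batch "b1").
#' @return A manifest tibble with the standard columns.
#' @export
array_design <- function(collection = "YKO", media = "SC",
                         conditions = character(), n_replicates = 3,
                         n_controls = 3, batches = "b1") {
  ctl <- tibble(
    array_id = sprintf("%s_%s_ctl_r%d", collection, media, seq_len(n_controls)),
    collection = collection, media = media, condition = media,
    replicate = seq_len(n_controls), role = "control")
  trt <- purrr::map_dfr(conditions, function(cond) {
    tibble(
      array_id = sprintf("%s_%s_r%d", collection, cond, seq_len(n_replicates)),
      collection = collection, media = media, condition = cond,
      replicate = seq_len(n_replicates), role = "treatment")
  })
  out <- bind_rows(ctl, trt)
  out$batch <- rep_len(batches, nrow(out))
  out[, .manifest_cols]
}

#' Simulate feature-level barcode-array intensities
#'
#' Draws one base log2 intensity per tag per collection x media set (present
#' tags from the present component, absent tags from the absent component),
#' applies the planted depletion `generations * d` to present strains on
#' treatment arrays, adds per-batch offsets, and expands each tag into
#' replicate features with noise and optional artifacts. The expected log2
#' intensity of a present strain's tag on a treatment array is therefore the
#' control mean minus `g * d`, before noise and batch terms.
#'
#' @param truth a `truth_bundle`.
#' @param params an `array_sim_params`.
#' @param design array manifest (see [array_design()]); every array's
#'   collection must exist in `truth`, every treatment condition must be
#'   registered in `truth$conditions`.
#' @param seed integer; defaults to a seed derived from `truth$seed`.
#' @return A list with `features` (tibble `tag_id`, `array_id`,
#'   `feature_1..n`), `tags` (a `tag_matrix` holding the noise-free tag-level
#'   generating values), and `manifest`.
#' @export
generate_array_screen <- function(truth, params = array_sim_params(),
                                  design, seed = NULL) {
  stopifnot(inherits(truth, "truth_bundle"), inherits(params, "array_sim_params"))
  design <- validate_manifest(design)
  bad_cl <- setdiff(unique(design$collection), truth$collections)
  if (length(bad_cl) > 0) {
    abort(sprintf("collection(s) not in truth: %s", paste(bad_cl, collapse = ", ")))
  }
  trt_conds <- unique(design$condition[design$role == "treatment"])
  bad_cond <- setdiff(trt_conds, truth$conditions)
  if (length(bad_cond) > 0) {
    abort(sprintf("condition(s) not in truth: %s", paste(bad_cond, collapse = ", ")))
  }
  seed <- seed %||% child_seed(truth$seed, 20L)
  set.seed(seed)

  batches <- unique(design$batch)
  batch_shift <- setNames(rnorm(length(batches), 0, params$batch_shift_sd), batches)

  g <- truth$generations
  d_tab <- truth$fitness
  sets <- distinct(design, .data$collection, .data$media)
  tag_rows <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    cl <- sets$collection[i]; md <- sets$media[i]
    arrays <- filter(design, .data$collection == cl, .data$media == md)
    present <- truth$present_by_collection[[cl]]
    tags <- tibble(strain_id = rep(truth$strains, each = 2),
                   tag_class = rep(c("uptag", "downtag"), length(truth$strains)))
    tags$tag_id <- tag_id(tags$strain_id, tags$tag_class)
    tags$present <- tags$strain_id %in% present
    tags$base <- if_else(
      tags$present,
      rnorm(nrow(tags), params$mu_present, params$sigma_present),
      rnorm(nrow(tags), params$mu_absent, params$sigma_absent))
    grid <- tidyr::crossing(tags, array_id = arrays$array_id) |>
      left_join(select(arrays, "array_id", "condition", "role", "batch"),
                by = "array_id") |>
      left_join(d_tab, by = c("strain_id", "condition"))
    grid$d <- if_else(is.na(grid$d), 0, grid$d)
    grid$value <- grid$base -
      if_else(grid$present & grid$role == "treatment", g * grid$d, 0) +
      unname(batch_shift[grid$batch])
    tag_rows[[i]] <- select(grid, "tag_id", "array_id", "value")
  }
  tag_values <- bind_rows(tag_rows)

  nf <- params$n_replicate_features
  n <- nrow(tag_values)
  feat <- matrix(rep(tag_values$value, nf), nrow = n) +
    matrix(rnorm(n * nf, 0, params$noise_sd), nrow = n)
  if (params$artifact_rate > 0) {
    hit <- matrix(runif(n * nf) < params$artifact_rate, nrow = n)
    feat <- feat + hit * params$artifact_shift
    artifact_idx <- which(hit, arr.ind = TRUE)
    artifacts <- tibble(tag_id = tag_values$tag_id[artifact_idx[, 1]],
                        array_id = tag_values$array_id[artifact_idx[, 1]],
                        feature = artifact_idx[, 2])
  } else {
    artifacts <- tibble(tag_id = character(), array_id = character(),
                        feature = integer())
  }
  colnames(feat) <- paste0("feature_", seq_len(nf))
  features <- bind_cols(select(tag_values, "tag_id", "array_id"),
                        as_tibble(feat))

  list(features = features,
       tags = new_tag_matrix(tag_values, design),
       artifacts = artifacts,
       manifest = design)
}

# Random unique barcodes of the given length.
random_barcodes <- function(n, len = 20) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Generate a strain barcode library
#'
#' Random unique 20-base uptag and downtag sequences for each strain.
#'
#' @param strains character vector of strain ids (or a `truth_bundle`).
#' @param seed integer seed.
#' @param tag_len barcode length (20).
#' @return A tibble `strain_id`, `uptag_seq`, `downtag_seq`.
#' @export
generate_tag_library <- function(strains, seed = 1, tag_len = 20) {
  if (inherits(strains, "truth_bundle")) strains <- strains$strains
  set.seed(child_seed(seed, 3L))
  tibble(strain_id = strains,
         uptag_seq = random_barcodes(length(strains), tag_len),
         downtag_seq = random_barcodes(length(strains), tag_len))
}

#' Build a Bar-seq sample manifest
#' @param conditions treatment condition labels.
#' @param n_replicates replicates per condition.
#' @param n_controls control samples.
#' @return tibble `sample_id`, `condition`, `replicate`, `role`.
#' @export
barseq_design <- function(conditions = character(), n_replicates = 3,
                          n_controls = 3) {
  ctl <- tibble(sample_id = sprintf("ctl_r%d", seq_len(n_controls)),
                condition = "control", replicate = seq_len(n_controls),
                role = "control")
  trt <- purrr::map_dfr(conditions, function(cond) {
    tibble(sample_id = sprintf("%s_r%d", cond, seq_len(n_replicates)),
           condition = cond, replicate = seq_len(n_replicates),
           role = "treatment")
  })
  bind_rows(ctl, trt)
}

# Introduce per-base substitution errors; returns the mutated reads and the
# number of errors landing inside [bc_start, bc_end] of each read.
add_read_errors <- function(reads, error_rate, bc_start, bc_end) {
  n_bc_err <- integer(length(reads))
  if (error_rate <= 0) return(list(reads = reads, bc_errors = n_bc_err))
  len <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), len, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(len, n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
    n_bc_err[i] <- sum(pos >= bc_start[i] & pos <= bc_end[i])
  }
  list(reads = reads, bc_errors = n_bc_err)
}

#' Simulate Bar-seq reads for a pooled screen
#'
#' Per sample, strain abundances after `generations` doublings are
#' proportional to `2^(-g * d)` for present strains (equal at the start of
#' the competition); tag counts are a single multinomial draw of `depth`
#' reads over uptags and downtags (each tag carries half a strain's
#' abundance). Reads are `<primer context><20-base barcode><suffix>` padded
#' to `read_len`, with independent per-base substitution errors. The exact
#' multinomial draw is returned so matcher recovery is checkable
#' read-for-read.
#'
#' @param truth a `truth_bundle`.
#' @param library tag library tibble (`strain_id`, `uptag_seq`,
#'   `downtag_seq`); barcodes must be unique within the uptag and within the
#'   downtag sets.
#' @param design sample manifest from [barseq_design()].
#' @param outdir directory for FASTQ files (created if needed).
#' @param collection which collection's roster to use (default first).
#' @param depth reads per sample.
#' @param error_rate per-base substitution probability.
#' @param read_len read length (reads are trimmed to 50 downstream).
#' @param gzip write gzipped FASTQ.
#' @param seed integer; defaults to a seed derived from `truth$seed`.
#' @return list with `fastq` (named file paths), `expected_counts` (tibble
#'   `tag_id`, `sample_id`, `count`: the multinomial draw), `read_info`
#'   (per-read tag and barcode-error count), and `manifest`.
#' @export
generate_barseq_reads <- function(truth, library, design, outdir,
                                  collection = NULL, depth = 10000,
                                  error_rate = 0.01, read_len = 60,
                                  gzip = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "truth_bundle"))
  check_columns(library, c("strain_id", "uptag_seq", "downtag_seq"), "library")
  if (anyDuplicated(library$uptag_seq) || anyDuplicated(library$downtag_seq)) {
    abort("duplicate barcode sequences in library")
  }
  collection <- collection %||% truth$collections[1]
  present <- truth$present_by_collection[[collection]]
  if (is.null(present)) abort(sprintf("collection %s not in truth", collection))
  bad_cond <- setdiff(unique(design$condition[design$role == "treatment"]),
                      truth$conditions)
  if (length(bad_cond) > 0) {
    abort(sprintf("condition(s) not in truth: %s", paste(bad_cond, collapse = ", ")))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% child_seed(truth$seed, 30L)
  set.seed(seed)

  lib <- filter(library, .data$strain_id %in% present)
  g <- truth$generations
  tags <- tibble(
    strain_id = rep(lib$strain_id, 2),
    tag_id = c(tag_id(lib$strain_id, "uptag"), tag_id(lib$strain_id, "downtag")),
    barcode = c(lib$uptag_seq, lib$downtag_seq),
    tag_class = rep(c("uptag", "downtag"), each = nrow(lib)))

  pad_to <- function(x, anchor, suffix) {
    body <- paste0(anchor, x, suffix)
    filler <- paste(rep("A", read_len), collapse = "")
    substr(paste0(body, filler), 1, read_len)
  }
  tags$template <- if_else(
    tags$tag_class == "uptag",
    pad_to(tags$barcode, .up_anchor, .up_suffix),
    pad_to(tags$barcode, .dn_anchor, .dn_suffix))
  tags$bc_start <- if_else(tags$tag_class == "uptag",
                           nchar(.up_anchor) + 1L, nchar(.dn_anchor) + 1L)

  fastq <- character(0)
  counts_rows <- list()
  info_rows <- list()
  for (si in seq_len(nrow(design))) {
    smp <- design$sample_id[si]
    cond <- design$condition[si]
    d <- left_join(tags["strain_id"],
                   filter(truth$fitness, .data$condition == cond),
                   by = "strain_id")$d
    d[is.na(d)] <- 0
    if (design$role[si] == "control") d[] <- 0
    ab <- 2^(-g * d) / 2        # half a strain's abundance per tag
    prob <- ab / sum(ab)
    cnt <- as.integer(rmultinom(1, depth, prob))
    counts_rows[[si]] <- tibble(tag_id = tags$tag_id, sample_id = smp,
                                count = cnt)
    reads <- rep(tags$template, cnt)
    bc_start <- rep(tags$bc_start, cnt)
    tag_of_read <- rep(tags$tag_id, cnt)
    ord <- sample.int(length(reads))
    reads <- reads[ord]; bc_start <- bc_start[ord]; tag_of_read <- tag_of_read[ord]
    err <- add_read_errors(reads, error_rate, bc_start, bc_start + 19L)
    info_rows[[si]] <- tibble(sample_id = smp, read = seq_along(reads),
                              tag_id = tag_of_read,
                              barcode_errors = err$bc_errors)
    path <- file.path(outdir, paste0(smp, if (gzip) ".fastq.gz" else ".fastq"))
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    qual <- strrep("I", read_len)
    writeLines(as.vector(rbind(sprintf("@%s_%06d", smp, seq_along(reads)),
                               err$reads, "+", qual)), con)
    close(con)
    fastq[smp] <- path
  }
  list(fastq = fastq,
       expected_counts = bind_rows(counts_rows),
       read_info = bind_rows(info_rows),
       manifest = design)
}

#' Write a complete small fixture bundle to disk
#'
#' Generates a self-consistent screen (truth, library, array intensities with
#' manifest, Bar-seq reads) and writes it as plain-text files that round-trip
#' through the package readers: `intensities.tsv`, `manifest.tsv`,
#' `library.tsv`, `truth.tsv` and one FASTQ per Bar-seq sample.
#'
#' @param outdir output directory (created).
#' @param n_strains pool size.
#' @param seed integer seed; the same seed reproduces identical files.
#' @param depth Bar-seq reads per sample.
#' @param error_rate Bar-seq per-base error rate.
#' @return Invisibly, a list with `paths` (named TSV paths), `fastq`
#'   (named FASTQ paths) and the in-memory `truth`, `library`, `screen`
#'   and `reads` objects.
#' @export
write_fixture_bundle <- function(outdir, n_strains = 120, seed = 42,
                                 depth = 4000, error_rate = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create directory %s", outdir))
  truth <- generate_truth(
    n_strains, collections = "YKO", dropout_fracs = list(YKO = 0.1),
    effect_spec = list(cond_a = list(n_hit = 10, fd = 2)),
    seed = seed)
  library <- generate_tag_library(truth, seed = seed)
  design <- array_design("YKO", "SC", conditions = "cond_a")
  screen <- generate_array_screen(truth, array_sim_params(), design)
  reads <- generate_barseq_reads(
    truth, library, barseq_design("cond_a"), outdir,
    depth = depth, error_rate = error_rate)

  paths <- list(
    intensities = file.path(outdir, "intensities.tsv"),
    manifest = file.path(outdir, "manifest.tsv"),
    library = file.path(outdir, "library.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  write_tsv_file(screen$features, paths$intensities)
  write_tsv_file(design, paths$manifest)
  write_tsv_file(library, paths$library)
  write_truth_table(truth, paths$truth)
  invisible(list(paths = paths, fastq = reads$fastq, truth = truth,
                 library = library, screen = screen, reads = reads))
}

#' Serialize / read back a truth bundle as tidy TSV
#'
#' @param truth a `truth_bundle`.
#' @param path TSV path.
#' @return `write_truth_table` returns the path invisibly;
#'   `read_truth_table` returns a `truth_bundle`.
#' @export
write_truth_table <- function(truth, path) {
  pres <- purrr::imap_dfr(truth$present_by_collection, function(p, cl) {
    tibble(record = "presence", strain_id = truth$strains, collection = cl,
           condition = NA_character_,
           value = as.numeric(truth$strains %in% p))
  })
  fit <- mutate(truth$fitness, record = "fitness", collection = NA_character_) |>
    select("record", "strain_id", "collection", "condition", value = "d")
  sig <- tibble(record = "signature", strain_id = truth$signature_members,
                collection = NA_character_, condition = NA_character_, value = 1)
  cond <- tibble(record = "condition", strain_id = NA_character_,
                 collection = NA_character_, condition = truth$conditions,
                 value = 1)
  meta <- tibble(record = "meta", strain_id = NA_character_,
                 collection = NA_character_,
                 condition = c("generations", "seed"),
                 value = c(truth$generations, truth$seed))
  write_tsv_file(bind_rows(pres, fit, sig, cond, meta), path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read_tsv_file(path, readr::cols(
    record = readr::col_character(), strain_id = readr::col_character(),
    collection = readr::col_character(), condition = readr::col_character(),
    value = readr::col_double()))
  meta <- filter(df, .data$record == "meta")
  generations <- meta$value[meta$condition == "generations"]
  seed <- as.integer(meta$value[meta$condition == "seed"])
  pres <- filter(df, .data$record == "presence")
  strains <- sort(unique(pres$strain_id))
  collections <- unique(pres$collection)
  present_by_collection <- lapply(setNames(collections, collections), function(cl) {
    sort(pres$strain_id[pres$collection == cl & pres$value == 1])
  })
  fitness <- filter(df, .data$record == "fitness") |>
    select("strain_id", "condition", d = "value") |>
    mutate(fd = .data$d * generations)
  structure(
    list(strains = strains, collections = collections,
         present_by_collection = present_by_collection,
         fitness = fitness,
         signature_members = sort(df$strain_id[df$record == "signature"]),
         conditions = sort(df$condition[df$record == "condition"]),
         generations = generations, seed = seed),
    class = "truth_bundle")
}
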