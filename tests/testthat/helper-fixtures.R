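# Shared small fixtures, built in code at test time.

# A small planted screen: one collection, one treatment condition.
small_screen <- function(n_strains = 200, n_hit = 15, fd = 2,
                         noise_sd = 0.3, dropout = 0, seed = 7,
                         conditions = "trt") {
  truth <- generate_truth(
    n_strains, collections = "YKO",
    dropout_fracs = list(YKO = dropout),
    effect_spec = setNames(
      lapply(conditions, function(x) list(n_hit = n_hit, fd = fd)),
      conditions),
    seed = seed)
  design <- array_design("YKO", "SC", conditions = conditions)
  screen <- generate_array_screen(
    truth, array_sim_params(noise_sd = noise_sd), design)
  list(truth = truth, design = design, screen = screen,
       library = generate_tag_library(truth, seed = seed))
}

# Run presence -> FD on a screen, quietly (no-separation messages are
# expected on fixtures without dropout). normalize = FALSE bypasses the
# tag-class median normalization for exactness checks (median
# normalization itself shifts arrays when a planted fraction is large).
quiet_fd <- function(sc, var_pool = "condition", normalize = TRUE) {
  tm <- summarize_to_tags(sc$screen$features, sc$screen$manifest)
  pc <- suppressWarnings(suppressMessages({
    fits <- fit_control_mixtures(tm)
    call_strain_presence(call_tag_presence(fits), sc$library)
  }))
  nm <- if (normalize) normalize_by_tag_class_median(tm) else tm
  ft <- nm |>
    select_best_tag(strains = pc$strain_id[pc$present]) |>
    batch_correct() |>
    compute_fd_scores() |>
    test_significance(var_pool = var_pool)
  list(tm = tm, presence = pc, ft = ft)
}

# Hand-built tag matrix from a wide strain x array table of tag values.
toy_tag_matrix <- function(values_long, manifest) {
  new_tag_matrix(values_long, manifest)
}

# Minimal count_matrix for filter/combine tests.
toy_count_matrix <- function(counts, manifest) {
  structure(list(
    counts = counts,
    stats = counts |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(total = sum(count), matched = sum(count),
                       ambiguous = 0L, unmatched = 0L, .groups = "drop"),
    manifest = manifest), class = "count_matrix")
}

# Write a FASTQ file from bare read strings.
write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(
    sprintf("@r%04d", seq_along(reads)), reads, "+",
    vapply(reads, function(r) strrep("I", nchar(r)), character(1)))), path)
  path
}

# Mutate specific positions of a sequence.
mutate_bases <- function(seq, pos, to) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- to[i]
  seq
}
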