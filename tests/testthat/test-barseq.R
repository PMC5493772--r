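test_that("error-free reads are recovered read-for-read", {
  truth <- generate_truth(60, effect_spec = list(trt = list(n_hit = 8, fd = 2)),
                          seed = 61)
  lib <- generate_tag_library(truth, seed = 61)
  des <- barseq_design("trt", n_replicates = 2, n_controls = 2)
  dir <- withr::local_tempdir()
  rd <- generate_barseq_reads(truth, lib, des, dir, depth = 2000,
                              error_rate = 0)
  cm <- trim_and_match(rd$fastq, lib, manifest = des)
  j <- dplyr::inner_join(cm$counts, rd$expected_counts,
                         by = c("tag_id", "sample_id"))
  expect_true(all(j$count.x == j$count.y))
  # conservation: matched + ambiguous + unmatched = total
  expect_true(all(cm$stats$matched + cm$stats$ambiguous +
                    cm$stats$unmatched == cm$stats$total))
  expect_true(all(cm$stats$unmatched == 0))
})

test_that("gzipped FASTQ input gives identical counts", {
  truth <- generate_truth(10, seed = 62)
  lib <- generate_tag_library(truth, seed = 62)
  des <- barseq_design(character(), n_controls = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  plain <- generate_barseq_reads(truth, lib, des, d1, depth = 300,
                                 error_rate = 0, gzip = FALSE)
  gz <- generate_barseq_reads(truth, lib, des, d2, depth = 300,
                              error_rate = 0, gzip = TRUE)
  c1 <- trim_and_match(plain$fastq, lib, manifest = des)
  c2 <- trim_and_match(gz$fastq, lib, manifest = des)
  expect_equal(c1$counts, c2$counts)
})

test_that("the unique-best-hit rule counts 2-error reads and rejects ties", {
  anchors <- barseq_anchors()
  lib <- tibble::tibble(
    strain_id = c("sA", "sB"),
    uptag_seq = c(strrep("A", 20), paste0(strrep("A", 18), "CC")),
    downtag_seq = c(strrep("G", 20), strrep("T", 20)))
  dir <- withr::local_tempdir()

  # two errors in sA's uptag at non-discriminating positions: distance 2
  # to sA, 4 to sB -> unique best, counted
  bc2 <- mutate_bases(strrep("A", 20), c(3, 7), c("T", "G"))
  # one error at a discriminating position: distance 1 to both -> tie
  bc_tie <- mutate_bases(strrep("A", 20), 19, "C")
  # hopeless read
  junk <- paste0(strrep("C", 10), strrep("T", 10))
  reads <- paste0(anchors$uptag, c(bc2, bc_tie, junk), strrep("A", 12))
  fq <- write_fastq(reads, file.path(dir, "s1.fastq"))
  cm <- trim_and_match(c(s1 = fq), lib,
                       manifest = tibble::tibble(sample_id = "s1",
                                                 condition = "c",
                                                 replicate = 1,
                                                 role = "control"))
  expect_equal(cm$stats$matched, 1)
  expect_equal(cm$stats$ambiguous, 1)
  expect_equal(cm$stats$unmatched, 1)
  expect_equal(cm$counts$count[cm$counts$tag_id == "sA|up"], 1)
})

test_that("reads with a damaged anchor are still matched by window scan", {
  anchors <- barseq_anchors()
  lib <- tibble::tibble(strain_id = "sA",
                        uptag_seq = strrep("A", 20),
                        downtag_seq = strrep("G", 20))
  broken_anchor <- mutate_bases(anchors$uptag, c(2, 9), c("T", "T"))
  reads <- paste0(broken_anchor, strrep("A", 20), strrep("C", 12))
  dir <- withr::local_tempdir()
  fq <- write_fastq(reads, file.path(dir, "s1.fastq"))
  cm <- trim_and_match(c(s1 = fq), lib,
                       manifest = tibble::tibble(sample_id = "s1",
                                                 condition = "c",
                                                 replicate = 1,
                                                 role = "control"))
  expect_equal(cm$stats$matched, 1)
  expect_equal(cm$counts$count[cm$counts$tag_id == "sA|up"], 1)
})

test_that("most reads with <= 2 barcode errors are counted at 1% error rate", {
  truth <- generate_truth(100, seed = 63)
  lib <- generate_tag_library(truth, seed = 63)
  des <- barseq_design(character(), n_controls = 2)
  dir <- withr::local_tempdir()
  rd <- generate_barseq_reads(truth, lib, des, dir, depth = 2500,
                              error_rate = 0.01)
  cm <- trim_and_match(rd$fastq, lib, manifest = des)
  recoverable <- rd$read_info |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(n = sum(barcode_errors <= 2))
  st <- dplyr::inner_join(cm$stats, recoverable, by = "sample_id")
  expect_true(all(st$matched / st$n >= 0.99))
})

test_that("the control-count filter and tag combination follow the >= rule", {
  man <- tibble::tibble(sample_id = c("c1", "c2", "c3", "t1"),
                        condition = c("ctl", "ctl", "ctl", "trt"),
                        replicate = c(1:3, 1),
                        role = c(rep("control", 3), "treatment"))
  counts <- tibble::tibble(
    tag_id = rep(c("s1|up", "s1|dn", "s2|up", "s2|dn"), each = 4),
    sample_id = rep(man$sample_id, 4),
    count = c(100, 100, 100, 80,    # s1|up passes
              60, 60, 60, 40,       # s1|dn passes
              50, 50, 49, 10,       # s2|up fails (49 < 50)
              30, 30, 30, 5))       # s2|dn fails
  cm <- toy_count_matrix(counts, man)
  res <- suppressMessages(filter_and_combine(cm, min_control_count = 50))
  expect_setequal(res$kept_tags, c("s1|up", "s1|dn"))
  expect_equal(attr(res, "dropped_strains"), "s2")
  # uptag 100 + downtag 60 -> 160 in controls
  expect_equal(res$counts$count[res$counts$sample_id == "c1"], 160)
  expect_equal(res$counts$count[res$counts$sample_id == "t1"], 120)

  # min 0 keeps everything
  res0 <- filter_and_combine(cm, min_control_count = 0)
  expect_length(res0$kept_tags, 4)
  expect_error(filter_and_combine(cm, min_control_count = 1000),
               "no tag passes")
})

test_that("count-based FDs are zero for equal libraries and depth-invariant", {
  man <- tibble::tibble(sample_id = c("c1", "c2", "c3", "t1"),
                        condition = c("ctl", "ctl", "ctl", "trt"),
                        replicate = c(1:3, 1),
                        role = c(rep("control", 3), "treatment"))
  base <- tibble::tibble(strain_id = rep(sprintf("s%d", 1:10), each = 4),
                         sample_id = rep(man$sample_id, 10),
                         count = rep(c(100, 100, 100, 100), 10) +
                           rep(seq(0, 90, by = 10), each = 4))
  comb <- list(counts = base, manifest = man)
  ft <- count_fitness(comb)
  expect_true(all(abs(ft$stats$fd_median) < 1e-12))

  # doubled treatment depth, equal composition -> size factors absorb it
  dbl <- dplyr::mutate(base, count = count * ifelse(sample_id == "t1", 2, 1))
  ft2 <- count_fitness(list(counts = dbl, manifest = man))
  expect_true(all(abs(ft2$stats$fd_median) < 1e-12))

  # global scaling leaves FDs unchanged
  tripled <- dplyr::mutate(base, count = count * 3)
  ft3 <- count_fitness(list(counts = tripled, manifest = man))
  expect_equal(ft3$stats$fd_median, ft$stats$fd_median, tolerance = 0.01)

  # planted 4-fold depletion on exact counts -> FD = 2
  depl <- dplyr::mutate(base, count = ifelse(
    strain_id == "s1" & sample_id == "t1", count / 4, count))
  ft4 <- count_fitness(list(counts = depl, manifest = man))
  fd_s1 <- ft4$stats$fd_median[ft4$stats$strain_id == "s1"]
  expect_equal(fd_s1, 2, tolerance = 0.05)
})

test_that("size factors match the DESeq2 estimator", {
  set.seed(64)
  mat <- matrix(rpois(300, lambda = rep(c(50, 200, 120), each = 100)),
                nrow = 100)
  rownames(mat) <- sprintf("s%03d", 1:100)
  colnames(mat) <- c("a", "b", "c")
  mine <- size_factors(mat)
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})
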