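write_fastq <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("r%03d", seq_along(seqs))
  qual <- Biostrings::BStringSet(strrep("F", nchar(seqs)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  path
}

test_that("exactly composed reads yield their spacer", {
  sp <- paste0("G", strrep("ACTG", 4), "TAC")
  expect_equal(nchar(sp), 20L)
  fq <- write_fastq(paste0(screen_adapter5(), sp, screen_scaffold3()),
                    withr::local_tempfile(fileext = ".fastq"))
  tr <- trim_reads(fq)
  expect_equal(tr$spacers, sp)
  expect_equal(sum(tr$discarded), 0L)
})

test_that("the cloning G is stripped from 21-nt variable regions", {
  sp <- paste0("A", strrep("CT", 8), "GAC")
  fq <- write_fastq(paste0(screen_adapter5(), "G", sp, screen_scaffold3()),
                    withr::local_tempfile(fileext = ".fastq"))
  expect_equal(trim_reads(fq)$spacers, sp)
})

test_that("reads missing an anchor are discarded with the right reason", {
  sp <- strrep("AC", 10)
  seqs <- c(paste0(screen_adapter5(), sp, strrep("T", 21)),   # no scaffold
            paste0(strrep("T", 21), sp, screen_scaffold3()))  # no adapter
  fq <- write_fastq(seqs, withr::local_tempfile(fileext = ".fastq"))
  tr <- trim_reads(fq)
  expect_length(tr$spacers, 0)
  expect_equal(unname(tr$discarded["no_scaffold"]), 1L)
  expect_equal(unname(tr$discarded["no_adapter"]), 1L)
})

test_that("a known 90/10 valid/corrupt mixture recovers the truth table", {
  lib <- sim_guide_library(8, seed = 23)
  cfg <- sim_config(seed = 23, n_genes = 8, n_hit_genes = 0,
                    sequencing_depth = 100)
  sc <- sim_screen_counts(lib, cfg, n_input = 2, n_sorted = 2, spike = FALSE)
  d <- withr::local_tempdir()
  fq <- sim_screen_fastq(lib, sc$counts, samples = "input_01", outdir = d,
                         corrupt_frac = 0.1, seed = 4)
  n_corrupt <- unname(attr(fq, "corrupted")["input_01"])
  tr <- trim_reads(fq[["input_01"]])
  total <- sum(sc$counts$counts[guide_ids(lib), "input_01"])
  expect_equal(tr$n_reads, total)
  expect_length(tr$spacers, total - n_corrupt)
  expect_equal(sum(tr$discarded), n_corrupt)
  # conservation: reads in = retained + discarded
  expect_equal(length(tr$spacers) + sum(tr$discarded), tr$n_reads)
})

test_that("counting matches a known multinomial draw exactly", {
  lib <- sim_guide_library(10, seed = 2)  # 50-plus-controls dictionary
  set.seed(9)
  ids <- guide_ids(lib)
  spac <- c(lib$guides$spacer, lib$controls$spacer)
  draw <- sample(seq_along(spac), 1000, replace = TRUE)
  res <- count_guides(spac[draw], lib)
  expect_equal(unname(res$counts[ids]),
               unname(as.integer(table(factor(ids[draw], levels = ids)))))
  expect_equal(res$unassigned, 0L)
  expect_equal(sum(res$counts) + res$unassigned, 1000L)

  # counting is order-invariant
  res2 <- count_guides(spac[rev(draw)], lib)
  expect_equal(res2$counts, res$counts)

  # empty input and unassignable spacers
  res0 <- count_guides(character(0), lib)
  expect_true(all(res0$counts == 0L))
  expect_equal(res0$unassigned, 0L)
  res1 <- count_guides(strrep("N", 20), lib)
  expect_equal(res1$unassigned, 1L)
})

test_that("QC passes clean samples and fails planted defects", {
  lib <- sim_guide_library(60, seed = 14)
  cfg <- sim_config(seed = 14, n_genes = 60, n_hit_genes = 6,
                    sequencing_depth = 3e5)
  sc <- sim_screen_counts(lib, cfg, n_input = 4, n_sorted = 4)
  spike_guides <- grep("^spikeG4_6\\|", rownames(sc$counts$counts),
                       value = TRUE)
  qc <- sample_qc(sc$counts, positive_guides = spike_guides)
  expect_true(all(qc$pass))
  expect_true(all(qc$control_enrichment[qc$role == "sorted"] >= 1))

  # replace a sorted sample by a permutation of an input sample:
  # correlation structure breaks
  bad <- sc$counts$counts
  set.seed(1)
  bad[, "yfp_01"] <- sample(bad[, "input_01"])
  tab_bad <- guide_count_table(bad, sc$counts$sample_roles)
  qc_bad <- sample_qc(tab_bad, positive_guides = spike_guides)
  expect_false(qc_bad$pass[qc_bad$sample == "yfp_01"])
  expect_match(qc_bad$reasons[qc_bad$sample == "yfp_01"], "clustering")

  # a dead sample fails coverage
  dead <- sc$counts$counts
  dead[, "input_02"] <- 0
  tab_dead <- guide_count_table(dead, sc$counts$sample_roles)
  qc_dead <- suppressWarnings(sample_qc(tab_dead,
                                        positive_guides = spike_guides))
  expect_false(qc_dead$pass[qc_dead$sample == "input_02"])
  expect_match(qc_dead$reasons[qc_dead$sample == "input_02"], "coverage")
})

test_that("FASTQ deconvolution reproduces the simulated count column", {
  lib <- sim_guide_library(12, seed = 6)
  cfg <- sim_config(seed = 6, n_genes = 12, n_hit_genes = 2,
                    sequencing_depth = 2000)
  sc <- sim_screen_counts(lib, cfg, n_input = 2, n_sorted = 2, spike = FALSE)
  d <- withr::local_tempdir()
  fq <- sim_screen_fastq(lib, sc$counts,
                         samples = c("input_01", "yfp_01"), outdir = d,
                         corrupt_frac = 0)
  tab <- deconvolve_fastq(fq, lib,
                          sc$counts$sample_roles[c("input_01", "yfp_01")])
  expect_equal(unname(tab$counts[, "input_01"]),
               unname(sc$counts$counts[rownames(tab$counts), "input_01"]))
  expect_equal(unname(tab$counts[, "yfp_01"]),
               unname(sc$counts$counts[rownames(tab$counts), "yfp_01"]))
  expect_true(all(tab$unassigned == 0L))
})
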