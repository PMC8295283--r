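toy_samples <- function(n_reps = 2L, mark = "chip") {
  data.frame(
    sample = c(sprintf("%s_P1_rep%d", mark, seq_len(n_reps)),
               sprintf("%s_P28_rep%d", mark, seq_len(n_reps)),
               "input_P1", "input_P28"),
    stage = rep(c("P1", "P28", "P1", "P28"), c(n_reps, n_reps, 1L, 1L)),
    replicate = c(seq_len(n_reps), seq_len(n_reps), 1L, 1L),
    is_input = rep(c(FALSE, TRUE), c(2L * n_reps, 2L)),
    stringsAsFactors = FALSE)
}

test_that("ChIP identical to input gives zero signal and no occupancy", {
  set.seed(1)
  base <- rpois(50, 200) + 1L
  m <- cbind(base, base, base, base, base, base)
  rownames(m) <- sprintf("g%02d", 1:50)
  colnames(m) <- toy_samples()$sample
  len <- stats::setNames(rep(1000L, 50), rownames(m))
  sig <- h2bub_gene_signal(m, toy_samples(), len)
  expect_equal(sig$signal_P1, rep(0, 50), tolerance = 1e-12)
  expect_false(any(sig$occupied_P1))
  expect_false(any(sig$occupied_P28))
})

test_that("planted enrichment dominates unenriched genes", {
  set.seed(2)
  base <- rpois(60, 300) + 1L
  chip <- cbind(base, base, base, base)
  input <- cbind(base, base)
  chip[7, ] <- chip[7, ] * 3L          # 3x enriched gene
  m <- cbind(chip, input)
  rownames(m) <- sprintf("g%02d", 1:60)
  colnames(m) <- toy_samples()$sample
  len <- stats::setNames(rep(2000L, 60), rownames(m))
  sig <- h2bub_gene_signal(m, toy_samples(), len)
  expect_true(sig$occupied_P1[7])
  expect_gt(min(sig$signal_P1[7], sig$signal_P28[7]),
            max(sig$signal_P1[-7]))
})

test_that("equal per-base coverage gives equal signal regardless of length", {
  # genes A/B/C share per-base enrichment at lengths L, 2L, 4L; a block
  # of unenriched background genes pins the size factors
  bg <- matrix(80, 11, 6, dimnames = list(sprintf("bg%02d", 1:11), NULL))
  m <- rbind(matrix(c(100, 100, 100, 100, 25, 25,
                      200, 200, 200, 200, 50, 50,
                      400, 400, 400, 400, 100, 100), 3, byrow = TRUE,
                    dimnames = list(c("gA", "gB", "gC"), NULL)), bg)
  colnames(m) <- toy_samples()$sample
  len <- stats::setNames(c(1000L, 2000L, 4000L, rep(1000L, 11)),
                         rownames(m))
  sig <- h2bub_gene_signal(m, toy_samples(), len)
  expect_gt(sig$signal_P1[1], 0)
  expect_equal(sig$signal_P1[1], sig$signal_P1[2], tolerance = 1e-12)
  expect_equal(sig$signal_P1[2], sig$signal_P1[3], tolerance = 1e-12)
})

test_that("signals are invariant to library scaling and replicate order", {
  set.seed(4)
  m <- matrix(rpois(40 * 6, 150) + 1L, 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), toy_samples()$sample))
  len <- stats::setNames(sample(500:5000, 40), rownames(m))
  sig1 <- h2bub_gene_signal(m, toy_samples(), len)
  m2 <- m
  m2[, 1] <- m2[, 1] * 7L              # scale one library
  sig2 <- h2bub_gene_signal(m2, toy_samples(), len)
  # relative normalization pins signals up to one common library-scale
  # constant; ratios, signs and occupancy are unchanged
  k <- sig2$signal_P1 / sig1$signal_P1
  expect_equal(k, rep(k[1], length(k)), tolerance = 1e-10)
  expect_gt(k[1], 0)
  expect_equal(sig2$occupied_P1, sig1$occupied_P1)
  # swap replicate columns
  m3 <- m[, c(2, 1, 4, 3, 5, 6)]
  colnames(m3) <- colnames(m)[c(2, 1, 4, 3, 5, 6)]
  sig3 <- h2bub_gene_signal(m3, toy_samples(), len)
  expect_equal(sig3$signal_P28, sig1$signal_P28, tolerance = 1e-12)
})

test_that("best TSS is kept and the RPKM floor gates retention", {
  samples <- toy_samples(mark = "k4")
  lib <- stats::setNames(rep(2e7, 6), samples$sample)
  # RPKM = cov * 1e9 / 2e7 = 50 * cov: covs 16 and 6 -> 800 and 300
  m <- matrix(c(16, 16, 16, 16, 0, 0,
                6, 6, 6, 6, 0, 0,
                4, 4, 4, 4, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("gA|tss1", "gA|tss2", "gB|tss1"),
                              samples$sample))
  res <- h3k4me3_tss_signal(m, samples, c("gA", "gA", "gB"), lib,
                            stage = "P1")
  a <- res[res$gene_id == "gA", ]
  expect_equal(a$best_tss, "gA|tss1")
  expect_equal(a$score, 800)
  expect_true(a$retained)
  b <- res[res$gene_id == "gB", ]
  expect_equal(b$score, 200)
  expect_false(b$retained)
  # no reads near the TSS: score ~ 0, not retained
  m0 <- m
  m0["gB|tss1", ] <- 0
  res0 <- h3k4me3_tss_signal(m0, samples, c("gA", "gA", "gB"), lib)
  expect_equal(res0$score[res0$gene_id == "gB"], 0)
  expect_false(res0$retained[res0$gene_id == "gB"])
})

test_that("gene-body RPKM follows the formula and quintiles are exact", {
  samples <- data.frame(sample = c("k36_P1_rep1", "k36_P28_rep1"),
                        stage = c("P1", "P28"), replicate = 1L,
                        is_input = FALSE, stringsAsFactors = FALSE)
  m <- matrix(c(10, 10), 1, 2,
              dimnames = list("gA", samples$sample))
  res <- h3k36me3_gene_signal(m, samples, c(gA = 1000L),
                              stats::setNames(c(1e6, 1e6), samples$sample))
  expect_equal(res$signal$score, 10)   # 10 reads / 1 kb / 1 M reads

  # all-equal scores: retention is the first fifth in gene-id order
  m2 <- matrix(5, 25, 2, dimnames = list(sprintf("g%02d", 1:25),
                                         samples$sample))
  res2 <- h3k36me3_gene_signal(m2, samples,
                               stats::setNames(rep(1000L, 25), rownames(m2)),
                               stats::setNames(c(1e6, 1e6), samples$sample))
  expect_equal(res2$retained, sprintf("g%02d", 1:5))
  expect_error(h3k36me3_gene_signal(
    m2, samples, stats::setNames(rep(1000L, 25), rownames(m2)),
    stats::setNames(c(0, 1e6), samples$sample)), "library size")
})

test_that("shared occupancy between stages is recovered from counts", {
  cfg <- sim_config(seed = 27)
  mo <- sim_multiomics(config = cfg, n_genes = 4000, shared_occupancy = 0.9)
  len <- stats::setNames(mo$gene_info$length, mo$gene_info$gene_id)
  h2 <- mo$chip$h2bub1
  sig <- h2bub_gene_signal(h2$counts, h2$samples, len)
  tt <- mo$truth$delta
  true_shared <- sum(tt$occupied_p1 & tt$occupied_p28) /
    sum(tt$occupied_p1 | tt$occupied_p28)
  est_shared <- sum(sig$occupied_P1 & sig$occupied_P28) /
    sum(sig$occupied_P1 | sig$occupied_P28)
  expect_lt(abs(est_shared - true_shared), 0.03)
})
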