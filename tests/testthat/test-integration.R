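test_that("maturational DE recovers planted fold-changes and flags zeros", {
  cfg <- sim_config(seed = 33, nb_dispersion = 0.05)
  mo <- sim_multiomics(config = cfg, n_genes = 800)
  cts <- mo$rna$maturation
  fc <- maturational_fc(cts, mo$rna$maturation_stage)
  tt <- mo$truth$delta
  # strong planted genes land near their configured effect
  strong <- abs(tt$delta_rna) > 1.5 & rowMeans(cts) > 50
  expect_gt(cor(fc$log2fc[strong], tt$delta_rna[strong]), 0.9)
  # null-ish genes are centred
  null_g <- abs(tt$delta_rna) < 0.05 & rowMeans(cts) > 100
  expect_lt(abs(mean(fc$log2fc[null_g])), 0.1)
  # all-zero gene is flagged NA
  cts0 <- cts
  cts0[5, ] <- 0
  fc0 <- maturational_fc(cts0, mo$rna$maturation_stage)
  expect_true(fc0$flagged[5])
  expect_true(is.na(fc0$log2fc[5]))
  expect_error(maturational_fc(cts[, c(1, 6)],
                               mo$rna$maturation_stage[c(1, 6)]),
               ">= 2 replicates")
})

test_that("stage gene sets are the sorted head and tail of the ranking", {
  set.seed(2)
  fc <- data.frame(gene_id = sprintf("g%03d", 1:300),
                   log2fc = rnorm(300), stringsAsFactors = FALSE)
  sets <- make_stage_gene_sets(fc, k = 100)
  ord <- fc$gene_id[order(-fc$log2fc, fc$gene_id)]
  expect_equal(sort(sets$adult$members), sort(ord[1:100]))
  expect_equal(sort(sets$neonatal$members), sort(rev(ord)[1:100]))
  expect_length(intersect(sets$adult$members, sets$neonatal$members), 0)
  expect_equal(length(sets$adult$members), 100L)

  # boundary ties resolve deterministically by gene id
  fc$log2fc <- rep(c(2, 1, 0), each = 100)
  s1 <- make_stage_gene_sets(fc, k = 100)
  s2 <- make_stage_gene_sets(fc[sample(nrow(fc)), ], k = 100)
  expect_equal(sort(s1$adult$members), sort(s2$adult$members))
  expect_error(make_stage_gene_sets(fc[1:150, ], k = 100), "at least 200")
})

test_that("quadrant labels follow the sign/threshold definition", {
  gid <- sprintf("g%02d", 1:12)
  mat <- data.frame(gene_id = gid,
                    log2fc = c(1, -1, 1, -1, 1, -1, 1, 1, NA, 1, 1, -1))
  h2b <- data.frame(gene_id = gid, signal_P1 = 1,
                    delta = c(1, 1, -1, -1, -1, 1, 1, 1, 1, NA, 1, -1))
  ko <- data.frame(gene_id = gid,
                   log2fc = c(2, 2, -2, -2, 2, -2, 0.5, 2, 2, -2, 2, -2),
                   adj_p = c(rep(0.001, 7), 0.5, rep(0.001, 4)))
  it <- integration_table(mat, h2b, ko)
  it <- it[match(gid, it$gene_id), ]
  # hand enumeration: g07 fails |lfc| > 1, g08 fails the p cut,
  # g09/g10 lack a delta
  expect_equal(it$quadrant,
               c("UR", "UL", "LR", "LL", "LR", "UL", "none", "none",
                 "none", "none", "UR", "LL"))
  expect_equal(it$ko_call[c(1, 3, 7, 8)], c("up", "down", "ns", "ns"))
  qc <- quadrant_classify(it)
  expect_equal(unname(qc$counts), c(2L, 2L, 2L, 2L))
  expect_equal(sum(qc$counts), qc$n_classified)
  # UR (g01 up, g11 up); outside: g02 up, g03 down, g04 down, g05 up,
  # g06 down, g12 down
  expect_equal(unname(qc$tables$UR$ko_down),
               unname(matrix(c(0L, 2L, 4L, 2L), 2, byrow = TRUE)))
  expect_equal(unname(qc$tables$UR$ko_up),
               unname(matrix(c(2L, 0L, 2L, 4L), 2, byrow = TRUE)))

  # no gene passing the 2-fold filter leaves every summary empty
  ko0 <- ko
  ko0$log2fc <- 0.1
  it0 <- integration_table(mat, h2b, ko0)
  qc0 <- quadrant_classify(it0)
  expect_equal(sum(qc0$counts), 0L)
  expect_true(all(vapply(qc0$tables, function(t) sum(t$ko_down), 0) == 0))
})

test_that("Fisher exact test matches enumeration and its invariances", {
  # identical proportions: p = 1, odds ratio 1
  m_eq <- matrix(c(5, 5, 5, 5), 2)
  r <- fisher_quadrant(m_eq)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$odds_ratio, 1)

  # 3/5 vs 1/5 against exhaustive hypergeometric enumeration
  m <- matrix(c(3, 2, 1, 4), 2, byrow = TRUE)
  r <- fisher_quadrant(m)
  o <- oracle_fisher(m)
  expect_equal(r$p_two_sided, o$two, tolerance = 1e-12)
  expect_equal(r$p_greater, o$greater, tolerance = 1e-12)
  expect_equal(r$p_less, o$less, tolerance = 1e-12)

  # invariance under simultaneous row and column swap
  m2 <- m[2:1, 2:1]
  r2 <- fisher_quadrant(m2)
  expect_equal(r2$p_two_sided, r$p_two_sided, tolerance = 1e-12)
  expect_equal(r2$odds_ratio, r$odds_ratio, tolerance = 1e-12)

  # one-sided tails overlap at the observed table
  expect_gte(r$p_greater + r$p_less, 1)

  # Haldane correction with a zero cell
  rz <- fisher_quadrant(matrix(c(4, 0, 2, 6), 2, byrow = TRUE))
  expect_equal(rz$odds_ratio, (4.5 * 6.5) / (0.5 * 2.5))
})

test_that("binned summaries follow the box-and-whisker conventions", {
  set.seed(7)
  it <- data.frame(gene_id = sprintf("g%03d", 1:400),
                   rna_log2fc_maturation = runif(400, -2, 2),
                   h2bub_p1 = rnorm(400),
                   h2bub_delta = rnorm(400),
                   ko_log2fc = 0, ko_adj_p = 1, ko_call = "ns",
                   quadrant = "none", stringsAsFactors = FALSE)
  class(it) <- c("IntegrationTable", "data.frame")
  one <- bin_delta_summary(it, c(-2.01, 2.01))
  expect_equal(one$n[one$variable == "h2bub_delta"], 400L)
  y <- it$h2bub_delta
  q <- quantile(y, c(0.25, 0.75), names = FALSE)
  row <- one[one$variable == "h2bub_delta", ]
  expect_equal(row$lo, min(y[y >= q[1] - 1.5 * (q[2] - q[1])]))
  expect_equal(row$hi, max(y[y <= q[2] + 1.5 * (q[2] - q[1])]))

  bins <- bin_delta_summary(it, c(-2.01, -1, 0, 1, 2.01))
  expect_equal(sum(bins$n[bins$variable == "h2bub_delta"]), 400L)
})

test_that("coupled simulations show monotone binned deltas, uncoupled none", {
  cfg <- sim_config(seed = 15, chip_rna_coupling = 0.4)
  mo <- sim_multiomics(config = cfg, n_genes = 4000)
  len <- stats::setNames(mo$gene_info$length, mo$gene_info$gene_id)
  sig <- h2bub_gene_signal(mo$chip$h2bub1$counts, mo$chip$h2bub1$samples, len)
  fc <- maturational_fc(mo$rna$maturation, mo$rna$maturation_stage)
  ko <- ko_fc(mo$rna$ko, mo$rna$ko_group)
  it <- integration_table(fc, sig, ko)
  bins <- bin_delta_summary(it, c(-Inf, -2, -1, 0, 1, 2, Inf))
  med <- bins$median[bins$variable == "h2bub_delta"]
  expect_true(all(diff(med) >= 0))

  cfg0 <- sim_config(seed = 15, chip_rna_coupling = 0)
  mo0 <- sim_multiomics(config = cfg0, n_genes = 4000)
  tt0 <- mo0$truth$delta
  expect_lt(abs(cor(tt0$delta_rna, tt0$delta_h2bub)), 0.05)
})
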