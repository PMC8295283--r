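test_that("same seed reproduces genome and annotation byte-for-byte", {
  cfg <- sim_config(seed = 13, genome_length = 5e4, n_genes = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- gen_genome(cfg, outdir = d1)
  g2 <- gen_genome(cfg, outdir = d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gtf), readLines(g2$gtf))
  expect_identical(g1$sequence, g2$sequence)
})

test_that("generated gene models satisfy the model invariants", {
  cfg <- sim_config(seed = 5, genome_length = 1.5e5, n_genes = 10)
  g <- gen_genome(cfg)
  expect_length(g$genemodels, 10)
  for (gm in g$genemodels) expect_true(validate_gene_model(gm))
  # at least one gene exercises constitutive-exon logic
  multi <- vapply(g$genemodels, function(gm) length(gm$transcripts) > 1,
                  logical(1))
  expect_true(any(multi))
  gm <- g$genemodels[[which(multi)[1]]]
  all_ex <- sum(IRanges::width(IRanges::reduce(gm$transcripts[[1]]$exons)))
  expect_lt(sum(IRanges::width(constitutive_exons(gm))), all_ex)
})

test_that("zero genes yields sequence only, and infeasible packing errors", {
  cfg0 <- sim_config(seed = 1, genome_length = 2e4, n_genes = 0)
  d <- withr::local_tempdir()
  g <- gen_genome(cfg0, outdir = d)
  expect_length(g$genemodels, 0)
  expect_length(readLines(g$gtf), 0)
  expect_equal(nchar(g$sequence[["chr1"]]), 2e4)
  expect_error(gen_genome(sim_config(seed = 1, genome_length = 5e3,
                                     n_genes = 20)),
               "infeasible packing")
})

test_that("null screen has centred fold-changes and NB mean-variance", {
  lib <- sim_guide_library(80, seed = 3)
  cfg <- sim_config(seed = 3, n_genes = 80, n_hit_genes = 0, hit_log2fc = 0,
                    sequencing_depth = 1e6)
  sc <- sim_screen_counts(lib, cfg, n_input = 10, n_sorted = 10,
                          spike = FALSE)
  cts <- sc$counts$counts
  roles <- sc$counts$sample_roles
  lfc <- log2((rowMeans(cts[, roles == "sorted"]) + 0.5) /
                (rowMeans(cts[, roles == "input"]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.05)

  # var = mu + alpha mu^2 within 20% around mu ~ 500
  mu_hat <- rowMeans(cts)
  v_hat <- apply(cts, 1, stats::var)
  band <- mu_hat > 200 & mu_hat < 1500
  ratio <- v_hat[band] / (mu_hat[band] + 0.1 * mu_hat[band]^2)
  expect_lt(abs(median(ratio) - 1), 0.2)
})

test_that("planted hit effects are recovered at the configured magnitude", {
  lib <- sim_guide_library(100, seed = 8)
  cfg <- sim_config(seed = 8, n_genes = 100, n_hit_genes = 10,
                    hit_log2fc = 3, sequencing_depth = 1e6)
  sc <- sim_screen_counts(lib, cfg, n_input = 10, n_sorted = 10,
                          spike = FALSE)
  cts <- sc$counts$counts
  roles <- sc$counts$sample_roles
  sf <- size_factors(cts)
  nrm <- sweep(cts, 2, sf, "/")
  lfc <- log2((rowMeans(nrm[, roles == "sorted"]) + 0.5) /
                (rowMeans(nrm[, roles == "input"]) + 0.5))
  hit_guides <- names(sc$truth$guide_log2fc)[
    sub("\\|.*", "", names(sc$truth$guide_log2fc)) %in% sc$truth$hit_genes]
  expect_lt(abs(median(lfc[hit_guides]) - 3), 0.3)
})

test_that("multi-omics truth reproduces the configured coupling", {
  cfg0 <- sim_config(seed = 4, chip_rna_coupling = 0)
  mo0 <- sim_multiomics(config = cfg0, n_genes = 5000)
  r0 <- cor(mo0$truth$delta$delta_h2bub, mo0$truth$delta$delta_rna)
  expect_lt(abs(r0), 0.05)

  cfg4 <- sim_config(seed = 4, chip_rna_coupling = 0.4)
  mo4 <- sim_multiomics(config = cfg4, n_genes = 5000)
  r4 <- cor(mo4$truth$delta$delta_h2bub, mo4$truth$delta$delta_rna)
  expect_lt(abs(r4 - 0.4), 0.05)
})

test_that("oppose-maturation rule plants a quadrant association", {
  cfg <- sim_config(seed = 6, chip_rna_coupling = 0.4,
                    ko_effect_rule = "oppose_maturation")
  mo <- sim_multiomics(config = cfg, n_genes = 3000)
  tt <- mo$truth$delta
  de <- abs(tt$ko_log2fc) > 1
  ur <- de & tt$delta_rna > 0 & tt$delta_h2bub > 0
  m <- matrix(c(sum(ur & tt$ko_log2fc < 0), sum(ur & tt$ko_log2fc > 0),
                sum(de & !ur & tt$ko_log2fc < 0),
                sum(de & !ur & tt$ko_log2fc > 0)), 2, byrow = TRUE)
  expect_lt(fisher_quadrant(m)$p_two_sided, 1e-3)
})

test_that("sim config survives a text round-trip", {
  cfg <- sim_config(seed = 99, n_genes = 42, chip_rna_coupling = -0.25,
                    transcripts_per_gene = c(2, 4))
  p <- withr::local_tempfile()
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2, cfg)
  expect_error(sim_config(chip_rna_coupling = 1.5), "coupling")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(n_genes = 5, n_hit_genes = 9), "n_hit_genes")
})
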