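#' Simulate stage-resolved ChIP and RNA count tables with coupled truth
#'
#' Per gene, true maturational changes in H2Bub1 gene-body signal
#' (`delta_h2bub`, log2 adult/neonatal) and in RNA expression
#' (`delta_rna`) are drawn from a bivariate normal whose correlation is
#' `config$chip_rna_coupling`. The dynamic-ChIP subset is the
#' `frac_dynamic_chip` fraction of genes with largest |delta_h2bub|.
#' Under `ko_effect_rule = "oppose_maturation"`, the true knockout
#' log2 fold-change is `-0.8 * delta_rna + N(0, 0.4)`, so genes with
#' maturational gains are preferentially downregulated in the knockout
#' (planting the quadrant enrichment). Replicates are independent NB
#' draws (`var = mu + alpha mu^2`) around gene-level means, with
#' per-sample library-size factors drawn in `[0.7, 1.3]` to exercise
#' normalization. Occupancy structure: a fraction of genes carries
#' H2Bub1 above the input background; of those, `shared_occupancy` are
#' occupied at both stages and the rest at one stage only.
#'
#' @param genemodels list of `GeneModel`, or `NULL` to synthesize
#'   `n_genes` gene lengths directly.
#' @param config a [sim_config()].
#' @param n_genes used when `genemodels` is `NULL`.
#' @param n_reps replicates per ChIP stage (default 2).
#' @param n_rna_reps replicates per RNA group (default 5).
#' @param frac_occupied fraction of genes with H2Bub1 above background
#'   (default 0.5: the gene universe includes silent/unmarked genes, and
#'   median-of-ratios normalization of ChIP against input centres the
#'   occupancy call on the median enrichment ratio, so a bimodal
#'   enrichment structure around an ~50% marked fraction is what the
#'   gene-body scheme can faithfully recover).
#' @param shared_occupancy of occupied genes, fraction occupied at both
#'   stages (default 0.9).
#' @param truth optional `GroundTruth` to extend.
#' @return list with `chip` (per-mark count tables + sample sheets +
#'   library sizes), `rna` (`maturation` and `ko` tables + groups),
#'   `gene_info`, and the extended `truth` (true deltas, dynamic set,
#'   signed KO differential-expression set, occupancy).
#' @export
sim_multiomics <- function(genemodels = NULL, config = sim_config(),
                           n_genes = NULL, n_reps = 2L, n_rna_reps = 5L,
                           frac_occupied = 0.5, shared_occupancy = 0.9,
                           truth = NULL) {
  validate_sim_config(config)
  if (!is.null(genemodels)) {
    if (length(genemodels) == 0L) stop("genemodels is empty", call. = FALSE)
    gids <- names(genemodels)
    glen <- vapply(genemodels, gene_length, integer(1))
    n_tss <- vapply(genemodels, function(gm) length(gm$transcripts), integer(1))
  } else {
    if (is.null(n_genes)) n_genes <- config$n_genes
    if (n_genes == 0L) stop("need at least one gene", call. = FALSE)
    gids <- sprintf("gene%05d", seq_len(n_genes))
    glen <- NULL
    n_tss <- NULL
  }
  ng <- length(gids)
  rho <- config$chip_rna_coupling

  tr <- with_stream(config$seed, "truth", {
    if (is.null(glen)) glen <- pmax(500, round(stats::rlnorm(ng, log(8000), 0.6)))
    if (is.null(n_tss)) n_tss <- sample(1:3, ng, replace = TRUE)
    z1 <- stats::rnorm(ng)
    z2 <- stats::rnorm(ng)
    d_h <- 1.2 * z1
    d_r <- 1.5 * (rho * z1 + sqrt(1 - rho^2) * z2)
    ko <- if (config$ko_effect_rule == "oppose_maturation") {
      -0.8 * d_r + stats::rnorm(ng, 0, 0.4)
    } else rep(0, ng)
    occ <- stats::runif(ng) < frac_occupied
    both <- occ & (stats::runif(ng) < shared_occupancy)
    single <- occ & !both
    p1_only <- single & (stats::runif(ng) < 0.5)
    p28_only <- single & !p1_only
    dyn_cut <- stats::quantile(abs(d_h), 1 - config$frac_dynamic_chip)
    list(glen = glen, n_tss = n_tss, d_h = d_h, d_r = d_r, ko = ko,
         occ_p1 = both | p1_only, occ_p28 = both | p28_only,
         dynamic = gids[abs(d_h) >= dyn_cut])
  })
  names(tr$d_h) <- names(tr$d_r) <- names(tr$ko) <- gids

  if (is.null(truth)) {
    truth <- structure(list(hit_genes = character(0),
                            guide_log2fc = numeric(0), spike_gene = NULL),
                       class = "GroundTruth")
  }
  truth$delta <- data.frame(gene_id = gids, delta_h2bub = tr$d_h,
                            delta_rna = tr$d_r, ko_log2fc = tr$ko,
                            occupied_p1 = tr$occ_p1, occupied_p28 = tr$occ_p28,
                            row.names = NULL, stringsAsFactors = FALSE)
  truth$dynamic_chip_genes <- tr$dynamic
  truth$ko_de_genes <- stats::setNames(sign(tr$ko)[abs(tr$ko) > 1],
                                       gids[abs(tr$ko) > 1])

  alpha <- config$nb_dispersion
  nb_draw <- function(mu) {
    if (alpha > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
    else stats::rpois(length(mu), mu)
  }

  chip <- with_stream(config$seed, "chip", {
    len_kb <- tr$glen / 1000
    bg <- 0.6                                      # input background density
    # marked genes sit well above background; unmarked gene bodies are
    # depleted relative to input (ChIP reads concentrate at marked loci)
    dens <- bg * (4 + stats::rlnorm(ng, log(4), 0.6))
    lo <- 2 * bg
    d1 <- ifelse(tr$occ_p1, pmax(lo, dens * 2^(-tr$d_h / 2)), 0.3 * bg)
    d28 <- ifelse(tr$occ_p28, pmax(lo, dens * 2^(tr$d_h / 2)), 0.3 * bg)
    scale <- 20                                     # reads per kb unit dens
    mk <- function(d) scale * len_kb * d
    cols <- c(sprintf("h2bub1_P1_rep%d", seq_len(n_reps)),
              sprintf("h2bub1_P28_rep%d", seq_len(n_reps)),
              sprintf("input_P1_rep%d", seq_len(n_reps)),
              sprintf("input_P28_rep%d", seq_len(n_reps)))
    sf <- stats::runif(length(cols), 0.7, 1.3)
    mus <- cbind(matrix(rep(mk(d1), n_reps), ncol = n_reps),
                 matrix(rep(mk(d28), n_reps), ncol = n_reps),
                 matrix(rep(mk(rep(bg, ng)), 2L * n_reps), ncol = 2L * n_reps))
    mus <- sweep(mus, 2, sf, "*")
    h2b <- matrix(nb_draw(mus), nrow = ng,
                  dimnames = list(gids, cols))
    h2b_samples <- data.frame(
      sample = cols,
      stage = rep(rep(c("P1", "P28"), 2L), each = n_reps),
      replicate = rep(seq_len(n_reps), 4L),
      is_input = rep(c(FALSE, TRUE), each = 2L * n_reps),
      stringsAsFactors = FALSE)

    # H3K4me3: per-TSS max per-base coverage; calibrated so ~20% of genes
    # exceed the 500-RPKM retention floor at a 2e7-read library
    tss_gene <- rep(gids, tr$n_tss)
    tss_id <- unlist(lapply(seq_len(ng), function(i) {
      sprintf("%s|tss%d", gids[i], seq_len(tr$n_tss[i]))
    }))
    nt <- length(tss_id)
    # gene-level promoter strength calibrated so P(strength > 10) ~ 0.2,
    # i.e. ~20% of genes clear the 500-RPKM floor at a 2e7-read library;
    # the strongest TSS carries the full strength, others a fraction
    strength <- stats::rlnorm(ng, log(4), 1.1)
    prom <- unlist(lapply(seq_len(ng), function(i) {
      k <- tr$n_tss[i]
      s <- c(1, stats::runif(k - 1L, 0.2, 0.6))
      strength[i] * s[seq_len(k)]
    }))
    k4cols <- c(sprintf("h3k4me3_P1_rep%d", seq_len(n_reps)),
                sprintf("h3k4me3_P28_rep%d", seq_len(n_reps)),
                "input_P1", "input_P28")
    k4sf <- stats::runif(length(k4cols), 0.85, 1.15)
    k4mu <- cbind(matrix(rep(prom, 2L * n_reps), ncol = 2L * n_reps),
                  matrix(rep(0.05, nt * 2L), ncol = 2L))
    k4mu <- sweep(k4mu, 2, k4sf, "*")
    k4 <- matrix(nb_draw(k4mu * 10) / 10, nrow = nt,
                 dimnames = list(tss_id, k4cols))
    k4_samples <- data.frame(
      sample = k4cols,
      stage = rep(c("P1", "P28", "P1", "P28"), c(n_reps, n_reps, 1L, 1L)),
      replicate = c(seq_len(n_reps), seq_len(n_reps), 1L, 1L),
      is_input = rep(c(FALSE, TRUE), c(2L * n_reps, 2L)),
      stringsAsFactors = FALSE)
    k4_lib <- stats::setNames(rep(2e7, length(k4cols)) * k4sf, k4cols)

    # H3K36me3: gene-body counts proportional to expression-like levels
    k36cols <- c(sprintf("h3k36me3_P1_rep%d", seq_len(n_reps)),
                 sprintf("h3k36me3_P28_rep%d", seq_len(n_reps)))
    body <- stats::rlnorm(ng, log(2), 1)
    k36sf <- stats::runif(length(k36cols), 0.8, 1.2)
    k36mu <- sweep(matrix(rep(30 * len_kb * body, length(k36cols)),
                          ncol = length(k36cols)), 2, k36sf, "*")
    k36 <- matrix(nb_draw(k36mu), nrow = ng,
                  dimnames = list(gids, k36cols))
    k36_samples <- data.frame(
      sample = k36cols, stage = rep(c("P1", "P28"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2L),
      is_input = FALSE, stringsAsFactors = FALSE)
    list(h2bub1 = list(counts = h2b, samples = h2b_samples,
                       lib_sizes = stats::setNames(colSums(h2b), cols)),
         h3k4me3 = list(counts = k4, samples = k4_samples,
                        lib_sizes = k4_lib, tss_gene = tss_gene),
         h3k36me3 = list(counts = k36, samples = k36_samples,
                         lib_sizes = stats::setNames(colSums(k36), k36cols)))
  })

  rna <- with_stream(config$seed, "rna", {
    base <- stats::rlnorm(ng, log(150), 1.2)
    mu_p1 <- base * 2^(-tr$d_r / 2)
    mu_p28 <- base * 2^(tr$d_r / 2)
    mu_ko <- mu_p28 * 2^tr$ko
    mat_cols <- c(sprintf("wt_P1_rep%d", seq_len(n_rna_reps)),
                  sprintf("wt_P28_rep%d", seq_len(n_rna_reps)))
    ko_cols <- c(sprintf("ctrl_rep%d", seq_len(n_rna_reps)),
                 sprintf("ko_rep%d", seq_len(n_rna_reps)))
    msf <- stats::runif(length(mat_cols), 0.8, 1.2)
    ksf <- stats::runif(length(ko_cols), 0.8, 1.2)
    mmu <- sweep(cbind(matrix(rep(mu_p1, n_rna_reps), ncol = n_rna_reps),
                       matrix(rep(mu_p28, n_rna_reps), ncol = n_rna_reps)),
                 2, msf, "*")
    kmu <- sweep(cbind(matrix(rep(mu_p28, n_rna_reps), ncol = n_rna_reps),
                       matrix(rep(mu_ko, n_rna_reps), ncol = n_rna_reps)),
                 2, ksf, "*")
    maturation <- matrix(nb_draw(mmu), nrow = ng,
                         dimnames = list(gids, mat_cols))
    ko_counts <- matrix(nb_draw(kmu), nrow = ng,
                        dimnames = list(gids, ko_cols))
    list(maturation = maturation,
         maturation_stage = stats::setNames(
           rep(c("P1", "P28"), each = n_rna_reps), mat_cols),
         ko = ko_counts,
         ko_group = stats::setNames(
           rep(c("control", "ko"), each = n_rna_reps), ko_cols))
  })

  list(chip = chip, rna = rna,
       gene_info = data.frame(gene_id = gids, length = tr$glen,
                              n_tss = tr$n_tss, stringsAsFactors = FALSE),
       truth = truth)
}
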