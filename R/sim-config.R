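#' Simulation configuration
#'
#' One configuration object drives every synthetic artifact (genome,
#' screen counts, ChIP and RNA tables) so that a single root seed fully
#' determines every output byte. Defaults encode the study conditions the
#' downstream recovery tests assume: a 500-gene screen with 50 hit genes
#' at log2 fold-change 3, per-guide effect heterogeneity of sd 0.5,
#' NB dispersion 0.1, one million reads per sample, a 20% dynamic-H2Bub1
#' gene fraction, an H2Bub1/RNA maturational coupling of 0.4, and a
#' knockout rule that opposes maturational expression changes.
#'
#' @param seed root seed (integer); child streams are derived per artifact.
#' @param genome_length genome size in bp.
#' @param n_genes number of genes to place.
#' @param transcripts_per_gene integer range `c(min, max)` of isoforms.
#' @param n_hit_genes number of screen hit genes (default:
#'   `min(50, n_genes)`).
#' @param hit_log2fc gene-level sorted-vs-input log2 fold-change of hits.
#' @param guide_effect_sd sd of the per-guide Gaussian perturbation of the
#'   gene effect (guide-efficacy heterogeneity).
#' @param nb_dispersion NB dispersion alpha in `var = mu + alpha mu^2`,
#'   shared across guides/genes.
#' @param sequencing_depth expected reads per screen sample.
#' @param frac_dynamic_chip fraction of genes labelled as the dynamic
#'   H2Bub1 subset (largest |true delta|).
#' @param chip_rna_coupling correlation of true maturational deltaH2Bub1
#'   and deltaRNA, in `[-1, 1]`.
#' @param ko_effect_rule `"oppose_maturation"` (knockout preferentially
#'   reverses maturational expression changes) or `"none"`.
#' @return a `SimConfig` object (validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_genes = 500L,
                       transcripts_per_gene = c(1L, 3L),
                       n_hit_genes = NULL,
                       hit_log2fc = 3,
                       guide_effect_sd = 0.5,
                       nb_dispersion = 0.1,
                       sequencing_depth = 1e6,
                       frac_dynamic_chip = 0.2,
                       chip_rna_coupling = 0.4,
                       ko_effect_rule = c("oppose_maturation", "none")) {
  ko_effect_rule <- match.arg(ko_effect_rule)
  if (is.null(n_hit_genes)) n_hit_genes <- min(50L, n_genes)
  cfg <- structure(list(seed = as.integer(seed),
                        genome_length = genome_length,
                        n_genes = as.integer(n_genes),
                        transcripts_per_gene = as.integer(transcripts_per_gene),
                        n_hit_genes = as.integer(n_hit_genes),
                        hit_log2fc = hit_log2fc,
                        guide_effect_sd = guide_effect_sd,
                        nb_dispersion = nb_dispersion,
                        sequencing_depth = sequencing_depth,
                        frac_dynamic_chip = frac_dynamic_chip,
                        chip_rna_coupling = chip_rna_coupling,
                        ko_effect_rule = ko_effect_rule),
                   class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_hit_genes > cfg$n_genes)
    stop("n_hit_genes must be <= n_genes", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$sequencing_depth < 0) stop("sequencing_depth must be >= 0", call. = FALSE)
  if (cfg$frac_dynamic_chip < 0 || cfg$frac_dynamic_chip > 1)
    stop("frac_dynamic_chip must be in [0, 1]", call. = FALSE)
  if (abs(cfg$chip_rna_coupling) > 1)
    stop("chip_rna_coupling must be in [-1, 1]", call. = FALSE)
  if (length(cfg$transcripts_per_gene) != 2L ||
      cfg$transcripts_per_gene[1] > cfg$transcripts_per_gene[2] ||
      cfg$transcripts_per_gene[1] < 1L)
    stop("transcripts_per_gene must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  invisible(TRUE)
}

#' Write / read a SimConfig as key: value text
#' @param cfg a `SimConfig`.
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  vals <- vapply(cfg, function(v) paste(format(v, scientific = FALSE), collapse = ","),
                 character(1))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  sim_config(seed = num(vals$seed), genome_length = num(vals$genome_length),
             n_genes = num(vals$n_genes),
             transcripts_per_gene = num(vals$transcripts_per_gene),
             n_hit_genes = num(vals$n_hit_genes),
             hit_log2fc = num(vals$hit_log2fc),
             guide_effect_sd = num(vals$guide_effect_sd),
             nb_dispersion = num(vals$nb_dispersion),
             sequencing_depth = num(vals$sequencing_depth),
             frac_dynamic_chip = num(vals$frac_dynamic_chip),
             chip_rna_coupling = num(vals$chip_rna_coupling),
             ko_effect_rule = vals$ko_effect_rule)
}
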