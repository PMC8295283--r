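#' Synthesize a guide library without a genome
#'
#' Generates a library of distinct random spacers (6 per gene plus
#' non-targeting controls) for count-level screen simulations where the
#' guide sequences themselves are immaterial. Genome-anchored libraries
#' come from [design_library()].
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene (default 6).
#' @param n_controls non-targeting controls (default 7).
#' @param seed seed.
#' @return a `GuideLibrary` (coordinates `NA`, attribute
#'   `synthetic = TRUE`).
#' @export
sim_guide_library <- function(n_genes, guides_per_gene = 6L, n_controls = 7L,
                              seed = 1L) {
  n_sp <- n_genes * guides_per_gene + n_controls
  with_stream(seed, "library", {
    sp <- character(0)
    while (length(sp) < n_sp) {
      batch <- vapply(seq_len(n_sp - length(sp) + 10L), function(i) {
        paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
              collapse = "")
      }, character(1))
      sp <- unique(c(sp, batch))
    }
    sp <- sp[seq_len(n_sp)]
    gids <- if (n_genes > 0L) sprintf("gene%04d", seq_len(n_genes)) else character(0)
    guides <- data.frame(
      gene_id = rep(gids, each = guides_per_gene),
      spacer = sp[seq_len(n_genes * guides_per_gene)],
      chrom = NA_character_, strand = NA_character_,
      start = NA_integer_, end = NA_integer_, cut_pos = NA_integer_,
      cds_percent = NA_real_, constitutive = NA, n0 = NA_integer_,
      n1 = NA_integer_, n2 = NA_integer_, oof_score = NA_real_,
      tier = NA_integer_, stringsAsFactors = FALSE)
    ctrl_sp <- sp[seq.int(n_genes * guides_per_gene + 1L, n_sp)]
    controls <- data.frame(control_id = sprintf("ctrl%d", seq_len(n_controls)),
                           spacer = ctrl_sp, stringsAsFactors = FALSE)
    lib <- structure(list(guides = guides, controls = controls,
                          genes_targeted = n_genes,
                          undesignable = character(0),
                          tier_usage = table(factor(integer(0), levels = 1:5))),
                     class = "GuideLibrary")
    attr(lib, "synthetic") <- TRUE
    validate_guide_library(lib, k = guides_per_gene)
    lib
  })
}

guide_ids <- function(lib) {
  c(sprintf("%s|%s", lib$guides$gene_id, lib$guides$spacer),
    lib$controls$control_id)
}

#' Simulate screen guide counts for input and sorted samples
#'
#' Counts are negative-binomial draws (`var = mu + alpha mu^2`, shared
#' dispersion) around per-guide expected proportions of the sequencing
#' depth. Guides of hit genes are scaled in sorted samples by
#' `2^(hit_log2fc + per-guide N(0, guide_effect_sd))`; non-targeting and
#' non-hit guides keep equal expected representation in both roles. A
#' spiked positive-control gene (entering at low input abundance,
#' emulating a co-packaged control virus) carries a designated strong
#' effect of `hit_log2fc + 2` on each of its guides.
#'
#' @param library a `GuideLibrary`.
#' @param config a [sim_config()]; uses `n_hit_genes`, `hit_log2fc`,
#'   `guide_effect_sd`, `nb_dispersion`, `sequencing_depth`, `seed`.
#' @param n_input,n_sorted replicate counts per role (>= 2).
#' @param truth optional pre-built `GroundTruth` to reuse.
#' @param spike add the spiked positive-control gene (default TRUE).
#' @return list with `counts` (a `GuideCountTable`: matrix + roles) and
#'   `truth` (`GroundTruth`: hit genes, per-guide true log2fc, spike id).
#' @export
sim_screen_counts <- function(library, config, n_input = 15L, n_sorted = 15L,
                              truth = NULL, spike = TRUE) {
  validate_sim_config(config)
  if (nrow(library$guides) == 0L) stop("library is empty", call. = FALSE)
  if (n_input < 2L || n_sorted < 2L)
    stop("need >= 2 samples per role", call. = FALSE)
  glib <- library$guides
  if (is.null(truth)) {
    truth <- with_stream(config$seed, "truth", {
      gids <- unique(glib$gene_id)
      hits <- sort(sample(gids, min(config$n_hit_genes, length(gids))))
      eff_gene <- stats::setNames(rep(0, length(gids)), gids)
      eff_gene[hits] <- config$hit_log2fc
      guide_eff <- eff_gene[glib$gene_id] +
        ifelse(glib$gene_id %in% hits,
               stats::rnorm(nrow(glib), 0, config$guide_effect_sd), 0)
      names(guide_eff) <- sprintf("%s|%s", glib$gene_id, glib$spacer)
      ctrl_eff <- stats::setNames(rep(0, nrow(library$controls)),
                                  library$controls$control_id)
      spike_eff <- NULL
      if (spike) {
        n_spike <- max(table(glib$gene_id))
        spike_eff <- stats::setNames(
          rep(config$hit_log2fc + 2, n_spike),
          sprintf("spikeG4_6|spike_g%d", seq_len(n_spike)))
      }
      structure(list(hit_genes = hits,
                     guide_log2fc = c(guide_eff, ctrl_eff, spike_eff),
                     spike_gene = if (spike) "spikeG4_6" else NULL,
                     dynamic_chip_genes = NULL, delta = NULL,
                     ko_de_genes = NULL),
                class = "GroundTruth")
    })
  }
  ids <- guide_ids(library)
  if (!is.null(truth$spike_gene))
    ids <- c(ids, grep("^spikeG4_6\\|", names(truth$guide_log2fc),
                       value = TRUE))
  eff <- truth$guide_log2fc[ids]
  stopifnot(!anyNA(eff))
  with_stream(config$seed, "screen", {
    n_g <- length(ids)
    w <- exp(stats::rnorm(n_g, 0, 0.5))      # baseline representation
    if (!is.null(truth$spike_gene)) {
      # spiked virus enters at low input abundance
      w[grepl("^spikeG4_6\\|", ids)] <- 0.25 * exp(mean(log(w)))
    }
    p_in <- w / sum(w)
    w_s <- w * 2^eff
    p_so <- w_s / sum(w_s)
    depth <- config$sequencing_depth
    alpha <- config$nb_dispersion
    draw <- function(p, n) {
      mu <- rep(depth * p, n)
      m <- if (alpha > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
      } else stats::rpois(length(mu), mu)
      matrix(m, nrow = length(p), ncol = n)
    }
    counts <- cbind(draw(p_in, n_input), draw(p_so, n_sorted))
    rownames(counts) <- ids
    colnames(counts) <- c(sprintf("input_%02d", seq_len(n_input)),
                          sprintf("yfp_%02d", seq_len(n_sorted)))
    roles <- stats::setNames(rep(c("input", "sorted"), c(n_input, n_sorted)),
                             colnames(counts))
    tab <- guide_count_table(counts, roles)
    list(counts = tab, truth = truth)
  })
}

#' Construct a guide count table
#'
#' @param counts non-negative integer matrix, guides x samples.
#' @param sample_roles named character vector mapping each sample to
#'   `"input"` or `"sorted"`.
#' @param unassigned integer per-sample unassigned-read counts.
#' @return a `GuideCountTable`.
#' @export
guide_count_table <- function(counts, sample_roles,
                              unassigned = stats::setNames(
                                rep(0L, ncol(counts)), colnames(counts))) {
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            all(colnames(counts) %in% names(sample_roles)),
            all(sample_roles[colnames(counts)] %in% c("input", "sorted")))
  structure(list(counts = counts,
                 sample_roles = sample_roles[colnames(counts)],
                 unassigned = unassigned[colnames(counts)]),
            class = "GuideCountTable")
}

#' @export
print.GuideCountTable <- function(x, ...) {
  cat(sprintf("GuideCountTable: %d guides x %d samples (%d input, %d sorted)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_roles == "input"), sum(x$sample_roles == "sorted")))
  invisible(x)
}

#' Emit screen reads as FASTQ for selected samples
#'
#' Each counted guide yields reads of the form `adapter5 + G-extended
#' spacer + scaffold3 (+ filler)`; a configurable fraction of reads is
#' corrupted (scaffold destroyed) to exercise trimming. Read counts per
#' guide equal the count-table entries, so trimming + counting recovers
#' the table exactly on the uncorrupted fraction.
#'
#' @param library `GuideLibrary`.
#' @param table `GuideCountTable`.
#' @param samples sample names to emit (default: first sample).
#' @param outdir output directory for `<sample>.fastq`.
#' @param adapter5,scaffold3 anchor sequences.
#' @param corrupt_frac fraction of reads with a destroyed scaffold.
#' @param seed seed for corruption choice.
#' @return named vector of FASTQ paths.
#' @export
sim_screen_fastq <- function(library, table, samples = colnames(table$counts)[1],
                             outdir, adapter5 = screen_adapter5(),
                             scaffold3 = screen_scaffold3(),
                             corrupt_frac = 0, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spac <- stats::setNames(c(library$guides$spacer, library$controls$spacer),
                          guide_ids(library))
  paths <- character(0)
  with_stream(seed, "reads", {
    for (s in samples) {
      cnt <- table$counts[, s]
      cnt <- cnt[names(cnt) %in% names(spac)]
      reads <- rep(names(cnt), cnt)
      ins <- ifelse(substr(spac[reads], 1, 1) == "G", spac[reads],
                    paste0("G", spac[reads]))
      seqs <- paste0(adapter5, ins, scaffold3)
      if (corrupt_frac > 0 && length(seqs)) {
        bad <- sample(length(seqs), round(corrupt_frac * length(seqs)))
        seqs[bad] <- paste0(adapter5, substr(ins[bad], 1, 20),
                            strrep("A", nchar(scaffold3)))
        attr(paths, "corrupted") <- c(attr(paths, "corrupted"),
                                      stats::setNames(length(bad), s))
      }
      dna <- Biostrings::DNAStringSet(seqs)
      names(dna) <- sprintf("%s_read%06d", s, seq_along(dna))
      qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
      p <- file.path(outdir, paste0(s, ".fastq"))
      Biostrings::writeXStringSet(dna, p, format = "fastq", qualities = qual)
      paths[s] <- p
    }
  })
  paths
}

#' Screen read anchor constants
#'
#' Fixed vector-derived sequences flanking the guide variable region in
#' sequencing reads: the 5' adapter ends at the U6 +1 position, the 3'
#' scaffold is the invariant sgRNA backbone start.
#' @return character scalar.
#' @export
screen_adapter5 <- function() "TTGTGGAAAGGACGAAACACC"

#' @rdname screen_adapter5
#' @export
screen_scaffold3 <- function() "GTTTTAGAGCTAGAAATAGCA"
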