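#' Generate a synthetic genome with gene annotation
#'
#' Draws a uniform-composition DNA sequence and places non-overlapping
#' multi-exon genes on alternating strands with >= 1 kb intergenic
#' spacing. Exon widths are multiples of 3 and the CDS of every
#' transcript covers whole exons, so all CDS lengths are divisible by 3.
#' Additional isoforms skip one internal exon; when the configured
#' isoform range allows more than one transcript, the first gene is
#' guaranteed to have at least two isoforms sharing only a subset of
#' exons, so constitutive-exon logic is always exercised.
#'
#' @param config a [sim_config()] object.
#' @param outdir optional directory; when given, writes `genome.fa`
#'   (60-column wrapped FASTA) and `genes.gtf`.
#' @return list with `sequence` (named character, one chromosome),
#'   `genemodels` (list of `GeneModel`), and file paths when written.
#' @export
gen_genome <- function(config, outdir = NULL) {
  validate_sim_config(config)
  with_stream(config$seed, "genome", {
    L <- as.integer(config$genome_length)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    genemodels <- list()
    pos <- 1001L
    tmin <- config$transcripts_per_gene[1]
    tmax <- config$transcripts_per_gene[2]
    if (config$n_genes > 0L) {
      for (g in seq_len(config$n_genes)) {
        n_ex <- sample(3:5, 1L)
        widths <- 3L * sample(30:100, n_ex, replace = TRUE)
        introns <- sample(80:200, n_ex - 1L, replace = TRUE)
        starts <- pos + cumsum(c(0L, widths[-n_ex] + introns))
        ends <- starts + widths - 1L
        if (ends[n_ex] + 1000L > L)
          stop(sprintf(paste0("infeasible packing: %d genes do not fit in ",
                              "%d bp"), config$n_genes, L), call. = FALSE)
        exons <- IRanges::IRanges(starts, ends)
        n_tx <- sample(tmin:tmax, 1L)
        if (g == 1L && tmax >= 2L) n_tx <- max(2L, n_tx)
        gid <- sprintf("gene%04d", g)
        txs <- list()
        txs[[paste0(gid, ".t1")]] <- list(exons = exons, cds = exons)
        if (n_tx > 1L) {
          skippable <- 2:(n_ex - 1L)
          drop <- sample(skippable, min(n_tx - 1L, length(skippable)))
          for (k in seq_along(drop)) {
            keep <- setdiff(seq_len(n_ex), drop[k])
            txs[[sprintf("%s.t%d", gid, k + 1L)]] <-
              list(exons = exons[keep], cds = exons[keep])
          }
        }
        strand <- if (g %% 2L == 1L) "+" else "-"
        genemodels[[gid]] <- gene_model(gid, "chr1", strand, txs)
        pos <- ends[n_ex] + 1001L
      }
    }
    out <- list(sequence = c(chr1 = seq), genemodels = genemodels)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(outdir, "genome.fa")
      dna <- Biostrings::DNAStringSet(stats::setNames(seq, "chr1"))
      Biostrings::writeXStringSet(dna, fa, width = 60L)
      gtf <- file.path(outdir, "genes.gtf")
      write_gtf(genemodels, gtf)
      out$fasta <- fa
      out$gtf <- gtf
    }
    out
  })
}
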