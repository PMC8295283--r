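# One quantification scheme per histone mark, operating on
# feature-count tables (read alignment is upstream of this package).

.chip_check <- function(counts, samples) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(c("sample", "stage", "is_input") %in% colnames(samples)),
            all(samples$sample %in% colnames(counts)))
}

#' H2Bub1 gene-body signal
#'
#' Counts are median-of-ratios normalized across all samples (ChIP and
#' input), divided by gene length (first TSS to last TSE), replicates
#' averaged per stage, and the identically processed input subtracted.
#' Genes with signal > 0 are called occupied. Negative post-subtraction
#' signals are retained (no clipping), so stage deltas stay linear.
#'
#' @param counts gene x sample count matrix (ChIP replicates and inputs).
#' @param samples sample sheet: sample, stage, is_input.
#' @param gene_lengths named lengths in bp (gene ids matching rows);
#'   genes missing a length are skipped with a warning.
#' @param stages two stage labels, neonatal first (delta = second minus
#'   first).
#' @return `GeneSignalTable` data.frame: gene_id, one signal and one
#'   occupied column per stage, delta, gene_length.
#' @export
h2bub_gene_signal <- function(counts, samples, gene_lengths,
                              stages = c("P1", "P28")) {
  .chip_check(counts, samples)
  known <- rownames(counts) %in% names(gene_lengths)
  if (!all(known)) {
    warning(sum(!known), " gene(s) absent from annotation; skipped")
    counts <- counts[known, , drop = FALSE]
  }
  len <- gene_lengths[rownames(counts)]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/") / len
  sig <- lapply(stages, function(st) {
    chip_cols <- samples$sample[!samples$is_input & samples$stage == st]
    in_cols <- samples$sample[samples$is_input & samples$stage == st]
    if (length(chip_cols) < 1L) stop("no ChIP replicate for stage ", st)
    chip_avg <- rowMeans(norm[, chip_cols, drop = FALSE])
    in_avg <- if (length(in_cols)) rowMeans(norm[, in_cols, drop = FALSE])
      else 0
    chip_avg - in_avg
  })
  out <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    out[[paste0("signal_", stages[i])]] <- sig[[i]]
    out[[paste0("occupied_", stages[i])]] <- sig[[i]] > 0
  }
  out$delta <- sig[[2]] - sig[[1]]
  out$gene_length <- unname(len)
  class(out) <- c("GeneSignalTable", "data.frame")
  out
}

#' H3K4me3 TSS signal (max per-base coverage, RPKM scale)
#'
#' Per TSS +/- 1 kb window, the maximum per-base coverage is scaled to
#' RPKM (`cov * 1e9 / library_size`, a 1-bp bin), replicates are
#' averaged, input signal subtracted, and only the highest-scoring TSS
#' kept per gene. Genes are retained when the best score exceeds the
#' floor (500 RPKM).
#'
#' @param counts TSS x sample matrix of window max-coverage values.
#' @param samples sample sheet (sample, stage, is_input).
#' @param tss_gene character vector mapping each TSS row to its gene.
#' @param lib_sizes named per-sample library sizes (mapped reads).
#' @param stage stage to score.
#' @param floor retention floor in RPKM (default 500).
#' @return `TssSignalTable` data.frame: gene_id, best_tss, score,
#'   retained.
#' @export
h3k4me3_tss_signal <- function(counts, samples, tss_gene, lib_sizes,
                               stage = "P1", floor = 500) {
  .chip_check(counts, samples)
  stopifnot(length(tss_gene) == nrow(counts),
            all(colnames(counts) %in% names(lib_sizes)))
  rpkm <- sweep(counts, 2, lib_sizes[colnames(counts)] / 1e9, "/")
  chip_cols <- samples$sample[!samples$is_input & samples$stage == stage]
  in_cols <- samples$sample[samples$is_input & samples$stage == stage]
  score_tss <- rowMeans(rpkm[, chip_cols, drop = FALSE]) -
    (if (length(in_cols)) rowMeans(rpkm[, in_cols, drop = FALSE]) else 0)
  ord <- order(tss_gene, -score_tss, rownames(counts))
  best <- !duplicated(tss_gene[ord])
  out <- data.frame(gene_id = tss_gene[ord][best],
                    best_tss = rownames(counts)[ord][best],
                    score = score_tss[ord][best],
                    stringsAsFactors = FALSE)
  out$retained <- out$score > floor
  rownames(out) <- NULL
  class(out) <- c("TssSignalTable", "data.frame")
  out
}

#' H3K36me3 gene-body RPKM with top-quintile retention
#'
#' Per gene, reads are scaled to RPKM (library size and gene length),
#' replicates averaged per stage, and the overall score is the mean
#' across stages. The retained set is the top 20% by score with a
#' deterministic tie-break by gene id.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample sheet (sample, stage, is_input).
#' @param gene_lengths named lengths in bp.
#' @param lib_sizes named per-sample library sizes (must be > 0).
#' @param stages stage labels, neonatal first.
#' @return list with `signal` (`GeneSignalTable`-like data.frame with
#'   per-stage scores, overall `score`, `delta`, `retained`) and
#'   `retained` (gene ids of the top quintile).
#' @export
h3k36me3_gene_signal <- function(counts, samples, gene_lengths, lib_sizes,
                                 stages = c("P1", "P28")) {
  .chip_check(counts, samples)
  if (any(lib_sizes[colnames(counts)] <= 0))
    stop("zero library size", call. = FALSE)
  len <- gene_lengths[rownames(counts)]
  rpkm <- sweep(counts, 2, lib_sizes[colnames(counts)] / 1e9, "/") / len
  per_stage <- lapply(stages, function(st) {
    cols <- samples$sample[!samples$is_input & samples$stage == st]
    rowMeans(rpkm[, cols, drop = FALSE])
  })
  score <- Reduce(`+`, per_stage) / length(per_stage)
  out <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  for (i in seq_along(stages)) out[[paste0("signal_", stages[i])]] <- per_stage[[i]]
  out$score <- score
  out$delta <- per_stage[[2]] - per_stage[[1]]
  n_keep <- floor(nrow(out) / 5)
  ord <- order(-out$score, out$gene_id)
  out$retained <- FALSE
  out$retained[ord[seq_len(n_keep)]] <- TRUE
  list(signal = out, retained = sort(out$gene_id[out$retained]))
}
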