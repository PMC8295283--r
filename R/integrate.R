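# Integration layer: maturational fold-changes, stage gene sets,
# delta-vs-delta binning, quadrant classification, Fisher exact tests.

#' Maturational differential expression (adult vs neonatal)
#'
#' NB-Wald differential expression of P28 versus P1 wild-type counts
#' (shared core with the guide-level screen test). Genes with zero
#' counts in both stages are flagged `NA`.
#'
#' @param counts gene x sample matrix covering both stages.
#' @param stage named vector mapping samples to the two stage labels,
#'   neonatal first.
#' @param stages stage labels (reference first).
#' @return data.frame: gene_id, base_mean, log2fc (adult vs neonatal),
#'   wald_se, wald_p, adj_p, flagged.
#' @export
maturational_fc <- function(counts, stage, stages = c("P1", "P28")) {
  stage <- stage[colnames(counts)]
  stopifnot(all(stage %in% stages))
  if (any(table(factor(stage, stages)) < 2L))
    stop("need >= 2 replicates per stage", call. = FALSE)
  res <- nb_wald(counts, factor(stage, levels = stages))
  data.frame(gene_id = res$feature_id, base_mean = res$base_mean,
             log2fc = res$log2fc, wald_se = res$wald_se,
             wald_p = res$wald_p, adj_p = res$bh_adj_p,
             flagged = res$flagged, stringsAsFactors = FALSE)
}

#' Knockout differential expression (KO vs control)
#'
#' @param counts gene x sample matrix.
#' @param group named vector `"control"`/`"ko"`.
#' @return as [maturational_fc()], log2fc is KO vs control.
#' @export
ko_fc <- function(counts, group) {
  maturational_fc(counts, group, stages = c("control", "ko"))
}

#' Stage-specific gene sets from the maturational ranking
#'
#' The highest `k` genes by maturational log2 ratio form the
#' adult-specific set and the lowest `k` the neonatal-specific set,
#' with a deterministic tie-break by gene id.
#'
#' @param fc_table output of [maturational_fc()].
#' @param k set size (default 100).
#' @return list of two `GeneSet`s: `adult`, `neonatal`.
#' @export
make_stage_gene_sets <- function(fc_table, k = 100L) {
  tb <- fc_table[!is.na(fc_table$log2fc), , drop = FALSE]
  if (nrow(tb) < 2L * k)
    stop("need at least ", 2L * k, " genes with defined fold-change",
         call. = FALSE)
  ord <- order(-tb$log2fc, tb$gene_id)
  adult <- tb$gene_id[ord][seq_len(k)]
  ord_lo <- order(tb$log2fc, tb$gene_id)
  neonatal <- tb$gene_id[ord_lo][seq_len(k)]
  list(adult = gene_set("adult_specific", adult),
       neonatal = gene_set("neonatal_specific", neonatal))
}

#' Assemble the per-gene integration table
#'
#' Joins maturational RNA fold-changes, H2Bub1 gene-body signal
#' (neonatal signal and maturational delta) and knockout differential
#' expression; calls `ko_call` (up/down/ns at |log2fc| > `lfc_cut` and
#' adjusted p < `p_cut`) and assigns quadrants by the joint sign of the
#' maturational RNA change and the H2Bub1 delta, restricted to
#' KO-responsive genes (UR = both positive, LL = both negative, UL =
#' RNA down / H2Bub1 up, LR = RNA up / H2Bub1 down).
#'
#' @param mat_fc output of [maturational_fc()].
#' @param h2b `GeneSignalTable` from [h2bub_gene_signal()].
#' @param ko output of [ko_fc()].
#' @param lfc_cut KO fold-change cut on the log2 scale (default 1, i.e.
#'   2-fold).
#' @param p_cut KO adjusted-p cut (default 0.05).
#' @param neonatal_stage stage label of the neonatal signal column.
#' @return `IntegrationTable` data.frame: gene_id,
#'   rna_log2fc_maturation, h2bub_p1, h2bub_delta, ko_log2fc, ko_adj_p,
#'   ko_call, quadrant.
#' @export
integration_table <- function(mat_fc, h2b, ko, lfc_cut = 1, p_cut = 0.05,
                              neonatal_stage = "P1") {
  df <- merge(data.frame(gene_id = mat_fc$gene_id,
                         rna_log2fc_maturation = mat_fc$log2fc,
                         stringsAsFactors = FALSE),
              data.frame(gene_id = h2b$gene_id,
                         h2bub_p1 = h2b[[paste0("signal_", neonatal_stage)]],
                         h2bub_delta = h2b$delta, stringsAsFactors = FALSE),
              by = "gene_id", all = TRUE)
  df <- merge(df, data.frame(gene_id = ko$gene_id, ko_log2fc = ko$log2fc,
                             ko_adj_p = ko$adj_p, stringsAsFactors = FALSE),
              by = "gene_id", all = TRUE)
  df$ko_call <- "ns"
  de <- !is.na(df$ko_log2fc) & !is.na(df$ko_adj_p) &
    abs(df$ko_log2fc) > lfc_cut & df$ko_adj_p < p_cut
  df$ko_call[de & df$ko_log2fc > 0] <- "up"
  df$ko_call[de & df$ko_log2fc < 0] <- "down"
  df$quadrant <- "none"
  cl <- df$ko_call != "ns" & !is.na(df$rna_log2fc_maturation) &
    !is.na(df$h2bub_delta) & df$rna_log2fc_maturation != 0 &
    df$h2bub_delta != 0
  up_r <- df$rna_log2fc_maturation > 0
  up_h <- df$h2bub_delta > 0
  df$quadrant[cl & up_r & up_h] <- "UR"
  df$quadrant[cl & !up_r & up_h] <- "UL"
  df$quadrant[cl & up_r & !up_h] <- "LR"
  df$quadrant[cl & !up_r & !up_h] <- "LL"
  class(df) <- c("IntegrationTable", "data.frame")
  df
}

#' Quadrant classification summaries
#'
#' For each focal quadrant, emits the 2x2 contingency tables comparing
#' the KO-downregulated (and KO-upregulated) fractions inside versus
#' outside the quadrant, over all quadrant-classified genes.
#'
#' @param integration an `IntegrationTable`.
#' @return list with `counts` (genes per quadrant) and `tables`
#'   (per-quadrant list of `ko_down`/`ko_up` 2x2 matrices; rows
#'   in/out of quadrant, columns call/other).
#' @export
quadrant_classify <- function(integration) {
  cl <- integration[integration$quadrant != "none", , drop = FALSE]
  quads <- c("UR", "UL", "LR", "LL")
  counts <- vapply(quads, function(q) sum(cl$quadrant == q), integer(1))
  tables <- lapply(quads, function(q) {
    inq <- cl$quadrant == q
    lapply(stats::setNames(c("down", "up"), c("ko_down", "ko_up")),
           function(dir) {
             m <- matrix(c(sum(inq & cl$ko_call == dir),
                           sum(inq & cl$ko_call != dir),
                           sum(!inq & cl$ko_call == dir),
                           sum(!inq & cl$ko_call != dir)),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("in_quadrant", "outside"),
                                         c(dir, "other")))
             m
           })
  })
  names(tables) <- quads
  list(counts = counts, n_classified = nrow(cl), tables = tables)
}

#' Fisher exact test on a 2x2 quadrant table
#'
#' Hypergeometric exact test: the two-sided p sums the probabilities of
#' all tables (fixed margins) no more probable than the observed one;
#' both one-sided tails are also reported since figure-level tests do
#' not state sidedness. The odds ratio uses the Haldane 0.5 correction
#' when any cell is zero.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return list: odds_ratio, p_two_sided, p_greater, p_less.
#' @export
fisher_quadrant <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0), all(m == round(m)))
  h <- if (any(m == 0)) 0.5 else 0
  or <- ((m[1, 1] + h) * (m[2, 2] + h)) / ((m[1, 2] + h) * (m[2, 1] + h))
  list(odds_ratio = or,
       p_two_sided = stats::fisher.test(m)$p.value,
       p_greater = stats::fisher.test(m, alternative = "greater")$p.value,
       p_less = stats::fisher.test(m, alternative = "less")$p.value)
}

#' Bin the integration table by maturational RNA change
#'
#' Bins are left-open right-closed (the "(a, b]" convention); per bin
#' and per variable (neonatal H2Bub1 signal and H2Bub1 delta) the
#' summary holds n, median, quartiles and whisker bounds (the most
#' extreme observations within quartile +/- 1.5 IQR).
#'
#' @param integration an `IntegrationTable`.
#' @param edges increasing bin edges over `rna_log2fc_maturation`.
#' @return data.frame: variable, bin, n, median, q1, q3, lo, hi.
#' @export
bin_delta_summary <- function(integration, edges) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  df <- integration[!is.na(integration$rna_log2fc_maturation) &
                      !is.na(integration$h2bub_delta), , drop = FALSE]
  x <- df$rna_log2fc_maturation
  if (any(x <= edges[1] | x > edges[length(edges)]))
    warning("bin edges do not cover the fold-change range; ",
            "outside genes dropped")
  bin <- cut(x, edges, right = TRUE)
  out <- list()
  for (v in c("h2bub_p1", "h2bub_delta")) {
    for (b in levels(bin)) {
      y <- df[[v]][!is.na(bin) & bin == b]
      y <- y[!is.na(y)]
      if (!length(y)) {
        out[[length(out) + 1L]] <- data.frame(
          variable = v, bin = b, n = 0L, median = NA_real_, q1 = NA_real_,
          q3 = NA_real_, lo = NA_real_, hi = NA_real_)
        next
      }
      q <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      out[[length(out) + 1L]] <- data.frame(
        variable = v, bin = b, n = length(y), median = q[2], q1 = q[1],
        q3 = q[3],
        lo = min(y[y >= q[1] - 1.5 * iqr]),
        hi = max(y[y <= q[3] + 1.5 * iqr]))
    }
  }
  do.call(rbind, out)
}
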