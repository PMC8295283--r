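# Alpha-restricted robust rank aggregation of guide-level statistics
# into gene scores.

# rho for one gene: sorted normalized ranks r, significance prefix j;
# min over k <= j of Beta(k, n-k+1) lower tail at r_k.
.rra_rho <- function(r_sorted, j) {
  n <- length(r_sorted)
  if (j == 0L) return(1)
  k <- seq_len(j)
  min(stats::pbeta(r_sorted[k], k, n - k + 1))
}

#' Gene-level robust rank aggregation of guide statistics
#'
#' Guides are ranked by one-sided p-value in the chosen direction
#' (derived from the signed Wald statistic); non-targeting guides stay
#' in the ranking but receive no gene score. Per gene, guides
#' significant at `alpha_p` contribute their normalized ranks, and the
#' gene score rho is the minimum over k of the Beta(k, n-k+1) lower-tail
#' probability of the k-th smallest normalized rank. The gene p-value
#' comes from permuting the guide-to-gene assignment (preserving
#' guides-per-gene counts), or from exhaustive enumeration of all guide
#' subsets when `exact = TRUE`.
#'
#' @param stats `GuideStatTable` from [guide_test()].
#' @param gene_map named vector guide_id -> gene_id; guides absent from
#'   the map (e.g. non-targeting controls) are ranked but unscored.
#' @param direction `"enrich"` or `"deplete"`.
#' @param alpha_p significance level restricting contributing guides
#'   (default 0.001). Set to 1 to let every guide contribute.
#' @param n_perm permutations (default 10000).
#' @param seed permutation seed.
#' @param exact exhaustively enumerate guide subsets per gene size
#'   (feasible for small libraries only).
#' @return `GeneScoreTable` data.frame: gene_id, n_guides, n_sig_guides
#'   (BH-adjusted two-sided p < 0.001), rho, p, rank (permutation p,
#'   ties broken by rho then gene id).
#' @export
gene_rra <- function(stats, gene_map, direction = c("enrich", "deplete"),
                     alpha_p = 0.001, n_perm = 10000L, seed = 1L,
                     exact = FALSE) {
  direction <- match.arg(direction)
  ok <- !stats$flagged & !is.na(stats$wald_stat)
  st <- stats[ok, , drop = FALSE]
  p_one <- if (direction == "enrich") stats::pnorm(-st$wald_stat) else
    stats::pnorm(st$wald_stat)
  ord <- order(p_one, st$guide_id)
  st <- st[ord, , drop = FALSE]
  p_one <- p_one[ord]
  N <- nrow(st)
  nr <- seq_len(N) / N
  sig <- p_one < alpha_p
  r_alpha <- if (any(sig)) max(nr[sig]) else 0
  gm <- gene_map[st$guide_id]
  genes <- sort(unique(gm[!is.na(gm)]))
  obs <- lapply(genes, function(g) {
    idx <- which(!is.na(gm) & gm == g)
    r <- sort(nr[idx])
    j <- sum(r <= r_alpha)
    list(n = length(idx), rho = .rra_rho(r, j),
         n_sig = sum(st$bh_adj_p[idx] < 0.001, na.rm = TRUE))
  })
  sizes <- vapply(obs, `[[`, 0L, "n")
  rhos <- vapply(obs, `[[`, 0, "rho")
  p <- rep(NA_real_, length(genes))
  for (n in unique(sizes)) {
    which_g <- which(sizes == n)
    if (exact) {
      if (choose(N, n) > 2e5)
        stop("exact enumeration infeasible for choose(", N, ", ", n, ")")
      subs <- utils::combn(N, n)
      null_rho <- apply(subs, 2, function(idx) {
        r <- nr[idx]
        .rra_rho(r, sum(r <= r_alpha))
      })
      for (g in which_g) p[g] <- mean(null_rho <= rhos[g])
    } else {
      null_rho <- with_stream(seed, "perm", {
        vapply(seq_len(n_perm), function(b) {
          r <- sort(nr[sample.int(N, n)])
          .rra_rho(r, sum(r <= r_alpha))
        }, numeric(1))
      })
      for (g in which_g)
        p[g] <- (1 + sum(null_rho <= rhos[g])) / (n_perm + 1)
    }
  }
  out <- data.frame(gene_id = genes, n_guides = sizes,
                    n_sig_guides = vapply(obs, `[[`, 0L, "n_sig"),
                    rho = rhos, p = p, stringsAsFactors = FALSE)
  ord <- order(out$p, out$rho, out$gene_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  names(out)[names(out) == "rho"] <- paste0(direction, "_rho")
  names(out)[names(out) == "p"] <- paste0(direction, "_p")
  out
}

#' Consolidated gene scores in both directions
#'
#' Runs [gene_rra()] for enrichment and depletion and merges the
#' results; `rank` orders genes by enrichment p.
#'
#' @inheritParams gene_rra
#' @return merged `GeneScoreTable`.
#' @export
gene_scores <- function(stats, gene_map, alpha_p = 0.001, n_perm = 10000L,
                        seed = 1L) {
  e <- gene_rra(stats, gene_map, "enrich", alpha_p, n_perm, seed)
  d <- gene_rra(stats, gene_map, "deplete", alpha_p, n_perm, seed)
  out <- merge(e[, c("gene_id", "n_guides", "n_sig_guides", "enrich_rho",
                     "enrich_p")],
               d[, c("gene_id", "deplete_rho", "deplete_p")], by = "gene_id")
  ord <- order(out$enrich_p, out$enrich_rho, out$gene_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out[ord, ]
}
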