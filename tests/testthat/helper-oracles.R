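# Independent brute-force oracles used to check the package's
# implementations on small instances.

# full-genome sliding-window off-target scan (naive O(L * 23))
oracle_offtargets <- function(spacer, seq, max_mm = 2L) {
  n <- integer(max_mm + 1L)
  L <- nchar(seq)
  spv <- strsplit(spacer, "")[[1]]
  rc1 <- function(x) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (s in seq_len(L - 22L)) {
    sub <- substr(seq, s, s + 22L)
    if (substr(sub, 22L, 23L) == "GG") {
      mm <- sum(strsplit(substr(sub, 1L, 20L), "")[[1]] != spv)
      if (mm <= max_mm) n[mm + 1L] <- n[mm + 1L] + 1L
    }
    if (substr(sub, 1L, 2L) == "CC") {
      mm <- sum(strsplit(rc1(substr(sub, 4L, 23L)), "")[[1]] != spv)
      if (mm <= max_mm) n[mm + 1L] <- n[mm + 1L] + 1L
    }
  }
  n
}

# exhaustive microhomology enumeration: collect every repeated >=2-mer
# pair across the cut, then drop patterns contained in a longer pattern
# implying the same deletion (set-filter formulation, independent of the
# package's incremental dedup)
oracle_oof <- function(w, cut) {
  n <- nchar(w)
  pats <- list()
  for (k in 2:min(cut, n - cut)) {
    for (i in 1:(cut - k + 1L)) {
      for (j in (cut + 1L):(n - k + 1L)) {
        if (substr(w, i, i + k - 1L) == substr(w, j, j + k - 1L))
          pats[[length(pats) + 1L]] <- c(i = i, j = j, k = k)
      }
    }
  }
  if (!length(pats)) return(0)
  keep <- rep(TRUE, length(pats))
  for (a in seq_along(pats)) {
    pa <- pats[[a]]
    for (b in seq_along(pats)) {
      pb <- pats[[b]]
      if (pb["k"] > pa["k"] && pa["i"] >= pb["i"] &&
          pa["i"] + pa["k"] <= pb["i"] + pb["k"] &&
          pa["j"] >= pb["j"] && pa["j"] + pa["k"] <= pb["j"] + pb["k"] &&
          pa["i"] - pb["i"] == pa["j"] - pb["j"]) {
        keep[a] <- FALSE
        break
      }
    }
  }
  pats <- pats[keep]
  tot <- 0
  oof <- 0
  for (p in pats) {
    mh <- substr(w, p["i"], p["i"] + p["k"] - 1L)
    gc <- nchar(gsub("[AT]", "", mh))
    sc <- 100 * exp(-(p["j"] - p["i"]) / 20) * ((p["k"] - gc) + 2 * gc)
    tot <- tot + sc
    if ((p["j"] - p["i"]) %% 3 != 0) oof <- oof + sc
  }
  as.numeric(100 * oof / tot)
}

# Beta lower tail via the binomial-sum identity (independent of pbeta)
oracle_beta_tail <- function(x, k, n) {
  stats::pbinom(k - 1, n, x, lower.tail = FALSE)
}

oracle_rra_rho <- function(ranks, r_alpha) {
  r <- sort(ranks)
  j <- sum(r <= r_alpha)
  if (j == 0L) return(1)
  n <- length(r)
  min(vapply(seq_len(j), function(k) oracle_beta_tail(r[k], k, n),
             numeric(1)))
}

# full running-sum GSEA ES (position-by-position)
oracle_gsea_es <- function(scores, members) {
  ord <- order(scores, decreasing = TRUE)
  ids <- names(scores)[ord]
  w <- abs(scores[ord])
  hit <- ids %in% members
  ph <- cumsum(w * hit) / sum(w[hit])
  pm <- cumsum(!hit) / sum(!hit)
  run <- ph - pm
  run[which.max(abs(run))]
}

# exact hypergeometric enumeration of all 2x2 tables with fixed margins
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  list(two = sum(probs[probs <= p_obs * (1 + 1e-7)]),
       greater = sum(probs[ks >= m[1, 1]]),
       less = sum(probs[ks <= m[1, 1]]))
}

# BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

# toy two-exon gene (CDS 120 + 180 bp) used across tests
toy_two_exon_gene <- function(strand = "+") {
  ex <- IRanges::IRanges(c(101L, 301L), c(220L, 480L))
  gene_model("toy", "chr1", strand,
             list(t1 = list(exons = ex, cds = ex)))
}

# 30-bp toy genome with a single forward NGG site whose cut falls in CDS
toy_pam_genome <- function() {
  base <- rep("A", 30L)
  base[c(2, 5, 9, 12, 16, 20)] <- "T"
  base[23:24] <- "G"
  paste(base, collapse = "")
}
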