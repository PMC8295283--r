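# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running
# sum (weight exponent 1), gene-label permutations.

# ES from sorted hit indices: running-sum extrema occur adjacent to
# hits, so only 2m candidate deviations need evaluating.
.gsea_es <- function(hit_idx, w, N) {
  m <- length(hit_idx)
  idx <- sort(hit_idx)
  wh <- w[idx]
  H <- cumsum(wh) / sum(wh)
  miss_after <- (idx - seq_len(m)) / (N - m)
  dev_after <- H - miss_after                       # just after each hit
  dev_before <- c(0, H[-m]) - (idx - 1 - (seq_len(m) - 1)) / (N - m)
  cand <- c(dev_after, dev_before)
  unname(cand[which.max(abs(cand))])
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ranked by a signed score (descending); the enrichment
#' score is the signed extremum of the weighted running sum with weight
#' exponent 1. The nominal p-value is the fraction of gene-label
#' permutations whose |ES| of matching sign reaches |ES|; NES divides
#' ES by the mean |permuted ES| of matching sign. Sets smaller than
#' `min_size` are refused unless `enforce_min_size = FALSE`.
#'
#' @param scores named numeric ranking metric (e.g. KO log2 fold-changes).
#' @param set a `GeneSet` (see [gene_set()]) or character vector of ids.
#' @param n_perm permutations (default 10000).
#' @param seed permutation seed.
#' @param weight running-sum weight exponent (default 1).
#' @param min_size minimum eligible set size (default 30).
#' @param enforce_min_size waive the floor (for tiny oracle instances).
#' @return `GseaResult` list: set, size, ES, NES, nominal_p, n_perm.
#' @export
gsea_preranked <- function(scores, set, n_perm = 10000L, seed = 1L,
                           weight = 1, min_size = 30L,
                           enforce_min_size = TRUE) {
  members <- if (is.list(set)) set$members else set
  set_name <- if (is.list(set)) set$name else deparse(substitute(set))
  stopifnot(!is.null(names(scores)))
  members <- unique(members)
  if (!all(members %in% names(scores)))
    stop("set is not a subset of the ranked universe", call. = FALSE)
  m <- length(members)
  if (enforce_min_size && m < min_size)
    stop("set has fewer than ", min_size, " genes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  w <- abs(scores[ord])^weight
  N <- length(ranked)
  if (m >= N) stop("set must be smaller than the universe", call. = FALSE)
  es <- .gsea_es(which(ranked %in% members), w, N)
  perm_es <- with_stream(seed, "perm", {
    vapply(seq_len(n_perm), function(b) {
      .gsea_es(sample.int(N, m), w, N)
    }, numeric(1))
  })
  same <- perm_es[sign(perm_es) == sign(es)]
  nominal_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  structure(list(set = set_name, size = m, ES = es, NES = nes,
                 nominal_p = nominal_p, n_perm = n_perm),
            class = "GseaResult")
}

#' @export
print.GseaResult <- function(x, ...) {
  cat(sprintf("GseaResult '%s' (n=%d): ES=%.3f NES=%.3f p=%.4g\n",
              x$set, x$size, x$ES, x$NES, x$nominal_p))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param members unique gene ids.
#' @return `GeneSet` list.
#' @export
gene_set <- function(name, members) {
  list(name = name, members = unique(as.character(members)))
}
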