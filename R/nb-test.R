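# Negative-binomial Wald core: median-of-ratios normalization,
# method-of-moments dispersion shrunk toward a mean-dispersion trend,
# vectorized IRLS for the two-group log-linear model.

#' Median-of-ratios size factors
#'
#' Per sample, the median over features of count / geometric-mean-
#' across-samples, computed over features with all-nonzero rows. When no
#' all-nonzero row exists, falls back (with a warning) to rows nonzero
#' in at least 90% of samples, with geometric means and ratios over
#' positive entries only.
#'
#' @param counts feature x sample matrix of non-negative counts.
#' @return named per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub / ref, 2, stats::median)
  } else {
    warning("no feature nonzero in all samples; ",
            "using features nonzero in >= 90% of samples")
    ok <- rowMeans(counts > 0) >= 0.9
    if (!any(ok)) stop("no usable features for size factors", call. = FALSE)
    sub <- counts[ok, , drop = FALSE]
    ref <- exp(apply(sub, 1, function(r) mean(log(r[r > 0]))))
    sf <- vapply(seq_len(ncol(sub)), function(j) {
      r <- sub[, j] / ref
      r <- r[sub[, j] > 0]
      if (!length(r)) NA_real_ else stats::median(r)
    }, numeric(1))
  }
  if (anyNA(sf)) {
    warning("sample(s) with no usable counts; size factor set to 1")
    sf[is.na(sf)] <- 1
  }
  stats::setNames(sf, colnames(counts))
}

# Vectorized IRLS for y_ij ~ NB(mu_ij, alpha_i),
# log mu_ij = log sf_j + b0_i + b1_i x_j, x binary. Tiny ridge keeps
# degenerate (all-zero group) fits finite.
.nb_irls <- function(counts, x, sf, alpha, maxit = 30L, ridge = 1e-6) {
  G <- nrow(counts)
  N <- ncol(counts)
  o <- matrix(log(sf), G, N, byrow = TRUE)
  xm <- matrix(x, G, N, byrow = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  m_in <- rowMeans(norm[, x == 0, drop = FALSE])
  m_so <- rowMeans(norm[, x == 1, drop = FALSE])
  b0 <- log(m_in + 0.1)
  b1 <- log(m_so + 0.1) - b0
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(o + b0 + b1 * xm, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    Z <- (eta - o) + (counts - mu) / mu
    A <- rowSums(W)
    B <- rowSums(W * xm)
    P <- rowSums(W * Z)
    Q <- rowSums(W * Z * xm)
    det <- (A + ridge) * (B + ridge) - B * B
    b0n <- ((B + ridge) * P - B * Q) / det
    b1n <- ((A + ridge) * Q - B * P) / det
    if (max(abs(b0n - b0), abs(b1n - b1), na.rm = TRUE) < 1e-10) {
      b0 <- b0n; b1 <- b1n
      break
    }
    b0 <- b0n
    b1 <- b1n
  }
  eta <- pmin(pmax(o + b0 + b1 * xm, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  A <- rowSums(W)
  B <- rowSums(W * xm)
  det0 <- A * B - B * B
  se1 <- sqrt(ifelse(det0 > 0, A / det0, NA_real_))
  list(b0 = b0, b1 = b1, se1 = se1, base_mean = rowMeans(norm))
}

# MoM dispersion per feature, shrunk 50/50 (log scale) toward a
# log-linear mean-dispersion trend; floored at 1e-8.
.dispersion_estimates <- function(counts, x, sf) {
  norm <- sweep(counts, 2, sf, "/")
  grp <- split(seq_len(ncol(counts)), x)
  ss <- 0
  df <- 0
  mu_bar <- rowMeans(norm)
  for (g in grp) {
    if (length(g) < 2L) next
    sub <- norm[, g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + (length(g) - 1L)
  }
  s2 <- ss / df
  raw <- pmax((s2 - mu_bar) / mu_bar^2, 1e-8)
  use <- is.finite(raw) & raw > 1e-8 & mu_bar > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(log(raw[use]) ~ log(mu_bar[use]))
    trend <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * log(mu_bar))
  } else {
    trend <- rep(stats::median(raw[is.finite(raw)]), length(raw))
  }
  trend[!is.finite(trend)] <- stats::median(raw[is.finite(raw)])
  pmax(exp(0.5 * log(raw) + 0.5 * log(pmax(trend, 1e-8))), 1e-8)
}

# Shared NB-Wald two-group test. condition: factor-like with reference
# level first; returns one row per feature.
nb_wald <- function(counts, condition, sf = NULL) {
  counts <- as.matrix(counts)
  lev <- unique(condition)
  stopifnot(length(lev) == 2L)
  x <- as.integer(condition == lev[2])
  if (is.null(sf)) sf <- size_factors(counts)
  usable <- rowSums(counts) > 0
  res <- data.frame(feature_id = rownames(counts),
                    base_mean = NA_real_, log2fc = NA_real_,
                    wald_se = NA_real_, wald_stat = NA_real_,
                    wald_p = NA_real_, bh_adj_p = NA_real_,
                    flagged = !usable, stringsAsFactors = FALSE)
  if (any(usable)) {
    sub <- counts[usable, , drop = FALSE]
    alpha <- .dispersion_estimates(sub, x, sf)
    fit <- .nb_irls(sub, x, sf, alpha)
    stat <- fit$b1 / fit$se1
    res$base_mean[usable] <- fit$base_mean
    res$log2fc[usable] <- fit$b1 / log(2)
    res$wald_se[usable] <- fit$se1 / log(2)
    res$wald_stat[usable] <- stat
    res$wald_p[usable] <- 2 * stats::pnorm(-abs(stat))
    res$bh_adj_p[usable] <- stats::p.adjust(res$wald_p[usable], "BH")
  }
  attr(res, "dispersion") <- if (any(usable)) alpha else numeric(0)
  attr(res, "size_factors") <- sf
  res
}

#' Per-guide differential representation test (sorted vs input)
#'
#' NB log-linear model with sample role as the single covariate:
#' median-of-ratios normalization, per-guide method-of-moments
#' dispersion shrunk toward a mean-dispersion trend, Wald statistic
#' log2fc / se against the normal null, BH correction across testable
#' guides. Guides with zero counts in both roles are flagged and
#' excluded from the BH denominator. Only QC-passing samples are used
#' when a `QCReport` is supplied.
#'
#' @param table a `GuideCountTable`.
#' @param qc optional `QCReport` from [sample_qc()].
#' @return `GuideStatTable` data.frame: guide_id, gene_id, base_mean,
#'   log2fc (sorted vs input), wald_se, wald_stat, wald_p, bh_adj_p,
#'   flagged.
#' @export
guide_test <- function(table, qc = NULL) {
  counts <- table$counts
  roles <- table$sample_roles
  if (!is.null(qc)) {
    keep <- qc$sample[qc$pass]
    counts <- counts[, colnames(counts) %in% keep, drop = FALSE]
    roles <- roles[colnames(counts)]
  }
  if (sum(roles == "input") < 2L || sum(roles == "sorted") < 2L)
    stop("need >= 2 QC-passing samples per role", call. = FALSE)
  res <- nb_wald(counts, factor(roles, levels = c("input", "sorted")))
  names(res)[names(res) == "feature_id"] <- "guide_id"
  res$gene_id <- sub("\\|.*$", "", res$guide_id)
  res$gene_id[!grepl("|", res$guide_id, fixed = TRUE)] <- NA_character_
  res[, c("guide_id", "gene_id", "base_mean", "log2fc", "wald_se",
          "wald_stat", "wald_p", "bh_adj_p", "flagged")]
}
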