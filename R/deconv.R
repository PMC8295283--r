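# Screen deconvolution: FASTQ -> spacers -> guide counts -> sample QC.

#' Trim screen reads to the 20-bp guide variable region
#'
#' A read yields a spacer iff the 5' adapter occurs (at most one
#' mismatch), is followed by at least 20 nt, and the 3' scaffold anchor
#' follows that variable region (at most one mismatch). The reported
#' spacer is the last 20 nt of the variable region, which strips the 5'
#' G prepended during cloning from 21-nt inserts. Quality strings are
#' ignored.
#'
#' @param fastq path to a FASTQ file (gzip allowed).
#' @param adapter5,scaffold3 anchor sequences (defaults
#'   [screen_adapter5()], [screen_scaffold3()]).
#' @return list with `spacers` (one per retained read), `n_reads`, and
#'   `discarded` (named counts by reason: `no_adapter`, `no_scaffold`,
#'   `short_variable`).
#' @export
trim_reads <- function(fastq, adapter5 = screen_adapter5(),
                       scaffold3 = screen_scaffold3()) {
  reads <- tryCatch(
    unname(as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))),
    error = function(e) stop("malformed FASTQ (", fastq, "): ",
                             conditionMessage(e), call. = FALSE))
  n <- length(reads)
  discarded <- c(no_adapter = 0L, no_scaffold = 0L, short_variable = 0L)
  if (n == 0L) return(list(spacers = character(0), n_reads = 0L,
                           discarded = discarded))
  dna <- Biostrings::DNAStringSet(reads)
  am <- Biostrings::vmatchPattern(adapter5, dna, max.mismatch = 1L)
  sm <- Biostrings::vmatchPattern(scaffold3, dna, max.mismatch = 1L)
  spacers <- character(0)
  for (i in seq_len(n)) {
    a <- am[[i]]
    if (length(a) == 0L) {
      discarded["no_adapter"] <- discarded["no_adapter"] + 1L
      next
    }
    aend <- BiocGenerics::end(a)[1]
    s <- sm[[i]]
    sstart <- BiocGenerics::start(s)
    sstart <- sstart[sstart >= aend + 21L]
    if (length(sstart) == 0L) {
      # distinguish a scaffold that exists but leaves <20 nt
      if (length(BiocGenerics::start(s)[BiocGenerics::start(s) > aend])) {
        discarded["short_variable"] <- discarded["short_variable"] + 1L
      } else {
        discarded["no_scaffold"] <- discarded["no_scaffold"] + 1L
      }
      next
    }
    var_region <- substr(reads[i], aend + 1L, sstart[1] - 1L)
    spacers <- c(spacers, substr(var_region, nchar(var_region) - 19L,
                                 nchar(var_region)))
  }
  list(spacers = spacers, n_reads = n, discarded = discarded)
}

#' Count trimmed spacers against the designed library
#'
#' Exact-match assignment to the library's 20-mers as designed (any
#' cloning G was already stripped by [trim_reads()]); non-matching
#' spacers are tallied as unassigned. Assigned + unassigned equals the
#' number of input spacers.
#'
#' @param spacers character vector of 20-nt spacers.
#' @param library a `GuideLibrary` (duplicate spacers are an error).
#' @return list with `counts` (named integer over all library guides and
#'   controls) and `unassigned`.
#' @export
count_guides <- function(spacers, library) {
  validate_guide_library(library, k = max(table(library$guides$gene_id), 6L))
  dict <- stats::setNames(guide_ids(library),
                          c(library$guides$spacer, library$controls$spacer))
  ids <- dict[spacers]
  counts <- stats::setNames(integer(length(dict)), unname(dict))
  tab <- table(ids[!is.na(ids)])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, unassigned = sum(is.na(ids)))
}

#' Deconvolve FASTQ files into a guide count table
#'
#' @param fastqs named character vector of FASTQ paths (names = samples).
#' @param library a `GuideLibrary`.
#' @param sample_roles named role vector (`"input"`/`"sorted"`).
#' @param adapter5,scaffold3 anchors passed to [trim_reads()].
#' @return a `GuideCountTable` with per-sample unassigned counts.
#' @export
deconvolve_fastq <- function(fastqs, library, sample_roles,
                             adapter5 = screen_adapter5(),
                             scaffold3 = screen_scaffold3()) {
  cols <- lapply(fastqs, function(p) {
    tr <- trim_reads(p, adapter5, scaffold3)
    c(count_guides(tr$spacers, library),
      list(discarded = sum(tr$discarded), n_reads = tr$n_reads))
  })
  counts <- vapply(cols, function(x) x$counts,
                   numeric(length(cols[[1]]$counts)))
  rownames(counts) <- names(cols[[1]]$counts)
  colnames(counts) <- names(fastqs)
  tab <- guide_count_table(counts, sample_roles,
                           vapply(cols, function(x) as.integer(x$unassigned),
                                  integer(1)))
  attr(tab, "discarded") <- vapply(cols, function(x) as.integer(x$discarded),
                                   integer(1))
  tab
}

#' Three-criterion sample quality control
#'
#' Reproduces the screen's sample-exclusion logic: a sorted sample fails
#' when its positive-control (spike) guides are insufficiently enriched
#' over the input mean; any sample fails when its mean Pearson
#' correlation (log1p of median-of-ratios-normalized counts) with its
#' own role group does not exceed its mean correlation with the other
#' group by more than `clustering_margin`; any sample fails when fewer
#' than `coverage` of library guides are detected.
#'
#' @param table a `GuideCountTable`.
#' @param positive_guides ids of spiked positive-control guides.
#' @param thresholds list: `control_log2` (default 1), `coverage`
#'   (default 0.5), `clustering_margin` (default 0).
#' @return `QCReport` data.frame: sample, role, control_enrichment,
#'   clustering_margin, coverage, pass, reasons.
#' @export
sample_qc <- function(table, positive_guides = character(0),
                      thresholds = list(control_log2 = 1, coverage = 0.5,
                                        clustering_margin = 0)) {
  counts <- table$counts
  roles <- table$sample_roles
  if (length(unique(roles)) < 2L)
    stop("need both input and sorted samples", call. = FALSE)
  alive <- colSums(counts) > 0
  sf <- rep(1, ncol(counts))
  names(sf) <- colnames(counts)
  if (any(alive)) sf[alive] <- size_factors(counts[, alive, drop = FALSE])
  norm <- sweep(counts, 2, sf, "/")
  lg <- log1p(norm)
  cm <- stats::cor(lg)
  n_s <- ncol(counts)
  clust <- vapply(seq_len(n_s), function(j) {
    own <- which(roles == roles[j])
    own <- setdiff(own, j)
    oth <- which(roles != roles[j])
    if (length(own) == 0L) return(NA_real_)
    mean(cm[j, own]) - mean(cm[j, oth])
  }, numeric(1))
  coverage <- colMeans(counts > 0)
  pos <- intersect(positive_guides, rownames(norm))
  ctrl_enr <- rep(NA_real_, n_s)
  if (length(pos)) {
    ab <- colSums(norm[pos, , drop = FALSE])
    in_mean <- mean(ab[roles == "input"])
    ctrl_enr[roles == "sorted"] <- log2((ab[roles == "sorted"] + 0.5) /
                                          (in_mean + 0.5))
  }
  reasons <- character(n_s)
  pass <- rep(TRUE, n_s)
  for (j in seq_len(n_s)) {
    rs <- character(0)
    if (roles[j] == "sorted" && length(pos) &&
        ctrl_enr[j] < thresholds$control_log2)
      rs <- c(rs, "control_enrichment")
    if (!is.na(clust[j]) && clust[j] <= thresholds$clustering_margin)
      rs <- c(rs, "clustering")
    if (coverage[j] < thresholds$coverage) rs <- c(rs, "coverage")
    if (length(rs)) {
      pass[j] <- FALSE
      reasons[j] <- paste(rs, collapse = ";")
    }
  }
  out <- data.frame(sample = colnames(counts), role = unname(roles),
                    control_enrichment = ctrl_enr,
                    clustering_margin = clust, coverage = coverage,
                    pass = pass, reasons = reasons,
                    stringsAsFactors = FALSE)
  class(out) <- c("QCReport", "data.frame")
  out
}
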