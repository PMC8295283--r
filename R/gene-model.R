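#' Gene models
#'
#' A `GeneModel` is the unit of annotation used throughout the package:
#' one gene with its transcript isoforms, each a set of exon intervals and
#' CDS intervals on the genome. Coordinates are 1-based inclusive (the
#' native R/Bioconductor convention); GTF input/output uses the same
#' convention, BED export is 0-based half-open.
#'
#' @param gene_id,chrom,strand gene identifier, contig name, "+" or "-".
#' @param transcripts named list; each element a list with `exons` and
#'   `cds`, both [IRanges::IRanges] objects.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  gm <- structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                       transcripts = transcripts), class = "GeneModel")
  validate_gene_model(gm)
  gm
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s) %d transcript(s), span %d-%d\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts),
              gene_span(x)[1], gene_span(x)[2]))
  invisible(x)
}

#' Validate GeneModel invariants
#'
#' Checks that exons within each transcript are sorted and non-overlapping,
#' that every CDS interval is contained in an exon, and that the total CDS
#' length per transcript is positive and divisible by 3.
#'
#' @param gm a `GeneModel`.
#' @return invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_gene_model <- function(gm) {
  stopifnot(inherits(gm, "GeneModel"))
  if (!gm$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(gm$transcripts) < 1L) stop(gm$gene_id, ": gene has no transcripts")
  for (tx_id in names(gm$transcripts)) {
    tx <- gm$transcripts[[tx_id]]
    ex <- tx$exons
    if (length(ex) == 0L) stop(tx_id, ": transcript has no exons")
    st <- IRanges::start(ex)
    if (is.unsorted(st, strictly = TRUE))
      stop(tx_id, ": exons not sorted")
    if (length(ex) > 1L && any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      stop(tx_id, ": exons overlap")
    cds <- tx$cds
    if (sum(IRanges::width(cds)) <= 0L)
      stop(tx_id, ": CDS length must be > 0")
    if (sum(IRanges::width(cds)) %% 3L != 0L)
      stop(tx_id, ": CDS length not a multiple of 3")
    ov <- IRanges::countOverlaps(cds, ex, type = "within")
    if (any(ov == 0L)) stop(tx_id, ": CDS interval not contained in an exon")
  }
  invisible(TRUE)
}

gene_span <- function(gm) {
  ex <- unlist(lapply(gm$transcripts, function(t) c(IRanges::start(t$exons),
                                                    IRanges::end(t$exons))))
  c(min(ex), max(ex))
}

#' Constitutive exonic intervals of a gene
#'
#' Returns the genomic bases present in the exon set of *every* transcript
#' isoform, as maximal intervals. These are the regions a knockout guide
#' can target without isoform escape.
#'
#' @param gm a `GeneModel`.
#' @return an [IRanges::IRanges] of maximal constitutive intervals (may be
#'   empty when isoform exon sets are disjoint).
#' @export
constitutive_exons <- function(gm) {
  stopifnot(inherits(gm, "GeneModel"))
  if (length(gm$transcripts) == 0L) stop("gene has zero transcripts")
  acc <- IRanges::reduce(gm$transcripts[[1]]$exons)
  for (tx in gm$transcripts[-1]) {
    acc <- IRanges::intersect(acc, IRanges::reduce(tx$exons))
    if (length(acc) == 0L) break
  }
  IRanges::reduce(acc)
}

# Coding bases 5' of a cut boundary, in translation order, for one
# transcript. The boundary `b` means the cut falls between genomic
# positions b and b+1.
.cds_bases_5prime <- function(tx, strand, b) {
  cds <- tx$cds
  if (strand == "+") {
    sum(pmax(0L, pmin(IRanges::end(cds), b) - IRanges::start(cds) + 1L))
  } else {
    sum(pmax(0L, IRanges::end(cds) - pmax(IRanges::start(cds), b + 1L) + 1L))
  }
}

.cds_contains_boundary <- function(tx, b) {
  cds <- tx$cds
  b >= min(IRanges::start(cds)) - 1L && b <= max(IRanges::end(cds))
}

#' Position of a cut within a gene's coding sequence, as a percent
#'
#' The Cas9 blunt cut falls between genomic positions `cut_pos` and
#' `cut_pos + 1`. The score is 100 x (coding bases strictly 5' of the cut
#' in translation order) / (total CDS length), computed on the
#' longest-CDS transcript whose CDS span contains the cut. A cut at the
#' first coding base scores 0; a cut immediately after the last coding
#' base scores 100.
#'
#' @param gm a `GeneModel`.
#' @param cut_pos genomic coordinate of the base immediately 5' (forward
#'   sense) of the blunt cut.
#' @return percent in `[0, 100]`, or `NA_real_` (with attribute
#'   `undefined = TRUE`) when the cut lies in no transcript's CDS.
#' @export
cds_percent <- function(gm, cut_pos) {
  stopifnot(inherits(gm, "GeneModel"))
  b <- as.integer(cut_pos)
  cand <- Filter(function(tx) .cds_contains_boundary(tx, b), gm$transcripts)
  if (length(cand) == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  lens <- vapply(cand, function(tx) sum(IRanges::width(tx$cds)), integer(1))
  tx <- cand[[which.max(lens)]]
  total <- sum(IRanges::width(tx$cds))
  100 * .cds_bases_5prime(tx, gm$strand, b) / total
}

# TRUE when both bases flanking the boundary are coding in >=1 transcript
# (a blunt cut inside coding sequence).
cut_in_cds <- function(gm, b) {
  for (tx in gm$transcripts) {
    cds <- tx$cds
    in5 <- any(IRanges::start(cds) <= b & b <= IRanges::end(cds))
    in3 <- any(IRanges::start(cds) <= b + 1L & b + 1L <= IRanges::end(cds))
    if (in5 && in3) return(TRUE)
  }
  FALSE
}

# first-TSS-to-last-TSE span length (gene length for ChIP schemes)
#' Gene length from first transcription start to last transcription end
#' @param gm a `GeneModel`.
#' @return span length in bp.
#' @export
gene_length <- function(gm) {
  sp <- gene_span(gm)
  sp[2] - sp[1] + 1L
}

#' Write gene models as GTF (v2.2 dialect)
#'
#' Emits gene, transcript, exon and CDS features, 1-based inclusive, with
#' `gene_id`/`transcript_id` attributes and computed CDS frames.
#'
#' @param genemodels list of `GeneModel`.
#' @param path output file.
#' @export
write_gtf <- function(genemodels, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s, e, strand, frame, attrs) {
    sprintf("%s\tcrisprmat\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, feat, s, e, strand, frame, attrs)
  }
  for (gm in genemodels) {
    sp <- gene_span(gm)
    ga <- sprintf('gene_id "%s";', gm$gene_id)
    lines <- c(lines, fmt(gm$chrom, "gene", sp[1], sp[2], gm$strand, ".", ga))
    for (tx_id in names(gm$transcripts)) {
      tx <- gm$transcripts[[tx_id]]
      ta <- sprintf('gene_id "%s"; transcript_id "%s";', gm$gene_id, tx_id)
      lines <- c(lines, fmt(gm$chrom, "transcript",
                            min(IRanges::start(tx$exons)),
                            max(IRanges::end(tx$exons)), gm$strand, ".", ta))
      for (i in seq_along(tx$exons)) {
        lines <- c(lines, fmt(gm$chrom, "exon", IRanges::start(tx$exons)[i],
                              IRanges::end(tx$exons)[i], gm$strand, ".", ta))
      }
      cds <- tx$cds
      ord <- if (gm$strand == "+") order(IRanges::start(cds)) else
        order(IRanges::start(cds), decreasing = TRUE)
      cum <- 0L
      for (i in ord) {
        frame <- (3L - (cum %% 3L)) %% 3L
        lines <- c(lines, fmt(gm$chrom, "CDS", IRanges::start(cds)[i],
                              IRanges::end(cds)[i], gm$strand, frame, ta))
        cum <- cum + IRanges::width(cds)[i]
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' @param path GTF file with gene/transcript/exon/CDS features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @return named list of `GeneModel` objects.
#' @export
read_gtf_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  out <- list()
  for (gid in unique(df$gene_id[df$type %in% c("exon", "CDS")])) {
    sub <- df[df$gene_id == gid & df$type %in% c("exon", "CDS"), ]
    txs <- list()
    for (tid in unique(sub$transcript_id)) {
      ts <- sub[sub$transcript_id == tid, ]
      ex <- ts[ts$type == "exon", ]
      cd <- ts[ts$type == "CDS", ]
      ex <- ex[order(ex$start), ]
      cd <- cd[order(cd$start), ]
      txs[[tid]] <- list(exons = IRanges::IRanges(ex$start, ex$end),
                         cds = IRanges::IRanges(cd$start, cd$end))
    }
    out[[gid]] <- gene_model(gid, as.character(sub$seqnames[1]),
                             as.character(sub$strand[1]), txs)
  }
  out
}
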