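# Candidate-site discovery and off-target profiling (SpCas9, NGG PAM).
# The blunt cut falls between protospacer positions 17 and 18, i.e. 3 bp
# 5' of the PAM.

#' Extract all PAM-adjacent protospacers of a genome
#'
#' Scans both strands for NGG PAMs and records every 20-nt protospacer
#' with its strand-sequence, coordinates and cut boundary. The returned
#' index is the substrate for [count_offtargets()] and
#' [find_candidate_sites()].
#'
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with columns chrom, start, end, strand, proto
#'   (protospacer read 5'->3' on its strand), pam, cut_pos (genomic
#'   coordinate of the forward-strand base immediately 5' of the cut).
#' @export
protospacer_index <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  res <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    dna <- Biostrings::DNAString(seq)
    # forward: GG at g..g+1 -> PAM g-1..g+1, protospacer g-21..g-2
    gg <- Biostrings::start(Biostrings::matchPattern("GG", dna))
    gg <- gg[gg >= 22L]
    if (length(gg)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = gg - 21L, end = gg - 2L, strand = "+",
        proto = substring(seq, gg - 21L, gg - 2L),
        pam = substring(seq, gg - 1L, gg + 1L),
        cut_pos = gg - 5L, stringsAsFactors = FALSE)
    }
    # reverse: CC at c..c+1 (forward) -> protospacer at c+3..c+22 (minus)
    cc <- Biostrings::start(Biostrings::matchPattern("CC", dna))
    cc <- cc[cc + 22L <= L]
    if (length(cc)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = cc + 3L, end = cc + 22L, strand = "-",
        proto = revcomp(substring(seq, cc + 3L, cc + 22L)),
        pam = revcomp(substring(seq, cc, cc + 2L)),
        cut_pos = cc + 5L, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      proto = character(), pam = character(),
                      cut_pos = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count genomic off-target sites at 0, 1 and 2 mismatches
#'
#' For each query spacer, counts NGG-adjacent genomic sites (either
#' strand) whose protospacer matches with exactly 0, 1 or 2 mismatches
#' over the 20 protospacer bases (the PAM N position is free). The
#' on-target locus is included in the 0-mismatch count, so a uniquely
#' targeting spacer that exists in the genome reports `(1, 0, 0)`.
#' Genomic N bases never match.
#'
#' @param spacers character vector of 20-nt spacers (ACGT only).
#' @param genome named character vector of chromosomes, or a
#'   pre-computed [protospacer_index()] data.frame.
#' @param max_mm maximum mismatch count profiled (default 2).
#' @return integer matrix, one row per spacer, columns `n0..n<max_mm>`.
#' @export
count_offtargets <- function(spacers, genome, max_mm = 2L) {
  if (any(nchar(spacers) != 20L))
    stop("spacers must be 20 nt", call. = FALSE)
  if (any(grepl("[^ACGT]", spacers)))
    stop("spacers must contain only A, C, G, T", call. = FALSE)
  idx <- if (is.data.frame(genome)) genome else protospacer_index(genome)
  m <- mm_profile_cpp(spacers, idx$proto, as.integer(max_mm))
  dimnames(m) <- list(spacers, paste0("n", 0:max_mm))
  m
}

#' Find candidate guide sites within a gene's coding sequence
#'
#' Enumerates every NGG protospacer (either strand) whose blunt cut falls
#' inside exonic CDS of the gene, annotating the CDS-position percent and
#' whether the cut lies in constitutive exonic sequence (present in every
#' isoform).
#'
#' @param gm a `GeneModel`.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame of candidate sites (possibly empty): gene_id,
#'   spacer, pam, chrom, strand, start, end, cut_pos, cds_percent,
#'   constitutive.
#' @export
find_candidate_sites <- function(gm, genome) {
  stopifnot(inherits(gm, "GeneModel"))
  seq <- genome[[gm$chrom]]
  if (is.null(seq)) stop("gene chromosome not present in genome")
  total_cds <- sum(vapply(gm$transcripts,
                          function(tx) sum(IRanges::width(tx$cds)), numeric(1)))
  if (total_cds == 0) {
    warning(gm$gene_id, ": gene has no CDS; no candidate sites")
    return(.empty_sites())
  }
  sp <- gene_span(gm)
  lo <- max(1L, sp[1] - 25L)
  hi <- min(nchar(seq), sp[2] + 25L)
  region <- substr(seq, lo, hi)
  idx <- protospacer_index(stats::setNames(region, gm$chrom))
  if (nrow(idx) == 0L) return(.empty_sites())
  idx$start <- idx$start + lo - 1L
  idx$end <- idx$end + lo - 1L
  idx$cut_pos <- idx$cut_pos + lo - 1L
  keep <- vapply(idx$cut_pos, function(b) cut_in_cds(gm, b), logical(1))
  idx <- idx[keep & !grepl("[^ACGT]", idx$proto), , drop = FALSE]
  if (nrow(idx) == 0L) return(.empty_sites())
  const_iv <- constitutive_exons(gm)
  is_const <- vapply(idx$cut_pos, function(b) {
    any(IRanges::start(const_iv) <= b & b + 1L <= IRanges::end(const_iv))
  }, logical(1))
  data.frame(gene_id = gm$gene_id, spacer = idx$proto, pam = idx$pam,
             chrom = idx$chrom, strand = idx$strand, start = idx$start,
             end = idx$end, cut_pos = idx$cut_pos,
             cds_percent = vapply(idx$cut_pos,
                                  function(b) as.numeric(cds_percent(gm, b)),
                                  numeric(1)),
             constitutive = is_const, stringsAsFactors = FALSE)
}

.empty_sites <- function() {
  data.frame(gene_id = character(), spacer = character(), pam = character(),
             chrom = character(), strand = character(), start = integer(),
             end = integer(), cut_pos = integer(), cds_percent = numeric(),
             constitutive = logical(), stringsAsFactors = FALSE)
}

#' Sequence window centered on a cut boundary
#'
#' Returns up to `flank` bases on each side of the blunt cut for
#' microhomology scoring; windows truncated at a contig edge carry a
#' `truncated` attribute.
#'
#' @param genome named character vector.
#' @param chrom,cut_pos cut location (boundary between `cut_pos` and
#'   `cut_pos + 1`).
#' @param flank bases per side (default 30).
#' @return character window with attribute `cut` (left-side length).
#' @export
cut_window <- function(genome, chrom, cut_pos, flank = 30L) {
  seq <- genome[[chrom]]
  lo <- max(1L, cut_pos - flank + 1L)
  hi <- min(nchar(seq), cut_pos + flank)
  w <- substr(seq, lo, hi)
  attr(w, "cut") <- cut_pos - lo + 1L
  attr(w, "truncated") <- (lo != cut_pos - flank + 1L) || (hi != cut_pos + flank)
  w
}
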