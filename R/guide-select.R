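#' The five-tier guide selection rule cascade
#'
#' Rules are applied in order, each only if the running candidate set
#' still holds fewer than the requested number of guides: (1)
#' constitutive exons, CDS 5-50%, mismatch profile 1,0,0, out-of-frame
#' score > 60; (2) constitutive, CDS 5-80%, profile 1,N,N, OOF > 60; (3)
#' any exon, CDS 5-80%, 1,N,N, OOF > 60; (4) any exon, CDS 5-80%, N,N,N,
#' OOF > 60; (5) any exon, any CDS, N,N,N, any OOF. `NA` entries are
#' unconstrained.
#'
#' @return data.frame, one row per tier.
#' @export
selection_rules <- function() {
  data.frame(tier = 1:5,
             require_constitutive = c(TRUE, TRUE, FALSE, FALSE, FALSE),
             cds_min = c(5, 5, 5, 5, 0),
             cds_max = c(50, 80, 80, 80, 100),
             n0_exact = c(1L, 1L, 1L, NA, NA),
             n1_max = c(0L, NA, NA, NA, NA),
             n2_max = c(0L, NA, NA, NA, NA),
             oof_min = c(60, 60, 60, 60, NA))
}

#' Select guides for one gene through the rule cascade
#'
#' Candidates are admitted at the most stringent tier whose predicate
#' they satisfy, rules applied sequentially until `k` guides are
#' collected. Within a tier, ties are broken by out-of-frame score
#' (descending), then CDS percent (ascending, preferring 5'-biased
#' cuts), then genomic cut coordinate; no spacer is selected twice.
#'
#' @param candidates data.frame from [find_candidate_sites()] augmented
#'   with `n0`, `n1`, `n2` and `oof_score` columns.
#' @param rules rule table, by default [selection_rules()].
#' @param k number of guides to select (default 6).
#' @return data.frame of selected guides with a `tier` column; when the
#'   gene has zero candidates the result is empty with attribute
#'   `undesignable = TRUE`.
#' @export
select_guides <- function(candidates, rules = selection_rules(), k = 6L) {
  need_cols <- c("spacer", "cds_percent", "constitutive", "n0", "n1", "n2",
                 "oof_score", "cut_pos")
  if (nrow(candidates) == 0L) {
    out <- cbind(candidates, tier = integer(0))
    attr(out, "undesignable") <- TRUE
    return(out)
  }
  stopifnot(all(need_cols %in% colnames(candidates)))
  selected <- NULL
  for (r in seq_len(nrow(rules))) {
    if (!is.null(selected) && nrow(selected) >= k) break
    rule <- rules[r, ]
    ok <- (!rule$require_constitutive | candidates$constitutive) &
      candidates$cds_percent >= rule$cds_min &
      candidates$cds_percent <= rule$cds_max &
      (is.na(rule$n0_exact) | candidates$n0 == rule$n0_exact) &
      (is.na(rule$n1_max) | candidates$n1 <= rule$n1_max) &
      (is.na(rule$n2_max) | candidates$n2 <= rule$n2_max) &
      (is.na(rule$oof_min) | candidates$oof_score > rule$oof_min)
    ok[is.na(ok)] <- FALSE
    pool <- candidates[ok, , drop = FALSE]
    if (!is.null(selected)) pool <- pool[!pool$spacer %in% selected$spacer, , drop = FALSE]
    if (nrow(pool) == 0L) next
    pool <- pool[order(-pool$oof_score, pool$cds_percent, pool$cut_pos), , drop = FALSE]
    pool <- pool[!duplicated(pool$spacer), , drop = FALSE]
    have <- if (is.null(selected)) 0L else nrow(selected)
    take <- utils::head(pool, k - have)
    take$tier <- rule$tier
    selected <- if (is.null(selected)) take else rbind(selected, take)
  }
  if (is.null(selected)) {
    out <- cbind(candidates[0, , drop = FALSE], tier = integer(0))
    attr(out, "undesignable") <- TRUE
    return(out)
  }
  rownames(selected) <- NULL
  selected
}

# SapI cassette geometry: SapI (GCTCTTC, cuts 1/4 nt downstream) flanks
# the insert in opposite orientations so digestion releases exactly the
# (possibly G-extended) spacer with 3-nt 5' overhangs.
.SAPI <- "GCTCTTC"
.SAPI_RC <- "GAAGAGC"
.LEFT_HANDLE <- "TATCTTGTGGAAAGGACGAA"
.RIGHT_BASE <- "CACCGAGTCGGTGCTTTTTTGGATC"

#' Build the 80-nt synthesis oligo for a spacer
#'
#' A 5' G is prepended when the spacer does not already begin with G (for
#' efficient U6-promoter expression); the insert is flanked by SapI
#' recognition cassettes and fixed PCR-handle padding so the oligo is
#' exactly 80 nt and simulated SapI digestion ([sapI_digest()]) releases
#' the G-extended spacer.
#'
#' @param spacer 20-nt spacer (ACGT).
#' @return 80-nt oligo string.
#' @export
build_oligo <- function(spacer) {
  if (nchar(spacer) != 20L) stop("spacer must be 20 nt", call. = FALSE)
  ins <- if (substr(spacer, 1L, 1L) == "G") spacer else paste0("G", spacer)
  if (grepl(.SAPI, ins, fixed = TRUE) || grepl(.SAPI_RC, ins, fixed = TRUE))
    stop("spacer contains a SapI recognition site (would self-cleave)",
         call. = FALSE)
  n <- nchar(ins)
  right <- substr(.RIGHT_BASE, 1L, 41L - n)
  oligo <- paste0(.LEFT_HANDLE, .SAPI, "A", ins, "AGGT", .SAPI_RC, right)
  stopifnot(nchar(oligo) == 80L)
  n_sites <- lengths(regmatches(oligo, gregexpr(.SAPI, oligo, fixed = TRUE))) +
    lengths(regmatches(oligo, gregexpr(.SAPI_RC, oligo, fixed = TRUE)))
  if (n_sites != 2L)
    stop("oligo assembly created an extra SapI site", call. = FALSE)
  oligo
}

#' Simulate SapI digestion of a library oligo
#'
#' Cuts 1 nt downstream of the forward recognition site and 4 nt
#' upstream of the reverse-oriented site (top strand), returning the
#' released insert.
#'
#' @param oligo oligo from [build_oligo()].
#' @return the released top-strand fragment (G-extended spacer).
#' @export
sapI_digest <- function(oligo) {
  r <- regexpr(.SAPI, oligo, fixed = TRUE)[1]
  q <- regexpr(.SAPI_RC, oligo, fixed = TRUE)[1]
  if (r < 0 || q < 0 || q <= r) stop("oligo lacks paired SapI sites")
  substr(oligo, r + 8L, q - 5L)
}

#' Design a pooled guide library for a set of genes
#'
#' Runs candidate discovery, off-target profiling, microhomology
#' scoring and the five-tier cascade for every gene, then appends
#' verified non-targeting control spacers (no 0-, 1- or 2-mismatch site
#' anywhere in the design genome) and builds the 80-nt oligo pool.
#'
#' @param genemodels list of `GeneModel`.
#' @param genome named character vector of chromosome sequences.
#' @param controls number of non-targeting controls (default 7).
#' @param k guides per gene (default 6).
#' @param seed seed for control-spacer search.
#' @return `GuideLibrary`: list with `guides` (data.frame incl. tier,
#'   mm counts, OOF and CDS percents, oligo), `controls`,
#'   `genes_targeted`, `undesignable` (gene ids), `tier_usage`.
#' @export
design_library <- function(genemodels, genome, controls = 7L, k = 6L,
                           seed = 1L) {
  idx <- protospacer_index(genome)
  cand_list <- lapply(genemodels, find_candidate_sites, genome = genome)
  cand <- do.call(rbind, c(cand_list, list(.empty_sites())))
  if (nrow(cand) > 0L) {
    compatible <- vapply(cand$spacer, function(s) {
      !is.null(tryCatch(build_oligo(s), error = function(e) NULL))
    }, logical(1), USE.NAMES = FALSE)
    cand <- cand[compatible, , drop = FALSE]
  }
  if (nrow(cand) > 0L) {
    usp <- unique(cand$spacer)
    prof <- count_offtargets(usp, idx)
    m <- match(cand$spacer, usp)
    cand$n0 <- prof[m, "n0"]
    cand$n1 <- prof[m, "n1"]
    cand$n2 <- prof[m, "n2"]
    cand$oof_score <- vapply(seq_len(nrow(cand)), function(i) {
      as.numeric(out_of_frame_score(
        cut_window(genome, cand$chrom[i], cand$cut_pos[i])))
    }, numeric(1))
  }
  guides <- NULL
  undesignable <- character(0)
  for (gid in names(genemodels)) {
    gc_ <- cand[cand$gene_id == gid, , drop = FALSE]
    sel <- select_guides(gc_, k = k)
    if (nrow(sel) == 0L) {
      undesignable <- c(undesignable, gid)
    } else {
      guides <- if (is.null(guides)) sel else rbind(guides, sel)
    }
  }
  if (is.null(guides)) {
    guides <- cbind(.empty_sites(), n0 = integer(0), n1 = integer(0),
                    n2 = integer(0), oof_score = numeric(0),
                    tier = integer(0))
  }
  guides$oligo <- vapply(guides$spacer, build_oligo, character(1),
                         USE.NAMES = FALSE)
  ctrl <- .make_control_spacers(controls, idx, seed)
  lib <- structure(list(guides = guides, controls = ctrl,
                        genes_targeted = length(genemodels) - length(undesignable),
                        undesignable = undesignable,
                        tier_usage = table(factor(guides$tier, levels = 1:5))),
                   class = "GuideLibrary")
  validate_guide_library(lib)
  lib
}

# random spacers verified to have zero 0/1/2-mismatch NGG sites in the
# design genome (synthetic stand-ins for non-targeting controls)
.make_control_spacers <- function(n, idx, seed) {
  found <- character(0)
  with_stream(seed, "library", {
    tries <- 0L
    while (length(found) < n && tries < 200L) {
      batch <- vapply(seq_len(max(2L * n, 8L)), function(i) {
        paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
              collapse = "")
      }, character(1))
      batch <- batch[vapply(batch, function(s) {
        !is.null(tryCatch(build_oligo(s), error = function(e) NULL))
      }, logical(1))]
      if (length(batch)) {
        prof <- count_offtargets(batch, idx)
        ok <- rowSums(prof) == 0L
        found <- unique(c(found, batch[ok]))
      }
      tries <- tries + 1L
    }
  })
  if (length(found) < n)
    stop("could not find ", n, " non-targeting control spacers")
  found <- found[seq_len(n)]
  data.frame(control_id = sprintf("ctrl%d", seq_len(n)), spacer = found,
             oligo = vapply(found, build_oligo, character(1),
                            USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Validate GuideLibrary invariants
#'
#' Per-gene guide counts are at most the design target and spacers are
#' unique across guides and controls.
#' @param lib a `GuideLibrary`.
#' @param k design target guides per gene.
#' @export
validate_guide_library <- function(lib, k = 6L) {
  stopifnot(inherits(lib, "GuideLibrary"))
  all_sp <- c(lib$guides$spacer, lib$controls$spacer)
  if (anyDuplicated(all_sp)) stop("duplicate spacers in library")
  per <- table(lib$guides$gene_id)
  if (length(per) && any(per > k)) stop("gene with more than ", k, " guides")
  invisible(TRUE)
}

#' @export
print.GuideLibrary <- function(x, ...) {
  cat(sprintf("GuideLibrary: %d guides / %d genes, %d controls",
              nrow(x$guides), x$genes_targeted, nrow(x$controls)))
  if (length(x$undesignable))
    cat(sprintf(", %d undesignable", length(x$undesignable)))
  cat("\n")
  invisible(x)
}

#' Write a designed library to disk
#'
#' Emits `library.tsv` (per-guide annotation), `controls.tsv`,
#' `oligos.fa` (80-nt pool) and `guides.bed` (0-based half-open loci).
#'
#' @param lib a `GuideLibrary`.
#' @param outdir output directory (created if needed).
#' @export
write_guide_library <- function(lib, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- lib$guides
  write_tsv_table(g[, c("gene_id", "spacer", "chrom", "start", "end",
                        "strand", "tier", "n0", "n1", "n2", "oof_score",
                        "cds_percent")],
                  file.path(outdir, "library.tsv"))
  write_tsv_table(lib$controls[, c("control_id", "spacer")],
                  file.path(outdir, "controls.tsv"))
  oligos <- c(stats::setNames(g$oligo,
                              sprintf("%s|%s", g$gene_id, g$spacer)),
              stats::setNames(lib$controls$oligo, lib$controls$control_id))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(oligos),
                              file.path(outdir, "oligos.fa"), width = 80L)
  bed <- data.frame(g$chrom, g$start - 1L, g$end,
                    paste0(g$gene_id, "|", g$spacer), 0L, g$strand)
  utils::write.table(bed, file.path(outdir, "guides.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(outdir)
}
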