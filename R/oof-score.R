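#' Microhomology-associated out-of-frame score
#'
#' Predicts the propensity of a Cas9 cut to yield frameshifting
#' deletions via microhomology-mediated end joining. All microhomologies
#' of length >= 2 nt flanking the cut are enumerated; each implied
#' deletion is scored `100 * exp(-deletion_length / 20) * (AT + 2 * GC)`
#' over the microhomology bases, with patterns contained in a longer
#' pattern implying the same deletion removed. The out-of-frame score is
#' `100 * sum(scores of deletions with length %% 3 != 0) / sum(all
#' scores)`.
#'
#' @param window sequence window spanning the cut (default convention:
#'   even length, cut at the midpoint; a `cut` attribute or argument
#'   overrides).
#' @param cut number of bases 5' of the cut within `window`; defaults to
#'   the `cut` attribute, else `nchar(window) / 2`.
#' @return score in `[0, 100]`. When no microhomology of length >= 2
#'   exists the score is 0 and the attribute `no_microhomology` is set.
#' @export
out_of_frame_score <- function(window, cut = NULL) {
  w <- toupper(as.character(window))
  n <- nchar(w)
  if (n < 4L) stop("window must be at least 4 nt", call. = FALSE)
  if (is.null(cut)) cut <- attr(window, "cut")
  if (is.null(cut)) {
    if (n %% 2L != 0L)
      stop("window length must be even when no cut position is given",
           call. = FALSE)
    cut <- n %/% 2L
  }
  cut <- as.integer(cut)
  stopifnot(cut >= 1L, cut < n)
  pat <- .enumerate_microhomologies(w, cut)
  if (nrow(pat) == 0L) {
    out <- 0
    attr(out, "no_microhomology") <- TRUE
    return(out)
  }
  total <- sum(pat$score)
  100 * sum(pat$score[pat$del_len %% 3L != 0L]) / total
}

# Enumerate flanking microhomologies >= 2 nt. A pattern is (i, j, k):
# left copy at window positions [i, i+k-1] with i+k-1 <= cut, right copy
# at [j, j+k-1] with j > cut; the implied deletion removes j - i bases.
# Patterns contained in an already-kept longer pattern with the same
# deletion length (same i-j offset) are duplicates.
.enumerate_microhomologies <- function(w, cut) {
  n <- nchar(w)
  L <- cut
  R <- n - cut
  kept <- list()
  if (min(L, R) < 2L) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      del_len = integer(), score = numeric()))
  }
  for (k in seq(min(L, R), 2L)) {
    li <- seq_len(L - k + 1L)
    rj <- cut + seq_len(R - k + 1L)
    ls <- substring(w, li, li + k - 1L)
    rs <- substring(w, rj, rj + k - 1L)
    hit <- which(outer(ls, rs, "=="), arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    for (h in seq_len(nrow(hit))) {
      i <- li[hit[h, 1L]]
      j <- rj[hit[h, 2L]]
      dup <- FALSE
      for (p in kept) {
        if (p$k > k && i >= p$i && i + k <= p$i + p$k &&
            j >= p$j && j + k <= p$j + p$k && (i - p$i) == (j - p$j)) {
          dup <- TRUE
          break
        }
      }
      if (!dup) kept[[length(kept) + 1L]] <- list(i = i, j = j, k = k)
    }
  }
  if (!length(kept)) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      del_len = integer(), score = numeric()))
  }
  i <- vapply(kept, `[[`, 0L, "i")
  j <- vapply(kept, `[[`, 0L, "j")
  k <- vapply(kept, `[[`, 0L, "k")
  mh <- substring(w, i, i + k - 1L)
  gc <- nchar(gsub("[AT]", "", mh))
  at <- k - gc
  del <- j - i
  data.frame(i = i, j = j, k = k, del_len = del,
             score = 100 * exp(-del / 20) * (at + 2 * gc))
}
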