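# Reverse complement and pairwise global alignment.

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement; `N` maps to `N`. Input may be lowercase;
#' output is uppercase. Characters outside `ACGTN` are an error.
#'
#' @param sequence DNA string.
#' @return The reverse complement.
#' @examples
#' reverse_complement("ACGT") # palindrome
#' @export
reverse_complement <- function(sequence) {
  sequence <- .check_dna(sequence)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
}

#' Default alignment scoring
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2 (megablast-like). A gap
#' of length L costs `gap_open + L * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; `match`
#'   must be positive and the penalties non-positive.
#' @return Named list of scoring parameters.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                              gap_extend = -2) {
  if (match <= 0) stop("`match` must be positive", call. = FALSE)
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0", call. = FALSE)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap costs, computed with
#' the `Biostrings` alignment engine. `N` scores as a mismatch against every
#' base (including another `N`).
#'
#' @param a,b Non-empty DNA strings.
#' @param scoring See [alignment_scoring()].
#' @return Object of class `pairwise_alignment` with elements
#'   `seq_a_aligned`, `seq_b_aligned` (equal-length gapped strings) and
#'   `score`. Removing the gap characters recovers the inputs exactly.
#' @export
align_global <- function(a, b, scoring = alignment_scoring()) {
  if (!nzchar(a) || !nzchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
  a <- .check_dna(a, "sequence a")
  b <- .check_dna(b, "sequence b")
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- scoring$match
  mat["N", ] <- scoring$mismatch
  mat[, "N"] <- scoring$mismatch
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  structure(list(
    seq_a_aligned = as.character(Biostrings::alignedPattern(pa)),
    seq_b_aligned = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, %d columns\n", x$score,
              nchar(x$seq_a_aligned)))
  cat(" a: ", substr(x$seq_a_aligned, 1, 60), "\n")
  cat(" b: ", substr(x$seq_b_aligned, 1, 60), "\n")
  invisible(x)
}
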