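# Oligonucleotide thermodynamics: GC content and nearest-neighbor melting
# temperature (SantaLucia 1998 unified parameters).

#' GC content of a DNA string
#'
#' @param sequence Non-empty DNA string without `N`.
#' @return Exact fraction of `G`+`C` in `[0, 1]`.
#' @examples
#' gc_content("GGCC")
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  sequence <- .check_dna(sequence, allow_n = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

# Unified nearest-neighbor parameters (SantaLucia 1998):
# dH in kcal/mol, dS in cal/(mol K) per stacked dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
.INIT_DH <- c(AT = 2.3, GC = 0.1)
.INIT_DS <- c(AT = 4.1, GC = -2.8)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement
#' under the unified nearest-neighbor model (SantaLucia 1998): stacking and
#' initiation enthalpies/entropies, an entropic salt correction
#' `0.368 * (n - 1) * ln([Na+])`, and
#' `Tm = 1000 * dH / (dS + R * ln(CT / 4)) - 273.15` with `CT` the total
#' oligonucleotide concentration (non-self-complementary duplex).
#'
#' @param sequence DNA string of length 15-30 without `N`.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param primer_uM Total primer concentration in uM (default 0.25).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(sequence, na_mM = 50, primer_uM = 0.25) {
  sequence <- .check_dna(sequence, allow_n = FALSE)
  n <- nchar(sequence)
  if (n < 15L || n > 30L)
    stop("primer length must be 15-30 nt, got ", n, call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  for (term in chars[c(1L, n)]) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dh <- dh + .INIT_DH[[key]]
    ds <- ds + .INIT_DS[[key]]
  }
  ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- primer_uM * 1e-6
  1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
}

#' Wallace-rule melting temperature
#'
#' The classic `2 * (A + T) + 4 * (G + C)` rule of thumb, exposed as a
#' secondary cross-check formula (not used by the design filters).
#'
#' @param sequence DNA string without `N`.
#' @return Temperature in degrees Celsius.
#' @export
wallace_tm <- function(sequence) {
  sequence <- .check_dna(sequence, allow_n = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  2 * (length(chars) - gc) + 4 * gc
}
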