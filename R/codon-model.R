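# Codon-level machinery shared by the divergence estimator and the sequence
# simulator: synonymous/nonsynonymous site fractions per codon, and
# pathway-averaged difference counts per codon pair (Nei & Gojobori 1986).

.codon_cache <- new.env(parent = emptyenv())

.all_codons <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(outer(outer(bases, bases, paste0), bases, paste0))
}

#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  # names are codons over ACGT (T not U); "*" marks stop codons
  gc[.all_codons()]
}

.is_stop <- function(codon) unname(.genetic_code()[codon] == "*")

# Per-codon synonymous site fraction: for each of the 3 positions, the
# fraction of the 3 possible single-base changes that preserve the amino
# acid. Changes that create a stop codon count as nonsynonymous.
.build_site_table <- function() {
  code <- .genetic_code()
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  syn <- numeric(length(codons))
  names(syn) <- codons
  for (cd in codons) {
    if (code[[cd]] == "*") {
      syn[[cd]] <- NA_real_
      next
    }
    s <- 0
    cs <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, cs[pos])) {
        mut <- cs
        mut[pos] <- b
        mut <- paste(mut, collapse = "")
        if (code[[mut]] != "*" && code[[mut]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    syn[[cd]] <- s
  }
  syn
}

# Average synonymous / nonsynonymous differences between two codons over all
# shortest mutational pathways, weighting pathways equally. Pathways passing
# through a stop codon are excluded; if every pathway is excluded the average
# falls back to all pathways, counting steps into or out of a stop codon as
# nonsynonymous.
.codon_pair_diffs <- function(a, b) {
  code <- .genetic_code()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- switch(d,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  walk <- function(order) {
    cur <- ca
    syn <- 0; nonsyn <- 0; via_stop <- FALSE
    for (k in order) {
      p <- pos[k]
      nxt <- cur
      nxt[p] <- cb[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa1 == "*" || aa2 == "*") {
        via_stop <- TRUE
        nonsyn <- nonsyn + 1
      } else if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    # endpoints are non-stop by precondition, so via_stop means an
    # intermediate codon was a stop
    list(syn = syn, nonsyn = nonsyn, via_stop = via_stop)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  use <- if (any(ok)) paths[ok] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

# Lazily built lookup tables: syn-site fractions (length-64 vector) and
# 64x64 pairwise difference matrices. Stop codons carry NA.
.codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  codons <- .all_codons()
  syn_sites <- .build_site_table()
  n <- length(codons)
  sd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  stops <- .is_stop(codons)
  for (i in seq_len(n)) {
    if (stops[i]) next
    for (j in i:n) {
      if (stops[j]) next
      dd <- .codon_pair_diffs(codons[i], codons[j])
      sd_mat[i, j] <- sd_mat[j, i] <- dd[["syn"]]
      nd_mat[i, j] <- nd_mat[j, i] <- dd[["nonsyn"]]
    }
  }
  .codon_cache$tables <- list(codons = codons, syn_sites = syn_sites,
                              sd = sd_mat, nd = nd_mat, stop = stops)
  .codon_cache$tables
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-base changes that leave the encoded amino acid unchanged is summed
#' into the synonymous site count; the remainder (changes that alter the
#' amino acid or create a stop codon) is nonsynonymous. The two counts always
#' total 3.
#'
#' @param codon A single 3-base string over `A`, `C`, `G`, `T`.
#' @return Named numeric vector with components `syn_sites` and
#'   `nonsyn_sites`.
#' @examples
#' count_codon_sites("TTT") # 1/3 synonymous site (only TTT->TTC is silent)
#' count_codon_sites("GGG") # a fully synonymous third position
#' @export
count_codon_sites <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("`codon` must be a single 3-base string", call. = FALSE)
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon))
    stop("ambiguous or non-DNA base in codon '", codon, "'", call. = FALSE)
  if (.is_stop(codon))
    stop("'", codon, "' is a stop codon", call. = FALSE)
  s <- .codon_tables()$syn_sites[[codon]]
  c(syn_sites = s, nonsyn_sites = 3 - s)
}

#' @noRd
.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n)
  substring(seq, starts, starts + 2L)
}
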