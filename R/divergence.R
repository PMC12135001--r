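# Synonymous divergence between X and Y gene copies (Nei-Gojobori with
# Jukes-Cantor correction), fixed X-Y difference calling, and the
# gene-selection filters used to shortlist marker candidates.

#' Nei-Gojobori synonymous and nonsynonymous divergence
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' codon-aligned coding sequences, averaging differences over all shortest
#' mutational pathways with equal weight (pathways through stop codons are
#' excluded), and applies the Jukes-Cantor multiple-hit correction
#' `d = -3/4 * log(1 - 4/3 * p)`. Estimates with `p >= 3/4` are flagged as
#' saturated (`NA` with the corresponding `saturated_*` flag set).
#'
#' Codons containing a gap (`-`) or `N` in either sequence are excluded
#' pairwise before counting. A trailing incomplete codon is trimmed, and a
#' stop codon in the final codon position is ignored; a premature stop codon
#' is an error.
#'
#' @param cds_a,cds_b Codon-aligned coding sequences of equal length
#'   (characters over `ACGTN-`).
#' @return Object of class `divergence_estimate` with fields `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `ps`, `pn`, `ds`, `dn`,
#'   `saturated_ds`, `saturated_dn`, `n_codons`.
#' @examples
#' est <- nei_gojobori_ds(
#'   "ATGAAACCCGGG",
#'   "ATGAAACCCGGA")  # one synonymous third-position change
#' est$ds
#' @export
nei_gojobori_ds <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (grepl("[^ACGTN-]", cds_a) || grepl("[^ACGTN-]", cds_b))
    stop("sequences must be over ACGTN-", call. = FALSE)
  if (nchar(cds_a) != nchar(cds_b))
    stop("coding sequences differ in length after alignment (",
         nchar(cds_a), " vs ", nchar(cds_b), ")", call. = FALSE)
  n_full <- nchar(cds_a) %/% 3L
  cod_a <- .split_codons(substr(cds_a, 1L, n_full * 3L))
  cod_b <- .split_codons(substr(cds_b, 1L, n_full * 3L))
  tab <- .codon_tables()
  clean <- !grepl("[N-]", cod_a) & !grepl("[N-]", cod_b)
  ia <- match(cod_a, tab$codons)
  ib <- match(cod_b, tab$codons)
  stop_a <- clean & tab$stop[ia]
  stop_b <- clean & tab$stop[ib]
  is_stop <- stop_a | stop_b
  if (any(is_stop)) {
    premature <- which(is_stop) < n_full
    if (any(premature))
      stop("premature stop codon at codon ",
           paste(which(is_stop)[premature], collapse = ", "), call. = FALSE)
    clean[is_stop] <- FALSE  # terminal stop: not compared
  }
  if (!any(clean))
    stop("no comparable codons after filtering gaps/Ns", call. = FALSE)
  ia <- ia[clean]; ib <- ib[clean]
  s_a <- sum(tab$syn_sites[ia]); s_b <- sum(tab$syn_sites[ib])
  n_cod <- sum(clean)
  S <- (s_a + s_b) / 2
  N <- 3 * n_cod - S
  sd <- sum(tab$sd[cbind(ia, ib)])
  nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(c(NA_real_, TRUE))
    c(-3 / 4 * log(1 - 4 / 3 * p), FALSE)
  }
  ds <- jc(ps); dn <- jc(pn)
  structure(list(syn_sites = S, nonsyn_sites = N, syn_diffs = sd,
                 nonsyn_diffs = nd, ps = ps, pn = pn,
                 ds = ds[1], dn = dn[1],
                 saturated_ds = as.logical(ds[2]),
                 saturated_dn = as.logical(dn[2]),
                 n_codons = n_cod),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  fmt <- function(v, sat) if (sat) "saturated" else sprintf("%.4f", v)
  cat(sprintf(
    "<divergence_estimate> %d codons: S=%.1f N=%.1f  dS=%s dN=%s\n",
    x$n_codons, x$syn_sites, x$nonsyn_sites,
    fmt(x$ds, x$saturated_ds), fmt(x$dn, x$saturated_dn)))
  invisible(x)
}

#' Call fixed X-Y differences
#'
#' Globally aligns each X haplotype to the Y sequence, projects the alignment
#' columns onto Y coordinates, and reports every Y position at which all X
#' haplotypes carry the same unambiguous, ungapped base and that base differs
#' from the Y base. These are the sites usable to anchor Y-specific primers.
#'
#' @param y A [seq_record()] (or plain string) holding the Y sequence.
#' @param x_set Non-empty list of `seq_record` (or character vector) of X
#'   haplotypes. Fewer than 3 haplotypes triggers a warning, since fixity
#'   across populations is better supported by several independent X sources.
#' @param scoring Alignment scoring, see [alignment_scoring()].
#' @return `data.frame` with columns `column_index` (0-based position on Y),
#'   `y_allele`, `x_allele`.
#' @export
call_fixed_differences <- function(y, x_set, scoring = alignment_scoring()) {
  y_seq <- if (inherits(y, "seq_record")) y$sequence else .check_dna(y)
  if (is.character(x_set)) x_set <- as.list(x_set)
  if (length(x_set) == 0L) stop("`x_set` must be non-empty", call. = FALSE)
  if (length(x_set) < 3L)
    warning("fewer than 3 X haplotypes supplied; fixed differences may not ",
            "be shared across populations", call. = FALSE)
  x_seqs <- vapply(x_set, function(x)
    if (inherits(x, "seq_record")) x$sequence else .check_dna(x), character(1))
  ylen <- nchar(y_seq)
  # x_mat[i, h]: base of haplotype h at Y position i, or NA under a gap
  x_mat <- matrix(NA_character_, nrow = ylen, ncol = length(x_seqs))
  for (h in seq_along(x_seqs)) {
    aln <- align_global(y_seq, x_seqs[[h]], scoring)
    ac <- strsplit(aln$seq_a_aligned, "")[[1]]
    bc <- strsplit(aln$seq_b_aligned, "")[[1]]
    keep <- ac != "-"
    x_mat[, h] <- bc[keep]
  }
  y_chars <- strsplit(y_seq, "")[[1]]
  ok <- y_chars %in% c("A", "C", "G", "T")
  unamb <- matrix(x_mat %in% c("A", "C", "G", "T"), nrow = ylen)
  all_unamb <- rowSums(unamb) == ncol(x_mat)
  same <- apply(x_mat, 1L, function(r) length(unique(r)) == 1L)
  fixed <- ok & all_unamb & same & x_mat[, 1L] != y_chars
  idx <- which(fixed)
  data.frame(column_index = idx - 1L, y_allele = y_chars[idx],
             x_allele = x_mat[idx, 1L], stringsAsFactors = FALSE)
}

#' Shortlist candidate genes for marker design
#'
#' Applies the four selection filters in order: (1) the Y copy must still be
#' expressed; (2) the gene must lie in the oldest stratum present (minimum
#' ordinal label); (3) among the survivors, only the `top_k` genes with the
#' highest synonymous divergence are kept (descending `ds`, ties broken by
#' `gene_id`; saturated estimates rank above all finite ones); (4) the
#' intron must be at least `min_intron_bp` long.
#'
#' @param genes List of [gene_record()].
#' @param top_k Number of top-divergence genes retained (default 20).
#' @param min_intron_bp Minimum intron length in bp (default 300).
#' @return List of the selected `gene_record`s, ordered by decreasing `ds`.
#' @export
select_candidate_genes <- function(genes, top_k = 20L, min_intron_bp = 300L) {
  if (length(genes) == 0L) return(list())
  for (g in genes) {
    need <- c("stratum", "y_expressed", "intron_length_bp", "ds")
    miss <- need[vapply(need, function(f) is.null(g[[f]]), logical(1))]
    if (length(miss))
      stop("gene ", g$gene_id, " lacks metadata field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  expressed <- Filter(function(g) isTRUE(g$y_expressed), genes)
  if (length(expressed) == 0L) return(list())
  strata <- vapply(expressed, `[[`, FUN.VALUE = vector(mode = mode(expressed[[1]]$stratum), 1L), "stratum")
  oldest <- sort(unique(strata))[1L]
  in_oldest <- expressed[strata == oldest]
  ds <- vapply(in_oldest, `[[`, numeric(1), "ds")
  rank_ds <- ifelse(is.na(ds), Inf, ds)  # saturated = maximal divergence
  ids <- vapply(in_oldest, `[[`, character(1), "gene_id")
  ord <- order(-rank_ds, ids)
  top <- in_oldest[ord][seq_len(min(top_k, length(in_oldest)))]
  Filter(function(g) g$intron_length_bp >= min_intron_bp, top)
}

#' Write a per-gene divergence/selection report
#'
#' @param genes List of [gene_record()] considered.
#' @param selected List of `gene_record` returned by
#'   [select_candidate_genes()].
#' @param n_fixed Named integer vector of fixed-difference counts per gene
#'   (optional).
#' @param path Output TSV path with columns
#'   `gene_id  ds  n_fixed_diffs  selected  reason`.
#' @param top_k,min_intron_bp Filter parameters, echoed into `reason`.
#' @return `path`, invisibly.
#' @export
write_divergence_report <- function(genes, selected, path,
                                    n_fixed = integer(0),
                                    top_k = 20L, min_intron_bp = 300L) {
  sel_ids <- vapply(selected, `[[`, character(1), "gene_id")
  strata <- vapply(genes, function(g) format(g$stratum), character(1))
  expressed <- vapply(genes, function(g) isTRUE(g$y_expressed), logical(1))
  oldest <- if (any(expressed))
    sort(unique(strata[expressed]))[1L] else NA_character_
  reason <- vapply(genes, function(g) {
    if (g$gene_id %in% sel_ids) return("selected")
    if (!isTRUE(g$y_expressed)) return("y_not_expressed")
    if (format(g$stratum) != oldest) return("not_oldest_stratum")
    if (g$intron_length_bp < min_intron_bp) return("intron_too_short")
    "below_ds_rank"
  }, character(1))
  df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    ds = vapply(genes, function(g)
      if (is.na(g$ds)) NA_real_ else round(g$ds, 6), numeric(1)),
    n_fixed_diffs = vapply(genes, function(g) {
      v <- n_fixed[g$gene_id]
      if (is.na(v)) NA_integer_ else as.integer(v)
    }, integer(1)),
    selected = ifelse(vapply(genes, `[[`, character(1), "gene_id")
                      %in% sel_ids, "true", "false"),
    reason = reason, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
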