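# Mismatch-tolerant in silico PCR: binding-site search on both strands,
# amplicon prediction, per-genome marker validation and multiplex sex
# calling.

#' In silico PCR settings
#'
#' Defaults: up to 2 mismatches per binding site, an exactly matching
#' 3'-terminal window of 3 nt (so 3'-anchored allele differences abolish
#' binding), and a maximum product size of 3000 bp. `N` in the template
#' counts as a mismatch; `N` in a primer is not allowed.
#'
#' @param max_mismatch Mismatch budget outside the 3' window.
#' @param three_prime_exact_nt Length of the exact-match 3' window.
#' @param amp_max Maximum reported product size (bp).
#' @param size_tol_frac Band-size attribution tolerance for [call_sex()]
#'   as a fraction of the expected size (gel-resolution proxy).
#' @return Named list of settings.
#' @export
insilico_settings <- function(max_mismatch = 2L, three_prime_exact_nt = 3L,
                              amp_max = 3000L, size_tol_frac = 0.10) {
  list(max_mismatch = as.integer(max_mismatch),
       three_prime_exact_nt = as.integer(three_prime_exact_nt),
       amp_max = as.integer(amp_max), size_tol_frac = size_tol_frac)
}

#' Find primer binding sites on both strands
#'
#' Scans a template for positions where the primer anneals with at most
#' `max_mismatch` mismatches and no mismatch within its 3'-terminal
#' `three_prime_exact_nt` bases. Plus-strand sites are primer matches read
#' directly; minus-strand sites are matches of the primer's reverse
#' complement, with the primer 3' end at the leftmost template position of
#' the site.
#'
#' @param primer A [primer()] or plain DNA string (no `N`).
#' @param template A [seq_record()] or plain DNA string, at least as long as
#'   the primer.
#' @param max_mismatch,three_prime_exact_nt See [insilico_settings()].
#' @return `data.frame` with columns `template_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `n_mismatches`,
#'   `three_prime_mismatch` (always `FALSE` for reported sites).
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 2L,
                               three_prime_exact_nt = 3L) {
  pseq <- if (inherits(primer, "primer")) primer$sequence
          else .check_dna(primer, allow_n = FALSE)
  tid <- if (inherits(template, "seq_record")) template$id else ""
  tseq <- if (inherits(template, "seq_record")) template$sequence
          else .check_dna(template)
  plen <- nchar(pseq)
  if (nchar(tseq) < plen)
    stop("template shorter than primer", call. = FALSE)
  tp <- min(three_prime_exact_nt, plen)

  scan <- function(query, strand) {
    hits <- Biostrings::matchPattern(query, Biostrings::DNAString(tseq),
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0L) return(NULL)
    qc <- strsplit(query, "")[[1]]
    starts <- Biostrings::start(hits)
    res <- lapply(starts, function(s) {
      frag <- substr(tseq, s, s + plen - 1L)
      mm <- strsplit(frag, "")[[1]] != qc
      # primer 3' end: rightmost base on "+", leftmost on "-"
      tp_idx <- if (strand == "+") (plen - tp + 1L):plen else 1:tp
      if (any(mm[tp_idx])) return(NULL)
      data.frame(template_id = tid, start = s - 1L, end = s - 1L + plen,
                 strand = strand, n_mismatches = sum(mm),
                 three_prime_mismatch = FALSE, stringsAsFactors = FALSE)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) do.call(rbind, res) else NULL
  }
  out <- rbind(scan(pseq, "+"), scan(reverse_complement(pseq), "-"))
  if (is.null(out))
    out <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatches = integer(0),
                      three_prime_mismatch = logical(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR products of a primer pair on a template
#'
#' Pairs every plus-strand binding site of the forward primer with every
#' minus-strand site of the reverse primer lying downstream, rejecting
#' overlapping footprints and products longer than `amp_max`. Product length
#' runs from the forward primer's 5' end to the reverse primer's 5' end on
#' the plus strand (both footprints included).
#'
#' @param pair A [primer_pair()].
#' @param template A [seq_record()] or DNA string.
#' @param settings See [insilico_settings()].
#' @return `data.frame` sorted by position with columns `template_id`,
#'   `start`, `end`, `length_bp`, `fwd_start`, `rev_start`, `mismatches_f`,
#'   `mismatches_r`.
#' @export
predict_amplicons <- function(pair, template, settings = insilico_settings()) {
  f <- find_binding_sites(pair$forward, template, settings$max_mismatch,
                          settings$three_prime_exact_nt)
  f <- f[f$strand == "+", , drop = FALSE]
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      fwd_start = integer(0), rev_start = integer(0),
                      mismatches_f = integer(0), mismatches_r = integer(0))
  if (nrow(f) == 0L) return(empty)
  r <- find_binding_sites(pair$reverse, template, settings$max_mismatch,
                          settings$three_prime_exact_nt)
  r <- r[r$strand == "-", , drop = FALSE]
  if (nrow(r) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      if (r$start[j] < f$end[i]) next  # overlapping footprints
      len <- r$end[j] - f$start[i]
      if (len > settings$amp_max) next
      out[[length(out) + 1L]] <- data.frame(
        template_id = f$template_id[i], start = f$start[i], end = r$end[j],
        length_bp = len, fwd_start = f$start[i], rev_start = r$start[j],
        mismatches_f = f$n_mismatches[i], mismatches_r = r$n_mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Validate a marker across genome templates
#'
#' Runs [predict_amplicons()] over every record of every genome and
#' summarises amplification per genome. A Y-specific pair is valid when
#' every male genome yields exactly one product and every female genome
#' none; an autosomal control is valid when every genome yields exactly one
#' product.
#'
#' @param pair A [primer_pair()].
#' @param genomes List of genomes; each genome is a list with elements
#'   `genome_id`, `records` (list of [seq_record()]) and `expected_sex`
#'   (`"male"`, `"female"` or `"unknown"`).
#' @param settings See [insilico_settings()].
#' @return Object of class `marker_validation`: a list with `pair_id`,
#'   `target_type`, `valid`, and `per_genome` (`data.frame` with
#'   `genome_id`, `expected_sex`, `n_amplicons`, `sizes` as a
#'   comma-separated string).
#' @export
validate_marker <- function(pair, genomes, settings = insilico_settings()) {
  if (length(genomes) == 0L) stop("`genomes` must be non-empty", call. = FALSE)
  rows <- lapply(genomes, function(g) {
    sizes <- integer(0)
    for (rec in g$records) {
      if (nchar(rec$sequence) < nchar(pair$forward$sequence)) next
      amps <- predict_amplicons(pair, rec, settings)
      sizes <- c(sizes, amps$length_bp)
    }
    data.frame(genome_id = g$genome_id, expected_sex = g$expected_sex,
               n_amplicons = length(sizes),
               sizes = paste(sizes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  per_genome <- do.call(rbind, rows)
  male <- per_genome$expected_sex == "male"
  female <- per_genome$expected_sex == "female"
  valid <- if (pair$target_type == "y_specific") {
    all(per_genome$n_amplicons[male] == 1L) &&
      all(per_genome$n_amplicons[female] == 0L)
  } else {
    all(per_genome$n_amplicons == 1L)
  }
  structure(list(pair_id = pair$pair_id, target_type = pair$target_type,
                 valid = valid, per_genome = per_genome),
            class = "marker_validation")
}

#' @export
print.marker_validation <- function(x, ...) {
  cat(sprintf("<marker_validation> %s [%s]: %s\n", x$pair_id, x$target_type,
              if (x$valid) "VALID" else "INVALID"))
  print(x$per_genome, row.names = FALSE)
  invisible(x)
}

#' Call the sex of a sample from its multiplex band pattern
#'
#' The autosomal control band reports whether the reaction worked: control
#' absent is a failed experiment; control present with at least one
#' Y-marker band is a male; control present with no Y band is a female.
#' Observed bands are attributed to panel products within
#' `settings$size_tol_frac` of the expected size; an unattributable band is
#' flagged but does not change the call.
#'
#' @param band_sizes Numeric vector of observed band sizes (bp); may be
#'   empty.
#' @param panel A `multiplex_panel` from [select_multiplex()].
#' @param settings See [insilico_settings()].
#' @return List with `call` (`"male"`, `"female"` or `"failed"`),
#'   `markers_present` (named logical over the panel's pair ids) and
#'   `unattributed` (numeric vector of unexplained band sizes).
#' @export
call_sex <- function(band_sizes, panel, settings = insilico_settings()) {
  pairs <- panel_pairs(panel)
  expected <- vapply(pairs, `[[`, integer(1), "expected_amplicon_bp")
  ids <- vapply(pairs, `[[`, character(1), "pair_id")
  types <- vapply(pairs, `[[`, character(1), "target_type")
  present <- stats::setNames(rep(FALSE, length(pairs)), ids)
  unattributed <- numeric(0)
  for (b in band_sizes) {
    rel <- abs(b - expected) / expected
    hit <- which(rel <= settings$size_tol_frac)
    if (length(hit) == 0L) {
      unattributed <- c(unattributed, b)
    } else {
      present[hit[which.min(rel[hit])]] <- TRUE
    }
  }
  control_ok <- any(present[types == "autosomal_control"])
  y_present <- any(present[types == "y_specific"])
  call <- if (!control_ok) "failed" else if (y_present) "male" else "female"
  list(call = call, markers_present = present, unattributed = unattributed)
}

#' Write an amplicon report
#'
#' @param amplicons `data.frame` accumulating [predict_amplicons()] output
#'   with added `pair_id` and `genome_id` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_amplicon_report <- function(amplicons, path) {
  cols <- c("pair_id", "genome_id", "template_id", "start", "end",
            "length_bp", "fwd_start", "rev_start", "mismatches_f",
            "mismatches_r")
  keep <- intersect(cols, names(amplicons))
  utils::write.table(amplicons[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
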