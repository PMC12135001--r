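# Y-allele-anchored primer pair enumeration, primer-dimer screening, and
# multiplex panel assembly.
#
# The design logic follows allele-specific PCR practice: a Y-specific pair
# must place a fixed X-Y difference near the 3' end of at least one primer
# (so the X allele fails to extend), must span at least two fixed
# differences in total, and at least one primer of the pair must fail to
# bind the reconstructed X allele under the in silico PCR binding model.

#' Primer design constraints
#'
#' Defaults: length 18-24 nt, Tm 55-62 degrees C at 50 mM Na+ / 0.25 uM
#' (panels must work at a 58 degrees C annealing step), GC 30-70%, amplicon
#' 100-600 bp on the design sequence, a fixed difference within the
#' 3'-terminal 5 nt of at least one primer, at least 2 fixed differences per
#' amplicon, and dimer rejection at a complementary run of 8 or a 3'-anchored
#' run of 4. `x_rejection_check` additionally requires that at least one
#' primer of a Y-specific pair would fail to bind its X-allele counterpart
#' under the binding model of [find_binding_sites()] (mismatch budget
#' `max_mismatch`, exact 3' window `three_prime_exact_nt`).
#'
#' @param len_min,len_max Primer length bounds (nt).
#' @param tm_min,tm_max Melting-temperature window (degrees C).
#' @param gc_min,gc_max GC-fraction window.
#' @param amp_min,amp_max Amplicon size window on the design sequence (bp).
#' @param anchor_window_nt 3'-terminal window (nt) in which a fixed
#'   difference anchors a primer.
#' @param min_fixed_covered Minimum fixed differences inside the amplicon.
#' @param max_comp_run_limit,three_prime_run_limit Dimer rejection limits
#'   (a score at or above either limit rejects).
#' @param max_mismatch,three_prime_exact_nt X-allele rejection model
#'   parameters (mirroring [insilico_settings()]).
#' @param x_rejection_check Apply the X-allele binding filter to Y-specific
#'   pairs (default `TRUE`).
#' @param na_mM,primer_uM Conditions for [melting_temp()].
#' @param max_pairs Stop after this many accepted pairs, scanning in the
#'   deterministic output order (default `Inf`).
#' @return Named list of constraints.
#' @export
primer_constraints <- function(len_min = 18L, len_max = 24L,
                               tm_min = 55, tm_max = 62,
                               gc_min = 0.30, gc_max = 0.70,
                               amp_min = 100L, amp_max = 600L,
                               anchor_window_nt = 5L,
                               min_fixed_covered = 2L,
                               max_comp_run_limit = 8L,
                               three_prime_run_limit = 4L,
                               max_mismatch = 2L,
                               three_prime_exact_nt = 3L,
                               x_rejection_check = TRUE,
                               na_mM = 50, primer_uM = 0.25,
                               max_pairs = Inf) {
  stopifnot(len_min >= 15L, len_max <= 30L, len_min <= len_max,
            amp_min <= amp_max, gc_min <= gc_max, tm_min <= tm_max)
  as.list(environment())
}

#' Read primer design constraints from a config file
#'
#' Key-value YAML file; every key of [primer_constraints()] may be
#' overridden, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return Constraint list.
#' @export
read_primer_constraints <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(primer_constraints))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown constraint key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(primer_constraints, vals)
}

#' Construct a primer
#'
#' @param sequence 5'->3' DNA string, 15-30 nt.
#' @param gene_id Gene the primer targets.
#' @param orientation `"forward"` or `"reverse"`.
#' @param anchor_offsets Integer offsets (0 = 3'-terminal base) of fixed
#'   X-Y differences covered by the primer.
#' @param na_mM,primer_uM Conditions for [melting_temp()].
#' @return Object of class `primer` with `tm_c` and `gc_fraction` filled in.
#' @export
primer <- function(sequence, gene_id = "", orientation = c("forward", "reverse"),
                   anchor_offsets = integer(0), na_mM = 50, primer_uM = 0.25) {
  orientation <- match.arg(orientation)
  sequence <- .check_dna(sequence, allow_n = FALSE)
  n <- nchar(sequence)
  if (n < 15L || n > 30L)
    stop("primer length must be 15-30 nt", call. = FALSE)
  if (length(anchor_offsets) && any(anchor_offsets >= n))
    stop("anchor offset beyond primer length", call. = FALSE)
  structure(list(sequence = sequence, gene_id = gene_id,
                 orientation = orientation,
                 anchor_offsets = as.integer(anchor_offsets),
                 tm_c = melting_temp(sequence, na_mM, primer_uM),
                 gc_fraction = gc_content(sequence)),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s %s %s (%d nt, Tm %.1f C, GC %.2f)\n",
              x$gene_id, x$orientation, x$sequence, nchar(x$sequence),
              x$tm_c, x$gc_fraction))
  invisible(x)
}

#' Primer-dimer complementarity score
#'
#' Slides one primer along the reverse complement of the other over every
#' ungapped offset and records the longest contiguous Watson-Crick
#' complementary run (`max_comp_run`) and the longest run that ends exactly
#' at either primer's 3' terminus (`three_prime_run`). Symmetric in its
#' arguments.
#'
#' @param p1,p2 [primer()] objects or plain DNA strings.
#' @return Named integer vector `c(max_comp_run, three_prime_run)`.
#' @export
dimer_score <- function(p1, p2) {
  s1 <- if (inherits(p1, "primer")) p1$sequence else .check_dna(p1)
  s2 <- if (inherits(p2, "primer")) p2$sequence else .check_dna(p2)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(reverse_complement(s2), "")[[1]]
  n1 <- length(a); n2 <- length(b)
  max_run <- 0L; tp_run <- 0L
  for (off in (-(n2 - 1L)):(n1 - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(n1, n2 + off)
    if (i2 < i1) next
    ia <- i1:i2               # positions in a; positions in b are ia - off
    m <- a[ia] == b[ia - off]
    r <- rle(m)
    runs <- r$lengths[r$values]
    if (length(runs) && max(runs) > max_run) max_run <- max(runs)
    nm <- length(m)
    # p2's 3' terminus is b position 1 = the first overlap column iff off >= 0
    if (off >= 0L && m[1L]) {
      head_run <- r$lengths[1L]
      if (head_run > tp_run) tp_run <- head_run
    }
    # p1's 3' terminus (a position n1) is the last overlap column iff it is
    # covered, i.e. off >= n1 - n2
    if (i2 == n1 && m[nm]) {
      tail_run <- r$lengths[length(r$lengths)]
      if (tail_run > tp_run) tp_run <- tail_run
    }
  }
  c(max_comp_run = as.integer(max_run), three_prime_run = as.integer(tp_run))
}

.passes_dimer <- function(score, constraints) {
  score[["max_comp_run"]] < constraints$max_comp_run_limit &&
    score[["three_prime_run"]] < constraints$three_prime_run_limit
}

# X-allele counterpart of a window [start, end) on the Y sequence: the Y
# window with every fixed-difference position substituted by its X allele.
.x_allele_window <- function(y_window, win_start, fixed_sites) {
  chars <- strsplit(y_window, "")[[1]]
  inside <- fixed_sites$column_index >= win_start &
    fixed_sites$column_index < win_start + length(chars)
  for (k in which(inside)) {
    chars[fixed_sites$column_index[k] - win_start + 1L] <-
      fixed_sites$x_allele[k]
  }
  paste(chars, collapse = "")
}

# Would `primer_seq` bind `target` (same length, same register) under the
# mismatch-tolerant binding model? three_prime side: "last" = 3' end is the
# window's right edge (forward primer), "first" = left edge (reverse primer
# checked against the plus strand).
.binds_allele <- function(primer_chars, target, max_mismatch, tp_nt,
                          three_prime = c("last", "first")) {
  three_prime <- match.arg(three_prime)
  t_chars <- strsplit(target, "")[[1]]
  mm <- primer_chars != t_chars
  n <- length(mm)
  tp_idx <- if (three_prime == "last") (n - tp_nt + 1L):n else 1:tp_nt
  sum(mm) <= max_mismatch && !any(mm[tp_idx])
}

#' Enumerate candidate primer pairs on a Y sequence
#'
#' Exhaustively enumerates forward/reverse primer windows over the design
#' (Y) sequence that satisfy the length, Tm, GC and amplicon-size windows of
#' `constraints`, then keeps pairs obeying the Y-specificity rules: at least
#' one primer carries a fixed X-Y difference within its 3'-terminal
#' `anchor_window_nt` bases, the amplicon spans at least
#' `min_fixed_covered` fixed differences, and (when `x_rejection_check` is
#' on) at least one primer fails to bind the reconstructed X allele under
#' the binding model. Pairs whose primers self- or cross-dimerise beyond the
#' limits are removed. For `target_type = "autosomal_control"` the
#' Y-specificity rules are skipped.
#'
#' Primer footprints never span a position listed in `forbidden_boundaries`
#' (used to keep primers off exon-intron junctions of the genomic template).
#'
#' @param gene A [gene_record()] whose `y_sequence` is the design template
#'   (for controls, the autosomal sequence).
#' @param fixed_sites `data.frame` from [call_fixed_differences()], in the
#'   coordinate frame of `gene$y_sequence`.
#' @param constraints See [primer_constraints()].
#' @param target_type `"y_specific"` or `"autosomal_control"`.
#' @param forbidden_boundaries Integer vector of 0-based positions; a primer
#'   window `[s, e)` is discarded when `s < b < e` for any boundary `b`.
#' @return List of `primer_pair` objects, deterministically sorted by
#'   forward start, forward length, reverse start, reverse length. An empty
#'   list is a valid result.
#' @export
enumerate_candidates <- function(gene, fixed_sites = NULL,
                                 constraints = primer_constraints(),
                                 target_type = c("y_specific",
                                                 "autosomal_control"),
                                 forbidden_boundaries = integer(0)) {
  target_type <- match.arg(target_type)
  y <- gene$y_sequence
  L <- nchar(y)
  cn <- constraints
  if (is.null(fixed_sites))
    fixed_sites <- data.frame(column_index = integer(0),
                              y_allele = character(0),
                              x_allele = character(0))
  y_specific <- target_type == "y_specific"
  if (y_specific && nrow(fixed_sites) < cn$min_fixed_covered)
    return(list())

  # all windows passing per-primer QC, shared by both orientations
  wins <- list()
  for (len in cn$len_min:cn$len_max) {
    if (len > L) next
    starts <- 0:(L - len)
    for (s in starts) {
      if (length(forbidden_boundaries) &&
          any(forbidden_boundaries > s & forbidden_boundaries < s + len))
        next
      sq <- substr(y, s + 1L, s + len)
      if (grepl("N", sq, fixed = TRUE)) next
      gc <- gc_content(sq)
      if (gc < cn$gc_min || gc > cn$gc_max) next
      tm <- melting_temp(sq, cn$na_mM, cn$primer_uM)
      if (tm < cn$tm_min || tm > cn$tm_max) next
      wins[[length(wins) + 1L]] <- list(start = s, len = len, seq = sq,
                                        gc = gc, tm = tm)
    }
  }
  if (length(wins) == 0L) return(list())
  w_start <- vapply(wins, `[[`, numeric(1), "start")
  w_len <- vapply(wins, `[[`, numeric(1), "len")
  ord <- order(w_start, w_len)
  wins <- wins[ord]; w_start <- w_start[ord]; w_len <- w_len[ord]
  w_end <- w_start + w_len
  fs <- fixed_sites$column_index
  # anchored = fixed difference within the 3'-terminal anchor window
  anch_f <- vapply(seq_along(wins), function(i)
    any(fs >= w_end[i] - cn$anchor_window_nt & fs < w_end[i]), logical(1))
  anch_r <- vapply(seq_along(wins), function(i)
    any(fs >= w_start[i] & fs < w_start[i] + cn$anchor_window_nt), logical(1))

  # self-dimer caches; orientation matters for the 3'-anchored run, so the
  # reverse use of a window is screened on its reverse complement
  self_f_ok <- rep(NA, length(wins))
  self_r_ok <- rep(NA, length(wins))
  self_ok_f <- function(i) {
    if (is.na(self_f_ok[i]))
      self_f_ok[i] <<- .passes_dimer(dimer_score(wins[[i]]$seq,
                                                 wins[[i]]$seq), cn)
    self_f_ok[i]
  }
  self_ok_r <- function(i) {
    if (is.na(self_r_ok[i])) {
      rc <- reverse_complement(wins[[i]]$seq)
      self_r_ok[i] <<- .passes_dimer(dimer_score(rc, rc), cn)
    }
    self_r_ok[i]
  }
  x_rejected <- rep(NA, length(wins))  # primer fails to bind its X allele
  rejects_x <- function(i, side) {
    if (is.na(x_rejected[i])) {
      xa <- .x_allele_window(wins[[i]]$seq, w_start[i], fixed_sites)
      pc <- strsplit(wins[[i]]$seq, "")[[1]]
      x_rejected[i] <<- !.binds_allele(pc, xa, cn$max_mismatch,
                                       cn$three_prime_exact_nt, side)
    }
    x_rejected[i]
  }

  fs_sorted <- sort(fs)
  n_before <- function(p) findInterval(p - 0.5, fs_sorted)  # sites < p
  cov_start <- n_before(w_start)  # fixed sites before each window start
  cov_end <- n_before(w_end)      # fixed sites before each window end
  pairs <- list()
  for (i in seq_along(wins)) {
    js <- which(w_start >= w_end[i] &
                w_end - w_start[i] >= cn$amp_min &
                w_end - w_start[i] <= cn$amp_max)
    if (y_specific) {
      if (!anch_f[i]) js <- js[anch_r[js]]
      js <- js[cov_end[js] - cov_start[i] >= cn$min_fixed_covered]
    }
    for (j in js) {
      amp_len <- w_end[j] - w_start[i]
      if (y_specific) {
        n_cov <- cov_end[j] - cov_start[i]
        if (cn$x_rejection_check &&
            !(rejects_x(i, "last") || rejects_x(j, "first"))) next
      } else n_cov <- 0L
      if (!self_ok_f(i) || !self_ok_r(j)) next
      fwd_seq <- wins[[i]]$seq
      rev_seq <- reverse_complement(wins[[j]]$seq)
      if (!.passes_dimer(dimer_score(fwd_seq, rev_seq), cn)) next
      fwd_anchors <- (w_end[i] - 1L) - fs[fs >= w_start[i] & fs < w_end[i]]
      rev_anchors <- fs[fs >= w_start[j] & fs < w_end[j]] - w_start[j]
      pairs[[length(pairs) + 1L]] <- primer_pair(
        forward = primer(fwd_seq, gene$gene_id, "forward",
                         sort(fwd_anchors), cn$na_mM, cn$primer_uM),
        reverse = primer(rev_seq, gene$gene_id, "reverse",
                         sort(rev_anchors), cn$na_mM, cn$primer_uM),
        expected_amplicon_bp = amp_len,
        target_type = target_type,
        n_fixed_diffs_covered = n_cov,
        fwd_start = w_start[i], rev_start = w_start[j],
        rev_window_len = w_len[j])
      if (length(pairs) >= cn$max_pairs) return(pairs)
    }
  }
  pairs
}

#' Construct a primer pair
#'
#' @param forward,reverse [primer()] objects (the reverse primer is given
#'   5'->3' on the minus strand).
#' @param expected_amplicon_bp Expected product length including both primer
#'   footprints.
#' @param target_type `"y_specific"` or `"autosomal_control"`.
#' @param n_fixed_diffs_covered Fixed X-Y differences inside the amplicon
#'   (must be >= 2 for Y-specific pairs).
#' @param pair_id Optional identifier.
#' @param fwd_start,rev_start,rev_window_len Design-sequence coordinates
#'   (0-based), kept for reporting.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, expected_amplicon_bp,
                        target_type = c("y_specific", "autosomal_control"),
                        n_fixed_diffs_covered = 0L, pair_id = NULL,
                        fwd_start = NA_integer_, rev_start = NA_integer_,
                        rev_window_len = NA_integer_) {
  target_type <- match.arg(target_type)
  if (target_type == "y_specific" && n_fixed_diffs_covered < 2L)
    stop("a y_specific pair must cover at least 2 fixed differences",
         call. = FALSE)
  if (expected_amplicon_bp <
      nchar(forward$sequence) + nchar(reverse$sequence))
    stop("amplicon shorter than the two primer footprints", call. = FALSE)
  structure(list(forward = forward, reverse = reverse,
                 expected_amplicon_bp = as.integer(expected_amplicon_bp),
                 target_type = target_type,
                 n_fixed_diffs_covered = as.integer(n_fixed_diffs_covered),
                 pair_id = pair_id %||% paste0(forward$gene_id, "_",
                                               fwd_start, "_", rev_start),
                 fwd_start = fwd_start, rev_start = rev_start,
                 rev_window_len = rev_window_len),
            class = "primer_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s [%s] %d bp, %d fixed diff(s)\n  F: %s\n  R: %s\n",
              x$pair_id, x$target_type, x$expected_amplicon_bp,
              x$n_fixed_diffs_covered, x$forward$sequence,
              x$reverse$sequence))
  invisible(x)
}

#' Assemble a multiplex panel
#'
#' Searches all feasible triples of two Y-specific pairs from distinct genes
#' plus one autosomal control, requiring every pairwise amplicon-size gap to
#' be at least `min_size_gap_bp` (so products resolve on a gel) and every
#' cross-pair primer combination to pass the dimer limits. Feasible triples
#' are ranked by total fixed differences covered (descending), then total
#' cross-pair `max_comp_run` (ascending), then concatenated gene ids; the
#' best triple is returned.
#'
#' @param y_candidates List of Y-specific `primer_pair`s (>= 2 distinct
#'   genes required).
#' @param control_candidates List of autosomal-control `primer_pair`s.
#' @param min_size_gap_bp Minimum pairwise amplicon-size difference
#'   (default 60).
#' @param dimer_limits List with `max_comp_run_limit` and
#'   `three_prime_run_limit` (defaults 8 and 4).
#' @return Object of class `multiplex_panel` with elements `y_pairs`
#'   (list of 2), `control_pair`, `min_size_gap_bp`.
#' @export
select_multiplex <- function(y_candidates, control_candidates,
                             min_size_gap_bp = 60L,
                             dimer_limits = list(max_comp_run_limit = 8L,
                                                 three_prime_run_limit = 4L)) {
  if (length(y_candidates) == 0L || length(control_candidates) == 0L)
    stop("multiplex infeasible: empty candidate list (",
         length(y_candidates), " y_specific, ",
         length(control_candidates), " control)", call. = FALSE)
  cn <- list(max_comp_run_limit = dimer_limits$max_comp_run_limit %||% 8L,
             three_prime_run_limit = dimer_limits$three_prime_run_limit %||% 4L)
  genes <- vapply(y_candidates, function(p) p$forward$gene_id, character(1))
  if (length(unique(genes)) < 2L)
    stop("multiplex infeasible: need y_specific pairs from 2 distinct ",
         "genes, got only '", paste(unique(genes), collapse = "', '"), "'",
         call. = FALSE)
  n_fail_gene <- 0L; n_fail_gap <- 0L; n_fail_dimer <- 0L
  best <- NULL; best_key <- NULL
  cross_ok_cache <- new.env(parent = emptyenv())
  cross <- function(pa, ia, pb, ib) {
    key <- paste(ia, ib)
    hit <- cross_ok_cache[[key]]
    if (!is.null(hit)) return(hit)
    runs <- 0L
    ok <- TRUE
    for (x in list(pa$forward, pa$reverse)) {
      for (y in list(pb$forward, pb$reverse)) {
        sc <- dimer_score(x, y)
        runs <- runs + sc[["max_comp_run"]]
        if (!.passes_dimer(sc, cn)) ok <- FALSE
      }
    }
    res <- list(ok = ok, runs = runs)
    cross_ok_cache[[key]] <- res
    res
  }
  sizes_ok <- function(sz) all(abs(diff(sort(sz))) >= min_size_gap_bp)
  ny <- length(y_candidates)
  for (i in seq_len(ny - 1L)) {
    for (j in (i + 1L):ny) {
      if (genes[i] == genes[j]) { n_fail_gene <- n_fail_gene + 1L; next }
      for (k in seq_along(control_candidates)) {
        pa <- y_candidates[[i]]; pb <- y_candidates[[j]]
        pc <- control_candidates[[k]]
        sz <- c(pa$expected_amplicon_bp, pb$expected_amplicon_bp,
                pc$expected_amplicon_bp)
        if (!sizes_ok(sz)) { n_fail_gap <- n_fail_gap + 1L; next }
        c1 <- cross(pa, paste0("y", i), pb, paste0("y", j))
        c2 <- cross(pa, paste0("y", i), pc, paste0("c", k))
        c3 <- cross(pb, paste0("y", j), pc, paste0("c", k))
        if (!(c1$ok && c2$ok && c3$ok)) {
          n_fail_dimer <- n_fail_dimer + 1L; next
        }
        tot_fixed <- pa$n_fixed_diffs_covered + pb$n_fixed_diffs_covered
        tot_runs <- c1$runs + c2$runs + c3$runs
        gene_key <- paste(sort(c(genes[i], genes[j])), collapse = "|")
        key <- list(-tot_fixed, tot_runs, gene_key,
                    pa$pair_id, pb$pair_id, pc$pair_id)
        if (is.null(best) || .key_lt(key, best_key)) {
          best <- list(y_pairs = list(pa, pb), control_pair = pc)
          best_key <- key
        }
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0(
      "multiplex infeasible: no triple satisfies the constraints ",
      "(%d rejected for shared gene, %d for amplicon-size gap < %d bp, ",
      "%d for cross-pair dimers)"),
      n_fail_gene, n_fail_gap, min_size_gap_bp, n_fail_dimer),
      call. = FALSE)
  }
  structure(c(best, list(min_size_gap_bp = as.integer(min_size_gap_bp))),
            class = "multiplex_panel")
}

# lexicographic comparison of mixed numeric/character ranking keys
.key_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.character(a[[i]])) {
      if (a[[i]] < b[[i]]) return(TRUE)
      if (a[[i]] > b[[i]]) return(FALSE)
    } else {
      if (a[[i]] < b[[i]]) return(TRUE)
      if (a[[i]] > b[[i]]) return(FALSE)
    }
  }
  FALSE
}

#' @export
print.multiplex_panel <- function(x, ...) {
  cat("<multiplex_panel>\n")
  for (p in c(x$y_pairs, list(x$control_pair)))
    cat(sprintf("  %-12s %-17s %4d bp  F:%s R:%s\n", p$pair_id,
                p$target_type, p$expected_amplicon_bp,
                p$forward$sequence, p$reverse$sequence))
  cat("  min size gap:", x$min_size_gap_bp, "bp\n")
  invisible(x)
}

#' All primer pairs of a panel, control last
#' @param panel A `multiplex_panel`.
#' @return List of three `primer_pair`s.
#' @export
panel_pairs <- function(panel) c(panel$y_pairs, list(panel$control_pair))

#' Read a primer table
#'
#' Tab-separated table mirroring a published primer panel:
#' `primer_id  type  gene_id  forward_seq  reverse_seq  xy_ds  amplicon_bp`
#' with `type` one of `XY` (Y-specific) or `autosomal`.
#'
#' @param path TSV path. The packaged fixture
#'   `system.file("extdata", "table1_primers.tsv", package = "sexmarker")`
#'   holds the published three-pair sexing panel.
#' @return `data.frame`, one row per pair.
#' @export
read_primer_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("primer_id", "type", "gene_id", "forward_seq", "reverse_seq",
            "xy_ds", "amplicon_bp")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("primer table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !df$type %in% c("XY", "autosomal")
  if (any(bad)) stop("primer type must be XY or autosomal", call. = FALSE)
  df$forward_seq <- toupper(df$forward_seq)
  df$reverse_seq <- toupper(df$reverse_seq)
  df
}

#' Write a primer table
#' @param df `data.frame` in the layout of [read_primer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert primer-table rows into primer pairs
#'
#' Published panels carry no window coordinates, so anchor offsets are left
#' empty and `n_fixed_diffs_covered` is set to 2 for Y-specific rows (the
#' design floor) purely to satisfy the pair invariant.
#'
#' @param df `data.frame` from [read_primer_table()].
#' @return List of `primer_pair`.
#' @export
primer_table_to_pairs <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    ty <- if (df$type[i] == "XY") "y_specific" else "autosomal_control"
    primer_pair(
      forward = primer(df$forward_seq[i], df$gene_id[i], "forward"),
      reverse = primer(df$reverse_seq[i], df$gene_id[i], "reverse"),
      expected_amplicon_bp = df$amplicon_bp[i],
      target_type = ty,
      n_fixed_diffs_covered = if (ty == "y_specific") 2L else 0L,
      pair_id = df$primer_id[i])
  })
}
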