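# GC content, melting temperature, dimer screening, candidate enumeration
# and multiplex panel assembly.

test_that("gc content is the exact base fraction", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GTTATATGGACATGGACTCT"), 8 / 20)
  expect_equal(gc_content("AAAAGGGGTGAAAAGGTG"), 8 / 18)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGN"), "illegal")
})

test_that("nearest-neighbor Tm matches an independent reference implementation", {
  # frozen values from a second implementation of the same unified
  # parameter set (50 mM Na+, 62.5 nM duplex concentration term)
  frozen <- c(GTTATATGGACATGGACTCT = 47.849, TTTTTCTGATAGTGCGCC = 49.818,
              AAAAGGGGTGAAAAGGTG = 49.167, CCTCTCTTTCTTGATGAACT = 48.650,
              GTTTCATCGGTTGCTTTCT = 50.545, TCCCTATTCTCATCCCTCT = 49.700)
  for (s in names(frozen))
    expect_lt(abs(melting_temp(s) - frozen[[s]]), 0.5)
  expect_gt(melting_temp("GCGCGCGCGCGCGCGC"),
            melting_temp("ATATATATATATATAT"))
  expect_error(melting_temp("ACGTACGTACGT"), "15-30")
  expect_equal(wallace_tm("GTTATATGGACATGGACTCT"), 56)
})

test_that("dimer scores match the quadratic oracle and are symmetric", {
  p <- "GTTATATGGACATGGACTCT"
  expect_equal(dimer_score(p, reverse_complement(p))[["max_comp_run"]],
               nchar(p))
  expect_equal(
    dimer_score("AAAAAAAAAAAAAAAAAA",
                "TTTTTTTTTTTTTTTTTT")[["max_comp_run"]], 18L)
  set.seed(61)
  for (i in 1:15) {
    a <- random_dna(20)
    b <- random_dna(20)
    expect_identical(dimer_score(a, b), bf_dimer(a, b), info = paste(a, b))
    expect_identical(dimer_score(a, b), dimer_score(b, a))
  }
})

# A designable Y template: random sequence with planted fixed differences.
make_design_case <- function(len = 250L, fixed_at = c(100L, 150L),
                             seed = 71L) {
  set.seed(seed)
  y <- random_dna(len)
  data_sites <- data.frame(
    column_index = fixed_at,
    y_allele = vapply(fixed_at + 1L, function(p) substr(y, p, p),
                      character(1)),
    x_allele = vapply(fixed_at + 1L, function(p)
      setdiff(c("A", "C", "G", "T"), substr(y, p, p))[1], character(1)),
    stringsAsFactors = FALSE)
  list(gene = gene_record("gy", y, c(x = y)), sites = data_sites)
}

loose_cn <- function(...) {
  base <- list(len_min = 20L, len_max = 20L, tm_min = 40, tm_max = 70,
               gc_min = 0.2, gc_max = 0.8, amp_min = 80L, amp_max = 250L)
  do.call(primer_constraints, utils::modifyList(base, list(...)))
}

test_that("no fixed sites means no Y-specific candidates", {
  case <- make_design_case()
  out <- enumerate_candidates(case$gene, NULL, loose_cn(), "y_specific")
  expect_identical(out, list())
})

test_that("every Y-specific pair spans both planted sites when only two exist", {
  case <- make_design_case()
  out <- enumerate_candidates(case$gene, case$sites, loose_cn(),
                              "y_specific")
  expect_gt(length(out), 0L)
  for (p in out) {
    expect_gte(p$n_fixed_diffs_covered, 2L)
    amp_start <- p$fwd_start
    amp_end <- p$rev_start + p$rev_window_len
    expect_true(all(case$sites$column_index >= amp_start &
                      case$sites$column_index < amp_end))
    # 3' anchoring on at least one primer
    expect_true(any(p$forward$anchor_offsets < 5) ||
                  any(p$reverse$anchor_offsets < 5))
  }
})

test_that("enumeration equals a brute-force double loop over windows", {
  case <- make_design_case()
  cn <- loose_cn(x_rejection_check = FALSE)
  got <- enumerate_candidates(case$gene, case$sites, cn, "y_specific")
  y <- case$gene$y_sequence
  L <- nchar(y)
  fs <- case$sites$column_index
  len <- 20L
  qc <- function(s) {
    sq <- substr(y, s + 1L, s + len)
    gc <- gc_content(sq)
    tm <- melting_temp(sq)
    gc >= cn$gc_min && gc <= cn$gc_max && tm >= cn$tm_min && tm <= cn$tm_max
  }
  want <- list()
  for (i in 0:(L - len)) {
    if (!qc(i)) next
    for (j in 0:(L - len)) {
      if (j < i + len) next
      amp <- j + len - i
      if (amp < cn$amp_min || amp > cn$amp_max) next
      if (!qc(j)) next
      anchored <- any(fs >= i + len - 5L & fs < i + len) ||
        any(fs >= j & fs < j + 5L)
      if (!anchored) next
      if (sum(fs >= i & fs < j + len) < 2L) next
      fwd <- substr(y, i + 1L, i + len)
      rev <- reverse_complement(substr(y, j + 1L, j + len))
      d_ok <- function(sc) sc[["max_comp_run"]] < cn$max_comp_run_limit &&
        sc[["three_prime_run"]] < cn$three_prime_run_limit
      if (!d_ok(dimer_score(fwd, fwd)) || !d_ok(dimer_score(rev, rev)) ||
          !d_ok(dimer_score(fwd, rev))) next
      want[[length(want) + 1L]] <- c(i, j)
    }
  }
  got_coords <- lapply(got, function(p) c(p$fwd_start, p$rev_start))
  expect_identical(length(got), length(want))
  expect_setequal(vapply(got_coords, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
})

test_that("enumeration is invariant to fixed-site order and to filter tightening", {
  case <- make_design_case()
  out1 <- enumerate_candidates(case$gene, case$sites, loose_cn(),
                               "y_specific")
  out2 <- enumerate_candidates(case$gene, case$sites[2:1, ], loose_cn(),
                               "y_specific")
  ids <- function(l) vapply(l, `[[`, character(1), "pair_id")
  expect_identical(ids(out1), ids(out2))
  # narrower Tm window: output is a subset
  tight <- enumerate_candidates(case$gene, case$sites,
                                loose_cn(tm_min = 48, tm_max = 58),
                                "y_specific")
  expect_true(all(ids(tight) %in% ids(out1)))
  # larger minimum amplicon: also a subset
  tight2 <- enumerate_candidates(case$gene, case$sites,
                                 loose_cn(amp_min = 150L), "y_specific")
  expect_true(all(ids(tight2) %in% ids(out1)))
})

test_that("primer footprints never span forbidden boundaries", {
  case <- make_design_case()
  bnd <- 110L
  out <- enumerate_candidates(case$gene, case$sites, loose_cn(),
                              "y_specific", forbidden_boundaries = bnd)
  for (p in out) {
    expect_false(p$fwd_start < bnd && p$fwd_start + 20L > bnd)
    expect_false(p$rev_start < bnd && p$rev_start + 20L > bnd)
  }
})

test_that("pair invariants are enforced at construction", {
  f <- primer("GTTATATGGACATGGACTCT", "g", "forward")
  r <- primer("AGAGTCCATGTCCATATAAC", "g", "reverse")
  expect_error(primer_pair(f, r, 174L, "y_specific",
                           n_fixed_diffs_covered = 1L),
               "at least 2 fixed")
  expect_error(primer_pair(f, r, 30L, "autosomal_control"),
               "shorter than the two primer")
  expect_error(primer("ACGT", "g", "forward"), "15-30")
})

test_that("the published panel's product sizes admit a 100 bp gel gap", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  sizes <- sort(vapply(pairs, `[[`, integer(1), "expected_amplicon_bp"))
  expect_identical(sizes, c(174L, 300L, 514L))
  expect_true(all(diff(sizes) >= 100L))
  y <- Filter(function(p) p$target_type == "y_specific", pairs)
  ctrl <- Filter(function(p) p$target_type == "autosomal_control", pairs)
  panel <- select_multiplex(y, ctrl, min_size_gap_bp = 100L)
  expect_s3_class(panel, "multiplex_panel")
  expect_setequal(vapply(panel_pairs(panel), `[[`, character(1), "pair_id"),
                  c("primer23", "primer36", "primer9"))
})

test_that("published primers pass the default per-primer QC", {
  tab <- read_primer_table(table1_path())
  for (i in seq_len(nrow(tab))) {
    for (s in c(tab$forward_seq[i], tab$reverse_seq[i])) {
      expect_true(nchar(s) >= 18 && nchar(s) <= 20)
      expect_true(gc_content(s) >= 0.30 && gc_content(s) <= 0.70)
      expect_lt(dimer_score(s, s)[["three_prime_run"]], 4L)
    }
  }
})

test_that("multiplex selection needs two distinct Y genes and reports binding constraints", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  y <- Filter(function(p) p$target_type == "y_specific", pairs)
  ctrl <- Filter(function(p) p$target_type == "autosomal_control", pairs)
  expect_error(select_multiplex(y[1], ctrl), "distinct")
  expect_error(select_multiplex(list(), ctrl), "empty candidate")
  # an impossible size gap names the constraint
  expect_error(select_multiplex(y, ctrl, min_size_gap_bp = 400L),
               "amplicon-size gap")
})

test_that("multiplex selection matches exhaustive search on small candidate sets", {
  case <- make_design_case(len = 400L, fixed_at = c(60L, 90L, 250L, 320L),
                           seed = 83L)
  cands <- enumerate_candidates(case$gene, case$sites,
                                loose_cn(amp_max = 400L), "y_specific")
  # fabricate a second gene by relabelling half the candidates
  stopifnot(length(cands) >= 4L)
  cands <- cands[seq_len(min(6L, length(cands)))]
  half <- seq_len(length(cands) %/% 2)
  for (i in half) {
    cands[[i]]$forward$gene_id <- "gz"
    cands[[i]]$pair_id <- sub("^gy", "gz", cands[[i]]$pair_id)
  }
  set.seed(97)
  ctrl_seq <- random_dna(300)
  ctrl_gene <- gene_record("ga", ctrl_seq, c(x = ctrl_seq))
  ctrls <- enumerate_candidates(ctrl_gene, NULL,
                                loose_cn(amp_min = 200L, amp_max = 300L),
                                "autosomal_control")
  ctrls <- ctrls[seq_len(min(2L, length(ctrls)))]
  gap <- 20L
  got <- select_multiplex(cands, ctrls, min_size_gap_bp = gap)
  # exhaustive oracle over all (y1 < y2, control) triples
  lims <- list(max_comp_run_limit = 8L, three_prime_run_limit = 4L)
  d_ok <- function(p, q) {
    for (x in list(p$forward, p$reverse)) for (y in list(q$forward,
                                                         q$reverse)) {
      sc <- dimer_score(x, y)
      if (sc[["max_comp_run"]] >= lims$max_comp_run_limit ||
          sc[["three_prime_run"]] >= lims$three_prime_run_limit)
        return(FALSE)
    }
    TRUE
  }
  cross_runs <- function(p, q) {
    tot <- 0L
    for (x in list(p$forward, p$reverse)) for (y in list(q$forward,
                                                         q$reverse))
      tot <- tot + dimer_score(x, y)[["max_comp_run"]]
    tot
  }
  best <- NULL
  for (i in seq_along(cands)) for (j in seq_along(cands)) for (k in
                                                   seq_along(ctrls)) {
    if (j <= i) next
    p <- cands[[i]]; q <- cands[[j]]; r <- ctrls[[k]]
    if (p$forward$gene_id == q$forward$gene_id) next
    sz <- sort(c(p$expected_amplicon_bp, q$expected_amplicon_bp,
                 r$expected_amplicon_bp))
    if (any(diff(sz) < gap)) next
    if (!d_ok(p, q) || !d_ok(p, r) || !d_ok(q, r)) next
    key <- list(-(p$n_fixed_diffs_covered + q$n_fixed_diffs_covered),
                cross_runs(p, q) + cross_runs(p, r) + cross_runs(q, r),
                paste(sort(c(p$forward$gene_id, q$forward$gene_id)),
                      collapse = "|"),
                p$pair_id, q$pair_id, r$pair_id)
    if (is.null(best) || isTRUE(.lt(key, best$key)))
      best <- list(key = key, ids = c(p$pair_id, q$pair_id, r$pair_id))
  }
  expect_false(is.null(best))
  expect_setequal(vapply(panel_pairs(got), `[[`, character(1), "pair_id"),
                  best$ids)
})
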