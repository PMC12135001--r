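# Independent brute-force oracles used to cross-check the package
# implementations on small instances. Each oracle is written as a direct
# transcription of the definition, not a second copy of the production code.

# -- global alignment: exhaustive recursion over alignment paths with affine
#    gap costs (a gap of length L costs gap_open + L * gap_extend)
bf_align_score <- function(a, b, sc = alignment_scoring()) {
  na <- nchar(a); nb <- nchar(b)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (substr(a, i, i) == substr(b, j, j)) sc$match else sc$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= na) {
      pen <- sc$gap_extend + if (last != "D") sc$gap_open else 0
      best <- max(best, pen + rec(i + 1L, j, "D"))
    }
    if (j <= nb) {
      pen <- sc$gap_extend + if (last != "I") sc$gap_open else 0
      best <- max(best, pen + rec(i, j + 1L, "I"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# -- Nei-Gojobori: codon-by-codon pathway enumeration written from the
#    definition (recursive path walk, direct mutant enumeration for sites)
bf_ng86 <- function(cds_a, cds_b) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons_of <- function(s) substring(s, seq(1, nchar(s), 3),
                                     seq(3, nchar(s), 3))
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(cod, p, p))) {
      mut <- cod
      substr(mut, p, p) <- b
      if (code[[mut]] != "*" && code[[mut]] == code[[cod]]) s <- s + 1 / 3
    }
    s
  }
  path_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    walk <- function(cur, remaining) {
      if (!length(remaining))
        return(list(c(syn = 0, nonsyn = 0, stop = 0)))
      out <- list()
      for (k in seq_along(remaining)) {
        p <- remaining[k]
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        step_stop <- code[[cur]] == "*" || code[[nxt]] == "*"
        step <- if (step_stop) c(0, 1, 1)
                else if (code[[cur]] == code[[nxt]]) c(1, 0, 0) else c(0, 1, 0)
        for (tail in walk(nxt, remaining[-k]))
          out[[length(out) + 1L]] <- step + tail
      }
      out
    }
    paths <- walk(c1, pos)
    ok <- vapply(paths, function(p) p[3] == 0, logical(1))
    use <- if (any(ok)) paths[ok] else paths
    c(mean(vapply(use, `[`, numeric(1), 1)),
      mean(vapply(use, `[`, numeric(1), 2)))
  }
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
          sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) path_diffs(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S
  pn <- d[2] / N
  list(S = S, N = N, sd = d[1], nd = d[2], ps = ps,
       ds = if (ps >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * ps),
       dn = if (pn >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * pn))
}

# -- dimer score: quadratic all-offsets, per-position run scan
bf_dimer <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(reverse_complement(s2), "")[[1]]
  n1 <- length(a); n2 <- length(b)
  max_run <- 0L; tp_run <- 0L
  for (off in (-(n2 - 1L)):(n1 - 1L)) {
    for (start in 1:n1) {
      if (start - off < 1L || start - off > n2) next
      run <- 0L
      k <- start
      while (k <= n1 && k - off >= 1L && k - off <= n2 &&
             a[k] == b[k - off]) {
        run <- run + 1L
        # run currently ends at a position k / b position k - off
        if (run > max_run) max_run <- run
        if ((k == n1 || (k - off) == 1L) && run > tp_run) tp_run <- run
        k <- k + 1L
      }
    }
  }
  # for runs touching b position 1, the run ending AT the 3' terminus of p2
  # extends from b position 1 upward; rescan explicitly
  for (off in 0:(n1 - 1L)) {
    run <- 0L
    k <- off + 1L  # a position aligned to b position 1
    while (k <= n1 && k - off <= n2 && a[k] == b[k - off]) {
      run <- run + 1L
      k <- k + 1L
    }
    if (run > tp_run) tp_run <- run
  }
  c(max_comp_run = max_run, three_prime_run = tp_run)
}

# -- binding sites: naive scan of every offset on both strands
bf_binding_sites <- function(primer_seq, template_seq, max_mismatch,
                             tp_exact) {
  plen <- nchar(primer_seq)
  tlen <- nchar(template_seq)
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") primer_seq else reverse_complement(primer_seq)
    qc <- strsplit(q, "")[[1]]
    for (s in 1:(tlen - plen + 1L)) {
      frag <- strsplit(substr(template_seq, s, s + plen - 1L), "")[[1]]
      mm <- frag != qc
      tp_idx <- if (strand == "+") (plen - tp_exact + 1L):plen else
        1:tp_exact
      if (sum(mm) <= max_mismatch && !any(mm[tp_idx]))
        out <- rbind(out, data.frame(start = s - 1L, strand = strand,
                                     n_mismatches = sum(mm)))
    }
  }
  out
}

# -- random stop-free coding sequence
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sense <- chartr("U", "T", sense)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

table1_path <- function() system.file("extdata", "table1_primers.tsv",
                                      package = "sexmarker")

# lexicographic comparison of mixed numeric/character ranking keys
.lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[[i]] < b[[i]]) return(TRUE)
    if (a[[i]] > b[[i]]) return(FALSE)
  }
  FALSE
}

# a ready-made three-pair panel from the packaged fixture
.panel_stub <- function() {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  structure(list(y_pairs = pairs[1:2], control_pair = pairs[[3]],
                 min_size_gap_bp = 100L), class = "multiplex_panel")
}
table2_path <- function() system.file("extdata", "table2_counts.tsv",
                                      package = "sexmarker")
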