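# Codon site counting, Nei-Gojobori divergence, fixed-difference calling,
# and the gene-selection filters.

test_that("codon site counts match single-mutant enumeration", {
  expect_equal(count_codon_sites("TTT")[["syn_sites"]], 1 / 3)
  expect_equal(count_codon_sites("ATG")[["syn_sites"]], 0)
  expect_equal(count_codon_sites("GGG")[["syn_sites"]], 1)
  # every codon: totals 3, and agrees with the oracle's direct enumeration
  code <- Biostrings::GENETIC_CODE
  for (cod in sample(names(code)[code != "*"], 15)) {
    got <- count_codon_sites(cod)
    expect_equal(sum(got), 3)
    expect_equal(got[["syn_sites"]], bf_ng86(cod, cod)$S, info = cod)
  }
  expect_error(count_codon_sites("TAA"), "stop codon")
  expect_error(count_codon_sites("ANA"), "ambiguous")
})

test_that("identical sequences have zero divergence", {
  s <- random_cds(30, seed = 5)
  est <- nei_gojobori_ds(s, s)
  expect_equal(est$ds, 0)
  expect_equal(est$dn, 0)
  expect_equal(est$syn_sites + est$nonsyn_sites, 3 * 30)
})

test_that("a single synonymous change follows the closed form", {
  set.seed(23)
  cds <- random_cds(300)
  # mutate one third position synonymously (GGG -> GGA style)
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  code <- Biostrings::GENETIC_CODE
  idx <- which(vapply(cods, function(cd) {
    alt <- cd
    substr(alt, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(cd, 3, 3))[1]
    code[[alt]] != "*" && code[[alt]] == code[[cd]]
  }, logical(1)))[1]
  alt <- cods[idx]
  substr(alt, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(alt, 3, 3))[1]
  cods2 <- cods
  cods2[idx] <- alt
  est <- nei_gojobori_ds(cds, paste(cods2, collapse = ""))
  S <- est$syn_sites
  expect_equal(est$syn_diffs, 1)
  expect_equal(est$ps, 1 / S)
  expect_equal(est$ds, -3 / 4 * log(1 - 4 / 3 / S))
})

test_that("divergence matches the pathway-enumeration oracle on 30-codon pairs", {
  set.seed(31)
  for (rep in 1:5) {
    a <- random_cds(30)
    b <- mutate_cds(a, target_ds = 0.15, seed = rep)
    got <- nei_gojobori_ds(a, b)
    want <- bf_ng86(a, b)
    expect_equal(got$syn_sites, want$S)
    expect_equal(got$syn_diffs, want$sd)
    expect_equal(got$nonsyn_diffs, want$nd)
    expect_equal(got$ds, want$ds)
    # symmetry
    rev <- nei_gojobori_ds(b, a)
    expect_equal(rev$ds, got$ds)
    expect_equal(rev$dn, got$dn)
  }
})

test_that("ds grows with added synonymous differences and saturates at ps >= 3/4", {
  cds <- paste(rep("GGG", 40), collapse = "")  # third position fully synonymous
  mutate_k <- function(k) {
    cods <- rep("GGG", 40)
    if (k > 0) cods[seq_len(k)] <- "GGA"
    paste(cods, collapse = "")
  }
  ds_vals <- vapply(0:5, function(k)
    nei_gojobori_ds(cds, mutate_k(k))$ds, numeric(1))
  expect_true(all(diff(ds_vals) > 0))
  # all 40 synonymous sites differing: ps = 1 -> saturated
  est <- nei_gojobori_ds(cds, mutate_k(40))
  expect_true(est$saturated_ds)
  expect_true(is.na(est$ds))
})

test_that("gapped/N codons are dropped pairwise and premature stops abort", {
  est_full <- nei_gojobori_ds("AAAGGGTTT", "AAAGGATTT")
  est_gap <- nei_gojobori_ds("AAA---GGGTTT", "AAACCCGGATTT")
  expect_equal(est_gap$syn_diffs, est_full$syn_diffs)
  expect_equal(est_gap$n_codons, 3L)
  est_n <- nei_gojobori_ds("AANGGGTTT", "AAAGGATTT")
  expect_equal(est_n$n_codons, 2L)
  expect_error(nei_gojobori_ds("TAAGGG", "AAAGGG"), "premature stop")
  # terminal stop codons are tolerated, just not compared
  est_term <- nei_gojobori_ds("AAAGGGTAA", "AAAGGATAA")
  expect_equal(est_term$n_codons, 2L)
  expect_error(nei_gojobori_ds("AAA", "AAAGGG"), "differ in length")
  expect_error(nei_gojobori_ds("N-A", "AAA"), "no comparable codons")
})

test_that("fixed differences require fixity across all X haplotypes", {
  expect_identical(nrow(suppressWarnings(
    call_fixed_differences("ACGT", list("ACGT")))), 0L)
  y <- "ACGTACGTACGTACGTACGT"
  x <- y
  substr(x, 5, 5) <- "G"  # A -> G at 0-based position 4
  fd <- call_fixed_differences(y, list(x, x, x))
  expect_identical(fd$column_index, 4L)
  expect_identical(fd$y_allele, "A")
  expect_identical(fd$x_allele, "G")
  # polymorphic in X: not fixed
  fd2 <- call_fixed_differences(y, list(x, x, y))
  expect_identical(nrow(fd2), 0L)
  expect_warning(call_fixed_differences(y, list(x)), "fewer than 3")
  expect_error(suppressWarnings(call_fixed_differences(y, list())),
               "non-empty")
})

test_that("with one X haplotype every ungapped mismatch column is reported", {
  set.seed(41)
  y <- random_dna(120)
  x <- y
  pos <- sample(120, 10)
  for (p in pos) {
    substr(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(x, p, p))[sample(3, 1)]
  }
  fd <- suppressWarnings(call_fixed_differences(y, list(x)))
  expect_setequal(fd$column_index, pos - 1L)
})

test_that("N or gap under any haplotype masks a site", {
  y <- "ACGTACGTACGTACGTACGT"
  x1 <- y; substr(x1, 5, 5) <- "G"
  x2 <- x1; substr(x2, 5, 5) <- "N"
  expect_identical(nrow(call_fixed_differences(y, list(x1, x1, x2))), 0L)
})

test_that("gene selection applies all four filters in order", {
  mk <- function(id, stratum = 1L, expr = TRUE, intron = 400L, ds = 0.2)
    gene_record(id, "ATGAAA", c(x = "ATGAAA"), stratum = stratum,
                y_expressed = expr, intron_length_bp = intron, ds = ds)
  genes <- list(mk("g_unexpr", expr = FALSE, ds = 0.9),
                mk("g_young", stratum = 2L, ds = 0.9),
                mk("g_short_intron", intron = 250L, ds = 0.9),
                mk("g_ok1", ds = 0.30), mk("g_ok2", ds = 0.10))
  sel <- select_candidate_genes(genes, top_k = 20L, min_intron_bp = 300L)
  expect_identical(vapply(sel, `[[`, character(1), "gene_id"),
                   c("g_ok1", "g_ok2"))
  # top_k applies before the intron filter, on the stratum survivors
  sel2 <- select_candidate_genes(genes, top_k = 1L, min_intron_bp = 300L)
  expect_identical(vapply(sel2, `[[`, character(1), "gene_id"),
                   character(0))  # the single top-ds gene has a short intron
})

test_that("top-k selection matches a sort oracle and is idempotent", {
  set.seed(53)
  ds_vals <- round(runif(30), 6)
  genes <- lapply(seq_along(ds_vals), function(i)
    gene_record(sprintf("g%02d", i), "ATGAAA", c(x = "ATGAAA"),
                stratum = 1L, y_expressed = TRUE, intron_length_bp = 500L,
                ds = ds_vals[i]))
  sel <- select_candidate_genes(genes, top_k = 20L, min_intron_bp = 300L)
  expect_length(sel, 20L)
  want <- sprintf("g%02d", order(-ds_vals)[1:20])
  expect_setequal(vapply(sel, `[[`, character(1), "gene_id"), want)
  again <- select_candidate_genes(sel, top_k = 20L, min_intron_bp = 300L)
  expect_identical(vapply(again, `[[`, character(1), "gene_id"),
                   vapply(sel, `[[`, character(1), "gene_id"))
})

test_that("missing metadata is reported with the gene id", {
  g <- gene_record("g_bad", "ATGAAA", c(x = "ATGAAA"))
  g$ds <- NULL
  expect_error(select_candidate_genes(list(g)), "g_bad")
})
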