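# Binding-site search, amplicon prediction, marker validation, sex calling.

embed_at <- function(template, insert, pos) {
  paste0(substr(template, 1, pos), insert,
         substr(template, pos + nchar(insert) + 1, nchar(template)))
}

test_that("a verbatim embedded primer yields exactly one plus-strand site", {
  set.seed(101)
  p <- random_dna(20)
  tmpl <- embed_at(random_dna(200), p, 80)
  sites <- find_binding_sites(p, tmpl, max_mismatch = 0)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 80L)
  expect_identical(sites$end, 100L)
  expect_identical(sites$strand, "+")
  expect_identical(sites$n_mismatches, 0L)
  expect_false(sites$three_prime_mismatch)
})

test_that("an embedded reverse complement is found on the minus strand", {
  set.seed(103)
  p <- random_dna(20)
  tmpl <- embed_at(random_dna(200), reverse_complement(p), 60)
  sites <- find_binding_sites(p, tmpl, max_mismatch = 0)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$strand, "-")
  expect_identical(sites$start, 60L)
})

test_that("a 3'-terminal mismatch abolishes binding regardless of budget", {
  set.seed(107)
  p <- random_dna(20)
  mism <- p
  substr(mism, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(p, 20, 20))[1]
  tmpl <- embed_at(random_dna(200), mism, 90)
  expect_identical(nrow(find_binding_sites(p, tmpl, max_mismatch = 2,
                                           three_prime_exact_nt = 3)), 0L)
  # the same mismatch placed outside the 3' window is tolerated
  mism2 <- p
  substr(mism2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 substr(p, 5, 5))[1]
  tmpl2 <- embed_at(random_dna(200), mism2, 90)
  sites <- find_binding_sites(p, tmpl2, max_mismatch = 2)
  expect_identical(sites$n_mismatches, 1L)
  # N in the template counts as a mismatch
  mism3 <- p
  substr(mism3, 5, 5) <- "N"
  tmpl3 <- embed_at(random_dna(200), mism3, 90)
  expect_identical(find_binding_sites(p, tmpl3,
                                      max_mismatch = 0)$n_mismatches,
                   integer(0))
  expect_identical(find_binding_sites(p, tmpl3,
                                      max_mismatch = 1)$n_mismatches, 1L)
})

test_that("site search matches a naive scan and respects strand symmetry", {
  set.seed(109)
  for (rep in 1:5) {
    p <- random_dna(12)
    tmpl <- random_dna(400)
    for (mm in 0:2) {
      got <- find_binding_sites(p, tmpl, max_mismatch = mm,
                                three_prime_exact_nt = 3)
      want <- bf_binding_sites(p, tmpl, mm, 3)
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(nrow(got), nrow(want))
        key <- function(d) sort(paste(d$start, d$strand, d$n_mismatches))
        expect_identical(key(got), key(want))
      }
      # reverse-complementing the template swaps strands, preserves counts
      rc <- find_binding_sites(p, reverse_complement(tmpl),
                               max_mismatch = mm, three_prime_exact_nt = 3)
      expect_identical(nrow(rc), nrow(got))
      expect_identical(sum(rc$strand == "+"), sum(got$strand == "-"))
    }
  }
})

test_that("a constructed template yields one amplicon of the designed size", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  p23 <- pairs[[1]]
  set.seed(113)
  tmpl <- paste0(random_dna(50), p23$forward$sequence, random_dna(136),
                 reverse_complement(p23$reverse$sequence), random_dna(50))
  amps <- predict_amplicons(p23, tmpl)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length_bp, 174L)
  expect_identical(amps$start, 50L)
})

test_that("forward-only templates and out-of-range products give no amplicon", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  p23 <- pairs[[1]]
  set.seed(127)
  expect_identical(nrow(predict_amplicons(
    p23, paste0(random_dna(30), p23$forward$sequence, random_dna(100)))),
    0L)
  # product longer than amp_max is suppressed
  tmpl <- paste0(p23$forward$sequence, random_dna(500),
                 reverse_complement(p23$reverse$sequence))
  expect_identical(nrow(predict_amplicons(p23, tmpl,
                                          insilico_settings(amp_max = 300L))),
                   0L)
  expect_identical(nrow(predict_amplicons(p23, tmpl)), 1L)
})

test_that("multiple forward sites pair combinatorially with a reverse site", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  p23 <- pairs[[1]]
  set.seed(131)
  tmpl <- paste0(p23$forward$sequence, random_dna(80),
                 p23$forward$sequence, random_dna(80),
                 reverse_complement(p23$reverse$sequence))
  amps <- predict_amplicons(p23, tmpl)
  expect_identical(nrow(amps), 2L)
  expect_true(all(amps$length_bp >=
                    nchar(p23$forward$sequence) +
                      nchar(p23$reverse$sequence)))
})

test_that("marker validation applies the sex-specific amplification rule", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  p23 <- pairs[[1]]
  ctrl <- pairs[[3]]
  set.seed(137)
  target <- paste0(p23$forward$sequence, random_dna(136),
                   reverse_complement(p23$reverse$sequence))
  ctrl_target <- paste0(ctrl$forward$sequence, random_dna(476),
                        reverse_complement(ctrl$reverse$sequence))
  male <- list(genome_id = "m1", expected_sex = "male",
               records = list(seq_record("chrY",
                                         paste0(random_dna(40), target,
                                                random_dna(40))),
                              seq_record("auto_m", ctrl_target)))
  female <- list(genome_id = "f1", expected_sex = "female",
                 records = list(seq_record("chrX", random_dna(400)),
                                seq_record("auto_f", ctrl_target)))
  mv <- validate_marker(p23, list(male, female))
  expect_true(mv$valid)
  expect_identical(mv$per_genome$n_amplicons, c(1L, 0L))
  # Y target leaking onto the female X invalidates the marker
  female_bad <- female
  female_bad$records[[1]] <- seq_record("chrX", paste0(random_dna(40),
                                                       target))
  expect_false(validate_marker(p23, list(male, female_bad))$valid)
  # a control must amplify once in every genome
  expect_true(validate_marker(ctrl, list(male, female))$valid)
  no_ctrl <- list(genome_id = "g0", expected_sex = "female",
                  records = list(seq_record("chrX", random_dna(400))))
  expect_false(validate_marker(ctrl, list(male, female, no_ctrl))$valid)
})

test_that("sex calling follows the control/Y band logic", {
  pairs <- primer_table_to_pairs(read_primer_table(table1_path()))
  panel <- structure(list(y_pairs = pairs[1:2], control_pair = pairs[[3]],
                          min_size_gap_bp = 100L),
                     class = "multiplex_panel")
  expect_identical(call_sex(c(514, 174, 300), panel)$call, "male")
  expect_identical(call_sex(c(514, 174), panel)$call, "male")
  expect_identical(call_sex(514, panel)$call, "female")
  expect_identical(call_sex(numeric(0), panel)$call, "failed")
  expect_identical(call_sex(c(174, 300), panel)$call, "failed")
  # band sizes are matched within 10%
  expect_identical(call_sex(c(530, 180), panel)$call, "male")
  # an unattributable band is flagged but does not change the call
  res <- call_sex(c(514, 1000), panel)
  expect_identical(res$call, "female")
  expect_identical(res$unattributed, 1000)
})
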