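# Orchestration of the full marker-development workflow:
# simulate -> design -> validate -> evaluate.

#' Pipeline configuration
#'
#' One nested configuration covering every stage, with all defaults in one
#' place. Unknown keys (top-level or nested) are rejected.
#'
#' @param simulation A [simulation_config()] or a list of overrides for it.
#' @param selection List with `top_k` (default 20) and `min_intron_bp`
#'   (default 300).
#' @param primer List of overrides for [primer_constraints()].
#' @param insilico List of overrides for [insilico_settings()].
#' @param multiplex List with `min_size_gap_bp` (default 60) and
#'   `max_candidates_per_gene` (default 6; only the best few size-diverse
#'   candidates per gene enter the combinatorial panel search).
#' @param verbosity `"quiet"`, `"info"` or `"debug"`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), selection = list(),
                            primer = list(), insilico = list(),
                            multiplex = list(), verbosity = "info") {
  merge_known <- function(defaults, overrides, what) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    # shallow merge: overrides replace defaults wholesale (a strata
    # data.frame must not be merged element-wise)
    for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
    defaults
  }
  sim <- if (inherits(simulation, "simulation_config")) simulation else {
    if (!is.null(simulation$strata) && is.list(simulation$strata) &&
        !is.data.frame(simulation$strata))
      simulation$strata <- do.call(rbind,
                                   lapply(simulation$strata, as.data.frame))
    do.call(simulation_config,
            merge_known(formals_defaults(simulation_config), simulation,
                        "simulation"))
  }
  sel <- merge_known(list(top_k = 20L, min_intron_bp = 300L), selection,
                     "selection")
  prm <- merge_known(formals_defaults(primer_constraints), primer, "primer")
  ins <- merge_known(formals_defaults(insilico_settings), insilico,
                     "insilico")
  mpx <- merge_known(list(min_size_gap_bp = 60L,
                          max_candidates_per_gene = 6L), multiplex,
                     "multiplex")
  if (!verbosity %in% c("quiet", "info", "debug"))
    stop("unknown verbosity '", verbosity, "'", call. = FALSE)
  structure(list(simulation = sim, selection = sel, primer = prm,
                 insilico = ins, multiplex = mpx, verbosity = verbosity),
            class = "pipeline_config")
}

# enumerate candidates in consecutive amplicon-size bands (band_bp wide),
# stopping each band's position-ordered scan after `per_band` accepted
# pairs: bounds the work while guaranteeing size-diverse candidates
.enumerate_banded <- function(gene, fixed_sites, primer_overrides,
                              target_type, boundaries, band_bp,
                              per_band = 12L) {
  base <- do.call(primer_constraints, primer_overrides)
  lo <- base$amp_min
  out <- list()
  while (lo <= base$amp_max) {
    hi <- min(lo + band_bp - 1L, base$amp_max)
    cn <- do.call(primer_constraints,
                  utils::modifyList(primer_overrides,
                                    list(amp_min = lo, amp_max = hi,
                                         max_pairs = per_band)))
    out <- c(out, enumerate_candidates(gene, fixed_sites, cn, target_type,
                                       forbidden_boundaries = boundaries))
    lo <- hi + 1L
  }
  out
}

# keep up to k candidates spread over distinct amplicon-size bins, so the
# panel search can satisfy the pairwise size-gap constraint; within a bin
# the candidate covering most fixed differences (ties: pair_id) wins
.diverse_by_size <- function(cands, bin_bp, k) {
  if (length(cands) == 0L) return(list())
  sizes <- vapply(cands, `[[`, integer(1), "expected_amplicon_bp")
  nfx <- vapply(cands, `[[`, integer(1), "n_fixed_diffs_covered")
  ids <- vapply(cands, `[[`, character(1), "pair_id")
  bin <- sizes %/% max(bin_bp, 1L)
  ord <- order(-nfx, ids)
  seen <- character(0)
  keep <- integer(0)
  for (i in ord) {
    b <- as.character(bin[i])
    if (b %in% seen) next
    seen <- c(seen, b)
    keep <- c(keep, i)
    if (length(keep) >= k) break
  }
  cands[sort(keep)]
}

# evaluated default arguments of a function, as a named list
formals_defaults <- function(fn) {
  fm <- formals(fn)
  out <- list()
  for (nm in names(fm)) {
    v <- fm[[nm]]
    out[[nm]] <- if (is.language(v)) eval(v) else v
  }
  out
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML path with any subset of the [pipeline_config()]
#'   sections.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Design a multiplex panel for a cohort
#'
#' Runs the design stage: gene selection by divergence and metadata
#' filters, fixed-difference calling of each selected gene, primer-pair
#' enumeration with exon-junction exclusion, genomic product-size
#' adjustment (an amplicon spanning the exon junction gains the intron
#' length), and multiplex panel assembly against autosomal control
#' candidates.
#'
#' @param cohort A `synthetic_cohort` (or any list with the same fields).
#' @param config A [pipeline_config()].
#' @return List with `panel` (a `multiplex_panel`), `selected_genes`,
#'   `fixed_sites` (per-gene list), `y_candidates`, `control_candidates`.
#' @export
design_markers <- function(cohort, config = pipeline_config()) {
  cn <- do.call(primer_constraints, config$primer)
  selected <- select_candidate_genes(cohort$gene_records,
                                     top_k = config$selection$top_k,
                                     min_intron_bp =
                                       config$selection$min_intron_bp)
  if (length(selected) == 0L)
    stop("design infeasible: no gene passes the selection filters",
         call. = FALSE)
  fixed_sites <- list()
  y_cands <- list()
  for (g in selected) {
    fs <- suppressWarnings(call_fixed_differences(g$y_sequence,
                                                  as.list(g$x_sequences)))
    fixed_sites[[g$gene_id]] <- fs
    tr <- cohort$truth[[g$gene_id]]
    boundary <- if (!is.null(tr)) tr$exon_boundary else integer(0)
    cands <- .enumerate_banded(g, fs, config$primer, "y_specific", boundary,
                               band_bp = 2L * config$multiplex$min_size_gap_bp)
    if (length(cands) == 0L) next
    # genomic product size: amplicons spanning the junction gain the intron
    if (!is.null(tr) && tr$intron_length_bp > 0) {
      cands <- lapply(cands, function(p) {
        spans <- p$fwd_start < tr$exon_boundary &&
          (p$rev_start + p$rev_window_len) > tr$exon_boundary
        if (spans)
          p$expected_amplicon_bp <- p$expected_amplicon_bp +
            as.integer(tr$intron_length_bp)
        p
      })
    }
    y_cands <- c(y_cands,
                 .diverse_by_size(cands,
                                  2L * config$multiplex$min_size_gap_bp,
                                  config$multiplex$max_candidates_per_gene))
  }
  if (length(y_cands) == 0L)
    stop("design infeasible: no y_specific primer pair found on the ",
         length(selected), " selected gene(s)", call. = FALSE)
  ctrl_cands <- list()
  for (a in names(cohort$autosomal_genes)) {
    ag <- gene_record(a, cohort$autosomal_genes[[a]],
                      c(placeholder = cohort$autosomal_genes[[a]]))
    cands <- .enumerate_banded(ag, NULL, config$primer, "autosomal_control",
                               integer(0),
                               band_bp = 2L * config$multiplex$min_size_gap_bp)
    ctrl_cands <- c(ctrl_cands,
                    .diverse_by_size(cands,
                                     2L * config$multiplex$min_size_gap_bp,
                                     config$multiplex$max_candidates_per_gene))
    if (length(ctrl_cands) >= config$multiplex$max_candidates_per_gene)
      break
  }
  panel <- select_multiplex(y_cands, ctrl_cands,
                            min_size_gap_bp =
                              config$multiplex$min_size_gap_bp,
                            dimer_limits = list(
                              max_comp_run_limit = cn$max_comp_run_limit,
                              three_prime_run_limit =
                                cn$three_prime_run_limit))
  list(panel = panel, selected_genes = selected, fixed_sites = fixed_sites,
       y_candidates = y_cands, control_candidates = ctrl_cands)
}

#' Run the marker-development pipeline
#'
#' Subcommands: `simulate` writes a synthetic cohort directory; `design`
#' reads a cohort and writes the primer table of the selected multiplex
#' panel; `validate` predicts amplicons of the panel on every cohort genome
#' and writes amplicon and marker-validation reports; `evaluate`
#' summarises an assay results (or count) table into confusion statistics;
#' `all` chains the four stages on one cohort. Every run appends a log
#' (`pipeline.log`) with a config echo and the package version.
#'
#' @param command One of `"simulate"`, `"design"`, `"validate"`,
#'   `"evaluate"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param in_dir Input directory (cohort dir for `design`/`validate`;
#'   defaults to `out_dir`).
#' @param results_path For `evaluate`: a results TSV
#'   (`sample_id cultivar phenotypic_sex called_sex`) or a per-cultivar
#'   count TSV; defaults to the assay simulated by `all`.
#' @param seed Overrides the simulation seed.
#' @return Invisibly, a list of produced artifact paths (and in-memory
#'   objects for `all`).
#' @export
run_pipeline <- function(command = c("all", "simulate", "design", "validate",
                                     "evaluate"),
                         config = pipeline_config(), out_dir,
                         in_dir = out_dir, results_path = NULL,
                         seed = NULL) {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$simulation$seed <- as.integer(seed)
  log_path <- file.path(out_dir, "pipeline.log")
  # no wall-clock stamps: identical runs must leave byte-identical artifacts
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbosity != "quiet") message(msg)
  }
  logline("sexmarker ", as.character(utils::packageVersion("sexmarker")),
          " command=", command, " seed=", config$simulation$seed)
  cfg_echo <- file.path(out_dir, "pipeline_config.yaml")
  echo <- list(selection = config$selection, primer = config$primer,
               insilico = config$insilico, multiplex = config$multiplex,
               simulation = {
                 s <- unclass(config$simulation)
                 s$strata <- lapply(seq_len(nrow(s$strata)), function(i)
                   list(label = s$strata$label[i],
                        target_ds = s$strata$target_ds[i]))
                 s
               })
  yaml::write_yaml(echo, cfg_echo)
  artifacts <- list(log = log_path, config_echo = cfg_echo)

  settings <- do.call(insilico_settings, config$insilico)
  cohort <- NULL
  design <- NULL

  if (command %in% c("simulate", "all")) {
    cohort <- simulate_cohort(config$simulation)
    cdir <- file.path(out_dir, "cohort")
    write_cohort(cohort, cdir)
    logline("simulate: wrote cohort (", length(cohort$gene_records),
            " genes, ", nrow(cohort$samples), " samples) to ",
            basename(cdir), "/")
    artifacts$cohort_dir <- cdir
  }
  if (command %in% c("design", "validate") && is.null(cohort)) {
    cdir <- if (dir.exists(file.path(in_dir, "cohort")))
      file.path(in_dir, "cohort") else in_dir
    if (!dir.exists(cdir))
      stop("missing input: cohort directory ", cdir, call. = FALSE)
    cohort <- read_cohort(cdir)
  }
  if (command %in% c("design", "validate", "all")) {
    design <- design_markers(cohort, config)
    pp <- panel_pairs(design$panel)
    tab <- data.frame(
      primer_id = vapply(pp, `[[`, character(1), "pair_id"),
      type = ifelse(vapply(pp, `[[`, character(1), "target_type") ==
                      "y_specific", "XY", "autosomal"),
      gene_id = vapply(pp, function(p) p$forward$gene_id, character(1)),
      forward_seq = vapply(pp, function(p) p$forward$sequence, character(1)),
      reverse_seq = vapply(pp, function(p) p$reverse$sequence, character(1)),
      xy_ds = vapply(pp, function(p) {
        g <- cohort$gene_records[[p$forward$gene_id]]
        if (is.null(g) || is.na(g$ds)) NA_real_ else round(g$ds, 4)
      }, numeric(1)),
      amplicon_bp = vapply(pp, `[[`, integer(1), "expected_amplicon_bp"),
      stringsAsFactors = FALSE)
    ppath <- file.path(out_dir, "panel_primers.tsv")
    write_primer_table(tab, ppath)
    logline("design: panel ", paste(tab$primer_id, collapse = ", "),
            " (products ", paste(tab$amplicon_bp, collapse = "/"), " bp)")
    artifacts$primer_table <- ppath
  }
  if (command %in% c("validate", "all")) {
    amp_rows <- list()
    val_rows <- list()
    for (p in panel_pairs(design$panel)) {
      mv <- validate_marker(p, cohort$genomes, settings)
      val_rows[[length(val_rows) + 1L]] <-
        cbind(pair_id = p$pair_id, target_type = p$target_type,
              valid = mv$valid, mv$per_genome)
      for (g in cohort$genomes) {
        for (rec in g$records) {
          amps <- predict_amplicons(p, rec, settings)
          if (nrow(amps))
            amp_rows[[length(amp_rows) + 1L]] <-
              cbind(pair_id = p$pair_id, genome_id = g$genome_id, amps)
        }
      }
    }
    vpath <- file.path(out_dir, "marker_validation.tsv")
    utils::write.table(do.call(rbind, val_rows), vpath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    apath <- file.path(out_dir, "amplicons.tsv")
    amp_df <- if (length(amp_rows)) do.call(rbind, amp_rows) else
      data.frame(pair_id = character(0), genome_id = character(0))
    write_amplicon_report(amp_df, apath)
    logline("validate: ", length(val_rows), " marker(s) against ",
            length(cohort$genomes), " genome(s)")
    artifacts$marker_validation <- vpath
    artifacts$amplicon_report <- apath
  }
  if (command %in% c("evaluate", "all")) {
    results <- if (!is.null(results_path)) {
      if (!file.exists(results_path))
        stop("missing input: ", results_path, call. = FALSE)
      hdr <- names(utils::read.delim(results_path, nrows = 1))
      if ("called_sex" %in% hdr) read_assay_results(results_path)
      else counts_to_results(read_count_table(results_path))
    } else {
      if (is.null(design))
        stop("missing input: `results_path` is required for a standalone ",
             "evaluate", call. = FALSE)
      simulate_assay(design$panel, cohort, settings = settings)
    }
    summ <- summarize_assay(results)
    spath <- file.path(out_dir, "confusion_summary.tsv")
    utils::write.table(summ, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    tot <- summ[summ$cultivar == "Total", ]
    logline(sprintf(
      "evaluate: n=%d, true positive rate %.1f%%, specificity %s",
      tot$n, tot$tpr_percent,
      if (is.na(tot$specificity_percent)) "NA"
      else sprintf("%.1f%%", tot$specificity_percent)))
    artifacts$confusion_summary <- spath
    artifacts$summary <- summ
  }
  if (command == "all") {
    artifacts$cohort <- cohort
    artifacts$design <- design
  }
  invisible(artifacts)
}
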