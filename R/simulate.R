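# Seeded simulator of XY gene systems, cultivar cohorts and genome
# templates. The generator's defaults mirror the data regime the design
# pipeline targets: a small set of sex-linked genes spread over strata of
# decreasing X-Y synonymous divergence (oldest stratum near dS 0.25, the
# range in which usable markers sit), three X haplotype lineages from
# distinct cultivar groups with far lower intra-X diversity, 300-codon
# genes carrying one intron, and a 12-cultivar cohort of 192 samples with a
# roughly even sex ratio.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic per-component subseeds below 2^31
.subseed <- function(seed, i) (as.numeric(seed) * 1103L + i * 12347) %% 2147483647

#' Simulation configuration
#'
#' @param n_genes Number of sex-linked genes.
#' @param strata `data.frame` with columns `label` (ordinal, lower = older)
#'   and `target_ds` (X-Y synonymous divergence the Y copy is mutated to;
#'   must stay below the Jukes-Cantor saturation region, < 0.74).
#' @param n_x_haplotypes Number of X haplotype lineages (>= 1).
#' @param intra_x_diversity Per-site substitution probability applied
#'   independently to each X lineage; must be much smaller than the
#'   smallest stratum `target_ds`.
#' @param gene_length_codons Coding length of every gene, in codons.
#' @param intron_length_bp Intron inserted at a random codon boundary of
#'   every gene.
#' @param n_autosomal_genes Autosomal genes shared by both sexes.
#' @param n_cultivars,n_samples_per_cultivar Cohort layout.
#' @param y_expressed_rate Fraction of sex-linked genes whose Y copy is
#'   flagged as still expressed.
#' @param phenotyping_error_rate Probability that a sample's recorded
#'   phenotypic sex is wrong.
#' @param seed Master seed; all randomness derives from it.
#' @return Validated config list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 12L,
                              strata = data.frame(
                                label = c(1L, 2L, 3L),
                                target_ds = c(0.25, 0.10, 0.03)),
                              n_x_haplotypes = 3L,
                              intra_x_diversity = 0.002,
                              gene_length_codons = 300L,
                              intron_length_bp = 400L,
                              n_autosomal_genes = 2L,
                              n_cultivars = 12L,
                              n_samples_per_cultivar = 16L,
                              y_expressed_rate = 347 / 565,
                              phenotyping_error_rate = 1 / 192,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (!is.data.frame(strata) ||
      !all(c("label", "target_ds") %in% names(strata)))
    stop("invalid config field `strata`: need columns label, target_ds",
         call. = FALSE)
  if (any(strata$target_ds < 0 | strata$target_ds >= 0.74))
    stop("invalid config field `strata`: target_ds must be in [0, 0.74)",
         call. = FALSE)
  num_fields <- c("n_genes", "n_x_haplotypes", "gene_length_codons",
                  "intron_length_bp", "n_autosomal_genes", "n_cultivars",
                  "n_samples_per_cultivar")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop("invalid config field `", f, "`", call. = FALSE)
  if (cfg$n_x_haplotypes < 1L)
    stop("invalid config field `n_x_haplotypes`: need >= 1", call. = FALSE)
  for (f in c("intra_x_diversity", "phenotyping_error_rate",
              "y_expressed_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config field `", f, "`", call. = FALSE)
  if (nrow(strata) > 0 && cfg$n_genes > 0 &&
      cfg$intra_x_diversity > min(strata$target_ds) / 4)
    stop("invalid config field `intra_x_diversity`: X haplotypes must be ",
         "far closer to each other than to Y", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# random stop-free CDS of n codons (uniform over the 61 sense codons)
.random_cds <- function(n_codons) {
  tab <- .codon_tables()
  sense <- tab$codons[!tab$stop]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Mutate a coding sequence to a target synonymous divergence
#'
#' Introduces random substitutions into `cds`, never creating a stop codon
#' and accepting nonsynonymous changes with low probability (synonymous
#' changes always), until the Nei-Gojobori `ds` between input and output
#' first reaches `target_ds`. Deterministic given `seed`.
#'
#' @param cds Stop-free coding sequence (length a multiple of 3).
#' @param target_ds Target synonymous divergence (below saturation).
#' @param seed Integer seed.
#' @param p_accept_nonsyn Acceptance probability for nonsynonymous
#'   proposals (default 0.1).
#' @return The mutated coding sequence.
#' @export
mutate_cds <- function(cds, target_ds, seed, p_accept_nonsyn = 0.1) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("`cds` length must be a multiple of 3", call. = FALSE)
  if (target_ds < 0) stop("`target_ds` must be >= 0", call. = FALSE)
  if (target_ds == 0) return(cds)
  tab <- .codon_tables()
  codons <- .split_codons(cds)
  if (any(tab$stop[match(codons, tab$codons)]))
    stop("`cds` contains a stop codon", call. = FALSE)
  n_cod <- length(codons)
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    cur <- codons
    max_iter <- 2000L * n_cod
    for (iter in seq_len(max_iter)) {
      ci <- sample.int(n_cod, 1L)
      pos <- sample.int(3L, 1L)
      old_cod <- cur[ci]
      old_base <- substr(old_cod, pos, pos)
      new_base <- sample(setdiff(bases, old_base), 1L)
      new_cod <- old_cod
      substr(new_cod, pos, pos) <- new_base
      if (tab$stop[match(new_cod, tab$codons)]) next
      syn <- Biostrings::GENETIC_CODE[[new_cod]] ==
        Biostrings::GENETIC_CODE[[old_cod]]
      if (!syn && stats::runif(1L) > p_accept_nonsyn) next
      cur[ci] <- new_cod
      est <- nei_gojobori_ds(cds, paste(cur, collapse = ""))
      if (!est$saturated_ds && est$ds >= target_ds)
        return(paste(cur, collapse = ""))
    }
  })
  stop("target synonymous divergence ", target_ds,
       " unreachable for a ", n_cod, "-codon sequence", call. = FALSE)
}

# low-rate X-lineage mutation: per-site substitution with probability p,
# resampled when a stop codon would arise
.mutate_low_rate <- function(cds, p) {
  if (p <= 0) return(cds)
  tab <- .codon_tables()
  codons <- .split_codons(cds)
  bases <- c("A", "C", "G", "T")
  n <- nchar(cds)
  hit <- which(stats::runif(n) < p)
  for (i in hit) {
    ci <- (i - 1L) %/% 3L + 1L
    pos <- (i - 1L) %% 3L + 1L
    old <- codons[ci]
    nb <- sample(setdiff(bases, substr(old, pos, pos)), 1L)
    cand <- old
    substr(cand, pos, pos) <- nb
    if (!tab$stop[match(cand, tab$codons)]) codons[ci] <- cand
  }
  paste(codons, collapse = "")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

#' Simulate a cohort of XY gene systems and genomes
#'
#' For each sex-linked gene an ancestral coding sequence is drawn, the Y
#' copy is produced by [mutate_cds()] at its stratum's target divergence,
#' and each X lineage receives independent low-rate mutations. A gene
#' structure is built by inserting a neutral random intron at a random
#' codon boundary; X, Y and autosomal chromosome-like templates concatenate
#' the gene structures with random 200-1000 bp spacers. Reference genomes
#' (one male and one female per X lineage) and a per-sample truth table for
#' `n_cultivars * n_samples_per_cultivar` samples are assembled, with
#' genotypic sex alternating within each cultivar (roughly a 1:1 ratio) and
#' each cultivar carrying one X lineage.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: list with `gene_records`
#'   (list of [gene_record()]), `autosomal_genes` (named CDS vector),
#'   `truth` (per-gene list with true fixed-difference positions, stratum
#'   target, exon boundary and intron), `genomes` (list of reference
#'   genomes as used by [validate_marker()]), `samples` (`data.frame` with
#'   `sample_id`, `cultivar`, `x_lineage`, `genotypic_sex`, `genome_id`),
#'   and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cfg <- config
  strata <- cfg$strata
  .with_seed(cfg$seed, {
    gene_records <- list()
    truth <- list()
    y_parts <- list()   # genomic gene structures for the Y chromosome
    x_parts <- lapply(seq_len(cfg$n_x_haplotypes), function(h) list())
    if (cfg$n_genes > 0 && nrow(strata) == 0L)
      stop("invalid config field `strata`: empty but n_genes > 0",
           call. = FALSE)
    for (g in seq_len(cfg$n_genes)) {
      st <- ((g - 1L) %% nrow(strata)) + 1L
      anc <- .random_cds(cfg$gene_length_codons)
      y_cds <- mutate_cds(anc, strata$target_ds[st], .subseed(cfg$seed, g))
      x_cds <- vapply(seq_len(cfg$n_x_haplotypes), function(h)
        .mutate_low_rate(anc, cfg$intra_x_diversity), character(1))
      names(x_cds) <- paste0("lineage", seq_len(cfg$n_x_haplotypes))
      gid <- sprintf("gene%02d", g)
      # true fixed differences, in Y coding coordinates (equal-length
      # ungapped copies, so coordinates align 1:1)
      yc <- strsplit(y_cds, "")[[1]]
      xm <- vapply(x_cds, function(s) strsplit(s, "")[[1]],
                   character(nchar(y_cds)))
      xm <- matrix(xm, ncol = length(x_cds))
      same <- apply(xm, 1L, function(r) length(unique(r)) == 1L)
      fixed_pos <- which(same & xm[, 1L] != yc) - 1L
      ds_est <- nei_gojobori_ds(y_cds, x_cds[[1L]])
      y_expressed <- g <= round(cfg$y_expressed_rate * cfg$n_genes)
      gene_records[[gid]] <- gene_record(
        gid, y_cds, x_cds, stratum = strata$label[st],
        y_expressed = y_expressed,
        intron_length_bp = cfg$intron_length_bp,
        ds = if (ds_est$saturated_ds) NA_real_ else ds_est$ds)
      # gene structure: intron at a random interior codon boundary
      n_bp <- nchar(y_cds)
      bnd_codon <- sample(seq(max(1L, cfg$gene_length_codons %/% 5L),
                              cfg$gene_length_codons -
                                max(1L, cfg$gene_length_codons %/% 5L)), 1L)
      exon_boundary <- bnd_codon * 3L  # 0-based CDS position of junction
      intron <- if (cfg$intron_length_bp > 0)
        .random_dna(cfg$intron_length_bp) else ""
      genomic <- function(cds) paste0(substr(cds, 1L, exon_boundary),
                                      intron,
                                      substr(cds, exon_boundary + 1L, n_bp))
      truth[[gid]] <- list(gene_id = gid, stratum = strata$label[st],
                           target_ds = strata$target_ds[st],
                           fixed_positions = fixed_pos,
                           exon_boundary = exon_boundary,
                           intron_length_bp = cfg$intron_length_bp)
      y_parts[[length(y_parts) + 1L]] <- genomic(y_cds)
      for (h in seq_len(cfg$n_x_haplotypes))
        x_parts[[h]][[length(x_parts[[h]]) + 1L]] <- genomic(x_cds[[h]])
    }
    autosomal <- character(0)
    auto_parts <- list()
    for (a in seq_len(cfg$n_autosomal_genes)) {
      cds <- .random_cds(cfg$gene_length_codons)
      autosomal[[sprintf("auto%02d", a)]] <- cds
      auto_parts[[a]] <- cds
    }
    glue <- function(parts) {
      if (length(parts) == 0L) return(.random_dna(500L))
      out <- character(2L * length(parts) + 1L)
      out[1L] <- .random_dna(sample(200:1000, 1L))
      for (i in seq_along(parts)) {
        out[2L * i] <- parts[[i]]
        out[2L * i + 1L] <- .random_dna(sample(200:1000, 1L))
      }
      paste(out, collapse = "")
    }
    chr_y <- glue(y_parts)
    chr_x <- vapply(x_parts, glue, character(1))
    chr_auto <- glue(auto_parts)
    genomes <- list()
    for (h in seq_len(cfg$n_x_haplotypes)) {
      xrec <- seq_record(sprintf("chrX_l%d", h), chr_x[[h]])
      arec <- seq_record(sprintf("auto_l%d", h), chr_auto)
      genomes[[sprintf("male_l%d", h)]] <- list(
        genome_id = sprintf("male_l%d", h), expected_sex = "male",
        records = list(xrec, seq_record(sprintf("chrY_l%d", h), chr_y), arec))
      genomes[[sprintf("female_l%d", h)]] <- list(
        genome_id = sprintf("female_l%d", h), expected_sex = "female",
        records = list(xrec,
                       seq_record(sprintf("chrX2_l%d", h), chr_x[[h]]),
                       arec))
    }
    n_samp <- cfg$n_cultivars * cfg$n_samples_per_cultivar
    samples <- NULL
    if (n_samp > 0) {
      cultivar <- rep(sprintf("cv%02d", seq_len(cfg$n_cultivars)),
                      each = cfg$n_samples_per_cultivar)
      lineage <- ((match(cultivar, unique(cultivar)) - 1L) %%
                    max(cfg$n_x_haplotypes, 1L)) + 1L
      sex <- rep(c("male", "female"),
                 length.out = cfg$n_samples_per_cultivar)
      sex <- unlist(lapply(seq_len(cfg$n_cultivars), function(i) sex))
      samples <- data.frame(
        sample_id = sprintf("s%04d", seq_len(n_samp)),
        cultivar = cultivar, x_lineage = lineage, genotypic_sex = sex,
        genome_id = sprintf("%s_l%d", sex, lineage),
        stringsAsFactors = FALSE)
    }
    structure(list(gene_records = gene_records, autosomal_genes = autosomal,
                   truth = truth, genomes = genomes, samples = samples,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d sex-linked gene(s), %d autosomal, ",
                     "%d X lineage(s), %d sample(s)\n"),
              length(x$gene_records), length(x$autosomal_genes),
              x$config$n_x_haplotypes,
              if (is.null(x$samples)) 0L else nrow(x$samples)))
  invisible(x)
}

#' Simulate running a multiplex assay on a cohort
#'
#' For every sample, predicts the band pattern of the panel on the sample's
#' genome (per-lineage genomes are shared across samples, so patterns are
#' cached), calls the sex with [call_sex()], and independently flips the
#' recorded phenotypic sex with probability `phenotyping_error_rate`
#' (modelling occasional phenotyping mistakes or sex reversion).
#'
#' @param panel A `multiplex_panel`.
#' @param cohort A `synthetic_cohort`.
#' @param phenotyping_error_rate Flip probability; defaults to the cohort
#'   config value.
#' @param seed Integer seed for the phenotype flips.
#' @param settings See [insilico_settings()].
#' @return An [assay_results()] table.
#' @export
simulate_assay <- function(panel, cohort,
                           phenotyping_error_rate =
                             cohort$config$phenotyping_error_rate,
                           seed = cohort$config$seed,
                           settings = insilico_settings()) {
  if (is.null(cohort$samples) || nrow(cohort$samples) == 0L)
    stop("cohort has no samples", call. = FALSE)
  pattern_cache <- new.env(parent = emptyenv())
  band_sizes <- function(genome_id) {
    hit <- pattern_cache[[genome_id]]
    if (!is.null(hit)) return(hit)
    g <- cohort$genomes[[genome_id]]
    sizes <- numeric(0)
    for (p in panel_pairs(panel)) {
      for (rec in g$records) {
        amps <- predict_amplicons(p, rec, settings)
        sizes <- c(sizes, amps$length_bp)
      }
    }
    pattern_cache[[genome_id]] <- sizes
    sizes
  }
  calls <- vapply(cohort$samples$genome_id, function(gid)
    call_sex(band_sizes(gid), panel, settings)$call, character(1))
  .with_seed(seed, {
    flip <- stats::runif(nrow(cohort$samples)) < phenotyping_error_rate
    pheno <- ifelse(flip,
                    ifelse(cohort$samples$genotypic_sex == "male",
                           "female", "male"),
                    cohort$samples$genotypic_sex)
    assay_results(cohort$samples$sample_id, cohort$samples$cultivar,
                  pheno, unname(calls))
  })
}

#' Write a cohort to disk in the formats the pipeline consumes
#'
#' Emits, under `dir`: one FASTA per reference genome plus a
#' `genomes.tsv` manifest, a gene FASTA (`genes.fasta`, Y copy and X
#' haplotypes per gene), the gene metadata TSV (`gene_metadata.tsv`), a
#' gene structure TSV (`gene_structures.tsv`: exon boundary and intron
#' length), the autosomal gene FASTA, a sample truth TSV (`truth.tsv`) and
#' a `config.yaml` echo.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gene_recs <- list()
  for (g in cohort$gene_records) {
    gene_recs[[length(gene_recs) + 1L]] <-
      seq_record(paste0(g$gene_id, "_Y"), g$y_sequence)
    for (h in seq_along(g$x_sequences))
      gene_recs[[length(gene_recs) + 1L]] <-
        seq_record(paste0(g$gene_id, "_X_", names(g$x_sequences)[h]),
                   g$x_sequences[[h]])
  }
  write_fasta(gene_recs, file.path(dir, "genes.fasta"))
  if (length(cohort$autosomal_genes))
    write_fasta(cohort$autosomal_genes, file.path(dir, "autosomal.fasta"))
  meta <- data.frame(
    gene_id = vapply(cohort$gene_records, `[[`, character(1), "gene_id"),
    stratum = vapply(cohort$gene_records, function(g) as.integer(g$stratum),
                     integer(1)),
    y_expressed = vapply(cohort$gene_records, `[[`, logical(1),
                         "y_expressed"),
    intron_length_bp = vapply(cohort$gene_records, `[[`, integer(1),
                              "intron_length_bp"),
    row.names = NULL, stringsAsFactors = FALSE)
  write_gene_metadata(meta, file.path(dir, "gene_metadata.tsv"))
  structs <- data.frame(
    gene_id = names(cohort$truth),
    exon_boundary = vapply(cohort$truth, function(t)
      as.integer(t$exon_boundary), integer(1)),
    intron_length_bp = vapply(cohort$truth, function(t)
      as.integer(t$intron_length_bp), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(structs, file.path(dir, "gene_structures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(genome_id = character(0), fasta_path = character(0),
                         expected_sex = character(0))
  for (g in cohort$genomes) {
    fa <- paste0(g$genome_id, ".fasta")
    write_fasta(g$records, file.path(dir, fa))
    manifest <- rbind(manifest, data.frame(
      genome_id = g$genome_id, fasta_path = fa,
      expected_sex = g$expected_sex, stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "genomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$samples))
    utils::write.table(cohort$samples, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$strata <- lapply(seq_len(nrow(cfg$strata)), function(i)
    list(label = cfg$strata$label[i], target_ds = cfg$strata$target_ds[i]))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `synthetic_cohort` (truth limited to what the files record).
#' @export
read_cohort <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfgl$strata <- do.call(rbind, lapply(cfgl$strata, as.data.frame))
  cfg <- do.call(simulation_config, cfgl)
  genes <- read_fasta(file.path(dir, "genes.fasta"))
  meta <- read_gene_metadata(file.path(dir, "gene_metadata.tsv"))
  structs <- utils::read.delim(file.path(dir, "gene_structures.tsv"),
                               stringsAsFactors = FALSE)
  seqs <- .records_to_vector(genes)
  gene_records <- list()
  truth <- list()
  for (i in seq_len(nrow(meta))) {
    gid <- meta$gene_id[i]
    y <- seqs[[paste0(gid, "_Y")]]
    xs <- seqs[grep(paste0("^", gid, "_X_"), names(seqs))]
    names(xs) <- sub(paste0("^", gid, "_X_"), "", names(xs))
    est <- nei_gojobori_ds(y, xs[[1L]])
    gene_records[[gid]] <- gene_record(
      gid, y, xs, stratum = meta$stratum[i],
      y_expressed = meta$y_expressed[i],
      intron_length_bp = meta$intron_length_bp[i],
      ds = if (est$saturated_ds) NA_real_ else est$ds)
    srow <- structs[structs$gene_id == gid, ]
    truth[[gid]] <- list(gene_id = gid, stratum = meta$stratum[i],
                         target_ds = NA_real_, fixed_positions = NULL,
                         exon_boundary = srow$exon_boundary[1],
                         intron_length_bp = srow$intron_length_bp[1])
  }
  autos <- character(0)
  if (file.exists(file.path(dir, "autosomal.fasta")))
    autos <- .records_to_vector(read_fasta(file.path(dir, "autosomal.fasta")))
  manifest <- read_genome_manifest(file.path(dir, "genomes.tsv"))
  genomes <- list()
  for (i in seq_len(nrow(manifest))) {
    gid <- manifest$genome_id[i]
    genomes[[gid]] <- list(genome_id = gid,
                           expected_sex = manifest$expected_sex[i],
                           records = read_fasta(manifest$fasta_path[i]))
  }
  samples <- NULL
  if (file.exists(file.path(dir, "truth.tsv")))
    samples <- utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE)
  structure(list(gene_records = gene_records, autosomal_genes = autos,
                 truth = truth, genomes = genomes, samples = samples,
                 config = cfg),
            class = "synthetic_cohort")
}
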