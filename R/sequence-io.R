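# Sequence records, FASTA and tabular I/O.
#
# Conventions used across the package: DNA is uppercase over {A,C,G,T,N};
# IUPAC ambiguity codes other than N are rejected on input because the
# fixed-difference caller needs unambiguous bases. All exposed coordinates
# are 0-based, half-open; strand is "+"/"-".

.DNA_RE <- "[^ACGTN]"

.check_dna <- function(sequence, what = "sequence", allow_n = TRUE) {
  sequence <- toupper(sequence)
  bad_re <- if (allow_n) .DNA_RE else "[^ACGT]"
  if (grepl(bad_re, sequence)) {
    pos <- regexpr(bad_re, sequence)
    stop(sprintf("illegal character '%s' at position %d of %s",
                 substr(sequence, pos, pos), as.integer(pos), what),
         call. = FALSE)
  }
  sequence
}

#' Create a sequence record
#'
#' A lightweight container for one DNA sequence: an identifier, the uppercase
#' sequence over `A`, `C`, `G`, `T`, `N`, and a free-text description.
#'
#' @param id Non-empty identifier, unique within a collection.
#' @param sequence DNA string; lowercase input is uppercased, any character
#'   outside `ACGTN` (including IUPAC ambiguity codes other than `N`) is an
#'   error.
#' @param description Optional free text.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a non-empty string", call. = FALSE)
  sequence <- .check_dna(sequence, what = paste0("record '", id, "'"))
  structure(list(id = id, sequence = sequence, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a list of
#' [seq_record()] objects, preserving record order. Sequences are uppercased.
#' Malformed input (sequence before the first header, an empty identifier, a
#' duplicated identifier, or a character outside `ACGTN`) raises an error
#' naming the offending line.
#'
#' @param path Path to a FASTA file. An empty file yields an empty list.
#' @return List of `seq_record`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  records <- list()
  ids <- character(0)
  cur_id <- NULL
  cur_desc <- ""
  cur_chunks <- character(0)
  flush <- function() {
    if (is.null(cur_id)) return()
    seq <- paste(cur_chunks, collapse = "")
    records[[length(records) + 1L]] <<- seq_record(cur_id, seq, cur_desc)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush()
      header <- trimws(substring(line, 2L))
      if (!nzchar(header))
        stop(sprintf("%s:%d: empty FASTA header", path, i), call. = FALSE)
      parts <- strsplit(header, "[ \t]+")[[1]]
      cur_id <- parts[[1]]
      if (cur_id %in% ids)
        stop(sprintf("%s:%d: duplicate record id '%s'", path, i, cur_id),
             call. = FALSE)
      ids <- c(ids, cur_id)
      cur_desc <- if (length(parts) > 1L)
        paste(parts[-1L], collapse = " ") else ""
      cur_chunks <- character(0)
    } else {
      if (is.null(cur_id))
        stop(sprintf("%s:%d: sequence data before first FASTA header",
                     path, i), call. = FALSE)
      chunk <- toupper(gsub("[ \t]", "", line))
      if (grepl(.DNA_RE, chunk)) {
        pos <- regexpr(.DNA_RE, chunk)
        stop(sprintf("%s:%d: illegal character '%s' in sequence", path, i,
                     substr(chunk, pos, pos)), call. = FALSE)
      }
      cur_chunks <- c(cur_chunks, chunk)
    }
  }
  flush()
  records
}

#' Write records to a FASTA file
#'
#' @param records List of [seq_record()] (or a named character vector of
#'   sequences).
#' @param path Output path.
#' @param width Line-wrap width, default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- Map(seq_record, names(records), unname(records))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description))
      paste(rec$id, rec$description) else rec$id
    writeLines(paste0(">", header), con)
    n <- nchar(rec$sequence)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(rec$sequence, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

#' @noRd
.records_to_vector <- function(records) {
  out <- vapply(records, `[[`, character(1), "sequence")
  names(out) <- vapply(records, `[[`, character(1), "id")
  out
}

#' Read a gene metadata table
#'
#' Tab-separated table with header columns `gene_id`, `stratum`,
#' `y_expressed`, `intron_length_bp`; booleans encoded `true`/`false`.
#' Stratum labels are ordinal: lower sorts older.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with one row per gene.
#' @export
read_gene_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stratum", "y_expressed", "intron_length_bp")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gene metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.character(df$y_expressed))
    df$y_expressed <- tolower(df$y_expressed) == "true"
  if (anyNA(df$y_expressed) || !is.logical(df$y_expressed))
    stop("y_expressed must be true/false", call. = FALSE)
  if (any(df$intron_length_bp < 0))
    stop("intron_length_bp must be non-negative", call. = FALSE)
  df
}

#' Write a gene metadata table
#' @param meta `data.frame` as returned by [read_gene_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_metadata <- function(meta, path) {
  out <- meta
  out$y_expressed <- ifelse(out$y_expressed, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a candidate gene record
#'
#' Bundles the Y-linked coding sequence of one gene with its X-haplotype
#' coding sequences and the metadata used by the selection filters: sex
#' chromosome stratum (ordinal, lower = older), whether the Y copy is still
#' expressed, intron length, and X-Y synonymous divergence.
#'
#' @param gene_id Gene identifier.
#' @param y_sequence Y-copy coding DNA (length >= 3).
#' @param x_sequences Named character vector of X-copy coding DNA; names label
#'   the source (e.g. cultivar of origin).
#' @param stratum Ordinal stratum label.
#' @param y_expressed Logical flag.
#' @param intron_length_bp Non-negative integer.
#' @param ds X-Y synonymous divergence; `NA` marks a saturated estimate.
#' @return Object of class `gene_record`.
#' @export
gene_record <- function(gene_id, y_sequence, x_sequences, stratum = 1L,
                        y_expressed = TRUE, intron_length_bp = 0L, ds = NA_real_) {
  if (length(x_sequences) < 1L)
    stop("at least one X sequence is required", call. = FALSE)
  y_sequence <- .check_dna(y_sequence, paste0("Y copy of ", gene_id))
  x_sequences <- vapply(seq_along(x_sequences), function(i)
    .check_dna(x_sequences[[i]], sprintf("X copy %d of %s", i, gene_id)),
    character(1), USE.NAMES = FALSE) |>
    stats::setNames(if (is.null(names(x_sequences)))
      paste0("X", seq_along(x_sequences)) else names(x_sequences))
  if (nchar(y_sequence) < 3L || any(nchar(x_sequences) < 3L))
    stop("coding sequences must be at least one codon long", call. = FALSE)
  if (intron_length_bp < 0)
    stop("intron_length_bp must be non-negative for ", gene_id, call. = FALSE)
  structure(list(gene_id = gene_id, y_sequence = y_sequence,
                 x_sequences = x_sequences, stratum = stratum,
                 y_expressed = isTRUE(y_expressed),
                 intron_length_bp = as.integer(intron_length_bp), ds = ds),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s: Y %d bp, %d X haplotype(s), stratum %s, dS %s\n",
              x$gene_id, nchar(x$y_sequence), length(x$x_sequences),
              format(x$stratum),
              if (is.na(x$ds)) "saturated/NA" else format(round(x$ds, 4))))
  invisible(x)
}

#' Read a genome manifest
#'
#' Tab-separated table `genome_id  fasta_path  expected_sex` mapping each
#' genome to its FASTA file; `expected_sex` is one of `male`, `female`,
#' `unknown`. Relative FASTA paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to the manifest TSV.
#' @return `data.frame` with columns `genome_id`, `fasta_path`,
#'   `expected_sex`.
#' @export
read_genome_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "fasta_path", "expected_sex")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("genome manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !df$expected_sex %in% c("male", "female", "unknown")
  if (any(bad))
    stop("invalid expected_sex: ", paste(unique(df$expected_sex[bad]),
                                         collapse = ", "), call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$fasta_path)
  df$fasta_path[rel] <- file.path(dirname(path), df$fasta_path[rel])
  df
}
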