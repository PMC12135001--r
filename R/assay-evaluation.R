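# Confusion statistics of a sexing assay: per-cultivar counts, true positive
# success rate, and specificity over phenotypic males.

.SEX_LEVELS <- c("male", "female")
.CALL_LEVELS <- c("male", "female", "failed")

#' Build an assay results table
#'
#' @param sample_id,cultivar Character vectors.
#' @param phenotypic_sex `"male"`/`"female"` per sample.
#' @param called_sex `"male"`/`"female"`/`"failed"` per sample.
#' @return `data.frame` of class `assay_results`.
#' @export
assay_results <- function(sample_id, cultivar, phenotypic_sex, called_sex) {
  if (anyDuplicated(sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  bad <- !phenotypic_sex %in% .SEX_LEVELS
  if (any(bad))
    stop("invalid phenotypic_sex for sample ",
         sample_id[which(bad)[1]], ": '", phenotypic_sex[which(bad)[1]], "'",
         call. = FALSE)
  bad <- !called_sex %in% .CALL_LEVELS
  if (any(bad))
    stop("invalid called_sex for sample ",
         sample_id[which(bad)[1]], ": '", called_sex[which(bad)[1]], "'",
         call. = FALSE)
  structure(data.frame(sample_id = sample_id, cultivar = cultivar,
                       phenotypic_sex = phenotypic_sex,
                       called_sex = called_sex, stringsAsFactors = FALSE),
            class = c("assay_results", "data.frame"))
}

#' Read / write assay results
#'
#' TSV with columns `sample_id  cultivar  phenotypic_sex  called_sex`.
#'
#' @param path File path.
#' @return For `read_assay_results`, an `assay_results` table.
#' @export
read_assay_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "phenotypic_sex", "called_sex")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("assay results lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  assay_results(df$sample_id, df$cultivar, df$phenotypic_sex, df$called_sex)
}

#' @rdname read_assay_results
#' @param results An `assay_results` table.
#' @export
write_assay_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise assay results into confusion statistics
#'
#' Produces one row per cultivar plus a `Total` row with the counts
#' `male_as_male`, `female_as_female`, `male_as_female`, `female_as_male`,
#' `failed`, the true positive success rate
#' `100 * (male_as_male + female_as_female) / n` (failed experiments count
#' in `n` but never in the numerator), and the specificity
#' `100 * male_as_male / (male_as_male + male_as_female)` computed over
#' phenotypic males (`NA` when a cultivar has no males). Per-cultivar rates
#' are rounded to the nearest integer and the `Total` rate to one decimal,
#' matching the conventional reporting precision of such panels.
#'
#' @param results An `assay_results` table (or plain `data.frame` with the
#'   same columns).
#' @return `data.frame` of class `confusion_summary` with columns
#'   `cultivar`, `n`, `male_as_male`, `female_as_female`, `male_as_female`,
#'   `female_as_male`, `failed`, `tpr_percent`, `specificity_percent`.
#' @export
summarize_assay <- function(results) {
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  bad <- !results$phenotypic_sex %in% .SEX_LEVELS
  if (any(bad))
    stop("unknown phenotypic_sex in row ", which(bad)[1], ": '",
         results$phenotypic_sex[which(bad)[1]], "'", call. = FALSE)
  bad <- !results$called_sex %in% .CALL_LEVELS
  if (any(bad))
    stop("unknown called_sex in row ", which(bad)[1], ": '",
         results$called_sex[which(bad)[1]], "'", call. = FALSE)
  one <- function(df) {
    mm <- sum(df$phenotypic_sex == "male" & df$called_sex == "male")
    ff <- sum(df$phenotypic_sex == "female" & df$called_sex == "female")
    mf <- sum(df$phenotypic_sex == "male" & df$called_sex == "female")
    fm <- sum(df$phenotypic_sex == "female" & df$called_sex == "male")
    fl <- sum(df$called_sex == "failed")
    c(n = nrow(df), male_as_male = mm, female_as_female = ff,
      male_as_female = mf, female_as_male = fm, failed = fl)
  }
  cultivars <- unique(results$cultivar)
  counts <- t(vapply(cultivars, function(cv)
    one(results[results$cultivar == cv, , drop = FALSE]),
    numeric(6)))
  total <- one(results)
  tpr <- function(x) 100 * (x[["male_as_male"]] + x[["female_as_female"]]) /
    x[["n"]]
  spec <- function(x) {
    denom <- x[["male_as_male"]] + x[["male_as_female"]]
    if (denom == 0) NA_real_ else 100 * x[["male_as_male"]] / denom
  }
  out <- data.frame(cultivar = c(cultivars, "Total"),
                    rbind(counts, total), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$tpr_percent <- c(round(apply(counts, 1L, tpr)),
                       round(tpr(total), 1))
  out$specificity_percent <- c(apply(counts, 1L, spec), spec(total))
  structure(out, class = c("confusion_summary", "data.frame"))
}

#' Join sex calls with phenotypic truth
#'
#' @param calls `data.frame` with columns `sample_id`, `called_sex`.
#' @param truth `data.frame` with columns `sample_id`, `cultivar`,
#'   `phenotypic_sex`. Sample sets must match exactly.
#' @return An `assay_results` table in the row order of `truth`.
#' @export
compare_to_truth <- function(calls, truth) {
  only_c <- setdiff(calls$sample_id, truth$sample_id)
  only_t <- setdiff(truth$sample_id, calls$sample_id)
  if (length(only_c) || length(only_t))
    stop("sample sets differ: ",
         if (length(only_c)) paste0("only in calls: ",
                                    paste(utils::head(only_c, 3),
                                          collapse = ", "), " "),
         if (length(only_t)) paste0("only in truth: ",
                                    paste(utils::head(only_t, 3),
                                          collapse = ", ")),
         call. = FALSE)
  idx <- match(truth$sample_id, calls$sample_id)
  assay_results(truth$sample_id, truth$cultivar, truth$phenotypic_sex,
                calls$called_sex[idx])
}

#' Read a per-cultivar count table
#'
#' TSV with columns `cultivar  n  male_as_male  female_as_female
#' male_as_female  female_as_male  failed` (no Total row). The packaged
#' fixture `table2_counts.tsv` transcribes the published 192-sample,
#' 12-cultivar validation of the sexing panel.
#'
#' @param path TSV path.
#' @return `data.frame` of counts.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "n", "male_as_male", "female_as_female",
            "male_as_female", "female_as_male", "failed")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("count table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  chk <- df$male_as_male + df$female_as_female + df$male_as_female +
    df$female_as_male + df$failed
  if (any(chk != df$n))
    stop("count rows do not sum to n for cultivar ",
         df$cultivar[which(chk != df$n)[1]], call. = FALSE)
  df
}

#' Expand a count table into per-sample rows
#'
#' Reconstructs a sample-level [assay_results()] table from per-cultivar
#' counts (the confusion statistics depend only on the counts, so any
#' consistent expansion is equivalent). Failed experiments are expanded with
#' phenotypic sex `male`, an arbitrary but documented convention: a count
#' table does not record the phenotype of failed samples.
#'
#' @param counts `data.frame` from [read_count_table()].
#' @return An `assay_results` table with `n` rows per cultivar.
#' @export
counts_to_results <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    cv <- counts$cultivar[i]
    add <- function(k, pheno, call)
      if (k > 0) rows[[length(rows) + 1L]] <<- data.frame(
        cultivar = cv, phenotypic_sex = pheno, called_sex = call,
        k = k, stringsAsFactors = FALSE)
    add(counts$male_as_male[i], "male", "male")
    add(counts$female_as_female[i], "female", "female")
    add(counts$male_as_female[i], "male", "female")
    add(counts$female_as_male[i], "female", "male")
    add(counts$failed[i], "male", "failed")
  }
  df <- do.call(rbind, rows)
  df <- df[rep(seq_len(nrow(df)), df$k), c("cultivar", "phenotypic_sex",
                                           "called_sex")]
  assay_results(sprintf("s%04d", seq_len(nrow(df))), df$cultivar,
                df$phenotypic_sex, df$called_sex)
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
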