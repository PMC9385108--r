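#' Write genotypes in the PLINK .raw additive dialect
#'
#' Space-delimited text with the header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one `<snp_id>_<minor_allele>` column per marker; entries are
#' minor-allele dosages 0/1/2 with `NA` for missing calls.
#'
#' @param geno an [mdr_geno] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(geno, path) {
  stopifnot(inherits(geno, "mdr_geno"))
  minor <- geno$snp_info$minor_allele
  minor[is.na(minor)] <- "N"
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(geno$snp_info$snp_id, "_", minor))
  d <- geno$dosage
  body <- cbind(geno$subjects, geno$subjects, "0", "0", "0", "-9",
                matrix(ifelse(is.na(d), "NA", as.character(d)), nrow(d)))
  writeLines(c(paste(header, collapse = " "),
               apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a PLINK .raw additive-dosage file
#'
#' Strict parser for the dialect written by [write_plink_raw()] (and by
#' PLINK's `--recodeA`): whitespace-delimited, six leading pedigree columns,
#' then `<snp_id>_<minor_allele>` dosage columns. Malformed input is
#' rejected, never coerced: ragged rows, non-integer or out-of-range
#' dosages and duplicated SNP columns all raise an error naming the
#' offending line.
#'
#' @param path input file path.
#' @return An [mdr_geno] object; `input_index` reflects column order and
#'   the minor allele comes from the header suffix.
#' @export
read_plink_raw <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) abort("empty file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6 || !identical(header[1:6], fixed)) {
    abort("line 1: header must start with 'FID IID PAT MAT SEX PHENOTYPE'")
  }
  snp_cols <- header[-(1:6)]
  if (!length(snp_cols)) abort("no SNP columns in header")
  snp_id <- sub("_[^_]*$", "", snp_cols)
  minor <- sub("^.*_", "", snp_cols)
  if (anyDuplicated(snp_id)) {
    abort(sprintf("duplicated SNP column '%s' in header",
                  snp_id[duplicated(snp_id)][1]))
  }
  n <- length(toks) - 1
  if (n < 1) abort("no subject rows")
  m <- length(snp_cols)
  dosage <- matrix(NA_integer_, n, m)
  subjects <- character(n)
  for (i in seq_len(n)) {
    row <- toks[[i + 1]]
    if (length(row) != 6 + m) {
      abort(sprintf("line %d: expected %d fields, found %d", i + 1, 6 + m,
                    length(row)))
    }
    subjects[i] <- row[2]
    vals <- row[-(1:6)]
    isna <- vals == "NA"
    parsed <- suppressWarnings(as.integer(vals))
    bad <- !isna & (is.na(parsed) | vals != as.character(parsed) |
                      !(parsed %in% 0:2))
    if (any(bad)) {
      abort(sprintf("line %d, column '%s': invalid dosage '%s'",
                    i + 1, snp_cols[which(bad)[1]], vals[which(bad)[1]]))
    }
    dosage[i, ] <- parsed
  }
  if (anyDuplicated(subjects)) abort("duplicated subject ids")
  mdr_geno(dosage,
           snp_info = tibble::tibble(snp_id = snp_id, minor_allele = minor),
           subjects = subjects)
}

pheno_columns <- function() {
  c("subject_id", "time_years", "event", "status5y", "included5y",
    covariate_names())
}

#' Write a phenotype/covariate table
#'
#' @param pheno phenotype tibble (the `pheno` component of an
#'   `mdr_cohort`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pheno, path) {
  readr::write_tsv(pheno[, intersect(pheno_columns(), names(pheno))], path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a `subject_id` key, survival columns (`time_years` in
#' years > 0, `event` 0/1), optional 5-year binary columns (`status5y`,
#' `included5y`) and the clinical covariates. Validation is strict: missing
#' required columns, non-positive times and out-of-range indicators raise
#' errors naming the offending row; unknown extra columns are dropped with
#' a warning.
#'
#' @param path input TSV path.
#' @return A phenotype tibble.
#' @export
read_phenotype_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "time_years", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(paste("missing required column(s):", paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), pheno_columns())
  if (length(extra)) {
    warn(paste("ignoring extra column(s):", paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra)]
  }
  bad_t <- which(!is.finite(df$time_years) | df$time_years <= 0)
  if (length(bad_t)) {
    abort(sprintf("row %d: time_years must be > 0 (found %s)", bad_t[1],
                  format(df$time_years[bad_t[1]])))
  }
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_e)) abort(sprintf("row %d: event must be 0 or 1", bad_e[1]))
  for (col in c("status5y", "included5y", "msi", "location", "chemo", "radio")) {
    if (!is.null(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & !df[[col]] %in% c(0, 1))
      if (length(bad)) abort(sprintf("row %d: %s must be 0 or 1", bad[1], col))
    }
  }
  if (!is.null(df$stage)) {
    bad <- which(!is.na(df$stage) & !df$stage %in% 1:4)
    if (length(bad)) abort(sprintf("row %d: stage must be in 1..4", bad[1]))
  }
  df
}

# "(1GT,0TT,2GG)"-style rendering of a genotype cell: dosage digit followed
# by the genotype letters (minor allele listed first, the table convention).
format_cell <- function(dosages, major, minor) {
  paste0("(", paste0(dosages, ifelse(dosages == 0, paste0(major, major),
                                     ifelse(dosages == 1, paste0(minor, major),
                                            paste0(minor, minor))),
                     collapse = ","), ")")
}

high_cell_string <- function(model, snp_info) {
  j <- match(model$snp_ids, snp_info$snp_id)
  major <- snp_info$major_allele[j]; minor <- snp_info$minor_allele[j]
  major[is.na(major)] <- "?"; minor[is.na(minor)] <- "?"
  hc <- cell_grid(model$k)[model$labels == 1L, , drop = FALSE]
  if (!nrow(hc)) return("")
  paste(vapply(seq_len(nrow(hc)),
               function(i) format_cell(hc[i, ], major, minor), character(1)),
        collapse = " ")
}

model_row <- function(k, top, perm, regression, snp_info) {
  tibble::tibble(
    k = k,
    snp_ids = paste(top$model$snp_ids, collapse = ","),
    high_risk_genotypes = high_cell_string(top$model, snp_info),
    frequency = top$frequency, n_runs = top$n_runs,
    mean_tba = top$mean_tba, cvc = top$cvc,
    permutation_p = perm$p_value, permutation_p_label = perm$p_label,
    effect = if (!is.null(regression)) regression$effect else NA_character_,
    estimate = if (!is.null(regression)) regression$estimate else NA_real_,
    ci_lower = if (!is.null(regression)) regression$conf_low else NA_real_,
    ci_upper = if (!is.null(regression)) regression$conf_high else NA_real_,
    regression_p = if (!is.null(regression)) regression$p_value else NA_real_
  )
}

#' Tabulate a pipeline report's models
#'
#' One row per reported model (each main-effect iteration and each
#' multiway order), in the shape of the published result tables: SNP ids,
#' high-risk genotypes in additive coding, permutation p, regression
#' effect estimate with CI.
#'
#' @param report an `mdr_pipeline_report`.
#' @return A tibble.
#' @export
report_models <- function(report) {
  rows <- list()
  for (rec in report$iterations) {
    if (is.null(rec$top)) next
    r <- model_row(1L, rec$top, rec$perm, rec$regression, report$snp_info)
    r$iteration <- rec$iteration
    r$removed_snps <- paste(rec$removed, collapse = ",")
    rows[[length(rows) + 1]] <- r
  }
  for (res in report$multiway) {
    r <- model_row(res$k, res$top, res$perm, res$regression, report$snp_info)
    r$iteration <- NA_integer_
    r$removed_snps <- ""
    rows[[length(rows) + 1]] <- r
  }
  if (!length(rows)) {
    return(tibble::tibble(k = integer(), snp_ids = character()))
  }
  dplyr::bind_rows(rows)
}

report_to_list <- function(report) {
  list(
    config = report$config,
    engine = report$engine,
    qc = list(n_input = nrow(report$qc_report),
              n_passed = sum(report$qc_report$pass),
              n_duplicates = sum(report$dedup_report$removal_reason == "duplicate_r2")),
    models = as.data.frame(report_models(report)),
    final_snps = report$final_snps
  )
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable, round-trips through
#' [read_report()]), `models.tsv` and `qc.tsv` tables, and a short run log.
#' Content is deterministic given the report. An empty result (no
#' significant models) still produces valid files saying so.
#'
#' @param report an `mdr_pipeline_report`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mdr_pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  readr::write_tsv(report_models(report), file.path(dir, "models.tsv"))
  readr::write_tsv(tibble::as_tibble(report$qc_report), file.path(dir, "qc.tsv"))
  models <- report_models(report)
  n_sig <- sum(models$permutation_p < report$config$alpha, na.rm = TRUE)
  writeLines(c(
    sprintf("engine: %s; strategy: %s; seed: %d", report$engine,
            report$config$strategy, report$config$seed),
    "balanced accuracy: mean of score-mass sensitivity and specificity",
    sprintf("models reported: %d (%d significant at alpha = %g)",
            nrow(models), n_sig, report$config$alpha),
    if (n_sig == 0) "no significant models were identified" else character()
  ), file.path(dir, "run.log"))
  invisible(dir)
}

#' Read back a written pipeline report
#'
#' @param dir directory written by [write_report()].
#' @return The report's serialized list form.
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
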