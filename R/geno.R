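#' Genotype container
#'
#' A `mdr_geno` object bundles a subjects-by-SNPs additive dosage matrix
#' (entries 0/1/2 = copies of the minor allele, `NA` = missing) with per-SNP
#' metadata. The metadata tibble carries, for each marker: its identifier,
#' a gene label, major/minor alleles, the target minor allele frequency used
#' at simulation time (if simulated), the position of the marker in the input
#' file (`input_index`, the tie-break key for order-dependent model
#' selection), and whether allele labels were swapped during QC.
#'
#' @param dosage integer matrix, subjects in rows, SNPs in columns. Column
#'   names are taken as SNP identifiers when `snp_info` is missing.
#' @param snp_info tibble with at least `snp_id`; missing metadata columns
#'   are filled with defaults.
#' @param subjects character vector of unique subject identifiers.
#' @return An object of class `mdr_geno`.
#' @export
mdr_geno <- function(dosage, snp_info = NULL, subjects = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }
  if (is.null(subjects)) {
    subjects <- rownames(dosage)
    if (is.null(subjects)) subjects <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(subjects)) abort("duplicated subject ids")
  if (length(subjects) != nrow(dosage)) abort("subjects must match dosage rows")
  if (is.null(snp_info)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("snp_%04d", seq_len(ncol(dosage)))
    snp_info <- tibble::tibble(snp_id = ids)
  }
  snp_info <- tibble::as_tibble(snp_info)
  if (nrow(snp_info) != ncol(dosage)) abort("snp_info must have one row per SNP")
  if (anyDuplicated(snp_info$snp_id)) abort("duplicated snp ids")
  defaults <- list(gene = NA_character_, major_allele = NA_character_,
                   minor_allele = NA_character_, target_maf = NA_real_,
                   swapped = FALSE)
  for (nm in names(defaults)) {
    if (is.null(snp_info[[nm]])) snp_info[[nm]] <- defaults[[nm]]
  }
  snp_info$input_index <- seq_len(nrow(snp_info))
  rownames(dosage) <- subjects
  colnames(dosage) <- snp_info$snp_id
  structure(list(dosage = dosage, snp_info = snp_info, subjects = subjects),
            class = "mdr_geno")
}

#' @export
print.mdr_geno <- function(x, ...) {
  cat(sprintf("<mdr_geno> %d subjects x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$dosage))))
  print(head(x$snp_info, 5))
  invisible(x)
}

#' @export
dim.mdr_geno <- function(x) dim(x$dosage)

#' Tidy view of a genotype matrix
#'
#' @param x an `mdr_geno` object.
#' @param ... unused.
#' @return A tibble with `subject_id` followed by one dosage column per SNP.
#' @export
as_tibble.mdr_geno <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(subject_id = x$subjects),
                   tibble::as_tibble(x$dosage))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Subset a genotype object by SNP (id or index) and/or subject position.
# input_index is re-densified so it always reflects current column order.
geno_subset <- function(geno, snps = NULL, subjects = NULL) {
  stopifnot(inherits(geno, "mdr_geno"))
  j <- seq_len(ncol(geno$dosage))
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, geno$snp_info$snp_id) else snps
    if (anyNA(j)) abort("unknown snp id(s)")
  }
  i <- if (is.null(subjects)) seq_len(nrow(geno$dosage)) else subjects
  mdr_geno(geno$dosage[i, j, drop = FALSE],
           snp_info = geno$snp_info[j, setdiff(names(geno$snp_info), "input_index")],
           subjects = geno$subjects[i])
}

# Resolve a geno argument (mdr_geno or plain matrix) into a dosage matrix.
geno_dosage <- function(geno, allow_missing = TRUE) {
  d <- if (inherits(geno, "mdr_geno")) geno$dosage else {
    d0 <- as.matrix(geno)
    storage.mode(d0) <- "integer"
    d0
  }
  if (!allow_missing && anyNA(d)) {
    abort("missing genotype calls present; run QC with max_missing = 0 first")
  }
  d
}

# Resolve a score argument (mdr_scores tibble or numeric vector).
score_vec <- function(scores) {
  if (is.data.frame(scores)) {
    if (is.null(scores$score)) abort("score column missing")
    return(scores$score)
  }
  as.numeric(scores)
}
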