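#' Minor allele frequency of a dosage column
#'
#' MAF is the allele count over twice the number of non-missing calls. When
#' the coded allele turns out to be the major one (frequency > 0.5) the
#' reported frequency is flipped to the minor allele and the `swapped`
#' attribute is set; matrix-level QC relabels such columns (`dosage <- 2 -
#' dosage`) so that dosage always counts the minor allele.
#'
#' @param x integer dosage vector (0/1/2, `NA` = missing call).
#' @return The MAF (<= 0.5) with a logical attribute `swapped`.
#' @export
compute_maf <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("all calls missing; MAF undefined")
  if (!all(x %in% 0:2)) abort("dosages must be 0, 1 or 2")
  f <- sum(x) / (2 * length(x))
  swapped <- f > 0.5
  structure(if (swapped) 1 - f else f, swapped = swapped)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the Levene-Haldane probabilities of every heterozygote count
#' whose probability does not exceed that of the observed count (the PLINK
#' convention; no mid-p adjustment). Monomorphic markers return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact two-sided p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0)) abort("genotype counts must be >= 0")
  n <- sum(counts)
  if (n < 1) abort("at least one genotype required")
  n_minor <- 2 * n_aa + n_Aa
  n_major <- 2 * n_AA + n_Aa
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  logp <- lfactorial(n) - lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial((n_major - hets) / 2) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# Per-SNP QC statistics; assumes minor-allele relabeling already applied.
snp_stats <- function(dosage) {
  n_tot <- nrow(dosage)
  tibble::tibble(
    snp_id = colnames(dosage),
    maf = apply(dosage, 2, function(x) as.numeric(compute_maf(x))),
    hwe_p = apply(dosage, 2, function(x) {
      x <- x[!is.na(x)]
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    }),
    missing_rate = colSums(is.na(dosage)) / n_tot
  )
}

relabel_to_minor <- function(geno) {
  swap <- vapply(seq_len(ncol(geno$dosage)), function(j) {
    x <- geno$dosage[, j]
    x <- x[!is.na(x)]
    length(x) > 0 && sum(x) / (2 * length(x)) > 0.5
  }, logical(1))
  if (any(swap)) {
    geno$dosage[, swap] <- 2L - geno$dosage[, swap]
    tmp <- geno$snp_info$major_allele[swap]
    geno$snp_info$major_allele[swap] <- geno$snp_info$minor_allele[swap]
    geno$snp_info$minor_allele[swap] <- tmp
    geno$snp_info$swapped[swap] <- !geno$snp_info$swapped[swap]
  }
  geno
}

new_qc_report <- function(stats, reason) {
  out <- dplyr::mutate(stats, pass = reason == "none", removal_reason = reason)
  class(out) <- c("mdr_qc_report", class(out))
  out
}

#' Apply marker-level quality-control filters
#'
#' Keeps exactly the SNPs with MAF >= `maf_min`, exact HWE p > `hwe_min_p`
#' and missing-call rate <= `max_missing` (defaults: the common
#' association-study screen MAF >= 0.05, HWE p > 1e-4, no missingness).
#' Columns whose coded allele is the major one are relabeled to minor-allele
#' dosage first and flagged in `snp_info$swapped`. When a marker fails
#' several filters a single reason is recorded, in the precedence missing >
#' maf > hwe.
#'
#' @param geno an [mdr_geno] object.
#' @param maf_min,hwe_min_p,max_missing thresholds in \[0, 1\].
#' @return A list: `geno` (filtered, possibly with zero SNPs) and `report`
#'   (per-SNP tibble of class `mdr_qc_report`: maf, hwe_p, missing_rate,
#'   pass, removal_reason).
#' @export
apply_qc_filters <- function(geno, maf_min = 0.05, hwe_min_p = 1e-4,
                             max_missing = 0) {
  stopifnot(inherits(geno, "mdr_geno"))
  thr <- c(maf_min, hwe_min_p, max_missing)
  if (any(thr < 0 | thr > 1)) abort("thresholds must be in [0, 1]")
  geno <- relabel_to_minor(geno)
  stats <- snp_stats(geno$dosage)
  reason <- dplyr::case_when(
    stats$missing_rate > max_missing ~ "missing",
    stats$maf < maf_min ~ "maf",
    stats$hwe_p <= hwe_min_p ~ "hwe",
    TRUE ~ "none"
  )
  keep <- which(reason == "none")
  list(geno = geno_subset(geno, snps = keep), report = new_qc_report(stats, reason))
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of two dosage columns over complete cases --
#' the genotype-scale (composite) LD measure, invariant to allele-coding
#' flips of either column.
#'
#' @param geno an [mdr_geno] object or dosage matrix.
#' @param i,j SNP ids or column indices.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(geno, i, j) {
  d <- geno_dosage(geno)
  ids <- colnames(d)
  ij <- vapply(list(i, j), function(k) {
    if (is.character(k)) match(k, ids) else as.integer(k)
  }, integer(1))
  if (anyNA(ij)) abort("unknown snp id")
  x <- d[, ij[1]]; y <- d[, ij[2]]
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (sd(x) == 0 || sd(y) == 0) abort("monomorphic column: r^2 undefined")
  cor(x, y)^2
}

# Full m x m genotype r^2 matrix (NA where a column is monomorphic).
r2_matrix <- function(dosage) {
  sds <- apply(dosage, 2, sd, na.rm = TRUE)
  r <- suppressWarnings(cor(dosage, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  r^2
}

#' Prune statistically redundant markers
#'
#' Markers with pairwise r-squared of exactly 1 score identically in the MDR
#' procedure; from every such group only the member appearing earliest in
#' the input file (smallest `input_index`) is retained. Groups are the
#' connected components of the r-squared = 1 relation.
#'
#' @param geno a QC-passed [mdr_geno] object.
#' @param tol numerical tolerance on r-squared = 1.
#' @return A list: `geno` (pruned) and `report` (`mdr_qc_report` with
#'   removal_reason `"duplicate_r2"` for dropped markers).
#' @export
prune_duplicate_snps <- function(geno, tol = 1e-12) {
  stopifnot(inherits(geno, "mdr_geno"))
  m <- ncol(geno$dosage)
  stats <- snp_stats(geno$dosage)
  if (m < 2) {
    return(list(geno = geno, report = new_qc_report(stats, rep("none", m))))
  }
  r2 <- r2_matrix(geno$dosage)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(m - 1)) for (b in seq((a + 1), m)) {
    if (!is.na(r2[a, b]) && r2[a, b] >= 1 - tol) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  keep <- !duplicated(root)          # smallest input_index per component
  reason <- ifelse(keep, "none", "duplicate_r2")
  list(geno = geno_subset(geno, snps = which(keep)),
       report = new_qc_report(stats, reason))
}

#' High-LD partners of a marker
#'
#' All other markers whose genotype r-squared with the query SNP meets the
#' threshold (inclusive). Used to remove a main-effect SNP together with its
#' proxies before multi-locus search.
#'
#' @param geno an [mdr_geno] object.
#' @param snp_id query SNP id.
#' @param r2_threshold inclusion threshold, default 0.8.
#' @return A tibble `snp_id`, `r2`, ordered by input index.
#' @export
ld_partners <- function(geno, snp_id, r2_threshold = 0.8) {
  stopifnot(inherits(geno, "mdr_geno"))
  j <- match(snp_id, geno$snp_info$snp_id)
  if (is.na(j)) abort(sprintf("unknown snp id '%s'", snp_id))
  x <- geno$dosage[, j]
  r2 <- vapply(seq_len(ncol(geno$dosage)), function(k) {
    if (k == j) return(NA_real_)
    y <- geno$dosage[, k]
    cc <- complete.cases(x, y)
    if (sd(x[cc]) == 0 || sd(y[cc]) == 0) return(NA_real_)
    cor(x[cc], y[cc])^2
  }, numeric(1))
  hit <- which(!is.na(r2) & r2 >= r2_threshold)
  tibble::tibble(snp_id = geno$snp_info$snp_id[hit], r2 = r2[hit])
}
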