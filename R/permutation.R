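#' Permute genotypes against outcomes
#'
#' Shuffles the genotype rows relative to the (outcome, covariate) rows,
#' preserving every marginal distribution and the outcome-covariate
#' relationship while destroying any genotype-outcome association. This is
#' the null-generating operation of the permutation test: covariate
#' confounding stays intact, only the genetic signal is broken.
#'
#' @param cohort an `mdr_cohort` (or an [mdr_geno], in which case only the
#'   row order of the genotype matrix is returned permuted).
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return The cohort with permuted genotype rows; the applied permutation
#'   is attached as attribute `"permutation"`.
#' @export
permute_dataset <- function(cohort, seed) {
  set.seed(seed)
  if (inherits(cohort, "mdr_geno")) {
    perm <- sample(nrow(cohort$dosage))
    out <- cohort
    out$dosage <- out$dosage[perm, , drop = FALSE]
    rownames(out$dosage) <- cohort$subjects
    attr(out, "permutation") <- perm
    return(out)
  }
  stopifnot(inherits(cohort, "mdr_cohort"))
  perm <- sample(nrow(cohort$geno$dosage))
  cohort$geno$dosage <- cohort$geno$dosage[perm, , drop = FALSE]
  rownames(cohort$geno$dosage) <- cohort$geno$subjects
  attr(cohort, "permutation") <- perm
  cohort
}

#' Permutation test of the k-way search
#'
#' Assesses how extreme the observed run-best mean testing balanced accuracy
#' is against the null in which genotype rows are permuted against the
#' (outcome, covariate) rows. The fold partition is held fixed at
#' `partition_seed`; for each of `n_perm` permutations one full
#' cross-validated search is re-run on the permuted genotypes and its
#' run-best mean TBA recorded. Because the covariate-only null scores do not
#' depend on genotypes, the score vector is computed once and only its
#' alignment to genotype rows changes -- an exact shortcut for re-running
#' the scoring on each permuted dataset. The observed statistic is computed
#' the same single-run way for comparability.
#'
#' @inheritParams cv_search
#' @param n_perm number of permutations, default 1000.
#' @param seed seed for the permutation stream.
#' @param partition_seed seed of the fixed fold partition (defaults to
#'   `seed`).
#' @param add_one if `TRUE`, uses the (1 + #)/(n_perm + 1) estimator;
#'   the default reports #\{null >= observed\}/n_perm, matching the
#'   "p < 1/n_perm" granularity convention (a zero count is labelled so).
#' @return A list of class `mdr_perm`: `observed`, `null` (length
#'   `n_perm`), `p_value`, `p_label`, `n_perm`, `k`, `strategy`, the
#'   single-run observed `best_model` and bookkeeping seeds.
#' @export
permutation_test <- function(geno, scores, k, n_perm = 1000, seed,
                             strategy = c("tba", "cvc_first_in_file"),
                             partition_seed = seed, n_folds = 5,
                             threshold = 0, add_one = FALSE) {
  strategy <- match.arg(strategy)
  if (n_perm < 1) abort("n_perm must be >= 1")
  d <- geno_dosage(geno, allow_missing = FALSE)
  s <- score_vec(scores)
  if (nrow(d) != length(s)) abort("scores not aligned with genotype rows")
  if (all(s == 0)) abort("uninformative scores: all scores are zero")
  fold <- make_cv_folds(nrow(d), n_folds, partition_seed)
  obs <- cv_search_fast(d, s, fold, k, strategy, n_folds, threshold)
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(d))
    null[b] <- cv_search_fast(d[perm, , drop = FALSE], s, fold, k, strategy,
                              n_folds, threshold)$mean_tba
  }
  hits <- sum(null >= obs$mean_tba)
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  label <- if (!add_one && hits == 0) sprintf("< %g", 1 / n_perm) else
    format(p, digits = 4)
  best <- classify_cells(d[, obs$best_idx, drop = FALSE], s, threshold)
  structure(list(observed = obs$mean_tba, null = null, p_value = p,
                 p_label = label, n_perm = n_perm, k = k, strategy = strategy,
                 seed = seed, partition_seed = partition_seed,
                 best_model = best, best_idx = obs$best_idx,
                 cvc = obs$cvc, add_one = add_one),
            class = "mdr_perm")
}

#' @export
print.mdr_perm <- function(x, ...) {
  cat(sprintf("<mdr_perm> %d-way (%s): observed mean TBA %.4f, p %s (%d permutations)\n",
              x$k, x$strategy, x$observed, x$p_label, x$n_perm))
  invisible(x)
}
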