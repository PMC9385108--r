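#' Number of k-way SNP combinations
#'
#' Total count of candidate interaction models: the sum over the requested
#' orders of `choose(n_snps, k)`. For a 100-SNP panel the 3-way count alone
#' is 161700, which is why exhaustive interaction scans need data-reduction
#' machinery at all.
#'
#' @param n_snps panel size.
#' @param orders subset of 1:3 giving the interaction orders.
#' @return Exact combination count (numeric; exact for any panel this
#'   package can scan).
#' @export
count_combinations <- function(n_snps, orders = 1:3) {
  orders <- as.integer(orders)
  if (!length(orders) || !all(orders %in% 1:3)) abort("orders must be a subset of 1:3")
  if (anyDuplicated(orders)) abort("duplicated orders")
  if (n_snps < max(orders)) abort("order exceeds the number of SNPs")
  sum(choose(n_snps, orders))
}

labels_key <- function(labels) paste(labels, collapse = "")

new_risk_model <- function(snp_ids, labels, threshold = 0, cell_stats = NULL) {
  k <- as.integer(round(log(length(labels), 3)))
  structure(list(snp_ids = snp_ids, k = k, labels = as.integer(labels),
                 threshold = threshold, cell_stats = cell_stats),
            class = "mdr_risk_model")
}

#' @export
print.mdr_risk_model <- function(x, ...) {
  cat(sprintf("<mdr_risk_model> %d-way: %s\n", x$k,
              paste(x$snp_ids, collapse = " + ")))
  cat(sprintf("  high-risk cells: %d of %d\n", sum(x$labels), length(x$labels)))
  invisible(x)
}

# all 3^k cells as a matrix, first SNP varying fastest (matches cell_index)
cell_grid <- function(k) {
  g <- as.matrix(expand.grid(rep(list(0:2), k)))
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Classify multilocus genotype cells as high or low risk
#'
#' Each joint genotype cell of the k supplied SNPs receives the sum of the
#' covariate-adjusted scores of the training subjects falling in it; cells
#' whose sum exceeds the threshold (default 0) are labelled high-risk, cells
#' at or below the threshold -- and cells unobserved in training -- are
#' low-risk. This is the MDR reduction of a k-locus genotype table to one
#' binary attribute.
#'
#' @param dosage n x k dosage matrix (or vector for k = 1) of the SNPs in
#'   the combination, 0/1/2, no missing values.
#' @param scores numeric score vector or `mdr_scores` tibble aligned with
#'   the rows of `dosage`.
#' @param threshold classification threshold on the cell score sum.
#' @return An `mdr_risk_model`: SNP ids, the 3^k cell label vector and a
#'   per-cell tibble (`cell_stats`) of score sums, counts and labels.
#' @export
classify_cells <- function(dosage, scores, threshold = 0) {
  s <- score_vec(scores)
  d <- if (is.null(dim(dosage))) matrix(as.integer(dosage), ncol = 1) else {
    d0 <- as.matrix(dosage); storage.mode(d0) <- "integer"; d0
  }
  if (anyNA(d) || !all(d %in% 0:2)) abort("dosage must be 0/1/2 with no missing values")
  k <- ncol(d)
  if (!k %in% 1:3) abort("k must be 1, 2 or 3")
  if (nrow(d) != length(s)) abort("scores not aligned with dosage rows")
  if (all(s == 0)) abort("uninformative scores: all scores are zero")
  idx <- cell_index(d)
  ncell <- 3L^k
  sums <- counts <- numeric(ncell)
  agg <- rowsum(cbind(s, 1), idx)
  at <- as.integer(rownames(agg))
  sums[at] <- agg[, 1]; counts[at] <- agg[, 2]
  labels <- as.integer(sums > threshold)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("snp", seq_len(k))
  grid <- cell_grid(k)
  stats <- tibble::as_tibble(as.data.frame(grid))
  names(stats) <- ids
  stats$score_sum <- sums
  stats$n <- as.integer(counts)
  stats$label <- ifelse(labels == 1L, "high", "low")
  new_risk_model(ids, labels, threshold, stats)
}

#' Score-weighted balanced accuracy of a risk model
#'
#' With P the total positive score mass and N the total negative score
#' magnitude of the evaluation subjects, sensitivity is the positive mass
#' falling in high-risk cells over P and specificity the negative magnitude
#' falling in low-risk cells over N; balanced accuracy is their mean. Cells
#' absent from the model's map take the default low-risk label.
#'
#' @param model an `mdr_risk_model`.
#' @param dosage evaluation dosage matrix for the model's SNPs.
#' @param scores evaluation scores aligned with `dosage` rows.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(model, dosage, scores) {
  stopifnot(inherits(model, "mdr_risk_model"))
  s <- score_vec(scores)
  d <- if (is.null(dim(dosage))) matrix(as.integer(dosage), ncol = 1) else {
    d0 <- as.matrix(dosage); storage.mode(d0) <- "integer"; d0
  }
  if (!length(s)) abort("empty evaluation set")
  if (nrow(d) != length(s)) abort("scores not aligned with dosage rows")
  if (ncol(d) != model$k) abort("dosage has wrong number of SNPs for the model")
  P <- sum(s[s > 0]); N <- -sum(s[s < 0])
  if (P == 0 || N == 0) {
    abort("balanced accuracy undefined: evaluation scores are one-sided")
  }
  hi <- model$labels[cell_index(d)] == 1L
  sens <- sum(s[s > 0 & hi]) / P
  spec <- -sum(s[s < 0 & !hi]) / N
  (sens + spec) / 2
}

#' Random cross-validation folds
#'
#' Partitions subjects into folds of size `floor(n/n_folds)` or
#' `ceiling(n/n_folds)`, uniformly at random, deterministic under the seed.
#' Optionally stratified on a grouping vector (e.g. the event indicator) so
#' each fold carries a proportional share of each stratum.
#'
#' @param n_subjects number of subjects.
#' @param n_folds number of folds, default 5.
#' @param seed integer seed.
#' @param stratify optional vector of length `n_subjects`; folds are
#'   balanced within its levels.
#' @return Integer vector of fold labels in `1:n_folds`.
#' @export
make_cv_folds <- function(n_subjects, n_folds = 5, seed, stratify = NULL) {
  if (n_subjects < n_folds) abort("need at least one subject per fold")
  set.seed(seed)
  if (is.null(stratify)) {
    return(sample(rep_len(seq_len(n_folds), n_subjects)))
  }
  out <- integer(n_subjects)
  for (g in unique(stratify)) {
    i <- which(stratify == g)
    out[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  out
}

# Fast internal CV search: plain-list result, no retraining, no tibbles.
cv_search_fast <- function(dosage, s, fold, k, strategy, n_folds, threshold = 0) {
  scan <- mdr_scan_cpp(dosage, s, fold, k, n_folds, threshold)
  combos <- scan$best_combo
  keys <- apply(combos, 1, paste, collapse = ",")
  uk <- unique(keys)
  cvc <- vapply(uk, function(x) sum(keys == x), integer(1))
  mtba <- vapply(uk, function(x) mean(scan$test_ba[keys == x]), numeric(1))
  tup <- lapply(strsplit(uk, ","), as.integer)
  first <- vapply(tup, `[`, integer(1), 1)
  second <- vapply(tup, function(x) if (length(x) >= 2) x[2] else 0L, integer(1))
  third <- vapply(tup, function(x) if (length(x) >= 3) x[3] else 0L, integer(1))
  pick <- if (strategy == "tba") {
    order(-mtba, -cvc, first, second, third)[1]
  } else {
    order(-cvc, first, second, third)[1]
  }
  list(best_idx = tup[[pick]], cvc = cvc[[pick]], mean_tba = mtba[[pick]],
       fold_combo = combos, fold_train_ba = scan$train_ba,
       fold_test_ba = scan$test_ba, fold_labels = scan$labels, keys = keys)
}

#' Cross-validated exhaustive k-way MDR search
#'
#' Enumerates every k-SNP combination; per fold, cell labels are trained on
#' the 4/5 training scores and the fold-best combination (highest training
#' balanced accuracy, ties to the lexicographically smallest column-index
#' tuple) is evaluated on the held-out 1/5 for its testing balanced accuracy
#' (TBA). The run-best model is then chosen by strategy: `"tba"` takes the
#' fold-best model with the highest mean TBA over the folds where it won
#' (column-order invariant); `"cvc_first_in_file"` takes the highest
#' cross-validation consistency (CVC) and resolves ties by the earliest
#' input position -- deliberately reproducing the order-dependent behaviour
#' of CVC-based selection.
#'
#' @param geno an [mdr_geno] object or complete dosage matrix.
#' @param scores aligned scores (`mdr_scores` tibble or numeric vector).
#' @param k interaction order, 1-3.
#' @param folds optional precomputed fold labels; otherwise drawn with
#'   `seed`.
#' @param n_folds number of folds, default 5.
#' @param seed partition seed (required when `folds` is missing).
#' @param strategy `"tba"` or `"cvc_first_in_file"`.
#' @param threshold cell-classification threshold, default 0.
#' @return A list of class `mdr_run`: `fold_results` tibble (fold, combo,
#'   training and testing BA), `best_model` (an `mdr_risk_model` retrained
#'   on all subjects), `cvc`, `mean_tba`, `strategy`, `k`, `seed`.
#' @export
cv_search <- function(geno, scores, k, folds = NULL, n_folds = 5, seed = NULL,
                      strategy = c("tba", "cvc_first_in_file"), threshold = 0) {
  strategy <- match.arg(strategy)
  d <- geno_dosage(geno, allow_missing = FALSE)
  s <- score_vec(scores)
  if (nrow(d) != length(s)) abort("scores not aligned with genotype rows")
  if (ncol(d) < k) abort("need at least k SNPs")
  if (all(s == 0)) abort("uninformative scores: all scores are zero")
  if (is.null(folds)) {
    if (is.null(seed)) abort("either folds or seed must be supplied")
    folds <- make_cv_folds(nrow(d), n_folds, seed)
  }
  res <- cv_search_fast(d, s, folds, k, strategy, n_folds, threshold)
  ids <- colnames(d)
  best <- classify_cells(d[, res$best_idx, drop = FALSE], s, threshold)
  fold_results <- tibble::tibble(
    fold = seq_len(n_folds),
    combo = lapply(seq_len(n_folds), function(f) ids[res$fold_combo[f, ]]),
    train_ba = res$fold_train_ba,
    test_ba = res$fold_test_ba
  )
  structure(list(k = k, strategy = strategy, seed = seed,
                 fold_results = fold_results, best_model = best,
                 best_idx = res$best_idx,
                 cvc = res$cvc, mean_tba = res$mean_tba),
            class = "mdr_run")
}

#' @export
print.mdr_run <- function(x, ...) {
  cat(sprintf("<mdr_run> %d-way search (%s): best %s | CVC %d/5 | mean TBA %.4f\n",
              x$k, x$strategy, paste(x$best_model$snp_ids, collapse = "+"),
              x$cvc, x$mean_tba))
  invisible(x)
}

#' Repeated-run consensus ("top") model
#'
#' Repeats the cross-validated search with `n_runs` independent fold
#' partitions and groups the run-best models by SNP set and high-risk cell
#' map. The top model is the most frequently selected one; frequency ties go
#' to the higher mean TBA, then the higher CVC -- the prioritisation used
#' when consolidating 20 differently partitioned runs into one reported
#' model.
#'
#' @inheritParams cv_search
#' @param n_runs number of repeated runs, default 20.
#' @param base_seed seed from which the per-run partition seeds are drawn.
#' @return A list of class `mdr_top_model`: `model` (`mdr_risk_model`),
#'   `frequency`, `n_runs`, `mean_tba`, `cvc`, `runs` tibble, and a
#'   `perm_p` slot filled by [permutation_test()]-based workflows.
#' @export
repeated_search <- function(geno, scores, k, n_runs = 20, base_seed,
                            strategy = c("tba", "cvc_first_in_file"),
                            n_folds = 5, threshold = 0) {
  strategy <- match.arg(strategy)
  n_runs <- as.integer(n_runs)
  if (n_runs < 1) abort("n_runs must be >= 1")
  d <- geno_dosage(geno, allow_missing = FALSE)
  s <- score_vec(scores)
  if (all(s == 0)) abort("uninformative scores: all scores are zero")
  set.seed(base_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fold <- make_cv_folds(nrow(d), n_folds, run_seeds[r])
    fast <- cv_search_fast(d, s, fold, k, strategy, n_folds, threshold)
    model <- classify_cells(d[, fast$best_idx, drop = FALSE], s, threshold)
    runs[[r]] <- list(seed = run_seeds[r], idx = fast$best_idx,
                      snp_ids = model$snp_ids, labels = model$labels,
                      cvc = fast$cvc, mean_tba = fast$mean_tba)
  }
  key <- vapply(runs, function(r) {
    paste(paste(r$idx, collapse = ","), labels_key(r$labels), sep = "|")
  }, character(1))
  grp <- split(seq_len(n_runs), key)
  freq <- lengths(grp)
  gtba <- vapply(grp, function(i) mean(vapply(runs[i], `[[`, 0, "mean_tba")), numeric(1))
  gcvc <- vapply(grp, function(i) max(vapply(runs[i], `[[`, 0L, "cvc")), numeric(1))
  pick <- order(-freq, -gtba, -gcvc)[1]
  ri <- grp[[pick]][1]
  best <- classify_cells(d[, runs[[ri]]$idx, drop = FALSE], s, threshold)
  runs_tbl <- tibble::tibble(
    run = seq_len(n_runs), seed = run_seeds,
    snp_ids = lapply(runs, `[[`, "snp_ids"),
    cvc = vapply(runs, `[[`, 0L, "cvc"),
    mean_tba = vapply(runs, `[[`, 0, "mean_tba")
  )
  structure(list(model = best, best_idx = runs[[ri]]$idx,
                 frequency = unname(freq[pick]), n_runs = n_runs,
                 mean_tba = unname(gtba[pick]), cvc = unname(gcvc[pick]),
                 strategy = strategy, k = k, runs = runs_tbl, perm_p = NA_real_),
            class = "mdr_top_model")
}

#' @export
print.mdr_top_model <- function(x, ...) {
  cat(sprintf("<mdr_top_model> %d-way (%s): %s | %d/%d runs | mean TBA %.4f | CVC %d\n",
              x$k, x$strategy, paste(x$model$snp_ids, collapse = "+"),
              x$frequency, x$n_runs, x$mean_tba, x$cvc))
  if (!is.na(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}
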