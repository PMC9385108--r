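# Naive reference implementations of the MDR machinery, kept deliberately
# independent of the package's vectorised/compiled code paths: plain loops,
# string-keyed cell maps, per-subject accumulation.

oracle_cell_key <- function(dosages) paste(dosages, collapse = "/")

# label map: cell key -> "high"/"low" from training scores
oracle_classify <- function(dosage, scores, threshold = 0) {
  dosage <- as.matrix(dosage)
  sums <- list()
  for (i in seq_len(nrow(dosage))) {
    key <- oracle_cell_key(dosage[i, ])
    sums[[key]] <- (if (is.null(sums[[key]])) 0 else sums[[key]]) + scores[i]
  }
  lab <- list()
  for (key in names(sums)) {
    lab[[key]] <- if (sums[[key]] > threshold) "high" else "low"
  }
  lab
}

oracle_ba <- function(label_map, dosage, scores) {
  dosage <- as.matrix(dosage)
  P <- N <- pos_hi <- neg_lo <- 0
  for (i in seq_len(nrow(dosage))) {
    key <- oracle_cell_key(dosage[i, ])
    lab <- label_map[[key]]
    if (is.null(lab)) lab <- "low"   # unseen cell defaults to low risk
    s <- scores[i]
    if (s > 0) {
      P <- P + s
      if (lab == "high") pos_hi <- pos_hi + s
    } else if (s < 0) {
      N <- N - s
      if (lab == "low") neg_lo <- neg_lo - s
    }
  }
  (pos_hi / P + neg_lo / N) / 2
}

# per-fold exhaustive search: best training-BA combo (first wins ties in
# lexicographic enumeration order), then its testing BA on the held-out fold
oracle_cv <- function(dosage, scores, fold, k) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  combos <- utils::combn(m, k)
  res <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    best <- NULL; best_ba <- -Inf
    for (ci in seq_len(ncol(combos))) {
      combo <- combos[, ci]
      lab <- oracle_classify(dosage[tr, combo, drop = FALSE], scores[tr])
      ba <- oracle_ba(lab, dosage[tr, combo, drop = FALSE], scores[tr])
      if (ba > best_ba) { best_ba <- ba; best <- combo }
    }
    lab <- oracle_classify(dosage[tr, best, drop = FALSE], scores[tr])
    test_ba <- oracle_ba(lab, dosage[!tr, best, drop = FALSE], scores[!tr])
    res[[f]] <- list(combo = best, train_ba = best_ba, test_ba = test_ba)
  }
  res
}

# training BA of one specific combo on one fold, for tie-aware comparisons
oracle_train_ba <- function(dosage, scores, tr, combo) {
  dosage <- as.matrix(dosage)
  lab <- oracle_classify(dosage[tr, combo, drop = FALSE], scores[tr])
  oracle_ba(lab, dosage[tr, combo, drop = FALSE], scores[tr])
}

# TRUE when the package's fold-best agrees with the oracle's: identical
# combos, or exactly tied optima (equal training BA within tol), in which
# case the argmax is not unique and either pick is correct
oracle_fold_agrees <- function(pkg_combo, pkg_train_ba, orc, dosage, scores,
                               tr, tol = 1e-12) {
  if (identical(pkg_combo, orc$combo)) return(TRUE)
  ba_pkg <- oracle_train_ba(dosage, scores, tr, pkg_combo)
  abs(ba_pkg - orc$train_ba) <= tol && abs(pkg_train_ba - orc$train_ba) <= tol
}

# Kaplan-Meier product-limit estimator by direct computation
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  list(time = tt, surv = out)
}
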