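# Small simulated datasets shared across test files.

quick_cohort <- function(seed, n = 200, m = 8, effect = NULL, ...) {
  simulate_cohort(sim_config(n_subjects = n, n_snps = m, seed = seed, ...),
                  effect = effect)
}

# TRUE when every fold's training-BA maximum over single SNPs is unique:
# exact training ties make the fold-best depend on column order, which the
# order-invariance property deliberately excludes
tie_free_folds <- function(dosage, scores, fold, tol = 1e-9) {
  all(vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    bas <- vapply(seq_len(ncol(dosage)), function(j) {
      m <- classify_cells(dosage[tr, j], scores[tr])
      balanced_accuracy(m, dosage[tr, j], scores[tr])
    }, numeric(1))
    top <- sort(bas, decreasing = TRUE)
    top[1] - top[2] > tol
  }, logical(1)))
}

# iid dosage matrix + centered continuous scores, for oracle comparisons;
# scores are redrawn until every fold carries both score signs (the
# balanced-accuracy precondition)
random_instance <- function(seed, n, m, maf = 0.3, fold = NULL) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(NULL, sprintf("s%02d", seq_len(m))))
  repeat {
    s <- rnorm(n)
    s <- s - mean(s)
    if (is.null(fold)) break
    two_sided <- vapply(split(s, fold), function(x) any(x > 0) && any(x < 0),
                        logical(1))
    if (all(two_sided)) break
  }
  list(dosage = d, scores = s)
}
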