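# Engine-appropriate pieces shared by the workflow: scores, the phenotype
# rows the engine uses, and the matching validation call.
engine_context <- function(cohort, engine, covariates) {
  if (engine == "cox") {
    scores <- cox_scores(cohort, covariates)
    list(scores = scores, pheno = cohort$pheno, geno = cohort$geno,
         subjects = cohort$pheno$subject_id)
  } else {
    keep <- which(cohort$pheno$included5y == 1)
    pheno <- cohort$pheno[keep, ]
    geno <- geno_subset(cohort$geno, subjects = keep)
    model <- fit_logistic_null(pheno, covariates = covariates)
    list(scores = logistic_residual_scores(model, pheno), pheno = pheno,
         geno = geno, subjects = pheno$subject_id)
  }
}

validate_model <- function(model, ctx, engine, covariates) {
  grp <- assign_risk_groups(ctx$geno, model)
  if (length(unique(grp)) < 2) return(NULL)
  if (engine == "cox") {
    cox_regression_validation(grp, ctx$pheno, covariates)
  } else {
    logistic_regression_validation(grp, ctx$pheno, covariates)
  }
}

#' Iterative removal of main-effect SNPs
#'
#' Implements the single-locus stage of the workflow: run the repeated
#' 1-way search, permutation-test its top model, and -- while the
#' permutation p-value stays below `alpha` -- validate the grouping by
#' regression, then remove the top SNP together with every marker in high
#' LD with it (r-squared at or above `r2_threshold`) and repeat. A SNP with
#' a strong main effect would otherwise masquerade as part of higher-order
#' interactions, so all of them are stripped before the 2- and 3-way scans.
#' The final, non-significant iteration is recorded too.
#'
#' @param cohort an `mdr_cohort`.
#' @param engine `"cox"` (martingale-residual scores, survival outcome) or
#'   `"logistic"` (response-residual scores, 5-year status).
#' @param covariates covariate column names.
#' @param alpha permutation significance level gating continued removal.
#' @param r2_threshold LD threshold for co-removal of partners.
#' @param n_runs repeated-search runs per iteration.
#' @param n_perm permutations per iteration.
#' @param seed master seed; per-iteration search/permutation seeds derive
#'   from it.
#' @param strategy model-selection strategy passed to the search.
#' @param require_regression if `TRUE`, removal additionally requires the
#'   regression group term to reach `alpha` (strict mode); by default the
#'   permutation p-value alone gates removal and the regression result is
#'   only reported.
#' @return A list: `geno` (the reduced genotype data), `iterations` (one
#'   record per iteration: top model, permutation p, regression summary,
#'   removed SNPs with their r-squared, stop reason), and the engine
#'   context's scores.
#' @export
run_main_effect_iterations <- function(cohort, engine = c("cox", "logistic"),
                                       covariates = covariate_names(),
                                       alpha = 0.05, r2_threshold = 0.8,
                                       n_runs = 20, n_perm = 1000, seed,
                                       strategy = c("tba", "cvc_first_in_file"),
                                       require_regression = FALSE) {
  engine <- match.arg(engine)
  strategy <- match.arg(strategy)
  ctx <- engine_context(cohort, engine, covariates)
  geno <- ctx$geno
  set.seed(seed)
  iter_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * (ncol(geno$dosage) + 1)),
                       ncol = 2)
  iterations <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    if (ncol(geno$dosage) < 1) {
      iterations[[it]] <- list(iteration = it, k = 1L, top = NULL, perm = NULL,
                               regression = NULL, removed = character(),
                               removed_r2 = numeric(), stop_reason = "no_snps_left")
      break
    }
    top <- repeated_search(geno, ctx$scores, k = 1, n_runs = n_runs,
                           base_seed = iter_seeds[it, 1], strategy = strategy)
    perm <- permutation_test(geno, ctx$scores, k = 1, n_perm = n_perm,
                             seed = iter_seeds[it, 2], strategy = strategy)
    top$perm_p <- perm$p_value
    rec <- list(iteration = it, k = 1L, top = top, perm = perm,
                regression = NULL, removed = character(),
                removed_r2 = numeric(), stop_reason = NA_character_)
    if (perm$p_value < alpha) {
      ctx_iter <- list(geno = geno, pheno = ctx$pheno)
      rec$regression <- validate_model(top$model, ctx_iter, engine, covariates)
      reg_ok <- !is.null(rec$regression) &&
        rec$regression$p_value < alpha
      if (require_regression && !reg_ok) {
        rec$stop_reason <- "regression_not_significant"
        iterations[[it]] <- rec
        break
      }
      snp <- top$model$snp_ids[1]
      partners <- ld_partners(geno, snp, r2_threshold)
      rec$removed <- c(snp, partners$snp_id)
      rec$removed_r2 <- c(1, partners$r2)
      keep <- setdiff(geno$snp_info$snp_id, rec$removed)
      geno <- geno_subset(geno, snps = keep)
      iterations[[it]] <- rec
      if (!length(keep)) next  # records a terminal no-SNP iteration
    } else {
      rec$stop_reason <- "not_significant"
      iterations[[it]] <- rec
      break
    }
  }
  list(geno = geno, iterations = iterations, scores = ctx$scores,
       pheno = ctx$pheno, engine = engine)
}

#' Run the full MDR interaction workflow
#'
#' End-to-end orchestration on one dataset: genotype QC (MAF/HWE/missingness
#' filters and exact-duplicate pruning), covariate-adjusted scoring for the
#' chosen engine, iterative removal of significant main-effect SNPs with
#' their LD partners, then repeated 2-way and 3-way searches with
#' permutation testing and regression validation of any significant model.
#'
#' @inheritParams run_main_effect_iterations
#' @param k_max highest interaction order to scan (2 or 3).
#' @param maf_min,hwe_min_p,max_missing QC thresholds.
#' @param n_folds cross-validation folds.
#' @return A list of class `mdr_pipeline_report`: configuration echo, QC
#'   reports, main-effect iteration records, per-order multiway results
#'   (top model, permutation result, regression/KM validation when
#'   significant), and the final SNP panel.
#' @export
run_full_pipeline <- function(cohort, engine = c("cox", "logistic"),
                              covariates = covariate_names(),
                              k_max = 3, alpha = 0.05, r2_threshold = 0.8,
                              n_runs = 20, n_perm = 1000, n_folds = 5, seed,
                              strategy = c("tba", "cvc_first_in_file"),
                              maf_min = 0.05, hwe_min_p = 1e-4,
                              max_missing = 0, require_regression = FALSE) {
  engine <- match.arg(engine)
  strategy <- match.arg(strategy)
  qc <- apply_qc_filters(cohort$geno, maf_min, hwe_min_p, max_missing)
  dedup <- prune_duplicate_snps(qc$geno)
  cohort$geno <- dedup$geno
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 1 + 2 * max(0, k_max - 1))
  main <- run_main_effect_iterations(
    cohort, engine = engine, covariates = covariates, alpha = alpha,
    r2_threshold = r2_threshold, n_runs = n_runs, n_perm = n_perm,
    seed = stage_seeds[1], strategy = strategy,
    require_regression = require_regression)
  geno <- main$geno
  multiway <- list()
  ctx <- list(geno = geno, pheno = main$pheno)
  for (k in seq(2, k_max)) {
    if (ncol(geno$dosage) < k) break
    s_top <- stage_seeds[2 * (k - 1)]
    s_perm <- stage_seeds[2 * (k - 1) + 1]
    top <- repeated_search(geno, main$scores, k = k, n_runs = n_runs,
                           base_seed = s_top, strategy = strategy)
    perm <- permutation_test(geno, main$scores, k = k, n_perm = n_perm,
                             seed = s_perm, strategy = strategy)
    top$perm_p <- perm$p_value
    res <- list(k = k, top = top, perm = perm, regression = NULL, km = NULL)
    if (perm$p_value < alpha) {
      res$regression <- validate_model(top$model, ctx, engine, covariates)
      grp <- assign_risk_groups(geno, top$model)
      if (length(unique(grp)) == 2) {
        res$km <- km_logrank(grp, main$pheno$time_years, main$pheno$event)
      }
    }
    multiway[[as.character(k)]] <- res
  }
  structure(list(
    config = list(engine = engine, covariates = covariates, k_max = k_max,
                  alpha = alpha, r2_threshold = r2_threshold, n_runs = n_runs,
                  n_perm = n_perm, n_folds = n_folds, seed = seed,
                  strategy = strategy, maf_min = maf_min,
                  hwe_min_p = hwe_min_p, max_missing = max_missing),
    qc_report = qc$report, dedup_report = dedup$report,
    snp_info = dedup$geno$snp_info,
    iterations = main$iterations, multiway = multiway,
    final_snps = geno$snp_info$snp_id, engine = engine),
    class = "mdr_pipeline_report")
}

#' @export
print.mdr_pipeline_report <- function(x, ...) {
  cat(sprintf("<mdr_pipeline_report> engine %s, strategy %s\n",
              x$engine, x$config$strategy))
  cat(sprintf("  QC: %d/%d SNPs passed, %d duplicates pruned\n",
              sum(x$qc_report$pass), nrow(x$qc_report),
              sum(x$dedup_report$removal_reason == "duplicate_r2")))
  cat(sprintf("  main-effect iterations: %d (removed %d SNPs)\n",
              length(x$iterations),
              sum(lengths(lapply(x$iterations, `[[`, "removed")))))
  for (res in x$multiway) {
    cat(sprintf("  %d-way top: %s, permutation p %s\n", res$k,
                paste(res$top$model$snp_ids, collapse = "+"),
                res$perm$p_label))
  }
  invisible(x)
}
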