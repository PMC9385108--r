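#' Assign subjects to high/low risk groups
#'
#' Looks each subject's multilocus genotype cell up in a risk model's label
#' map; cells absent from the map default to low risk (and are counted in
#' the `"n_unmapped"` attribute).
#'
#' @param geno an [mdr_geno] object or dosage matrix containing the model's
#'   SNPs.
#' @param model an `mdr_risk_model`.
#' @return Integer vector (1 = high risk, 0 = low risk) aligned with the
#'   genotype rows.
#' @export
assign_risk_groups <- function(geno, model) {
  stopifnot(inherits(model, "mdr_risk_model"))
  d <- geno_dosage(geno, allow_missing = FALSE)
  if (inherits(geno, "mdr_geno")) {
    j <- match(model$snp_ids, geno$snp_info$snp_id)
    if (anyNA(j)) abort("model SNPs not present in genotype data")
    d <- d[, j, drop = FALSE]
  }
  if (ncol(d) != model$k) abort("dosage has wrong number of SNPs for the model")
  grp <- model$labels[cell_index(d)]
  unmapped <- if (!is.null(model$cell_stats)) {
    sum(model$cell_stats$n[cell_index(d)] == 0)
  } else 0L
  structure(as.integer(grp), n_unmapped = unmapped)
}

regression_ci <- function(est, se) {
  c(lower = exp(est - 1.96 * se), upper = exp(est + 1.96 * se))
}

new_regression <- function(effect, term_table, group_term, n, direction) {
  row <- term_table[term_table$term == group_term, ]
  structure(list(effect = effect, estimate = row$estimate,
                 conf_low = row$conf_low, conf_high = row$conf_high,
                 p_value = row$p_value, term_table = term_table,
                 n = n, direction = direction),
            class = "mdr_regression")
}

#' Multivariable Cox validation of a risk grouping
#'
#' Fits a proportional-hazards model of the high/low risk group plus the
#' clinical covariates (Breslow ties, matching the null-model convention)
#' and reports the Wald hazard ratio, 95% CI and p-value of the group term.
#' The default direction reports low- vs high-risk (HR < 1 when the
#' high-risk group fares worse), the convention used for survival-engine
#' models; `"high_vs_low"` inverts it.
#'
#' @param group 0/1 risk-group vector from [assign_risk_groups()].
#' @param data tibble with time, event and covariate columns.
#' @param covariates covariate column names.
#' @param time,event column names.
#' @param direction `"low_vs_high"` or `"high_vs_low"`.
#' @return A list of class `mdr_regression` with `effect = "HR"`, the group
#'   estimate and CI, and the full term table.
#' @export
cox_regression_validation <- function(group, data, covariates = covariate_names(),
                                      time = "time_years", event = "event",
                                      direction = c("low_vs_high", "high_vs_low")) {
  direction <- match.arg(direction)
  group <- as.integer(group)
  if (length(unique(group)) < 2) abort("both risk groups must be non-empty")
  if (sum(data[[event]]) < 1) abort("no events")
  g <- if (direction == "high_vs_low") group else 1L - group
  df <- dplyr::mutate(data, .g = g)
  fml <- as.formula(paste("survival::Surv(", time, ",", event, ") ~ .g",
                          if (length(covariates))
                            paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        abort(paste("validation Cox model did not converge:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (anyNA(coef(fit))) abort("rank-deficient validation model (group aliased with a covariate)")
  terms <- rownames(sm)
  tt <- tibble::tibble(
    term = ifelse(terms == ".g", "risk_group", terms),
    estimate = exp(sm[, "coef"]),
    conf_low = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
    conf_high = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
    p_value = sm[, "Pr(>|z|)"]
  )
  new_regression("HR", tt, "risk_group", nrow(df), direction)
}

#' Multivariable logistic validation of a risk grouping
#'
#' Fits the dichotomized outcome on the risk group plus covariates and
#' reports the Wald odds ratio, 95% CI and p-value of the group term. The
#' default direction is high- vs low-risk (OR > 1 when high-risk subjects
#' have worse 5-year status), the convention used for binary-engine models.
#'
#' @param group 0/1 risk-group vector.
#' @param data tibble with the status and covariate columns (excluded
#'   subjects already dropped).
#' @param covariates covariate column names.
#' @param status status column name.
#' @param direction `"high_vs_low"` or `"low_vs_high"`.
#' @return A list of class `mdr_regression` with `effect = "OR"`.
#' @export
logistic_regression_validation <- function(group, data,
                                           covariates = covariate_names(),
                                           status = "status5y",
                                           direction = c("high_vs_low", "low_vs_high")) {
  direction <- match.arg(direction)
  group <- as.integer(group)
  if (length(unique(group)) < 2) abort("both risk groups must be non-empty")
  y <- data[[status]]
  if (anyNA(y)) abort("status contains NA; drop excluded subjects first")
  if (length(unique(y)) < 2) abort("single-class outcome")
  g <- if (direction == "high_vs_low") group else 1L - group
  df <- dplyr::mutate(data, .g = g)
  fml <- as.formula(paste(status, "~ .g",
                          if (length(covariates))
                            paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort("separation in validation logistic model")
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) abort("validation logistic model did not converge")
  sm <- summary(fit)$coefficients
  if (anyNA(coef(fit))) abort("rank-deficient validation model")
  terms <- rownames(sm)
  tt <- tibble::tibble(
    term = ifelse(terms == ".g", "risk_group", terms),
    estimate = exp(sm[, "Estimate"]),
    conf_low = exp(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
    conf_high = exp(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"]
  )
  new_regression("OR", tt, "risk_group", nrow(df), direction)
}

#' @export
print.mdr_regression <- function(x, ...) {
  cat(sprintf("<mdr_regression> %s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d (%s)\n",
              x$effect, x$estimate, x$conf_low, x$conf_high, x$p_value, x$n,
              x$direction))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for risk groups
#'
#' Product-limit survival curves per risk group with censor marks, and the
#' two-sample log-rank test when both groups are present.
#'
#' @param group 0/1 risk-group vector (a single-group vector yields the
#'   pooled curve and no test).
#' @param time,event numeric follow-up times (years) and event indicators.
#' @return A list of class `mdr_km`: `curves` tibble (`group`, `time`,
#'   `surv`, `n_risk`, `n_event`, `n_censor`), `logrank_chisq`,
#'   `logrank_p`, group sizes.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.integer(group)
  df <- data.frame(time = time, event = event,
                   group = factor(ifelse(group == 1, "high", "low"),
                                  levels = c("low", "high")))
  two <- length(unique(group)) == 2
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(as.character(df$group[1]), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(group = strata, time = fit$time, surv = fit$surv,
                           n_risk = fit$n.risk, n_event = fit$n.event,
                           n_censor = fit$n.censor)
  if (two) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- lr$chisq
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  structure(list(curves = curves, logrank_chisq = chisq, logrank_p = p,
                 n = table(df$group)),
            class = "mdr_km")
}

#' @export
print.mdr_km <- function(x, ...) {
  cat(sprintf("<mdr_km> groups n = {%s}; log-rank chi^2 = %.3f, p = %.3g\n",
              paste(sprintf("%s: %d", names(x$n), x$n), collapse = ", "),
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}
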