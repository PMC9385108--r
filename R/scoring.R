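#' Fit the covariates-only Cox null model
#'
#' Proportional-hazards fit of the clinical covariates alone (no genotypes),
#' by partial likelihood with the Breslow tie approximation, plus the
#' Breslow estimate of the baseline cumulative hazard. Its martingale
#' residuals are the per-subject scores that drive survival-engine MDR cell
#' classification.
#'
#' @param data tibble with the time, event and covariate columns.
#' @param time,event column names of the follow-up time (years) and event
#'   indicator (1 = event).
#' @param covariates character vector of covariate column names (may be
#'   empty, in which case the model is the baseline hazard alone).
#' @return A list of class `mdr_null_model` with elements `engine`
#'   (`"cox"`), `gamma` (coefficients), `baseline` (tibble `time`, `cumhaz`
#'   of the step baseline; right-constant beyond the last event),
#'   `loglik`, `converged`, `ties = "breslow"` and the fitted
#'   [survival::coxph] object.
#' @export
fit_cox_null <- function(data, time = "time_years", event = "event",
                         covariates = character()) {
  tm <- data[[time]]; ev <- data[[event]]
  if (is.null(tm) || is.null(ev)) abort("time/event columns not found")
  if (sum(ev) < 1) abort("no events: null Cox model cannot be fitted")
  if (length(covariates)) {
    x <- as.matrix(data[, covariates, drop = FALSE])
    if (qr(cbind(1, x))$rank < ncol(x) + 1) {
      abort("covariate matrix is rank deficient (collinear covariates)")
    }
    fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(covariates, collapse = " + ")))
    df <- dplyr::mutate(data, .time = tm, .event = ev)
    fit <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = "breslow",
                      control = survival::coxph.control(eps = 1e-12,
                                                        iter.max = 50)),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
          abort(paste("Cox null model did not converge:", conditionMessage(w)))
        }
        invokeRestart("muffleWarning")
      })
    gamma <- coef(fit)
    if (any(!is.finite(gamma))) {
      abort("Cox null model did not converge: non-finite coefficients")
    }
    lp <- as.vector(x %*% gamma)
    loglik <- fit$loglik[length(fit$loglik)]
  } else {
    # no covariates: partial likelihood is flat, the model is the Breslow
    # (Nelson-Aalen) baseline alone
    fit <- NULL
    gamma <- setNames(numeric(0), character(0))
    lp <- rep(0, length(tm))
    loglik <- NA_real_
  }
  # Breslow baseline: increments d_j / sum_{risk set} exp(lp)
  et <- sort(unique(tm[ev == 1]))
  inc <- vapply(et, function(t0) {
    sum(ev == 1 & tm == t0) / sum(exp(lp[tm >= t0]))
  }, numeric(1))
  structure(list(engine = "cox", gamma = gamma, covariates = covariates,
                 time = time, event = event,
                 baseline = tibble::tibble(time = et, cumhaz = cumsum(inc)),
                 loglik = loglik,
                 converged = TRUE, ties = "breslow", fit = fit),
            class = "mdr_null_model")
}

#' Martingale residuals of the null Cox model
#'
#' `s_i = event_i - Lambda0(t_i) * exp(gamma' z_i)`: the observed minus
#' model-expected number of events for subject i. Positive scores mark
#' subjects who fared worse than their covariates predict. Residuals sum to
#' zero by the Breslow baseline's score equation. Times beyond the baseline
#' support use its right-constant extension.
#'
#' @param model an `mdr_null_model` with engine `"cox"`.
#' @param data tibble carrying the same time/event/covariate columns the
#'   model was fitted on (defaults to evaluating at the training rows).
#' @return A tibble of class `mdr_scores`: `subject_id` (if present in
#'   `data`), `engine`, `score`.
#' @export
martingale_residuals <- function(model, data) {
  stopifnot(inherits(model, "mdr_null_model"))
  if (model$engine != "cox") abort("model engine must be 'cox'")
  tm <- data[[model$time]]; ev <- data[[model$event]]
  lp <- if (length(model$covariates)) {
    as.vector(as.matrix(data[, model$covariates, drop = FALSE]) %*% model$gamma)
  } else rep(0, length(tm))
  bl <- model$baseline
  cumhaz <- if (nrow(bl)) {
    stats::stepfun(bl$time, c(0, bl$cumhaz), right = FALSE)(tm)
  } else rep(0, length(tm))
  new_scores(data, ev - cumhaz * exp(lp), "cox")
}

#' Fit the covariates-only logistic null model
#'
#' Maximum-likelihood logistic regression of the dichotomized outcome on the
#' clinical covariates (with intercept). Subjects excluded by the horizon
#' rule must be dropped before calling. Its response residuals are the
#' scores of the binary-engine (GMDR-style) classifier.
#'
#' @param data tibble with the status and covariate columns.
#' @param status column name of the 0/1 outcome.
#' @param covariates character vector of covariate column names.
#' @return A list of class `mdr_null_model` with engine `"logistic"`,
#'   coefficients, fitted probabilities and diagnostics.
#' @export
fit_logistic_null <- function(data, status = "status5y",
                              covariates = character()) {
  y <- data[[status]]
  if (is.null(y)) abort("status column not found")
  if (anyNA(y)) abort("status contains NA; drop excluded subjects first")
  if (length(unique(y)) < 2) abort("single-class outcome: logistic null model undefined")
  fml <- if (length(covariates)) {
    as.formula(paste(status, "~", paste(covariates, collapse = " + ")))
  } else as.formula(paste(status, "~ 1"))
  fit <- withCallingHandlers(
    glm(fml, data = data, family = binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort("separation in logistic null model: fitted probabilities at 0/1")
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(coef(fit)) > 20)) {
    abort("logistic null model did not converge (possible separation)")
  }
  structure(list(engine = "logistic", gamma = coef(fit),
                 covariates = covariates, status = status,
                 fitted = as.vector(stats::fitted(fit)),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = TRUE, fit = fit),
            class = "mdr_null_model")
}

#' Logistic score residuals
#'
#' `s_i = y_i - p_hat_i`, the response residual of the null logistic fit;
#' with an intercept these sum to zero (the MLE score equation) and lie in
#' (-1, 1).
#'
#' @param model an `mdr_null_model` with engine `"logistic"`.
#' @param data tibble carrying the status and covariate columns.
#' @return A tibble of class `mdr_scores`.
#' @export
logistic_residual_scores <- function(model, data) {
  stopifnot(inherits(model, "mdr_null_model"))
  if (model$engine != "logistic") abort("model engine must be 'logistic'")
  y <- data[[model$status]]
  if (is.null(y)) abort("status column not found")
  x <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(model$covariates)) {
    x <- cbind(x, as.matrix(data[, model$covariates, drop = FALSE]))
  }
  if (nrow(x) != length(y)) abort("length mismatch between status and covariates")
  p <- stats::plogis(as.vector(x %*% model$gamma[colnames(x)]))
  new_scores(data, y - p, "logistic")
}

new_scores <- function(data, score, engine) {
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(data)) data[["subject_id"]]
                 else sprintf("S%04d", seq_along(score)),
    engine = engine, score = score)
  class(out) <- c("mdr_scores", class(out))
  out
}

#' Covariate-adjusted scores for a cohort
#'
#' One-call wrappers producing the per-subject scores each MDR engine
#' consumes: martingale residuals of the Cox null model (`cox_scores`) or
#' response residuals of the logistic null model on the 5-year status
#' (`logistic_scores`, which drops subjects excluded by the horizon rule and
#' returns scores for the included subjects only).
#'
#' @param cohort an `mdr_cohort`.
#' @param covariates covariate column names, default the full clinical set.
#' @return A tibble of class `mdr_scores`.
#' @export
cox_scores <- function(cohort, covariates = covariate_names()) {
  model <- fit_cox_null(cohort$pheno, covariates = covariates)
  martingale_residuals(model, cohort$pheno)
}

#' @rdname cox_scores
#' @export
logistic_scores <- function(cohort, covariates = covariate_names()) {
  df <- dplyr::filter(cohort$pheno, .data$included5y == 1)
  model <- fit_logistic_null(df, covariates = covariates)
  logistic_residual_scores(model, df)
}
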