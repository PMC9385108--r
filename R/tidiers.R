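#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-element table (folds, cells, permutation draws, regression terms,
#' survival-curve steps) and `glance()` a one-row model summary.
#'
#' @param x a survmdr result object.
#' @param ... unused.
#' @return A tibble.
#' @name survmdr-tidiers
NULL

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_risk_model <- function(x, ...) x$cell_stats

#' @rdname survmdr-tidiers
#' @export
glance.mdr_risk_model <- function(x, ...) {
  tibble::tibble(k = x$k, snp_ids = paste(x$snp_ids, collapse = ","),
                 n_high_cells = sum(x$labels), n_cells = length(x$labels),
                 threshold = x$threshold)
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_run <- function(x, ...) {
  dplyr::mutate(x$fold_results,
                combo = vapply(.data$combo, paste, "", collapse = ","))
}

#' @rdname survmdr-tidiers
#' @export
glance.mdr_run <- function(x, ...) {
  tibble::tibble(k = x$k, strategy = x$strategy,
                 best = paste(x$best_model$snp_ids, collapse = ","),
                 cvc = x$cvc, mean_tba = x$mean_tba)
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_top_model <- function(x, ...) {
  dplyr::mutate(x$runs,
                snp_ids = vapply(.data$snp_ids, paste, "", collapse = ","))
}

#' @rdname survmdr-tidiers
#' @export
glance.mdr_top_model <- function(x, ...) {
  tibble::tibble(k = x$k, strategy = x$strategy,
                 model = paste(x$model$snp_ids, collapse = ","),
                 frequency = x$frequency, n_runs = x$n_runs,
                 mean_tba = x$mean_tba, cvc = x$cvc, perm_p = x$perm_p)
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_perm <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), statistic = x$null)
}

#' @rdname survmdr-tidiers
#' @export
glance.mdr_perm <- function(x, ...) {
  tibble::tibble(k = x$k, strategy = x$strategy, observed = x$observed,
                 p_value = x$p_value, p_label = x$p_label, n_perm = x$n_perm)
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_regression <- function(x, ...) x$term_table

#' @rdname survmdr-tidiers
#' @export
glance.mdr_regression <- function(x, ...) {
  tibble::tibble(effect = x$effect, estimate = x$estimate,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 p_value = x$p_value, n = x$n, direction = x$direction)
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_km <- function(x, ...) x$curves

#' @rdname survmdr-tidiers
#' @export
glance.mdr_km <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
                 n_low = as.integer(x$n["low"]),
                 n_high = as.integer(if (!is.na(x$n["high"])) x$n["high"] else 0))
}

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_qc_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname survmdr-tidiers
#' @export
tidy.mdr_pipeline_report <- function(x, ...) report_models(x)
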