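#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier plot of risk groups
#'
#' Step survival curves for the high- and low-risk groups, with vertical
#' ticks at censoring times.
#'
#' @param object an `mdr_km` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_km <- function(object, ...) {
  cv <- object$curves
  start <- dplyr::distinct(cv, .data$group)
  start <- dplyr::mutate(start, time = 0, surv = 1)
  steps <- dplyr::bind_rows(start, cv[, c("group", "time", "surv")])
  cens <- dplyr::filter(cv, .data$n_censor > 0)
  p <- ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$surv,
                                           colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = "|", size = 3, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Follow-up time (years)", y = "Cumulative survival",
                  colour = "Risk group") +
    ggplot2::theme_minimal()
  if (!is.na(object$logrank_p)) {
    p <- p + ggplot2::labs(subtitle = sprintf("log-rank p = %.3g", object$logrank_p))
  }
  p
}

#' Permutation null-distribution plot
#'
#' Histogram of the permutation null statistics with the observed mean
#' testing balanced accuracy marked.
#'
#' @param object an `mdr_perm` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_perm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "null mean testing balanced accuracy", y = "count",
                  subtitle = sprintf("observed %.4f, p %s", object$observed,
                                     object$p_label)) +
    ggplot2::theme_minimal()
}

#' Genotype-cell risk map
#'
#' Tile plot of a 1- or 2-way risk model's cells: score sum, subject count
#' and high/low label per joint genotype.
#'
#' @param object an `mdr_risk_model` with k of 1 or 2.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_risk_model <- function(object, ...) {
  if (!object$k %in% 1:2) abort("cell map plot supports k = 1 or 2 only")
  cs <- object$cell_stats
  x <- object$snp_ids[1]
  y <- if (object$k == 2) object$snp_ids[2] else NULL
  cs$.x <- factor(cs[[x]])
  cs$.y <- if (is.null(y)) factor(0) else factor(cs[[y]])
  ggplot2::ggplot(cs, ggplot2::aes(.data$.x, .data$.y, fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(n=%d)", .data$score_sum, .data$n)), size = 3) +
    ggplot2::scale_fill_manual(values = c(high = "indianred2", low = "skyblue2")) +
    ggplot2::labs(x = paste(x, "dosage"),
                  y = if (is.null(y)) NULL else paste(y, "dosage"),
                  fill = "risk") +
    ggplot2::theme_minimal()
}
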