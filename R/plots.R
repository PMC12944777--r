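#' Plot false-omission curves against caseload reduction
#'
#' Renders the FOR family (gross, net, and each adjusted-net scenario) as
#' a function of the caseload reduction rate, the standard way to read a
#' rule-out trade-off: the x-axis is the workload benefit, the y-axis the
#' omission risk. An optional bootstrap band (for one metric, typically
#' the gross rate) is drawn as a shaded ribbon, and an optional vertical
#' marker highlights a selected operating point's caseload reduction.
#'
#' @param sweep A `ruleout_sweep` from [run_sweep()].
#' @param bands Optional `ruleout_bands`; rows whose `metric` matches a
#'   plotted curve are drawn as ribbons.
#' @param mark_crr Optional caseload reduction rate (proportion) to mark
#'   with a vertical line.
#' @return A ggplot object.
#' @export
plot_for_curves <- function(sweep, bands = NULL, mark_crr = NULL) {
  if (!inherits(sweep, "ruleout_sweep")) {
    stop_config("`sweep` must be a `ruleout_sweep`.")
  }
  fractions <- attr(sweep, "fractions")
  metric_cols <- c("g_for", "n_for", vapply(fractions, anfor_name, character(1)))
  long <- tidyr_longer(sweep, metric_cols)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = 100 * .data$crr, y = 100 * .data$value,
    colour = .data$metric, linetype = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Caseload reduction rate (%)",
                  y = "False omission rate (%)",
                  colour = "Metric", linetype = "Metric") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    bl <- merge(as_tibble(bands)[c("threshold", "metric", "lower", "upper")],
                sweep[c("threshold", "crr")], by = "threshold")
    bl <- bl[bl$metric %in% metric_cols, , drop = FALSE]
    if (nrow(bl) > 0) {
      p <- p + ggplot2::geom_ribbon(
        data = bl,
        ggplot2::aes(x = 100 * .data$crr, ymin = 100 * .data$lower,
                     ymax = 100 * .data$upper, group = .data$metric),
        inherit.aes = FALSE, alpha = 0.2, fill = "red", na.rm = TRUE)
    }
  }
  if (!is.null(mark_crr)) {
    p <- p + ggplot2::geom_vline(xintercept = 100 * mark_crr,
                                 linewidth = 0.3, colour = "black")
  }
  p
}

#' Plot the false-discovery curve against caseload reduction
#'
#' @inheritParams plot_for_curves
#' @return A ggplot object.
#' @export
plot_fdr_curve <- function(sweep, bands = NULL, mark_crr = NULL) {
  if (!inherits(sweep, "ruleout_sweep")) {
    stop_config("`sweep` must be a `ruleout_sweep`.")
  }
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = 100 * .data$crr,
                                           y = 100 * .data$fdr)) +
    ggplot2::geom_line(linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "Caseload reduction rate (%)",
                  y = "False discovery rate (%)") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    bl <- merge(as_tibble(bands)[c("threshold", "metric", "lower", "upper")],
                sweep[c("threshold", "crr")], by = "threshold")
    bl <- bl[bl$metric == "fdr", , drop = FALSE]
    if (nrow(bl) > 0) {
      p <- p + ggplot2::geom_ribbon(
        data = bl,
        ggplot2::aes(x = 100 * .data$crr, ymin = 100 * .data$lower,
                     ymax = 100 * .data$upper),
        inherit.aes = FALSE, alpha = 0.2, fill = "red", na.rm = TRUE)
    }
  }
  if (!is.null(mark_crr)) {
    p <- p + ggplot2::geom_vline(xintercept = 100 * mark_crr,
                                 linewidth = 0.3, colour = "black")
  }
  p
}

# Minimal wide-to-long pivot for plotting (threshold/crr + metric columns).
tidyr_longer <- function(sweep, metric_cols) {
  parts <- lapply(metric_cols, function(m) {
    tibble(threshold = sweep$threshold, crr = sweep$crr,
           metric = m, value = sweep[[m]])
  })
  dplyr::bind_rows(parts)
}
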