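#' Concentration-time plot
#'
#' Spaghetti plot of observed concentrations per subject, faceted by cohort
#' when available; BLQ samples are omitted.
#'
#' @param pk A pk tibble (`id`, `time`, `dv`, `evid`; optional `cohort`).
#' @param log_y Log concentration axis (default TRUE).
#' @return A ggplot.
#' @export
plot_concentration_time <- function(pk, log_y = TRUE) {
  check_columns(pk, c("id", "time", "dv", "evid"), "pk data")
  obs <- dplyr::filter(pk, .data$evid == 0, !is.na(.data$dv))
  p <- ggplot2::ggplot(obs, ggplot2::aes(.data$time / 24, .data$dv,
                                         group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "time (days)", y = "concentration (ug/mL)",
                  title = "Observed concentration-time profiles") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  if ("cohort" %in% names(pk)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cohort), scales = "free")
  }
  p
}
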