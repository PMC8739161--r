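#' Power-model dose-proportionality assessment
#'
#' Ordinary least squares of `ln(value)` on `ln(dose)`; the confidence
#' interval for the slope uses the t distribution with n - 2 degrees of
#' freedom. PK is judged dose proportional when the interval encompasses 1.
#'
#' @param data A data frame with one row per subject.
#' @param dose Column with the dose (mg/kg for weight-based escalation);
#'   tidy-evaluated.
#' @param value Column with the exposure parameter (Cmax, AUC, ...);
#'   tidy-evaluated. Missing values are dropped (so a subject with a
#'   non-estimable parameter simply reduces n).
#' @param conf Confidence level for the slope interval (default 0.90).
#' @param parameter Optional label carried into the result.
#' @return An object of class `dose_prop`; `tidy()` gives the one-row
#'   summary (`n`, `slope`, `se`, `ci_lo`, `ci_hi`, `proportional`).
#' @examples
#' d <- data.frame(dose = rep(c(1, 3, 10), each = 4),
#'                 auc = rep(c(1, 3, 10), each = 4) * exp(rnorm(12, 0, .2)))
#' tidy(power_model_fit(d, dose, auc))
#' @export
power_model_fit <- function(data, dose, value, conf = 0.90, parameter = NULL) {
  dose_v <- rlang::eval_tidy(rlang::enquo(dose), data)
  value_v <- rlang::eval_tidy(rlang::enquo(value), data)
  keep <- !is.na(value_v) & !is.na(dose_v)
  dose_v <- dose_v[keep]; value_v <- value_v[keep]
  n <- length(dose_v)
  if (n < 3) stop_phasepk("at least 3 subjects with non-missing values are required")
  if (any(dose_v <= 0) || any(value_v <= 0)) {
    stop_phasepk("doses and values must be > 0 for the power model")
  }
  if (length(unique(dose_v)) < 2) {
    stop_phasepk("at least 2 distinct dose levels are required (slope unidentifiable)")
  }
  check_number(conf, "conf", positive = TRUE)
  fit <- lm(log(value_v) ~ log(dose_v))
  slope <- unname(coef(fit)[2])
  se <- unname(sqrt(diag(vcov_safe(fit))[2]))
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 2)
  ci <- slope + c(-1, 1) * tcrit * se
  res <- tibble::tibble(
    parameter = parameter %||% rlang::as_label(rlang::enquo(value)),
    n = n, slope = slope, se = se, conf = conf,
    ci_lo = ci[1], ci_hi = ci[2],
    # machine-epsilon guard so an exactly proportional fit (zero-width CI
    # at slope 1) is not rejected on floating-point noise
    proportional = ci[1] <= 1 + 1e-9 && 1 <= ci[2] + 1e-9)
  structure(list(result = res, fit = fit,
                 data = tibble::tibble(dose = dose_v, value = value_v)),
            class = "dose_prop")
}

# vcov that tolerates a perfect fit (zero residual variance -> SE 0,
# without the "essentially perfect fit" warning)
vcov_safe <- function(fit) {
  v <- suppressWarnings(stats::vcov(fit))
  v[!is.finite(v)] <- 0
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dose_prop <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<dose_prop> %s: n=%d slope=%.3f (SE %.3f), %d%% CI (%.2f-%.2f) -> %s\n",
    r$parameter, r$n, r$slope, r$se, round(100 * r$conf), r$ci_lo, r$ci_hi,
    if (r$proportional) "dose proportional" else "not dose proportional"))
  invisible(x)
}

#' @rdname power_model_fit
#' @param x A `dose_prop` object.
#' @param ... Unused.
#' @export
tidy.dose_prop <- function(x, ...) x$result

#' @rdname power_model_fit
#' @export
glance.dose_prop <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$result$n, r.squared = s$r.squared, sigma = s$sigma)
}

#' Dose-proportionality table over several PK parameters
#'
#' Runs [power_model_fit()] for each listed parameter of an [nca()] result
#' and binds the one-row summaries, mirroring the usual slope/SE/CI/verdict
#' presentation.
#'
#' @param nca_tbl An [nca()] result (or any data frame).
#' @param dose Dose column (tidy-evaluated).
#' @param parameters Character vector of value columns to assess.
#' @param conf Confidence level.
#' @return A tibble with one row per parameter.
#' @export
dose_proportionality <- function(nca_tbl, dose,
                                 parameters = c("cmax", "auc_0_tau",
                                                "auc_0_inf"),
                                 conf = 0.90) {
  dose_q <- rlang::enquo(dose)
  purrr::map_dfr(parameters, function(p) {
    tidy(power_model_fit(nca_tbl, !!dose_q, .data[[p]], conf = conf,
                         parameter = p))
  })
}

#' @rdname power_model_fit
#' @param object A `dose_prop` object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dose_prop <- function(object, ...) {
  r <- object$result
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$value)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "dose", y = r$parameter,
      title = sprintf("Power model: slope %.2f (%d%% CI %.2f-%.2f)",
                      r$slope, round(100 * r$conf), r$ci_lo, r$ci_hi)) +
    ggplot2::theme_minimal()
}
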