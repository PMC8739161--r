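#' Sigmoid concentration-occupancy relation
#'
#' `RO(C) = C^h / (EC50^h + C^h)`: the forward model linking serum
#' concentration to the receptor-occupancy assay ratio (1 = saturation /
#' full RO). Monotone non-decreasing in concentration and bounded in
#' `[0, 1)`.
#'
#' @param concentration Serum concentration, ug/mL (vectorised, >= 0).
#' @param ec50 Concentration at half-maximal occupancy, ug/mL.
#' @param hill Hill coefficient (> 0).
#' @return Predicted occupancy ratio.
#' @examples
#' emax_ro(c(0, 0.81, 9 * 0.81), ec50 = 0.81, hill = 2)
#' @export
emax_ro <- function(concentration, ec50, hill = 1) {
  if (any(concentration < 0)) stop_phasepk("`concentration` must be >= 0")
  check_number(ec50, "ec50", positive = TRUE)
  check_number(hill, "hill", positive = TRUE)
  ch <- concentration^hill
  ch / (ec50^hill + ch)
}

#' Full receptor-occupancy criterion
#'
#' An assay ratio of 1 reflects maximal stimulation (full RO); a measurement
#' counts as full RO when the ratio is within `tolerance` of 1, i.e.
#' `value >= 1 - tolerance`.
#'
#' @param value Assay ratio (CD3+ binding or IL-2 stimulation; vectorised).
#' @param tolerance Band below 1 still counted as full RO (default 0.10).
#' @return Logical vector.
#' @export
is_full_ro <- function(value, tolerance = 0.10) {
  check_number(tolerance, "tolerance", non_negative = TRUE)
  value >= 1 - tolerance
}

#' Minimum concentration with full receptor occupancy
#'
#' Per subject (and per assay when an `assay` column is present), the lowest
#' paired serum concentration among full-RO measurements; the cohort
#' threshold estimate is the arithmetic mean of the per-subject minima.
#' Anomalous-flagged measurements and measurements without a paired
#' concentration are excluded; subjects with no full-RO measurement are
#' excluded from the mean and reported separately.
#'
#' @param data A tibble with `id`, `value`, `conc`, optional `assay` and
#'   `anomalous` columns.
#' @param tolerance Full-RO tolerance passed to [is_full_ro()].
#' @return A list of class `ro_summary`: `per_subject` (per-subject minima),
#'   `summary` (per assay: `n_subjects`, `mean_min_conc`), `non_achievers`.
#'   `tidy()` returns `per_subject`.
#' @export
min_full_ro_concentration <- function(data, tolerance = 0.10) {
  check_columns(data, c("id", "value", "conc"), "RO data")
  if (!"assay" %in% names(data)) data$assay <- "ro"
  if (!"anomalous" %in% names(data)) data$anomalous <- FALSE
  valid <- dplyr::filter(data, !.data$anomalous, !is.na(.data$conc))
  if (!nrow(valid)) {
    warn("no valid concentration-paired RO measurements")
    empty <- tibble::tibble(assay = character(), id = character(),
                            min_conc = numeric())
    return(structure(list(per_subject = empty,
                          summary = tibble::tibble(assay = character(),
                                                   n_subjects = integer(),
                                                   mean_min_conc = numeric()),
                          non_achievers = empty[, 1:2]),
                     class = "ro_summary"))
  }
  valid$full <- is_full_ro(valid$value, tolerance)
  per <- dplyr::summarise(
    dplyr::group_by(valid, .data$assay, .data$id),
    any_full = any(.data$full),
    min_conc = if (any(.data$full)) min(.data$conc[.data$full]) else NA_real_,
    .groups = "drop")
  achievers <- dplyr::select(dplyr::filter(per, .data$any_full),
                             "assay", "id", "min_conc")
  non <- dplyr::select(dplyr::filter(per, !.data$any_full), "assay", "id")
  if (!nrow(achievers)) warn("no subject achieved full RO")
  summary <- dplyr::summarise(
    dplyr::group_by(achievers, .data$assay),
    n_subjects = dplyr::n(),
    mean_min_conc = mean(.data$min_conc), .groups = "drop")
  structure(list(per_subject = achievers, summary = summary,
                 non_achievers = non),
            class = "ro_summary")
}

#' @export
print.ro_summary <- function(x, ...) {
  cat("<ro_summary>\n")
  print(x$summary)
  if (nrow(x$non_achievers)) {
    cat(sprintf("subjects without full RO: %s\n",
                paste(unique(x$non_achievers$id), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname min_full_ro_concentration
#' @param x An `ro_summary` object.
#' @param ... Unused.
#' @export
tidy.ro_summary <- function(x, ...) x$per_subject

#' Occupancy-versus-concentration plot
#'
#' @param ro An RO measurement tibble (`value`, `conc`, optional `assay`,
#'   `anomalous`).
#' @param tolerance Full-RO band drawn as a reference.
#' @return A ggplot.
#' @export
plot_ro_occupancy <- function(ro, tolerance = 0.10) {
  if (!"assay" %in% names(ro)) ro$assay <- "ro"
  if (!"anomalous" %in% names(ro)) ro$anomalous <- FALSE
  ggplot2::ggplot(dplyr::filter(ro, !is.na(.data$conc)),
                  ggplot2::aes(.data$conc, .data$value,
                               colour = .data$anomalous)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1 - tolerance, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay)) +
    ggplot2::labs(x = "serum concentration (ug/mL)", y = "assay ratio",
                  title = "Receptor occupancy vs concentration") +
    ggplot2::theme_minimal()
}
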