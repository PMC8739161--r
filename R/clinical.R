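#' Dose-escalation decision rules
#'
#' A dose level is declared safe when fewer than 33% of evaluable patients
#' experience a dose-limiting toxicity. For the 3+3 design: 0/3 safe, 1/3
#' expand to 6, >= 2 DLT among 3-6 exceeded, <= 1/6 safe. For the modified
#' 6+6 design: on 6 evaluable, 0/6 safe, the borderline 1/6 expands to 12,
#' >= 2/6 (33%) exceeded; on 7-12 evaluable the < 33% rule applies directly.
#'
#' @param n_dlt Number of patients with a DLT.
#' @param n_eval Number of DLT-evaluable patients (3 or 6 for `3+3`; 6-12
#'   for `6+6`).
#' @param design `"three_plus_three"` or `"six_plus_six"`.
#' @param dose_level Optional label carried into the result.
#' @return A one-row tibble: `dose_level`, `design`, `n_eval`, `n_dlt`,
#'   `decision` (`"safe"`, `"expand"` or `"exceeded"`).
#' @examples
#' dlt_decision(0, 6, "three_plus_three")  # safe
#' dlt_decision(1, 6, "six_plus_six")      # expand
#' @export
dlt_decision <- function(n_dlt, n_eval,
                         design = c("three_plus_three", "six_plus_six"),
                         dose_level = NA_character_) {
  design <- match.arg(design)
  if (n_eval < 3) stop_phasepk("at least 3 evaluable patients are required")
  if (n_dlt < 0 || n_dlt > n_eval) stop_phasepk("`n_dlt` must be in [0, n_eval]")
  decision <- if (design == "three_plus_three") {
    if (!n_eval %in% c(3L, 6L)) {
      stop_phasepk("3+3 cohorts have 3 or 6 evaluable patients")
    }
    if (n_dlt >= 2) "exceeded"
    else if (n_eval == 3) { if (n_dlt == 0) "safe" else "expand" }
    else "safe"                       # <= 1 of 6
  } else {
    if (n_eval < 6) stop_phasepk("the 6+6 design needs at least 6 evaluable patients")
    if (n_eval > 12) stop_phasepk("the 6+6 design stops at 12 evaluable patients")
    if (n_eval == 6) {
      if (n_dlt == 0) "safe" else if (n_dlt == 1) "expand" else "exceeded"
    } else {
      if (n_dlt / n_eval < 1 / 3) "safe" else "exceeded"
    }
  }
  tibble::tibble(dose_level = dose_level, design = design,
                 n_eval = as.integer(n_eval), n_dlt = as.integer(n_dlt),
                 decision = decision)
}

ae_categories <- function(records) {
  g3 <- records$grade >= 3
  list(
    "Any AE" = rep(TRUE, nrow(records)),
    "Related AE" = records$related,
    "Any grade >=3 AE" = g3,
    "Related grade >=3 AE" = g3 & records$related,
    "Any serious AE" = records$serious,
    "Related serious AE" = records$serious & records$related,
    "AE leading to withdrawal" = records$withdrawal,
    "Related AE leading to withdrawal" = records$withdrawal & records$related,
    "AE leading to interruption" = records$interruption,
    "Immune-related AE" = records$immune_related)
}

#' Treatment-emergent adverse-event summary
#'
#' Subject-level incidence (count and percent, one decimal, half-up) of the
#' standard AE category rows — any AE; related; grade >= 3; related grade
#' >= 3; serious; related serious; leading to withdrawal; related leading to
#' withdrawal; leading to interruption; immune-related — per dose group, per
#' study part and pooled. A subject counts once per category regardless of
#' how many qualifying events they had. Related AEs are also tabulated by
#' preferred term, keeping terms whose incidence reaches the cutoff in at
#' least one dose group of a study part.
#'
#' @param records AE records: `id`, `term`, `grade` (1-5), and logical
#'   `related`, `serious`, `withdrawal`, `interruption`, `immune_related`.
#' @param roster Subject roster: `id`, `part`, optional `group` (dose
#'   group / cohort). Every record id must appear in the roster.
#' @param term_incidence_cutoff Fraction (default 0.10).
#' @return A list of class `ae_summary`: `categories` (columns `part`,
#'   `group`, `n_group`, `category`, `n`, `pct`) and `related_terms`
#'   (per-part term incidence). `tidy()` returns `categories`.
#' @export
summarize_aes <- function(records, roster, term_incidence_cutoff = 0.10) {
  check_columns(roster, c("id", "part"), "roster")
  if (!"group" %in% names(roster)) roster$group <- roster$part
  check_columns(records, c("id", "term", "grade", "related", "serious",
                           "withdrawal", "interruption", "immune_related"),
                "AE records")
  if (any(!records$id %in% roster$id)) {
    stop_phasepk(sprintf("AE records for subjects absent from the roster: %s",
                         paste(setdiff(records$id, roster$id), collapse = ", ")))
  }
  if (nrow(records) && (any(is.na(records$grade)) ||
                        any(!records$grade %in% 1:5))) {
    stop_phasepk("`grade` must be in 1..5")
  }
  flags <- ae_categories(records)
  tab_group <- function(ids, part, group) {
    n_group <- length(ids)
    purrr::map_dfr(names(flags), function(cat) {
      n <- length(unique(records$id[flags[[cat]] & records$id %in% ids]))
      tibble::tibble(part = part, group = group, n_group = n_group,
                     category = cat, n = n, pct = pct_1d(n, n_group))
    })
  }
  parts <- unique(roster$part)
  cats <- purrr::map_dfr(parts, function(p) {
    sub <- roster[roster$part == p, ]
    dplyr::bind_rows(
      purrr::map_dfr(unique(sub$group),
                     function(gr) tab_group(sub$id[sub$group == gr], p, gr)),
      tab_group(sub$id, p, "Total"))
  })
  cats <- dplyr::bind_rows(cats, tab_group(roster$id, "All", "Total"))
  # related AEs by preferred term, filtered on incidence within a study part
  rel <- records[records$related, ]
  terms <- purrr::map_dfr(parts, function(p) {
    sub <- roster[roster$part == p, ]
    part_rel <- rel[rel$id %in% sub$id, ]
    if (!nrow(part_rel)) return(NULL)
    per_term <- purrr::map_dfr(unique(part_rel$term), function(tm) {
      ids_tm <- unique(part_rel$id[part_rel$term == tm])
      by_group <- vapply(unique(sub$group), function(gr) {
        gids <- sub$id[sub$group == gr]
        length(intersect(ids_tm, gids)) / length(gids)
      }, numeric(1))
      tibble::tibble(part = p, term = tm, n = length(ids_tm),
                     n_part = nrow(sub), pct = pct_1d(length(ids_tm), nrow(sub)),
                     keep = any(by_group >= term_incidence_cutoff))
    })
    dplyr::select(dplyr::filter(per_term, .data$keep), -"keep")
  })
  structure(list(categories = cats, related_terms = terms),
            class = "ae_summary")
}

#' @export
print.ae_summary <- function(x, ...) {
  cat("<ae_summary>\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$categories, "part", "group", "category", "pct"),
    names_from = c("part", "group"), values_from = "pct"), n = 12)
  invisible(x)
}

#' @rdname summarize_aes
#' @param x An `ae_summary` object.
#' @param ... Unused.
#' @export
tidy.ae_summary <- function(x, ...) x$categories

resp_levels <- c("irCR", "irPR", "irSD", "irPD", "NE")
resp_rank <- c(irCR = 4, irPR = 3, irSD = 2, irPD = 1, NE = 0)

#' Best overall confirmed response (immune-related criteria)
#'
#' A complete or partial response counts only when a second assessment at
#' least `confirmation_window_days` later shows the same or a better
#' category; progression likewise requires confirmation. An unconfirmed
#' response contributes stable disease (no minimum duration is required for
#' stable disease). Time to response is the first assessment showing the
#' subsequently-confirmed response; duration runs until the first
#' progression afterwards, otherwise it is censored at the last assessment.
#'
#' @param data Assessments: `id`, `time` (days from first dose,
#'   non-decreasing per subject) and `category` (one of irCR, irPR, irSD,
#'   irPD, NE).
#' @param confirmation_window_days Minimum spacing of the confirming
#'   assessment (default 28, operationalising "at least 4 weeks").
#' @return A tibble per subject: `best_response`, `response_time_days`,
#'   `duration_days`, `progression_observed`.
#' @export
best_overall_response <- function(data, confirmation_window_days = 28) {
  check_columns(data, c("id", "time", "category"), "response data")
  if (any(!data$category %in% resp_levels)) {
    stop_phasepk(sprintf("unknown response category: %s",
                         paste(setdiff(data$category, resp_levels),
                               collapse = ", ")))
  }
  if (any(data$time < 0)) stop_phasepk("assessment times must be >= 0")
  purrr::map_dfr(split(data, data$id), function(g) {
    g <- dplyr::arrange(g, .data$time)
    bor_one(g$id[1], g$time, g$category, confirmation_window_days)
  })
}

bor_one <- function(id, time, category, window) {
  assessed <- category != "NE"
  out <- function(best, rt = NA_real_, dur = NA_real_, prog = NA) {
    tibble::tibble(id = id, best_response = best, response_time_days = rt,
                   duration_days = dur, progression_observed = prog)
  }
  if (!any(assessed)) return(out("NE"))
  rk <- resp_rank[category]
  confirmed_at <- function(target_rank) {
    # first assessment at/above the target later confirmed at/above it
    idx <- which(rk >= target_rank)
    for (i in idx) {
      if (any(rk[idx] >= target_rank & time[idx] - time[i] >= window)) {
        return(time[i])
      }
    }
    NA_real_
  }
  for (target in c("irCR", "irPR")) {
    t_resp <- confirmed_at(resp_rank[target])
    if (!is.na(t_resp)) {
      after <- which(time > t_resp & category == "irPD")
      prog <- length(after) > 0
      t_end <- if (prog) time[after[1]] else max(time)
      return(out(target, t_resp, t_end - t_resp, prog))
    }
  }
  if (any(category %in% c("irSD", "irPR", "irCR"))) return(out("irSD"))
  if (any(category == "irPD")) return(out("irPD"))
  out("NE")
}

#' Objective-response and disease-control rates
#'
#' `ORR = (irCR + irPR) / n` and `DCR = (irCR + irPR + irSD) / n`, as
#' percentages rounded half-up to one decimal.
#'
#' @param best Best-response categories: a character vector or a
#'   [best_overall_response()] result.
#' @param n_evaluable Denominator (default: the number of responses given).
#' @return A one-row tibble with counts, `orr_pct` and `dcr_pct`.
#' @examples
#' response_rates(c("irPR", "irPR", rep("irSD", 5), rep("irPD", 14)))
#' @export
response_rates <- function(best, n_evaluable = NULL) {
  if (is.data.frame(best)) best <- best$best_response
  if (is.null(n_evaluable)) n_evaluable <- length(best)
  if (n_evaluable <= 0) stop_phasepk("`n_evaluable` must be > 0")
  n_cr <- sum(best == "irCR")
  n_pr <- sum(best == "irPR")
  n_sd <- sum(best == "irSD")
  tibble::tibble(
    n_evaluable = n_evaluable, n_cr = n_cr, n_pr = n_pr, n_sd = n_sd,
    orr_pct = pct_1d(n_cr + n_pr, n_evaluable),
    dcr_pct = pct_1d(n_cr + n_pr + n_sd, n_evaluable))
}
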