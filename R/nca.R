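#' Terminal rate-constant estimation
#'
#' Log-linear least squares on a terminal subset of the profile. All
#' contiguous subsets of at least 3 points ending at the last quantifiable
#' sample and strictly after Tmax (Tmax itself excluded) are evaluated; the
#' subset maximising the adjusted R-squared is selected, preferring more
#' points when adjusted R-squared ties within 1e-4.
#'
#' @param time Sample times, h (strictly increasing).
#' @param conc Concentrations, ug/mL (quantifiable, > 0 after Tmax).
#' @return A tibble with `lambda_z` (1/h), `n_points`, `adj_r2` and
#'   `t_first` (start of the selected window). When fewer than 3 eligible
#'   points exist (or no subset declines), `lambda_z` is `NA` — the
#'   not-estimable case, and parameters depending on it are reported missing.
#' @examples
#' t <- c(24, 48, 96, 168, 336, 504)
#' lambda_z(t, 10 * exp(-0.002 * t))
#' @export
lambda_z <- function(time, conc) {
  if (length(time) != length(conc)) stop_phasepk("time/conc length mismatch")
  if (is.unsorted(time, strictly = TRUE)) {
    stop_phasepk("`time` must be strictly increasing")
  }
  na_result <- tibble::tibble(lambda_z = NA_real_, n_points = NA_integer_,
                              adj_r2 = NA_real_, t_first = NA_real_)
  keep <- is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  n <- length(time)
  if (n < 3) return(na_result)
  imax <- which.max(conc)
  starts <- seq_along(time)
  starts <- starts[starts > imax & starts <= n - 2]
  if (!length(starts)) return(na_result)
  best <- NULL
  for (j in starts) {  # ascending j: larger subsets considered first
    sel <- j:n
    f <- loglin_fit(time[sel], log(conc[sel]))
    if (is.null(f) || f$slope >= 0) next
    m <- length(sel)
    adj <- 1 - (1 - f$r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj > best$adj + 1e-4) {
      best <- list(lz = -f$slope, adj = adj, m = m, t1 = time[j])
    }
  }
  if (is.null(best)) return(na_result)
  tibble::tibble(lambda_z = best$lz, n_points = best$m, adj_r2 = best$adj,
                 t_first = best$t1)
}

# internal: per-interval AUC and AUMC with the linear-up/log-down rule.
# Linear trapezoid when rising (C2 >= C1) or either endpoint is zero;
# logarithmic trapezoid when strictly declining and positive.
auc_segments <- function(time, conc) {
  n <- length(time)
  auc <- aumc <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    t1 <- time[i]; t2 <- time[i + 1]
    c1 <- conc[i]; c2 <- conc[i + 1]
    dt <- t2 - t1
    if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
      auc[i] <- dt * (c1 + c2) / 2
      aumc[i] <- dt * (t1 * c1 + t2 * c2) / 2
    } else {
      k <- log(c1 / c2) / dt
      auc[i] <- (c1 - c2) / k
      aumc[i] <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Linear-up/log-down trapezoidal AUC
#'
#' Per-interval rule: linear trapezoid when the concentration is rising or
#' either endpoint is zero; logarithmic trapezoid when strictly declining and
#' positive. A `t_end` falling inside the last interval is handled by
#' interpolating consistently with that interval's rule (linear or
#' mono-exponential).
#'
#' @param time Sample times, h (strictly increasing).
#' @param conc Concentrations, ug/mL.
#' @param t_end Upper limit of integration (default the last sample; must
#'   not exceed it — extension beyond the data is the job of the
#'   extrapolated AUC).
#' @return AUC in ug.h/mL.
#' @examples
#' auc_lin_up_log_down(c(0, 24), c(10, 10))            # 240
#' auc_lin_up_log_down(c(0, 1), c(10, 5))              # 5 / log(2)
#' @export
auc_lin_up_log_down <- function(time, conc, t_end = NULL) {
  if (length(time) < 2) stop_phasepk("at least 2 points are required")
  if (length(time) != length(conc)) stop_phasepk("time/conc length mismatch")
  if (is.unsorted(time, strictly = TRUE)) {
    stop_phasepk("`time` must be strictly increasing")
  }
  if (is.null(t_end)) t_end <- time[length(time)]
  if (t_end > time[length(time)] + 1e-9) {
    stop_phasepk("`t_end` must not exceed the last sample time")
  }
  if (t_end <= time[1]) stop_phasepk("`t_end` must exceed the first sample time")
  # truncate to t_end, interpolating the partial interval per its rule
  last_full <- max(which(time <= t_end))
  tt <- time[1:last_full]; cc <- conc[1:last_full]
  if (t_end > tt[last_full] + 1e-12) {
    c1 <- conc[last_full]; c2 <- conc[last_full + 1]
    t1 <- time[last_full]; t2 <- time[last_full + 1]
    ci <- if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
      c1 + (c2 - c1) * (t_end - t1) / (t2 - t1)
    } else {
      c1 * exp(-log(c1 / c2) * (t_end - t1) / (t2 - t1))
    }
    tt <- c(tt, t_end); cc <- c(cc, ci)
  }
  sum(auc_segments(tt, cc)$auc)
}

#' Geometric summary statistics
#'
#' Geometric mean `exp(mean(log x))` and geometric CV
#' `100 * sqrt(exp(s^2) - 1)` with `s^2` the (n-1)-denominator variance of
#' `log x`. For `n <= 2` only the minimum and maximum are presented
#' (`geo_mean` and `gcv_pct` are `NA`), following the usual reporting
#' convention for tiny cohorts.
#'
#' @param values Positive values.
#' @return A one-row tibble: `n`, `geo_mean`, `gcv_pct`, `min`, `max`.
#' @examples
#' geo_stats(c(1, 10, 100))
#' @export
geo_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    return(tibble::tibble(n = 0L, geo_mean = NA_real_, gcv_pct = NA_real_,
                          min = NA_real_, max = NA_real_))
  }
  if (any(values <= 0)) stop_phasepk("geometric statistics need values > 0")
  n <- length(values)
  if (n <= 2) {
    return(tibble::tibble(n = n, geo_mean = NA_real_, gcv_pct = NA_real_,
                          min = min(values), max = max(values)))
  }
  lx <- log(values)
  tibble::tibble(n = n, geo_mean = exp(mean(lx)),
                 gcv_pct = 100 * sqrt(exp(var(lx)) - 1),
                 min = min(values), max = max(values))
}

# cohort metadata for the default trial design: dosing interval for AUC(0-tau)
# (a full 28-day window for the PK/PDy cohorts, 14 days otherwise) and the
# nominal trough sampling time
#' Cohort dosing-interval metadata
#'
#' @return A tibble with `cohort`, `tau` (h) and `trough_time` (h) for the
#'   default trial design; pass a modified copy to [nca()] for other designs.
#' @export
cohort_meta <- function() {
  ch <- default_cohorts()
  tibble::tibble(cohort = ch$cohort, tau = ch$tau, trough_time = ch$trough_time)
}

#' Noncompartmental analysis of single-dose profiles
#'
#' Computes the full single-dose parameter set per subject: observed
#' `cmax`/`tmax`, trough at the nominal time, AUC(0-tau), AUC(0-last),
#' extrapolated AUC(0-inf), terminal slope and its diagnostics, terminal
#' half-life (days), clearance (L/day), `Vz` and `Vss` (infusion-corrected
#' mean residence time). BLQ policy: pre-dose BLQ samples are set to zero,
#' embedded BLQ samples are excluded, and the profile is truncated at the
#' last quantifiable point.
#'
#' @param data A concentration dataset: columns `id`, `time` (h), `amt`
#'   (mg; dose rows), `dv` (ug/mL; observation rows), `evid` (1 dose /
#'   0 observation), `blq` (logical), and optionally `wt`, `cohort`, `part`.
#' @param meta Per-cohort tibble with `cohort`, `tau`, `trough_time`
#'   (defaults to [cohort_meta()] when `data` has a `cohort` column).
#' @param tau Dosing interval, h, applied to all subjects when no `meta`
#'   applies.
#' @param trough_time Nominal trough time, h (defaults to `tau`).
#' @return A tibble with one row per subject. When the terminal slope is not
#'   estimable, the parameters depending on it are `NA`. Profiles whose
#'   extrapolated-AUC fraction exceeds 20% are flagged in `extrap_flag` (the
#'   values are still reported).
#' @export
nca <- function(data, meta = NULL, tau = NULL, trough_time = NULL) {
  check_columns(data, c("id", "time", "dv", "evid"), "pk data")
  if (!"blq" %in% names(data)) data$blq <- FALSE
  if (!"amt" %in% names(data)) {
    stop_phasepk("pk data needs an `amt` column with the dose rows (evid == 1)")
  }
  if (is.null(meta) && is.null(tau)) {
    if (!"cohort" %in% names(data)) {
      stop_phasepk("supply `tau` (or `meta` with a cohort column in the data)")
    }
    meta <- cohort_meta()
  }
  groups <- split(data, data$id)
  rows <- purrr::map(groups, function(g) {
    g <- g[order(g$time, -g$evid), ]
    this_tau <- tau
    this_trough <- trough_time
    if (!is.null(meta) && "cohort" %in% names(g)) {
      m <- meta[match(g$cohort[1], meta$cohort), ]
      if (nrow(m) == 1 && !is.na(m$tau[1])) {
        this_tau <- m$tau[1]
        this_trough <- m$trough_time[1]
      }
    }
    if (is.null(this_tau)) {
      stop_phasepk(sprintf("no dosing interval known for subject %s", g$id[1]))
    }
    if (is.null(this_trough)) this_trough <- this_tau
    nca_one(g, this_tau, this_trough)
  })
  dplyr::bind_rows(rows)
}

# single-subject NCA on the single-dose segment (before the second dose)
nca_one <- function(g, tau, trough_time) {
  doses <- g[g$evid == 1, ]
  if (!nrow(doses)) stop_phasepk(sprintf("subject %s has no dose row", g$id[1]))
  dose1 <- doses$time[1]
  dose_amt <- doses$amt[1]
  ti <- if ("rate" %in% names(g) && !is.na(doses$rate[1]) && doses$rate[1] > 0) {
    doses$amt[1] / doses$rate[1]
  } else 0.5
  t_next <- if (nrow(doses) > 1) doses$time[2] else Inf
  obs <- g[g$evid == 0 & g$time <= t_next, ]
  if (!nrow(obs)) {
    stop_phasepk(sprintf("subject %s has no observation rows", g$id[1]),
                 class = "phasepk_degenerate_profile")
  }
  t_rel <- obs$time - dose1
  conc <- obs$dv
  blq <- if (is.logical(obs$blq)) obs$blq else obs$blq == 1
  blq[is.na(blq)] <- FALSE
  # pre-dose BLQ (or pre-dose sample) counts as zero
  pre <- t_rel <= 0
  conc[pre & (blq | is.na(conc))] <- 0
  blq[pre] <- FALSE
  post <- !pre
  if (!any(post & !blq & !is.na(conc) & conc > 0)) {
    stop_phasepk(sprintf("subject %s: no quantifiable post-dose sample", g$id[1]),
                 class = "phasepk_degenerate_profile")
  }
  # truncate at last quantifiable point; drop embedded BLQ
  quant <- !blq & !is.na(conc)
  last_q <- max(which(quant))
  keep <- seq_len(last_q)
  keep <- keep[quant[keep]]
  tt <- t_rel[keep]; cc <- conc[keep]
  if (is.unsorted(tt, strictly = TRUE)) {
    ord <- order(tt); tt <- tt[ord]; cc <- cc[ord]
  }
  # zero anchor at dose start for the infusion rise
  if (tt[1] > 0) { tt <- c(0, tt); cc <- c(0, cc) }
  post_idx <- which(tt > 0)
  cmax <- max(cc[post_idx])
  tmax <- tt[post_idx[which.max(cc[post_idx])]]
  # trough: sample closest to the nominal time within +/- 10% of tau
  cand <- which(abs(t_rel - trough_time) <= 0.1 * tau)
  ctrough <- if (length(cand)) {
    i <- cand[which.min(abs(t_rel[cand] - trough_time))]
    if (blq[i] || is.na(conc[i])) NA_real_ else conc[i]
  } else NA_real_
  seg <- auc_segments(tt, cc)
  auc_last <- sum(seg$auc)
  aumc_last <- sum(seg$aumc)
  auc_tau <- if (tau >= tt[length(tt)]) auc_last else {
    auc_lin_up_log_down(tt, cc, t_end = tau)
  }
  lz <- lambda_z(tt, cc)
  c_last <- cc[length(cc)]
  t_last <- tt[length(tt)]
  if (!is.na(lz$lambda_z)) {
    auc_inf <- auc_last + c_last / lz$lambda_z
    aumc_inf <- aumc_last + c_last * t_last / lz$lambda_z +
      c_last / lz$lambda_z^2
    extrap <- 1 - auc_last / auc_inf
    cl_h <- dose_amt / auc_inf                # L/h
    vz <- cl_h / lz$lambda_z
    mrt <- aumc_inf / auc_inf - ti / 2        # infusion-corrected MRT
    vss <- cl_h * mrt
    t_half_d <- log(2) / lz$lambda_z / 24
    cl_d <- cl_h * 24
  } else {
    auc_inf <- extrap <- vz <- vss <- t_half_d <- cl_d <- NA_real_
  }
  tibble::tibble(
    id = g$id[1],
    cohort = if ("cohort" %in% names(g)) g$cohort[1] else NA_character_,
    part = if ("part" %in% names(g)) g$part[1] else NA_character_,
    wt = if ("wt" %in% names(g)) g$wt[1] else NA_real_,
    dose_mg = dose_amt, tau = tau,
    cmax = cmax, tmax = tmax, ctrough = ctrough,
    auc_0_tau = auc_tau, auc_0_last = auc_last, auc_0_inf = auc_inf,
    extrap_frac = extrap, extrap_flag = !is.na(extrap) && extrap > 0.2,
    lambda_z = lz$lambda_z, lambda_z_n = lz$n_points,
    lambda_z_adj_r2 = lz$adj_r2,
    t_half_d = t_half_d, cl_l_d = cl_d, vz_l = vz, vss_l = vss)
}

#' Multiple-dose accumulation ratios
#'
#' Ratio (in percent) of a later-cycle exposure to the cycle-1 exposure at
#' a matched dosing interval, for AUC(0-tau) and Cmax.
#'
#' @param result_cycle_n,result_cycle_1 [nca()] result tibbles for the same
#'   subjects (matched by `id`; the dosing interval must agree).
#' @return A tibble with `id`, `r_auc_pct`, `r_cmax_pct`.
#' @export
accumulation_ratio <- function(result_cycle_n, result_cycle_1) {
  joined <- dplyr::inner_join(
    dplyr::select(result_cycle_n, "id", "tau", auc_n = "auc_0_tau",
                  cmax_n = "cmax"),
    dplyr::select(result_cycle_1, "id", tau1 = "tau", auc_1 = "auc_0_tau",
                  cmax_1 = "cmax"),
    by = "id")
  if (!nrow(joined)) stop_phasepk("no matching subjects between cycles")
  if (any(abs(joined$tau - joined$tau1) > 1e-9)) {
    stop_phasepk("dosing intervals differ between the two cycles")
  }
  tibble::tibble(id = joined$id,
                 r_auc_pct = 100 * joined$auc_n / joined$auc_1,
                 r_cmax_pct = 100 * joined$cmax_n / joined$cmax_1)
}

#' Cohort-level geometric summary of NCA parameters
#'
#' @param nca_tbl An [nca()] result.
#' @param parameters Columns to summarise.
#' @return A long tibble: `cohort`, `parameter`, plus the [geo_stats()]
#'   columns.
#' @export
nca_summary <- function(nca_tbl,
                        parameters = c("auc_0_inf", "auc_0_tau", "cmax",
                                       "ctrough", "t_half_d", "cl_l_d",
                                       "vz_l", "vss_l")) {
  check_columns(nca_tbl, c("cohort", parameters), "nca result")
  long <- tidyr::pivot_longer(
    dplyr::select(nca_tbl, "cohort", dplyr::all_of(parameters)),
    -"cohort", names_to = "parameter", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  out <- dplyr::group_by(long, .data$cohort, .data$parameter)
  out <- dplyr::reframe(out, geo_stats(.data$value))
  dplyr::ungroup(out)
}
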