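#' Two-compartment disposition parameters
#'
#' Micro-constant parameterisation of the linear two-compartment model:
#' clearance `CL` (L/h), central volume `V1` (L), inter-compartmental
#' clearance `Q` (L/h) and peripheral volume `V2` (L). Derived quantities:
#' steady-state volume `Vss = V1 + V2`, terminal volume `Vz = CL / beta` and
#' terminal half-life `ln(2) / beta`.
#'
#' @param CL Clearance, L/h.
#' @param V1 Central volume of distribution, L.
#' @param Q Inter-compartmental clearance, L/h.
#' @param V2 Peripheral volume of distribution, L.
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(CL = 0.0083, V1 = 3.5, Q = 0.03, V2 = 1.5)
#' macro_constants(p)
#' @export
pk_params <- function(CL, V1, Q, V2) {
  vals <- c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop_phasepk("all of CL, V1, Q, V2 must be single finite positive numbers",
                 class = "phasepk_invalid_parameters")
  }
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> CL=%.4g L/h, V1=%.4g L, Q=%.4g L/h, V2=%.4g L\n",
              x$CL, x$V1, x$Q, x$V2))
  mc <- macro_constants(x)
  cat(sprintf("  alpha=%.4g /h, beta=%.4g /h, terminal t1/2=%.3g d\n",
              mc$alpha, mc$beta, log(2) / mc$beta / 24))
  invisible(x)
}

as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("CL", "V1", "Q", "V2") %in% names(x))) {
    return(pk_params(x[["CL"]], x[["V1"]], x[["Q"]], x[["V2"]]))
  }
  if (is.list(x) && all(c("CL", "V1", "Q", "V2") %in% names(x))) {
    return(pk_params(x$CL, x$V1, x$Q, x$V2))
  }
  stop_phasepk("cannot interpret `params` as pk_params",
               class = "phasepk_invalid_parameters")
}

#' Macro (hybrid) rate constants of the two-compartment model
#'
#' Converts micro constants to the hybrid exponents `alpha > beta > 0` and
#' the unit-bolus coefficients `A`, `B` such that a bolus of `D` mg gives
#' `C(t) = D * (A * exp(-alpha t) + B * exp(-beta t))`. The identities
#' `alpha * beta = (CL/V1) * (Q/V2)` and
#' `alpha + beta = CL/V1 + Q/V1 + Q/V2` hold.
#'
#' @param params A [pk_params()] object.
#' @return A list with `alpha`, `beta` (1/h) and `A`, `B` (ug/mL per mg).
#'   When the two roots coincide to within relative 1e-8, `A` and `B` are
#'   `NA` and concentration evaluation uses the repeated-root limit.
#' @export
macro_constants <- function(params) {
  params <- as_pk_params(params)
  d <- disposition(params)
  if (d$repeated) {
    list(alpha = d$lambda, beta = d$lambda, A = NA_real_, B = NA_real_)
  } else {
    list(alpha = d$lambda[1], beta = d$lambda[2],
         A = d$coef[1], B = d$coef[2])
  }
}

# internal: eigen-structure of the disposition system
disposition <- function(params) {
  k10 <- params$CL / params$V1
  k12 <- params$Q / params$V1
  k21 <- params$Q / params$V2
  s <- k10 + k12 + k21
  p <- k10 * k21
  root <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  if ((alpha - beta) / alpha < 1e-8) {
    # repeated-root analytic limit: C_bolus(t) = e^{-lt}(1 + (k21 - l) t)/V1
    list(repeated = TRUE, lambda = s / 2, k21 = k21, V1 = params$V1)
  } else {
    list(repeated = FALSE, lambda = c(alpha, beta),
         coef = c(alpha - k21, k21 - beta) / (params$V1 * (alpha - beta)))
  }
}

# internal: cumulative unit-rate infusion response
# G(t) = integral_0^t C_bolus(u) du for a 1 mg bolus; concentration of an
# infusion at rate R starting at 0 with duration TI is R*(G(t) - G(t - TI)).
infusion_G <- function(d, t) {
  if (!d$repeated) {
    d$coef[1] * (1 - exp(-d$lambda[1] * t)) / d$lambda[1] +
      d$coef[2] * (1 - exp(-d$lambda[2] * t)) / d$lambda[2]
  } else {
    l <- d$lambda
    ((1 - exp(-l * t)) / l +
       (d$k21 - l) * (1 - exp(-l * t) * (1 + l * t)) / l^2) / d$V1
  }
}

#' Dosing events
#'
#' @param time Infusion start times, h.
#' @param amount Dose amounts, mg.
#' @param duration Infusion durations, h (default 0.5, a 30-minute infusion).
#' @return A tibble with columns `time`, `amount`, `duration`, sorted by
#'   `time`.
#' @export
dose_events <- function(time = 0, amount, duration = 0.5) {
  n <- max(length(time), length(amount), length(duration))
  time <- rep_len(time, n)
  amount <- rep_len(amount, n)
  duration <- rep_len(duration, n)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_phasepk("dose times must be finite and >= 0")
  }
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop_phasepk("dose amounts must be finite and > 0")
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop_phasepk("infusion durations must be finite and > 0")
  }
  ord <- order(time)
  tibble::tibble(time = time[ord], amount = amount[ord],
                 duration = duration[ord])
}

as_dose_events <- function(doses) {
  if (is.data.frame(doses)) {
    check_columns(doses, c("time", "amount"), "doses")
    if (!"duration" %in% names(doses)) doses$duration <- 0.5
    return(dose_events(doses$time, doses$amount, doses$duration))
  }
  stop_phasepk("`doses` must be a data frame with time, amount, duration")
}

# validation-free evaluation core shared by conc_2cmt() and the tight
# optimisation loops (doses as plain vectors, params as a CL/V1/Q/V2 list)
conc_eval <- function(params, dtime, damt, ddur, t) {
  d <- disposition(params)
  out <- numeric(length(t))
  for (i in seq_along(dtime)) {
    rel <- t - dtime[i]
    on <- rel > 0
    if (!any(on)) next
    rate <- damt[i] / ddur[i]
    out[on] <- out[on] +
      rate * (infusion_G(d, rel[on]) - infusion_G(d, pmax(rel[on] - ddur[i], 0)))
  }
  out
}

#' Concentration of the two-compartment model under IV infusion(s)
#'
#' Analytic central-compartment concentration for any schedule of
#' constant-rate infusions, by superposition of the standard two-compartment
#' infusion solution (during- and post-infusion branches are continuous at
#' each infusion end). The model is linear: doubling every dose amount
#' doubles the concentration at every time.
#'
#' @param params A [pk_params()] object.
#' @param doses A [dose_events()] tibble.
#' @param t Times at which to evaluate, h (vectorised, all >= 0).
#' @return Concentrations in ug/mL (amounts in mg, volumes in L).
#' @examples
#' p <- pk_params(0.009, 3.5, 0.03, 1.5)
#' conc_2cmt(p, dose_events(0, 500), t = c(0, 0.5, 24, 336))
#' @export
conc_2cmt <- function(params, doses, t) {
  params <- as_pk_params(params)
  doses <- as_dose_events(doses)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_phasepk("`t` must be finite and >= 0", class = "phasepk_domain_error")
  }
  conc_eval(params, doses$time, doses$amount, doses$duration, t)
}

#' Dosing regimens
#'
#' A regimen is a repeating cycle with one or more dosing days; amounts are
#' either fixed (mg) or weight-based (mg/kg, rounded to 0.1 mg).
#' Constructors for the usual antibody schedules are provided:
#' `regimen_q2w()` doses on days 1 and 15 of a 28-day cycle (the `pk_pdy`
#' variant omits the cycle-1 day-15 dose to open a full-cycle sampling
#' window), `regimen_q3w()` doses on day 1 of a 21-day cycle, and
#' `regimen_q6w()` on day 1 of a 42-day cycle.
#'
#' @param label Regimen label.
#' @param cycle_h Cycle length, h.
#' @param dose_times_h Dosing times within the cycle, h (in `[0, cycle_h)`).
#' @param amount_mg Fixed dose, mg (exactly one of `amount_mg`/`mg_per_kg`).
#' @param mg_per_kg Weight-based dose, mg/kg.
#' @param skip_doses Integer indices (in the flattened, cycle-expanded dose
#'   sequence) of doses that are skipped.
#' @param duration Infusion duration, h.
#' @return An object of class `regimen`.
#' @export
regimen <- function(label, cycle_h, dose_times_h = 0, amount_mg = NULL,
                    mg_per_kg = NULL, skip_doses = integer(), duration = 0.5) {
  check_number(cycle_h, "cycle_h", positive = TRUE)
  if (is.null(amount_mg) == is.null(mg_per_kg)) {
    stop_phasepk("supply exactly one of `amount_mg` or `mg_per_kg`")
  }
  if (!is.null(amount_mg)) check_number(amount_mg, "amount_mg", positive = TRUE)
  if (!is.null(mg_per_kg)) check_number(mg_per_kg, "mg_per_kg", positive = TRUE)
  if (any(dose_times_h < 0) || any(dose_times_h >= cycle_h)) {
    stop_phasepk("`dose_times_h` must lie in [0, cycle_h)")
  }
  structure(list(label = label, cycle_h = cycle_h,
                 dose_times_h = sort(dose_times_h), amount_mg = amount_mg,
                 mg_per_kg = mg_per_kg, skip_doses = as.integer(skip_doses),
                 duration = duration),
            class = "regimen")
}

#' @rdname regimen
#' @param pk_pdy Logical; omit the cycle-1 day-15 dose (Q2W only).
#' @export
regimen_q2w <- function(mg_per_kg, pk_pdy = FALSE) {
  regimen(label = sprintf("%g mg/kg Q2W%s", mg_per_kg,
                          if (pk_pdy) " (PK/PDy)" else ""),
          cycle_h = 672, dose_times_h = c(0, 336), mg_per_kg = mg_per_kg,
          skip_doses = if (pk_pdy) 2L else integer())
}

#' @rdname regimen
#' @export
regimen_q3w <- function(amount_mg = 500) {
  regimen(label = sprintf("%g mg Q3W", amount_mg), cycle_h = 504,
          amount_mg = amount_mg)
}

#' @rdname regimen
#' @export
regimen_q6w <- function(amount_mg = 1000) {
  regimen(label = sprintf("%g mg Q6W", amount_mg), cycle_h = 1008,
          amount_mg = amount_mg)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s: cycle %g h, dose at h %s\n", x$label, x$cycle_h,
              paste(x$dose_times_h, collapse = ", ")))
  invisible(x)
}

#' Expand a regimen into dose events
#'
#' @param reg A [regimen()].
#' @param weight Body weight, kg (required for mg/kg regimens).
#' @param n_cycles Number of cycles to expand.
#' @return A [dose_events()] tibble.
#' @export
regimen_doses <- function(reg, weight = NULL, n_cycles = 1) {
  stopifnot(inherits(reg, "regimen"))
  amount <- regimen_amount(reg, weight)
  starts <- rep((seq_len(n_cycles) - 1) * reg$cycle_h,
                each = length(reg$dose_times_h)) + reg$dose_times_h
  keep <- setdiff(seq_along(starts), reg$skip_doses)
  dose_events(starts[keep], amount, reg$duration)
}

regimen_amount <- function(reg, weight = NULL) {
  if (!is.null(reg$amount_mg)) return(reg$amount_mg)
  if (is.null(weight)) {
    stop_phasepk("`weight` is required for a mg/kg regimen")
  }
  check_number(weight, "weight", positive = TRUE)
  # weight-based amounts rounded to 0.1 mg for reproducibility
  round_half_up(reg$mg_per_kg * weight, 1)
}

#' Inter-dose interval of a regimen
#'
#' @param reg A [regimen()].
#' @return The dosing interval tau, h (the spacing of consecutive doses in
#'   the steady-state schedule).
#' @export
dose_interval <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  times <- rep(c(0, reg$cycle_h), each = length(reg$dose_times_h)) +
    reg$dose_times_h
  min(diff(sort(times)))
}

#' Steady-state trough concentration
#'
#' Simulates successive cycles of the regimen and returns the concentration
#' immediately before the first dose of a cycle once the relative change of
#' successive-cycle troughs falls below `tol` (default 0.1%).
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()].
#' @param weight Body weight, kg (mg/kg regimens).
#' @param tol Relative successive-trough convergence tolerance.
#' @param max_cycles Safety bound on the number of cycles simulated.
#' @return Trough concentration at steady state, ug/mL.
#' @export
steady_state_ctrough <- function(params, reg, weight = NULL, tol = 1e-3,
                                 max_cycles = 1000) {
  params <- as_pk_params(params)
  stopifnot(inherits(reg, "regimen"))
  mc <- macro_constants(params)
  if (!is.finite(mc$beta) || mc$beta <= 0) {
    stop_phasepk("terminal rate constant is non-positive; profile does not converge")
  }
  d <- disposition(params)
  spacing <- regimen_spacing(reg)
  if (!d$repeated && !is.null(spacing)) {
    # evenly spaced equal doses: the trough before dose n+1 is
    # sum_{m=1..n} C(m*tau) with C(s) = sum_i b_i exp(-lambda_i s); the
    # partial geometric sums update in O(1) per dose. Doses skipped early in
    # the schedule do not change the converged trough.
    amt <- regimen_amount(reg, weight)
    ti <- reg$duration
    rate <- amt / ti
    lam <- d$lambda
    b <- rate * d$coef * (exp(lam * ti) - 1) / lam
    decay <- exp(-lam * spacing)
    s_part <- c(0, 0)
    prev <- NA_real_
    n_max <- max_cycles * length(reg$dose_times_h)
    for (n in seq_len(n_max)) {
      s_part <- (s_part + 1) * decay
      trough <- sum(b * s_part)
      if (!is.na(prev) && abs(trough - prev) / trough < tol) return(trough)
      prev <- trough
    }
    stop_phasepk("steady state not reached within `max_cycles` cycles")
  }
  prev <- NA_real_
  for (k in 2:max_cycles) {
    doses <- regimen_doses(reg, weight, n_cycles = k - 1)
    trough <- conc_2cmt(params, doses, (k - 1) * reg$cycle_h)
    if (!is.na(prev) && abs(trough - prev) / trough < tol) {
      return(trough)
    }
    prev <- trough
  }
  stop_phasepk("steady state not reached within `max_cycles` cycles")
}

# inter-dose spacing when the expanded schedule is evenly spaced (the fast
# steady-state path); NULL otherwise
regimen_spacing <- function(reg) {
  gaps <- diff(c(reg$dose_times_h, reg$cycle_h))
  if (all(abs(gaps - gaps[1]) < 1e-9)) gaps[1] else NULL
}

#' Steady-state AUC over a time window
#'
#' Integrates the concentration profile over `window_h` hours starting at a
#' converged cycle boundary (piecewise adaptive quadrature split at every
#' infusion start and end).
#'
#' @inheritParams steady_state_ctrough
#' @param window_h Window length, h (default one cycle).
#' @return AUC in ug.h/mL.
#' @export
steady_state_auc <- function(params, reg, weight = NULL, window_h = NULL,
                             tol = 1e-6, max_cycles = 1000) {
  params <- as_pk_params(params)
  stopifnot(inherits(reg, "regimen"))
  if (is.null(window_h)) window_h <- reg$cycle_h
  # locate a converged cycle boundary via the successive-trough criterion
  d <- disposition(params)
  spacing <- regimen_spacing(reg)
  k_ss <- NA_integer_
  if (!d$repeated && !is.null(spacing)) {
    amt <- regimen_amount(reg, weight)
    ti <- reg$duration
    lam <- d$lambda
    b <- (amt / ti) * d$coef * (exp(lam * ti) - 1) / lam
    decay <- exp(-lam * spacing)
    s_part <- c(0, 0)
    prev <- NA_real_
    for (n in seq_len(max_cycles * length(reg$dose_times_h))) {
      s_part <- (s_part + 1) * decay
      trough <- sum(b * s_part)
      if (!is.na(prev) && abs(trough - prev) / trough < tol) {
        k_ss <- ceiling(n * spacing / reg$cycle_h) + 1
        break
      }
      prev <- trough
    }
  } else {
    prev <- NA_real_
    for (k in 2:max_cycles) {
      doses <- regimen_doses(reg, weight, n_cycles = k - 1)
      trough <- conc_2cmt(params, doses, (k - 1) * reg$cycle_h)
      if (!is.na(prev) && abs(trough - prev) / trough < tol) {
        k_ss <- k
        break
      }
      prev <- trough
    }
  }
  if (is.na(k_ss)) stop_phasepk("steady state not reached within `max_cycles` cycles")
  t0 <- (k_ss - 1) * reg$cycle_h
  n_need <- ceiling((t0 + window_h) / reg$cycle_h) + 1
  doses <- regimen_doses(reg, weight, n_cycles = n_need)
  cuts <- sort(unique(c(t0, t0 + window_h,
                        doses$time[doses$time > t0 & doses$time < t0 + window_h],
                        (doses$time + doses$duration)[
                          doses$time + doses$duration > t0 &
                            doses$time + doses$duration < t0 + window_h])))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(
      function(tt) conc_2cmt(params, doses, tt),
      cuts[i], cuts[i + 1], rel.tol = 1e-10, subdivisions = 200L)$value
  }
  total
}
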