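# shared fixtures: typical antibody-like parameter sets and profile builders

typical_params <- function() pk_params(CL = 0.0083, V1 = 3.5, Q = 0.03, V2 = 1.5)

# rich washout schedule spanning >= 3 terminal half-lives (t1/2 ~ 425 h for
# the typical parameters); used where clearance must be identifiable
rich_times <- function() {
  c(0.5, 1, 2, 4, 8, 12, 24, 48, 72, 120, 168, 240, 336, 504, 672, 840,
    1008, 1176, 1344)
}

# noise-free single-dose profile as a pk-stream tibble
noise_free_pk <- function(params, dose = 500, times = rich_times(),
                          id = "S1", wt = 70, duration = 0.5) {
  conc <- conc_2cmt(params, dose_events(0, dose, duration), times)
  dplyr::bind_rows(
    tibble::tibble(id = id, time = 0, amt = dose, rate = dose / duration,
                   dv = NA_real_, evid = 1L, blq = FALSE, wt = wt,
                   cohort = NA_character_, part = NA_character_),
    tibble::tibble(id = id, time = times, amt = NA_real_, rate = NA_real_,
                   dv = conc, evid = 0L, blq = FALSE, wt = wt,
                   cohort = NA_character_, part = NA_character_))
}

# population-PK recovery cohort: rich noisy profiles generated from a known
# population model (weights drawn log-normally within the observed span)
recovery_cohort <- function(n, model, dose_mg_kg = 3, times = rich_times(),
                            weight_dist = list(meanlog = log(76),
                                               sdlog = 0.22, min = 45.6,
                                               max = 145.6)) {
  weights <- phasepk:::draw_truncated_lognormal(n, weight_dist)
  pars <- phasepk:::draw_individual_params(model, weights)
  purrr::map_dfr(seq_len(n), function(i) {
    dose <- round(dose_mg_kg * weights[i], 1)
    p <- pk_params(pars$CL[i], pars$V1[i], pars$Q[i], pars$V2[i])
    pred <- conc_2cmt(p, dose_events(0, dose), times)
    obs <- pred * (1 + model$residual$prop * rnorm(length(times))) +
      model$residual$add * rnorm(length(times))
    obs <- pmax(obs, 0.01)
    dplyr::bind_rows(
      tibble::tibble(id = sprintf("R%03d", i), time = 0, amt = dose,
                     rate = dose / 0.5, dv = NA_real_, evid = 1L,
                     blq = FALSE, wt = weights[i]),
      tibble::tibble(id = sprintf("R%03d", i), time = times, amt = NA_real_,
                     rate = NA_real_, dv = obs, evid = 0L, blq = FALSE,
                     wt = weights[i]))
  })
}

# deSolve oracle: numerically integrated two-compartment infusion system
ode_conc <- function(params, dose, duration, times) {
  f <- function(t, y, p) {
    inp <- if (t <= duration) dose / duration else 0
    dA1 <- inp - (p$CL / p$V1) * y[1] - (p$Q / p$V1) * y[1] +
      (p$Q / p$V2) * y[2]
    dA2 <- (p$Q / p$V1) * y[1] - (p$Q / p$V2) * y[2]
    list(c(dA1, dA2))
  }
  out <- deSolve::ode(c(0, 0), sort(unique(c(0, duration, times))), f,
                      params, rtol = 1e-12, atol = 1e-12)
  out[match(times, out[, 1]), 2] / params$V1
}
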