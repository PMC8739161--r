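# Default study layout: weight-based 3+3 escalation (1/3/10 mg/kg Q2W on a
# 28-day cycle, with dedicated PK/PDy cohorts skipping the cycle-1 day-15
# dose) and two fixed-dose cohorts (500 mg Q3W, 1000 mg Q6W) run under a
# modified 6+6 design. tau is the AUC(0-tau) window (a full 28 days for the
# PK/PDy cohorts, 14 days otherwise); trough_time is the nominal trough
# sampling time.
default_cohorts <- function() {
  tibble::tibble(
    cohort = c("1 mg/kg DLT", "1 mg/kg PKPD", "3 mg/kg DLT", "10 mg/kg DLT",
               "10 mg/kg PKPD", "500 mg Q3W", "1000 mg Q6W"),
    part = c("1", "1", "1", "1", "1", "2A", "2A"),
    n = c(3L, 3L, 3L, 6L, 6L, 6L, 7L),
    dose_type = c(rep("mg_kg", 5), "fixed", "fixed"),
    dose = c(1, 1, 3, 10, 10, 500, 1000),
    regimen_id = c("q2w", "q2w_pkpdy", "q2w", "q2w", "q2w_pkpdy", "q3w",
                   "q6w"),
    tau = c(336, 672, 336, 336, 672, 504, 1008),
    trough_time = c(336, 504, 336, 336, 504, 504, 1008))
}

cohort_regimen <- function(row) {
  switch(row$regimen_id,
         q2w = regimen_q2w(row$dose),
         q2w_pkpdy = regimen_q2w(row$dose, pk_pdy = TRUE),
         q3w = regimen_q3w(row$dose),
         q6w = regimen_q6w(row$dose),
         stop_phasepk(sprintf("unknown regimen id '%s'", row$regimen_id)))
}

#' Synthetic-trial generator configuration
#'
#' Defaults emulate the default study layout: 21 part-1 subjects across
#' 1/3/10 mg/kg Q2W (including 3 + 6 PK/PDy subjects) and 13 part-2A
#' subjects on 500 mg Q3W / 1000 mg Q6W; body weights log-normal, truncated
#' to 45.6-145.6 kg; typical two-compartment values giving clearance ~0.2
#' L/day, Vss ~5 L and a terminal half-life of ~2.5 weeks; log-normal
#' between-subject variability; combined residual error; a sigmoid
#' concentration-occupancy relation saturating near 2.44 ug/mL; AE term
#' probabilities approximating the usual anti-PD-1 related-AE frequencies
#' (fatigue ~1/3); and one anti-drug-antibody subject (94 kg, 1 mg/kg
#' PK/PDy) whose clearance is accelerated until the day-22 concentration
#' falls to `ada$target_conc`.
#'
#' @param cohorts Cohort layout tibble (see `phasepk:::default_cohorts`).
#' @param typical Typical [pk_params()] at `ref_weight`.
#' @param theta_wt Weight exponent on clearance.
#' @param ref_weight Reference weight, kg.
#' @param omega2 Named log-scale between-subject variances (CL, V1, Q, V2).
#' @param residual A [residual_error()] model.
#' @param lloq Lower limit of quantification, ug/mL; observations below it
#'   are flagged BLQ with a missing value.
#' @param weight `list(meanlog, sdlog, min, max)` for the body-weight draw.
#' @param schedule Nominal post-dose sampling times, h (the cohort trough
#'   time is appended; times past it are dropped).
#' @param jitter_frac Actual-time jitter as a fraction of the inter-sample
#'   gap (uniform, never crossing a dose time).
#' @param ro Occupancy-assay generation:
#'   `list(ec50, hill, ec50_sdlog, noise_sd, anomalous_prob, times)`.
#' @param ae Related-AE probability table (`term`, `prob`) plus background
#'   unrelated terms; see the returned object for the full structure.
#' @param response Latent best-response probabilities per part and the
#'   visit schedules in days.
#' @param ada `list(enabled, cohort, weight, target_conc, target_time)` for
#'   the anti-drug-antibody subject.
#' @param cycles Cycles whose sampling windows are generated (default 1;
#'   e.g. `c(1, 10)` also samples cycle 10, with dosing continued
#'   throughout).
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(cohorts = default_cohorts(),
                         typical = pk_params(CL = 0.0083, V1 = 3.5, Q = 0.03,
                                             V2 = 1.5),
                         theta_wt = 0.25, ref_weight = 70,
                         omega2 = c(CL = 0.0625, V1 = 0.04, Q = 0.09,
                                    V2 = 0.09),
                         residual = residual_error(0.15, 0.05), lloq = 0.1,
                         weight = list(meanlog = log(76), sdlog = 0.22,
                                       min = 45.6, max = 145.6),
                         schedule = c(0, 0.5, 1, 2, 4, 8, 12, 24, 48, 72,
                                      120, 168, 240, 336),
                         jitter_frac = 0.10,
                         ro = list(ec50 = 0.81, hill = 2, ec50_sdlog = 0.2,
                                   noise_sd = 0.03, anomalous_prob = 0.02,
                                   times = c(24, 168)),
                         ae = default_ae_table(),
                         response = default_response_config(),
                         ada = list(enabled = TRUE, cohort = "1 mg/kg PKPD",
                                    weight = 94, target_conc = 1.51,
                                    target_time = 504),
                         cycles = 1L) {
  typical <- as_pk_params(typical)
  residual <- residual_error(residual$prop, residual$add)
  omega2 <- omega2[c("CL", "V1", "Q", "V2")]
  if (any(is.na(omega2)) || any(omega2 < 0)) {
    stop_phasepk("`omega2` must give non-negative variances for CL, V1, Q, V2")
  }
  check_number(lloq, "lloq", non_negative = TRUE)
  check_number(jitter_frac, "jitter_frac", non_negative = TRUE)
  for (key in c("meanlog", "sdlog", "min", "max")) {
    if (is.null(weight[[key]])) {
      stop_phasepk(sprintf("`weight` is missing key '%s'", key))
    }
  }
  probs <- c(ae$related$prob, ae$background$prob,
             unlist(response$probs), ro$anomalous_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_phasepk("all probabilities must lie in [0, 1]")
  }
  if (any(schedule < 0)) stop_phasepk("sampling times must be >= 0")
  structure(list(cohorts = cohorts, typical = typical, theta_wt = theta_wt,
                 ref_weight = ref_weight, omega2 = omega2,
                 residual = residual, lloq = lloq, weight = weight,
                 schedule = sort(unique(schedule)),
                 jitter_frac = jitter_frac, ro = ro, ae = ae,
                 response = response, ada = ada,
                 cycles = sort(unique(as.integer(cycles)))),
            class = "trial_config")
}

default_ae_table <- function() {
  list(
    related = tibble::tibble(
      term = c("fatigue", "nausea", "pruritus", "arthralgia",
               "decreased appetite", "maculopapular rash", "alopecia",
               "vomiting", "anemia", "amylase increased", "hypokalemia",
               "pneumonitis", "transaminases increased", "lipase increased"),
      prob = c(0.34, 0.18, 0.12, 0.12, 0.11, 0.09, 0.06, 0.06, 0.05, 0.07,
               0.08, 0.03, 0.04, 0.04),
      grade3_prob = c(0.05, 0.02, 0, 0, 0, 0.02, 0, 0, 0.05, 0.10, 0.05,
                      0.4, 0.4, 0.5)),
    background = tibble::tibble(
      term = c("headache", "constipation", "back pain", "cough", "dyspnea",
               "abdominal pain", "disease progression"),
      prob = c(0.30, 0.22, 0.25, 0.18, 0.15, 0.20, 0.15),
      grade3_prob = c(0.02, 0, 0.10, 0, 0.35, 0.25, 0.85)),
    immune_terms = c("maculopapular rash", "pneumonitis", "arthritis",
                     "transaminases increased"),
    serious_given_g3 = 0.6, withdrawal_given_g3rel = 0.25,
    interruption_prob = 0.08, immune_prob = 0.3)
}

default_response_config <- function() {
  list(probs = list(`1` = c(irPR = 2 / 21, irSD = 5 / 21),
                    `2A` = c(irPR = 0, irSD = 2 / 13)),
       visits = list(`1` = c(70, 140, 210, 280),
                     `2A` = c(84, 126, 168, 210)))
}

#' Accelerated-clearance (anti-drug-antibody) subject
#'
#' Returns the subject with clearance scaled by `multiplier`, emulating
#' immunogenicity-driven accelerated elimination. A multiplier of 1 leaves
#' the subject unchanged (and the ADA flag unset).
#'
#' @param subject A one-row subject tibble with columns `CL` and `ada`.
#' @param multiplier Clearance multiplier (>= 1).
#' @return The modified subject row.
#' @export
make_ada_subject <- function(subject, multiplier) {
  check_number(multiplier, "multiplier", positive = TRUE)
  if (multiplier < 1) stop_phasepk("`multiplier` must be >= 1")
  subject$CL <- subject$CL * multiplier
  if (multiplier > 1) subject$ada <- TRUE
  subject
}

# clearance multiplier that brings the noise-free concentration at
# `target_time` (after a single dose) down to `target_conc`
ada_multiplier <- function(subject, reg, target_conc, target_time) {
  doses <- regimen_doses(reg, weight = subject$weight, n_cycles = 1)
  doses <- doses[1, ]  # single-dose window
  f <- function(logm) {
    p <- pk_params(subject$CL * exp(logm), subject$V1, subject$Q, subject$V2)
    conc_2cmt(p, doses, target_time) - target_conc
  }
  if (f(0) <= 0) return(1)  # already below target
  exp(stats::uniroot(f, c(0, log(200)), tol = 1e-10)$root)
}

#' Generate a synthetic trial
#'
#' Draws subjects (weights, individual PK parameters via the weight
#' covariate and log-normal deviations, occupancy EC50s), then emits four
#' linked record streams keyed by subject id: concentration-time rows
#' (doses and observations with nominal/jittered actual times and BLQ
#' flags), receptor-occupancy rows for both assays paired to observed
#' concentrations through the sigmoid relation, adverse-event rows drawn
#' from the per-term probability table, and response-assessment rows with
#' confirmation visits. Identical config and seed give identical output.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (all randomness derives from it; the global RNG
#'   is untouched).
#' @return A list of class `trial_data`: tibbles `subjects`, `pk`, `ro`,
#'   `ae`, `response`, plus the `config` and `seed`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1) {
  stopifnot(inherits(config, "trial_config"))
  withr::with_seed(seed, simulate_trial_impl(config))
}

simulate_trial_impl <- function(config) {
  subjects <- draw_subjects(config)
  pk <- purrr::map_dfr(seq_len(nrow(subjects)),
                       function(i) simulate_pk_stream(subjects[i, ], config))
  ro <- purrr::map_dfr(seq_len(nrow(subjects)),
                       function(i) simulate_ro_stream(subjects[i, ], pk, config))
  ae <- simulate_ae_stream(subjects, config)
  response <- simulate_response_stream(subjects, config)
  structure(list(subjects = subjects, pk = pk, ro = ro, ae = ae,
                 response = response, config = config),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d subjects; %d pk rows, %d ro, %d ae, %d response\n",
              nrow(x$subjects), nrow(x$pk), nrow(x$ro), nrow(x$ae),
              nrow(x$response)))
  invisible(x)
}

draw_subjects <- function(config) {
  ch <- config$cohorts
  rows <- purrr::map_dfr(seq_len(nrow(ch)), function(i) {
    tibble::tibble(cohort = ch$cohort[i], part = ch$part[i],
                   idx = seq_len(ch$n[i]))
  })
  n <- nrow(rows)
  weights <- draw_truncated_lognormal(n, config$weight)
  om <- sqrt(config$omega2)
  eta <- matrix(rnorm(4 * n), ncol = 4) %*% diag(om)
  subjects <- tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    cohort = rows$cohort, part = rows$part, weight = weights,
    CL = config$typical$CL * (weights / config$ref_weight)^config$theta_wt *
      exp(eta[, 1]),
    V1 = config$typical$V1 * exp(eta[, 2]),
    Q = config$typical$Q * exp(eta[, 3]),
    V2 = config$typical$V2 * exp(eta[, 4]),
    ec50 = config$ro$ec50 * exp(rnorm(n, 0, config$ro$ec50_sdlog)),
    ada = FALSE)
  if (isTRUE(config$ada$enabled) &&
      config$ada$cohort %in% subjects$cohort) {
    i <- which(subjects$cohort == config$ada$cohort)[1]
    subjects$weight[i] <- config$ada$weight
    # weight change propagates into the covariate part of CL
    subjects$CL[i] <- config$typical$CL *
      (subjects$weight[i] / config$ref_weight)^config$theta_wt * exp(eta[i, 1])
    reg <- cohort_regimen(config$cohorts[
      match(subjects$cohort[i], config$cohorts$cohort), ])
    m <- ada_multiplier(subjects[i, ], reg, config$ada$target_conc,
                        config$ada$target_time)
    subjects[i, ] <- make_ada_subject(subjects[i, ], max(m, 1 + 1e-9))
  }
  subjects
}

subject_schedule <- function(subject, config) {
  row <- config$cohorts[match(subject$cohort, config$cohorts$cohort), ]
  reg <- cohort_regimen(row)
  n_cycles <- max(config$cycles)
  doses <- regimen_doses(reg, weight = subject$weight, n_cycles = n_cycles)
  sched <- config$schedule[config$schedule <= row$trough_time]
  sched <- sort(unique(c(sched, row$trough_time)))
  nominal <- sort(unique(unlist(lapply(config$cycles, function(cy) {
    (cy - 1) * reg$cycle_h + sched
  }))))
  list(reg = reg, doses = doses, nominal = nominal, row = row)
}

simulate_pk_stream <- function(subject, config) {
  sc <- subject_schedule(subject, config)
  doses <- sc$doses
  nominal <- sc$nominal
  params <- pk_params(subject$CL, subject$V1, subject$Q, subject$V2)
  # actual times: uniform jitter of +/- jitter_frac of the preceding gap,
  # clamped so a sample never crosses a dose time; dose-time samples
  # (pre-dose, trough) only jitter earlier
  actual <- nominal
  gaps <- diff(c(0, nominal))
  for (k in seq_along(nominal)) {
    if (any(abs(doses$time - nominal[k]) < 1e-9) && nominal[k] == 0) next
    j <- runif(1, -1, 1) * config$jitter_frac * gaps[k]
    t_new <- nominal[k] + j
    later_doses <- doses$time[doses$time >= nominal[k] - 1e-9]
    if (length(later_doses)) t_new <- min(t_new, min(later_doses) - 1e-6)
    prev_events <- c(0, doses$time[doses$time < nominal[k] - 1e-9],
                     if (k > 1) actual[k - 1])
    t_new <- max(t_new, max(prev_events) + 1e-6)
    actual[k] <- t_new
  }
  pred <- conc_2cmt(params, doses, actual)
  obs <- pred * (1 + config$residual$prop * rnorm(length(pred))) +
    config$residual$add * rnorm(length(pred))
  obs <- pmax(obs, 0)
  blq <- obs < config$lloq
  dose_rows <- tibble::tibble(
    id = subject$id, time = doses$time, amt = doses$amount,
    rate = doses$amount / doses$duration, dv = NA_real_, evid = 1L,
    blq = FALSE, wt = subject$weight, cohort = subject$cohort,
    part = subject$part)
  obs_rows <- tibble::tibble(
    id = subject$id, time = actual, amt = NA_real_, rate = NA_real_,
    dv = ifelse(blq, NA_real_, obs), evid = 0L, blq = blq,
    wt = subject$weight, cohort = subject$cohort, part = subject$part)
  out <- dplyr::bind_rows(dose_rows, obs_rows)
  out[order(out$time, -out$evid), ]
}

simulate_ro_stream <- function(subject, pk, config) {
  sc <- subject_schedule(subject, config)
  ro_nominal <- sort(unique(c(0, config$ro$times[config$ro$times <=
                                                   sc$row$trough_time],
                              sc$row$trough_time)))
  obs <- pk[pk$id == subject$id & pk$evid == 0, ]
  # pair each RO draw with the nearest observed PK sample
  idx <- vapply(ro_nominal, function(tt) which.min(abs(obs$time - tt)),
                integer(1))
  idx <- unique(idx)
  times <- obs$time[idx]
  params <- pk_params(subject$CL, subject$V1, subject$Q, subject$V2)
  true_conc <- conc_2cmt(params, sc$doses, times)
  purrr::map_dfr(c("cd3", "il2"), function(assay) {
    true_ro <- emax_ro(true_conc, subject$ec50, config$ro$hill)
    value <- pmax(true_ro * (1 + rnorm(length(times), 0, config$ro$noise_sd)),
                  0)
    anomalous <- runif(length(times)) < config$ro$anomalous_prob
    value[anomalous] <- value[anomalous] * runif(sum(anomalous), 0.2, 0.7)
    tibble::tibble(id = subject$id, time = times, assay = assay,
                   value = value, conc = obs$dv[idx], anomalous = anomalous,
                   cohort = subject$cohort, part = subject$part)
  })
}

simulate_ae_stream <- function(subjects, config) {
  ae <- config$ae
  draw_events <- function(subject, table, related) {
    hit <- runif(nrow(table)) < table$prob
    if (!any(hit)) return(NULL)
    tab <- table[hit, ]
    grade <- ifelse(runif(nrow(tab)) < tab$grade3_prob, 3L,
                    sample(1:2, nrow(tab), replace = TRUE, prob = c(.6, .4)))
    g3 <- grade >= 3
    tibble::tibble(
      id = subject$id, term = tab$term, grade = grade, related = related,
      serious = g3 & runif(nrow(tab)) < ae$serious_given_g3,
      withdrawal = g3 & related & runif(nrow(tab)) < ae$withdrawal_given_g3rel,
      interruption = runif(nrow(tab)) < ae$interruption_prob,
      immune_related = tab$term %in% ae$immune_terms &
        runif(nrow(tab)) < ae$immune_prob,
      cohort = subject$cohort, part = subject$part)
  }
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    ev <- dplyr::bind_rows(draw_events(s, ae$related, TRUE),
                           draw_events(s, ae$background, FALSE))
    if (is.null(ev) || !nrow(ev)) {
      # every treated patient reports at least one treatment-emergent AE
      ev <- tibble::tibble(id = s$id, term = "procedural pain", grade = 1L,
                           related = FALSE, serious = FALSE,
                           withdrawal = FALSE, interruption = FALSE,
                           immune_related = FALSE, cohort = s$cohort,
                           part = s$part)
    }
    ev
  })
}

simulate_response_stream <- function(subjects, config) {
  rc <- config$response
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    probs <- rc$probs[[s$part]]
    visits <- rc$visits[[s$part]]
    u <- runif(1)
    latent <- if (u < probs[["irPR"]]) "irPR" else
      if (u < probs[["irPR"]] + probs[["irSD"]]) "irSD" else "irPD"
    cats <- switch(latent,
      irPR = {
        # response at the first or second visit, confirmed next visit
        start <- sample(1:2, 1)
        out <- rep("irPR", length(visits))
        if (start > 1) out[seq_len(start - 1)] <- "irSD"
        out
      },
      irSD = c(rep("irSD", length(visits) - 1), "irPD"),
      irPD = rep("irPD", length(visits)))
    n_keep <- if (latent == "irPD") 2L else length(visits)
    tibble::tibble(id = s$id, time = visits[seq_len(n_keep)],
                   category = cats[seq_len(n_keep)], cohort = s$cohort,
                   part = s$part)
  })
}
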