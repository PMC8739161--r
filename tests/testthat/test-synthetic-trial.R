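test_that("the generator is deterministic for a fixed config and seed", {
  cfg <- trial_config()
  t1 <- simulate_trial(cfg, seed = 7)
  t2 <- simulate_trial(cfg, seed = 7)
  expect_identical(t1$pk, t2$pk)
  expect_identical(t1$ro, t2$ro)
  expect_identical(t1$ae, t2$ae)
  expect_identical(t1$response, t2$response)
  t3 <- simulate_trial(cfg, seed = 8)
  expect_false(identical(t1$pk$dv, t3$pk$dv))
})

test_that("cohort sizes and streams match the configured layout", {
  tr <- simulate_trial(trial_config(), seed = 1)
  expect_equal(nrow(tr$subjects), 34L)
  counts <- table(tr$subjects$cohort)
  expect_equal(as.vector(counts[c("1 mg/kg DLT", "3 mg/kg DLT", "10 mg/kg DLT",
                                  "1 mg/kg PKPD", "10 mg/kg PKPD",
                                  "500 mg Q3W", "1000 mg Q6W")]),
               c(3L, 3L, 6L, 3L, 6L, 6L, 7L))
  expect_true(all(tr$subjects$weight >= 45.6 & tr$subjects$weight <= 145.6))
  expect_setequal(unique(tr$ro$assay), c("cd3", "il2"))
  expect_true(all(tr$pk$id %in% tr$subjects$id))
  # every subject reports at least one adverse event
  expect_setequal(unique(tr$ae$id), tr$subjects$id)
})

test_that("zero variability and zero residual error reproduce the model prediction exactly", {
  cfg <- trial_config(omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                      residual = residual_error(0, 0),
                      ro = list(ec50 = 0.81, hill = 2, ec50_sdlog = 0,
                                noise_sd = 0, anomalous_prob = 0,
                                times = c(24, 168)),
                      ada = list(enabled = FALSE))
  tr <- simulate_trial(cfg, seed = 3)
  for (i in seq_len(nrow(tr$subjects))) {
    s <- tr$subjects[i, ]
    expect_equal(s$CL,
                 cfg$typical$CL * (s$weight / 70)^cfg$theta_wt,
                 tolerance = 1e-12)
    rows <- tr$pk[tr$pk$id == s$id, ]
    obs <- rows[rows$evid == 0 & !rows$blq, ]
    doses <- rows[rows$evid == 1, ]
    pred <- conc_2cmt(pk_params(s$CL, s$V1, s$Q, s$V2),
                      dose_events(doses$time, doses$amt,
                                  doses$amt / doses$rate), obs$time)
    expect_equal(obs$dv, pred, tolerance = 1e-12)
  }
})

test_that("a 20% proportional error shows up as an empirical CV in [15%, 25%]", {
  cohorts <- default_cohorts()[6, ]  # 500 mg Q3W
  cohorts$n <- 50L
  cfg <- trial_config(cohorts = cohorts,
                      omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                      residual = residual_error(0.20, 0),
                      theta_wt = 0,  # identical predictions across subjects
                      ada = list(enabled = FALSE))
  tr <- simulate_trial(cfg, seed = 5)
  obs24 <- tr$pk[tr$pk$evid == 0 & !tr$pk$blq, ]
  # nominal 24 h sample: actual times jitter but predictions barely move,
  # so the spread at the sample is residual-dominated
  obs24 <- obs24[abs(obs24$time - 24) < 3, ]
  cv <- sd(obs24$dv) / mean(obs24$dv)
  expect_gte(cv, 0.15)
  expect_lte(cv, 0.25)
})

test_that("troughs are positive, below Cmax, and samples never cross dose times", {
  tr <- simulate_trial(trial_config(), seed = 11)
  n <- nca(tr$pk)
  expect_true(all(n$ctrough > 0, na.rm = TRUE))
  expect_true(all(n$ctrough < n$cmax, na.rm = TRUE))
  # jittered sample times never land on or beyond a later dose time
  # (the pre-dose anchor at t = 0 is the only dose-time sample)
  bad <- 0L
  for (i in seq_len(nrow(tr$subjects))) {
    rows <- tr$pk[tr$pk$id == tr$subjects$id[i], ]
    dose_t <- rows$time[rows$evid == 1]
    obs_t <- rows$time[rows$evid == 0]
    bad <- bad + sum(obs_t > 0 & obs_t %in% dose_t)
  }
  expect_identical(bad, 0L)
})

test_that("round-trip: NCA on noise-free rich generated profiles recovers CL and t1/2", {
  cohorts <- default_cohorts()[6, ]
  cohorts$n <- 8L
  cohorts$trough_time <- 1344  # washout >= 3 half-lives
  cohorts$tau <- 504
  cfg <- trial_config(cohorts = cohorts,
                      residual = residual_error(0, 0), jitter_frac = 0,
                      schedule = rich_times(),
                      ada = list(enabled = FALSE))
  tr <- simulate_trial(cfg, seed = 13)
  res <- nca(tr$pk, meta = tibble::tibble(cohort = "500 mg Q3W", tau = 504,
                                          trough_time = 1344))
  for (i in seq_len(nrow(res))) {
    s <- tr$subjects[tr$subjects$id == res$id[i], ]
    true_beta <- macro_constants(pk_params(s$CL, s$V1, s$Q, s$V2))$beta
    expect_equal(res$cl_l_d[i], s$CL * 24, tolerance = 0.02)
    expect_equal(res$t_half_d[i], log(2) / true_beta / 24, tolerance = 0.05)
  }
})

test_that("the accelerated-clearance subject undercuts the full-RO threshold at day 22", {
  cfg <- trial_config()
  tr <- simulate_trial(cfg, seed = 17)
  ada <- tr$subjects[tr$subjects$ada, ]
  expect_equal(nrow(ada), 1L)
  expect_equal(ada$cohort, "1 mg/kg PKPD")
  expect_equal(ada$weight, 94)
  # noise-free concentration at the day-22 sample sits at the construction
  # target, below the threshold
  doses <- dose_events(0, round(1 * 94, 1))
  c504 <- conc_2cmt(pk_params(ada$CL, ada$V1, ada$Q, ada$V2), doses, 504)
  expect_lt(c504, 2.44)
  expect_equal(c504, cfg$ada$target_conc, tolerance = 1e-6)
  # at the trough assessment the ADA subject fails the full-RO band while
  # every other subject in the same cohort passes it
  tol_band <- 0.10
  ro_trough <- dplyr::filter(tr$ro, .data$cohort == "1 mg/kg PKPD",
                             .data$time > 400)
  for (sid in unique(ro_trough$id)) {
    vals <- ro_trough$value[ro_trough$id == sid]
    if (sid == ada$id) {
      expect_true(all(!is_full_ro(vals, tol_band)))
    } else {
      expect_true(any(is_full_ro(vals, tol_band)))
    }
  }
  # multiplier 1 is the identity and leaves the ADA flag unset
  s0 <- tr$subjects[2, ]
  expect_identical(make_ada_subject(s0, 1), s0)
  expect_error(make_ada_subject(s0, 0.5), ">= 1")
})

test_that("dose-proportional construction: the power-model CI covers one in >= 85% of replicates", {
  # 12 subjects at 1/3/10 mg/kg (the single-dose escalation cohorts),
  # 200 seeded replicates through the full generation + NCA + power model
  cohorts <- default_cohorts()[c(1, 3, 4), ]
  cfg <- trial_config(cohorts = cohorts, ada = list(enabled = FALSE))
  covered <- vapply(1:200, function(rep) {
    tr <- simulate_trial(cfg, seed = 1000 + rep)
    res <- nca(tr$pk)
    res$mgkg <- res$dose_mg / res$wt
    r <- tidy(power_model_fit(res, mgkg, auc_0_tau, conf = 0.90))
    r$ci_lo <= 1 && 1 <= r$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(trial_config(omega2 = c(CL = -1, V1 = 0, Q = 0, V2 = 0)),
               "non-negative")
  expect_error(trial_config(schedule = c(-1, 0, 24)), ">= 0")
  bad_ro <- list(ec50 = 0.81, hill = 2, ec50_sdlog = 0.2, noise_sd = 0.03,
                 anomalous_prob = 1.5, times = c(24, 168))
  expect_error(trial_config(ro = bad_ro), "probabilities")
})
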