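test_that("lambda_z is exact on a mono-exponential decline", {
  t <- c(8, 24, 72, 168, 336, 504)
  res <- lambda_z(t, 50 * exp(-0.002 * t))
  expect_equal(res$lambda_z, 0.002, tolerance = 1e-10)
  expect_equal(res$n_points, 5L)  # all points after the peak, peak excluded
})

test_that("lambda_z subset choice equals the exhaustive-search oracle on noisy data", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      p <- typical_params()
      t <- c(0.5, 1, 2, 4, 8, 24, 72, 168, 336, 504, 672)
      cc <- conc_2cmt(p, dose_events(0, 500), t) * exp(rnorm(length(t), 0, 0.1))
      res <- lambda_z(t, cc)
      # independent brute force over contiguous terminal subsets
      imax <- which.max(cc)
      n <- length(t)
      best <- NULL
      for (j in seq_len(n)) {
        if (j <= imax || j > n - 2) next
        sel <- j:n
        f <- lm(log(cc[sel]) ~ t[sel])
        if (coef(f)[2] >= 0) next
        m <- length(sel)
        adj <- 1 - (1 - summary(f)$r.squared) * (m - 1) / (m - 2)
        if (is.null(best) || adj > best$adj + 1e-4) {
          best <- list(adj = adj, lz = -coef(f)[[2]], m = m)
        }
      }
      expect_equal(res$lambda_z, best$lz, tolerance = 1e-9)
      expect_equal(res$n_points, best$m)
    }
  })
})

test_that("lambda_z is not estimable with fewer than 3 post-peak points", {
  res <- lambda_z(c(1, 24, 72), c(5, 10, 4))  # peak at 24 h, 1 point after
  expect_true(is.na(res$lambda_z))
})

test_that("linear-up/log-down AUC handles rectangles, log intervals and partial windows", {
  expect_equal(auc_lin_up_log_down(c(0, 24), c(10, 10)), 240)
  # declining interval: (10 - 5) / ln(10/5)
  expect_equal(auc_lin_up_log_down(c(0, 1), c(10, 5)), 5 / log(2),
               tolerance = 1e-12)
  expect_equal(auc_lin_up_log_down(c(0, 1), c(10, 5)), 7.2135, tolerance = 1e-4)
  # partial last interval, log rule: integrates the fitted exponential
  k <- log(10 / 5) / 24
  expect_equal(auc_lin_up_log_down(c(0, 24), c(10, 5), t_end = 12),
               10 * (1 - exp(-12 * k)) / k, tolerance = 1e-12)
  # rising portion is linear even though later intervals decline
  expect_equal(auc_lin_up_log_down(c(0, 1, 2), c(0, 10, 10), t_end = 1), 5)
  expect_error(auc_lin_up_log_down(c(0), c(1)), "at least 2")
  expect_error(auc_lin_up_log_down(c(1, 0), c(1, 2)), "increasing")
  expect_error(auc_lin_up_log_down(c(0, 1), c(1, 2), t_end = 3), "exceed")
})

test_that("AUC on a rich profile is within 0.5% of the quadrature oracle", {
  p <- typical_params()
  t <- sort(unique(c(rich_times(), 336)))
  cc <- conc_2cmt(p, dose_events(0, 500), t)
  auc <- auc_lin_up_log_down(c(0, t), c(0, cc))
  oracle <- stats::integrate(function(x) conc_2cmt(p, dose_events(0, 500), x),
                             0, max(t), rel.tol = 1e-10,
                             subdivisions = 2000)$value
  expect_equal(auc, oracle, tolerance = 5e-3)
})

test_that("NCA recovers clearance and Vss from noise-free rich profiles", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      p <- pk_params(0.0083 * exp(rnorm(1, 0, 0.25)),
                     3.5 * exp(rnorm(1, 0, 0.2)),
                     0.03 * exp(rnorm(1, 0, 0.3)),
                     1.5 * exp(rnorm(1, 0, 0.3)))
      pk <- noise_free_pk(p, dose = 500)
      res <- nca(pk, tau = 336)
      expect_equal(res$cl_l_d, p$CL * 24, tolerance = 0.02)
      expect_equal(res$vss_l, p$V1 + p$V2, tolerance = 0.05)
      expect_equal(res$t_half_d,
                   log(2) / macro_constants(p)$beta / 24, tolerance = 0.05)
      # unit self-consistency: CL[L/d] * AUCinf / 24 = dose
      expect_equal(res$cl_l_d * res$auc_0_inf / 24, 500, tolerance = 1e-8)
      expect_true(res$auc_0_inf >= res$auc_0_last)
      expect_gte(res$extrap_frac, 0)
      expect_lt(res$extrap_frac, 1)
    }
  })
})

test_that("half-life conversion matches the closed form", {
  # lambda_z = 0.002/h -> t1/2 = 346.57 h = 14.44 d
  t <- c(24, 168, 336, 504, 672)
  pk <- noise_free_pk(typical_params())
  pk$dv[pk$evid == 0] <- 80 * exp(-0.002 * pk$time[pk$evid == 0])
  res <- nca(pk, tau = 336)
  expect_equal(res$t_half_d, log(2) / 0.002 / 24, tolerance = 1e-10)
  expect_equal(res$t_half_d, 14.44, tolerance = 1e-3)
})

test_that("BLQ policy: pre-dose zero, embedded excluded, trailing truncated", {
  p <- typical_params()
  times <- c(0, 0.5, 2, 24, 168, 336, 504)
  conc <- conc_2cmt(p, dose_events(0, 500), times)
  pk <- noise_free_pk(p, dose = 500, times = times[-1])
  # mark the 168 h sample BLQ (embedded) and the 504 h sample BLQ (trailing)
  pk$blq[pk$evid == 0 & pk$time == 168] <- TRUE
  pk$dv[pk$evid == 0 & pk$time == 168] <- NA
  pk$blq[pk$evid == 0 & pk$time == 504] <- TRUE
  pk$dv[pk$evid == 0 & pk$time == 504] <- NA
  res <- nca(pk, tau = 336)
  clean <- nca(noise_free_pk(p, dose = 500, times = c(0.5, 2, 24, 336)),
               tau = 336)
  expect_equal(res$auc_0_last, clean$auc_0_last, tolerance = 1e-12)
  # an entirely BLQ post-dose profile is an error, not a result
  all_blq <- noise_free_pk(p, dose = 500, times = c(24, 168))
  all_blq$blq[all_blq$evid == 0] <- TRUE
  all_blq$dv[all_blq$evid == 0] <- NA
  expect_error(nca(all_blq, tau = 336), class = "phasepk_degenerate_profile")
})

test_that("trough is the sample nearest the nominal time within 10% of tau", {
  p <- typical_params()
  pk <- noise_free_pk(p, times = c(0.5, 24, 168, 330))
  res <- nca(pk, tau = 336, trough_time = 336)
  expect_equal(res$ctrough, pk$dv[pk$evid == 0 & pk$time == 330])
  # no sample within the window -> missing
  res2 <- nca(noise_free_pk(p, times = c(0.5, 24, 168)), tau = 336,
              trough_time = 336)
  expect_true(is.na(res2$ctrough))
})

test_that("geometric summaries follow the small-n convention", {
  g <- geo_stats(c(5, 5, 5))
  expect_equal(g$geo_mean, 5)
  expect_equal(g$gcv_pct, 0)
  g2 <- geo_stats(c(1, 10))
  expect_true(is.na(g2$geo_mean))
  expect_equal(c(g2$min, g2$max), c(1, 10))
  g3 <- geo_stats(c(1, 10, 100))
  expect_equal(g3$geo_mean, 10, tolerance = 1e-12)
  expect_equal(g3$gcv_pct, 100 * sqrt(exp(var(log(c(1, 10, 100)))) - 1),
               tolerance = 1e-12)
  expect_error(geo_stats(c(1, -1, 2)), "values > 0")
})

test_that("accumulation ratios: identity, one-compartment closed form, Q2W band", {
  one <- tibble::tibble(id = "S1", tau = 336, auc_0_tau = 1000, cmax = 50)
  expect_equal(accumulation_ratio(one, one)$r_auc_pct, 100)
  # ~one-compartment, tau = one half-life -> steady-state AUC ratio ~200%
  k <- log(2) / 336; V1 <- 4
  p1 <- pk_params(k * V1, V1, 1e-8, 1e-8 / k)
  reg <- regimen("q", cycle_h = 336, dose_times_h = 0, amount_mg = 100)
  grid <- seq(0, 336, by = 0.25)
  auc1 <- auc_lin_up_log_down(grid, conc_2cmt(p1, regimen_doses(reg, n_cycles = 1), grid))
  n_ss <- 40
  t0 <- (n_ss - 1) * 336
  aucss <- auc_lin_up_log_down(
    grid + t0, conc_2cmt(p1, regimen_doses(reg, n_cycles = n_ss), grid + t0))
  expect_equal(100 * aucss / auc1, 200, tolerance = 0.01)
  # generated Q2W profile at the default typical values: steady-state AUC
  # accumulation inside the observed 180-374% band
  p <- typical_params()
  q2w <- regimen_q2w(3)
  grid2 <- seq(0, 336, by = 0.5)
  d1 <- regimen_doses(q2w, weight = 76, n_cycles = 1)[1, ]
  auc_c1 <- auc_lin_up_log_down(grid2, conc_2cmt(p, d1, grid2))
  t0 <- 19 * 672
  dss <- regimen_doses(q2w, weight = 76, n_cycles = 20)
  auc_ss <- auc_lin_up_log_down(grid2 + t0, conc_2cmt(p, dss, grid2 + t0))
  cmax_c1 <- max(conc_2cmt(p, d1, grid2))
  cmax_ss <- max(conc_2cmt(p, dss, grid2 + t0))
  r <- accumulation_ratio(
    tibble::tibble(id = "S1", tau = 336, auc_0_tau = auc_ss, cmax = cmax_ss),
    tibble::tibble(id = "S1", tau = 336, auc_0_tau = auc_c1, cmax = cmax_c1))
  expect_gte(r$r_auc_pct, 180)
  expect_lte(r$r_auc_pct, 374)
  expect_gte(r$r_cmax_pct, 126)
  expect_lte(r$r_cmax_pct, 259)
  # mismatched intervals are rejected
  expect_error(accumulation_ratio(
    tibble::tibble(id = "S1", tau = 504, auc_0_tau = 1, cmax = 1), one),
    "intervals differ")
})
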