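#' Combined residual-error model
#'
#' Proportional CV plus an additive floor: the residual standard deviation
#' at a predicted concentration `c` is `sqrt((prop * c)^2 + add^2)`.
#'
#' @param prop Proportional component (CV as a fraction, default 0.15).
#' @param add Additive floor, ug/mL (default 0.05).
#' @return A list with `prop` and `add`.
#' @export
residual_error <- function(prop = 0.15, add = 0.05) {
  check_number(prop, "prop", non_negative = TRUE)
  check_number(add, "add", non_negative = TRUE)
  list(prop = prop, add = add)
}

#' Population PK model object
#'
#' Two-compartment typical values at a reference body weight, an allometric
#' power exponent of weight on clearance, log-normal between-subject
#' variances and a combined residual-error model. Individual clearance is
#' `CL_i = theta_CL * (weight / ref_weight)^theta_wt * exp(eta)`.
#'
#' @param theta A [pk_params()] object of typical values (at `ref_weight`).
#' @param theta_wt Power exponent of weight on clearance.
#' @param ref_weight Reference body weight, kg (default 70).
#' @param omega2 Named numeric vector of log-scale between-subject variances
#'   for `CL`, `V1`, `Q`, `V2` (all >= 0).
#' @param residual A [residual_error()] model.
#' @param individual Optional tibble of per-subject estimates (added by
#'   [fit_poppk()]).
#' @return An object of class `poppk_model`.
#' @export
poppk_model <- function(theta, theta_wt = 0, ref_weight = 70,
                        omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                        residual = residual_error(), individual = NULL) {
  theta <- as_pk_params(theta)
  check_number(theta_wt, "theta_wt")
  check_number(ref_weight, "ref_weight", positive = TRUE)
  omega2 <- omega2[c("CL", "V1", "Q", "V2")]
  if (any(is.na(omega2)) || any(omega2 < 0)) {
    stop_phasepk("`omega2` must give non-negative variances for CL, V1, Q, V2")
  }
  structure(list(theta = theta, theta_wt = theta_wt, ref_weight = ref_weight,
                 omega2 = omega2, residual = residual,
                 individual = individual),
            class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf(
    "<poppk_model> CL=%.4g L/h (%.3g L/d) ^wt=%.3g @ %g kg, V1=%.3g, Q=%.4g, V2=%.3g\n",
    x$theta$CL, x$theta$CL * 24, x$theta_wt, x$ref_weight, x$theta$V1,
    x$theta$Q, x$theta$V2))
  cat(sprintf("  omega2: %s; residual %.0f%% CV + %.3g ug/mL\n",
              paste(sprintf("%s=%.3g", names(x$omega2), x$omega2),
                    collapse = ", "),
              100 * x$residual$prop, x$residual$add))
  if (!is.null(x$individual)) {
    cat(sprintf("  fitted from %d subjects (%d converged)\n",
                nrow(x$individual), sum(x$individual$converged)))
  }
  invisible(x)
}

#' Individual clearance under the weight covariate model
#'
#' @param model A [poppk_model()].
#' @param weight Body weight, kg (vectorised).
#' @param eta Log-scale individual deviation (default 0, the typical
#'   subject).
#' @return Clearance in L/h.
#' @export
individual_clearance <- function(model, weight, eta = 0) {
  stopifnot(inherits(model, "poppk_model"))
  if (any(weight <= 0)) stop_phasepk("`weight` must be > 0")
  model$theta$CL * (weight / model$ref_weight)^model$theta_wt * exp(eta)
}

# internal: NCA-derived starting values for an individual fit
nca_init <- function(time, conc, dose, duration) {
  fallback <- pk_params(0.008, 3.5, 0.03, 1.5)
  lz <- tryCatch(lambda_z(time, conc), error = function(e) NULL)
  if (is.null(lz) || is.na(lz$lambda_z)) return(fallback)
  auc_last <- tryCatch(auc_lin_up_log_down(time, conc),
                       error = function(e) NA_real_)
  if (is.na(auc_last)) return(fallback)
  auc_inf <- auc_last + conc[length(conc)] / lz$lambda_z
  cl <- dose / auc_inf
  vz <- cl / lz$lambda_z
  pk_params(CL = max(cl, 1e-6), V1 = max(0.7 * vz, 0.1), Q = 0.03,
            V2 = max(0.3 * vz, 0.1))
}

#' Fit a two-compartment model to one subject's profile
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt on log parameters)
#' of [conc_2cmt()] to an observed profile, with residuals weighted by the
#' combined error model. The fit is retried from `n_restarts` log-perturbed
#' starting points (+/- 50%, deterministic sub-seeds) and the best objective
#' is kept.
#'
#' @param time Observation times, h.
#' @param conc Observed concentrations, ug/mL (quantifiable).
#' @param doses A [dose_events()] tibble.
#' @param init Starting [pk_params()] (default: derived from an NCA pass).
#' @param residual A [residual_error()] model used for the weights.
#' @param n_restarts Number of perturbed restarts (default 5).
#' @param seed Integer controlling the restart perturbations.
#' @return A list: `params` ([pk_params()]), `converged`, `objective`
#'   (weighted residual sum of squares), `n_obs`.
#' @export
fit_individual_pk <- function(time, conc, doses, init = NULL,
                              residual = residual_error(), n_restarts = 5,
                              seed = 1) {
  keep <- is.finite(conc) & conc > 0 & time > min(doses$time)
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 6) {
    stop_phasepk("at least 6 quantifiable post-dose samples are required",
                 class = "phasepk_underdetermined")
  }
  doses <- as_dose_events(doses)
  if (is.null(init)) {
    init <- nca_init(time, conc, sum(doses$amount), doses$duration[1])
  } else {
    init <- as_pk_params(init)
  }
  dtime <- doses$time; damt <- doses$amount; ddur <- doses$duration
  resfun <- function(lp) {
    p <- exp(lp)
    pred <- conc_eval(list(CL = p[1], V1 = p[2], Q = p[3], V2 = p[4]),
                      dtime, damt, ddur, time)
    sd <- sqrt((residual$prop * pred)^2 + residual$add^2)
    (conc - pred) / pmax(sd, 1e-9)
  }
  # wide plausibility box (log scale) for an IgG-like antibody: keeps the
  # optimiser out of degenerate corners on weakly informative profiles
  lower <- log(c(1e-5, 0.2, 1e-5, 0.05))
  upper <- log(c(1, 50, 5, 100))
  lp0 <- pmin(pmax(log(unlist(init)), lower), upper)
  starts <- list(lp0)
  if (n_restarts > 0) {
    perturb <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts),
             function(i) pmin(pmax(lp0 + log(runif(4, 0.5, 1.5)), lower),
                              upper))
    })
    starts <- c(starts, perturb)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resfun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(params = init, converged = FALSE, objective = Inf,
                se_log_cl = NA_real_, n_obs = length(time)))
  }
  # precision gate: log-scale SE of CL from the Gauss-Newton approximation;
  # a profile too short to identify clearance is flagged not-converged and
  # excluded from stage 2
  se_log <- tryCatch({
    sigma2 <- best$deviance / max(length(time) - 4, 1)
    sqrt(diag(sigma2 * solve(best$hessian)))
  }, error = function(e) rep(NA_real_, 4))
  converged <- best$info %in% 1:3 && is.finite(se_log[1]) && se_log[1] < 0.5
  list(params = pk_params(exp(best$par[1]), exp(best$par[2]),
                          exp(best$par[3]), exp(best$par[4])),
       converged = converged, objective = best$deviance,
       se_log_cl = se_log[1], n_obs = length(time))
}

#' Two-stage population PK estimation
#'
#' Stage 1 fits each subject individually with [fit_individual_pk()];
#' stage 2 summarises the individual estimates on the log scale: the weight
#' exponent on clearance is the slope of `ln(CL_i)` on
#' `ln(weight_i / ref_weight)` (so typical CL is the back-transformed
#' intercept and the CL between-subject variance is residual to that
#' regression); the other typical values are geometric means with log-scale
#' sample variances; the proportional residual error is re-estimated from
#' pooled relative residuals.
#'
#' @param data A concentration dataset in the dialect of [read_pk_dataset()]
#'   (columns `id`, `time`, `amt`, `rate`, `dv`, `evid`, `blq`, `wt`).
#' @param ref_weight Reference weight, kg.
#' @param residual A [residual_error()] model for the stage-1 weights.
#' @param fix_theta_wt Fix the weight exponent instead of estimating it
#'   (e.g. 0 for a no-covariate model).
#' @param n_restarts,seed Passed to [fit_individual_pk()] (per-subject
#'   sub-seeds derive deterministically from `seed`).
#' @return A [poppk_model()] whose `individual` element holds the
#'   per-subject estimates; `tidy()` and `glance()` methods summarise it.
#' @export
fit_poppk <- function(data, ref_weight = 70, residual = residual_error(),
                      fix_theta_wt = NULL, n_restarts = 5, seed = 1) {
  check_columns(data, c("id", "time", "dv", "evid", "wt"), "pk data")
  if (!"blq" %in% names(data)) data$blq <- FALSE
  groups <- split(data, data$id)
  ind <- purrr::imap(groups, function(g, nm) {
    obs <- g[g$evid == 0 & !(g$blq %in% c(TRUE, 1)) & !is.na(g$dv), ]
    dr <- g[g$evid == 1, ]
    if (!nrow(dr) || nrow(obs) < 6) return(NULL)
    dur <- ifelse(!is.na(dr$rate) & dr$rate > 0, dr$amt / dr$rate, 0.5)
    doses <- dose_events(dr$time, dr$amt, dur)
    sub_seed <- (seed + match(nm, names(groups)) * 131L) %% .Machine$integer.max
    f <- fit_individual_pk(obs$time, obs$dv, doses, residual = residual,
                           n_restarts = n_restarts, seed = sub_seed)
    tibble::tibble(id = nm, wt = g$wt[1], CL = f$params$CL, V1 = f$params$V1,
                   Q = f$params$Q, V2 = f$params$V2, converged = f$converged,
                   objective = f$objective, se_log_cl = f$se_log_cl,
                   n_obs = f$n_obs)
  })
  ind <- dplyr::bind_rows(purrr::compact(ind))
  ok <- ind[ind$converged, ]
  if (nrow(ok) < 6) {
    stop_phasepk("fewer than 6 subjects with successful individual fits")
  }
  lw <- log(ok$wt / ref_weight)
  lcl <- log(ok$CL)
  if (!is.null(fix_theta_wt)) {
    check_number(fix_theta_wt, "fix_theta_wt")
    theta_wt <- fix_theta_wt
    adj <- lcl - theta_wt * lw
    theta_cl <- exp(mean(adj))
    om_cl <- var(adj)
  } else if (sd(lw) < 1e-10) {
    theta_wt <- 0
    theta_cl <- exp(mean(lcl))
    om_cl <- var(lcl)
  } else {
    f <- lm(lcl ~ lw)
    theta_wt <- unname(coef(f)[2])
    theta_cl <- exp(unname(coef(f)[1]))
    om_cl <- sum(stats::resid(f)^2) / (nrow(ok) - 2)
  }
  gm <- function(x) exp(mean(log(x)))
  vlog <- function(x) if (length(x) > 1) var(log(x)) else 0
  theta <- pk_params(theta_cl, gm(ok$V1), gm(ok$Q), gm(ok$V2))
  omega2 <- c(CL = om_cl, V1 = vlog(ok$V1), Q = vlog(ok$Q), V2 = vlog(ok$V2))
  # residual proportional CV re-estimated from pooled relative residuals
  rel <- purrr::map(seq_len(nrow(ok)), function(i) {
    g <- groups[[ok$id[i]]]
    obs <- g[g$evid == 0 & !(g$blq %in% c(TRUE, 1)) & !is.na(g$dv), ]
    dr <- g[g$evid == 1, ]
    dur <- ifelse(!is.na(dr$rate) & dr$rate > 0, dr$amt / dr$rate, 0.5)
    pred <- conc_2cmt(pk_params(ok$CL[i], ok$V1[i], ok$Q[i], ok$V2[i]),
                      dose_events(dr$time, dr$amt, dur), obs$time)
    # floor the denominator at the additive noise scale so near-zero
    # predictions cannot dominate the pooled relative residuals
    (obs$dv - pred) / pmax(pred, 10 * residual$add)
  })
  rel <- unlist(rel)
  # 4 structural parameters absorbed per subject: correct the pooled df
  df <- max(length(rel) - 4 * nrow(ok), 1)
  prop_hat <- sqrt(sum((rel - mean(rel))^2) / df)
  poppk_model(theta, theta_wt = theta_wt, ref_weight = ref_weight,
              omega2 = omega2,
              residual = residual_error(prop = prop_hat, add = residual$add),
              individual = ind)
}

#' @rdname fit_poppk
#' @param x,object A `poppk_model`.
#' @param ... Unused.
#' @export
tidy.poppk_model <- function(x, ...) {
  tibble::tibble(
    term = c("theta_CL", "theta_V1", "theta_Q", "theta_V2", "theta_wt",
             "omega2_CL", "omega2_V1", "omega2_Q", "omega2_V2",
             "sigma_prop", "sigma_add"),
    estimate = c(x$theta$CL, x$theta$V1, x$theta$Q, x$theta$V2, x$theta_wt,
                 unname(x$omega2), x$residual$prop, x$residual$add),
    unit = c("L/h", "L", "L/h", "L", "", rep("log-variance", 4), "CV", "ug/mL"))
}

#' @rdname fit_poppk
#' @export
glance.poppk_model <- function(x, ...) {
  ind <- x$individual
  tibble::tibble(
    n_subjects = if (is.null(ind)) NA_integer_ else nrow(ind),
    n_converged = if (is.null(ind)) NA_integer_ else sum(ind$converged),
    ref_weight = x$ref_weight,
    cl_l_day = x$theta$CL * 24,
    t_half_d = log(2) / macro_constants(x$theta)$beta / 24)
}

#' Clearance-weight covariate significance test
#'
#' OLS of `ln(CL)` on `ln(weight)` with a two-sided t test of zero slope at
#' the 0.05 level — the usual screen for whether body weight materially
#' drives antibody clearance.
#'
#' @param data A data frame of per-subject values.
#' @param cl Clearance column (tidy-evaluated).
#' @param weight Weight column (tidy-evaluated).
#' @return A one-row tibble: `n`, `slope`, `se`, `statistic`, `p_value`,
#'   `significant` (p < 0.05).
#' @export
weight_covariate_test <- function(data, cl, weight) {
  cl_v <- rlang::eval_tidy(rlang::enquo(cl), data)
  wt_v <- rlang::eval_tidy(rlang::enquo(weight), data)
  keep <- !is.na(cl_v) & !is.na(wt_v)
  cl_v <- cl_v[keep]; wt_v <- wt_v[keep]
  if (length(cl_v) < 4) stop_phasepk("at least 4 subjects are required")
  if (any(cl_v <= 0) || any(wt_v <= 0)) {
    stop_phasepk("clearances and weights must be > 0")
  }
  if (sd(log(wt_v)) < 1e-12) stop_phasepk("weights are constant; slope unidentifiable")
  fit <- lm(log(cl_v) ~ log(wt_v))
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm[2, 1]; se <- sm[2, 2]
  stat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- 2 * pt(-abs(stat), df = length(cl_v) - 2)
  tibble::tibble(n = length(cl_v), slope = slope, se = se, statistic = stat,
                 p_value = p, significant = p < 0.05)
}

#' Serialize / read a population PK model (YAML)
#'
#' @param model A [poppk_model()].
#' @param path File path.
#' @return `read_poppk_model()` returns a [poppk_model()] (individual
#'   estimates are not serialized).
#' @export
write_poppk_model <- function(model, path) {
  stopifnot(inherits(model, "poppk_model"))
  yaml::write_yaml(list(
    theta = lapply(unclass(model$theta), as.numeric),
    theta_wt = model$theta_wt, ref_weight = model$ref_weight,
    omega2 = as.list(model$omega2),
    residual = model$residual), path, precision = 17)
  invisible(path)
}

#' @rdname write_poppk_model
#' @export
read_poppk_model <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("theta", "theta_wt", "ref_weight", "omega2", "residual")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop_phasepk(sprintf("model file is missing key(s): %s",
                         paste(missing, collapse = ", ")))
  }
  poppk_model(pk_params(x$theta$CL, x$theta$V1, x$theta$Q, x$theta$V2),
              theta_wt = x$theta_wt, ref_weight = x$ref_weight,
              omega2 = unlist(x$omega2),
              residual = residual_error(x$residual$prop, x$residual$add))
}

# internal: draw individual parameter sets from a population model
draw_individual_params <- function(model, weights) {
  n <- length(weights)
  om <- sqrt(model$omega2)
  eta <- matrix(rnorm(4 * n), ncol = 4) %*% diag(om)
  tibble::tibble(
    weight = weights,
    CL = individual_clearance(model, weights, eta[, 1]),
    V1 = model$theta$V1 * exp(eta[, 2]),
    Q = model$theta$Q * exp(eta[, 3]),
    V2 = model$theta$V2 * exp(eta[, 4]))
}

#' Clearance versus body weight plot
#'
#' @param data A data frame (e.g. the `individual` element of a fitted
#'   [poppk_model()], or an [nca()] result joined to weights).
#' @param cl,weight Columns (tidy-evaluated).
#' @return A ggplot.
#' @export
plot_cl_weight <- function(data, cl, weight) {
  cl_q <- rlang::enquo(cl); wt_q <- rlang::enquo(weight)
  ggplot2::ggplot(data, ggplot2::aes(!!wt_q, !!cl_q)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "body weight (kg)", y = "clearance",
                  title = "Individual clearance vs body weight") +
    ggplot2::theme_minimal()
}

#' @rdname fit_poppk
#' @export
autoplot.poppk_model <- function(object, ...) {
  if (is.null(object$individual)) {
    stop_phasepk("model has no individual estimates to plot")
  }
  plot_cl_weight(dplyr::filter(object$individual, .data$converged),
                 .data$CL, .data$wt)
}
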