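# shared internal helpers

# round-half-up at `digits` decimals; printed clinical tables round 0.05 up,
# base R round() uses round-half-even
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of n out of total, rounded half-up to one decimal
pct_1d <- function(n, total) round_half_up(100 * n / total, 1)

stop_phasepk <- function(msg, class = "phasepk_error") {
  abort(msg, class = class)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_phasepk(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_phasepk(sprintf("`%s` must be > 0", name))
  if (non_negative && x < 0) stop_phasepk(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_phasepk(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# log-linear least squares, closed form (avoids lm() overhead in tight loops);
# returns slope, intercept, r2 or NULL when degenerate
loglin_fit <- function(t, logc) {
  n <- length(t)
  mx <- mean(t); my <- mean(logc)
  sxx <- sum((t - mx)^2)
  if (sxx == 0) return(NULL)
  sxy <- sum((t - mx) * (logc - my))
  slope <- sxy / sxx
  fitted <- my + slope * (t - mx)
  sst <- sum((logc - my)^2)
  sse <- sum((logc - fitted)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}
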