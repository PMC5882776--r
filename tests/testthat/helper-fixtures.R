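# Build a logistic time series (optionally replicated and noisy) in the
# single-series schema used by fit_logistic().
make_logistic_series <- function(params, days = c(0, 3, 7, 12, 17, 22, 40),
                                 noise_sd = 0, reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clean <- logistic_value(params, days)
  out <- lapply(seq_len(reps), function(r) {
    tibble::tibble(
      replicate = paste0("r", r),
      time_d = days,
      concentration = pmax(clean + stats::rnorm(length(days), 0, noise_sd), 0))
  })
  dplyr::bind_rows(out)
}

mean_series <- function(data) {
  dplyr::summarise(data, concentration = mean(concentration), .by = "time_d")
}

pcp_chain_species <- c("PCP", "2,3,4,5-TeCP", "3,4,5-TCP", "3,5-DCP", "3-CP")

# Independent ODE oracle for the first-order chain (written here, not taken
# from the package's internals).
oracle_chain_ode <- function(rates, initial, times) {
  lambda <- c(rates, 0)
  n <- length(lambda)
  deriv <- function(t, y, parms) {
    list(c(0, lambda[-n] * y[-n]) - lambda * y)
  }
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = initial, times = grid, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname(sol[match(times, grid), -1, drop = FALSE])
}

# Numerical maximum of dC/dt: dense central differences plus parabolic
# refinement at the grid maximum.
numeric_max_rate <- function(params) {
  k <- params$k
  h <- 1e-5 / k
  g <- function(t) (logistic_value(params, t + h) -
                      logistic_value(params, t - h)) / (2 * h)
  wide <- seq(h, 10 * log(max(params$b, 2)) / k + 10 / k, length.out = 2000)
  t0 <- wide[which.max(g(wide))]
  fine <- seq(t0 - 0.02 / k, t0 + 0.02 / k, length.out = 401)
  fine <- fine[fine > 0]
  gv <- g(fine)
  i <- which.max(gv)
  if (i == 1L || i == length(gv)) return(gv[i])
  # parabola through the three points around the maximum
  y0 <- gv[i]; ym <- gv[i - 1L]; yp <- gv[i + 1L]
  y0 + (yp - ym)^2 / (8 * (2 * y0 - yp - ym))
}
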