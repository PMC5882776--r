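test_that("logistic_value obeys the closed form, its bounds and monotonicity", {
  p <- logistic_params(a = 5.91, b = 9.03, k = 0.21)
  # half-maximum at the inflection time ln(b)/k
  expect_equal(logistic_value(p, log(9.03) / 0.21), 5.91 / 2, tolerance = 1e-12)
  # asymptote equals the capacity a
  expect_equal(logistic_value(p, 1000), 5.91, tolerance = 1e-9)
  expect_equal(logistic_value(logistic_params(1, 1, 1), 0), 0.5)
  t <- seq(-5, 60, by = 0.25)
  v <- logistic_value(p, t)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < p$a))
})

test_that("invalid logistic parameters and times are rejected", {
  expect_error(logistic_params(-1, 2, 0.5), class = "pcpredox_invalid_argument")
  expect_error(logistic_params(1, 0, 0.5), class = "pcpredox_invalid_argument")
  expect_error(logistic_params(1, 2, Inf), class = "pcpredox_invalid_argument")
  expect_error(logistic_value(logistic_params(1, 1, 1), NA_real_),
               class = "pcpredox_invalid_argument")
  expect_error(vmax(list(a = 1, b = 2)), class = "pcpredox_invalid_parameter")
})

test_that("derived rate statistics match 0.25*a*k and ln(b)/k", {
  cases <- list(
    list(p = logistic_params(5.91, 9.03, 0.21), vmax = 0.31, tv = 10.48),
    list(p = logistic_params(119.74, 179.09, 0.76), vmax = 22.75, tv = 6.83),
    list(p = logistic_params(149.61, 170.26, 0.52), vmax = 19.45, tv = 9.88)
  )
  for (cs in cases) {
    expect_equal(round(vmax(cs$p), 2), cs$vmax)
    expect_equal(round(t_vmax(cs$p), 2), cs$tv)
  }
  # k -> 0+ means no reaction and a vanishing maximum rate
  expect_lt(vmax(logistic_params(100, 5, 1e-9)), 1e-6)
  expect_equal(t_vmax(logistic_params(3, 1, 0.5)), 0)
})

test_that("the analytic maximum-rate and inflection identities hold", {
  set.seed(11)
  for (i in 1:8) {
    p <- logistic_params(a = stats::runif(1, 1, 200),
                         b = stats::runif(1, 1.5, 400),
                         k = stats::runif(1, 0.1, 1))
    expect_equal(numeric_max_rate(p), vmax(p), tolerance = 1e-9)
    expect_equal(logistic_value(p, t_vmax(p)), p$a / 2, tolerance = 1e-9)
  }
})

test_that("r_squared matches its definition and rejects degenerate input", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)  # SS_res 1, SS_tot 2
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 1)), class = "pcpredox_undefined_r2")
  expect_error(r_squared(1:3, 1:4), class = "pcpredox_invalid_argument")
})

test_that("to_decrement flips decreasing series against a baseline", {
  d <- tibble::tibble(time_d = c(0, 7, 40), concentration = c(150, 75, 0))
  expect_equal(to_decrement(d)$concentration, c(0, 75, 150))
  d2 <- tibble::tibble(time_d = c(0, 40), concentration = c(5.91, 5.91))
  expect_equal(to_decrement(d2)$concentration, c(0, 0))
  d3 <- tibble::tibble(time_d = c(0, 7, 40), concentration = c(100, 40, 10))
  expect_equal(to_decrement(d3, baseline = 100)$concentration, c(0, 60, 90))
  # small overshoot above the baseline is clipped, a large one is an error
  d4 <- tibble::tibble(time_d = c(0, 7), concentration = c(100, 101))
  expect_equal(to_decrement(d4)$concentration, c(0, 0))
  d5 <- tibble::tibble(time_d = c(0, 7), concentration = c(100, 110))
  expect_error(to_decrement(d5), class = "pcpredox_data_consistency")
})

test_that("fit_logistic recovers exact parameters from noiseless data", {
  truth <- logistic_params(149.61, 170.26, 0.52)
  fit <- fit_logistic(make_logistic_series(truth))
  expect_true(fit$converged)
  expect_equal(fit$params$a, truth$a, tolerance = 1e-6)
  expect_equal(fit$params$b, truth$b, tolerance = 1e-6)
  expect_equal(fit$params$k, truth$k, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$vmax, 0.25 * fit$params$a * fit$params$k)
  expect_equal(fit$t_vmax, log(fit$params$b) / fit$params$k)
})

test_that("fit_logistic recovers a within 5% and k within 10% under noise", {
  truth <- logistic_params(149.61, 170.26, 0.52)
  noisy <- make_logistic_series(truth, noise_sd = 2, reps = 3, seed = 42)
  fit <- fit_logistic(mean_series(noisy))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$a - truth$a) / truth$a, 0.05)
  expect_lt(abs(fit$params$k - truth$k) / truth$k, 0.10)
})

test_that("fitting is idempotent on the curve implied by a previous fit", {
  truth <- logistic_params(23.85, 37.91, 0.24)
  fit1 <- fit_logistic(make_logistic_series(truth, noise_sd = 0.4, seed = 7))
  fit2 <- fit_logistic(make_logistic_series(fit1$params))
  expect_equal(fit2$params$a, fit1$params$a, tolerance = 1e-8)
  expect_equal(fit2$params$b, fit1$params$b, tolerance = 1e-8)
  expect_equal(fit2$params$k, fit1$params$k, tolerance = 1e-8)
})

test_that("noiseless estimation error stays negligible across grid densities", {
  truth <- logistic_params(119.74, 179.09, 0.76)
  for (n in c(5, 9, 17, 33)) {
    days <- seq(0, 40, length.out = n)
    fit <- fit_logistic(make_logistic_series(truth, days = days))
    err <- max(abs(c(fit$params$a / truth$a, fit$params$b / truth$b,
                     fit$params$k / truth$k) - 1))
    expect_lt(err, 1e-6)
  }
})

test_that("degenerate fitting inputs raise typed errors", {
  expect_error(
    fit_logistic(tibble::tibble(time_d = c(0, 3, 7),
                                concentration = c(0, 1, 2))),
    class = "pcpredox_insufficient_data")
  expect_error(
    fit_logistic(tibble::tibble(time_d = c(0, 3, 7, 12),
                                concentration = rep(5.91, 4))),
    class = "pcpredox_degenerate_input")
})

test_that("fit_logistic_curves fits per treatment/analyte with decrementing", {
  truth <- logistic_params(149.61, 170.26, 0.52)
  days <- c(0, 3, 7, 12, 17, 22, 40)
  data <- dplyr::bind_rows(
    tibble::tibble(treatment_id = "control", analyte = "pcp", replicate = "r1",
                   time_d = days,
                   concentration = 150 - logistic_value(truth, days),
                   unit = "uM"),
    tibble::tibble(treatment_id = "control", analyte = "fe2", replicate = "r1",
                   time_d = days,
                   concentration = logistic_value(
                     logistic_params(119.74, 179.09, 0.76), days),
                   unit = "mM"))
  fits <- fit_logistic_curves(data)
  expect_equal(nrow(fits), 2L)
  expect_equal(fits$vmax, 0.25 * fits$a * fits$k)
  pcp_row <- fits[fits$analyte == "pcp", ]
  # decrement against the day-0 value: capacity shifted by C(0) = a/(1+b)
  expect_equal(pcp_row$a, truth$a - logistic_value(truth, 0), tolerance = 0.05)
  fe_row <- fits[fits$analyte == "fe2", ]
  expect_equal(fe_row$a, 119.74, tolerance = 1e-4)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_logistic(make_logistic_series(logistic_params(10, 20, 0.3)))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "k"))
  gl <- glance(fit)
  expect_equal(gl$vmax, 0.25 * gl$a * gl$k)
  expect_s3_class(autoplot(fit), "ggplot")
})
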