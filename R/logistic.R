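#' Three-parameter logistic model for cumulative redox processes
#'
#' Anaerobic reduction processes in flooded soils -- Fe(II) accumulation,
#' sulfate decrement, PCP decrement -- follow a sigmoidal course that is
#' conventionally summarised by the logistic
#' \deqn{C_t = \frac{a}{1 + b\,e^{-kt}}}
#' where `a` is the maximum capacity (same unit as the series), `b` a
#' dimensionless regression coefficient setting the initial displacement, and
#' `k` the rate constant (per day). Two derived statistics summarise each fit:
#' the maximum instantaneous rate \eqn{V_{max} = 0.25\,a\,k} and the time at
#' which it occurs \eqn{t_{V_{max}} = \ln(b)/k} (the inflection point, where
#' \eqn{C_t = a/2}).
#'
#' @param a Maximum capacity, > 0.
#' @param b Dimensionless regression coefficient, > 0.
#' @param k Rate constant per day, > 0.
#' @return `logistic_params()` returns a validated parameter object (a named
#'   list of class `logistic_params`).
#' @examples
#' p <- logistic_params(a = 5.91, b = 9.03, k = 0.21)
#' vmax(p)                      # 0.25 * a * k
#' t_vmax(p)                    # ln(b) / k
#' logistic_value(p, t_vmax(p)) # a / 2 at the inflection
#' @export
logistic_params <- function(a, b, k) {
  a <- check_scalar_number(a, "a", min = 0, strict = TRUE)
  b <- check_scalar_number(b, "b", min = 0, strict = TRUE)
  k <- check_scalar_number(k, "k", min = 0, strict = TRUE)
  structure(list(a = a, b = b, k = k), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> a = %g, b = %g, k = %g /d\n", x$a, x$b, x$k))
  invisible(x)
}

as_logistic_params <- function(params) {
  if (inherits(params, "logistic_params")) return(params)
  if (is.list(params) || is.numeric(params)) {
    params <- as.list(params)
    if (all(c("a", "b", "k") %in% names(params))) {
      return(logistic_params(params$a, params$b, params$k))
    }
  }
  abort("`params` must be a logistic_params object or a named list with a, b, k",
        class = "pcpredox_invalid_parameter")
}

#' @rdname logistic_params
#' @param params A [logistic_params()] object (or named list with `a`, `b`, `k`).
#' @param t Time in days (vectorised; must be finite).
#' @return `logistic_value()` returns the concentration at `t`, strictly
#'   increasing in `t` and bounded in (0, a).
#' @export
logistic_value <- function(params, t) {
  p <- as_logistic_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite", class = "pcpredox_invalid_argument")
  }
  p$a / (1 + p$b * exp(-p$k * t))
}

#' @rdname logistic_params
#' @return `vmax()` returns the maximum rate 0.25*a*k (series unit per day),
#'   the analytic maximum of dC/dt.
#' @export
vmax <- function(params) {
  p <- as_logistic_params(params)
  0.25 * p$a * p$k
}

#' @rdname logistic_params
#' @return `t_vmax()` returns ln(b)/k in days, the inflection time where the
#'   curve crosses a/2.
#' @export
t_vmax <- function(params) {
  p <- as_logistic_params(params)
  log(p$b) / p$k
}

#' Coefficient of determination for a fitted series
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed against the mean of the observed
#' values. May be negative for fits worse than the mean; undefined (an error)
#' for constant observations.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A single number <= 1.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    abort("`observed` and `predicted` must have equal length >= 2",
          class = "pcpredox_invalid_argument")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("R^2 is undefined for constant observations",
          class = "pcpredox_undefined_r2")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Convert a decreasing analyte series to its cumulative decrement
#'
#' The logistic is fitted to *cumulative* quantities: accumulated Fe(II)
#' directly, but the *decrease* of nitrate, sulfate or PCP relative to a
#' baseline. This verb replaces `concentration` with `baseline -
#' concentration`. Small negative decrements (measurement jitter around the
#' baseline, e.g. at day 0) are clipped to zero up to a tolerance expressed as
#' a fraction of the baseline; larger ones raise a data-consistency error.
#'
#' @param data A data frame with columns `time_d` and `concentration` for a
#'   single series, ordered or not.
#' @param baseline Baseline concentration; defaults to the value at the
#'   earliest time point. Must be at least `max(concentration)` up to the
#'   tolerance.
#' @param tol_frac Negative-decrement tolerance as a fraction of the baseline
#'   (default 0.02).
#' @return The input tibble with `concentration` replaced by the decrement,
#'   and the baseline recorded in attribute `"baseline"`.
#' @examples
#' d <- tibble::tibble(time_d = c(0, 7, 40), concentration = c(150, 75, 0))
#' to_decrement(d)$concentration  # 0 75 150
#' @export
to_decrement <- function(data, baseline = NULL, tol_frac = 0.02) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("time_d", "concentration"))
  data <- dplyr::arrange(tibble::as_tibble(data), .data$time_d)
  baseline <- baseline %||% data$concentration[[1L]]
  baseline <- check_scalar_number(baseline, "baseline", min = 0)
  dec <- baseline - data$concentration
  too_negative <- dec < -tol_frac * baseline
  if (any(too_negative)) {
    abort(paste0("concentration exceeds baseline ", signif(baseline, 6),
                 " beyond the ", tol_frac * 100, "% tolerance at time(s) ",
                 paste(data$time_d[too_negative], collapse = ", ")),
          class = "pcpredox_data_consistency")
  }
  data$concentration <- pmax(dec, 0)
  attr(data, "baseline") <- baseline
  data
}

# Data-driven start values: capacity a little above the observed maximum,
# k from the slope of the logit-linearised interior, b from the t=0 value.
logistic_start <- function(times, values) {
  a0 <- max(values) * 1.05
  eps <- 1e-6 * a0
  b0 <- a0 / max(values[[1L]], eps) - 1
  interior <- values > 0.01 * a0 & values < 0.99 * a0
  k0 <- 0.2
  if (sum(interior) >= 2L) {
    z <- log(a0 / values[interior] - 1)
    sl <- coef(lm(z ~ times[interior]))[[2L]]
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  c(a = a0, b = max(b0, eps), k = k0)
}

#' Fit the logistic model to one cumulative time series
#'
#' Bounded (all parameters positive) Levenberg-Marquardt nonlinear least
#' squares on a single series of cumulative values -- accumulated Fe(II), or a
#' decrement series produced by [to_decrement()]. Start values are derived
#' from the data (capacity from the observed maximum, rate from a
#' logit-linearised interior slope). Requires at least 4 distinct time points
#' and non-constant values.
#'
#' @param data A data frame with columns `time_d`, `concentration` (one
#'   series; average replicates first or use [fit_logistic_curves()]).
#' @param start Optional named vector `c(a=, b=, k=)` overriding the automatic
#'   start values.
#' @param max_iter Maximum number of iterations/evaluations (default 10000).
#' @param ftol,ptol Relative convergence tolerances passed to the optimizer
#'   (default 1e-10).
#' @return An object of class `logistic_fit`: a list with `params`
#'   ([logistic_params()]), `vmax`, `t_vmax`, `r2`, `n_points`, `converged`,
#'   `residuals`, `data`. Non-convergence is reported honestly via
#'   `converged = FALSE`, never silently.
#' @seealso [tidy.logistic_fit()], [glance.logistic_fit()],
#'   [autoplot.logistic_fit()]
#' @examples
#' p <- logistic_params(a = 149.61, b = 170.26, k = 0.52)
#' d <- tibble::tibble(time_d = c(0, 3, 7, 12, 17, 22, 40),
#'                     concentration = logistic_value(p, time_d))
#' fit <- fit_logistic(d)
#' glance(fit)
#' @export
fit_logistic <- function(data, start = NULL, max_iter = 10000,
                         ftol = 1e-10, ptol = 1e-10) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("time_d", "concentration"))
  data <- dplyr::arrange(tibble::as_tibble(data), .data$time_d)
  times <- data$time_d
  values <- data$concentration
  if (any(!is.finite(times)) || any(!is.finite(values)) || any(values < 0)) {
    abort("times and concentrations must be finite and non-negative",
          class = "pcpredox_invalid_argument")
  }
  if (length(unique(times)) < 4L) {
    abort("logistic fitting needs at least 4 distinct time points",
          class = "pcpredox_insufficient_data")
  }
  if (diff(range(values)) == 0) {
    abort("cannot fit a logistic to a constant series",
          class = "pcpredox_degenerate_input")
  }
  start <- start %||% logistic_start(times, values)
  resid_fn <- function(p) values - p[["a"]] / (1 + p[["b"]] * exp(-p[["k"]] * times))
  lower <- rep(sqrt(.Machine$double.eps), 3L)
  fit <- minpack.lm::nls.lm(
    par = pmax(start, lower), lower = lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(max_iter, 1024L), maxfev = max_iter,
      ftol = ftol, ptol = ptol)
  )
  est <- fit$par
  params <- logistic_params(est[["a"]], est[["b"]], est[["k"]])
  predicted <- logistic_value(params, times)
  converged <- fit$info %in% 1:4
  structure(list(
    params = params,
    vmax = vmax(params),
    t_vmax = t_vmax(params),
    r2 = r_squared(values, predicted),
    n_points = length(times),
    converged = converged,
    residuals = values - predicted,
    data = data
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> a = %.4g, b = %.4g, k = %.4g /d | Vmax = %.4g, t_Vmax = %.4g d, R2 = %.4f (%d points%s)\n",
    x$params$a, x$params$b, x$params$k, x$vmax, x$t_vmax, x$r2, x$n_points,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Broom-style accessors for logistic fits
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row model
#' summary including the derived rate statistics.
#'
#' @param x A `logistic_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "k"),
    estimate = c(x$params$a, x$params$b, x$params$k)
  )
}

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    a = x$params$a, b = x$params$b, k = x$params$k,
    vmax = x$vmax, t_vmax = x$t_vmax, r2 = x$r2,
    n_points = x$n_points, converged = x$converged
  )
}

#' @rdname tidy.logistic_fit
#' @param object A `logistic_fit` object.
#' @param n_curve Number of points on the fitted curve.
#' @export
autoplot.logistic_fit <- function(object, n_curve = 200, ...) {
  grid <- tibble::tibble(
    time_d = seq(min(object$data$time_d), max(object$data$time_d),
                 length.out = n_curve))
  grid$concentration <- logistic_value(object$params, grid$time_d)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_d, y = .data$concentration)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$t_vmax, linetype = "dashed") +
    ggplot2::labs(x = "Time (d)", y = "Cumulative concentration",
                  subtitle = sprintf("Vmax = %.3g at t = %.3g d (R2 = %.3f)",
                                     object$vmax, object$t_vmax, object$r2))
}

#' Fit logistic curves across treatments and analytes
#'
#' Data-frame-first fitting over a tidy long table. Decreasing analytes
#' (nitrate, sulfate, PCP) are converted to decrements via [to_decrement()]
#' before fitting; Fe(II) (and any other analyte) is fitted as accumulated
#' directly. Replicates are averaged per time point by default ("means") or
#' fitted as pooled points ("pooled").
#'
#' @param data Tidy data frame with columns `treatment_id`, `analyte`,
#'   `replicate`, `time_d`, `concentration`.
#' @param analytes Analytes to fit (default: all present except congener
#'   names, which belong to the chain module).
#' @param replicates `"means"` (fit per-time means, default) or `"pooled"`.
#' @param decreasing Character vector of analytes to decrement before
#'   fitting; defaults to nitrate, sulfate and pcp.
#' @param tol_frac Negative-decrement tolerance forwarded to [to_decrement()].
#' @return A tibble with one row per (treatment_id, analyte): columns `a`,
#'   `b`, `k`, `vmax`, `t_vmax`, `r2`, `n_points`, `converged`.
#' @export
fit_logistic_curves <- function(data, analytes = NULL,
                                replicates = c("means", "pooled"),
                                decreasing = DECREASING_ANALYTES,
                                tol_frac = 0.02) {
  stopifnot(is.data.frame(data))
  replicates <- match.arg(replicates)
  check_columns(data, c("treatment_id", "analyte", "replicate",
                        "time_d", "concentration"))
  if (is.null(analytes)) {
    present <- unique(data$analyte)
    is_congener <- vapply(present, function(a) {
      !inherits(tryCatch(parse_congener(a), error = function(e) e), "error")
    }, logical(1))
    analytes <- present[!is_congener]
  }
  data |>
    dplyr::filter(.data$analyte %in% analytes) |>
    dplyr::group_by(.data$treatment_id, .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      series <- if (replicates == "means") {
        dplyr::summarise(d, concentration = mean(.data$concentration),
                         .by = "time_d")
      } else {
        d[c("time_d", "concentration")]
      }
      if (key$analyte %in% decreasing) {
        # the series maximum always satisfies the baseline precondition; for
        # a decreasing analyte it equals the earliest observation up to noise
        series <- to_decrement(series, baseline = max(series$concentration),
                               tol_frac = tol_frac)
      }
      glance(fit_logistic(series))
    }) |>
    dplyr::ungroup()
}
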