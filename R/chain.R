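#' Sequential first-order dechlorination chain model
#'
#' Models the metabolite cascade of anaerobic PCP dechlorination (e.g.
#' PCP -> 2,3,4,5-TeCP -> 3,4,5-TCP -> 3,5-DCP -> 3-CP) as an irreversible
#' chain of first-order reactions with per-step rate constants `k_i` (per
#' day), an optional hard onset lag (microcosms typically show a 3--7 day lag
#' before dechlorination starts) and arbitrary non-negative initial
#' concentrations. The terminal species does not decay.
#'
#' @param species Ordered congener names (or position vectors), parent to
#'   terminus; consecutive pairs must be single-chlorine-removal steps
#'   (validated with [infer_pathway()]).
#' @param rates Per-step rate constants, length `length(species) - 1`, all
#'   > 0 (per day).
#' @param initial Initial concentrations in uM, length `length(species)`,
#'   all >= 0; typically all mass in the head species.
#' @param lag_d Onset delay in days (>= 0, default 0): the state is frozen at
#'   `initial` until `lag_d`.
#' @return A validated list of class `chain_model` (with the pathway step
#'   table attached as `$steps`).
#' @examples
#' m <- chain_model(c("PCP", "2,3,4,5-TeCP", "3,4,5-TCP", "3,5-DCP", "3-CP"),
#'                  rates = c(0.5, 0.4, 0.3, 0.2),
#'                  initial = c(150, 0, 0, 0, 0), lag_d = 3)
#' simulate_chain(m, times = c(0, 3, 7, 12, 17, 22, 40))
#' @export
chain_model <- function(species, rates, initial, lag_d = 0) {
  if (!is.list(species)) species <- as.list(species)
  names <- vapply(species, function(s) canonical_name(as_positions(s)),
                  character(1))
  steps <- infer_pathway(names)
  n <- length(names)
  if (n < 2L) {
    abort("a chain needs at least two species", class = "pcpredox_invalid_argument")
  }
  if (length(rates) != n - 1L || any(!is.finite(rates)) || any(rates <= 0)) {
    abort("`rates` must be length(species) - 1 positive numbers",
          class = "pcpredox_invalid_argument")
  }
  if (length(initial) != n || any(!is.finite(initial)) || any(initial < 0)) {
    abort("`initial` must be length(species) non-negative numbers",
          class = "pcpredox_invalid_argument")
  }
  lag_d <- check_scalar_number(lag_d, "lag_d", min = 0)
  structure(list(species = names, rates = as.numeric(rates),
                 initial = as.numeric(initial), lag_d = lag_d, steps = steps),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model> ", paste(x$species, collapse = " -> "), "\n", sep = "")
  cat("  rates (/d): ", paste(signif(x$rates, 4), collapse = ", "),
      if (x$lag_d > 0) paste0(" | lag ", x$lag_d, " d"), "\n", sep = "")
  invisible(x)
}

# Per-species decay constants: each non-terminal species decays at its
# outgoing step rate; the terminus does not decay.
chain_lambdas <- function(model) c(model$rates, 0)

# Closed-form Bateman solution for mass starting in species `start`, evaluated
# for species start..n at times t (vector). Requires the decay constants of
# the involved sub-chain to be pairwise distinct.
bateman_block <- function(lambda, start, times) {
  n <- length(lambda)
  out <- matrix(0, nrow = length(times), ncol = n)
  for (j in start:n) {
    idx <- start:j
    prod_rates <- if (j > start) prod(lambda[start:(j - 1L)]) else 1
    acc <- 0
    for (i in idx) {
      denom <- prod(lambda[setdiff(idx, i)] - lambda[i])
      acc <- acc + exp(-lambda[i] * times) / denom
    }
    out[, j] <- prod_rates * acc
  }
  out
}

min_lambda_gap <- function(lambda) {
  d <- abs(outer(lambda, lambda, "-"))
  scale <- max(lambda, 1)
  min(d[upper.tri(d)]) / scale
}

chain_ode <- function(model, times, y0) {
  lambda <- chain_lambdas(model)
  n <- length(lambda)
  deriv <- function(t, y, parms) {
    inflow <- c(0, lambda[-n] * y[-n])
    list(inflow - lambda * y)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  unname(sol[, -1, drop = FALSE])
}

#' Simulate a dechlorination chain
#'
#' Evaluates the chain at the requested times using the closed-form Bateman
#' solution when all decay constants in each sub-chain are distinct, or
#' adaptive numerical integration (relative tolerance 1e-9) when rates are
#' (near-)repeated. For `t < lag_d` the state equals `initial`; afterwards
#' the chain evolves on the shifted clock `t - lag_d`.
#'
#' @param model A [chain_model()].
#' @param times Non-decreasing vector of times in days, >= 0.
#' @param tidy If `TRUE` (default) return a tidy tibble (`time_d`, `congener`,
#'   `concentration_uM`); otherwise a time-by-species matrix.
#' @return Tibble or matrix of non-negative concentrations.
#' @export
simulate_chain <- function(model, times, tidy = TRUE) {
  stopifnot(inherits(model, "chain_model"))
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times)) {
    abort("`times` must be non-negative and non-decreasing",
          class = "pcpredox_invalid_argument")
  }
  lambda <- chain_lambdas(model)
  n <- length(lambda)
  tau <- pmax(times - model$lag_d, 0)
  # solve on the unique shifted clock once, then index back
  tau_u <- sort(unique(tau))
  use_bateman <- min_lambda_gap(lambda) > 1e-6
  conc_u <- matrix(0, nrow = length(tau_u), ncol = n)
  if (use_bateman) {
    for (s in seq_len(n)) {
      if (model$initial[s] > 0) {
        conc_u <- conc_u + model$initial[s] * bateman_block(lambda, s, tau_u)
      }
    }
  } else if (length(tau_u) == 1L && tau_u == 0) {
    conc_u <- matrix(model$initial, nrow = 1L)
  } else {
    grid <- if (tau_u[1] > 0) c(0, tau_u) else tau_u
    sol <- chain_ode(model, grid, y0 = model$initial)
    conc_u <- sol[match(tau_u, grid), , drop = FALSE]
  }
  conc <- pmax(conc_u[match(tau, tau_u), , drop = FALSE], 0)
  colnames(conc) <- model$species
  if (!tidy) return(conc)
  tibble::tibble(
    time_d = rep(times, times = n),
    congener = rep(model$species, each = length(times)),
    concentration_uM = as.vector(conc)
  )
}

#' Chlorine mass balance of a simulated chain
#'
#' Organically bound chlorine at each time is the position-count-weighted sum
#' of congener concentrations; chloride released is the initial bound total
#' minus the bound amount, and is non-decreasing in time for a forward chain.
#'
#' @param matrix Time-by-species concentration matrix (uM), columns matching
#'   `species` (e.g. `simulate_chain(..., tidy = FALSE)`).
#' @param species Congener names for the columns.
#' @param times Optional time vector for the output.
#' @return A tibble with columns `time_d` (if given), `bound_cl_uM`,
#'   `released_cl_uM`, `total_cl_uM`.
#' @export
chlorine_balance <- function(matrix, species, times = NULL) {
  if (!is.matrix(matrix) || ncol(matrix) != length(species)) {
    abort("`matrix` must have one column per species",
          class = "pcpredox_invalid_argument")
  }
  n_cl <- vapply(species, function(s) length(as_positions(s)), numeric(1))
  bound <- as.vector(matrix %*% n_cl)
  total0 <- bound[1L]
  out <- tibble::tibble(
    bound_cl_uM = bound,
    released_cl_uM = total0 - bound,
    total_cl_uM = total0
  )
  if (!is.null(times)) out <- dplyr::bind_cols(tibble::tibble(time_d = times), out)
  out
}

#' Fit chain rate constants to observed congener trajectories
#'
#' Least-squares estimation of the per-step rate constants of a
#' [chain_model()] skeleton on a log-rate parameterisation (rates stay
#' positive without explicit bounds). Initial concentrations and the lag are
#' taken from the skeleton; only the rates are estimated.
#'
#' @param data Tidy observations with columns `time_d`, `congener`,
#'   `concentration_uM`; at least two chain species observed over at least
#'   five time points.
#' @param skeleton A [chain_model()] giving species order, initial state, lag
#'   and start rates.
#' @return A list with `model` (fitted [chain_model()]), `residual_norm` and
#'   `converged`.
#' @export
fit_chain_rates <- function(data, skeleton) {
  stopifnot(is.data.frame(data), inherits(skeleton, "chain_model"))
  check_columns(data, c("time_d", "congener", "concentration_uM"))
  data <- dplyr::filter(data, .data$congener %in% skeleton$species)
  if (all(data$concentration_uM == 0)) {
    abort("all observations are zero; rates are unidentifiable",
          class = "pcpredox_unidentifiable")
  }
  if (length(unique(data$congener)) < 2L || length(unique(data$time_d)) < 5L) {
    abort("need >= 2 observed species and >= 5 time points",
          class = "pcpredox_insufficient_data")
  }
  obs <- dplyr::summarise(data,
                          concentration_uM = mean(.data$concentration_uM),
                          .by = c("time_d", "congener"))
  times <- sort(unique(obs$time_d))
  resid_fn <- function(log_k) {
    m <- chain_model(skeleton$species, exp(log_k), skeleton$initial,
                     skeleton$lag_d)
    sim <- simulate_chain(m, times, tidy = FALSE)
    pred <- sim[cbind(match(obs$time_d, times),
                      match(obs$congener, skeleton$species))]
    obs$concentration_uM - pred
  }
  fit <- minpack.lm::nls.lm(
    par = log(skeleton$rates), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  model <- chain_model(skeleton$species, exp(fit$par), skeleton$initial,
                       skeleton$lag_d)
  list(model = model,
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = fit$info %in% 1:4)
}

#' @rdname chain_model
#' @param object A `chain_model`.
#' @param times Time grid for plotting (default 0--40 d).
#' @param ... Unused.
#' @export
autoplot.chain_model <- function(object, times = seq(0, 40, by = 0.25), ...) {
  sim <- simulate_chain(object, times)
  sim$congener <- factor(sim$congener, levels = object$species)
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$time_d,
                                    y = .data$concentration_uM,
                                    colour = .data$congener)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (d)", y = "Concentration (µM)",
                  colour = NULL)
}
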