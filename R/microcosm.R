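#' Default ground-truth parameters for the synthetic microcosm
#'
#' The generating parameters emulate a flooded paddy-soil slurry amended with
#' lactate and PCP: fast zero-order nitrate depletion (gone by day 3),
#' logistic Fe(II) accumulation, a logistic sulfate decrement whose capacity
#' is a fixed fraction of the available pool (background plus amendment), and
#' a sequential first-order dechlorination chain with an onset lag. Sulfate
#' and nitrate amendments suppress the chain rates through the
#' phenomenological factor `1 / (1 + alpha_s * sulfate_mM + alpha_n *
#' nitrate_mM)`; molybdate caps the sulfate reduction fraction at a ceiling.
#'
#' @return A named list of truth parameters; override entries via the `truth`
#'   argument of [microcosm_config()].
#' @export
default_truth <- function() {
  list(
    fe2 = list(a = 119.74, b = 179.09, k = 0.76),      # mM, accumulation
    sulfate = list(b = 9.03, k = 0.21),                # decrement shape
    sulfate_reduction_fraction = 0.9,                  # of the available pool
    molybdate_ceiling_fraction = 0.25,                 # under molybdate
    nitrate_depletion_day = 3,
    chain_species = c("PCP", "2,3,4,5-TeCP", "3,4,5-TCP", "3,5-DCP", "3-CP"),
    chain_rates = c(0.15, 0.40, 0.30, 0.20),           # per day, uninhibited
    chain_lag_d = 5,
    alpha_s = 0.025,                                   # per mM sulfate
    alpha_n = 0.0125                                   # per mM nitrate
  )
}

#' Configure a synthetic anaerobic microcosm
#'
#' Captures the experimental design of a soil-slurry microcosm -- 15 g dry
#' soil in 15 mL water (1:1 w/v), 20 mM lactate as electron donor, 150 uM PCP,
#' optional sulfate / nitrate / molybdate amendments, triplicate sampling at
#' days 0, 3, 7, 12, 17, 22, 40 -- together with the generating truth and the
#' random seed. The background soil sulfate default (6.67 mM in pore water)
#' corresponds to 640.9 mg sulfate per kg dry soil at this soil:water ratio.
#'
#' @param sulfate_mM,nitrate_mM,molybdate_mM Amendment concentrations (mM).
#' @param lactate_mM Electron-donor concentration (mM).
#' @param soil_g Dry soil mass (g).
#' @param water_L Aqueous volume (L).
#' @param pcp0_uM Initial PCP (uM).
#' @param background_sulfate_mM Native pore-water sulfate (mM).
#' @param sampling_days Sampling times (days).
#' @param replicates Number of replicate bottles (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (0 disables noise).
#' @param seed Integer seed; mandatory, so every dataset is reproducible.
#' @param treatment_id Optional label; derived from the amendments by default.
#' @param truth Truth parameters (see [default_truth()]); partial overrides
#'   are merged over the defaults.
#' @return A validated list of class `microcosm_config`.
#' @export
microcosm_config <- function(sulfate_mM = 0, nitrate_mM = 0, molybdate_mM = 0,
                             lactate_mM = 20, soil_g = 15.0, water_L = 0.015,
                             pcp0_uM = 150, background_sulfate_mM = 6.67,
                             sampling_days = c(0, 3, 7, 12, 17, 22, 40),
                             replicates = 3, noise_cv = 0.03, seed,
                             treatment_id = NULL, truth = list()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed)) {
    abort("`seed` is mandatory and must be a single integer",
          class = "pcpredox_invalid_config")
  }
  for (nm in c("sulfate_mM", "nitrate_mM", "molybdate_mM", "lactate_mM",
               "soil_g", "water_L", "pcp0_uM", "background_sulfate_mM",
               "noise_cv")) {
    check_scalar_number(get(nm), nm, min = 0)
  }
  if (water_L <= 0) abort("`water_L` must be > 0", class = "pcpredox_invalid_config")
  if (!is.numeric(sampling_days) || length(sampling_days) < 2L ||
      is.unsorted(sampling_days, strictly = TRUE) || any(sampling_days < 0)) {
    abort("`sampling_days` must be >= 2 strictly increasing non-negative days",
          class = "pcpredox_invalid_config")
  }
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates)) {
    abort("`replicates` must be a positive integer",
          class = "pcpredox_invalid_config")
  }
  tr <- utils::modifyList(default_truth(), truth)
  if (is.null(treatment_id)) {
    parts <- c(
      if (sulfate_mM > 0) sprintf("S%g", sulfate_mM),
      if (nitrate_mM > 0) sprintf("N%g", nitrate_mM),
      if (molybdate_mM > 0) sprintf("Mo%g", molybdate_mM))
    treatment_id <- if (length(parts) == 0L) "control" else paste(parts, collapse = "_")
  }
  structure(list(
    sulfate_mM = sulfate_mM, nitrate_mM = nitrate_mM,
    molybdate_mM = molybdate_mM, lactate_mM = lactate_mM,
    soil_g = soil_g, water_L = water_L, pcp0_uM = pcp0_uM,
    background_sulfate_mM = background_sulfate_mM,
    sampling_days = as.numeric(sampling_days),
    replicates = as.integer(replicates), noise_cv = noise_cv,
    seed = as.integer(seed), treatment_id = treatment_id, truth = tr
  ), class = "microcosm_config")
}

# Resolve the config-dependent truth: sulfate capacity, inhibited chain rates.
resolve_truth <- function(config) {
  tr <- config$truth
  pool <- config$background_sulfate_mM + config$sulfate_mM
  fraction <- if (config$molybdate_mM > 0) {
    tr$molybdate_ceiling_fraction
  } else {
    tr$sulfate_reduction_fraction
  }
  inhibition <- 1 / (1 + tr$alpha_s * config$sulfate_mM +
                       tr$alpha_n * config$nitrate_mM)
  tr$sulfate_pool_mM <- pool
  tr$sulfate$a <- fraction * pool
  tr$inhibition_factor <- inhibition
  tr$chain_rates_effective <- tr$chain_rates * inhibition
  tr$pcp0_uM <- config$pcp0_uM
  tr
}

#' Generate a synthetic microcosm dataset
#'
#' Produces the full tidy time-series bundle of one treatment: nitrate (if
#' amended), measured sulfate (pool minus logistic decrement), accumulated
#' Fe(II), and the PCP congener block from the sequential dechlorination
#' chain. Multiplicative Gaussian noise (truncated at zero) is applied per
#' replicate from a single RNG stream seeded by `config$seed`, so identical
#' configs yield identical datasets.
#'
#' @param config A [microcosm_config()].
#' @return An object of class `synthetic_microcosm`: a list with `samples`
#'   (tidy tibble: `treatment_id`, `analyte`, `replicate`, `time_d`,
#'   `concentration`, `unit`), `truth` (resolved generating parameters,
#'   including the inhibited chain rates) and `config`.
#' @examples
#' ds <- generate_microcosm(microcosm_config(seed = 1))
#' dplyr::count(ds$samples, analyte)
#' @export
generate_microcosm <- function(config) {
  if (!inherits(config, "microcosm_config")) {
    abort("`config` must be a microcosm_config object",
          class = "pcpredox_invalid_config")
  }
  tr <- resolve_truth(config)
  days <- config$sampling_days

  clean <- list()
  if (config$nitrate_mM > 0) {
    clean$nitrate <- list(
      values = pmax(config$nitrate_mM *
                      (1 - days / tr$nitrate_depletion_day), 0),
      unit = "mM")
  }
  sulfate_truth <- logistic_params(tr$sulfate$a, tr$sulfate$b, tr$sulfate$k)
  clean$sulfate <- list(
    values = pmax(tr$sulfate_pool_mM - logistic_value(sulfate_truth, days), 0),
    unit = "mM")
  fe_truth <- logistic_params(tr$fe2$a, tr$fe2$b, tr$fe2$k)
  clean$fe2 <- list(values = logistic_value(fe_truth, days), unit = "mM")

  chain <- chain_model(tr$chain_species, tr$chain_rates_effective,
                       initial = c(config$pcp0_uM,
                                   rep(0, length(tr$chain_species) - 1L)),
                       lag_d = tr$chain_lag_d)
  chain_conc <- simulate_chain(chain, days, tidy = FALSE)
  for (sp in tr$chain_species) {
    nm <- if (sp == "PCP") "pcp" else sp
    clean[[nm]] <- list(values = chain_conc[, sp], unit = "uM")
  }

  set.seed(config$seed)
  rows <- purrr::imap(clean, function(block, analyte) {
    purrr::map(seq_len(config$replicates), function(rep_i) {
      noise <- if (config$noise_cv > 0) {
        stats::rnorm(length(days), mean = 1, sd = config$noise_cv)
      } else {
        rep(1, length(days))
      }
      tibble::tibble(
        treatment_id = config$treatment_id,
        analyte = analyte,
        replicate = paste0("r", rep_i),
        time_d = days,
        concentration = pmax(block$values * noise, 0),
        unit = block$unit)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(list(samples = rows, truth = tr, config = config),
            class = "synthetic_microcosm")
}

#' @export
print.synthetic_microcosm <- function(x, ...) {
  cat(sprintf(
    "<synthetic_microcosm> %s: %d analytes x %d days x %d replicates (seed %d)\n",
    x$config$treatment_id, length(unique(x$samples$analyte)),
    length(x$config$sampling_days), x$config$replicates, x$config$seed))
  invisible(x)
}

#' @rdname generate_microcosm
#' @param object A `synthetic_microcosm`.
#' @param ... Unused.
#' @export
autoplot.synthetic_microcosm <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$time_d, y = .data$concentration,
                               colour = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time (d)", y = "Concentration (mM or µM)",
                  title = object$config$treatment_id)
}

#' Run the full pipeline on a synthetic dataset and score recovery
#'
#' Fits the logistic model to the Fe(II) accumulation and the sulfate
#' decrement (decremented against the known truth pool), re-estimates the
#' chain rate constants from the congener block, infers the dechlorination
#' pathway by first detection, and tabulates relative errors against the
#' generating truth.
#'
#' @param dataset A `synthetic_microcosm` with truth attached.
#' @param detection_threshold Congener detection threshold in uM for pathway
#'   inference (default 1).
#' @return A tibble with columns `process`, `parameter`, `truth`, `estimate`,
#'   `rel_error`, carrying the inferred pathway as attributes
#'   `pathway_chain` and `pathway_classes`.
#' @export
truth_recovery_report <- function(dataset, detection_threshold = 1) {
  if (!inherits(dataset, "synthetic_microcosm") || is.null(dataset$truth)) {
    abort("`dataset` must be a synthetic_microcosm with truth attached",
          class = "pcpredox_missing_truth")
  }
  tr <- dataset$truth
  samples <- dataset$samples
  means <- function(analyte) {
    samples |>
      dplyr::filter(.data$analyte == !!analyte) |>
      dplyr::summarise(concentration = mean(.data$concentration),
                       .by = "time_d")
  }

  fe_fit <- fit_logistic(means("fe2"))
  sulf <- means("sulfate")
  sulf$concentration <- pmax(tr$sulfate_pool_mM - sulf$concentration, 0)
  sulf_fit <- fit_logistic(sulf)

  congeners <- c("pcp", tr$chain_species[-1L])
  chain_obs <- samples |>
    dplyr::filter(.data$analyte %in% congeners) |>
    dplyr::mutate(congener = ifelse(.data$analyte == "pcp", "PCP",
                                    .data$analyte)) |>
    dplyr::rename(concentration_uM = "concentration")
  skeleton <- chain_model(tr$chain_species, tr$chain_rates,
                          initial = c(tr$pcp0_uM,
                                      rep(0, length(tr$chain_species) - 1L)),
                          lag_d = tr$chain_lag_d)
  chain_fit <- fit_chain_rates(chain_obs, skeleton)

  pathway <- detect_pathway(
    dplyr::transmute(chain_obs, analyte = .data$congener,
                     time_d = .data$time_d,
                     concentration = .data$concentration_uM),
    threshold = detection_threshold)

  row <- function(process, parameter, truth, estimate) {
    tibble::tibble(process = process, parameter = parameter, truth = truth,
                   estimate = estimate,
                   rel_error = abs(estimate - truth) / abs(truth))
  }
  report <- dplyr::bind_rows(
    row("fe2", c("a", "b", "k"),
        c(tr$fe2$a, tr$fe2$b, tr$fe2$k),
        c(fe_fit$params$a, fe_fit$params$b, fe_fit$params$k)),
    row("sulfate", c("a", "b", "k"),
        c(tr$sulfate$a, tr$sulfate$b, tr$sulfate$k),
        c(sulf_fit$params$a, sulf_fit$params$b, sulf_fit$params$k)),
    row("chain", paste0("k", seq_along(tr$chain_rates_effective)),
        tr$chain_rates_effective, chain_fit$model$rates)
  )
  attr(report, "pathway_chain") <- pathway$chain
  attr(report, "pathway_classes") <- pathway$steps$position_class
  report
}
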