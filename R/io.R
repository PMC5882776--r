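TS_COLUMNS <- c("treatment_id", "analyte", "replicate", "time_d",
                "concentration", "unit")

#' Read and write tidy microcosm time-series tables
#'
#' The package's interchange schema is a tidy long CSV with columns
#' `treatment_id`, `analyte`, `replicate`, `time_d`, `concentration`, `unit`.
#' The unit column is mandatory -- nitrate/sulfate/Fe(II) in mM, chlorophenols
#' in uM -- and is validated, never guessed. "µM" is normalised to "uM" on
#' read.
#'
#' @param path CSV file path.
#' @return `read_timeseries_csv()` returns a validated tibble.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path),
          class = "pcpredox_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(data, TS_COLUMNS, what = paste0("'", basename(path), "'"))
  data$unit <- sub("µM", "uM", data$unit)
  bad_unit <- setdiff(unique(data$unit), c("mM", "uM"))
  if (length(bad_unit) > 0L) {
    abort(paste0("unrecognised unit(s): ", paste(bad_unit, collapse = ", "),
                 " (expected mM or uM)"),
          class = "pcpredox_schema_error")
  }
  if (any(!is.finite(data$concentration)) || any(data$concentration < 0)) {
    abort("concentrations must be finite and >= 0",
          class = "pcpredox_schema_error")
  }
  data
}

#' @rdname read_timeseries_csv
#' @param data A data frame in the interchange schema.
#' @param force Overwrite an existing file (default `FALSE`; an existing file
#'   is never silently overwritten).
#' @return `write_timeseries_csv()` invisibly returns `path`.
#' @export
write_timeseries_csv <- function(data, path, force = FALSE) {
  check_columns(data, TS_COLUMNS, what = "output")
  if (file.exists(path) && !force) {
    abort(paste0(path, " exists; use force = TRUE to overwrite"),
          class = "pcpredox_io_error")
  }
  readr::write_csv(data[TS_COLUMNS], path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, comma-separated values as numeric vectors.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_keyvalue_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file does not exist: ", path),
          class = "pcpredox_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort(paste0("malformed config line: '", ln, "'"),
            class = "pcpredox_io_error")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  out
}

write_keyvalue <- function(x, path) {
  flat <- unlist(x)
  writeLines(paste0(names(flat), " = ", vapply(flat, format, character(1))),
             path)
  invisible(path)
}

#' Simulate a microcosm dataset to disk
#'
#' Reads a flat key=value simulator config (keys matching
#' [microcosm_config()] arguments, e.g. `seed = 1`, `sulfate_mM = 20`),
#' generates the dataset and writes the tidy samples CSV plus a
#' `*_truth.txt` key=value sidecar with the resolved generating parameters.
#'
#' @param config A [microcosm_config()] object or the path of a key=value
#'   config file.
#' @param outdir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @return Invisibly, the paths written (named character vector).
#' @export
run_simulate <- function(config, outdir = ".", force = FALSE) {
  if (is.character(config)) {
    raw <- read_keyvalue_config(config)
    known <- setdiff(names(formals(microcosm_config)), c("truth", "treatment_id"))
    unknown <- setdiff(names(raw), c(known, "treatment_id"))
    if (length(unknown) > 0L) {
      abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
            class = "pcpredox_invalid_config")
    }
    config <- do.call(microcosm_config, raw)
  }
  dataset <- generate_microcosm(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stem <- file.path(outdir, config$treatment_id)
  paths <- c(samples = paste0(stem, "_samples.csv"),
             truth = paste0(stem, "_truth.txt"))
  write_timeseries_csv(dataset$samples, paths[["samples"]], force = force)
  if (file.exists(paths[["truth"]]) && !force) {
    abort(paste0(paths[["truth"]], " exists; use force = TRUE to overwrite"),
          class = "pcpredox_io_error")
  }
  write_keyvalue(dataset$truth, paths[["truth"]])
  invisible(paths)
}

#' Fit logistic curves from a CSV and write the fit table
#'
#' @param input Path of a tidy time-series CSV (interchange schema).
#' @param output Path of the fit-table CSV to write.
#' @param force Overwrite an existing output.
#' @inheritParams fit_logistic_curves
#' @return The fit table tibble, invisibly; columns `treatment_id`,
#'   `analyte`, `a`, `b`, `k`, `vmax`, `t_vmax`, `r2`, `n_points`,
#'   `converged`.
#' @export
run_fit <- function(input, output = NULL, force = FALSE,
                    replicates = c("means", "pooled")) {
  data <- read_timeseries_csv(input)
  fits <- fit_logistic_curves(data, replicates = match.arg(replicates))
  if (!is.null(output)) {
    if (file.exists(output) && !force) {
      abort(paste0(output, " exists; use force = TRUE to overwrite"),
            class = "pcpredox_io_error")
    }
    readr::write_csv(fits, output)
  }
  invisible(fits)
}

#' Build an electron-equivalent ledger from a per-pathway CSV
#'
#' @param input Path of a CSV with columns `treatment_id`, `pathway`
#'   (fe3/no3/so4/dechlorination), `mmol` (eeq consumed).
#' @param donor_mM,volume_L Design metadata for [eeq_added()].
#' @param coeff [eeq_coefficients()].
#' @param output Optional ledger CSV path.
#' @param force Overwrite an existing output.
#' @return The `eeq_ledger` tibble, invisibly.
#' @export
run_eeq <- function(input, donor_mM = 20, volume_L = 0.015,
                    coeff = eeq_coefficients(), output = NULL, force = FALSE) {
  data <- readr::read_csv(input, show_col_types = FALSE)
  check_columns(data, c("treatment_id", "pathway", "mmol"),
                what = paste0("'", basename(input), "'"))
  added <- eeq_added(donor_mM, volume_L, coeff)
  ledger <- ledger_from_table(data, added_mmol = added)
  if (!is.null(output)) {
    if (file.exists(output) && !force) {
      abort(paste0(output, " exists; use force = TRUE to overwrite"),
            class = "pcpredox_io_error")
    }
    readr::write_csv(tibble::as_tibble(ledger), output)
  }
  invisible(ledger)
}

#' Infer the dechlorination pathway from a CSV
#'
#' @param input Path of a tidy time-series CSV containing congener analytes.
#' @param threshold Detection threshold (uM).
#' @param output Optional path for the per-step CSV report.
#' @param force Overwrite an existing output.
#' @return The [detect_pathway()] result, invisibly; the chain is printed as
#'   `"PCP -> ... -> 3-CP"` with the per-step position classes.
#' @export
run_pathway <- function(input, threshold = 1, output = NULL, force = FALSE) {
  data <- read_timeseries_csv(input)
  data <- dplyr::mutate(data, analyte = ifelse(.data$analyte == "pcp", "PCP",
                                               .data$analyte))
  pw <- detect_pathway(data, threshold = threshold)
  if (length(pw$chain) == 0L) {
    message("no congeners detected above ", threshold, " uM; empty report")
  } else {
    message(paste(pw$chain, collapse = " -> "))
    if (nrow(pw$steps) > 0L) {
      message("position classes: ",
              paste(pw$steps$position_class, collapse = ", "))
    }
  }
  if (!is.null(output)) {
    if (file.exists(output) && !force) {
      abort(paste0(output, " exists; use force = TRUE to overwrite"),
            class = "pcpredox_io_error")
    }
    readr::write_csv(pw$steps, output)
  }
  invisible(pw)
}

#' Published logistic fits and electron-equivalent ledger
#'
#' Reference tables from an anaerobic flooded paddy-soil microcosm study of
#' competing reduction processes, shipped with the package:
#' `reference_kinetics()` returns the fitted logistic parameters (a, b, k)
#' with the reported Vmax, t_Vmax and R-squared for sulfate reduction,
#' Fe(III) reduction and PCP degradation across six treatments;
#' `reference_eeq_ledger()` returns the reported end-of-incubation
#' electron-equivalent balance. These serve as desk-scale checks of the
#' derived-statistic formulas and the ledger arithmetic.
#'
#' @return A tibble.
#' @examples
#' rk <- reference_kinetics()
#' all.equal(round(0.25 * rk$a * rk$k, 2), rk$vmax)
#' @export
reference_kinetics <- function() {
  readr::read_csv(system.file("extdata", "reference_logistic_fits.csv",
                              package = "pcpredox", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname reference_kinetics
#' @export
reference_eeq_ledger <- function() {
  readr::read_csv(system.file("extdata", "reference_eeq_ledger.csv",
                              package = "pcpredox", mustWork = TRUE),
                  show_col_types = FALSE)
}
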