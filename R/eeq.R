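#' Electron-equivalent coefficients for anaerobic reducing processes
#'
#' Half-reaction electron equivalents per mole of acceptor: Fe(III) -> Fe(II)
#' takes 1 eeq, NO3- -> N2 takes 5, SO4(2-) -> S(2-) takes 8, and each C-Cl
#' bond replaced by C-H during reductive dechlorination takes 2. Lactate as
#' the donor contributes 12 eeq per mole on complete oxidation to CO2.
#'
#' @param fe3,no3,so4 Electron equivalents per mol acceptor.
#' @param per_chlorine Eeq per mol chlorine removed during dechlorination.
#' @param lactate_donor Eeq per mol lactate donated.
#' @return A named list of class `eeq_coefficients`.
#' @export
eeq_coefficients <- function(fe3 = 1, no3 = 5, so4 = 8,
                             per_chlorine = 2, lactate_donor = 12) {
  vals <- list(fe3 = fe3, no3 = no3, so4 = so4,
               per_chlorine = per_chlorine, lactate_donor = lactate_donor)
  for (nm in names(vals)) check_scalar_number(vals[[nm]], nm, min = 0, strict = TRUE)
  structure(vals, class = "eeq_coefficients")
}

#' Electron equivalents added by the lactate donor
#'
#' @param donor_mM Donor concentration in mM (>= 0).
#' @param volume_L Aqueous volume in L (> 0); the default microcosm holds
#'   0.015 L (15 g soil at 1:1 w/v).
#' @param coeff An [eeq_coefficients()] object.
#' @return Millimoles of electron equivalents added.
#' @examples
#' eeq_added(20, 0.015)  # 3.6 mmol eeq
#' @export
eeq_added <- function(donor_mM, volume_L = 0.015, coeff = eeq_coefficients()) {
  donor_mM <- check_scalar_number(donor_mM, "donor_mM", min = 0)
  volume_L <- check_scalar_number(volume_L, "volume_L", min = 0, strict = TRUE)
  donor_mM * volume_L * coeff$lactate_donor
}

#' Electron equivalents consumed by an inorganic reduction pathway
#'
#' Linear in the amount reduced: `mmol * eeq-per-mol`.
#'
#' @param moles_reduced_mmol Millimoles of acceptor reduced (>= 0, vectorised).
#' @param pathway One of `"fe3"`, `"no3"`, `"so4"` (recycled against the
#'   amounts).
#' @inheritParams eeq_added
#' @return Millimoles of electron equivalents.
#' @examples
#' pathway_eeq(0.075, "no3")  # 0.375 mmol eeq for full reduction of 5 mM
#'                            # nitrate in 0.015 L
#' @export
pathway_eeq <- function(moles_reduced_mmol, pathway, coeff = eeq_coefficients()) {
  if (!is.numeric(moles_reduced_mmol) || any(!is.finite(moles_reduced_mmol)) ||
      any(moles_reduced_mmol < 0)) {
    abort("`moles_reduced_mmol` must be finite and >= 0",
          class = "pcpredox_invalid_argument")
  }
  if (!all(pathway %in% c("fe3", "no3", "so4"))) {
    abort("`pathway` must be one of \"fe3\", \"no3\", \"so4\"",
          class = "pcpredox_invalid_argument")
  }
  moles_reduced_mmol * unlist(coeff[pathway], use.names = FALSE)
}

congener_profile_cl <- function(profile) {
  if (length(profile) == 0L) return(c(cl = 0, skeleton = 0))
  if (is.null(names(profile)) || any(names(profile) == "")) {
    abort("congener profiles must be named numeric vectors (name -> mmol)",
          class = "pcpredox_invalid_argument")
  }
  if (any(!is.finite(profile)) || any(profile < 0)) {
    abort("congener amounts must be finite and >= 0",
          class = "pcpredox_invalid_argument")
  }
  n_cl <- vapply(names(profile), function(nm) length(parse_congener(nm)),
                 numeric(1))
  c(cl = sum(n_cl * profile), skeleton = sum(profile))
}

#' Electron equivalents consumed by reductive dechlorination
#'
#' Compares the chlorine inventory of an initial and a final congener profile.
#' In the default `"per_chlorine"` mode each chlorine removed costs 2 eeq, so
#' PCP fully converted to 3-CP costs 4 x 2 = 8 eeq per mol. The alternative
#' `"per_mol"` mode charges 2 eeq per mol of parent transformed regardless of
#' the number of chlorines removed (a literal per-acceptor reading); the two
#' modes differ by the mean number of chlorines removed.
#'
#' The phenol skeleton is conserved by dechlorination alone, so the total
#' moles of the two profiles must agree within `tol`.
#'
#' @param initial_profile,final_profile Named numeric vectors mapping congener
#'   names to mmol.
#' @param coeff An [eeq_coefficients()] object.
#' @param mode `"per_chlorine"` (default) or `"per_mol"`.
#' @param tol Relative tolerance for the skeleton mole balance (default 1e-6).
#' @return Millimoles of electron equivalents, never negative for a conserved
#'   skeleton undergoing only dechlorination.
#' @examples
#' dechlorination_eeq(c(PCP = 1), c(`3-CP` = 1))        # 8 mmol eeq
#' dechlorination_eeq(c(PCP = 0.00225), c(`3-CP` = 0.00225))  # 0.018
#' @export
dechlorination_eeq <- function(initial_profile, final_profile,
                               coeff = eeq_coefficients(),
                               mode = c("per_chlorine", "per_mol"),
                               tol = 1e-6) {
  mode <- match.arg(mode)
  ini <- congener_profile_cl(initial_profile)
  fin <- congener_profile_cl(final_profile)
  scale <- max(ini[["skeleton"]], fin[["skeleton"]], 1e-12)
  if (abs(ini[["skeleton"]] - fin[["skeleton"]]) > tol * scale) {
    abort(paste0("phenol-skeleton moles not conserved: initial ",
                 signif(ini[["skeleton"]], 6), " vs final ",
                 signif(fin[["skeleton"]], 6), " mmol"),
          class = "pcpredox_mass_balance")
  }
  cl_removed <- ini[["cl"]] - fin[["cl"]]
  if (cl_removed < -tol * max(ini[["cl"]], 1e-12)) {
    abort("final profile carries more chlorine than the initial profile",
          class = "pcpredox_mass_balance")
  }
  if (mode == "per_chlorine") {
    return(max(cl_removed, 0) * coeff$per_chlorine)
  }
  # literal per-acceptor reading: 2 eeq per mol of the most-chlorinated
  # initial congener (the parent, e.g. PCP) transformed to anything lighter
  n_cl_ini <- vapply(names(initial_profile), function(nm)
    length(parse_congener(nm)), numeric(1))
  parent <- names(initial_profile)[n_cl_ini == max(n_cl_ini)]
  parent_final <- sum(final_profile[names(final_profile) %in% parent])
  transformed <- max(sum(initial_profile[parent]) - parent_final, 0)
  transformed * coeff$per_chlorine
}

#' Assemble an electron-equivalent ledger
#'
#' Bundles donor equivalents added and per-pathway equivalents consumed into
#' one tidy row per treatment, with an exact total.
#'
#' @param treatment_id Treatment label.
#' @param added_mmol Donor eeq added (mmol), e.g. from [eeq_added()].
#' @param fe3,no3,so4,dechlorination Per-pathway eeq consumed (mmol, >= 0).
#' @return A tibble of class `eeq_ledger` with columns `treatment_id`,
#'   `added_mmol`, the four pathways, `total_consumed_mmol` (exact sum) and
#'   `fraction_of_added`.
#' @examples
#' build_ledger("control", added_mmol = 3.60,
#'              fe3 = 1.65, no3 = 0, so4 = 0.72, dechlorination = 0.021)
#' @export
build_ledger <- function(treatment_id, added_mmol, fe3, no3, so4,
                         dechlorination) {
  vals <- list(added_mmol = added_mmol, fe3 = fe3, no3 = no3, so4 = so4,
               dechlorination = dechlorination)
  for (nm in names(vals)) check_scalar_number(vals[[nm]], nm, min = 0)
  total <- fe3 + no3 + so4 + dechlorination
  out <- tibble::tibble(
    treatment_id = as.character(treatment_id),
    added_mmol = added_mmol,
    fe3 = fe3, no3 = no3, so4 = so4, dechlorination = dechlorination,
    total_consumed_mmol = total,
    fraction_of_added = if (added_mmol > 0) total / added_mmol else NA_real_
  )
  class(out) <- c("eeq_ledger", class(out))
  out
}

#' Fraction of the added equivalents routed through one pathway
#'
#' @param ledger An `eeq_ledger` tibble (one or more rows).
#' @param pathway One of `"fe3"`, `"no3"`, `"so4"`, `"dechlorination"`.
#' @return Numeric vector `consumed / added` per row.
#' @export
eeq_fraction <- function(ledger, pathway) {
  stopifnot(inherits(ledger, "eeq_ledger"))
  if (!pathway %in% c("fe3", "no3", "so4", "dechlorination")) {
    abort("unknown pathway", class = "pcpredox_invalid_argument")
  }
  ledger[[pathway]] / ledger$added_mmol
}

#' Build a ledger table from a tidy per-pathway table
#'
#' @param data Data frame with columns `treatment_id`, `pathway` (fe3 / no3 /
#'   so4 / dechlorination) and `mmol` (eeq consumed).
#' @param added_mmol Donor eeq added per treatment (single value recycled, or
#'   a named vector by treatment).
#' @return An `eeq_ledger` tibble, one row per treatment.
#' @export
ledger_from_table <- function(data, added_mmol) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("treatment_id", "pathway", "mmol"))
  bad <- setdiff(unique(data$pathway), c("fe3", "no3", "so4", "dechlorination"))
  if (length(bad) > 0L) {
    abort(paste0("unknown pathway(s): ", paste(bad, collapse = ", ")),
          class = "pcpredox_invalid_argument")
  }
  wide <- data |>
    dplyr::summarise(mmol = sum(.data$mmol), .by = c("treatment_id", "pathway")) |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "mmol",
                       values_fill = 0)
  for (p in c("fe3", "no3", "so4", "dechlorination")) {
    if (is.null(wide[[p]])) wide[[p]] <- 0
  }
  rows <- purrr::pmap(wide, function(treatment_id, fe3, no3, so4,
                                     dechlorination, ...) {
    added <- if (length(added_mmol) > 1L) added_mmol[[treatment_id]] else added_mmol
    build_ledger(treatment_id, added, fe3, no3, so4, dechlorination)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eeq_ledger", class(out))
  out
}

#' @rdname build_ledger
#' @param object An `eeq_ledger`.
#' @param ... Unused.
#' @export
autoplot.eeq_ledger <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("fe3", "no3", "so4", "dechlorination"),
    names_to = "pathway", values_to = "mmol")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment_id, y = .data$mmol,
                                     fill = .data$pathway)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      mapping = ggplot2::aes(x = .data$treatment_id, y = .data$added_mmol),
      inherit.aes = FALSE, shape = 95, size = 8) +
    ggplot2::labs(x = NULL, y = "Electron equivalents (mmol)",
                  caption = "dash = donor eeq added") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
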