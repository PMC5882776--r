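test_that("config validation happens before any generation", {
  expect_error(microcosm_config(), class = "pcpredox_invalid_config")
  expect_error(microcosm_config(seed = 1.5), class = "pcpredox_invalid_config")
  expect_error(microcosm_config(seed = 1, sulfate_mM = -5),
               class = "pcpredox_invalid_argument")
  expect_error(microcosm_config(seed = 1, replicates = 0),
               class = "pcpredox_invalid_config")
  expect_error(microcosm_config(seed = 1, sampling_days = c(3, 0)),
               class = "pcpredox_invalid_config")
  expect_error(generate_microcosm(list(seed = 1)),
               class = "pcpredox_invalid_config")
})

test_that("identical config and seed regenerate identical datasets", {
  cfg <- microcosm_config(seed = 123, sulfate_mM = 5)
  d1 <- generate_microcosm(cfg)
  d2 <- generate_microcosm(cfg)
  expect_identical(d1$samples, d2$samples)
  d3 <- generate_microcosm(microcosm_config(seed = 124, sulfate_mM = 5))
  expect_false(identical(d1$samples, d3$samples))
})

test_that("noiseless sulfate decrement equals the truth logistic exactly", {
  cfg <- microcosm_config(seed = 1, noise_cv = 0)
  ds <- generate_microcosm(cfg)
  truth <- ds$truth
  sulf <- dplyr::filter(ds$samples, analyte == "sulfate", replicate == "r1")
  dec <- truth$sulfate_pool_mM - sulf$concentration
  p <- logistic_params(truth$sulfate$a, truth$sulfate$b, truth$sulfate$k)
  expect_equal(dec, logistic_value(p, sulf$time_d), tolerance = 1e-12)
  fe <- dplyr::filter(ds$samples, analyte == "fe2", replicate == "r1")
  pf <- logistic_params(truth$fe2$a, truth$fe2$b, truth$fe2$k)
  expect_equal(fe$concentration, logistic_value(pf, fe$time_d),
               tolerance = 1e-12)
})

test_that("the schema covers analytes x days x replicates with correct units", {
  ds <- generate_microcosm(microcosm_config(seed = 2, nitrate_mM = 5))
  n_analytes <- length(unique(ds$samples$analyte))
  expect_equal(n_analytes, 8L)  # nitrate, sulfate, fe2, pcp + 4 metabolites
  expect_equal(nrow(ds$samples), n_analytes * 7L * 3L)
  units <- dplyr::distinct(ds$samples, analyte, unit)
  expect_equal(units$unit[units$analyte == "sulfate"], "mM")
  expect_equal(units$unit[units$analyte == "pcp"], "uM")
  expect_true(all(ds$samples$concentration >= 0))
})

test_that("nitrate depletes by day 3, before sulfate reaches half capacity", {
  ds <- generate_microcosm(microcosm_config(seed = 7, nitrate_mM = 10))
  truth <- ds$truth
  per_rep <- ds$samples |>
    dplyr::filter(analyte %in% c("nitrate", "sulfate")) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "concentration",
                       id_cols = c("replicate", "time_d"))
  for (r in unique(per_rep$replicate)) {
    d <- dplyr::filter(per_rep, replicate == r)
    t_no3_gone <- min(d$time_d[d$nitrate <= 1e-9])
    expect_lte(t_no3_gone, truth$nitrate_depletion_day)
    dec_at_gone <- truth$sulfate_pool_mM - d$sulfate[d$time_d == t_no3_gone]
    expect_lt(dec_at_gone, 0.5 * truth$sulfate$a)
  }
})

test_that("molybdate caps the sulfate reduction at the ceiling fraction", {
  ds <- generate_microcosm(microcosm_config(seed = 4, molybdate_mM = 20,
                                            noise_cv = 0))
  truth <- ds$truth
  expect_equal(truth$sulfate$a,
               truth$molybdate_ceiling_fraction * truth$sulfate_pool_mM)
  sulf <- dplyr::filter(ds$samples, analyte == "sulfate", replicate == "r1")
  max_dec <- max(truth$sulfate_pool_mM - sulf$concentration)
  expect_lte(max_dec, truth$molybdate_ceiling_fraction * truth$sulfate_pool_mM)
})

test_that("chlorine is conserved exactly in the noiseless congener block", {
  ds <- generate_microcosm(microcosm_config(seed = 5, noise_cv = 0))
  species <- ds$truth$chain_species
  wide <- ds$samples |>
    dplyr::filter(replicate == "r1",
                  analyte %in% c("pcp", species)) |>
    dplyr::mutate(congener = ifelse(analyte == "pcp", "PCP", analyte)) |>
    tidyr::pivot_wider(id_cols = "time_d", names_from = "congener",
                       values_from = "concentration")
  mat <- as.matrix(wide[species])
  bal <- chlorine_balance(mat, species)
  expect_equal(bal$bound_cl_uM + bal$released_cl_uM,
               rep(5 * 150, nrow(mat)), tolerance = 1e-9)
})

test_that("the truth-trajectory electron budget stays within the donor pool", {
  ds <- generate_microcosm(microcosm_config(seed = 6, noise_cv = 0))
  truth <- ds$truth
  cfg <- ds$config
  added <- eeq_added(cfg$lactate_mM, cfg$water_L)
  fe_final <- dplyr::filter(ds$samples, analyte == "fe2",
                            replicate == "r1", time_d == 40)$concentration
  sulf_final <- dplyr::filter(ds$samples, analyte == "sulfate",
                              replicate == "r1", time_d == 40)$concentration
  consumed <-
    pathway_eeq(fe_final * cfg$water_L, "fe3") +
    pathway_eeq((truth$sulfate_pool_mM - sulf_final) * cfg$water_L, "so4") +
    dechlorination_eeq(
      c(PCP = cfg$pcp0_uM * cfg$water_L / 1000),
      c(`3-CP` = cfg$pcp0_uM * cfg$water_L / 1000))
  expect_lt(consumed, added)
})

test_that("noiseless recovery is essentially exact and truth is required", {
  ds <- generate_microcosm(microcosm_config(seed = 8, noise_cv = 0))
  report <- truth_recovery_report(ds)
  expect_true(all(report$rel_error < 1e-4))
  expect_equal(attr(report, "pathway_classes"),
               c("ortho", "ortho", "para", "meta"))
  stripped <- ds
  stripped$truth <- NULL
  expect_error(truth_recovery_report(stripped),
               class = "pcpredox_missing_truth")
})

test_that("noisy recovery keeps a within 5% and k within 10% of truth", {
  ds <- generate_microcosm(microcosm_config(seed = 9))
  report <- truth_recovery_report(ds)
  a_rows <- report[report$parameter == "a", ]
  k_rows <- report[report$parameter == "k", ]
  expect_true(all(a_rows$rel_error < 0.05))
  expect_true(all(k_rows$rel_error < 0.10))
  expect_equal(attr(report, "pathway_classes"),
               c("ortho", "ortho", "para", "meta"))
})

test_that("sulfate amendment slows the fitted PCP dechlorination", {
  # direction check on a handful of seeds; the acceptance suite runs 100
  slower <- vapply(1:10, function(seed) {
    fits <- lapply(c(0, 20), function(s_mM) {
      ds <- generate_microcosm(microcosm_config(seed = seed, sulfate_mM = s_mM))
      pcp <- ds$samples |>
        dplyr::filter(analyte == "pcp") |>
        dplyr::summarise(concentration = mean(concentration), .by = "time_d")
      fit_logistic(to_decrement(pcp, baseline = max(pcp$concentration)))
    })
    fits[[2]]$t_vmax > fits[[1]]$t_vmax
  }, logical(1))
  expect_true(all(slower))
})
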