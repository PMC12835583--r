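# Clinical-summary ingestion, pressure-estimate chain, baseline parameter
# formulas, and calibration bounds.

test_that("pressure estimates implement the initialization chain", {
  cs <- clinical_summary(HR = 70, CO = 5, PAWP = 12, mPAP = 24,
                         sPAP = 40, dPAP = 16, RAP = 6)
  pe <- derive_pressure_estimates(cs)
  expect_equal(pe[["P_MeanPA"]], 24)            # (2*16 + 40)/3
  expect_equal(pe[["P_SysRV"]], 40.5)           # sPAP + 0.5
  expect_equal(pe[["P_DiaRV"]], 2)
  expect_equal(pe[["P_MeanLA"]], 12)            # min(PAWP, dPAP)
  expect_equal(pe[["P_Grad"]], 12)
  expect_equal(pe[["P_MeanPC"]], 24 - 0.3 * 12)
  expect_equal(pe[["P_MeanPV"]], 24 - 0.6 * 12)
  expect_equal(pe[["P_MeanRA"]], 6)

  # min() branch of the LA estimate
  cs2 <- clinical_summary(HR = 70, CO = 5, PAWP = 12, mPAP = 20,
                          sPAP = 40, dPAP = 10)
  expect_equal(derive_pressure_estimates(cs2)[["P_MeanLA"]], 10)

  # chained arithmetic example: grad 20 split 30/30/40
  cs3 <- clinical_summary(HR = 70, CO = 5, PAWP = 10, mPAP = 30,
                          sPAP = 50, dPAP = 20, RAP = 8)
  pe3 <- derive_pressure_estimates(cs3)
  expect_equal(pe3[["P_Grad"]], 20)
  expect_equal(pe3[["P_MeanPC"]], 24)
  expect_equal(pe3[["P_MeanPV"]], 18)
})

test_that("sPAP/dPAP imputation preserves the mean-pressure estimate", {
  cs <- clinical_summary(HR = 68, CO = 4, PAWP = 12, mPAP = 38)
  expect_equal(cs$dPAP, 0.6 * 38)
  expect_equal((2 * cs$dPAP + cs$sPAP) / 3, 38)
  expect_true(cs$dPAP < cs$mPAP && cs$mPAP < cs$sPAP)
})

test_that("baseline parameters implement every initialization formula", {
  # subject #1-like record: CO 4.0 L/min at HR 68
  cs <- clinical_summary(HR = 68, CO = 4.0, PAWP = 12, mPAP = 38,
                         RAP = 9, cohort = "Pre-cap")
  pe <- derive_pressure_estimates(cs)
  p <- build_initial_parameters(cs, pe)
  SV <- 4000 / 68
  co <- 4000 / 60
  expect_equal(SV, 58.8, tolerance = 1e-3)
  expect_equal(p[["V0_PA"]], 0.23 * SV)  # 13.5 mL
  expect_equal(p[["V0_PC"]], 0.49 * SV)  # 28.8 mL
  expect_equal(p[["V0_PV"]], 0.28 * SV)  # 16.5 mL
  expect_equal(p[["V0_PA"]], 13.5, tolerance = 0.05)
  expect_equal(p[["V0_PC"]], 28.8, tolerance = 0.05)
  expect_equal(p[["V0_PV"]], 16.5, tolerance = 0.05)

  # one expression per parameter row
  expect_equal(p[["Rval_T"]], (pe[["P_MeanRA"]] - pe[["P_DiaRV"]]) / co)
  expect_equal(p[["Rval_P"]], 0.5 / co)
  expect_equal(p[["R_PA"]], (pe[["P_MeanPA"]] - pe[["P_MeanPC"]]) / co)
  expect_equal(p[["R_PC"]], (pe[["P_MeanPC"]] - pe[["P_MeanPV"]]) / co)
  expect_equal(p[["R_PV"]], (pe[["P_MeanPV"]] - pe[["P_MeanLA"]]) / co)
  expect_equal(p[["C_PA"]], p[["V0_PA"]] / pe[["P_MeanPA"]])
  expect_equal(p[["C_PC"]], p[["V0_PC"]] / pe[["P_MeanPC"]])
  expect_equal(p[["C_PV"]], p[["V0_PV"]] / pe[["P_MeanPV"]])
  expect_equal(p[["Emax"]], pe[["P_SysRV"]] / (120 - SV))
  expect_equal(p[["Emin"]], 2 / 120)
  expect_equal(p[["P_RA"]], 9)
  expect_equal(p[["P_LA"]], pe[["P_MeanLA"]])

  # timing at fixed cycle fractions
  cs60 <- clinical_summary(HR = 60, CO = 5, PAWP = 10, mPAP = 25)
  p60 <- build_initial_parameters(cs60)
  expect_equal(p60[["T"]], 1.0)
  expect_equal(p60[["tmax"]], 0.2)
  expect_equal(p60[["tmin"]], 0.5)
})

test_that("pulmonic valve resistance follows the +0.5 mmHg convention", {
  cs <- clinical_summary(HR = 60, CO = 5, PAWP = 10, mPAP = 25)
  p <- build_initial_parameters(cs)
  expect_equal(p[["Rval_P"]], 0.5 / (5000 / 60), tolerance = 1e-10)
  expect_equal(p[["Rval_P"]], 0.006, tolerance = 1e-3)
})

test_that("non-positive derived resistances are clamped with a warning", {
  cs <- clinical_summary(HR = 70, CO = 5, PAWP = 12, mPAP = 24, RAP = 1)
  expect_warning(p <- build_initial_parameters(cs), "clamped")
  expect_equal(p[["Rval_T"]], 1e-4)
})

test_that("bounds span 1% to 600% of baseline with fixed timing fractions", {
  theta0 <- c(Rval_T = 0.05, R_PA = 0.2, R_PC = 0.07, R_PV = 0.09,
              C_PA = 0.6, Emax = 0.5, Emin = 0.02, tmax = 0.2, tmin = 0.5)
  b <- build_bounds(theta0, T = 1.0)
  expect_equal(unname(b$lower[["R_PA"]]), 0.002)
  expect_equal(unname(b$upper[["R_PA"]]), 1.2)
  expect_equal(unname(b$lower[["tmax"]]), 0.05)
  expect_equal(unname(b$upper[["tmax"]]), 0.35)
  expect_equal(unname(b$lower[["tmin"]]), 0.35)
  expect_equal(unname(b$upper[["tmin"]]), 0.70)
  # baseline strictly interior except timing
  nt <- setdiff(names(theta0), c("tmax", "tmin"))
  expect_true(all(theta0[nt] > b$lower[nt] & theta0[nt] < b$upper[nt]))
  # zero baselines rejected
  expect_error(build_bounds(c(theta0, X = 0), T = 1.0), "zero")
})

test_that("initialization round trip is a consistent coarse start across the cohort", {
  # the printed resistance formulas distribute the atrial gradient over the
  # whole cycle while filling spans about half of it, so the uncalibrated
  # model systematically under-delivers flow; the start must still be
  # consistent (same-signed, bounded deficit) for every subject
  rel <- vapply(study_cohort(), function(cs) {
    p0 <- build_initial_parameters(cs)
    sim <- simulate_circulation(p0, grid_n = 100)
    (mean(sim$Q_val_P[-length(sim$t)]) * 60 / 1000 - cs$CO) / cs$CO
  }, numeric(1))
  expect_true(all(rel < 0))          # systematic deficit, never excess
  expect_true(all(abs(rel) < 0.45))  # bounded for every subject
  expect_lt(diff(range(rel)), 0.15)  # consistent across phenotypes
})
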