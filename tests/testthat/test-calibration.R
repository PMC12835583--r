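# Waveform preparation, cost arithmetic, R-squared, and the bounded
# multi-start fit.

make_patient_setup <- function(ph = "Pre-cap", seed = 42, noise = zero_noise,
                               Nt = 100) {
  pt <- generate_patient(phenotype_preset(ph), seed = seed, noise = noise)
  data <- prepare_waveforms(pt$pressure_obs, pt$flow_obs, Nt = Nt)
  list(pt = pt, data = data,
       theta_true = theta_from_parameters(pt$truth),
       bounds = build_bounds(theta_from_parameters(pt$truth),
                             pt$truth[["T"]]))
}

test_that("waveform resampling is idempotent and extracts static anchors", {
  Tc <- 0.8
  tg <- seq(0, Tc, length.out = 101)[1:100]
  pv <- 20 + 10 * sin(2 * pi * tg / Tc)
  qv <- pmax(0, 300 * sin(2 * pi * tg / Tc))
  d <- prepare_waveforms(waveform_series(tg, pv, "pressure", T = Tc),
                         waveform_series(tg, qv, "flow", T = Tc), Nt = 100)
  expect_equal(d$P, pv)
  expect_equal(d$Q, qv)
  expect_equal(d$P_max, max(pv))
  expect_equal(d$P_min, min(pv))
  expect_equal(d$Q_max, max(qv))

  # near-constant series survives resampling unchanged
  cv <- rep(15, 100) + 1e-9 * tg
  d2 <- prepare_waveforms(waveform_series(tg, cv, "pressure", T = Tc),
                          waveform_series(tg, qv, "flow", T = Tc), Nt = 50)
  expect_equal(max(d2$P), min(d2$P), tolerance = 1e-9)

  # cycle-length mismatch beyond 2% is rejected
  expect_error(
    prepare_waveforms(waveform_series(tg, pv, "pressure", T = Tc),
                      waveform_series(tg, qv, "flow", T = 1.1 * Tc)),
    "mismatch")
})

test_that("resampling error of a smooth wave obeys the interpolation bound", {
  Tc <- 1
  n <- 40
  tg <- seq(0, Tc, length.out = n + 1)[1:n]
  f <- function(t) 10 + 5 * sin(2 * pi * t)
  w <- waveform_series(tg, f(tg), "pressure", T = Tc)
  q <- waveform_series(tg, pmax(0.1, f(tg)), "flow", T = Tc)
  d <- prepare_waveforms(w, q, Nt = 2 * n)
  h <- Tc / n
  bound <- h^2 / 8 * 5 * (2 * pi)^2   # h^2 max|f''| / 8
  inside <- d$t <= max(tg)            # exclude the extrapolated tail
  expect_lt(max(abs(d$P[inside] - f(d$t[inside]))), bound * 1.0001)
})

test_that("R-squared matches its definition and hand example", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(rep(2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_lt(r_squared(c(10, -10, 10), c(1, 2, 3)), 0)
  expect_error(r_squared(c(1, 2), c(2, 2)), "zero-variance")
})

test_that("cost is zero at the generating parameters and equals the residual norm", {
  su <- make_patient_setup(seed = 7)
  J <- calibration_cost(su$theta_true, su$data, su$pt$truth, grid_n = 200)
  expect_lt(J, 1e-10)
  res <- calibration_residuals(su$theta_true, su$data, su$pt$truth,
                               grid_n = 200)
  expect_length(res, 2 * su$data$Nt + 3)
  expect_equal(J, sum(res^2))

  # equivalence at a perturbed point too
  th <- su$theta_true * c(1.2, 0.9, 1.1, 1, 1, 1.05, 1, 1, 1)
  expect_equal(calibration_cost(th, su$data, su$pt$truth, grid_n = 100),
               sum(calibration_residuals(th, su$data, su$pt$truth,
                                         grid_n = 100)^2),
               tolerance = 1e-12)
})

test_that("dynamic-term weighting keeps the cost stable under grid refinement", {
  pt <- generate_patient(phenotype_preset("Pre-cap"), seed = 7,
                         noise = zero_noise)
  th <- theta_from_parameters(pt$truth) *
    c(1.2, 0.9, 1.1, 1, 1, 1.05, 1, 1, 1)
  d50 <- prepare_waveforms(pt$pressure_obs, pt$flow_obs, Nt = 50)
  d100 <- prepare_waveforms(pt$pressure_obs, pt$flow_obs, Nt = 100)
  J50 <- calibration_cost(th, d50, pt$truth, grid_n = 100)
  J100 <- calibration_cost(th, d100, pt$truth, grid_n = 100)
  expect_equal(J50, J100, tolerance = 0.05)
})

test_that("a failed simulation maps to the finite penalty cost", {
  su <- make_patient_setup(seed = 7, Nt = 50)
  res <- calibration_residuals(su$theta_true, su$data, su$pt$truth,
                               n_cycles = 1)  # invalid, simulation errors
  expect_equal(sum(res^2), 1e6)
  expect_true(all(is.finite(res)))
})

test_that("self-calibration from the truth start converges immediately", {
  su <- make_patient_setup(seed = 3)
  fit <- calibrate_patient(su$data, su$theta_true, su$bounds, su$pt$truth,
                           n_starts = 1, seed = 1, grid_n = 200)
  expect_lt(fit$cost, 1e-8)
  expect_equal(fit$R2_pressure, 1, tolerance = 1e-6)
  expect_equal(fit$R2_flow, 1, tolerance = 1e-6)
  expect_equal(unname(fit$theta_hat), unname(su$theta_true),
               tolerance = 1e-3)
})

test_that("multi-start calibration is reproducible and respects bounds", {
  su <- make_patient_setup(seed = 5, noise = mult_noise())
  fit1 <- calibrate_patient(su$data, su$theta_true, su$bounds, su$pt$truth,
                            n_starts = 3, seed = 11, grid_n = 100)
  fit2 <- calibrate_patient(su$data, su$theta_true, su$bounds, su$pt$truth,
                            n_starts = 3, seed = 11, grid_n = 100)
  expect_identical(fit1$theta_hat, fit2$theta_hat)
  expect_identical(fit1$starts$cost, fit2$starts$cost)
  expect_true(all(fit1$theta_hat >= su$bounds$lower - 1e-12))
  expect_true(all(fit1$theta_hat <= su$bounds$upper + 1e-12))
  # the reported best is the per-start minimum and never worse than start 1
  expect_equal(fit1$cost, min(fit1$starts$cost, na.rm = TRUE))
  expect_lte(fit1$cost, fit1$starts$cost[1])
  expect_equal(nrow(fit1$starts), 3)

  fit3 <- calibrate_patient(su$data, su$theta_true, su$bounds, su$pt$truth,
                            n_starts = 3, seed = 12, grid_n = 100)
  expect_false(identical(fit3$starts$cost, fit1$starts$cost))
})

test_that("theta0 outside the bounds is rejected", {
  su <- make_patient_setup(seed = 3, Nt = 50)
  bad <- su$theta_true
  bad[["R_PA"]] <- su$bounds$upper[["R_PA"]] * 2
  expect_error(
    calibrate_patient(su$data, bad, su$bounds, su$pt$truth),
    "outside bounds")
})
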