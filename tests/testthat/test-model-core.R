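# Forward model: elastance shape, pressure/flow algebra, conservation,
# steady-state behavior.

test_that("elastance satisfies its anchor points and periodicity", {
  p <- quick_params()
  Emin <- p[["Emin"]]; Emax <- p[["Emax"]]
  expect_equal(elastance(0, p), Emin)
  expect_equal(elastance(p[["tmax"]], p), Emax)
  # diastolic plateau
  expect_equal(elastance((p[["tmin"]] + p[["T"]]) / 2, p), Emin)
  # raised-cosine midpoint of the upstroke
  expect_equal(elastance(p[["tmax"]] / 2, p), (Emin + Emax) / 2)
  # bounded, continuous, periodic
  tt <- seq(0, 3 * p[["T"]], length.out = 601)
  E <- elastance(tt, p)
  expect_true(all(E >= Emin - 1e-12 & E <= Emax + 1e-12))
  expect_equal(elastance(tt, p), elastance(tt + p[["T"]], p))
  expect_lt(max(abs(diff(E))), (Emax - Emin) * 0.06)  # no jumps on a fine grid
})

test_that("compartment pressures follow the elastance and compliance relations", {
  p <- quick_params()
  s <- c(V_RV = 100, V_PA = p[["V0_PA"]], V_PC = p[["V0_PC"]] + 10,
         V_PV = 30)
  pr <- compartment_pressures(s, p[["tmax"]], p)
  expect_equal(pr[["P_PA"]], 0)  # unstressed volume, zero pressure
  expect_equal(pr[["P_RV"]], p[["Emax"]] * 100)
  expect_equal(pr[["P_PC"]], 10 / p[["C_PC"]])
})

test_that("valves gate backflow, vascular segments do not", {
  p <- quick_params()
  pr <- c(P_RV = 50, P_PA = 30, P_PC = 20, P_PV = 5)
  q <- junction_flows(pr, p)
  expect_equal(q[["Q_val_T"]], 0)  # systole: P_RV above P_RA blocks inflow
  expect_equal(q[["Q_val_P"]], (50 - 30) / p[["Rval_P"]])
  expect_equal(q[["Q_PA"]], (30 - 20) / p[["R_PA"]])
  # venous segment may run backwards (P_PV below LA pressure)
  expect_lt(q[["Q_PV"]], 0)
})

test_that("rhs conserves volume and matches hand-computed derivatives", {
  p <- algebra_params()
  s <- c(V_RV = 100, V_PA = 50, V_PC = 60, V_PV = 40)
  d <- circulation_rhs(0, s, p)[[1]]
  # frozen hand arithmetic: E(0)=0.1 -> P = (10, 20, 10, 10); both valves shut
  expect_equal(unname(d), c(0, -2, 2, -2.5))
  # telescoping conservation at random states
  set.seed(1)
  for (i in 1:25) {
    s <- c(V_RV = runif(1, 20, 300), V_PA = runif(1, 10, 120),
           V_PC = runif(1, 20, 150), V_PV = runif(1, 15, 100))
    t <- runif(1, 0, p[["T"]])
    d <- circulation_rhs(t, s, p)[[1]]
    pr <- compartment_pressures(s, t, p)
    q <- junction_flows(pr, p)
    expect_equal(sum(d), q[["Q_val_T"]] - q[["Q_PV"]])
  }
})

test_that("compiled and R right-hand sides agree", {
  p <- quick_params()
  sim <- simulate_circulation(p, n_cycles = 5, grid_n = 60)
  # reconstruct derivatives from the reported flows and compare with the R rhs
  set.seed(2)
  for (i in sample(seq_along(sim$t), 10)) {
    s <- sim$volumes[i, c("V_RV", "V_PA", "V_PC", "V_PV")]
    d <- circulation_rhs(sim$t[i], s, p)[[1]]
    expect_equal(unname(d[1]), sim$Q_val_T[i] - sim$Q_val_P[i],
                 tolerance = 1e-10)
    expect_equal(unname(d[3]), sim$Q_PA[i] - sim$Q_PC[i],
                 tolerance = 1e-10)
  }
})

test_that("simulation reaches a periodic steady state with conserved throughput", {
  p <- quick_params()
  sim <- simulate_circulation(p)
  expect_lt(sim$periodicity_error, 1e-3)
  ix <- seq_len(length(sim$t) - 1)
  # cycle-mean inflow equals cycle-mean outflow at steady state
  expect_equal(mean(sim$Q_val_T[ix]), mean(sim$Q_val_P[ix]),
               tolerance = 5e-3)
  expect_equal(mean(sim$Q_val_P[ix]), mean(sim$Q_PV[ix]), tolerance = 5e-3)
  # diode invariant on the reported traces
  expect_gte(min(sim$Q_val_T), 0)
  expect_gte(min(sim$Q_val_P), 0)
})

test_that("mean PA pressure rises with arterial resistance and Emax steers systole", {
  p <- quick_params()
  means <- vapply(seq(0.5, 2.5, length.out = 5), function(f) {
    s <- simulate_circulation(update_parameters(p, c(R_PA = p[["R_PA"]] * f)),
                              n_cycles = 25, grid_n = 100)
    mean(s$P_PA)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  # ESP rises with contractility over the moderate range; at very high
  # Emax it saturates (ejection becomes afterload-limited), so the strict
  # monotonicity is asserted on 0.5-1.5x while ESV falls throughout
  esp <- esv <- numeric(5)
  for (i in 1:5) {
    f <- seq(0.5, 1.5, length.out = 5)[i]
    s <- simulate_circulation(update_parameters(p, c(Emax = p[["Emax"]] * f)),
                              n_cycles = 25, grid_n = 100)
    m <- pv_loop_metrics(s, periodicity_tol = 1e-2)
    esp[i] <- m$ESP; esv[i] <- m$ESV
  }
  expect_true(all(diff(esp) > 0))
  expect_true(all(diff(esv) < 0))
})

test_that("weak ventricle with large compliances approaches the resistor-chain limit", {
  p <- quick_params()
  # nearly constant elastance and huge compliances: the circuit degenerates
  # to a resistor chain from the RA source to the LA source
  # RA source must sit above the LA source for the diodes to conduct in
  # the static limit
  p2 <- update_parameters(p, c(
    Emax = 0.0205, Emin = 0.02,
    C_PA = 500, C_PC = 500, C_PV = 500,
    P_RA = 12, P_LA = 5))
  sim <- simulate_circulation(p2, n_cycles = 400, grid_n = 50)
  Rsum <- sum(unclass(p2)[c("Rval_T", "Rval_P", "R_PA", "R_PC", "R_PV")])
  q_chain <- (p2[["P_RA"]] - p2[["P_LA"]]) / Rsum
  expect_equal(mean(sim$Q_PV), q_chain, tolerance = 0.05)
})

test_that("simulation rejects bad inputs and reports blow-ups", {
  p <- quick_params()
  expect_error(simulate_circulation(p, n_cycles = 1), "n_cycles")
  expect_error(update_parameters(p, c(Emin = 2 * p[["Emax"]])), "Emin")
  expect_error(update_parameters(p, c(tmax = 0.9 * p[["T"]])), "tmax")
  expect_error(
    simulate_circulation(p, pressure_ceiling = 10),
    "blow-up")
})

test_that("simulation traces round-trip through CSV", {
  p <- quick_params()
  sim <- simulate_circulation(p, n_cycles = 5, grid_n = 40)
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(sim, f)
  d <- utils::read.csv(f)
  expect_identical(names(d), c("t", "P_RV", "P_PA", "P_PC", "P_PV",
                               "Q_val_T", "Q_val_P", "Q_PA", "Q_PC",
                               "Q_PV", "V_RV"))
  expect_equal(d$P_PA, unname(sim$P_PA))
})

test_that("parameters serialize to flat JSON and back", {
  p <- quick_params()
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters_json(p, f)
  p2 <- read_parameters_json(f)
  expect_equal(unclass(p2), unclass(p))
  keys <- names(jsonlite::read_json(f))
  expect_true(all(c("Rval_T", "Emax", "T") %in% keys))
})
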