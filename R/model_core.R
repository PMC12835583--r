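# Forward model: time-varying elastance RV driving three Windkessel beds
# between constant atrial pressure sources, with diode valves.

#' Time-varying right ventricular elastance
#'
#' Piecewise raised-cosine activation: elastance rises from `Emin` at the
#' cycle start to `Emax` at `t = tmax`, relaxes back to `Emin` at `t = tmin`,
#' and stays on the diastolic plateau until the cycle ends. Continuous in
#' `t` and periodic with period `T`.
#'
#' @param t time, s; vectorized, interpreted modulo the cycle length.
#' @param p a [model_parameters()] object (uses `Emax`, `Emin`, `tmax`,
#'   `tmin`, `T`).
#' @return Elastance E(t), mmHg/mL, same length as `t`.
#' @examples
#' p <- example_parameters()
#' elastance(0, p)            # Emin
#' elastance(p[["tmax"]], p)  # Emax
#' @export
elastance <- function(t, p) {
  Emax <- p[["Emax"]]; Emin <- p[["Emin"]]
  tmax <- p[["tmax"]]; tmin <- p[["tmin"]]; Tc <- p[["T"]]
  tt <- t %% Tc
  E <- rep(Emin, length(tt))
  up <- tt <= tmax
  E[up] <- Emin + 0.5 * (Emax - Emin) * (1 - cos(pi * tt[up] / tmax))
  dn <- tt > tmax & tt <= tmin
  E[dn] <- Emin + 0.5 * (Emax - Emin) *
    (1 + cos(pi * (tt[dn] - tmax) / (tmin - tmax)))
  E
}

#' Compartment pressures from volumes
#'
#' The RV pressure follows the time-varying elastance relation
#' `P_RV = E(t) (V_RV - V0_RV)`; each vascular compartment is linearly
#' compliant, `P_i = (V_i - V0_i) / C_i`.
#'
#' @param state named numeric vector with `V_RV`, `V_PA`, `V_PC`, `V_PV`
#'   (mL).
#' @param t time within the cycle, s.
#' @param p a [model_parameters()] object.
#' @return Named numeric vector `P_RV`, `P_PA`, `P_PC`, `P_PV` (mmHg).
#' @export
compartment_pressures <- function(state, t, p) {
  c(P_RV = elastance(t, p) * (state[["V_RV"]] - p[["V0_RV"]]),
    P_PA = (state[["V_PA"]] - p[["V0_PA"]]) / p[["C_PA"]],
    P_PC = (state[["V_PC"]] - p[["V0_PC"]]) / p[["C_PC"]],
    P_PV = (state[["V_PV"]] - p[["V0_PV"]]) / p[["C_PV"]])
}

#' Junction flows from pressures
#'
#' Flow across each resistive junction follows the electrical analog
#' `Q = (P_up - P_down) / R`. The tricuspid and pulmonic valves are ideal
#' diodes: their flow is clamped at zero when the gradient reverses. The
#' vascular segments (PA->PC, PC->PV, PV->LA) are not gated, so venous
#' backflow toward the left atrium is permitted.
#'
#' @param pressures named numeric vector with `P_RV`, `P_PA`, `P_PC`, `P_PV`
#'   (mmHg).
#' @param p a [model_parameters()] object (supplies `P_RA`, `P_LA` and the
#'   resistances).
#' @return Named numeric vector `Q_val_T`, `Q_val_P`, `Q_PA`, `Q_PC`, `Q_PV`
#'   (mL/s).
#' @export
junction_flows <- function(pressures, p) {
  c(Q_val_T = max(0, (p[["P_RA"]] - pressures[["P_RV"]]) / p[["Rval_T"]]),
    Q_val_P = max(0, (pressures[["P_RV"]] - pressures[["P_PA"]]) / p[["Rval_P"]]),
    Q_PA = (pressures[["P_PA"]] - pressures[["P_PC"]]) / p[["R_PA"]],
    Q_PC = (pressures[["P_PC"]] - pressures[["P_PV"]]) / p[["R_PC"]],
    Q_PV = (pressures[["P_PV"]] - p[["P_LA"]]) / p[["R_PV"]])
}

#' Right-hand side of the circulation ODE system
#'
#' Volume conservation for the four dynamic compartments: each volume
#' changes at the rate inflow minus outflow. This is the reference R
#' implementation; [simulate_circulation()] integrates an identical
#' compiled version for speed.
#'
#' @param t time, s.
#' @param state named numeric vector `V_RV`, `V_PA`, `V_PC`, `V_PV` (mL).
#' @param p a [model_parameters()] object.
#' @return List of one numeric vector `dV/dt` (mL/s) in state order, as
#'   expected by [deSolve::ode()].
#' @export
circulation_rhs <- function(t, state, p) {
  pr <- compartment_pressures(state, t, p)
  q <- junction_flows(pr, p)
  list(c(V_RV = q[["Q_val_T"]] - q[["Q_val_P"]],
         V_PA = q[["Q_val_P"]] - q[["Q_PA"]],
         V_PC = q[["Q_PA"]] - q[["Q_PC"]],
         V_PV = q[["Q_PC"]] - q[["Q_PV"]]))
}

# Initial state: vascular compartments filled to their baseline working
# pressure (V0/C when V0 > 0, else the LA pressure), RV filled to a 2 mmHg
# diastolic pressure at Emin. The transient is discarded over n_cycles.
.initial_state <- function(p) {
  pinit <- function(v0, cc) if (v0 > 0) v0 / cc else max(p[["P_LA"]], 5)
  c(V_RV = p[["V0_RV"]] + 2 / p[["Emin"]],
    V_PA = p[["V0_PA"]] + p[["C_PA"]] * pinit(p[["V0_PA"]], p[["C_PA"]]),
    V_PC = p[["V0_PC"]] + p[["C_PC"]] * pinit(p[["V0_PC"]], p[["C_PC"]]),
    V_PV = p[["V0_PV"]] + p[["C_PV"]] * pinit(p[["V0_PV"]], p[["C_PV"]]))
}

#' Simulate the circulation to periodic steady state
#'
#' Integrates the four-compartment model with a stiff-capable adaptive
#' solver (lsoda) for `n_cycles` cardiac cycles and returns the final cycle
#' resampled on a uniform grid. The periodicity error reported is the
#' maximum relative change of any state volume between the start of the
#' penultimate and the final cycle.
#'
#' @param p a [model_parameters()] object.
#' @param n_cycles number of cardiac cycles to run before reading out the
#'   final one (default 40, enough for the transient from the generic
#'   initial state to decay).
#' @param grid_n number of uniform output points over the final cycle.
#' @param rtol,atol relative / absolute (mL) integrator tolerances.
#' @param gate_eps smooth-valve width, mmHg; `0` (default) uses the ideal
#'   hard diode, a positive value replaces it with a tanh gate of that
#'   width for integrator robustness studies.
#' @param pressure_ceiling abort threshold, mmHg: simulations whose RV or
#'   PA pressure exceeds this are treated as non-physiological blow-ups.
#' @param state0 optional named initial state (`V_RV`, `V_PA`, `V_PC`,
#'   `V_PV`, mL); defaults to a generic filled state.
#' @return An object of class `simulation_result`: list with the final-cycle
#'   time grid `t` (s, from 0), pressure traces `P_RV`, `P_PA`, `P_PC`,
#'   `P_PV` (mmHg), flow traces `Q_val_T`, `Q_val_P`, `Q_PA`, `Q_PC`,
#'   `Q_PV` (mL/s), volume trace `V_RV` (mL), plus `cycles_run`,
#'   `periodicity_error` and the parameters used.
#' @examples
#' sim <- simulate_circulation(example_parameters(), n_cycles = 10)
#' mean(sim$Q_val_P) * 60 / 1000  # cardiac output, L/min
#' @export
simulate_circulation <- function(p, n_cycles = 40, grid_n = 200,
                                 rtol = 1e-6, atol = 1e-6, gate_eps = 0,
                                 pressure_ceiling = 1000, state0 = NULL) {
  validate_parameters(p)
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  Tc <- p[["T"]]
  y0 <- if (is.null(state0)) .initial_state(p) else state0[c("V_RV", "V_PA", "V_PC", "V_PV")]
  times <- seq(0, n_cycles * Tc, by = Tc / grid_n)
  cparms <- c(unclass(p)[.param_fields], gate_eps)
  out <- try(deSolve::ode(
    y = unname(y0), times = times, func = "rvcirc_derivs", parms = cparms,
    dllname = "rvcirc", initfunc = "rvcirc_initmod",
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      any(!is.finite(out[, -1]))) {
    stop("integration failed for parameter vector: ",
         paste(sprintf("%s=%.4g", .param_fields, unclass(p)[.param_fields]),
               collapse = ", "))
  }

  i1 <- (n_cycles - 1) * grid_n + 1  # start of final cycle
  i0 <- (n_cycles - 2) * grid_n + 1  # start of penultimate cycle
  v_last <- out[i1, -1]
  v_prev <- out[i0, -1]
  periodicity_error <- max(abs(v_last - v_prev) / pmax(abs(v_prev), 1))

  idx <- i1:(i1 + grid_n)            # final cycle inclusive of both ends
  t_rel <- times[idx] - times[i1]
  V <- out[idx, -1, drop = FALSE]
  colnames(V) <- c("V_RV", "V_PA", "V_PC", "V_PV")

  P_RV <- elastance(t_rel, p) * (V[, "V_RV"] - p[["V0_RV"]])
  P_PA <- (V[, "V_PA"] - p[["V0_PA"]]) / p[["C_PA"]]
  P_PC <- (V[, "V_PC"] - p[["V0_PC"]]) / p[["C_PC"]]
  P_PV <- (V[, "V_PV"] - p[["V0_PV"]]) / p[["C_PV"]]
  if (max(P_RV, P_PA) > pressure_ceiling) {
    stop("non-physiological blow-up (pressure > ", pressure_ceiling,
         " mmHg) for parameter vector: ",
         paste(sprintf("%s=%.4g", .param_fields, unclass(p)[.param_fields]),
               collapse = ", "))
  }
  if (gate_eps > 0) {
    gT <- 0.5 * (1 + tanh((p[["P_RA"]] - P_RV) / gate_eps))
    gP <- 0.5 * (1 + tanh((P_RV - P_PA) / gate_eps))
    Q_val_T <- (p[["P_RA"]] - P_RV) / p[["Rval_T"]] * gT
    Q_val_P <- (P_RV - P_PA) / p[["Rval_P"]] * gP
  } else {
    Q_val_T <- pmax(0, (p[["P_RA"]] - P_RV) / p[["Rval_T"]])
    Q_val_P <- pmax(0, (P_RV - P_PA) / p[["Rval_P"]])
  }

  res <- list(
    t = t_rel,
    P_RV = P_RV, P_PA = P_PA, P_PC = P_PC, P_PV = P_PV,
    Q_val_T = Q_val_T, Q_val_P = Q_val_P,
    Q_PA = (P_PA - P_PC) / p[["R_PA"]],
    Q_PC = (P_PC - P_PV) / p[["R_PC"]],
    Q_PV = (P_PV - p[["P_LA"]]) / p[["R_PV"]],
    V_RV = V[, "V_RV"],
    volumes = V,
    cycles_run = n_cycles,
    periodicity_error = periodicity_error,
    parameters = p
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Circulation simulation, final cycle of", x$cycles_run, "\n")
  cat(sprintf("  T = %.3f s, %d grid points, periodicity error %.2e\n",
              x$parameters[["T"]], length(x$t), x$periodicity_error))
  cat(sprintf("  P_PA %.1f/%.1f (mean %.1f) mmHg, CO %.2f L/min\n",
              max(x$P_PA), min(x$P_PA), mean(x$P_PA),
              mean(x$Q_val_P) * 60 / 1000))
  invisible(x)
}

#' Scalar summaries of a simulated cycle
#'
#' Convenience extractor for the quantities used throughout calibration and
#' screening: cycle-mean / extreme PA pressure, peak and cycle-mean pulmonic
#' valve flow (the model counterparts of mPAP, sPAP/dPAP and RVOT flow),
#' and cardiac output in L/min.
#'
#' @param sim a `simulation_result`.
#' @return Named numeric vector.
#' @export
simulation_summary <- function(sim) {
  co <- mean(sim$Q_val_P) * 60 / 1000
  c(mean_P_PA = mean(sim$P_PA), max_P_PA = max(sim$P_PA),
    min_P_PA = min(sim$P_PA), peak_Q_val_P = max(sim$Q_val_P),
    CO = co, EDV = max(sim$V_RV), ESV = min(sim$V_RV))
}
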