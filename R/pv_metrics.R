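# RV pressure-volume loop metrics from a converged simulation.

#' Stroke work of the RV pressure-volume loop
#'
#' The time integral of instantaneous ventricular pressure times the rate
#' of volume change over one cycle, i.e. the area enclosed by the PV loop,
#' evaluated by trapezoidal quadrature on the periodic grid (volume rate
#' by central differences). The sign convention makes the physiological
#' traversal (filling at low pressure, ejection at high pressure)
#' positive; a time-reversed trace yields the negated value.
#'
#' @param x a `simulation_result`, or a numeric time vector when `P` and
#'   `V` are supplied explicitly.
#' @param P,V pressure (mmHg) and volume (mL) traces matching `x` when
#'   `x` is a time vector. A closed loop repeats its first sample last.
#' @param gap_tol warn when the loop fails to close: relative gap
#'   `|V(end) - V(start)|` / volume excursion above this triggers a
#'   warning.
#' @return List with `mL_mmHg` and `J` (1 mL·mmHg = 1.33322e-4 J).
#' @examples
#' sim <- simulate_circulation(example_parameters(), n_cycles = 15)
#' stroke_work(sim)$J
#' @export
stroke_work <- function(x, P = NULL, V = NULL, gap_tol = 0.05) {
  if (inherits(x, "simulation_result")) {
    t <- x$t; P <- x$P_RV; V <- x$V_RV
  } else {
    t <- x
    if (is.null(P) || is.null(V)) stop("P and V required with a time vector")
  }
  n <- length(t)
  if (n < 4) stop("need at least 4 samples")
  gap <- abs(V[n] - V[1]) / max(diff(range(V)), .Machine$double.eps)
  if (gap > gap_tol)
    warning(sprintf("open PV loop: relative closure gap %.3f", gap))
  # drop the duplicate closing sample and differentiate periodically
  tt <- t[-n]; Pp <- P[-n]; Vv <- V[-n]
  m <- length(tt)
  dt <- diff(t)[1]
  Vdot <- (Vv[c(2:m, 1)] - Vv[c(m, 1:(m - 1))]) / (2 * dt)
  sw <- -sum(Pp * Vdot) * dt   # positive for the physiological orientation
  list(mL_mmHg = sw, J = sw * 1.33322e-4)
}

#' PV-loop metrics of a converged cycle
#'
#' End-diastolic and end-systolic volume are the extrema of the RV volume
#' trace; the corresponding pressures are sampled at the same instants
#' (EDP at maximum volume, on the filling/ejection corner; ESP at minimum
#' volume). Stroke volume is their difference and stroke work the loop
#' area.
#'
#' @param sim a `simulation_result`.
#' @param periodicity_tol refuse simulations whose periodicity error
#'   exceeds this.
#' @param min_sv refuse degenerate (non-beating) cycles with volume
#'   excursion below this, mL.
#' @return List of class `pv_metrics`: `EDV`, `ESV`, `SV` (mL), `EDP`,
#'   `ESP` (mmHg), `SW_mL_mmHg`, `SW_J`.
#' @export
pv_loop_metrics <- function(sim, periodicity_tol = 1e-3, min_sv = 1) {
  stopifnot(inherits(sim, "simulation_result"))
  if (sim$periodicity_error > periodicity_tol)
    stop(sprintf("cycle not periodic (error %.2e > %.0e); run more cycles",
                 sim$periodicity_error, periodicity_tol))
  i_ed <- which.max(sim$V_RV)
  i_es <- which.min(sim$V_RV)
  EDV <- sim$V_RV[i_ed]; ESV <- sim$V_RV[i_es]
  if (EDV - ESV < min_sv)
    stop("degenerate (near-constant) volume trace; no PV loop")
  sw <- stroke_work(sim)
  out <- list(EDV = EDV, ESV = ESV, SV = EDV - ESV,
              EDP = sim$P_RV[i_ed], ESP = sim$P_RV[i_es],
              SW_mL_mmHg = sw$mL_mmHg, SW_J = sw$J)
  class(out) <- "pv_metrics"
  out
}

#' @export
print.pv_metrics <- function(x, ...) {
  cat(sprintf(
    "PV loop: EDV %.1f, ESV %.1f, SV %.1f mL; EDP %.2f, ESP %.2f mmHg; SW %.0f mL·mmHg (%.3f J)\n",
    x$EDV, x$ESV, x$SV, x$EDP, x$ESP, x$SW_mL_mmHg, x$SW_J))
  invisible(x)
}

#' Write the PV loop trace to CSV
#'
#' Header `V_RV,P_RV`, one row per grid point of the final cycle.
#'
#' @param sim a `simulation_result`.
#' @param path file path.
#' @export
write_pv_loop_csv <- function(sim, path) {
  utils::write.csv(data.frame(V_RV = sim$V_RV, P_RV = sim$P_RV), path,
                   row.names = FALSE)
  invisible(path)
}
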