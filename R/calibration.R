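# Waveform calibration: bounded multi-start least squares on the weighted
# pressure/flow residual, with static systolic/diastolic anchors.

#' Align pressure and flow waveforms on a common grid
#'
#' Linearly resamples a one-cycle PA pressure series and an RVOT flow
#' series to `Nt` uniform points over `[0, T)` (times re-based to start at
#' zero) and extracts the static anchors used by the cost function:
#' maximum and minimum pressure and maximum flow.
#'
#' @param pressure,flow [waveform_series()] objects spanning one cycle;
#'   their cycle lengths must agree within 2%.
#' @param Nt number of uniform samples.
#' @return List of class `calibration_data`: `t`, `P`, `Q`, `T`, `Nt`, and
#'   anchors `P_max`, `P_min`, `Q_max`.
#' @export
prepare_waveforms <- function(pressure, flow, Nt = 100) {
  stopifnot(inherits(pressure, "waveform_series"),
            inherits(flow, "waveform_series"))
  if (pressure$kind != "pressure" || flow$kind != "flow")
    stop("arguments must be a pressure and a flow waveform, in that order")
  if (abs(pressure$T - flow$T) / pressure$T > 0.02)
    stop(sprintf("cycle-length mismatch > 2%%: %.3f vs %.3f s",
                 pressure$T, flow$T))
  Tc <- (pressure$T + flow$T) / 2
  tg <- seq(0, Tc, length.out = Nt + 1)[1:Nt]
  P <- stats::approx(pressure$t - pressure$t[1], pressure$v, xout = tg,
                     rule = 2)$y
  Q <- stats::approx(flow$t - flow$t[1], flow$v, xout = tg, rule = 2)$y
  out <- list(t = tg, P = P, Q = Q, T = Tc, Nt = Nt,
              P_max = max(P), P_min = min(P), Q_max = max(Q))
  class(out) <- "calibration_data"
  out
}

# model P_PA / Q_val_P interpolated onto the data grid
.model_on_grid <- function(theta, data, fixed_p, n_cycles, grid_n) {
  p <- update_parameters(fixed_p, theta)
  sim <- simulate_circulation(p, n_cycles = n_cycles, grid_n = grid_n)
  list(P = stats::approx(sim$t, sim$P_PA, xout = data$t, rule = 2)$y,
       Q = stats::approx(sim$t, sim$Q_val_P, xout = data$t, rule = 2)$y,
       sim = sim)
}

#' Weighted residual vector of the calibration cost
#'
#' Each summand of the cost enters as one residual (its square root), so
#' the sum of squared residuals equals the scalar cost exactly: dynamic
#' pressure and flow residuals normalized by the data maxima and weighted
#' by `1/Nt`, plus static residuals on minimum/maximum pressure and
#' maximum flow, each normalized by its own data value and weighted by 2.
#' A failed simulation yields a constant penalty vector of total squared
#' magnitude `1e6`, keeping the optimizer finite inside the bounds.
#'
#' @param theta named influential subvector.
#' @param data a [prepare_waveforms()] result.
#' @param fixed_p full [model_parameters()] holding the non-calibrated
#'   entries.
#' @param W_static static-anchor weight (default 2).
#' @param n_cycles,grid_n simulation settings.
#' @return Numeric residual vector of length `2 Nt + 3`.
#' @export
calibration_residuals <- function(theta, data, fixed_p, W_static = 2,
                                  n_cycles = 40, grid_n = 100) {
  n_res <- 2 * data$Nt + 3
  m <- tryCatch(.model_on_grid(theta, data, fixed_p, n_cycles, grid_n),
                error = function(e) NULL)
  if (is.null(m)) return(rep(sqrt(1e6 / n_res), n_res))
  wd <- sqrt(1 / data$Nt)
  ws <- sqrt(W_static)
  c(wd * (m$P - data$P) / data$P_max,
    wd * (m$Q - data$Q) / data$Q_max,
    ws * (min(m$P) - data$P_min) / data$P_min,
    ws * (max(m$P) - data$P_max) / data$P_max,
    ws * (max(m$Q) - data$Q_max) / data$Q_max)
}

#' Scalar calibration cost
#'
#' The weighted least-squares cost: sum of squared
#' [calibration_residuals()].
#'
#' @inheritParams calibration_residuals
#' @return Scalar cost `J` (dimensionless).
#' @export
calibration_cost <- function(theta, data, fixed_p, W_static = 2,
                             n_cycles = 40, grid_n = 100) {
  sum(calibration_residuals(theta, data, fixed_p, W_static,
                            n_cycles, grid_n)^2)
}

#' Coefficient of determination between model and data traces
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the data
#' mean; can be negative for fits worse than the flat mean.
#'
#' @param model,data equal-length numeric traces.
#' @return Scalar R-squared.
#' @export
r_squared <- function(model, data) {
  if (length(model) != length(data)) stop("traces must have equal length")
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot == 0) stop("zero-variance data trace; R^2 undefined")
  1 - sum((data - model)^2) / ss_tot
}

#' Calibrate the influential parameters to one patient's waveforms
#'
#' Bounded Levenberg-Marquardt least squares on the residual form of the
#' calibration cost, restarted from the baseline and `n_starts - 1` random
#' perturbations of it (log-uniform multiplicative in `perturb_range` for
#' scale parameters, uniform within bounds for the activation timings),
#' all clipped to the bounds. The reported fit is the minimum-cost
#' converged start; the full per-start audit table is retained.
#'
#' @param data a [prepare_waveforms()] result.
#' @param theta0 named baseline subvector (see
#'   [theta_from_parameters()]).
#' @param bounds a [build_bounds()] result for `theta0`.
#' @param fixed_p full [model_parameters()] baseline.
#' @param n_starts number of optimization starts (first = unperturbed).
#' @param seed integer seed making the perturbations reproducible.
#' @param perturb_range multiplicative perturbation interval.
#' @param n_cycles,grid_n simulation settings during optimization.
#' @param maxit maximum optimizer iterations per start.
#' @return Object of class `calibration_result`: `theta_hat`, `cost`,
#'   `R2_pressure`, `R2_flow`, the fitted `parameters` and `sim`, the
#'   per-start data frame `starts`, `n_starts`, `seed`.
#' @export
calibrate_patient <- function(data, theta0, bounds, fixed_p,
                              n_starts = 20, seed = 1,
                              perturb_range = c(0.5, 2),
                              n_cycles = 40, grid_n = 100, maxit = 100) {
  stopifnot(inherits(data, "calibration_data"))
  if (any(theta0 < bounds$lower | theta0 > bounds$upper))
    stop("theta0 outside bounds")
  timing <- names(theta0) %in% c("tmax", "tmin")

  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- theta0
  for (s in seq_len(n_starts - 1)) {
    th <- theta0
    fac <- exp(stats::runif(length(th), log(perturb_range[1]),
                            log(perturb_range[2])))
    th[!timing] <- th[!timing] * fac[!timing]
    th[timing] <- stats::runif(sum(timing), bounds$lower[timing],
                               bounds$upper[timing])
    # keep tmax < tmin strictly when both sampled near the shared endpoint
    if (all(c("tmax", "tmin") %in% names(th)) && th[["tmax"]] >= th[["tmin"]])
      th[["tmin"]] <- min(bounds$upper[["tmin"]], th[["tmax"]] + 0.05 * fixed_p[["T"]])
    starts[[s + 1]] <- pmin(pmax(th, bounds$lower), bounds$upper)
  }

  # all calibrated parameters are positive scale or timing quantities, so
  # the optimizer works on log parameters: steps are multiplicative, the
  # bounds map cleanly, and near-zero collapse of weakly identified
  # entries (notably Emin) costs many log units instead of one step
  log_resid <- function(phi, ...) {
    calibration_residuals(stats::setNames(exp(phi), names(theta0)), ...)
  }
  fits <- vector("list", n_starts)
  audit <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = log(starts[[s]]),
        lower = log(bounds$lower), upper = log(bounds$upper),
        fn = log_resid, data = data, fixed_p = fixed_p,
        n_cycles = n_cycles, grid_n = grid_n,
        # epsfcn keeps the finite-difference Jacobian step (~1e-3
        # multiplicative) well above the ODE solver's adaptive-tolerance
        # noise
        control = minpack.lm::nls.lm.control(
          maxiter = maxit, ftol = 1e-12, ptol = 1e-10, epsfcn = 1e-6)
      ),
      error = function(e) NULL)
    fits[[s]] <- fit
    init <- stats::setNames(as.list(starts[[s]]),
                            paste0("init_", names(theta0)))
    audit[[s]] <- cbind(
      data.frame(start = s), as.data.frame(init),
      data.frame(
        cost = if (is.null(fit)) NA_real_ else fit$deviance,
        iterations = if (is.null(fit)) NA_integer_ else fit$niter,
        converged = if (is.null(fit)) FALSE else fit$info %in% 1:4
      ))
  }
  audit <- do.call(rbind, audit)
  if (all(is.na(audit$cost)))
    stop("all calibration starts failed; see per-start diagnostics")

  best <- which.min(audit$cost)
  theta_hat <- stats::setNames(exp(as.numeric(fits[[best]]$par)),
                               names(theta0))
  # polish the winning start with a fine-step Jacobian: the coarse step
  # that stabilizes derivatives far from the optimum cannot resolve the
  # shallow valley floor near it
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = log(theta_hat), lower = log(bounds$lower),
      upper = log(bounds$upper),
      fn = log_resid, data = data, fixed_p = fixed_p,
      n_cycles = n_cycles, grid_n = grid_n,
      control = minpack.lm::nls.lm.control(
        maxiter = 50, ftol = 1e-14, ptol = 1e-12, epsfcn = 1e-10)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$deviance < audit$cost[best]) {
    theta_hat <- stats::setNames(exp(as.numeric(polish$par)), names(theta0))
    audit$cost[best] <- polish$deviance
  }
  m <- .model_on_grid(theta_hat, data, fixed_p, n_cycles, grid_n)
  out <- list(
    theta_hat = theta_hat,
    cost = audit$cost[best],
    R2_pressure = r_squared(m$P, data$P),
    R2_flow = r_squared(m$Q, data$Q),
    parameters = update_parameters(fixed_p, theta_hat),
    sim = m$sim,
    starts = audit, best_start = best,
    n_starts = n_starts, seed = seed
  )
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration: J = %.4g (start %d of %d), R2 pressure %.3f, flow %.3f\n",
    x$cost, x$best_start, x$n_starts, x$R2_pressure, x$R2_flow))
  print(round(x$theta_hat, 5))
  invisible(x)
}
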