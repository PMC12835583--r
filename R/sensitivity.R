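# Morris elementary-effects screening of the resistance, compliance and
# elastance parameters on mean PA pressure and peak pulmonic-valve flow.

# the 12 screened parameters (fixed sources and unstressed volumes are not)
.screened_set <- c("Rval_T", "Rval_P", "R_PA", "R_PC", "R_PV",
                   "C_PA", "C_PC", "C_PV", "Emax", "Emin", "tmax", "tmin")

#' Names of the screened parameter set
#' @return Character vector of length 12.
#' @export
screened_parameters <- function() .screened_set

#' Morris one-at-a-time trajectory design
#'
#' Builds `r` randomized trajectories on a `levels`-point grid in the unit
#' hypercube (step `delta = levels / (2 (levels - 1))`), mapped linearly
#' into the supplied bounds. Each trajectory perturbs every parameter
#' exactly once in a random order and direction, giving `r * (k + 1)`
#' model evaluations for `k` parameters.
#'
#' @param bounds a [build_bounds()] result (named `lower` / `upper`).
#' @param r number of trajectories (>= 4).
#' @param levels number of grid levels (even).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return List of class `morris_design`: design matrix `X`
#'   (`r*(k+1)` x `k`, named columns), per-step coordinate `coord` and
#'   signed unit step `step` matrices (`r` x `k`), `delta`, `r`, `levels`,
#'   and the bounds.
#' @export
morris_sample <- function(bounds, r = 20, levels = 8, seed = 1) {
  lower <- bounds$lower; upper <- bounds$upper
  if (any(upper - lower <= 0)) stop("degenerate bounds")
  if (r < 4) stop("need r >= 4 trajectories")
  if (levels %% 2 != 0) stop("levels must be even")
  k <- length(lower)
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, by = 1 / (levels - 1))

  set.seed(seed)
  X <- matrix(NA_real_, nrow = r * (k + 1), ncol = k,
              dimnames = list(NULL, names(lower)))
  coord <- matrix(NA_integer_, r, k)
  step <- matrix(NA_real_, r, k)
  for (tr in seq_len(r)) {
    x <- sample(base_levels, k, replace = TRUE)
    d <- sample(c(-1, 1), k, replace = TRUE)
    # keep every point on the grid inside [0, 1]
    d[x + d * delta < 0 | x + d * delta > 1] <- 1
    d[x + d * delta > 1] <- -1
    ord <- sample.int(k)
    row0 <- (tr - 1) * (k + 1) + 1
    X[row0, ] <- x
    for (j in seq_len(k)) {
      x[ord[j]] <- x[ord[j]] + d[ord[j]] * delta
      X[row0 + j, ] <- x
    }
    coord[tr, ] <- ord
    step[tr, ] <- d[ord] * delta
  }
  Xs <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  out <- list(X = Xs, U = X, coord = coord, step = step, delta = delta,
              r = r, levels = levels, lower = lower, upper = upper)
  class(out) <- "morris_design"
  out
}

#' Morris elementary-effects screen
#'
#' Evaluates an output functional on every design point and aggregates the
#' elementary effects per parameter: `mu_star` (mean absolute effect) and
#' `sigma` (SD of effects). Effects are computed on the unit hypercube
#' scale and normalized by the baseline output magnitude, so different
#' outputs are comparable. The functional may return scalar outputs (a
#' named numeric vector) or whole waveforms (a named list of numeric
#' vectors); for waveform outputs the elementary effect of a step is the
#' L2 norm of the waveform change per unit step, which credits
#' shape-shifting parameters (e.g. activation timings) that barely move
#' cycle averages. Trajectories containing a failed evaluation are
#' dropped; more than `max_fail_frac` failures aborts.
#'
#' @param design a [morris_sample()] design.
#' @param f function taking a named parameter vector (one design row) and
#'   returning named scalar outputs or a named list of waveform vectors;
#'   evaluations may signal an error for infeasible rows.
#' @param y0 named baseline output magnitudes used as normalizers;
#'   defaults to the median magnitude over successful evaluations.
#'   Normalization does not affect within-output rankings.
#' @param max_fail_frac maximum tolerated fraction of failed trajectories.
#' @return List of class `sensitivity_result`: per-output matrices
#'   `mu_star` and `sigma` (parameter x output), per-output `ranking`
#'   (parameter names, most to least influential), counts `r_used`, and
#'   the design metadata.
#' @export
morris_screen <- function(design, f, y0 = NULL, max_fail_frac = 0.2) {
  stopifnot(inherits(design, "morris_design"))
  X <- design$X
  k <- ncol(X); r <- design$r
  ys <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    ys[[i]] <- tryCatch(f(X[i, ]), error = function(e) NULL)
  }
  ok_row <- !vapply(ys, is.null, logical(1))
  first <- ys[[which(ok_row)[1]]]
  outs <- names(first)
  vector_valued <- is.list(first)

  traj_ok <- vapply(seq_len(r), function(tr) {
    all(ok_row[((tr - 1) * (k + 1) + 1):(tr * (k + 1))])
  }, logical(1))
  if (mean(!traj_ok) > max_fail_frac)
    stop(sum(!traj_ok), " of ", r, " Morris trajectories failed to simulate")
  if (is.null(y0)) {
    mag <- function(o) stats::median(vapply(ys[ok_row], function(y) {
      v <- if (vector_valued) y[[o]] else y[[o]]
      if (vector_valued) sqrt(sum(v^2)) else abs(v)
    }, numeric(1)))
    y0 <- stats::setNames(vapply(outs, mag, numeric(1)), outs)
  }

  ee <- array(NA_real_, dim = c(r, k, length(outs)),
              dimnames = list(NULL, colnames(X), outs))
  for (tr in which(traj_ok)) {
    row0 <- (tr - 1) * (k + 1) + 1
    for (j in seq_len(k)) {
      ci <- design$coord[tr, j]
      for (o in outs) {
        if (vector_valued) {
          dy <- sqrt(sum((ys[[row0 + j]][[o]] - ys[[row0 + j - 1]][[o]])^2)) /
            abs(design$step[tr, j])
        } else {
          dy <- (ys[[row0 + j]][[o]] - ys[[row0 + j - 1]][[o]]) /
            design$step[tr, j]
        }
        ee[tr, ci, o] <- dy / abs(y0[[o]])
      }
    }
  }
  mu_star <- apply(abs(ee), c(2, 3), mean, na.rm = TRUE)
  sigma <- apply(ee, c(2, 3), stats::sd, na.rm = TRUE)
  ranking <- lapply(outs, function(o) names(sort(mu_star[, o], decreasing = TRUE)))
  names(ranking) <- outs
  out <- list(mu_star = mu_star, sigma = sigma, ranking = ranking,
              r_used = sum(traj_ok), r = r, levels = design$levels)
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Morris screening (", x$r_used, "/", x$r, " trajectories, ",
      x$levels, " levels)\n", sep = "")
  print(round(x$mu_star, 4))
  invisible(x)
}

#' Select the influential parameter set
#'
#' Excludes the parameters ranked least influential (lowest `mu_star`) on
#' *both* outputs. With the default exclusion count of 3 on the screened
#' 12-parameter set this reproduces the pulmonic valve resistance and the
#' capillary and venous compliances as the excluded set, leaving the nine
#' calibrated parameters (see [influential_parameters()]). If the two
#' outputs' bottom sets share fewer than `n_exclude` parameters, the fixed
#' default exclusion is used with a notice.
#'
#' @param sres a [morris_screen()] result.
#' @param n_exclude number of parameters to drop (default 3).
#' @return Character vector of influential parameter names in canonical
#'   order, with the excluded set in attribute `"excluded"`.
#' @export
select_influential <- function(sres, n_exclude = 3) {
  stopifnot(inherits(sres, "sensitivity_result"))
  all_par <- rownames(sres$mu_star)
  if (n_exclude == 0) {
    out <- all_par
    attr(out, "excluded") <- character(0)
    return(out)
  }
  bottoms <- lapply(sres$ranking, function(rk) utils::tail(rk, n_exclude))
  common <- Reduce(intersect, bottoms)
  if (length(common) < n_exclude) {
    message("output rankings disagree on the least-influential set; ",
            "falling back to the default exclusion (Rval_P, C_PC, C_PV)")
    common <- intersect(c("Rval_P", "C_PC", "C_PV"), all_par)
  }
  out <- setdiff(.param_fields[.param_fields %in% all_par], common)
  attr(out, "excluded") <- common
  out
}

#' Output functional for screening the circulation model
#'
#' Returns a function mapping a named subvector of screened parameters to
#' the screening outputs of the converged final cycle. With
#' `waveform = FALSE` (default) these are scalars: cycle-mean PA pressure,
#' peak pulmonic-valve flow and cycle-mean pulmonic-valve flow (the anchor
#' quantities of the calibration cost, the last being the cardiac-output
#' anchor). With `waveform = TRUE` the whole PA pressure and pulmonic flow
#' waveforms are returned, for waveform-change elementary effects.
#'
#' @param p_base full [model_parameters()] baseline; screened entries are
#'   overwritten by the functional's argument.
#' @param n_cycles,grid_n forwarded to [simulate_circulation()].
#' @param include_l2 also return waveform L2 norms (scalar mode only).
#' @param waveform return full waveforms instead of scalars.
#' @return Function suitable for [morris_screen()].
#' @export
screening_functional <- function(p_base, n_cycles = 40, grid_n = 100,
                                 include_l2 = FALSE, waveform = FALSE) {
  force(p_base)
  function(theta) {
    # repair grid corners that violate parameter constraints: the shared
    # endpoint of the timing intervals (tmax = tmin = 0.35 T), and
    # diastolic elastance crossing above systolic under the wide
    # multiplicative bounds
    if (all(c("tmax", "tmin") %in% names(theta)) &&
        theta[["tmin"]] <= theta[["tmax"]])
      theta[["tmin"]] <- theta[["tmax"]] + 0.01 * p_base[["T"]]
    if (all(c("Emax", "Emin") %in% names(theta)) &&
        theta[["Emin"]] >= theta[["Emax"]])
      theta[["Emin"]] <- 0.8 * theta[["Emax"]]
    p <- update_parameters(p_base, theta)
    # a screening sweep may legitimately visit hypertensive extremes, so
    # no blow-up ceiling here
    sim <- simulate_circulation(p, n_cycles = n_cycles, grid_n = grid_n,
                                pressure_ceiling = Inf)
    if (waveform)
      return(list(P_PA = sim$P_PA, Q_val_P = sim$Q_val_P))
    out <- c(mean_P_PA = mean(sim$P_PA), peak_Q_val_P = max(sim$Q_val_P),
             mean_Q_val_P = mean(sim$Q_val_P))
    if (include_l2)
      out <- c(out, l2_P_PA = sqrt(mean(sim$P_PA^2)),
               l2_Q_val_P = sqrt(mean(sim$Q_val_P^2)))
    out
  }
}
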