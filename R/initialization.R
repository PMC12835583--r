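# Initialization: map routine RHC/echo scalars to the baseline parameter
# vector and the calibration bounds.

# Eq.-5 ordering of the influential (calibrated) parameter subvector
.influential_set <- c("Rval_T", "R_PA", "R_PC", "R_PV", "C_PA",
                      "Emax", "Emin", "tmax", "tmin")

#' The influential parameter set
#'
#' Names, in canonical order, of the nine parameters made patient-specific
#' during calibration: the tricuspid valve and three vascular-bed
#' resistances, the proximal arterial compliance, and the four elastance
#' parameters. The pulmonic valve resistance and the capillary/venous
#' compliances are excluded as least influential (see
#' [select_influential()]).
#'
#' @return Character vector of length 9.
#' @export
influential_parameters <- function() .influential_set

#' Construct a clinical summary record
#'
#' One patient's routine hemodynamics: heart rate, thermodilution cardiac
#' output, wedge pressure, mean (and optionally systolic/diastolic)
#' pulmonary artery pressure, mean right atrial pressure, and optional
#' echo-derived RV volumes. When sPAP/dPAP were not recorded they are
#' imputed from mPAP by inverting the mPAP = (2 dPAP + sPAP)/3 relation
#' with an assumed diastolic fraction `dPAP = dpap_frac * mPAP`.
#'
#' @param HR heart rate, beats/min.
#' @param CO cardiac output, L/min.
#' @param PAWP pulmonary arterial wedge pressure, mmHg.
#' @param mPAP mean pulmonary artery pressure, mmHg.
#' @param RAP mean right atrial pressure, mmHg; if `NA`, defaulted by
#'   phenotype (6 mmHg for No PH / Ipc-PH, 9 mmHg otherwise).
#' @param sPAP,dPAP systolic/diastolic PAP, mmHg; imputed when `NA`.
#' @param EDV,ESV RV end-diastolic / end-systolic volume, mL; when absent,
#'   `EDV = 120` and `ESV = EDV - SV` are assumed.
#' @param subject,cohort,sex,age metadata; `cohort` is one of
#'   `"Pre-cap"`, `"Ipc-PH"`, `"Cpc-PH"`, `"No PH"` (free text allowed).
#' @param dpap_frac assumed dPAP/mPAP ratio used for imputation.
#' @return An object of class `clinical_summary` (named list).
#' @examples
#' cs <- clinical_summary(HR = 68, CO = 4.0, PAWP = 12, mPAP = 38,
#'                        cohort = "Pre-cap")
#' cs$sPAP
#' @export
clinical_summary <- function(HR, CO, PAWP, mPAP, RAP = NA, sPAP = NA,
                             dPAP = NA, EDV = NA, ESV = NA,
                             subject = NA, cohort = NA, sex = NA, age = NA,
                             dpap_frac = 0.6) {
  for (f in c("HR", "CO", "PAWP", "mPAP")) {
    v <- get(f)
    if (is.na(v) || !is.numeric(v))
      stop("mandatory clinical field missing or non-numeric: ", f)
  }
  if (HR <= 0 || CO <= 0) stop("HR and CO must be > 0")
  if (PAWP < 0) stop("PAWP must be >= 0")
  if (is.na(dPAP)) dPAP <- dpap_frac * mPAP
  if (is.na(sPAP)) sPAP <- 3 * mPAP - 2 * dPAP  # keeps (2d+s)/3 = mPAP
  if (!(dPAP < mPAP && mPAP < sPAP))
    stop("require dPAP < mPAP < sPAP (got ", dPAP, ", ", mPAP, ", ", sPAP, ")")
  if (is.na(RAP)) {
    RAP <- if (!is.na(cohort) && cohort %in% c("No PH", "Ipc-PH")) 6 else 9
  }
  out <- list(subject = subject, cohort = cohort, sex = sex, age = age,
              HR = HR, CO = CO, PAWP = PAWP, mPAP = mPAP, RAP = RAP,
              sPAP = sPAP, dPAP = dPAP, EDV = EDV, ESV = ESV)
  class(out) <- "clinical_summary"
  out
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf("Clinical summary%s (%s)\n",
              if (!is.na(x$subject)) paste0(" ", x$subject) else "",
              if (!is.na(x$cohort)) x$cohort else "unlabeled"))
  cat(sprintf("  HR %.0f bpm, CO %.1f L/min, PAWP %.0f, mPAP %.0f (%.0f/%.0f), RAP %.0f mmHg\n",
              x$HR, x$CO, x$PAWP, x$mPAP, x$sPAP, x$dPAP, x$RAP))
  invisible(x)
}

#' Derive working pressure estimates from a clinical summary
#'
#' Implements the pressure-estimate chain used for initialization: RV
#' systolic pressure sits 0.5 mmHg above systolic PAP (a slight gradient
#' across the pulmonic valve), RV diastolic pressure starts at 2 mmHg
#' (an initial guess only; calibration determines the realized value),
#' mean PAP follows the (2 dPAP + sPAP)/3 estimate, left atrial pressure
#' is the lower of PAWP and diastolic PAP, and the transpulmonary gradient
#' is split 30/30/40 percent across the arterial, capillary and venous
#' segments.
#'
#' @param cs a [clinical_summary()].
#' @return Named numeric vector of class `pressure_estimates` with fields
#'   `P_MeanRA`, `P_SysRV`, `P_DiaRV`, `P_SysPA`, `P_DiaPA`, `P_MeanPA`,
#'   `P_MeanPC`, `P_MeanPV`, `P_MeanLA`, `P_Grad` (mmHg).
#' @export
derive_pressure_estimates <- function(cs) {
  stopifnot(inherits(cs, "clinical_summary"))
  P_SysPA <- cs$sPAP
  P_DiaPA <- cs$dPAP
  P_MeanPA <- (2 * P_DiaPA + P_SysPA) / 3
  P_MeanLA <- min(cs$PAWP, P_DiaPA)
  P_Grad <- P_MeanPA - P_MeanLA
  P_MeanPC <- P_MeanPA - 0.3 * P_Grad
  P_MeanPV <- P_MeanPC - 0.3 * P_Grad
  pe <- c(P_MeanRA = cs$RAP, P_SysRV = P_SysPA + 0.5, P_DiaRV = 2.0,
          P_SysPA = P_SysPA, P_DiaPA = P_DiaPA, P_MeanPA = P_MeanPA,
          P_MeanPC = P_MeanPC, P_MeanPV = P_MeanPV, P_MeanLA = P_MeanLA,
          P_Grad = P_Grad)
  class(pe) <- c("pressure_estimates", "numeric")
  pe
}

#' Build the baseline parameter vector from clinical summaries
#'
#' Maps a clinical summary and its pressure estimates to the complete model
#' parameter set: resistances from segment pressure drops over cardiac
#' output, unstressed vascular volumes as fixed fractions of stroke volume
#' (0.23 / 0.49 / 0.28 of SV for the arterial / capillary / venous beds),
#' compliances as unstressed volume over mean segment pressure, `Emax` and
#' `Emin` from RV systolic / diastolic pressure over the corresponding RV
#' volume, and activation timings at fixed fractions (0.2, 0.5) of the
#' cycle.
#'
#' Derived resistances that would be non-positive (e.g. when mean RA
#' pressure does not exceed the assumed diastolic RV pressure) are clamped
#' to `resistance_floor` with a warning, so that multiplicative calibration
#' bounds remain usable.
#'
#' @param cs a [clinical_summary()].
#' @param pe optional [derive_pressure_estimates()] result; computed from
#'   `cs` when omitted.
#' @param default_EDV RV end-diastolic volume assumed when echo volumes are
#'   absent, mL.
#' @param resistance_floor minimum admissible baseline resistance,
#'   mmHg·s/mL.
#' @return A [model_parameters()] object.
#' @examples
#' cs <- clinical_summary(HR = 68, CO = 4.0, PAWP = 12, mPAP = 38,
#'                        cohort = "Pre-cap")
#' p0 <- build_initial_parameters(cs)
#' @export
build_initial_parameters <- function(cs, pe = derive_pressure_estimates(cs),
                                     default_EDV = 120,
                                     resistance_floor = 1e-4) {
  co <- cs$CO * 1000 / 60              # L/min -> mL/s
  SV <- cs$CO * 1000 / cs$HR           # mL/beat
  # default EDV, enlarged for high-output patients so the implied ejection
  # fraction stays <= 60% and the derived ESV positive
  EDV <- if (is.na(cs$EDV)) max(default_EDV, SV / 0.6) else cs$EDV
  ESV <- if (is.na(cs$ESV)) EDV - SV else cs$ESV
  if (ESV <= 0) stop("derived ESV <= 0; provide EDV/ESV explicitly")
  Tc <- 60 / cs$HR

  res <- c(Rval_T = (pe[["P_MeanRA"]] - pe[["P_DiaRV"]]) / co,
           Rval_P = (pe[["P_SysRV"]] - pe[["P_SysPA"]]) / co,
           R_PA = (pe[["P_MeanPA"]] - pe[["P_MeanPC"]]) / co,
           R_PC = (pe[["P_MeanPC"]] - pe[["P_MeanPV"]]) / co,
           R_PV = (pe[["P_MeanPV"]] - pe[["P_MeanLA"]]) / co)
  low <- res < resistance_floor
  if (any(low)) {
    warning("baseline resistance(s) clamped to floor: ",
            paste(names(res)[low], collapse = ", "))
    res[low] <- resistance_floor
  }

  V0_PA <- 0.23 * SV; V0_PC <- 0.49 * SV; V0_PV <- 0.28 * SV
  model_parameters(
    Rval_T = res[["Rval_T"]], Rval_P = res[["Rval_P"]],
    R_PA = res[["R_PA"]], R_PC = res[["R_PC"]], R_PV = res[["R_PV"]],
    C_PA = V0_PA / pe[["P_MeanPA"]],
    C_PC = V0_PC / pe[["P_MeanPC"]],
    C_PV = V0_PV / pe[["P_MeanPV"]],
    Emax = pe[["P_SysRV"]] / ESV,
    Emin = pe[["P_DiaRV"]] / EDV,
    tmax = 0.2 * Tc, tmin = 0.5 * Tc,
    V0_PA = V0_PA, V0_PC = V0_PC, V0_PV = V0_PV, V0_RV = 0,
    P_RA = pe[["P_MeanRA"]], P_LA = pe[["P_MeanLA"]], T = Tc
  )
}

#' Calibration bounds for the influential subvector
#'
#' Non-timing parameters are bounded between 1% and 600% of their baseline
#' values; the activation timings are constrained to fixed fractions of the
#' cardiac cycle, `tmax` in `[0.05 T, 0.35 T]` and `tmin` in
#' `[0.35 T, 0.7 T]` (the disjoint intervals enforce `tmax < tmin` except
#' at the shared endpoint, which parameter validation rejects).
#'
#' @param theta0 named baseline subvector in [influential_parameters()]
#'   order (timing entries in s).
#' @param T cardiac cycle length, s.
#' @param lower_frac,upper_frac multiplicative bounds for non-timing
#'   parameters.
#' @return List of class `parameter_bounds` with named vectors `lower`,
#'   `upper`.
#' @export
build_bounds <- function(theta0, T, lower_frac = 0.01, upper_frac = 6) {
  stopifnot(!is.null(names(theta0)))
  if (any(theta0 == 0))
    stop("baseline contains zero entries; multiplicative bounds collapse")
  timing <- names(theta0) %in% c("tmax", "tmin")
  lower <- ifelse(timing, NA_real_, lower_frac * theta0)
  upper <- ifelse(timing, NA_real_, upper_frac * theta0)
  names(lower) <- names(upper) <- names(theta0)
  if ("tmax" %in% names(theta0)) {
    lower[["tmax"]] <- 0.05 * T; upper[["tmax"]] <- 0.35 * T
  }
  if ("tmin" %in% names(theta0)) {
    lower[["tmin"]] <- 0.35 * T; upper[["tmin"]] <- 0.7 * T
  }
  if (any(lower >= upper)) stop("degenerate bounds (lower >= upper)")
  out <- list(lower = lower, upper = upper)
  class(out) <- "parameter_bounds"
  out
}

#' Extract the influential baseline subvector
#'
#' @param p a [model_parameters()] object.
#' @param which parameter names; defaults to the calibrated set.
#' @return Named numeric vector.
#' @export
theta_from_parameters <- function(p, which = influential_parameters()) {
  unclass(p)[which]
}
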