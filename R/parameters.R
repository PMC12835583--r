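# Parameter container for the four-compartment RV / pulmonary circulation model.

# canonical field order; also the order handed to the compiled RHS
.param_fields <- c(
  "Rval_T", "Rval_P", "R_PA", "R_PC", "R_PV",
  "C_PA", "C_PC", "C_PV",
  "Emax", "Emin", "tmax", "tmin",
  "V0_PA", "V0_PC", "V0_PV", "V0_RV",
  "P_RA", "P_LA", "T"
)

#' Construct a model parameter set
#'
#' Bundles the full parameter vector of the lumped-parameter model: five
#' resistances (tricuspid and pulmonic valve, pulmonary arterial, capillary
#' and venous beds, mmHg·s/mL), three Windkessel compliances (mL/mmHg), the
#' time-varying elastance description of the right ventricle (`Emax`, `Emin`
#' in mmHg/mL and activation timings `tmax` < `tmin` in s), unstressed
#' volumes (mL), the fixed right- and left-atrial source pressures (mmHg),
#' and the cardiac cycle length `T` (s).
#'
#' @param Rval_T,Rval_P,R_PA,R_PC,R_PV resistances, mmHg·s/mL.
#' @param C_PA,C_PC,C_PV compliances, mL/mmHg.
#' @param Emax,Emin maximum (end-systolic) and minimum (diastolic) RV
#'   elastance, mmHg/mL.
#' @param tmax,tmin time of peak elastance and start of the diastolic
#'   plateau, s, with `0 < tmax < tmin < T`.
#' @param V0_PA,V0_PC,V0_PV unstressed vascular volumes, mL.
#' @param V0_RV RV volume at zero pressure, mL (default 0).
#' @param P_RA,P_LA constant right- and left-atrial pressures, mmHg.
#' @param T cardiac cycle length, s.
#' @return An object of class `model_parameters` (a named numeric vector).
#' @examples
#' p <- example_parameters()
#' p["Emax"]
#' @export
model_parameters <- function(Rval_T, Rval_P, R_PA, R_PC, R_PV,
                             C_PA, C_PC, C_PV,
                             Emax, Emin, tmax, tmin,
                             V0_PA = 0, V0_PC = 0, V0_PV = 0, V0_RV = 0,
                             P_RA, P_LA, T) {
  p <- c(
    Rval_T = Rval_T, Rval_P = Rval_P, R_PA = R_PA, R_PC = R_PC, R_PV = R_PV,
    C_PA = C_PA, C_PC = C_PC, C_PV = C_PV,
    Emax = Emax, Emin = Emin, tmax = tmax, tmin = tmin,
    V0_PA = V0_PA, V0_PC = V0_PC, V0_PV = V0_PV, V0_RV = V0_RV,
    P_RA = P_RA, P_LA = P_LA, T = T
  )
  class(p) <- c("model_parameters", "numeric")
  validate_parameters(p)
  p
}

#' Validate a model parameter set
#'
#' Checks the structural invariants: positive resistances, compliances and
#' `Emax`; `0 < Emin < Emax`; `0 < tmax < tmin < T`; non-negative unstressed
#' volumes and source pressures.
#'
#' @param p a `model_parameters` object or named numeric vector with the same
#'   fields.
#' @return `p`, invisibly, if valid; otherwise an error naming the violated
#'   constraint.
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(.param_fields, names(p))
  if (length(missing) > 0)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(unclass(p)[.param_fields])))
    stop("all parameters must be finite")
  pos <- c("Rval_T", "Rval_P", "R_PA", "R_PC", "R_PV",
           "C_PA", "C_PC", "C_PV", "Emax", "T")
  bad <- pos[unclass(p)[pos] <= 0]
  if (length(bad) > 0)
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (p[["Emin"]] <= 0 || p[["Emin"]] >= p[["Emax"]])
    stop("require 0 < Emin < Emax")
  if (!(p[["tmax"]] > 0 && p[["tmax"]] < p[["tmin"]] && p[["tmin"]] < p[["T"]]))
    stop("require 0 < tmax < tmin < T")
  nonneg <- c("V0_PA", "V0_PC", "V0_PV", "V0_RV", "P_RA", "P_LA")
  bad <- nonneg[unclass(p)[nonneg] < 0]
  if (length(bad) > 0)
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Update fields of a parameter set
#'
#' Returns a copy of `p` with the named entries of `values` substituted and
#' the result re-validated. Used to merge a calibrated subvector back into a
#' full parameter set.
#'
#' @param p a `model_parameters` object.
#' @param values named numeric vector of replacement values.
#' @export
update_parameters <- function(p, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  unknown <- setdiff(names(values), .param_fields)
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  p[names(values)] <- values
  validate_parameters(p)
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Lumped-parameter circulation model parameters\n")
  cat(sprintf("  cycle T = %.3f s (HR %.1f bpm)\n", x[["T"]], 60 / x[["T"]]))
  m <- matrix(unclass(x)[.param_fields], nrow = 1,
              dimnames = list("", .param_fields))
  print(round(m, 4), ...)
  invisible(x)
}

#' Write / read parameters as flat JSON
#'
#' Parameters serialize to a flat JSON object whose keys are exactly the
#' parameter field names, so files are interoperable with any tool that can
#' read a key-value document.
#'
#' @param p a `model_parameters` object.
#' @param path file path.
#' @return `read_parameters_json` returns a `model_parameters` object.
#' @export
write_parameters_json <- function(p, path) {
  validate_parameters(p)
  jsonlite::write_json(as.list(unclass(p)[.param_fields]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- unlist(x)[.param_fields]
  class(p) <- c("model_parameters", "numeric")
  validate_parameters(p)
  p
}

#' A ready-made physiological parameter set
#'
#' A convenience baseline (roughly a mildly hypertensive adult at 70 bpm)
#' used in examples and tests.
#'
#' @export
example_parameters <- function() {
  model_parameters(
    Rval_T = 0.05, Rval_P = 0.006, R_PA = 0.08, R_PC = 0.07, R_PV = 0.09,
    C_PA = 0.6, C_PC = 1.5, C_PV = 1.2,
    Emax = 0.55, Emin = 0.017, tmax = 0.17, tmin = 0.43,
    V0_PA = 15, V0_PC = 30, V0_PV = 17, V0_RV = 0,
    P_RA = 6, P_LA = 10, T = 60 / 70
  )
}
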