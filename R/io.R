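# File formats: two-column waveform CSV, clinical-summary CSV, simulation
# trace CSV, and the run-configuration record.

#' Construct a waveform series
#'
#' A sampled pressure or flow trace over one cardiac cycle: strictly
#' increasing times (s) and values (mmHg for pressure, mL/s for flow).
#'
#' @param t sample times, s, strictly increasing, spanning one cycle.
#' @param v sample values.
#' @param kind `"pressure"` or `"flow"`.
#' @param T cycle length, s; defaults to the time span extended by one
#'   median sampling interval.
#' @return Object of class `waveform_series`.
#' @export
waveform_series <- function(t, v, kind = c("pressure", "flow"), T = NULL) {
  kind <- match.arg(kind)
  if (length(t) != length(v)) stop("t and v must have equal length")
  if (length(t) < 20) stop("waveform needs at least 20 samples")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(t)) || any(!is.finite(v)))
    stop("waveform contains non-finite values")
  if (max(v) <= 0) stop("waveform must attain positive values")
  if (is.null(T)) T <- (max(t) - min(t)) + stats::median(diff(t))
  out <- list(t = as.numeric(t), v = as.numeric(v), kind = kind,
              T = as.numeric(T), Nt = length(t))
  class(out) <- "waveform_series"
  out
}

#' @export
print.waveform_series <- function(x, ...) {
  cat(sprintf("%s waveform: %d samples over %.3f s, range [%.2f, %.2f] %s\n",
              x$kind, x$Nt, x$T, min(x$v), max(x$v),
              if (x$kind == "pressure") "mmHg" else "mL/s"))
  invisible(x)
}

#' Read / write a waveform CSV
#'
#' Two-column CSV with a header: first column `t` (s), second column the
#' value with a unit-declaring name, `P_mmHg` for pressure or `Q_mL_s`
#' for flow. Malformed files (missing header, non-monotone time, NA
#' values) are rejected with the offending line reported.
#'
#' @param path file path.
#' @param w a `waveform_series` (for writing).
#' @param T optional cycle length override, s.
#' @return `read_waveform_csv` returns a [waveform_series()].
#' @export
read_waveform_csv <- function(path, T = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2 || names(d)[1] != "t")
    stop("waveform CSV must have header 't,<P_mmHg|Q_mL_s>': ", path)
  kind <- switch(names(d)[2], P_mmHg = "pressure", Q_mL_s = "flow",
                 stop("unknown value column '", names(d)[2],
                      "' (expected P_mmHg or Q_mL_s): ", path))
  bad <- which(!is.finite(d[[1]]) | !is.finite(d[[2]]))
  if (length(bad) > 0)
    stop("non-numeric/NaN waveform entries at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ", path)
  nonmono <- which(diff(d[[1]]) <= 0)
  if (length(nonmono) > 0)
    stop("non-monotone time at data line(s) ",
         paste(utils::head(nonmono + 1, 5), collapse = ", "), ": ", path)
  waveform_series(d[[1]], d[[2]], kind = kind, T = T)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform_series"))
  d <- data.frame(t = w$t, v = w$v)
  names(d)[2] <- if (w$kind == "pressure") "P_mmHg" else "Q_mL_s"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort of clinical summaries from CSV
#'
#' Expects headers `subject,cohort,sex,age,HR,CO,PAWP,mPAP` plus optional
#' `RAP,sPAP,dPAP,EDV,ESV`. Missing optional fields are defaulted (RAP by
#' phenotype, sPAP/dPAP by mPAP imputation) inside [clinical_summary()].
#' The routine hemodynamics of the 25-subject study cohort ship with the
#' package; see the example.
#'
#' @param path CSV file path.
#' @return List of [clinical_summary()] objects.
#' @examples
#' path <- system.file("extdata", "table1_cohort.csv", package = "rvcirc")
#' cohort <- read_clinical_csv(path)
#' length(cohort)
#' @export
read_clinical_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("HR", "CO", "PAWP", "mPAP")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("clinical CSV missing column(s): ", paste(missing, collapse = ", "))
  opt <- function(col, i) if (col %in% names(d)) d[[col]][i] else NA
  lapply(seq_len(nrow(d)), function(i) {
    for (f in need) {
      if (is.na(suppressWarnings(as.numeric(d[[f]][i]))))
        stop("malformed ", f, " in clinical CSV row ", i)
    }
    clinical_summary(
      HR = as.numeric(d$HR[i]), CO = as.numeric(d$CO[i]),
      PAWP = as.numeric(d$PAWP[i]), mPAP = as.numeric(d$mPAP[i]),
      RAP = as.numeric(opt("RAP", i)), sPAP = as.numeric(opt("sPAP", i)),
      dPAP = as.numeric(opt("dPAP", i)), EDV = as.numeric(opt("EDV", i)),
      ESV = as.numeric(opt("ESV", i)),
      subject = opt("subject", i), cohort = opt("cohort", i),
      sex = opt("sex", i), age = opt("age", i)
    )
  })
}

#' Path to the packaged study-cohort fixture
#'
#' @return File path of the 25-subject routine-hemodynamics CSV.
#' @export
study_cohort_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "rvcirc")
}

#' Write simulation traces to CSV
#'
#' Header: `t,P_RV,P_PA,P_PC,P_PV,Q_val_T,Q_val_P,Q_PA,Q_PC,Q_PV,V_RV`.
#'
#' @param sim a `simulation_result`.
#' @param path file path.
#' @export
write_simulation_csv <- function(sim, path) {
  cols <- c("t", "P_RV", "P_PA", "P_PC", "P_PV", "Q_val_T", "Q_val_P",
            "Q_PA", "Q_PC", "Q_PV", "V_RV")
  d <- as.data.frame(sim[cols])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable knobs of the pipeline in one serializable record, written
#' beside every run's outputs for reproducibility.
#'
#' @param ... overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_cycles = 40, grid_n = 200, rtol = 1e-6, atol = 1e-6, gate_eps = 0,
    pressure_ceiling = 1000,
    n_starts = 20, perturb_range = c(0.5, 2), optim_maxit = 100,
    morris_r = 20, morris_levels = 8,
    bound_lower_frac = 0.01, bound_upper_frac = 6,
    noise_multiplicative_sd = 0.05, noise_additive_sd_pressure = 1,
    noise_additive_sd_flow = 5, noise_phase_jitter = 0.02,
    dpap_frac = 0.6, default_EDV = 120, resistance_floor = 1e-4
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}
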