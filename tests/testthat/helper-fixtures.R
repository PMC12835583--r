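# Shared fixtures: a fast baseline parameter set, noise configurations,
# and cached study-cohort summaries.

quick_params <- function() example_parameters()

zero_noise <- list(multiplicative_sd = 0, additive_sd_pressure = 0,
                   additive_sd_flow = 0, phase_jitter = 0)

mult_noise <- function(sd = 0.05) {
  list(multiplicative_sd = sd, additive_sd_pressure = 0,
       additive_sd_flow = 0, phase_jitter = 0)
}

study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_clinical_csv(study_cohort_path())
    cache
  }
})

# hand-specified parameter set used for frozen-arithmetic checks
algebra_params <- function() {
  model_parameters(
    Rval_T = 2, Rval_P = 1, R_PA = 5, R_PC = 4, R_PV = 2,
    C_PA = 2, C_PC = 3, C_PV = 2,
    Emax = 1, Emin = 0.1, tmax = 0.2, tmin = 0.5,
    V0_PA = 10, V0_PC = 30, V0_PV = 20, V0_RV = 0,
    P_RA = 8, P_LA = 5, T = 1
  )
}
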