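/* Right side of the four-compartment RV / pulmonary circulation model,
 * in the deSolve compiled-model convention. States: V_RV, V_PA, V_PC, V_PV.
 * Parameter order must match .param_fields in R/parameters.R, plus one
 * trailing entry: the smooth-gate width eps (<= 0 means hard diode). */

#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 20
static double parms[N_PARMS];

#define RVAL_T parms[0]
#define RVAL_P parms[1]
#define R_PA   parms[2]
#define R_PC   parms[3]
#define R_PV   parms[4]
#define C_PA   parms[5]
#define C_PC   parms[6]
#define C_PV   parms[7]
#define EMAX   parms[8]
#define EMIN   parms[9]
#define TMAX   parms[10]
#define TMIN   parms[11]
#define V0_PA  parms[12]
#define V0_PC  parms[13]
#define V0_PV  parms[14]
#define V0_RV  parms[15]
#define P_RA   parms[16]
#define P_LA   parms[17]
#define TCYC   parms[18]
#define GATE_EPS parms[19]

void rvcirc_initmod(void (*odeparms)(int *, double *)) {
  int n = N_PARMS;
  odeparms(&n, parms);
}

/* piecewise raised-cosine activation between Emin and Emax */
static double elastance_c(double t) {
  double tt = fmod(t, TCYC);
  if (tt < 0) tt += TCYC;
  if (tt <= TMAX)
    return EMIN + 0.5 * (EMAX - EMIN) * (1.0 - cos(M_PI * tt / TMAX));
  if (tt <= TMIN)
    return EMIN + 0.5 * (EMAX - EMIN) *
           (1.0 + cos(M_PI * (tt - TMAX) / (TMIN - TMAX)));
  return EMIN;
}

static double valve_flow(double dP, double R) {
  if (GATE_EPS > 0.0) /* smooth sigmoid gate for integrator robustness */
    return (dP / R) * 0.5 * (1.0 + tanh(dP / GATE_EPS));
  return dP > 0.0 ? dP / R : 0.0;
}

void rvcirc_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double P_RV = elastance_c(*t) * (y[0] - V0_RV);
  double P_PA = (y[1] - V0_PA) / C_PA;
  double P_PC = (y[2] - V0_PC) / C_PC;
  double P_PV = (y[3] - V0_PV) / C_PV;

  double Q_val_T = valve_flow(P_RA - P_RV, RVAL_T);
  double Q_val_P = valve_flow(P_RV - P_PA, RVAL_P);
  double Q_PA = (P_PA - P_PC) / R_PA;
  double Q_PC = (P_PC - P_PV) / R_PC;
  double Q_PV = (P_PV - P_LA) / R_PV;

  ydot[0] = Q_val_T - Q_val_P;
  ydot[1] = Q_val_P - Q_PA;
  ydot[2] = Q_PA - Q_PC;
  ydot[3] = Q_PC - Q_PV;
}

static const R_CMethodDef CEntries[] = {
  {"rvcirc_initmod", (DL_FUNC) &rvcirc_initmod, 1},
  {"rvcirc_derivs",  (DL_FUNC) &rvcirc_derivs,  6},
  {NULL, NULL, 0}
};

void R_init_rvcirc(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
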