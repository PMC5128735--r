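/* Combined native-routine registration: the Rcpp .Call entries plus the
 * deSolve-facing C routines from ode_rhs.c. Rcpp::compileAttributes()
 * detects this R_init and does not emit its own. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp exports (defined in RcppExports.cpp) */
extern SEXP _gatefit_cpp_expm(SEXP);
extern SEXP _gatefit_cpp_expm_reversible(SEXP, SEXP);
extern SEXP _gatefit_cpp_spectral_radius(SEXP);
extern SEXP _gatefit_cpp_power_trace(SEXP, SEXP, SEXP);

/* deSolve compiled model (defined in ode_rhs.c) */
extern void gf_initmod(void (*odeparms)(int *, double *));
extern void gf_derivs(int *, double *, double *, double *, double *, int *);
extern void gf_jac(int *, double *, double *, int *, int *, double *, int *,
                   double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"_gatefit_cpp_expm", (DL_FUNC) &_gatefit_cpp_expm, 1},
    {"_gatefit_cpp_expm_reversible", (DL_FUNC) &_gatefit_cpp_expm_reversible, 2},
    {"_gatefit_cpp_spectral_radius", (DL_FUNC) &_gatefit_cpp_spectral_radius, 1},
    {"_gatefit_cpp_power_trace", (DL_FUNC) &_gatefit_cpp_power_trace, 3},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"gf_initmod", (DL_FUNC) &gf_initmod, 1},
    {"gf_derivs", (DL_FUNC) &gf_derivs, 6},
    {"gf_jac", (DL_FUNC) &gf_jac, 9},
    {NULL, NULL, 0}
};

void R_init_gatefit(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
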