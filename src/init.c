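#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP kinmech_enumerate(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                              SEXP, SEXP, SEXP);
extern SEXP kinmech_set_model(SEXP);
extern SEXP kinmech_sse_rk45(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern void kinmech_derivs(int *, double *, double *, double *, double *,
                           int *);

static const R_CallMethodDef CallEntries[] = {
    {"kinmech_enumerate", (DL_FUNC) &kinmech_enumerate, 10},
    {"kinmech_set_model", (DL_FUNC) &kinmech_set_model, 1},
    {"kinmech_sse_rk45", (DL_FUNC) &kinmech_sse_rk45, 6},
    {NULL, NULL, 0}
};

/* registered as a C routine so deSolve can look it up by name */
static const R_CMethodDef CEntries[] = {
    {"kinmech_derivs", (DL_FUNC) &kinmech_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_kinmech(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
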