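#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Symbols looked up by address from deSolve; signatures are opaque. */
void ca_initmod(void (*odeparms)(int *, double *));
void ca_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"ca_initmod", (DL_FUNC) &ca_initmod, 1},
    {"ca_derivs",  (DL_FUNC) &ca_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_microca(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
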