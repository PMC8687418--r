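#include <R.h>
#include <R_ext/Rdynload.h>

void mssnet_init(void (*odeparms)(int *, double *));
void mssnet_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"mssnet_init",  (DL_FUNC) &mssnet_init,  1},
    {"mssnet_deriv", (DL_FUNC) &mssnet_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_mssinfer(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve resolves the derivative routine by name at run time */
    R_useDynamicSymbols(dll, TRUE);
}
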