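#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void initmod_minimal(void (*odeparms)(int *, double *));
void derivs_minimal(int *, double *, double *, double *, double *, int *);
void initmod_bio(void (*odeparms)(int *, double *));
void derivs_bio(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"initmod_minimal", (DL_FUNC) &initmod_minimal, 1},
    {"derivs_minimal",  (DL_FUNC) &derivs_minimal,  6},
    {"initmod_bio",     (DL_FUNC) &initmod_bio,     1},
    {"derivs_bio",      (DL_FUNC) &derivs_bio,      6},
    {NULL, NULL, 0}
};

void R_init_dasynergy(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
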