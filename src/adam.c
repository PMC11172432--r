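#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* Fused Adam update, in place: one pass over the parameter, first- and
 * second-moment and gradient arrays. The caller owns p, m and v
 * exclusively (deep-copied at the start of training), so in-place
 * mutation is safe. c1, c2 are the bias-correction factors
 * 1/(1-beta1^t) and 1/(1-beta2^t). */
SEXP dfppi_adam_step(SEXP p, SEXP m, SEXP v, SEXP g,
                     SEXP lr_, SEXP b1_, SEXP b2_,
                     SEXP c1_, SEXP c2_, SEXP eps_)
{
    R_xlen_t n = XLENGTH(p);
    if (XLENGTH(m) != n || XLENGTH(v) != n || XLENGTH(g) != n)
        error("adam: length mismatch");
    double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
    double lr = asReal(lr_), b1 = asReal(b1_), b2 = asReal(b2_);
    double c1 = asReal(c1_), c2 = asReal(c2_), eps = asReal(eps_);
    for (R_xlen_t i = 0; i < n; i++) {
        double gi = pg[i];
        double mi = b1 * pm[i] + (1.0 - b1) * gi;
        double vi = b2 * pv[i] + (1.0 - b2) * gi * gi;
        pm[i] = mi;
        pv[i] = vi;
        pp[i] -= lr * (mi * c1) / (sqrt(vi * c2) + eps);
    }
    return R_NilValue;
}

static const R_CallMethodDef CallEntries[] = {
    {"dfppi_adam_step", (DL_FUNC) &dfppi_adam_step, 10},
    {NULL, NULL, 0}
};

void R_init_dfppi(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
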