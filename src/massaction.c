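/* Generic mass-action derivative routine for deSolve's compiled-model
 * interface.  The active model (net stoichiometry, reactant orders, rate
 * constants) is installed from R with kinmech_set_model() before each
 * integration; kinmech_derivs() is then passed to deSolve by name.
 *
 * rate_j = k_j * prod_i y_i^ord(j,i); dy_i/dt = sum_j nu(j,i) * rate_j.
 * Powers are expanded as repeated products so that slightly negative
 * solver states (within absolute tolerance) remain well-defined.
 */

#include <R.h>
#include <Rinternals.h>

#define KM_MAX_STEPS 16
#define KM_MAX_SPECIES 16

static int km_S = 0, km_N = 0;
static double km_nu[KM_MAX_STEPS * KM_MAX_SPECIES];  /* column-major S x N */
static double km_ord[KM_MAX_STEPS * KM_MAX_SPECIES];
static double km_k[KM_MAX_STEPS];

SEXP kinmech_set_model(SEXP packed)
{
    double *p = REAL(packed);
    int S = (int) p[0], N = (int) p[1], i;
    if (S < 1 || S > KM_MAX_STEPS || N < 1 || N > KM_MAX_SPECIES)
        error("model size out of range (max %d steps, %d species)",
              KM_MAX_STEPS, KM_MAX_SPECIES);
    if (LENGTH(packed) != 2 + 2 * S * N + S)
        error("packed model vector has wrong length");
    km_S = S; km_N = N;
    for (i = 0; i < S * N; i++) km_nu[i] = p[2 + i];
    for (i = 0; i < S * N; i++) km_ord[i] = p[2 + S * N + i];
    for (i = 0; i < S; i++) km_k[i] = p[2 + 2 * S * N + i];
    return R_NilValue;
}

void kinmech_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int i, j, m;
    double r;
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (j = 0; j < km_S; j++) {
        r = km_k[j];
        for (i = 0; i < km_N; i++) {
            int o = (int) km_ord[j + i * km_S];
            for (m = 0; m < o; m++) r *= y[i];
        }
        for (i = 0; i < km_N; i++)
            ydot[i] += km_nu[j + i * km_S] * r;
    }
}
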