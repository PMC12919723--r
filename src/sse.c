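/* Compiled sum-of-squared-errors objective for rate-constant fitting.
 *
 * Integrates the active mass-action model from each experiment's initial
 * condition with an adaptive Cash-Karp Runge-Kutta (4,5) scheme, stopping
 * exactly at the sampling times, and accumulates squared residuals over
 * the observed species.  Error control matches the package's solver
 * options: per-component scale atol + rtol*|y|, RMS norm.  An experiment
 * whose integration fails (step count exhausted, step size underflow, or
 * non-finite state) contributes the failure penalty instead, mirroring
 * the interpreted objective.
 *
 * This is the hot path of mechanism discovery (hundreds of candidate
 * models x multistart x finite-difference gradients); the interpreted
 * deSolve-based objective remains available and the two are checked
 * against each other in the test suite.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define SSE_MAX_SPECIES 16
#define SSE_MAX_STEPS_M 16

typedef struct {
    int S, N;
    double nu[SSE_MAX_STEPS_M * SSE_MAX_SPECIES];   /* column-major S x N */
    int ord[SSE_MAX_STEPS_M * SSE_MAX_SPECIES];
    double k[SSE_MAX_STEPS_M];
} ma_model;

static void ma_deriv(const ma_model *m, const double *y, double *ydot)
{
    int i, j, p;
    double r;
    for (i = 0; i < m->N; i++) ydot[i] = 0.0;
    for (j = 0; j < m->S; j++) {
        r = m->k[j];
        for (i = 0; i < m->N; i++)
            for (p = 0; p < m->ord[j + i * m->S]; p++) r *= y[i];
        for (i = 0; i < m->N; i++)
            ydot[i] += m->nu[j + i * m->S] * r;
    }
}

/* Cash-Karp tableau */
static const double CK_B5[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0,
                                512.0/1771};
static const double CK_B4[6] = {2825.0/27648, 0, 18575.0/48384,
                                13525.0/55296, 277.0/14336, 0.25};
static const double CK_A[6][5] = {
    {0, 0, 0, 0, 0},
    {0.2, 0, 0, 0, 0},
    {3.0/40, 9.0/40, 0, 0, 0},
    {0.3, -0.9, 1.2, 0, 0},
    {-11.0/54, 2.5, -70.0/27, 35.0/27, 0},
    {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}
};

/* integrate y in place from t0 to t1; returns 0 on success */
static int rk45_advance(const ma_model *m, double *y, double t0, double t1,
                        double rtol, double atol, long *steps_left)
{
    int i, s, n = m->N;
    double t = t0, h = (t1 - t0) / 16.0;
    double ks[6][SSE_MAX_SPECIES], ytmp[SSE_MAX_SPECIES],
           y5[SSE_MAX_SPECIES], err, sc;
    const double hmin = (t1 - t0) * 1e-14;

    while (t < t1) {
        if ((*steps_left)-- <= 0) return 1;
        if (h > t1 - t) h = t1 - t;
        if (h < hmin) return 2;
        for (s = 0; s < 6; s++) {
            for (i = 0; i < n; i++) {
                double acc = y[i];
                int q;
                for (q = 0; q < s; q++) acc += h * CK_A[s][q] * ks[q][i];
                ytmp[i] = acc;
            }
            ma_deriv(m, ytmp, ks[s]);
        }
        err = 0.0;
        for (i = 0; i < n; i++) {
            double d5 = 0.0, d4 = 0.0;
            for (s = 0; s < 6; s++) {
                d5 += CK_B5[s] * ks[s][i];
                d4 += CK_B4[s] * ks[s][i];
            }
            y5[i] = y[i] + h * d5;
            sc = atol + rtol * fmax(fabs(y[i]), fabs(y5[i]));
            d4 = h * (d5 - d4) / sc;
            err += d4 * d4;
        }
        err = sqrt(err / n);
        if (!R_FINITE(err)) return 3;
        if (err <= 1.0) {
            t += h;
            for (i = 0; i < n; i++) y[i] = y5[i];
            if (!R_FINITE(y[0])) return 3;
        }
        {
            double fac = (err > 1e-30) ? 0.9 * pow(err, -0.2) : 5.0;
            if (fac < 0.2) fac = 0.2;
            if (fac > 5.0) fac = 5.0;
            h *= fac;
        }
    }
    for (i = 0; i < n; i++) if (!R_FINITE(y[i])) return 3;
    return 0;
}

/* args: packed model (S, N, nu, ord) without k; k; list of experiments,
 * each list(t, y(nt x nobs), c0, obs0 (0-based)); rtol; atol; penalty */
SEXP kinmech_sse_rk45(SEXP packedS, SEXP kS, SEXP expsS, SEXP rtolS,
                      SEXP atolS, SEXP penaltyS)
{
    ma_model m;
    double *p = REAL(packedS);
    const double rtol = asReal(rtolS), atol = asReal(atolS),
                 penalty = asReal(penaltyS);
    double total = 0.0;
    int i, e;

    m.S = (int) p[0]; m.N = (int) p[1];
    if (m.S < 1 || m.S > SSE_MAX_STEPS_M || m.N < 1 || m.N > SSE_MAX_SPECIES)
        error("model size out of range");
    for (i = 0; i < m.S * m.N; i++) m.nu[i] = p[2 + i];
    for (i = 0; i < m.S * m.N; i++) m.ord[i] = (int) p[2 + m.S * m.N + i];
    if (LENGTH(kS) != m.S) error("rate-constant vector has wrong length");
    for (i = 0; i < m.S; i++) m.k[i] = REAL(kS)[i];

    for (e = 0; e < LENGTH(expsS); e++) {
        SEXP ex = VECTOR_ELT(expsS, e);
        SEXP tS = VECTOR_ELT(ex, 0), yS = VECTOR_ELT(ex, 1),
             c0S = VECTOR_ELT(ex, 2), obsS = VECTOR_ELT(ex, 3);
        const double *tt = REAL(tS), *yy = REAL(yS), *c0 = REAL(c0S);
        const int *obs = INTEGER(obsS);
        const int nt = LENGTH(tS), nobs = LENGTH(obsS);
        double y[SSE_MAX_SPECIES], sse = 0.0;
        long steps_left = 200000;
        int it, j, failed = 0;

        if (LENGTH(c0S) != m.N) error("initial condition has wrong length");
        for (i = 0; i < m.N; i++) y[i] = c0[i];
        for (j = 0; j < nobs; j++) {
            const double r = y[obs[j]] - yy[0 + j * nt];
            sse += r * r;
        }
        for (it = 1; it < nt && !failed; it++) {
            if (rk45_advance(&m, y, tt[it - 1], tt[it], rtol, atol,
                             &steps_left) != 0) {
                failed = 1;
                break;
            }
            for (j = 0; j < nobs; j++) {
                const double r = y[obs[j]] - yy[it + j * nt];
                sse += r * r;
            }
        }
        total += failed ? penalty : sse;
    }
    return ScalarReal(total);
}
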