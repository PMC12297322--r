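/* Compiled right-hand side of the feedback-regulated lineage system,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * State layout: y[0] = Q, y[1] = A, y[2 .. 2+n] = T0..Tn, y[n+3] = N,
 * with n = neq - 4 amplification steps.
 *
 * Parameter vector (set through the initfunc):
 *   0 r0, 1 r1, 2 K, 3 b0, 4 beta, 5 pA, 6 pT, 7 delta,
 *   8 c1 code, 9 c2 code, 10 c3 code, 11 d (chemotherapy kill rate).
 * Population selector codes: 1 Q, 2 A, 3 Q+A, 4 T0, 5 sum(Ti), 6 N.
 */
#include <R.h>

#define N_PARMS 12
static double parms[N_PARMS];

void lineage_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double selector(int code, const double *x, int n, int neq)
{
    switch (code) {
    case 1: return x[0];
    case 2: return x[1];
    case 3: return x[0] + x[1];
    case 4: return x[2];
    case 5: {
        double s = 0.0;
        for (int i = 0; i <= n; i++) s += x[2 + i];
        return s;
    }
    case 6: return x[neq - 1];
    }
    return 0.0;
}

void lineage_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int n = *neq - 4;
    double x[64];
    for (int i = 0; i < *neq; i++)
        x[i] = y[i] > 0.0 ? y[i] : 0.0; /* clip integrator undershoot */

    double c1 = selector((int) parms[8], x, n, *neq);
    double c2 = selector((int) parms[9], x, n, *neq);
    double c3 = selector((int) parms[10], x, n, *neq);
    double r = (parms[1] + parms[0] * c1) / (parms[2] + c2);
    double b = parms[3] / (1.0 + parms[4] * c3);
    double pA = parms[5], pT = parms[6], delta = parms[7], d = parms[11];
    double Q = x[0], A = x[1];

    ydot[0] = -r * Q + 2.0 * b * pA * A;
    ydot[1] = r * Q - pA * A - d * A;
    ydot[2] = 2.0 * (1.0 - b) * pA * A - (pT + d) * x[2];
    for (int i = 1; i <= n; i++)
        ydot[2 + i] = 2.0 * pT * x[1 + i] - (pT + d) * x[2 + i];
    ydot[*neq - 1] = 2.0 * pT * x[2 + n] - delta * x[*neq - 1];
}
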