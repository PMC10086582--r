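/* Compiled right-hand side of the two-compartment NSC model for deSolve.
 *
 * State: y[0] = qNSC, y[1] = aNSC.
 * Parameter vector (see .ode_parms() in R/model.R):
 *   [0] r0   [1] beta_r  [2] b0  [3] beta_b  [4] ps  [5] kb  [6] nb
 *   [7] activation law   (0 = constant, 1 = exponential decay)
 *   [8] self-renewal law (0 = constant, 1 = time-logistic, 2 = Hill)
 */
#include <R.h>
#include <math.h>

static double parms[9];

void nsc_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void nsc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double r0 = parms[0], beta_r = parms[1], b0 = parms[2],
                 beta_b = parms[3], ps = parms[4], kb = parms[5],
                 nb = parms[6];
    const int act = (int) parms[7], sr = (int) parms[8];

    double r = (act == 1) ? r0 * exp(-beta_r * (*t)) : r0;

    double b;
    if (sr == 0) {
        b = b0;
    } else if (sr == 1) {
        b = 0.5 * (1.0 + exp(-beta_b * (*t)) * (2.0 * b0 - 1.0));
    } else {
        double N = y[0] + y[1];
        double x = pow(kb * N, nb);   /* pow(0, nb<0) = Inf -> b = 1 */
        b = isinf(x) ? 1.0 : x / (1.0 + x);
    }

    ydot[0] = -r * y[0] + 2.0 * b * ps * y[1];
    ydot[1] = r * y[0] - ps * y[1];
}
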