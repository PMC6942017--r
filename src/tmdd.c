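/* Five-state quasi-equilibrium TMDD model with two receptor forms.
 *
 * States (amounts, nmol):
 *   y[0] A1 total antibody, central      y[1] A2 free antibody, peripheral
 *   y[2] A3 total soluble receptor       y[3] A4 total cellular receptor
 *   y[4] A5 SC depot
 *
 * The QE binding system is reduced to a scalar mass balance in the free
 * antibody concentration c (nM),
 *   A1/Vc = c (1 + (A3/Vc)/(KD1+c) + (A4/Vc)/(KD2+c)),
 * which is strictly increasing in c; it is solved by a Newton iteration
 * safeguarded by bisection on [0, A1/Vc]. This is algebraically the same
 * solution as the coupled quadratic pair solved in R by
 * solve_complex_pair(); the two are cross-checked in the test suite.
 *
 * Parameter vector (via initfunc, order fixed):
 *   0 CL_A  1 V_C  2 V_P  3 Q  4 k_A  5 CL_SR  6 CL_C1  7 KD1
 *   8 CL_CR  9 CL_C2  10 KD2  11 k_syn1  12 k_syn2
 */

#include <R.h>
#include <math.h>

static double parms[13];

void il7r_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

static double qe_free_conc(double a1, double a3, double a4,
                           double kd1, double kd2)
{
    double lo, hi, c, f, df, cn;
    int i;

    if (a1 <= 0.0)
        return 0.0;
    lo = 0.0;
    hi = a1;
    c = 0.5 * a1;
    for (i = 0; i < 100; i++) {
        f = c * (1.0 + a3 / (kd1 + c) + a4 / (kd2 + c)) - a1;
        if (f > 0.0)
            hi = c;
        else
            lo = c;
        df = 1.0 + a3 * kd1 / ((kd1 + c) * (kd1 + c))
                 + a4 * kd2 / ((kd2 + c) * (kd2 + c));
        cn = c - f / df;
        if (!(cn > lo && cn < hi))
            cn = 0.5 * (lo + hi);
        if (fabs(cn - c) <= 1e-14 * (c + a1 * 1e-16) + 1e-300) {
            c = cn;
            break;
        }
        c = cn;
    }
    return c;
}

void il7r_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double A1, A2, A3, A4, A5, Vc, c, cpx1, cpx2, fab, fsr, fcr;

    if (ip[0] < 5)
        error("nout must be at least 5");

    A1 = y[0] > 0.0 ? y[0] : 0.0;
    A2 = y[1];
    A3 = y[2] > 0.0 ? y[2] : 0.0;
    A4 = y[3] > 0.0 ? y[3] : 0.0;
    A5 = y[4] > 0.0 ? y[4] : 0.0;
    Vc = parms[1];

    c = qe_free_conc(A1 / Vc, A3 / Vc, A4 / Vc, parms[7], parms[10]);
    cpx1 = A3 * c / (parms[7] + c);
    cpx2 = A4 * c / (parms[10] + c);
    fab = A1 - cpx1 - cpx2;
    if (fab < 0.0)
        fab = 0.0;
    fsr = A3 - cpx1;
    fcr = A4 - cpx2;

    ydot[0] = parms[4] * A5
            + parms[3] * (A2 / parms[2] - fab / Vc)
            - parms[0] / Vc * fab
            - parms[6] / Vc * cpx1
            - parms[9] / Vc * cpx2;
    ydot[1] = parms[3] * (fab / Vc - A2 / parms[2]);
    ydot[2] = parms[11] - parms[5] / Vc * fsr - parms[6] / Vc * cpx1;
    ydot[3] = parms[12] - parms[8] / Vc * fcr - parms[9] / Vc * cpx2;
    ydot[4] = -parms[4] * A5;

    yout[0] = cpx1;
    yout[1] = cpx2;
    yout[2] = fab;
    yout[3] = fsr;
    yout[4] = fcr;
}
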