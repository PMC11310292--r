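/* Compiled right-hand sides for the tumor-estrogen-fat models and the
 * adjoint system, in the deSolve compiled-code convention (initfunc /
 * initforc / derivs looked up by name through the package DLL).
 *
 * These mirror the exported R reference implementations base_rhs(),
 * ext_rhs() and adjoint_rhs(); the test suite asserts their equivalence.
 */

#include <R.h>
#include <math.h>

/* decreasing Hill switch a^l / (a^l + E^l); safe for large l since
 * exp() saturates cleanly in IEEE arithmetic */
static double hill(double E, double a, double l)
{
    if (E <= 0.0) return 1.0;
    return 1.0 / (1.0 + exp(l * (log(E) - log(a))));
}

static double clip0(double x) { return x > 0.0 ? x : 0.0; }

/* ------------------------------------------------------------------ */
/* basic model: parms = (k1, a1, m1, r, mu, alpha)                     */

static double pb[6];

void init_basic(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, pb);
}

void derivs_basic(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double k1 = pb[0], a1 = pb[1], m1 = pb[2], r = pb[3], mu = pb[4],
           alpha = pb[5];
    double T = clip0(y[0]), E = clip0(y[1]), F = clip0(y[2]);
    ydot[0] = k1 * E / (a1 + E) * T * (1.0 - m1 * T);
    ydot[1] = r * F - mu * E;
    ydot[2] = -alpha * T * F;
}

/* ------------------------------------------------------------------ */
/* extended model: parms = (k1, a1, m1, r, mu, alpha, eta, c, l,
 *                          a2, a3, k3, k2, m2); control u is forcing 1 */

static double pe[14];
static double fe[1];

void init_ext(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, pe);
}

void forc_ext(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, fe);
}

void derivs_ext(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double k1 = pe[0], a1 = pe[1], m1 = pe[2], r = pe[3], mu = pe[4],
           alpha = pe[5], eta = pe[6], c = pe[7], l = pe[8], a2 = pe[9],
           a3 = pe[10], k3 = pe[11], k2 = pe[12], m2 = pe[13];
    double S = clip0(y[0]), R = clip0(y[1]), E = clip0(y[2]),
           F = clip0(y[3]);
    double u = fe[0];
    if (u < 0.0) u = 0.0;
    if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;

    double crowd = 1.0 - m1 * (S + eta * R);
    double h2 = hill(E, a2, l), h3 = hill(E, a3, l);
    ydot[0] = k1 * E / (a1 + E) * S * crowd - c * h2 * S - c * h3 * S;
    ydot[1] = k3 * R * crowd + c * h3 * S;
    ydot[2] = (1.0 - u) * r * F - mu * E;
    ydot[3] = k2 * F * (1.0 - m2 * F) - alpha * (S + R) * F;
}

/* ------------------------------------------------------------------ */
/* adjoint system in reversed time tau = t_f - t:
 * parms = extended parms + (omega_S, omega_R); forcings supply the
 * forward state (S, R, E, F) and control u, tabulated against tau.    */

static double pa[16];
static double fa[5];

void init_adj(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, pa);
}

void forc_adj(void (*odeforcs)(int *, double *))
{
    int n = 5;
    odeforcs(&n, fa);
}

void derivs_adj(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double k1 = pa[0], a1 = pa[1], m1 = pa[2], r = pa[3], mu = pa[4],
           alpha = pa[5], eta = pa[6], c = pa[7], l = pa[8], a2 = pa[9],
           a3 = pa[10], k3 = pa[11], k2 = pa[12], m2 = pa[13],
           wS = pa[14], wR = pa[15];
    double S = clip0(fa[0]), R = clip0(fa[1]), E = clip0(fa[2]),
           F = clip0(fa[3]), u = fa[4];
    double l1 = y[0], l2 = y[1], l3 = y[2], l4 = y[3];

    double g = k1 * E / (a1 + E);
    double dg = k1 * a1 / ((a1 + E) * (a1 + E));
    double h2 = hill(E, a2, l), h3 = hill(E, a3, l);
    double mdh2 = E > 0.0 ? (l / E) * h2 * (1.0 - h2) : 0.0;
    double mdh3 = E > 0.0 ? (l / E) * h3 * (1.0 - h3) : 0.0;
    double crowd = 1.0 - m1 * (S + eta * R);

    double d1 = -wS - l1 * (g * (1.0 - m1 * (2.0 * S + eta * R)) -
                            c * (h2 + h3)) +
                l2 * (m1 * k3 * R - c * h3) + l4 * alpha * F;
    double d2 = -wR + l1 * g * S * m1 * eta -
                l2 * k3 * (1.0 - m1 * (S + 2.0 * eta * R)) +
                l4 * alpha * F;
    double d3 = -l1 * (S * crowd * dg + c * S * (mdh2 + mdh3)) +
                l2 * c * S * mdh3 + l3 * mu;
    double d4 = -l3 * (1.0 - u) * r -
                l4 * (k2 - 2.0 * k2 * m2 * F - alpha * (S + R));

    /* reversed time */
    ydot[0] = -d1;
    ydot[1] = -d2;
    ydot[2] = -d3;
    ydot[3] = -d4;
}
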