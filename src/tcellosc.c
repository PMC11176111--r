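/* Compiled right-hand sides of the T-cell Ca2+ model for deSolve.
 *
 * Parameter vector layout (see .param_vector() on the R side):
 *  0 V_PLC   1 delta   2 C_t     3 gamma   4 V_PM    5 K_PM
 *  6 V_SOCE  7 s1      8 K_e     9 tau_s  10 V_SERCA 11 K_SERCA
 * 12 K_bar  13 k_f    14 k_beta 15 K_p    16 K_c     17 K_h
 * 18 tau_max 19 K_tau 20 tau_p  21 V_deg  22 K_deg
 *
 * The *_var entries integrate the variational (monodromy) equations
 * alongside the state: y = (x, vec(M)) with dM/dt = J(x) M, J obtained
 * by central finite differences of the compiled vector field.
 */
#include <R.h>
#include <math.h>

static double parms[23];

#define P_VPLC   parms[0]
#define P_DELTA  parms[1]
#define P_CT     parms[2]
#define P_GAMMA  parms[3]
#define P_VPM    parms[4]
#define P_KPM    parms[5]
#define P_VSOCE  parms[6]
#define P_S1     parms[7]
#define P_KE     parms[8]
#define P_TAUS   parms[9]
#define P_VSERCA parms[10]
#define P_KSERCA parms[11]
#define P_KBAR   parms[12]
#define P_KF     parms[13]
#define P_KBETA  parms[14]
#define P_KP     parms[15]
#define P_KC     parms[16]
#define P_KH     parms[17]
#define P_TAUMAX parms[18]
#define P_KTAU   parms[19]
#define P_TAUP   parms[20]
#define P_VDEG   parms[21]
#define P_KDEG   parms[22]

void tco_init(void (*odeparms)(int *, double *))
{
    int N = 23;
    odeparms(&N, parms);
}

static double sq(double x) { return x * x; }
static double q4(double x) { double y = x * x; return y * y; }

/* core fluxes shared by both cell models */
static void core_rates(double c, double ce, double h, double p,
                       double *jip, double *jser, double *dh, double *dp)
{
    double phic = q4(c) / (q4(c) + q4(P_KC));
    double phip = sq(p) / (sq(p) + sq(P_KP));
    double phipm = sq(P_KP) / (sq(p) + sq(P_KP));
    double hinf = q4(P_KH) / (q4(c) + q4(P_KH));
    double tauh = P_TAUMAX * q4(P_KTAU) / (q4(P_KTAU) + q4(c));
    double beta = phip * phic * h;
    double alpha = phipm * (1.0 - phic * hinf);
    double p0 = beta / (beta + P_KBETA * (beta + alpha));
    double jdeg = P_VDEG * sq(c) / (sq(c) + sq(P_KDEG)) * p;

    *jip = P_KF * p0 * (ce - c);
    *jser = P_VSERCA * (sq(c) - P_KBAR * sq(ce)) / (sq(c) + sq(P_KSERCA));
    *dh = (hinf - h) / tauh;
    *dp = (P_VPLC - jdeg) / P_TAUP;
}

static void f_open(double *y, double *dy)
{
    double c = y[0], ce = y[1], h = y[2], p = y[3], s = y[4];
    double jip, jser, dh, dp;
    core_rates(c, ce, h, p, &jip, &jser, &dh, &dp);
    double jpm = P_VPM * sq(c) / (sq(c) + sq(P_KPM));
    double jsoce = P_VSOCE / (1.0 + exp(P_S1 * (ce - P_KE)));
    dy[0] = jip - jser + P_DELTA * (s - jpm);
    dy[1] = P_GAMMA * (jser - jip);
    dy[2] = dh;
    dy[3] = dp;
    dy[4] = (jsoce - s) / P_TAUS;
}

static void f_closed(double *y, double *dy)
{
    double c = y[0], h = y[1], p = y[2];
    double ce = P_GAMMA * (P_CT - c);
    double jip, jser, dh, dp;
    core_rates(c, ce, h, p, &jip, &jser, &dh, &dp);
    dy[0] = jip - jser;
    dy[1] = dh;
    dy[2] = dp;
}

void tco_open(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    f_open(y, ydot);
}

void tco_closed(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    f_closed(y, ydot);
}

/* central-difference Jacobian of a compiled vector field */
static void fd_jac(void (*f)(double *, double *), double *y, int n,
                   double *J)
{
    double yp[5], fp[5], fm[5];
    int i, j;
    for (j = 0; j < n; j++) {
        double d = 1e-7 * (1.0 + fabs(y[j]));
        for (i = 0; i < n; i++) yp[i] = y[i];
        yp[j] = y[j] + d; f(yp, fp);
        yp[j] = y[j] - d; f(yp, fm);
        for (i = 0; i < n; i++) J[i + n * j] = (fp[i] - fm[i]) / (2.0 * d);
    }
}

static void var_rhs(void (*f)(double *, double *), int n, double *y,
                    double *ydot)
{
    double J[25];
    int i, j, k;
    f(y, ydot);
    fd_jac(f, y, n, J);
    /* columns of M stored after the state, column-major */
    for (j = 0; j < n; j++) {
        double *m = y + n + n * j;
        double *md = ydot + n + n * j;
        for (i = 0; i < n; i++) {
            double acc = 0.0;
            for (k = 0; k < n; k++) acc += J[i + n * k] * m[k];
            md[i] = acc;
        }
    }
}

void tco_open_var(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    var_rhs(f_open, 5, y, ydot);
}

void tco_closed_var(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    var_rhs(f_closed, 3, y, ydot);
}
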