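/* Compiled right-hand sides for deSolve: the macrocolumnar Liley model,
 * three benchmark systems, and the augmented tangent systems used for
 * partial Lyapunov spectra (continuous Gram-Schmidt and discrete QR).
 *
 * Parameter vector layout (padded to PARMS_LEN by the R wrappers):
 *   P[0] system id: 1 = liley, 2 = diagonal linear, 3 = hopf, 4 = lorenz63
 *   P[1] n      base-system dimension
 *   P[2] k      number of tangent vectors (0 for plain simulation)
 *   P[3] method 0 = continuous Gram-Schmidt, 1 = discrete (plain tangent)
 *   P[4..]      system parameters (order documented in R/systems.R)
 *
 * Augmented state layout: y[0..n-1] base state, then k tangent vectors of
 * length n, then k exponent accumulators nu_i (natural log, per ms once
 * divided by elapsed time).  Time unit throughout: ms.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define PARMS_LEN 64
#define NMAX 12

static double P[PARMS_LEN];

void lc_initmod(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, P);
}

/* ---- Liley macrocolumn model -------------------------------------- */

/* parameter slots, offset by 4 */
enum {
    L_HER = 4, L_HIR, L_HEEQ, L_HIEQ, L_TAUE, L_TAUI,
    L_GEE, L_GEI, L_GIE, L_GII,           /* Gamma (PSP peak, mV) */
    L_gEE, L_gEI, L_gIE, L_gII,           /* gamma (PSP rate, /ms) */
    L_NEE, L_NEI, L_NIE, L_NII,
    L_SEMAX, L_SIMAX, L_MUE, L_MUI, L_SIGE, L_SIGI,
    L_PEE, L_PEI, L_PIE, L_PII
};

static double sigm(double h, double smax, double mu, double sigma)
{
    return smax / (1.0 + exp(-M_SQRT2 * (h - mu) / sigma));
}

/* dS/dh expressed through S itself: S' = (sqrt(2)/sigma) S (1 - S/Smax) */
static double sigm_d(double h, double smax, double mu, double sigma)
{
    double s = sigm(h, smax, mu, sigma);
    return M_SQRT2 / sigma * s * (1.0 - s / smax);
}

/* Subscript convention (Liley): jk = target population j, synapse type
 * (source) k.  I_ee, I_ei are the excitatory and inhibitory PSP
 * activities at the excitatory population; I_ie, I_ii at the inhibitory
 * population.  p_ei is external inhibitory drive onto e-cells. */
static void liley_rhs(const double *y, double *dy)
{
    double he = y[0], hi = y[1];
    double dee = fabs(P[L_HEEQ] - P[L_HER]), die = fabs(P[L_HIEQ] - P[L_HER]);
    double dei = fabs(P[L_HEEQ] - P[L_HIR]), dii = fabs(P[L_HIEQ] - P[L_HIR]);
    double psi_ee = (P[L_HEEQ] - he) / dee, psi_ei = (P[L_HIEQ] - he) / die;
    double psi_ie = (P[L_HEEQ] - hi) / dei, psi_ii = (P[L_HIEQ] - hi) / dii;
    double se = sigm(he, P[L_SEMAX], P[L_MUE], P[L_SIGE]);
    double si = sigm(hi, P[L_SIMAX], P[L_MUI], P[L_SIGI]);
    double g, A;

    dy[0] = (P[L_HER] - he + psi_ee * y[2] + psi_ei * y[4]) / P[L_TAUE];
    dy[1] = (P[L_HIR] - hi + psi_ie * y[6] + psi_ii * y[8]) / P[L_TAUI];

    /* critically damped second-order synaptic responses; the source
     * population of channel jk is k */
    g = P[L_gEE]; A = M_E * P[L_GEE] * g;
    dy[2] = y[3];
    dy[3] = -2.0 * g * y[3] - g * g * y[2] + A * (P[L_NEE] * se + P[L_PEE]);
    g = P[L_gEI]; A = M_E * P[L_GEI] * g;
    dy[4] = y[5];
    dy[5] = -2.0 * g * y[5] - g * g * y[4] + A * (P[L_NEI] * si + P[L_PEI]);
    g = P[L_gIE]; A = M_E * P[L_GIE] * g;
    dy[6] = y[7];
    dy[7] = -2.0 * g * y[7] - g * g * y[6] + A * (P[L_NIE] * se + P[L_PIE]);
    g = P[L_gII]; A = M_E * P[L_GII] * g;
    dy[8] = y[9];
    dy[9] = -2.0 * g * y[9] - g * g * y[8] + A * (P[L_NII] * si + P[L_PII]);
}

static void liley_jac(const double *y, double *J, int n)
{
    double he = y[0], hi = y[1];
    double dee = fabs(P[L_HEEQ] - P[L_HER]), die = fabs(P[L_HIEQ] - P[L_HER]);
    double dei = fabs(P[L_HEEQ] - P[L_HIR]), dii = fabs(P[L_HIEQ] - P[L_HIR]);
    double sde = sigm_d(he, P[L_SEMAX], P[L_MUE], P[L_SIGE]);
    double sdi = sigm_d(hi, P[L_SIMAX], P[L_MUI], P[L_SIGI]);
    double g;
    int i;

    for (i = 0; i < n * n; i++) J[i] = 0.0;
#define JAC(r, c) J[(r) * n + (c)]
    JAC(0, 0) = (-1.0 - y[2] / dee - y[4] / die) / P[L_TAUE];
    JAC(0, 2) = (P[L_HEEQ] - he) / dee / P[L_TAUE];
    JAC(0, 4) = (P[L_HIEQ] - he) / die / P[L_TAUE];
    JAC(1, 1) = (-1.0 - y[6] / dei - y[8] / dii) / P[L_TAUI];
    JAC(1, 6) = (P[L_HEEQ] - hi) / dei / P[L_TAUI];
    JAC(1, 8) = (P[L_HIEQ] - hi) / dii / P[L_TAUI];

    g = P[L_gEE];
    JAC(2, 3) = 1.0;
    JAC(3, 2) = -g * g; JAC(3, 3) = -2.0 * g;
    JAC(3, 0) = M_E * P[L_GEE] * g * P[L_NEE] * sde;
    g = P[L_gEI];
    JAC(4, 5) = 1.0;
    JAC(5, 4) = -g * g; JAC(5, 5) = -2.0 * g;
    JAC(5, 1) = M_E * P[L_GEI] * g * P[L_NEI] * sdi;
    g = P[L_gIE];
    JAC(6, 7) = 1.0;
    JAC(7, 6) = -g * g; JAC(7, 7) = -2.0 * g;
    JAC(7, 0) = M_E * P[L_GIE] * g * P[L_NIE] * sde;
    g = P[L_gII];
    JAC(8, 9) = 1.0;
    JAC(9, 8) = -g * g; JAC(9, 9) = -2.0 * g;
    JAC(9, 1) = M_E * P[L_GII] * g * P[L_NII] * sdi;
#undef JAC
}

/* ---- benchmark systems -------------------------------------------- */

static void diag_rhs(const double *y, double *dy, int n)
{
    int i;
    for (i = 0; i < n; i++) dy[i] = P[4 + i] * y[i];
}

static void diag_jac(const double *y, double *J, int n)
{
    int i;
    for (i = 0; i < n * n; i++) J[i] = 0.0;
    for (i = 0; i < n; i++) J[i * n + i] = P[4 + i];
    (void) y;
}

static void hopf_rhs(const double *y, double *dy)
{
    double mu = P[4], om = P[5], r2 = y[0] * y[0] + y[1] * y[1];
    dy[0] = mu * y[0] - om * y[1] - r2 * y[0];
    dy[1] = om * y[0] + mu * y[1] - r2 * y[1];
}

static void hopf_jac(const double *y, double *J, int n)
{
    double mu = P[4], om = P[5], x = y[0], z = y[1];
    J[0 * n + 0] = mu - 3.0 * x * x - z * z;
    J[0 * n + 1] = -om - 2.0 * x * z;
    J[1 * n + 0] = om - 2.0 * x * z;
    J[1 * n + 1] = mu - x * x - 3.0 * z * z;
}

static void lorenz_rhs(const double *y, double *dy)
{
    double s = P[4], r = P[5], b = P[6];
    dy[0] = s * (y[1] - y[0]);
    dy[1] = y[0] * (r - y[2]) - y[1];
    dy[2] = y[0] * y[1] - b * y[2];
}

static void lorenz_jac(const double *y, double *J, int n)
{
    double s = P[4], r = P[5], b = P[6];
    J[0 * n + 0] = -s;   J[0 * n + 1] = s;     J[0 * n + 2] = 0.0;
    J[1 * n + 0] = r - y[2]; J[1 * n + 1] = -1.0; J[1 * n + 2] = -y[0];
    J[2 * n + 0] = y[1]; J[2 * n + 1] = y[0];  J[2 * n + 2] = -b;
}

static void sys_rhs(const double *y, double *dy, int n)
{
    switch ((int) P[0]) {
    case 1: liley_rhs(y, dy); break;
    case 2: diag_rhs(y, dy, n); break;
    case 3: hopf_rhs(y, dy); break;
    case 4: lorenz_rhs(y, dy); break;
    default: error("unknown system id %d", (int) P[0]);
    }
}

static void sys_jac(const double *y, double *J, int n)
{
    switch ((int) P[0]) {
    case 1: liley_jac(y, J, n); break;
    case 2: diag_jac(y, J, n); break;
    case 3: hopf_jac(y, J, n); break;
    case 4: lorenz_jac(y, J, n); break;
    default: error("unknown system id %d", (int) P[0]);
    }
}

/* ---- deSolve entry points ------------------------------------------ */

void lc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    sys_rhs(y, ydot, *neq);
    (void) t; (void) yout; (void) ip;
}

/* Augmented system: base flow + k tangent vectors + k log-growth
 * accumulators.  Continuous method builds Gram-Schmidt into the tangent
 * ODEs; discrete method integrates the raw tangent map and accumulates
 * at QR-renormalization events. */
void lc_derivs_aug(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int n = (int) P[1], k = (int) P[2], method = (int) P[3];
    double J[NMAX * NMAX], u[NMAX * NMAX];
    int i, j, c;

    sys_rhs(y, ydot, n);
    sys_jac(y, J, n);

    /* u_i = J e_i */
    for (i = 0; i < k; i++) {
        const double *e = y + n + i * n;
        double *ui = u + i * n;
        for (j = 0; j < n; j++) {
            double acc = 0.0;
            for (c = 0; c < n; c++) acc += J[j * n + c] * e[c];
            ui[j] = acc;
        }
    }

    for (i = 0; i < k; i++) {
        const double *ei = y + n + i * n;
        const double *ui = u + i * n;
        double *de = ydot + n + i * n;
        double aii = 0.0;
        for (c = 0; c < n; c++) aii += ei[c] * ui[c];
        ydot[n + k * n + i] = (method == 0) ? aii : 0.0;
        if (method == 0) {
            for (c = 0; c < n; c++) de[c] = ui[c] - aii * ei[c];
            for (j = 0; j < i; j++) {
                const double *ej = y + n + j * n;
                const double *uj = u + j * n;
                double a = 0.0, b = 0.0;
                for (c = 0; c < n; c++) {
                    a += ej[c] * ui[c];
                    b += ei[c] * uj[c];
                }
                for (c = 0; c < n; c++) de[c] -= (a + b) * ej[c];
            }
        } else {
            for (c = 0; c < n; c++) de[c] = ui[c];
        }
    }
    (void) t; (void) yout; (void) ip; (void) neq;
}

/* Event: modified Gram-Schmidt reorthonormalization of the tangent frame.
 * Discrete method folds the log of each diagonal norm into nu_i; the
 * continuous method uses the event purely as numerical insurance. */
void lc_event_renorm(int *neq, double *t, double *y)
{
    int n = (int) P[1], k = (int) P[2], method = (int) P[3];
    int i, j, c;

    for (i = 0; i < k; i++) {
        double *ei = y + n + i * n;
        double r = 0.0;
        for (j = 0; j < i; j++) {
            const double *ej = y + n + j * n;
            double a = 0.0;
            for (c = 0; c < n; c++) a += ej[c] * ei[c];
            for (c = 0; c < n; c++) ei[c] -= a * ej[c];
        }
        for (c = 0; c < n; c++) r += ei[c] * ei[c];
        r = sqrt(r);
        if (r <= 0.0 || !R_FINITE(r)) return;  /* degenerate frame: leave for R-side diagnosis */
        for (c = 0; c < n; c++) ei[c] /= r;
        if (method == 1) y[n + k * n + i] += log(r);
    }
    (void) t; (void) neq;
}

static const R_CMethodDef CEntries[] = {
    {"lc_initmod",      (DL_FUNC) &lc_initmod,      0},
    {"lc_derivs",       (DL_FUNC) &lc_derivs,       0},
    {"lc_derivs_aug",   (DL_FUNC) &lc_derivs_aug,   0},
    {"lc_event_renorm", (DL_FUNC) &lc_event_renorm, 0},
    {NULL, NULL, 0}
};

void R_init_lileyChaos(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
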