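/* Right-hand side of the extended glucose-insulin ODE system, compiled for
 * use with deSolve's native-code interface.  Parameter layout must match
 * edes_parms() in R/model.R exactly.
 *
 * States: y[0] gut glucose mass (mg)
 *         y[1] plasma glucose (mmol/L)
 *         y[2] integral secretion state, int (G - Gb) dt (mmol.min/L)
 *         y[3] plasma insulin (mU/L)
 *         y[4] remote (interstitial) insulin (mU/L)
 *         y[5] interstitial glucose (mmol/L)
 */
#include <R.h>
#include <math.h>

#define N_PARMS 27

static double p[N_PARMS];

void edes_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void edes_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double sigma = p[0],  k2 = p[1],    k3 = p[2],   k4 = p[3];
    const double k7 = p[4],     k8 = p[5],    k9 = p[6],   p_rem = p[7];
    const double tau_i = p[8],  tau_d = p[9], k_ren = p[10], G_thr = p[11];
    const double K_M = p[12],   V_G = p[13],  f_bio = p[14], beta = p[15];
    const double egp_b = p[16], f_conv = p[17];
    const double k1 = p[18],    k5 = p[19],   k6 = p[20],  tau_g = p[21];
    const double Gb = p[22],    Ib = p[23],   bw = p[24],  dose = p[25];

    const double M = y[0], G = y[1], Z = y[2], I = y[3], R = y[4], Gi = y[5];
    const double tt = *t;

    /* meal glucose flux into the gut: Weibull-shaped appearance, rate k1 */
    double m_meal = 0.0;
    if (tt > 0.0 && dose > 0.0) {
        double u = k1 * tt;
        m_meal = dose * 1000.0 * f_bio * sigma * k1 *
                 pow(u, sigma - 1.0) * exp(-pow(u, sigma));
    }

    /* steady-state closure: the insulin-independent uptake scale is set so
     * that total uptake balances basal endogenous production exactly at
     * (Gb, Ib); insulin-dependent uptake is driven by remote-insulin
     * elevation and vanishes at basal for every (k5, k6) */
    const double c_non = egp_b * (K_M + Gb) / Gb;

    const double g_liv = egp_b - k3 * (G - Gb) - k4 * k5 * beta * (R - Ib);
    const double g_gut = f_conv / (V_G * bw) * k2 * M;
    const double g_non = c_non * G / (K_M + G);
    const double g_it  = k5 * beta * (R - Ib) * G / (K_M + G);
    const double g_ren = (G > G_thr) ? k_ren * (G - G_thr) : 0.0;

    const double dG = g_liv + g_gut - g_non - g_it - g_ren;
    /* pancreatic secretion: PID drive with a smoothed non-negativity clamp
     * (exactly zero at basal; secretion shuts off, it never turns negative) */
    const double s_lin = k6 * (G - Gb) + (k7 / tau_i) * Z + k8 * tau_d * dG;
    const double s_eps = p[26];
    const double sec = 0.5 * (s_lin + sqrt(s_lin * s_lin + s_eps * s_eps))
                       - 0.5 * s_eps;
    const double dI = sec / beta - k9 * (I - Ib);

    ydot[0] = m_meal - k2 * M;
    ydot[1] = dG;
    ydot[2] = G - Gb;
    ydot[3] = dI;
    ydot[4] = p_rem * (I - R);
    /* interstitial lag; tau_g ~ 0 degenerates to Gi tracking G exactly */
    ydot[5] = (tau_g > 1e-9) ? (G - Gi) / tau_g : dG;
}
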