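/* Right-hand sides of the two dopaminergic-neuron models, in the
 * deSolve compiled-model convention (initmod_* receives the parameter
 * vector, derivs_* evaluates the derivatives).  Parameter order must
 * match the .pack_parms() helpers on the R side. */

#include <R.h>
#include <math.h>

/* ---------------- minimal model ---------------- */

static double pm[15];

void initmod_minimal(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, pm);
}

/* pm: 0 c, 1 eps, 2 a1, 3 a2, 4 a3, 5 a4, 6 g_kca, 7 e_k, 8 k_ca,
 *     9 k_w, 10 m_block, 11 e_n, 12 e_a, 13 g_a, 14 g_n */
void derivs_minimal(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double v = y[0], w = y[1];
    const double c = pm[0], eps = pm[1];
    const double w4 = w * w * w * w;
    const double k4 = pm[8] * pm[8] * pm[8] * pm[8];

    const double f = pm[2] * (v * v * v + pm[3] * v * v + pm[4] * v + pm[5]);
    const double jkca = pm[6] * (pm[7] - v) * w4 / (w4 + k4);
    const double gn = pm[14] / (1.0 + pm[10] * exp(-6.0 * v));
    const double jstim = gn * (pm[11] - v) + pm[13] * (pm[12] - v);
    /* upper branch applies at exactly w = 0 */
    const double g = (w >= 0.0) ? (v - pm[9]) : 0.01 * (v - pm[9]) - w;

    ydot[0] = (f + jkca + jstim) / c;
    ydot[1] = eps * g / c;
}

/* ---------------- biophysical model ---------------- */

static double pb[27];

void initmod_bio(void (*odeparms)(int *, double *))
{
    int n = 27;
    odeparms(&n, pb);
}

static double sigm(double v, double vhalf, double slope)
{
    return 1.0 / (1.0 + exp(-(v - vhalf) / slope));
}

/* pb: 0 cm, 1 gbar_ca, 2 e_ca, 3 gbar_kca, 4 k_ca, 5 gbar_erg,
 *     6 gbar_k, 7 e_k, 8 g_l, 9 e_l, 10 gbar_ampa, 11 e_ampa,
 *     12 gbar_nmda, 13 e_nmda, 14 mg, 15 radius, 16 beta_buf,
 *     17 z, 18 faraday, 19 p_ca, 20 erg_vhalf, 21 erg_slope,
 *     22 erg_tau_base, 23 erg_tau_amp, 24 erg_tau_v1, 25 erg_tau_v2,
 *     26 erg_tau_slope */
void derivs_bio(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double v = y[0], ca = y[1], n = y[2];

    /* L-type Ca conductance; removable singularity of alpha at v = -50 */
    const double x = v + 50.0;
    const double alpha = (fabs(x) < 1e-7)
        ? 0.0032 * 5.0
        : 0.0032 * x / (1.0 - exp(-x / 5.0));
    const double beta = 0.05 * exp(-(v + 55.0) / 40.0);
    double ab = alpha / (alpha + beta);
    ab *= ab; ab *= ab;
    const double gca = pb[1] * ab;

    const double ca4 = ca * ca * ca * ca;
    const double k4 = pb[4] * pb[4] * pb[4] * pb[4];
    const double gkca = pb[3] * ca4 / (ca4 + k4);

    const double gk = pb[6] * sigm(v, -10.0, 7.0);
    const double gnmda = pb[12] / (1.0 + 0.1 * pb[14] * exp(-0.062 * v));
    const double n4 = n * n * n * n;

    const double ninf = sigm(v, pb[20], pb[21]);
    /* decreasing-sigmoid convention keeps tau_n >= base everywhere */
    const double taun = pb[22] + pb[23] *
        (1.0 / (1.0 + exp((v - pb[24]) / pb[26])) -
         1.0 / (1.0 + exp((v - pb[25]) / pb[26])));

    ydot[0] = (gca * (pb[2] - v) +
               (gkca + pb[5] * n4 + gk) * (pb[7] - v) +
               pb[8] * (pb[9] - v) +
               pb[10] * (pb[11] - v) +
               gnmda * (pb[13] - v)) / pb[0];
    /* surface-to-volume flux scaling; with v in mV, g in mS/cm2, r in cm
     * and t in ms the net conversion to uM/ms is unity */
    ydot[1] = (2.0 * pb[16] / pb[15]) *
        (gca * (pb[2] - v) / (pb[17] * pb[18]) - pb[19] * ca);
    ydot[2] = (ninf - n) / taun;
}
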