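/* Compiled right-hand side of the single-compartment conductance-based
 * neuron for deSolve.  Seven voltage-gated channels (Na, CaS, CaT, A,
 * KCa, Kd, h) whose kinetic constants are passed in from the R-side
 * channel specifications, three passive channels (leak, e, i), and an
 * intracellular calcium pool.
 *
 * State vector (13):
 *   y[0]  V      membrane potential, mV
 *   y[1]  m_Na   y[2]  h_Na
 *   y[3]  m_CaS  y[4]  h_CaS
 *   y[5]  m_CaT  y[6]  h_CaT
 *   y[7]  m_A    y[8]  h_A
 *   y[9]  m_KCa
 *   y[10] m_Kd
 *   y[11] m_h
 *   y[12] Ca     intracellular calcium, uM
 *
 * Parameter vector layout (must match parms_vector() on the R side):
 *   0      Cm (uF/cm2)
 *   1..10  gbar: Na CaS CaT A KCa Kd h leak e i (mS/cm2)
 *   11..18 Erev: Na A KCa Kd h leak e i (mV; CaS/CaT dynamic)
 *   19     Nernst coefficient (mV, natural log)
 *   20     Cao (uM)
 *   21     tauCa (ms)
 *   22     effective calcium influx factor f/tauCa (uM cm2 / (uA ms))
 *   23     Ca baseline (uM)
 *   24     KCa coupling coefficient c
 *   25     KCa fixed-Ca value (uM; 0 => coupled to state Ca)
 *   26     KCa calcium half-saturation (uM)
 *   27..102  kinetic constants, see the offsets below
 *   103    stimulus kind (0 zero, 1 tonic, 2 pulse train)
 *   104    amplitude (uA/cm2)
 *   105    onset (ms)
 *   106    pulse width (ms)
 *   107    number of pulses
 *   108..  pulse onset times (ms, sorted)
 *
 * Kinetic blocks (all voltages mV, times ms):
 *   sigmoid        (a, k):                 1/(1 + exp((V+a)/k))
 *   scaled sigmoid (c0, c1, a, k):         c0 + c1/(1 + exp((V+a)/k))
 *   exp pair       (c0, c1, a1,k1,a2,k2):  c0 + c1/(e^((V+a1)/k1) + e^((V+a2)/k2))
 *   product        (two scaled sigmoids, 8 constants)
 */

#include <R.h>
#include <math.h>

#define NG_PARMS_LEN 50108   /* 108 header + up to 50000 pulse onsets */

/* kinetic-block offsets */
#define K_NA_M   27   /* sigmoid 2 */
#define K_NA_TM  29   /* scaled sigmoid 4 */
#define K_NA_H   33   /* sigmoid 2 */
#define K_NA_TH  35   /* product 8 */
#define K_CAS_M  43
#define K_CAS_TM 45   /* exp pair 6 */
#define K_CAS_H  51
#define K_CAS_TH 53   /* exp pair 6 */
#define K_CAT_M  59
#define K_CAT_TM 61
#define K_CAT_H  65
#define K_CAT_TH 67
#define K_A_M    71
#define K_A_TM   73
#define K_A_H    77
#define K_A_TH   79
#define K_KCA_M  83
#define K_KCA_TM 85
#define K_KD_M   89
#define K_KD_TM  91
#define K_H_M    95
#define K_H_TM   97   /* exp pair 6 */
#define K_STIM   103

static double p[NG_PARMS_LEN];

void ng_initmod(void (*odeparms)(int *, double *))
{
    int n = NG_PARMS_LEN;
    odeparms(&n, p);
}

static double sig2(double v, const double *q)
{
    return 1.0 / (1.0 + exp((v + q[0]) / q[1]));
}

static double ssig(double v, const double *q)
{
    return q[0] + q[1] / (1.0 + exp((v + q[2]) / q[3]));
}

static double epair(double v, const double *q)
{
    return q[0] + q[1] / (exp((v + q[2]) / q[3]) + exp((v + q[4]) / q[5]));
}

static double stim_current(double t)
{
    int kind = (int) p[K_STIM];
    if (kind == 1)
        return (t >= p[K_STIM + 2]) ? p[K_STIM + 1] : 0.0;
    if (kind == 2) {
        int n = (int) p[K_STIM + 4];
        const double *on = p + K_STIM + 5;
        int lo = 0, hi = n - 1, idx = -1;
        if (n <= 0 || t < on[0]) return 0.0;
        while (lo <= hi) {
            int mid = (lo + hi) / 2;
            if (on[mid] <= t) { idx = mid; lo = mid + 1; }
            else hi = mid - 1;
        }
        if (idx >= 0 && t < on[idx] + p[K_STIM + 3]) return p[K_STIM + 1];
        return 0.0;
    }
    return 0.0;
}

void ng_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double V = y[0];
    double Ca = y[12];
    if (Ca < 1e-9) Ca = 1e-9;

    double ca_eff = (p[25] > 0.0) ? p[25] : Ca;
    double ECa = p[19] * log(p[20] / Ca);

    /* currents, outward positive */
    double m;
    m = y[1];
    double INa  = p[1] * m * m * m * y[2] * (V - p[11]);
    m = y[3];
    double ICaS = p[2] * m * m * m * y[4] * (V - ECa);
    m = y[5];
    double ICaT = p[3] * m * m * m * y[6] * (V - ECa);
    m = y[7];
    double IA   = p[4] * m * m * m * y[8] * (V - p[12]);
    m = y[9];
    double IKCa = p[5] * m * m * m * m * (V - p[13]);
    m = y[10];
    double IKd  = p[6] * m * m * m * m * (V - p[14]);
    double Ih   = p[7] * y[11] * (V - p[15]);
    double Ileak = p[8] * (V - p[16]);
    double Ie    = p[9] * (V - p[17]);
    double Ii    = p[10] * (V - p[18]);

    double Isum = INa + ICaS + ICaT + IA + IKCa + IKd + Ih +
                  Ileak + Ie + Ii;
    double Istim = stim_current(*t);

    ydot[0]  = (Istim - Isum) / p[0];
    ydot[1]  = (sig2(V, p + K_NA_M)  - y[1]) / ssig(V, p + K_NA_TM);
    ydot[2]  = (sig2(V, p + K_NA_H)  - y[2]) /
               (ssig(V, p + K_NA_TH) * ssig(V, p + K_NA_TH + 4));
    ydot[3]  = (sig2(V, p + K_CAS_M) - y[3]) / epair(V, p + K_CAS_TM);
    ydot[4]  = (sig2(V, p + K_CAS_H) - y[4]) / epair(V, p + K_CAS_TH);
    ydot[5]  = (sig2(V, p + K_CAT_M) - y[5]) / ssig(V, p + K_CAT_TM);
    ydot[6]  = (sig2(V, p + K_CAT_H) - y[6]) / ssig(V, p + K_CAT_TH);
    ydot[7]  = (sig2(V, p + K_A_M)   - y[7]) / ssig(V, p + K_A_TM);
    ydot[8]  = (sig2(V, p + K_A_H)   - y[8]) / ssig(V, p + K_A_TH);
    ydot[9]  = (p[24] * (ca_eff / (ca_eff + p[26])) * sig2(V, p + K_KCA_M)
                - y[9]) / ssig(V, p + K_KCA_TM);
    ydot[10] = (sig2(V, p + K_KD_M)  - y[10]) / ssig(V, p + K_KD_TM);
    ydot[11] = (sig2(V, p + K_H_M)   - y[11]) / epair(V, p + K_H_TM);
    ydot[12] = -p[22] * (ICaT + ICaS) - (y[12] - p[23]) / p[21];

    if (ip[0] >= 1) yout[0] = Istim;
}
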