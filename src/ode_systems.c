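/* Compiled right-hand sides for the deSolve integrators.
 *
 * pk:   two-compartment model with parallel linear and Michaelis-Menten
 *       clearance from the central compartment.
 *       states  y0 = A1 (mg, central), y1 = A2 (mg, peripheral),
 *               y2 = cumulative AUC of C1 (mg*h/L)
 *       parms   0 CL (L/h), 1 V1 (L), 2 Q (L/h), 3 V2 (L),
 *               4 Vmax (mg/h), 5 Km (mg/L)
 *
 * pkpd: the pk system coupled to the xenograft tumor-growth model.
 *       states  y0 = A1, y1 = A2, y2 = I (drug-effect state, dimensionless),
 *               y3 = T (tumor volume, mm^3)
 *       parms   0-5 as above, then
 *               6 KG (mm^3/h), 7 KD (1/h), 8 Kio (1/h),
 *               9 EC50 (mg/L), 10 EC50_KD (mg/L),
 *               11 Emax_g, 12 Emax_d (dimensionless),
 *               13 lam (1/h), 14 progression flag (0 linear, 1 exponential)
 */

#include <math.h>

static double pk_p[6];
static double pkpd_p[15];

void pk_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, pk_p);
}

void pk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double C1 = y[0] / pk_p[1];
    double elim = pk_p[0] * C1 + pk_p[4] * C1 / (pk_p[5] + C1);
    double dist = pk_p[2] * C1 - pk_p[2] * y[1] / pk_p[3];

    ydot[0] = -elim - dist;
    ydot[1] = dist;
    ydot[2] = C1;
}

/* pk_multi: many independent copies of the pk system in one solve (used to
 * batch per-subject predictions during estimation).  parms = [m, then m
 * blocks of CL, V1, Q, V2, Vmax, Km], zero-padded to the fixed length the
 * initializer expects; states are 2 per copy (A1, A2). */
#define PK_MULTI_MAX_PAR 6145  /* up to 1024 copies */
static double pk_mp[PK_MULTI_MAX_PAR];

void pk_multi_init(void (*odeparms)(int *, double *))
{
    int n = PK_MULTI_MAX_PAR;
    odeparms(&n, pk_mp);
}

void pk_multi_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int m = (int) (pk_mp[0] + 0.5);
    int i;
    for (i = 0; i < m; i++) {
        const double *p = pk_mp + 1 + 6 * i;
        double C1 = y[2 * i] / p[1];
        double elim = p[0] * C1 + p[4] * C1 / (p[5] + C1);
        double dist = p[2] * C1 - p[2] * y[2 * i + 1] / p[3];
        ydot[2 * i] = -elim - dist;
        ydot[2 * i + 1] = dist;
    }
}

void pkpd_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, pkpd_p);
}

void pkpd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double C1 = y[0] / pkpd_p[1];
    double elim = pkpd_p[0] * C1 + pkpd_p[4] * C1 / (pkpd_p[5] + C1);
    double dist = pkpd_p[2] * C1 - pkpd_p[2] * y[1] / pkpd_p[3];
    double inh, kill, growth;

    if (C1 < 0.0)
        C1 = 0.0;

    ydot[0] = -elim - dist;
    ydot[1] = dist;

    /* indirect response on the growth flux: production inhibited by drug */
    inh = 1.0 - pkpd_p[11] * C1 / (pkpd_p[9] + C1);
    ydot[2] = pkpd_p[8] * inh - pkpd_p[8] * y[2];

    /* progression-inflated zero-order growth scaled by the effect state,
     * first-order kill stimulated by drug */
    if (pkpd_p[14] > 0.5)
        growth = pkpd_p[6] * exp(pkpd_p[13] * (*t));
    else
        growth = pkpd_p[6] * (1.0 + pkpd_p[13] * (*t));
    kill = pkpd_p[7] * pkpd_p[12] * C1 / (pkpd_p[10] + C1);
    ydot[3] = growth * y[2] - kill * y[3];
}
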