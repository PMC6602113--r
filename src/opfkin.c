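/* Mass-action right-hand side for the oxidative protein folding network.
 *
 * State vector (order shared with R/model.R, do not reorder):
 *   0 O2       4 DTT_red   8  PDI_red
 *   1 H2O2     5 DTT_ox    9  ERO_rr
 *   2 GSH      6 PDI_ox    10 ERO_r1
 *   3 GSSG     7 PDI_mix   11 ERO_act_ox
 *                          12 ERO_act_red
 *
 * Parameters (order shared with R/constants.R):
 *   0 k1   1 kox  2 ka1  3 ka2  4 kg  5 kdtt  6 kdiff  7 o2_sat
 *   8 diffusion_on (0/1)  9 gsh_activation (0/1)
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 10

static double parms[N_PARMS];

void opfkin_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void opfkin_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double k1    = parms[0];
    const double kox   = parms[1];
    const double ka1   = parms[2];
    const double ka2   = parms[3];
    const double kg    = parms[4];
    const double kdtt  = parms[5];
    const double kdiff = parms[6];
    const double o2sat = parms[7];
    const int diff_on  = parms[8] != 0.0;
    const int gsh_act  = parms[9] != 0.0;

    const double o2   = y[0];
    const double gsh  = y[2];
    const double dtt  = y[4];
    const double pox  = y[6];
    const double pmix = y[7];
    const double pred = y[8];
    const double err  = y[9];
    const double er1  = y[10];
    const double eaox = y[11];
    const double eard = y[12];

    /* activation reductant: reduced Pdi1p by default, GSH behind the switch */
    const double red = gsh_act ? gsh : pred;
    const double va1 = ka1 * red * err;   /* ERO_rr  -> ERO_r1      */
    const double va2 = ka2 * red * er1;   /* ERO_r1  -> ERO_act_ox  */
    const double vr2 = kox * pred * eaox; /* PDI_red + ERO_act_ox   */
    const double vr1 = k1 * eard * o2;    /* ERO_act_red + O2       */
    const double vg1 = kg * pox * gsh;    /* PDI_ox + GSH -> PDI_mix */
    const double vg2 = kg * pmix * gsh;   /* PDI_mix + GSH -> PDI_red + GSSG */
    const double vd1 = kdtt * dtt * err;
    const double vd2 = kdtt * dtt * er1;
    const double vd3 = kdtt * dtt * eaox;

    ydot[0] = -vr1 + (diff_on ? kdiff * (o2sat - o2) : 0.0); /* O2   */
    ydot[1] = vr1;                                           /* H2O2 */
    ydot[2] = -vg1 - vg2 - (gsh_act ? 2.0 * (va1 + va2) : 0.0);
    ydot[3] = vg2 + (gsh_act ? va1 + va2 : 0.0);             /* GSSG */
    ydot[4] = -(vd1 + vd2 + vd3);                            /* DTT_red */
    ydot[5] = vd1 + vd2 + vd3;                               /* DTT_ox  */
    if (gsh_act) {
        ydot[6] = vr2 - vg1;
        ydot[8] = vg2 - vr2;
    } else {
        ydot[6] = va1 + va2 + vr2 - vg1;                     /* PDI_ox  */
        ydot[8] = vg2 - va1 - va2 - vr2;                     /* PDI_red */
    }
    ydot[7] = vg1 - vg2;                                     /* PDI_mix */
    ydot[9]  = -va1 - vd1;                                   /* ERO_rr  */
    ydot[10] = va1 + vd1 - va2 - vd2;                        /* ERO_r1  */
    ydot[11] = va2 + vd2 - vr2 + vr1 - vd3;                  /* ERO_act_ox  */
    ydot[12] = vr2 + vd3 - vr1;                              /* ERO_act_red */
}

static const R_CMethodDef cMethods[] = {
    {"opfkin_init",   (DL_FUNC) &opfkin_init,   1},
    {"opfkin_derivs", (DL_FUNC) &opfkin_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_opfkin(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
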