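/* Mass-action right-hand side of the two-compartment TGF-beta/Smad network,
 * in the form deSolve expects from a compiled model.
 *
 * State (nM), order fixed and shared with R/model.R:
 *  1 R     free receptor                 (cytoplasm/membrane)
 *  2 LR    ligand-bound receptor
 *  3 LRa   active (phosphorylated) receptor
 *  4 LRaI  active receptor sequestered by I-Smad
 *  5 Sc    R-Smad, cytoplasm
 *  6 pSc   phospho-R-Smad, cytoplasm
 *  7 Cc    Co-Smad, cytoplasm
 *  8 Dc    phospho-R-Smad homodimer, cytoplasm
 *  9 Hc    phospho-R-Smad/Co-Smad heterodimer, cytoplasm
 * 10 mc    I-Smad mRNA, cytoplasm
 * 11 I     I-Smad protein, cytoplasm
 * 12 Sn    R-Smad, nucleus
 * 13 pSn   phospho-R-Smad, nucleus
 * 14 Cn    Co-Smad, nucleus
 * 15 Dn    homodimer, nucleus
 * 16 Hn    heterodimer, nucleus (the monitored output)
 * 17 mn    I-Smad mRNA, nucleus
 *
 * Parameters: k1..k19, hill, then the ligand protocol (ligand is a boundary
 * condition, never depleted): type 0 = constant L = pa; type 1 = triangular
 * ramp 0 -> pa over [0, pb], back to 0 over [pb, pc].  All in nM and seconds.
 */
#include <R.h>
#include <math.h>

static double parms[24];
#define k1   parms[0]
#define k2   parms[1]
#define k3   parms[2]
#define k4   parms[3]
#define k5   parms[4]
#define k6   parms[5]
#define k7   parms[6]
#define k8   parms[7]
#define k9   parms[8]
#define k10  parms[9]
#define k11  parms[10]
#define k12  parms[11]
#define k13  parms[12]
#define k14  parms[13]
#define k15  parms[14]
#define k16  parms[15]
#define k17  parms[16]
#define k18  parms[17]
#define k19  parms[18]
#define hill parms[19]
#define ptyp parms[20]
#define ppa  parms[21]
#define ppb  parms[22]
#define ppc  parms[23]

void tgf_initmod(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

static double ligand_at(double t)
{
    if (ptyp < 0.5)
        return ppa;
    /* triangular profile */
    if (t <= 0.0 || t >= ppc)
        return 0.0;
    if (t <= ppb)
        return ppa * t / ppb;
    return ppa * (1.0 - (t - ppb) / (ppc - ppb));
}

void tgf_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double R = y[0], LR = y[1], LRa = y[2], LRaI = y[3];
    double Sc = y[4], pSc = y[5], Cc = y[6], Dc = y[7], Hc = y[8];
    double mc = y[9], I = y[10];
    double Sn = y[11], pSn = y[12], Cn = y[13], Dn = y[14], Hn = y[15];
    double mn = y[16];

    double L = ligand_at(*t);

    double v_bind   = k2 * L * R;        /* reaction 1  */
    double v_unbind = k1 * LR;           /* reaction 2  */
    double v_act    = k3 * LR;           /* reaction 3  */
    double v_deact  = k4 * LRa;          /* reaction 4  */
    double v_seq    = k5 * LRa * I;      /* reaction 5  */
    double v_rel    = k6 * LRaI;         /* reaction 6  */
    double v_phos   = k7 * LRa * Sc;     /* reaction 7  */

    /* dimerisation in both compartments (reactions 10/11) */
    double v_Dc_on  = k10 * pSc * pSc, v_Dc_off = k11 * Dc;
    double v_Hc_on  = k10 * pSc * Cc,  v_Hc_off = k11 * Hc;
    double v_Dn_on  = k10 * pSn * pSn, v_Dn_off = k11 * Dn;
    double v_Hn_on  = k10 * pSn * Cn,  v_Hn_off = k11 * Hn;

    /* Hill-type transcriptional activation by nuclear heterodimer (14/15) */
    double Hh = (Hn > 0.0) ? pow(Hn, hill) : 0.0;
    double v_txn = k14 * Hh / (pow(k15, hill) + Hh);

    ydot[0]  = v_unbind - v_bind;                              /* R    */
    ydot[1]  = v_bind - v_unbind - v_act + v_deact;            /* LR   */
    ydot[2]  = v_act - v_deact - v_seq + v_rel;                /* LRa  */
    ydot[3]  = v_seq - v_rel;                                  /* LRaI */
    ydot[4]  = -v_phos - k8 * Sc + k9 * Sn;                    /* Sc   */
    ydot[5]  = v_phos - k8 * pSc + k9 * pSn
               - 2.0 * v_Dc_on + 2.0 * v_Dc_off
               - v_Hc_on + v_Hc_off;                           /* pSc  */
    ydot[6]  = -k8 * Cc + k9 * Cn - v_Hc_on + v_Hc_off;        /* Cc   */
    ydot[7]  = v_Dc_on - v_Dc_off - k12 * Dc;                  /* Dc   */
    ydot[8]  = v_Hc_on - v_Hc_off - k12 * Hc;                  /* Hc   */
    ydot[9]  = k16 * mn - k17 * mc;                            /* mc   */
    ydot[10] = k18 * mc - v_seq + v_rel - k19 * I;             /* I    */
    ydot[11] = k8 * Sc - k9 * Sn + k13 * pSn;                  /* Sn   */
    ydot[12] = k8 * pSc - k9 * pSn - k13 * pSn
               - 2.0 * v_Dn_on + 2.0 * v_Dn_off
               - v_Hn_on + v_Hn_off;                           /* pSn  */
    ydot[13] = k8 * Cc - k9 * Cn - v_Hn_on + v_Hn_off;         /* Cn   */
    ydot[14] = v_Dn_on - v_Dn_off + k12 * Dc;                  /* Dn   */
    ydot[15] = v_Hn_on - v_Hn_off + k12 * Hc;                  /* Hn   */
    ydot[16] = v_txn - k16 * mn;                               /* mn   */
}
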