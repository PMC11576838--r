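/* Coupled ADC + small-molecule PBPK right-hand side for deSolve.
 *
 * Blocks (all always evaluated; a block with zero dose/parameters is inert):
 *   1. DAR-stratified minimal PBPK of the conjugated antibody
 *      (plasma + endosomal space, quasi-equilibrium FcRn binding,
 *      catabolism, DAR-proportional additional clearance, deconjugation
 *      cascade, catabolite depot releasing payload).
 *   2. Whole-body PBPK for the released payload (MMAE): perfusion-limited
 *      tissues, permeability-limited liver (extracellular/intracellular)
 *      with CYP3A4 metabolism and P-gp biliary efflux, renal clearance.
 *   3. Perpetrator PK (one/two-compartment, first-order oral absorption)
 *      driving interaction terms.
 *   4. Shared hepatic CYP3A4 turnover pool (induction + mechanism-based
 *      inactivation).
 *   5. Victim small molecule (two-compartment, well-stirred hepatic CYP3A4
 *      clearance, P-gp pathway clearance, renal clearance).
 *
 * Units: time h, amounts nmol, volumes L, clearances L/h, concentrations
 * nmol/L (nM) internally; interaction constants in uM (hence /1000).
 */

#include <R.h>
#include <math.h>

#define NPARMS 101

static double p[NPARMS];

/* parameter indices */
#define P_INF        0   /* ADC infusion rate, nmol antibody / h (per segment) */
#define P_KUP        1
#define P_KRC        2
#define P_CLCAT      3
#define P_CLADD      4
#define P_KDECP      5
#define P_KDECT      6
#define P_FRELDEC    7
#define P_FRELCAT    8
#define P_KREL       9
#define P_KD        10
#define P_RTOT      11
#define P_VE        12
#define P_VP        13
#define P_NDAR      14
#define P_FRAC0     15   /* .. 23 */
#define P_FU        24
#define P_BP        25
#define P_CLR       26
#define P_CLMET     27
#define P_CLPGP     28
#define P_CLPD      29
#define P_RAF       30
#define P_MBISELF   31
#define P_VVEN      32
#define P_VART      33
#define P_VLU       34
#define P_VAD       35
#define P_VBO       36
#define P_VBR       37
#define P_VGU       38
#define P_VHT       39
#define P_VKI       40
#define P_VMU       41
#define P_VSK       42
#define P_VSP       43
#define P_VPA       44
#define P_VLEC      45
#define P_VLIC      46
#define P_QAD       47
#define P_QBO       48
#define P_QBR       49
#define P_QGU       50
#define P_QHT       51
#define P_QKI       52
#define P_QMU       53
#define P_QSK       54
#define P_QSP       55
#define P_QPA       56
#define P_QHA       57
#define P_KPLU      58
#define P_KPAD      59
#define P_KPBO      60
#define P_KPBR      61
#define P_KPGU      62
#define P_KPHT      63
#define P_KPKI      64
#define P_KPMU      65
#define P_KPSK      66
#define P_KPSP      67
#define P_KPPA      68
#define P_KPLIC     69
#define P_KDEG      70
#define P_PKA       71
#define P_PV1       72
#define P_PV2       73
#define P_PQ12      74
#define P_PCL       75
#define P_PFU       76
#define P_PF        77
#define P_PKICYP    78
#define P_PKAPP     79
#define P_PKINACT   80
#define P_PINDMAX   81
#define P_PINDC50   82
#define P_PKIPGP    83
#define P_MKIREV    84
#define P_MKAPP     85
#define P_MKINACT   86
#define P_MKIPGP    87
#define P_VKA       88
#define P_VV1       89
#define P_VV2       90
#define P_VQ12      91
#define P_VFU       92
#define P_VBP       93
#define P_VCLINT    94
#define P_VCLR      95
#define P_VCLPGP    96
#define P_VRAF      97
#define P_VFGGAIN   98
#define P_VF        99
#define P_MWADC    100

/* state indices */
#define S_AP0        0   /* .. 8 */
#define S_AE0        9   /* .. 17 */
#define S_DEP       18
#define S_REL       19
#define S_NOREL     20
#define S_VEN       21
#define S_ART       22
#define S_LUN       23
#define S_ADI       24
#define S_BON       25
#define S_BRA       26
#define S_GUT       27
#define S_HRT       28
#define S_KID       29
#define S_MUS       30
#define S_SKI       31
#define S_SPL       32
#define S_PAN       33
#define S_LEC       34
#define S_LIC       35
#define S_MET       36
#define S_BIL       37
#define S_REN       38
#define S_PGT       39
#define S_PCC       40
#define S_PPP       41
#define S_ENZ       42
#define S_VGT       43
#define S_VCC       44
#define S_VPP       45
#define S_VMET      46
#define S_VREN      47
#define S_VPGP      48
#define S_AUCM      49
#define S_AUCA      50

#define NSTATE      51

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

/* FcRn quasi-equilibrium 1:1 binding with a shared receptor pool.
 * Solves R_free from R_free + A_tot*R_free/(kd + R_free) = R_tot. */
static double fcrn_fb(double atot_um, double rtot, double kd)
{
    double b, rfree;
    if (rtot <= 0.0)
        return 0.0;
    b = kd + atot_um - rtot;
    rfree = 0.5 * (-b + sqrt(b * b + 4.0 * rtot * kd));
    if (kd + rfree <= 0.0)
        return (rfree > 0.0 || kd == 0.0) ? 1.0 : 0.0;
    return rfree / (kd + rfree);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int j, nd;
    double atot_um, fb, fue, catflux, addflux, decp, dect;
    double payload_cat = 0.0, payload_dec = 0.0;
    double qco, qh, cart, cven, clung_out, cv;
    double ce_p, cu_ic, iu_perp_sys, iu_perp_inlet, iu_mmae_liv, iu_mmae_sys;
    double mod_cyp_m, mod_pgp_m, mod_cyp_v, mod_pgp_v;
    double ind, mbi, abs_flux, pcc, pcp, x, clh_b, clh_p, feff, cvc, cvp;
    double elim_met, elim_pgp;

    (void) neq; (void) yout; (void) ip;

    nd = (int) (p[P_NDAR] + 0.5);

    /* ---- ADC block ---- */
    atot_um = 0.0;
    for (j = 0; j <= nd; j++)
        atot_um += y[S_AE0 + j];
    atot_um /= (p[P_VE] * 1000.0);
    fb = fcrn_fb(atot_um, p[P_RTOT], p[P_KD]);
    fue = 1.0 - fb;

    for (j = 0; j <= nd; j++) {
        double ap = y[S_AP0 + j], ae = y[S_AE0 + j];
        catflux = (p[P_CLCAT] / p[P_VE]) * fue * ae;
        addflux = (p[P_CLADD] * j / p[P_VP]) * ap;
        decp = (j >= 1) ? p[P_KDECP] * ap : 0.0;
        dect = (j >= 1) ? p[P_KDECT] * ae : 0.0;
        ydot[S_AP0 + j] = p[P_INF] * p[P_FRAC0 + j]
            - p[P_KUP] * ap + p[P_KRC] * fb * ae - addflux - decp;
        ydot[S_AE0 + j] = p[P_KUP] * ap - p[P_KRC] * fb * ae - catflux - dect;
        if (j < nd) {
            ydot[S_AP0 + j] += p[P_KDECP] * y[S_AP0 + j + 1];
            ydot[S_AE0 + j] += p[P_KDECT] * y[S_AE0 + j + 1];
        }
        payload_cat += j * (catflux + addflux);
        payload_dec += decp + dect;
    }
    ydot[S_DEP] = p[P_FRELCAT] * payload_cat + p[P_FRELDEC] * payload_dec
        - p[P_KREL] * y[S_DEP];
    ydot[S_REL] = p[P_KREL] * y[S_DEP];
    ydot[S_NOREL] = (1.0 - p[P_FRELCAT]) * payload_cat
        + (1.0 - p[P_FRELDEC]) * payload_dec;

    /* ---- perpetrator PK ---- */
    abs_flux = p[P_PKA] * p[P_PF] * y[S_PGT];
    pcc = (p[P_PV1] > 0.0) ? y[S_PCC] / p[P_PV1] : 0.0;
    pcp = (p[P_PV2] > 0.0) ? y[S_PPP] / p[P_PV2] : 0.0;
    ydot[S_PGT] = -p[P_PKA] * y[S_PGT];
    ydot[S_PCC] = abs_flux - p[P_PCL] * pcc;
    ydot[S_PPP] = 0.0;
    if (p[P_PV2] > 0.0) {
        ydot[S_PCC] -= p[P_PQ12] * (pcc - pcp);
        ydot[S_PPP] = p[P_PQ12] * (pcc - pcp);
    }

    qh = p[P_QGU] + p[P_QSP] + p[P_QPA] + p[P_QHA];
    iu_perp_sys = p[P_PFU] * pcc / 1000.0;
    iu_perp_inlet = p[P_PFU] * (pcc + abs_flux / qh) / 1000.0;

    /* ---- MMAE whole-body PBPK ---- */
    qco = p[P_QAD] + p[P_QBO] + p[P_QBR] + p[P_QGU] + p[P_QHT] + p[P_QKI]
        + p[P_QMU] + p[P_QSK] + p[P_QSP] + p[P_QPA] + p[P_QHA];
    cven = y[S_VEN] / p[P_VVEN];
    cart = y[S_ART] / p[P_VART];
    clung_out = y[S_LUN] * p[P_BP] / (p[P_VLU] * p[P_KPLU]);
    ce_p = y[S_LEC] / p[P_VLEC];
    cu_ic = p[P_FU] * y[S_LIC] / (p[P_VLIC] * p[P_KPLIC]);
    iu_mmae_liv = p[P_FU] * ce_p / 1000.0;
    iu_mmae_sys = p[P_FU] * (cven / p[P_BP]) / 1000.0;

    mod_cyp_m = 1.0;
    if (p[P_PKICYP] > 0.0)
        mod_cyp_m = 1.0 / (1.0 + iu_perp_inlet / p[P_PKICYP]);
    mod_pgp_m = 1.0;
    if (p[P_PKIPGP] > 0.0)
        mod_pgp_m = 1.0 / (1.0 + iu_perp_inlet / p[P_PKIPGP]);

    /* shared hepatic CYP3A4 turnover pool */
    ind = (p[P_PINDMAX] > 0.0)
        ? p[P_PINDMAX] * iu_perp_inlet / (p[P_PINDC50] + iu_perp_inlet)
        : 0.0;
    mbi = 0.0;
    if (p[P_PKAPP] > 0.0)
        mbi += p[P_PKINACT] * iu_perp_inlet / (p[P_PKAPP] + iu_perp_inlet);
    if (p[P_MBISELF] > 0.5 && p[P_MKAPP] > 0.0)
        mbi += p[P_MKINACT] * iu_mmae_liv / (p[P_MKAPP] + iu_mmae_liv);
    ydot[S_ENZ] = p[P_KDEG] * (1.0 + ind) - p[P_KDEG] * y[S_ENZ]
        - mbi * y[S_ENZ];

    elim_met = p[P_CLMET] * y[S_ENZ] * mod_cyp_m * cu_ic;
    elim_pgp = p[P_CLPGP] * p[P_RAF] * mod_pgp_m * cu_ic;

#define TISSUE(S, V, Q, KP)                                             \
    do {                                                                \
        cv = y[S] * p[P_BP] / (p[V] * p[KP]);                           \
        ydot[S] = p[Q] * (cart - cv);                                   \
    } while (0)

    TISSUE(S_ADI, P_VAD, P_QAD, P_KPAD);
    TISSUE(S_BON, P_VBO, P_QBO, P_KPBO);
    TISSUE(S_BRA, P_VBR, P_QBR, P_KPBR);
    TISSUE(S_GUT, P_VGU, P_QGU, P_KPGU);
    TISSUE(S_HRT, P_VHT, P_QHT, P_KPHT);
    TISSUE(S_KID, P_VKI, P_QKI, P_KPKI);
    TISSUE(S_MUS, P_VMU, P_QMU, P_KPMU);
    TISSUE(S_SKI, P_VSK, P_QSK, P_KPSK);
    TISSUE(S_SPL, P_VSP, P_QSP, P_KPSP);
    TISSUE(S_PAN, P_VPA, P_QPA, P_KPPA);
#undef TISSUE

    /* renal elimination drawn from the kidney compartment */
    {
        double renal = p[P_CLR] * (cart / p[P_BP]);
        ydot[S_KID] -= renal;
        ydot[S_REN] = renal;
    }

    ydot[S_LUN] = qco * (cven - clung_out);
    ydot[S_ART] = qco * clung_out
        - (p[P_QAD] + p[P_QBO] + p[P_QBR] + p[P_QGU] + p[P_QHT] + p[P_QKI]
           + p[P_QMU] + p[P_QSK] + p[P_QSP] + p[P_QPA] + p[P_QHA]) * cart;

    /* liver: extracellular (plasma-like) and intracellular spaces */
    {
        double cvg = y[S_GUT] * p[P_BP] / (p[P_VGU] * p[P_KPGU]);
        double cvs = y[S_SPL] * p[P_BP] / (p[P_VSP] * p[P_KPSP]);
        double cvp2 = y[S_PAN] * p[P_BP] / (p[P_VPA] * p[P_KPPA]);
        double exch = p[P_CLPD] * (p[P_FU] * ce_p - cu_ic);
        ydot[S_LEC] = p[P_QHA] * cart + p[P_QGU] * cvg + p[P_QSP] * cvs
            + p[P_QPA] * cvp2 - qh * ce_p * p[P_BP] - exch;
        ydot[S_LIC] = exch - elim_met - elim_pgp;
        ydot[S_MET] = elim_met;
        ydot[S_BIL] = elim_pgp;
    }

    /* venous pool: direct-draining tissues + liver outflow + payload input */
    {
        double sum_direct =
            y[S_ADI] * p[P_BP] / (p[P_VAD] * p[P_KPAD]) * p[P_QAD]
            + y[S_BON] * p[P_BP] / (p[P_VBO] * p[P_KPBO]) * p[P_QBO]
            + y[S_BRA] * p[P_BP] / (p[P_VBR] * p[P_KPBR]) * p[P_QBR]
            + y[S_HRT] * p[P_BP] / (p[P_VHT] * p[P_KPHT]) * p[P_QHT]
            + y[S_KID] * p[P_BP] / (p[P_VKI] * p[P_KPKI]) * p[P_QKI]
            + y[S_MUS] * p[P_BP] / (p[P_VMU] * p[P_KPMU]) * p[P_QMU]
            + y[S_SKI] * p[P_BP] / (p[P_VSK] * p[P_KPSK]) * p[P_QSK];
        ydot[S_VEN] = sum_direct + qh * ce_p * p[P_BP]
            + p[P_KREL] * y[S_DEP] - qco * cven;
    }

    /* ---- victim small molecule ---- */
    mod_cyp_v = 1.0;
    {
        double rev = 0.0;
        if (p[P_PKICYP] > 0.0)
            rev += iu_perp_inlet / p[P_PKICYP];
        if (p[P_MKIREV] > 0.0)
            rev += iu_mmae_liv / p[P_MKIREV];
        mod_cyp_v = 1.0 / (1.0 + rev);
    }
    {
        double revp = 0.0;
        if (p[P_PKIPGP] > 0.0)
            revp += iu_perp_sys / p[P_PKIPGP];
        if (p[P_MKIPGP] > 0.0)
            revp += iu_mmae_sys / p[P_MKIPGP];
        mod_pgp_v = 1.0 / (1.0 + revp);
    }
    x = (p[P_VFU] / p[P_VBP]) * p[P_VCLINT] * y[S_ENZ] * mod_cyp_v;
    clh_b = qh * x / (qh + x);
    clh_p = clh_b * p[P_VBP];
    feff = p[P_VF] * (1.0 + p[P_VFGGAIN] * (1.0 - mod_pgp_v));
    if (feff > 1.0)
        feff = 1.0;
    cvc = (p[P_VV1] > 0.0) ? y[S_VCC] / p[P_VV1] : 0.0;
    cvp = (p[P_VV2] > 0.0) ? y[S_VPP] / p[P_VV2] : 0.0;
    ydot[S_VGT] = -p[P_VKA] * y[S_VGT];
    ydot[S_VCC] = p[P_VKA] * feff * y[S_VGT]
        - clh_p * cvc - p[P_VCLR] * cvc
        - p[P_VCLPGP] * p[P_VRAF] * mod_pgp_v * cvc;
    ydot[S_VPP] = 0.0;
    if (p[P_VV2] > 0.0) {
        ydot[S_VCC] -= p[P_VQ12] * (cvc - cvp);
        ydot[S_VPP] = p[P_VQ12] * (cvc - cvp);
    }
    ydot[S_VMET] = clh_p * cvc;
    ydot[S_VREN] = p[P_VCLR] * cvc;
    ydot[S_VPGP] = p[P_VCLPGP] * p[P_VRAF] * mod_pgp_v * cvc;

    /* ---- cumulative-integral AUC ledgers ---- */
    ydot[S_AUCM] = cven / p[P_BP];     /* venous plasma nM */
    {
        double conj = 0.0;
        for (j = 1; j <= nd; j++)
            conj += y[S_AP0 + j];
        /* ug/mL = nmol * (g/mol) / (V_L * 1e6) */
        ydot[S_AUCA] = conj * p[P_MWADC] / (p[P_VP] * 1.0e6);
    }
}

/* direct access for unit tests: set parameters, evaluate derivative */
void pbpk_set_parms(double *parms, int *n)
{
    int i;
    for (i = 0; i < *n && i < NPARMS; i++)
        p[i] = parms[i];
}

void pbpk_eval_deriv(double *t, double *y, double *ydot)
{
    int neq = NSTATE;
    pbpk_derivs(&neq, t, y, ydot, NULL, NULL);
}
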