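/* Whole-body perfusion-limited PBPK right-hand side for deSolve.
 *
 * States (amounts in nmol unless noted):
 *   y[0]  stomach            y[1]  gut lumen        y[2]  gut tissue
 *   y[3]  liver              y[4]  lung             y[5]  kidney
 *   y[6]  adipose            y[7]  muscle           y[8]  skin
 *   y[9]  rest of body       y[10] arterial blood   y[11] venous blood
 *   y[12] CYP3A4 level (fraction of baseline, dimensionless)
 *   y[13] cumulative metabolized   y[14] cumulative renally excreted
 *
 * Conventions: amounts nmol, volumes L, flows L/h (blood), concentrations
 * nmol/L. Tissue partition coefficients are tissue:plasma; venous outflow
 * from tissue t has blood concentration C_t * Rbp / Kp_t. Hepatic metabolism
 * operates on the unbound plasma-equivalent liver concentration
 * Cu = fup * C_liver / Kp_liver; per-enzyme clearances are passed already
 * scaled to L/h of unbound plasma-equivalent clearance. Auto-inhibition
 * divides the CYP3A4+3A5 clearances by (1 + Cu/Ki); auto-induction is the
 * indirect-response enzyme-level ODE applied to CYP3A4 only.
 */

#include <R.h>

#define N_PARMS 40

static double parms[N_PARMS];

#define V_GUT  parms[0]
#define V_LIV  parms[1]
#define V_LUN  parms[2]
#define V_KID  parms[3]
#define V_ADI  parms[4]
#define V_MUS  parms[5]
#define V_SKI  parms[6]
#define V_RES  parms[7]
#define V_ART  parms[8]
#define V_VEN  parms[9]
#define Q_GUT  parms[10]
#define Q_HA   parms[11]
#define Q_KID  parms[12]
#define Q_ADI  parms[13]
#define Q_MUS  parms[14]
#define Q_SKI  parms[15]
#define Q_RES  parms[16]
#define KP_GUT parms[17]
#define KP_LIV parms[18]
#define KP_LUN parms[19]
#define KP_KID parms[20]
#define KP_ADI parms[21]
#define KP_MUS parms[22]
#define KP_SKI parms[23]
#define KP_RES parms[24]
#define RBP    parms[25]
#define FUP    parms[26]
#define KGE    parms[27]
#define KA     parms[28]
#define CLR    parms[29]   /* renal clearance, L/h, already times fup */
#define CL1A2  parms[30]
#define CL2A6  parms[31]
#define CL2C9  parms[32]
#define CL2E1  parms[33]
#define CL3A4  parms[34]
#define CL3A5  parms[35]
#define KI_NM  parms[36]   /* <= 0 disables auto-inhibition */
#define EMAX   parms[37]   /* <= 0 disables auto-induction */
#define EC50NM parms[38]
#define KDEG   parms[39]

void init_pbpk(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void derivs_pbpk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double co = Q_GUT + Q_HA + Q_KID + Q_ADI + Q_MUS + Q_SKI + Q_RES;

    double c_art = y[10] / V_ART;           /* blood */
    double c_ven = y[11] / V_VEN;

    double c_gut = y[2] / V_GUT;
    double c_liv = y[3] / V_LIV;
    double c_lun = y[4] / V_LUN;
    double c_kid = y[5] / V_KID;
    double c_adi = y[6] / V_ADI;
    double c_mus = y[7] / V_MUS;
    double c_ski = y[8] / V_SKI;
    double c_res = y[9] / V_RES;

    double cv_gut = c_gut * RBP / KP_GUT;   /* venous blood leaving tissue */
    double cv_liv = c_liv * RBP / KP_LIV;
    double cv_lun = c_lun * RBP / KP_LUN;
    double cv_kid = c_kid * RBP / KP_KID;
    double cv_adi = c_adi * RBP / KP_ADI;
    double cv_mus = c_mus * RBP / KP_MUS;
    double cv_ski = c_ski * RBP / KP_SKI;
    double cv_res = c_res * RBP / KP_RES;

    /* unbound plasma-equivalent liver concentration, nmol/L */
    double cu = FUP * c_liv / KP_LIV;
    if (cu < 0.0) cu = 0.0;

    double inhib = (KI_NM > 0.0) ? 1.0 / (1.0 + cu / KI_NM) : 1.0;
    double e3a4 = y[12];
    double cl_hep = CL1A2 + CL2A6 + CL2C9 + CL2E1 +
                    CL3A4 * e3a4 * inhib + CL3A5 * inhib;

    double met = cl_hep * cu;                   /* nmol/h */
    double exc = CLR * (c_kid / KP_KID);        /* GFR*fup on plasma-equiv */

    ydot[0] = -KGE * y[0];
    ydot[1] = KGE * y[0] - KA * y[1];
    ydot[2] = KA * y[1] + Q_GUT * (c_art - cv_gut);
    ydot[3] = Q_HA * c_art + Q_GUT * cv_gut - (Q_HA + Q_GUT) * cv_liv - met;
    ydot[4] = co * (c_ven - cv_lun);
    ydot[5] = Q_KID * (c_art - cv_kid) - exc;
    ydot[6] = Q_ADI * (c_art - cv_adi);
    ydot[7] = Q_MUS * (c_art - cv_mus);
    ydot[8] = Q_SKI * (c_art - cv_ski);
    ydot[9] = Q_RES * (c_art - cv_res);
    ydot[10] = co * cv_lun - co * c_art;
    ydot[11] = (Q_HA + Q_GUT) * cv_liv + Q_KID * cv_kid + Q_ADI * cv_adi +
               Q_MUS * cv_mus + Q_SKI * cv_ski + Q_RES * cv_res -
               co * c_ven;

    double induction = 0.0;
    if (EMAX > 0.0) {
        induction = EMAX * cu / (EC50NM + cu);
    }
    ydot[12] = KDEG * (1.0 + induction) - KDEG * e3a4;

    ydot[13] = met;
    ydot[14] = exc;
}
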