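/* Right-hand side of the five-state Beclin-1 autophagy/apoptosis model,
 * in the form expected by deSolve's compiled-code interface.
 *
 * States: y = (B, Bc, A, M, C)
 *   B  Beclin-1
 *   Bc cleaved Beclin-1 (Beclin-1C)
 *   A  autophagosomes
 *   M  damaged mitochondria
 *   C  active Caspase-3 (0..1)
 *
 * Parameters (fixed order, see .beclin_par_order in R/model.R):
 *   p[0]  S        effective ischemic stress over the current segment
 *   p[1]  alpha_B  p[2]  beta_B   p[3]  gamma_B  p[4]  gamma_BC
 *   p[5]  alpha_A  p[6]  beta_A   p[7]  phi_A
 *   p[8]  alpha_M  p[9]  sigma_M  p[10] gamma_M
 *   p[11] alpha_C  p[12] sigma_C  p[13] mu_C     p[14] gamma_C
 *   p[15] phi_C    p[16] sigma_J  p[17] u_B      p[18] u_M
 *
 * Stress is piecewise constant; the integration is split at the protocol
 * discontinuities on the R side, so S is a plain parameter here.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[19];

void beclin_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

void beclin_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double S   = parms[0],  aB  = parms[1],  bB  = parms[2],  gB = parms[3];
    double gBC = parms[4],  aA  = parms[5],  bA  = parms[6],  phA = parms[7];
    double aM  = parms[8],  sM  = parms[9],  gM  = parms[10];
    double aC  = parms[11], sC  = parms[12], mC  = parms[13], gC = parms[14];
    double phC = parms[15], sJ  = parms[16], uB  = parms[17], uM = parms[18];

    /* tiny negative excursions are solver noise; clip for the mass-action
     * products (larger violations are caught by the box check in R) */
    double B  = y[0] > 0 ? y[0] : 0;
    double Bc = y[1] > 0 ? y[1] : 0;
    double A  = y[2] > 0 ? y[2] : 0;
    double M  = y[3] > 0 ? y[3] : 0;
    double C  = y[4] > 0 ? y[4] : 0;

    double J = bA * A / (1.0 + A / phA);

    ydot[0] = aB * (1.0 + uB * S) - bB * C * B - gB * B;
    ydot[1] = bB * C * B - gBC * Bc;
    ydot[2] = aA * B - J;
    ydot[3] = aM * (1.0 + uM * S) + sM * Bc - gM * J * M;
    ydot[4] = (aC * M + sC * A + mC * C / (phC + 1.0 - C)) * (1.0 - C)
              - gC * C / (phC + sJ * J + C);

    if (ip[0] > 0) yout[0] = J;
}

static const R_CMethodDef cMethods[] = {
    {"beclin_initmod", (DL_FUNC) &beclin_initmod, 1},
    {"beclin_derivs",  (DL_FUNC) &beclin_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_beclinduality(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
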