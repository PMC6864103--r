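/* Compiled right-hand side of the four-compartment calcium model,
 * in the deSolve compiled-model convention (initializer + derivs).
 *
 * The parameter vector is packed by the R helper .pack_parms(); the
 * ordering below must match .param_names plus the trailing control
 * slots (vol_ud, inactivation flags, clamp flags/values).
 *
 * Eleven fluxes (cytosol-referenced, uM/s) are returned through the
 * global-output slots so trajectories carry the full flux breakdown
 * without recomputation in R.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 50

static double parms[NPAR];

/* offsets into parms */
#define VOL_CYT   parms[0]
#define VOL_ER    parms[1]
#define VOL_MT    parms[2]
/* 3..5: sa_mito, n_mito, d_er_mt (unused here; vol_ud is precomputed) */
#define BP_CYT    parms[6]
#define BP_ER     parms[7]
#define BP_MT     parms[8]
#define BP_UD     parms[9]
#define K_BUF_CYT parms[10]
#define K_BUF_ER  parms[11]
#define K_BUF_MT  parms[12]
#define K_BUF_UD  parms[13]
#define V_IP3R    parms[14]
#define D1        parms[15]
#define D2        parms[16]
#define D3        parms[17]
#define D5        parms[18]
#define A2        parms[19]
#define V_SERCA   parms[20]
#define K_SERCA   parms[21]
#define V_MCU0    parms[22]
#define K_MCU     parms[23]
#define B_MCU     parms[24]
#define PSI0      parms[25]
#define PSI       parms[26]
#define FARADAY   parms[27]
#define GAS_CONST parms[28]
#define TEMPER    parms[29]
#define V_MNCX    parms[30]
#define K_NA      parms[31]
#define K_MNCX    parms[32]
#define NA_CYT    parms[33]
#define NA_UD     parms[34]
#define K_L_EC    parms[35]
#define K_L_EU    parms[36]
#define K_L_UC    parms[37]
#define C_IP3R    parms[38]
#define C_SERCA   parms[39]
#define C_MCU     parms[40]
#define C_MNCX    parms[41]
#define IP3       parms[42]
#define VOL_UD    parms[43]
#define INACT_UD  parms[44]
#define INACT_MT  parms[45]
#define CLAMP_C_ON parms[46]
#define CLAMP_C_V  parms[47]
#define CLAMP_U_ON parms[48]
#define CLAMP_U_V  parms[49]

void ca_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double po_ip3r(double ip3, double ca, double h)
{
    double s = (ip3 / (ip3 + D1)) * (ca / (ca + D5)) * h;
    return s * s * s * s + 4.0 * s * s * s * (1.0 - s);
}

void ca_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double cc = y[0], ce = y[1], cm = y[2], cu = y[3], h = y[4], hu = y[5];
    double x, dphi, vmcu, na3c, na3u, alpha;
    double j_ip3r, j_ip3r_ud, j_serca, j_serca_ud, j_mcu, j_mcu_ud;
    double j_mncx, j_mncx_ud, jl_ec, jl_eu, jl_uc;
    double th_c, th_e, th_m, th_u;

    if (ip[0] < 11) error("nout must be >= 11");

    j_ip3r = (1.0 - C_IP3R) * V_IP3R * po_ip3r(IP3, cc, h) * (ce - cc);
    j_ip3r_ud = C_IP3R * V_IP3R * po_ip3r(IP3, cu, hu) * (ce - cu);
    if (CLAMP_C_ON > 0.5) j_ip3r = CLAMP_C_V;
    if (CLAMP_U_ON > 0.5) j_ip3r_ud = CLAMP_U_V;

    j_serca = (1.0 - C_SERCA) * V_SERCA * cc * cc / (K_SERCA * K_SERCA + cc * cc);
    j_serca_ud = C_SERCA * V_SERCA * cu * cu / (K_SERCA * K_SERCA + cu * cu);

    x = B_MCU * FARADAY * (PSI - PSI0) * 1e-3 / (GAS_CONST * TEMPER);
    dphi = x * exp(x) * sinh(x);
    vmcu = V_MCU0 * dphi;
    j_mcu = (1.0 - C_MCU) * vmcu * cc * cc / (K_MCU * K_MCU + cc * cc);
    j_mcu_ud = C_MCU * vmcu * cu * cu / (K_MCU * K_MCU + cu * cu);

    na3c = NA_CYT * NA_CYT * NA_CYT;
    na3u = NA_UD * NA_UD * NA_UD;
    j_mncx = (1.0 - C_MNCX) * V_MNCX * na3c / (K_NA * K_NA * K_NA + na3c)
             * cm / (K_MNCX + cm);
    j_mncx_ud = C_MNCX * V_MNCX * na3u / (K_NA * K_NA * K_NA + na3u)
                * cm / (K_MNCX + cm);

    jl_ec = K_L_EC * (ce - cc);
    jl_eu = K_L_EU * (ce - cu);
    jl_uc = K_L_UC * (cu - cc);

    if (INACT_UD > 0.5) {
        j_ip3r_ud = 0.0; j_serca_ud = 0.0; j_mcu_ud = 0.0; j_mncx_ud = 0.0;
        jl_eu = 0.0; jl_uc = 0.0;
    }
    if (INACT_MT > 0.5) {
        j_mcu = 0.0; j_mcu_ud = 0.0; j_mncx = 0.0; j_mncx_ud = 0.0;
    }

    th_c = BP_CYT * K_BUF_CYT / ((cc + K_BUF_CYT) * (cc + K_BUF_CYT));
    th_e = BP_ER * K_BUF_ER / ((ce + K_BUF_ER) * (ce + K_BUF_ER));
    th_m = BP_MT * K_BUF_MT / ((cm + K_BUF_MT) * (cm + K_BUF_MT));
    th_u = BP_UD * K_BUF_UD / ((cu + K_BUF_UD) * (cu + K_BUF_UD));

    ydot[0] = (j_ip3r + j_mncx + jl_uc + jl_ec - j_serca - j_mcu) / (1.0 + th_c);
    ydot[1] = (VOL_CYT / VOL_ER) *
        (j_serca + j_serca_ud - j_ip3r - j_ip3r_ud - jl_eu - jl_ec) / (1.0 + th_e);
    ydot[2] = (VOL_CYT / VOL_MT) *
        (j_mcu + j_mcu_ud - j_mncx - j_mncx_ud) / (1.0 + th_m);
    ydot[3] = (VOL_CYT / VOL_UD) *
        (j_ip3r_ud + j_mncx_ud + jl_eu - j_serca_ud - j_mcu_ud - jl_uc) /
        (1.0 + th_u);

    alpha = A2 * D2 * (IP3 + D1) / (IP3 + D3);
    ydot[4] = alpha * (1.0 - h) - A2 * cc * h;
    ydot[5] = alpha * (1.0 - hu) - A2 * cu * hu;

    if (INACT_UD > 0.5) { ydot[3] = 0.0; ydot[5] = 0.0; }
    if (INACT_MT > 0.5) ydot[2] = 0.0;

    yout[0] = j_ip3r;
    yout[1] = j_ip3r_ud;
    yout[2] = j_serca;
    yout[3] = j_serca_ud;
    yout[4] = j_mcu;
    yout[5] = j_mcu_ud;
    yout[6] = j_mncx;
    yout[7] = j_mncx_ud;
    yout[8] = jl_ec;
    yout[9] = jl_eu;
    yout[10] = jl_uc;
}
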