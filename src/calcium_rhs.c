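/* Right-hand side of the 4-variable ATP -> PLC -> IP3 -> IP3R/Ca model,
 * in the deSolve compiled-model convention. State: PLC, IP3, h, Ca.
 * Parameter order must match caParamNames() on the R side. */
#include <R.h>
#include <math.h>

static double parms[18];

#define P_ATP       parms[0]
#define P_K_ATP     parms[1]
#define P_K_OFF_ATP parms[2]
#define P_V_PLC     parms[3]
#define P_K_IP3     parms[4]
#define P_K_OFF_IP3 parms[5]
#define P_A         parms[6]
#define P_D_INH     parms[7]
#define P_K_E       parms[8]
#define P_B_E       parms[9]
#define P_D_1       parms[10]
#define P_D_5       parms[11]
#define P_EPS       parms[12]
#define P_ETA_1     parms[13]
#define P_ETA_2     parms[14]
#define P_ETA_3     parms[15]
#define P_C_0       parms[16]
#define P_K_3       parms[17]

void calchain_initmod(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms);
}

void calchain_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double plc = y[0], ip3 = y[1], h = y[2], ca = y[3];

    ydot[0] = P_ATP * exp(-P_K_ATP * (*t)) - P_K_OFF_ATP * plc;
    ydot[1] = P_V_PLC * plc * plc / (P_K_IP3 * P_K_IP3 + plc * plc)
              - P_K_OFF_IP3 * ip3;
    /* a*(Ca + d_inh)*(d_inh/(Ca + d_inh) - h) = a*(d_inh - (Ca + d_inh)*h) */
    ydot[2] = P_A * (P_D_INH - (ca + P_D_INH) * h);

    {
        double ke_ca = P_K_E + ca;
        double beta = 1.0 / (1.0 + P_K_E * P_B_E / (ke_ca * ke_ca));
        double m = (ip3 / (P_D_1 + ip3)) * (ca / (P_D_5 + ca));
        double gate = m * m * m * h * h * h;
        double pump = P_ETA_3 * ca * ca / (P_K_3 * P_K_3 + ca * ca);
        ydot[3] = beta * (P_EPS * (P_ETA_1 * gate + P_ETA_2)
                          * (P_C_0 - (1.0 + P_EPS) * ca) - pump);
    }
}
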