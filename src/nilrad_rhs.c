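/* Right-hand side of the sensitive/resistant/dead compartment model,
 * compiled for use with deSolve's compiled-model interface.
 *
 * State:  y[0] = S (sensitive), y[1] = R (resistant), y[2] = Dead.
 * Parms:  rS, rR (proliferation, /day), dS, dR (death, /day),
 *         nu (sensitive->resistant conversion, /day; already gated on c>0
 *         by the caller), K (carrying capacity).
 *
 * The logistic crowding factor applies to proliferation only; death and
 * conversion are linear mass-action terms.
 */
#include <R.h>

static double parms[6];
#define p_rS parms[0]
#define p_rR parms[1]
#define p_dS parms[2]
#define p_dR parms[3]
#define p_nu parms[4]
#define p_K  parms[5]

void nilrad_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void nilrad_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double S = y[0], R = y[1];
    double crowd = 1.0 - (S + R) / p_K;

    ydot[0] = p_rS * S * crowd - p_dS * S - p_nu * S;
    ydot[1] = p_rR * R * crowd - p_dR * R + p_nu * S;
    ydot[2] = p_dS * S + p_dR * R;
}
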