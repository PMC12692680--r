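/* Compiled right-hand side and root functions for the segregated batch
 * growth model, in the deSolve compiled-model convention.
 *
 * State vector (one integration segment, cluster layout fixed):
 *   y = [clusters of strain 1, clusters of strain 2, Xd, S, P, clocks]
 *
 * Parameter vector (seg_init):
 *   p[0] number of active strains (na <= 2)
 *   p[1] product dynamics on (0/1)
 *   p[2] lysis rate constant k_s, 1/h
 *   p[3] lysis lag theta, h (informational)
 *   p[4] delay in use (0/1): 1 -> delayed dead pool read from the forcing
 *   p[5] substrate-exhaustion root threshold, g/L
 *   p[6] depletion root disarmed (0/1)
 *   p[7] unused
 *   p[8 + j*10 .. 8 + j*10 + 9] per active strain j:
 *     [0] cluster count  [1] mu_max  [2] K_S  [3] 1/Y_XS  [4] k_d
 *     [5] product-inhibited (0/1)  [6] K_P  [7] producer (0/1)
 *     [8] 1/Y_XP  [9] has viable mass (0/1; freezes the division clock)
 *
 * One forcing function: the delayed dead pool X_d(t - theta), supplied as
 * a (time, value) table already shifted by theta.
 */

#include <R.h>
#include <Rmath.h>

#define SEG_NP (8 + 2 * 10)

static double parms[SEG_NP];
static double forc[1];

void seg_init(void (*odeparms)(int *, double *))
{
    int N = SEG_NP;
    odeparms(&N, parms);
}

void seg_initforc(void (*odeforcs)(int *, double *))
{
    int N = 1;
    odeforcs(&N, forc);
}

void seg_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int na = (int) parms[0];
    int prod_on = parms[1] > 0.5;
    double ks = parms[2];
    int use_delay = parms[4] > 0.5;

    int nclus = 0;
    for (int j = 0; j < na; j++)
        nclus += (int) parms[8 + j * 10];
    int i_xd = nclus, i_s = nclus + 1, i_p = nclus + 2;

    double S = y[i_s] > 0 ? y[i_s] : 0;
    double P = (prod_on && y[i_p] > 0) ? y[i_p] : 0;
    double Xd = y[i_xd];

    double cons = 0, death = 0, dP = 0;
    int idx = 0;
    for (int j = 0; j < na; j++) {
        const double *q = parms + 8 + j * 10;
        int nc = (int) q[0];
        double den = q[2] + S;
        if (prod_on && q[5] > 0.5)
            den += P / q[6];
        double mu = q[1] * S / den;
        double sX = 0;
        for (int k = 0; k < nc; k++) {
            double x = y[idx + k];
            ydot[idx + k] = (mu - q[4]) * x;
            sX += x;
        }
        cons += mu * q[3] * sX;
        death += q[4] * sX;
        ydot[i_p + 1 + j] = q[9] > 0.5 ? mu : 0;   /* division clock */
        if (prod_on && q[7] > 0.5)
            dP += mu * q[8] * sX;
        idx += nc;
    }

    double xcur = Xd > 0 ? Xd : 0;
    double xdel = use_delay ? (forc[0] > 0 ? forc[0] : 0) : xcur;
    /* cap the delayed drain so the dead pool cannot go negative */
    double drain = ks * (xdel < xcur ? xdel : xcur);

    ydot[i_xd] = death - drain;
    ydot[i_s] = -cons + drain;
    ydot[i_p] = dP;
}

/* roots: one per strain division clock (clock - ln 2), plus substrate
 * exhaustion (S - eps), the latter disarmed while parms[6] is set */
void seg_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *rpar, int *ipar)
{
    int na = (int) parms[0];
    int nclus = 0;
    for (int j = 0; j < na; j++)
        nclus += (int) parms[8 + j * 10];
    int i_s = nclus + 1, i_p = nclus + 2;

    for (int j = 0; j < na; j++)
        gout[j] = y[i_p + 1 + j] - M_LN2;
    gout[na] = parms[6] > 0.5 ? 1.0 : y[i_s] - parms[5];
}
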