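/* Generic mass-action right-hand side for deSolve's compiled-code interface.
 *
 * The network is packed into a fixed-length double vector (see pack_network()
 * on the R side):
 *   [0] n_species   [1] n_reactions
 *   [2] state index of the calcium input (0 if none)
 *   [3] state index of the dopamine input (0 if none)
 *   [4] n_clamped   [5 .. 5+n_clamped-1] clamped state indices (constant clamps)
 *   then per reaction 8 doubles: r1 r2 r3 p1 p2 p3 kf kr
 * Index slots are 1-based state indices; 0 means the slot is empty (factor 1).
 * Stoichiometry 2 is expressed by repeating an index across slots.
 *
 * Two forcing functions (calcium, dopamine trace) are interpolated by deSolve;
 * the corresponding state entries are overridden before rate evaluation and
 * their derivatives zeroed, so inputs act as prescribed transients.
 */

#include <R.h>

#define MSN_MAXP 4096
#define MSN_MAXS 256

static double parms[MSN_MAXP];
static double forc[2];

void msn_init(void (*odeparms)(int *, double *))
{
    int n = MSN_MAXP;
    odeparms(&n, parms);
}

void msn_forc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

void msn_rhs(int *neq, double *t, double *y, double *ydot,
             double *yout, int *ip)
{
    static double s[MSN_MAXS + 1];
    const int n_sp = (int) parms[0];
    const int n_rx = (int) parms[1];
    const int i_ca = (int) parms[2];
    const int i_da = (int) parms[3];
    const int n_cl = (int) parms[4];
    const double *cl = parms + 5;
    const double *rx = parms + 5 + n_cl;
    int i, k;

    s[0] = 1.0; /* empty slot -> multiplicative identity */
    for (i = 0; i < n_sp; i++) {
        double v = y[i];
        s[i + 1] = (v > 0.0) ? v : 0.0;
        ydot[i] = 0.0;
    }
    if (i_ca > 0) s[i_ca] = (forc[0] > 0.0) ? forc[0] : 0.0;
    if (i_da > 0) s[i_da] = (forc[1] > 0.0) ? forc[1] : 0.0;

    for (k = 0; k < n_rx; k++) {
        const double *r = rx + 8 * k;
        const int r1 = (int) r[0], r2 = (int) r[1], r3 = (int) r[2];
        const int p1 = (int) r[3], p2 = (int) r[4], p3 = (int) r[5];
        double flux = r[6] * s[r1] * s[r2] * s[r3]
                    - r[7] * s[p1] * s[p2] * s[p3];
        if (r1) ydot[r1 - 1] -= flux;
        if (r2) ydot[r2 - 1] -= flux;
        if (r3) ydot[r3 - 1] -= flux;
        if (p1) ydot[p1 - 1] += flux;
        if (p2) ydot[p2 - 1] += flux;
        if (p3) ydot[p3 - 1] += flux;
    }

    if (i_ca > 0) ydot[i_ca - 1] = 0.0;
    if (i_da > 0) ydot[i_da - 1] = 0.0;
    for (i = 0; i < n_cl; i++)
        ydot[(int) cl[i] - 1] = 0.0;
}
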