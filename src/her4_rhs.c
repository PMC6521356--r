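/* Compiled mass-action / Hill right-hand side for deSolve.
 *
 * The network is flattened into a fixed-length double vector on the R side
 * (see encode_network()):
 *   [ns, nr, s_offset,
 *    per reaction: kind, p1, p2, p3,
 *                  n_react, (idx, stoich)*n_react,
 *                  n_prod,  (idx, stoich)*n_prod,
 *                  n_mod,   idx*n_mod,
 *    ... zero padding ...,
 *    at s_offset: S_eff (ns x nr, column-major)]
 * kinds: 0 = mass action irreversible, 1 = reversible, 2 = Hill activation,
 * 3 = first-order transport (p1 = rate constant; reversible adds p2 = kr;
 * Hill uses p1 = V, p2 = K, p3 = n with the single modifier as driver).
 * Indices are 0-based. State entries are clamped at zero inside the rate
 * evaluation because a stiff integrator may step infinitesimally below zero.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define HER4_PARMS_LEN 8192
#define HER4_MAX_SPECIES 256
static double her4_parms[HER4_PARMS_LEN];

void her4_initparms(void (*odeparms)(int *, double *))
{
    int n = HER4_PARMS_LEN;
    odeparms(&n, her4_parms);
}

void her4_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *p = her4_parms;
    const int ns = (int) p[0];
    const int nr = (int) p[1];
    const double *S = p + (int) p[2];
    int pos = 3;
    double yc[HER4_MAX_SPECIES];
    int i, j, m;

    if (ns != *neq || ns > HER4_MAX_SPECIES)
        error("her4_derivs: species count mismatch (%d vs %d)", ns, *neq);
    for (i = 0; i < ns; i++) {
        yc[i] = (y[i] > 0.0) ? y[i] : 0.0;
        ydot[i] = 0.0;
    }

    for (j = 0; j < nr; j++) {
        const int kind = (int) p[pos];
        const double p1 = p[pos + 1], p2 = p[pos + 2], p3 = p[pos + 3];
        int nre, npr, nmod;
        double v, fwd = 1.0;
        const double *Sj = S + (long) j * ns;

        pos += 4;
        nre = (int) p[pos++];
        for (i = 0; i < nre; i++) {
            const int idx = (int) p[pos];
            const int st = (int) p[pos + 1];
            for (m = 0; m < st; m++) fwd *= yc[idx];
            pos += 2;
        }
        npr = (int) p[pos++];
        if (kind == 1) {
            double bwd = 1.0;
            int pp = pos;
            for (i = 0; i < npr; i++) {
                const int idx = (int) p[pp];
                const int st = (int) p[pp + 1];
                for (m = 0; m < st; m++) bwd *= yc[idx];
                pp += 2;
            }
            v = p1 * fwd - p2 * bwd;
        } else {
            v = p1 * fwd;
        }
        pos += 2 * npr;
        nmod = (int) p[pos++];
        if (kind == 2) {
            const double M = yc[(int) p[pos]];
            const double Mn = pow(M, p3);
            v = p1 * Mn / (pow(p2, p3) + Mn);
        } else {
            for (i = 0; i < nmod; i++)
                v *= yc[(int) p[pos + i]];
        }
        pos += nmod;

        for (i = 0; i < ns; i++)
            ydot[i] += Sj[i] * v;
    }
}

static const R_CMethodDef CEntries[] = {
    {"her4_derivs", (DL_FUNC) &her4_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_her4switch(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
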