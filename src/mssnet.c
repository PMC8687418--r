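/* Right-hand side of the interval-wise moment system for a mass-action
 * reaction network, in the form expected by deSolve's compiled-model
 * interface.
 *
 * State vector: the D species means x, followed (when the covariance flag is
 * set) by the D(D+1)/2 upper-triangle entries of the LNA covariance, stacked
 * column-major (j outer, i <= j inner).
 *
 *   dx/dt     = S v(x, theta)
 *   dSigma/dt = J Sigma + Sigma J' + D(x, theta) / Omega
 *
 * with J = S dv/dx and D_ij = sum_k S_ik S_jk v_k, both evaluated along the
 * evolving mean x(t).
 *
 * Rate laws are products theta_k * prod_i f(b_i, q_ik) where b_i is either
 * the species count x_i or, for moiety-complement factors, (T_i - x_i); the
 * complement total T_i is passed per (species, reaction) entry (negative
 * sentinel = plain factor).  f(b, e) is b^e by default, or the combinatorial
 * kernel b(b-1)...(b-e+1)/e! when the per-entry combinatorial flag is set.
 */

#include <R.h>
#include <Rmath.h>

#define MSS_MAXPAR 4096
#define MSS_MAXD   12
#define MSS_MAXR   64

static double parms[MSS_MAXPAR];

void mssnet_init(void (*odeparms)(int *, double *))
{
    int n = MSS_MAXPAR;
    odeparms(&n, parms);
}

void mssnet_deriv(int *neq, double *t, double *yfull, double *ydotfull,
                  double *yout, int *ip)
{
    const int D = (int) parms[0];
    const int r = (int) parms[1];
    const double omega = parms[2];
    const int with_cov = (int) parms[3];
    const int nblocks = (int) parms[4];
    const double *theta = parms + 5;
    const double *S = parms + 5 + r;
    const double *q = parms + 5 + r + D * r;
    const double *ct = parms + 5 + r + 2 * D * r;
    const double *cb = parms + 5 + r + 3 * D * r;
    const int bs = D + (with_cov ? D * (D + 1) / 2 : 0);
    int blk;

    double v[MSS_MAXR];
    double fac[MSS_MAXD], dfac[MSS_MAXD];
    double dvdx[MSS_MAXR][MSS_MAXD];
    int i, j, k, l, m;

    for (blk = 0; blk < nblocks; blk++) {
    const double *y = yfull + blk * bs;
    double *ydot = ydotfull + blk * bs;

    /* propensities and their state derivatives */
    for (k = 0; k < r; k++) {
        double prod = theta[k];
        for (i = 0; i < D; i++) {
            int e = (int) q[i + D * k];
            double b, sg;
            if (ct[i + D * k] >= 0.0) {
                b = ct[i + D * k] - y[i];
                sg = -1.0;
            } else {
                b = y[i];
                sg = 1.0;
            }
            if (e <= 0) {
                fac[i] = 1.0;
                dfac[i] = 0.0;
            } else if (cb[i + D * k] > 0.0) {
                /* combinatorial kernel b(b-1)...(b-e+1)/e! */
                double f = 1.0, df = 0.0, efac = 1.0;
                for (l = 0; l < e; l++) {
                    double excl = 1.0;
                    int l2;
                    for (l2 = 0; l2 < e; l2++)
                        if (l2 != l) excl *= (b - l2);
                    df += excl;
                    f *= (b - l);
                    efac *= (l + 1);
                }
                fac[i] = f / efac;
                dfac[i] = sg * df / efac;
            } else {
                fac[i] = R_pow_di(b, e);
                dfac[i] = sg * e * R_pow_di(b, e - 1);
            }
            prod *= fac[i];
        }
        v[k] = prod;
        if (with_cov) {
            for (i = 0; i < D; i++) {
                if (dfac[i] == 0.0) {
                    dvdx[k][i] = 0.0;
                } else {
                    /* product over the other factors, robust at fac = 0 */
                    double excl = theta[k];
                    for (j = 0; j < D; j++)
                        if (j != i) excl *= fac[j];
                    dvdx[k][i] = dfac[i] * excl;
                }
            }
        }
    }

    /* mean: dx = S v */
    for (i = 0; i < D; i++) {
        double s = 0.0;
        for (k = 0; k < r; k++)
            s += S[i + D * k] * v[k];
        ydot[i] = s;
    }

    if (!with_cov)
        continue;

    /* J = S dv/dx and Dm = S diag(v) S' / omega */
    double J[MSS_MAXD][MSS_MAXD], Dm[MSS_MAXD][MSS_MAXD];
    for (i = 0; i < D; i++) {
        for (j = 0; j < D; j++) {
            double sj = 0.0, sd = 0.0;
            for (k = 0; k < r; k++) {
                sj += S[i + D * k] * dvdx[k][j];
                sd += S[i + D * k] * S[j + D * k] * v[k];
            }
            J[i][j] = sj;
            Dm[i][j] = sd / omega;
        }
    }

    /* expand upper triangle to full Sigma */
    double Sig[MSS_MAXD][MSS_MAXD];
    m = 0;
    for (j = 0; j < D; j++)
        for (i = 0; i <= j; i++) {
            Sig[i][j] = y[D + m];
            Sig[j][i] = y[D + m];
            m++;
        }

    /* dSigma = J Sig + Sig J' + Dm, upper triangle only */
    m = 0;
    for (j = 0; j < D; j++)
        for (i = 0; i <= j; i++) {
            double s = Dm[i][j];
            for (k = 0; k < D; k++)
                s += J[i][k] * Sig[k][j] + Sig[i][k] * J[j][k];
            ydot[D + m] = s;
            m++;
        }
    }  /* block loop */
}
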