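/* Compiled RHS and Jacobian for the master equation dx/dt = Q x, used by
 * the deSolve reference backend. Parameters arrive as a fixed-length
 * vector: parms[0] = n, parms[1..n*n] = Q column-major, zero-padded to
 * GF_MAXN states. */
#include <R.h>

#define GF_MAXN 12
static double gf_parms[GF_MAXN * GF_MAXN + 1];

void gf_initmod(void (*odeparms)(int *, double *)) {
  int n = GF_MAXN * GF_MAXN + 1;
  odeparms(&n, gf_parms);
}

void gf_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip) {
  const int n = *neq;
  const double *Q = gf_parms + 1;
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int j = 0; j < n; j++) s += Q[i + j * n] * y[j];
    ydot[i] = s;
  }
}

void gf_jac(int *neq, double *t, double *y, int *ml, int *mu, double *pd,
            int *nrowpd, double *yout, int *ip) {
  const int n = *neq;
  const double *Q = gf_parms + 1;
  for (int j = 0; j < n; j++)
    for (int i = 0; i < n; i++) pd[i + j * (*nrowpd)] = Q[i + j * n];
}
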