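/* Right-hand sides of the built-in network models, shared between the
 * deSolve integrator (void derivs interface) and direct evaluation from R
 * (.Call wrappers), so both paths use one definition. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- toggle switch: 2 states (A, B), 10 parameters ----
 * parameter order: ga gb tau_a tau_b ka kb lambda_a lambda_b na nb */

static double ts_parms[10];

void fatemap_ts_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, ts_parms);
}

/* shifted Hill repression: lambda + (1 - lambda) / (1 + (x/k)^n) */
static double shill(double x, double k, double n, double lambda)
{
    double u;
    if (x <= 0.0) return 1.0;           /* no repressor present */
    u = pow(x / k, n);
    return lambda + (1.0 - lambda) / (1.0 + u);
}

static void ts_rhs(const double *y, const double *p, double *dy)
{
    double A = y[0], B = y[1];
    dy[0] = p[0] * shill(B, p[4], p[8], p[6]) - A / p[2];
    dy[1] = p[1] * shill(A, p[5], p[9], p[7]) - B / p[3];
}

void fatemap_ts_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    ts_rhs(y, ts_parms, ydot);
}

/* ---- EMT core network: 9 states, 44 parameters ----
 * states:  T  s  S  R3  z  Z  R2  E  N
 * (endogenous TGF-b, snail mRNA, SNAIL, miR-34, zeb mRNA, ZEB, miR-200,
 *  E-cadherin, N-cadherin)
 * parameter order (indices):
 *  0 TGF0   1 kT    2 ks    3 kS    4 k3    5 kz    6 kZ    7 k2
 *  8 ke1    9 ke2  10 kn1  11 kn2
 * 12 kdT   13 kds  14 kdS  15 kd3  16 kdz  17 kdZ  18 kd2  19 kde  20 kdn
 * 21 JT    22 Js   23 Jss  24 JS   25 J31  26 J32  27 Jz   28 JZ
 * 29 J21   30 J22  31 Je1  32 Je2  33 Jn1  34 Jn2
 * 35 nT    36 ns   37 nS   38 n3   39 nz   40 nZ   41 n2   42 ne   43 nn */

static double emt_parms[44];

void fatemap_emt_init(void (*odeparms)(int *, double *))
{
    int n = 44;
    odeparms(&n, emt_parms);
}

static double hillpow(double x, double J, double n)
{
    if (x <= 0.0) return 0.0;
    return pow(x / J, n);
}

static void emt_rhs(const double *y, const double *p, double *dy)
{
    double T = y[0], s = y[1], S = y[2], R3 = y[3], z = y[4];
    double Z = y[5], R2 = y[6], E = y[7], N = y[8];
    double Ttot = T + p[0];             /* endogenous + exogenous TGF-b */
    double act, u;

    /* endogenous TGF-b, translation repressed by miR-200 */
    dy[0] = p[1] / (1.0 + hillpow(R2, p[21], p[35])) - p[12] * T;

    /* snail mRNA: activated by total TGF-b, self-repressed by SNAIL */
    u = hillpow(Ttot, p[22], p[36]);
    act = u / (1.0 + u);
    dy[1] = p[2] * act / (1.0 + hillpow(S, p[23], p[36])) - p[13] * s;

    /* SNAIL protein: translation repressed by miR-34 */
    dy[2] = p[3] * s / (1.0 + hillpow(R3, p[24], p[37])) - p[14] * S;

    /* miR-34: repressed by SNAIL and ZEB */
    dy[3] = p[4] / (1.0 + hillpow(S, p[25], p[38]) + hillpow(Z, p[26], p[38]))
            - p[15] * R3;

    /* zeb mRNA: activated by SNAIL */
    u = hillpow(S, p[27], p[39]);
    dy[4] = p[5] * u / (1.0 + u) - p[16] * z;

    /* ZEB protein: translation repressed by miR-200 */
    dy[5] = p[6] * z / (1.0 + hillpow(R2, p[28], p[40])) - p[17] * Z;

    /* miR-200: repressed by SNAIL and ZEB */
    dy[6] = p[7] / (1.0 + hillpow(S, p[29], p[41]) + hillpow(Z, p[30], p[41]))
            - p[18] * R2;

    /* E-cadherin: repressed by SNAIL and by ZEB (two independent inputs) */
    dy[7] = p[8] / (1.0 + hillpow(S, p[31], p[42]))
          + p[9] / (1.0 + hillpow(Z, p[32], p[42])) - p[19] * E;

    /* N-cadherin: activated by SNAIL and by ZEB */
    u = hillpow(S, p[33], p[43]);
    act = u / (1.0 + u);
    u = hillpow(Z, p[34], p[43]);
    dy[8] = p[10] * act + p[11] * u / (1.0 + u) - p[20] * N;
}

void fatemap_emt_derivs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    emt_rhs(y, emt_parms, ydot);
}

/* ---- .Call wrappers for direct evaluation ---- */

SEXP C_ts_rhs(SEXP y, SEXP p)
{
    SEXP out = PROTECT(allocVector(REALSXP, 2));
    ts_rhs(REAL(y), REAL(p), REAL(out));
    UNPROTECT(1);
    return out;
}

SEXP C_emt_rhs(SEXP y, SEXP p)
{
    SEXP out = PROTECT(allocVector(REALSXP, 9));
    emt_rhs(REAL(y), REAL(p), REAL(out));
    UNPROTECT(1);
    return out;
}

/* ---- registration ---- */

static const R_CallMethodDef call_entries[] = {
    {"C_ts_rhs",  (DL_FUNC) &C_ts_rhs,  2},
    {"C_emt_rhs", (DL_FUNC) &C_emt_rhs, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"fatemap_ts_derivs",  (DL_FUNC) &fatemap_ts_derivs,  6},
    {"fatemap_ts_init",    (DL_FUNC) &fatemap_ts_init,    1},
    {"fatemap_emt_derivs", (DL_FUNC) &fatemap_emt_derivs, 6},
    {"fatemap_emt_init",   (DL_FUNC) &fatemap_emt_init,   1},
    {NULL, NULL, 0}
};

void R_init_fatemap(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
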