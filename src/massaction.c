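/* Generic mass-action right-hand side for deSolve's compiled-model interface.
 *
 * The network (reactant/factor indices and sparse stoichiometry triplets) and
 * the rate-constant vector are staged from R via .Call() before each ode()
 * call; ma_derivs() then evaluates
 *   flux_j  = k_j * y[f1_j] * (f2_j >= 0 ? y[f2_j] : 1)
 *   ydot_i  = sum over triplets (j, i, c): c * flux_j
 * Catalytic modifiers are encoded as second factors with zero net
 * stoichiometry. State is module-global, so only one staged network exists
 * per process at a time (the solver runs single-threaded).
 */
#include <stdlib.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static int n_reac = 0;
static int n_trip = 0;
static int *f1 = NULL;        /* first factor state index, 0-based */
static int *f2 = NULL;        /* second factor state index, -1 if unary */
static int *tr_reac = NULL;   /* stoichiometry triplet: reaction */
static int *tr_state = NULL;  /* stoichiometry triplet: state   */
static double *tr_coef = NULL;
static double *rate = NULL;
static double *flux = NULL;

static void ma_free(void)
{
    free(f1); free(f2); free(tr_reac); free(tr_state);
    free(tr_coef); free(rate); free(flux);
    f1 = f2 = tr_reac = tr_state = NULL;
    tr_coef = rate = flux = NULL;
    n_reac = n_trip = 0;
}

SEXP ma_set_network(SEXP sf1, SEXP sf2, SEXP s_tr_reac, SEXP s_tr_state,
                    SEXP s_tr_coef)
{
    ma_free();
    n_reac = LENGTH(sf1);
    n_trip = LENGTH(s_tr_reac);
    if (LENGTH(sf2) != n_reac)
        error("factor index vectors must have equal length");
    if (LENGTH(s_tr_state) != n_trip || LENGTH(s_tr_coef) != n_trip)
        error("stoichiometry triplet vectors must have equal length");

    f1 = (int *) malloc(sizeof(int) * n_reac);
    f2 = (int *) malloc(sizeof(int) * n_reac);
    tr_reac = (int *) malloc(sizeof(int) * n_trip);
    tr_state = (int *) malloc(sizeof(int) * n_trip);
    tr_coef = (double *) malloc(sizeof(double) * n_trip);
    rate = (double *) calloc(n_reac, sizeof(double));
    flux = (double *) malloc(sizeof(double) * n_reac);
    if (!f1 || !f2 || !tr_reac || !tr_state || !tr_coef || !rate || !flux) {
        ma_free();
        error("allocation failure in ma_set_network");
    }
    memcpy(f1, INTEGER(sf1), sizeof(int) * n_reac);
    memcpy(f2, INTEGER(sf2), sizeof(int) * n_reac);
    memcpy(tr_reac, INTEGER(s_tr_reac), sizeof(int) * n_trip);
    memcpy(tr_state, INTEGER(s_tr_state), sizeof(int) * n_trip);
    memcpy(tr_coef, REAL(s_tr_coef), sizeof(double) * n_trip);
    return ScalarInteger(n_reac);
}

SEXP ma_set_rates(SEXP k)
{
    if (LENGTH(k) != n_reac)
        error("rate vector length %d, expected %d", LENGTH(k), n_reac);
    memcpy(rate, REAL(k), sizeof(double) * n_reac);
    return ScalarLogical(1);
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int i, j;
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (j = 0; j < n_reac; j++) {
        double f = rate[j] * y[f1[j]];
        if (f2[j] >= 0) f *= y[f2[j]];
        flux[j] = f;
    }
    for (j = 0; j < n_trip; j++)
        ydot[tr_state[j]] += tr_coef[j] * flux[tr_reac[j]];
}

static const R_CallMethodDef call_entries[] = {
    {"ma_set_network", (DL_FUNC) &ma_set_network, 5},
    {"ma_set_rates",   (DL_FUNC) &ma_set_rates,   1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"ma_derivs", (DL_FUNC) &ma_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_dualRTK(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_forceSymbols(dll, FALSE);
}
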