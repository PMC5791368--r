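// Compiled kinetics of the IkBa/NF-kB decoy circuit.
//
// One mass-action core evaluates the deterministic derivative over the full
// state (11 bulk species + unbound/bound decoy pools per spectrum bin); it is
// shared by the R-facing rhs wrapper and by the deSolve integrator, which
// works on a reduced state with the exactly conserved coordinates (OFF and
// the unbound decoy pools) eliminated. The stochastic simulator is a direct
// Gillespie method over the compiled reaction set and uses R's RNG stream.

#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (copy-number units; primed = already divided or
// multiplied by omega on the R side):
//  0 k_on'  1 k_off  2 k_s'  3 k_tr'  4 k_tl  5 k_d  6 k_in  7 k_out
//  8 k_Nin  9 k_f'  10 k_b  11 k_fn' 12 k_bn 13 k_NIout 14 alpha
// 15 k_son' 16 k_soff 17 lambda_s(unbound) 18 lambda_s(bound)
// 19 degrade_bound_releases 20 k_don' 21 G_total 22 n_bins
// 23..23+n-1 k_doff[i] 23+n..23+2n-1 count[i]
#define MAXBINS 64
#define NPARMS (23 + 2 * MAXBINS)

// Full-state layout:
// 0 N_n 1 N_c 2 I_n 3 I_c 4 NI_n 5 NI_c 6 mRNA 7 ON 8 OFF 9 AD_U 10 AD_B
// 11..11+n-1 D_U[i]  11+n..11+2n-1 D_B[i]
static void decoy_core(const double *p, const double *y, double *yd) {
  const int n = (int) p[22];
  const double N_n = y[0], N_c = y[1], I_n = y[2], I_c = y[3];
  const double NI_n = y[4], NI_c = y[5], mRNA = y[6];
  const double ON = y[7], OFF = y[8], AD_U = y[9], AD_B = y[10];
  const double *D_U = y + 11, *D_B = y + 11 + n;
  const double *k_doff = p + 23;

  double sum_DU = 0.0, sum_DB = 0.0, sum_koff_DB = 0.0;
  for (int i = 0; i < n; ++i) {
    sum_DU += D_U[i];
    sum_DB += D_B[i];
    sum_koff_DB += k_doff[i] * D_B[i];
  }

  const double bind_prom = p[0] * N_n * OFF;       // k_on'
  const double strip_prom = p[2] * ON * I_n;       // k_s'
  const double strip_odn = p[2] * AD_B * I_n;
  const double assoc_n = p[11] * N_n * I_n;        // k_fn'
  const double assoc_c = p[9] * N_c * I_c;         // k_f'
  const double bind_odn = p[15] * AD_U * N_n;      // k_son'
  const double degr_b = p[18] * AD_B;              // bound-ODN degradation
  const double release = (p[19] != 0.0) ? degr_b : 0.0;

  yd[0] = -bind_prom + p[1] * ON + p[8] * N_c
          - assoc_n + p[12] * NI_n
          - p[20] * sum_DU * N_n + sum_koff_DB
          + p[16] * AD_B - bind_odn + release;                 // N_n
  yd[1] = -p[8] * N_c - assoc_c + p[10] * NI_c + p[14] * NI_c; // N_c
  yd[2] = p[6] * I_c - p[7] * I_n - assoc_n + p[12] * NI_n
          - p[2] * sum_DB * I_n - strip_prom - strip_odn;      // I_n
  yd[3] = p[4] * mRNA - p[6] * I_c + p[7] * I_n
          - assoc_c + p[10] * NI_c;                            // I_c
  yd[4] = assoc_n - p[12] * NI_n - p[13] * NI_n
          + p[2] * sum_DB * I_n + strip_prom + strip_odn;      // NI_n
  yd[5] = assoc_c - p[10] * NI_c - p[14] * NI_c
          + p[13] * NI_n;                                      // NI_c
  yd[6] = p[3] * ON - p[5] * mRNA;                             // mRNA
  yd[7] = bind_prom - p[1] * ON - strip_prom;                  // ON
  yd[8] = -yd[7];                                              // OFF
  yd[9] = -bind_odn + p[16] * AD_B + strip_odn
          - p[17] * AD_U;                                      // AD_U
  yd[10] = bind_odn - p[16] * AD_B - strip_odn - degr_b;       // AD_B
  for (int i = 0; i < n; ++i) {
    const double db = p[20] * D_U[i] * N_n - k_doff[i] * D_B[i]
                      - p[2] * D_B[i] * I_n;
    yd[11 + n + i] = db;   // D_B[i]
    yd[11 + i] = -db;      // D_U[i]
  }
}

// [[Rcpp::export]]
NumericVector rhs_full_cpp(NumericVector y, NumericVector parms) {
  const int n = (int) parms[22];
  if (y.size() != 11 + 2 * n) stop("state length does not match n_bins");
  NumericVector yd(y.size());
  decoy_core(REAL(parms), REAL(y), REAL(yd));
  return yd;
}

// ---- deSolve compiled interface (reduced state) ----
// Reduced layout: 0..7 as full, 8 AD_U, 9 AD_B, 10..10+n-1 D_B[i].
static double ode_parms[NPARMS];

extern "C" {

void initmod_decoy(void (*odeparms)(int *, double *)) {
  int N = NPARMS;
  odeparms(&N, ode_parms);
}

void derivs_decoy(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  (void) t; (void) yout; (void) ip;
  const double *p = ode_parms;
  const int n = (int) p[22];
  double yf[11 + 2 * MAXBINS], ydf[11 + 2 * MAXBINS];
  for (int i = 0; i < 8; ++i) yf[i] = y[i];
  yf[8] = p[21] - y[7];                  // OFF = G_total - ON
  yf[9] = y[8];                          // AD_U
  yf[10] = y[9];                         // AD_B
  const double *count = p + 23 + n;
  for (int i = 0; i < n; ++i) {
    yf[11 + i] = count[i] - y[10 + i];   // D_U = count - D_B
    yf[11 + n + i] = y[10 + i];
  }
  decoy_core(p, yf, ydf);
  for (int i = 0; i < 8; ++i) ydot[i] = ydf[i];
  ydot[8] = ydf[9];
  ydot[9] = ydf[10];
  for (int i = 0; i < n; ++i) ydot[10 + i] = ydf[11 + n + i];
  (void) neq;
}

} // extern "C"

// deSolve locates initmod_decoy/derivs_decoy by dynamic symbol lookup,
// which Rcpp's generated registration turns off; turn it back on.
// [[Rcpp::init]]
void decoy_enable_symbol_lookup(DllInfo *dll) {
  R_useDynamicSymbols(dll, TRUE);
}

// ---- exact stochastic simulation (Gillespie direct method) ----

// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector x0, IntegerMatrix stoich, NumericVector rate,
                 IntegerVector r1, IntegerVector r2,
                 double t_end, double record_dt,
                 double max_events, int log_max) {
  const int S = stoich.nrow(), R = stoich.ncol();
  if (x0.size() != S) stop("state length does not match stoichiometry");

  // compact per-reaction change lists
  std::vector<std::vector<std::pair<int, int> > > change(R);
  for (int j = 0; j < R; ++j)
    for (int i = 0; i < S; ++i)
      if (stoich(i, j) != 0) change[j].push_back(std::make_pair(i, stoich(i, j)));

  // dependency graph: firing j invalidates the propensities of every
  // reaction with a reactant among j's changed species
  std::vector<std::vector<int> > dep(R);
  {
    std::vector<std::vector<int> > by_species(S);
    for (int q = 0; q < R; ++q) {
      by_species[r1[q]].push_back(q);
      if (r2[q] >= 0 && r2[q] != r1[q]) by_species[r2[q]].push_back(q);
    }
    for (int j = 0; j < R; ++j) {
      std::vector<char> seen(R, 0);
      for (size_t k = 0; k < change[j].size(); ++k) {
        const std::vector<int> &qs = by_species[change[j][k].first];
        for (size_t u = 0; u < qs.size(); ++u)
          if (!seen[qs[u]]) { seen[qs[u]] = 1; dep[j].push_back(qs[u]); }
      }
    }
  }

  std::vector<double> x(S);
  for (int i = 0; i < S; ++i) x[i] = (double) x0[i];

  const int n_rec = (int) std::floor(t_end / record_dt + 1e-9) + 1;
  IntegerMatrix states(n_rec, S);
  NumericVector times(n_rec);
  for (int k = 0; k < n_rec; ++k) times[k] = k * record_dt;

  std::vector<double> ev_times;
  if (log_max > 0) ev_times.reserve(log_max);

  std::vector<double> a(R);
  const double *c = REAL(rate);
  const int *i1 = INTEGER(r1), *i2 = INTEGER(r2);

  double t = 0.0, n_events = 0.0;
  int rec = 0;
  bool done = false;

  double asum = 0.0;
  for (int j = 0; j < R; ++j) {
    double aj = c[j] * x[i1[j]];
    if (i2[j] >= 0) aj *= x[i2[j]];
    a[j] = aj;
    asum += aj;
  }
  long long since_refresh = 0;

  while (!done) {
    if (++since_refresh >= 100000) {   // limit round-off drift in asum
      asum = 0.0;
      for (int j = 0; j < R; ++j) {
        double aj = c[j] * x[i1[j]];
        if (i2[j] >= 0) aj *= x[i2[j]];
        a[j] = aj;
        asum += aj;
      }
      since_refresh = 0;
    }
    double t_next;
    if (asum <= 0.0) {
      t_next = t_end + 1.0;             // frozen: hold state to the horizon
    } else {
      t_next = t + exp_rand() / asum;
    }
    while (rec < n_rec && times[rec] < t_next) {
      for (int i = 0; i < S; ++i) states(rec, i) = (int) x[i];
      ++rec;
    }
    if (t_next > t_end || asum <= 0.0) {
      done = true;
      break;
    }
    double u = unif_rand() * asum;
    int j = 0;
    double acc = a[0];
    while (acc < u && j < R - 1) acc += a[++j];
    for (size_t k = 0; k < change[j].size(); ++k)
      x[change[j][k].first] += change[j][k].second;
    const std::vector<int> &ds = dep[j];
    for (size_t k = 0; k < ds.size(); ++k) {
      const int q = ds[k];
      asum -= a[q];
      double aq = c[q] * x[i1[q]];
      if (i2[q] >= 0) aq *= x[i2[q]];
      a[q] = aq;
      asum += aq;
    }
    if (asum < 0.0) asum = 0.0;
    t = t_next;
    n_events += 1.0;
    if (log_max > 0 && (int) ev_times.size() < log_max) ev_times.push_back(t);
    if (n_events >= max_events)
      stop("event cap (%g) exceeded at t = %g min; reduce omega or t_end",
           max_events, t);
  }
  while (rec < n_rec) {                  // pad any remaining grid points
    for (int i = 0; i < S; ++i) states(rec, i) = (int) x[i];
    ++rec;
  }

  List out = List::create(_["times"] = times, _["states"] = states,
                          _["n_events"] = n_events);
  if (log_max > 0) out["event_times"] = NumericVector(ev_times.begin(), ev_times.end());
  return out;
}
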