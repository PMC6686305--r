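#include <Rcpp.h>
using namespace Rcpp;

// All randomness flows through R's RNG so set.seed() governs every draw.

static inline int unif_index(int n) {
  // uniform integer in [0, n), rejection-free for practical n
  int k;
  do {
    k = int(R::unif_rand() * n);
  } while (k >= n);
  return k;
}

// ---------------------------------------------------------------- SIM2 ----
// Row sums fixed, columns equiprobable: each row's presences are placed in
// r_i distinct columns drawn uniformly without replacement.
// [[Rcpp::export]]
IntegerMatrix cpp_sim2(const IntegerMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  IntegerMatrix out(S, T);
  std::vector<int> cols(T);
  for (int i = 0; i < S; ++i) {
    int r = 0;
    for (int k = 0; k < T; ++k) r += m(i, k);
    for (int k = 0; k < T; ++k) cols[k] = k;
    // partial Fisher-Yates: first r entries are a uniform r-subset
    for (int k = 0; k < r; ++k) {
      int pick = k + unif_index(T - k);
      std::swap(cols[k], cols[pick]);
      out(i, cols[k]) = 1;
    }
  }
  out.attr("dimnames") = m.attr("dimnames");
  return out;
}

// ---------------------------------------------------------------- SIM9 ----
// Sequential swap on 2x2 checkerboard submatrices; proposals are uniform
// (row pair, column pair) draws, swapped only when a checkerboard is found.
// The proposal is symmetric, so the chain's stationary distribution is
// uniform over the fixed-marginal ensemble.

static inline void sim9_attempts(IntegerMatrix& m, int attempts, int S, int T) {
  for (int a = 0; a < attempts; ++a) {
    int i1 = unif_index(S);
    int i2 = unif_index(S - 1);
    if (i2 >= i1) ++i2;
    int j1 = unif_index(T);
    int j2 = unif_index(T - 1);
    if (j2 >= j1) ++j2;
    const int A = m(i1, j1), B = m(i1, j2), C = m(i2, j1), D = m(i2, j2);
    if (A == D && B == C && A != B) {
      m(i1, j1) = B; m(i1, j2) = A; m(i2, j1) = D; m(i2, j2) = C;
    }
  }
}

// [[Rcpp::export]]
bool cpp_has_checkerboard(const IntegerMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  for (int i = 0; i < S - 1; ++i)
    for (int j = i + 1; j < S; ++j)
      for (int k = 0; k < T - 1; ++k)
        for (int l = k + 1; l < T; ++l) {
          const int A = m(i, k), B = m(i, l), C = m(j, k), D = m(j, l);
          if (A == D && B == C && A != B) return true;
        }
  return false;
}

// Emit n_samples matrices from the swap chain (burn_in attempts, then one
// sample every `thin` attempts).
// [[Rcpp::export]]
List cpp_sim9_matrices(const IntegerMatrix& m, int burn_in, int thin,
                       int n_samples) {
  const int S = m.nrow(), T = m.ncol();
  IntegerMatrix state = clone(m);
  sim9_attempts(state, burn_in, S, T);
  List out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    sim9_attempts(state, thin, S, T);
    out[s] = clone(state);
  }
  return out;
}

// Compact bit-encoded samples for small matrices (S*T <= 30): cell (i,k)
// contributes bit i*T+k. Used for ensemble-frequency checks.
// [[Rcpp::export]]
IntegerVector cpp_sim9_codes(const IntegerMatrix& m, int burn_in, int thin,
                             int n_samples) {
  const int S = m.nrow(), T = m.ncol();
  if (S * T > 30) stop("matrix too large for bit encoding");
  IntegerMatrix state = clone(m);
  sim9_attempts(state, burn_in, S, T);
  IntegerVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    sim9_attempts(state, thin, S, T);
    int code = 0;
    for (int i = 0; i < S; ++i)
      for (int k = 0; k < T; ++k)
        if (state(i, k)) code |= (1 << (i * T + k));
    out[s] = code;
  }
  return out;
}

// ------------------------------------------------- binary null driver ----
// Null distributions of the requested binary indices under SIM2 (fresh
// randomization per replicate) or SIM9 (one long swap chain). Columns:
// CHECKER, C_SCORE, V_RATIO (NA when not requested).
int cpp_checker(const IntegerMatrix& m);
double cpp_cscore(const IntegerMatrix& m);
double cpp_vratio(const IntegerMatrix& m);
NumericVector cpp_ca_aa(const NumericMatrix& m);
double cpp_ma(const NumericMatrix& m);

// [[Rcpp::export]]
NumericMatrix cpp_binary_null(const IntegerMatrix& m, std::string algorithm,
                              LogicalVector want, int n_sim, int burn_in,
                              int thin) {
  const int S = m.nrow(), T = m.ncol();
  NumericMatrix out(n_sim, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  const bool sim9 = (algorithm == "SIM9");
  IntegerMatrix state;
  if (sim9) {
    state = clone(m);
    sim9_attempts(state, burn_in, S, T);
  }
  for (int s = 0; s < n_sim; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    IntegerMatrix null_m;
    if (sim9) {
      sim9_attempts(state, thin, S, T);
      null_m = state;
    } else {
      null_m = cpp_sim2(m);
    }
    if (want[0]) out(s, 0) = cpp_checker(null_m);
    if (want[1]) out(s, 1) = cpp_cscore(null_m);
    if (want[2]) out(s, 2) = cpp_vratio(null_m);
  }
  return out;
}

// ------------------------------------------------------------ IT / IA ----
// Weighted draw from `weights` restricted to active indices; `total` is the
// current sum of active weights. Linear scan (S, T are small).
static inline int weighted_pick(const std::vector<double>& w,
                                const std::vector<bool>& active,
                                double total) {
  double u = R::unif_rand() * total;
  double acc = 0.0;
  int last = -1;
  for (size_t i = 0; i < w.size(); ++i) {
    if (!active[i]) continue;
    acc += w[i];
    last = int(i);
    if (u <= acc) return last;
  }
  return last;  // guard against floating-point tail
}

// IT: place N individuals one at a time with cell probability proportional
// to R_i * C_j among cells whose row and column are not yet saturated;
// both marginals are reproduced exactly. A dead-end triggers a full restart
// (defensive: with product-form admissibility a dead-end cannot occur).
// [[Rcpp::export]]
IntegerMatrix cpp_it(const IntegerVector& row_totals,
                     const IntegerVector& col_totals, int max_restarts) {
  const int S = row_totals.size(), T = col_totals.size();
  long N = 0, Nc = 0;
  for (int i = 0; i < S; ++i) N += row_totals[i];
  for (int k = 0; k < T; ++k) Nc += col_totals[k];
  if (N != Nc) stop("row and column totals must have equal sums");
  IntegerMatrix out(S, T);
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    std::fill(out.begin(), out.end(), 0);
    std::vector<double> rw(S), cw(T);
    std::vector<int> rrem(S), crem(T);
    std::vector<bool> ract(S), cact(T);
    double rtot = 0.0, ctot = 0.0;
    for (int i = 0; i < S; ++i) {
      rw[i] = row_totals[i]; rrem[i] = row_totals[i];
      ract[i] = rrem[i] > 0; if (ract[i]) rtot += rw[i];
    }
    for (int k = 0; k < T; ++k) {
      cw[k] = col_totals[k]; crem[k] = col_totals[k];
      cact[k] = crem[k] > 0; if (cact[k]) ctot += cw[k];
    }
    bool ok = true;
    for (long n = 0; n < N; ++n) {
      if (rtot <= 0.0 || ctot <= 0.0) { ok = false; break; }
      int i = weighted_pick(rw, ract, rtot);
      int k = weighted_pick(cw, cact, ctot);
      if (i < 0 || k < 0) { ok = false; break; }
      ++out(i, k);
      if (--rrem[i] == 0) { ract[i] = false; rtot -= rw[i]; }
      if (--crem[k] == 0) { cact[k] = false; ctot -= cw[k]; }
    }
    if (ok) return out;
  }
  stop("IT randomization exhausted its restart budget");
}

// IA: N independent placements with cell probability R_i * C_j / N^2; only
// the grand total is constrained.
// [[Rcpp::export]]
IntegerMatrix cpp_ia(const IntegerVector& row_totals,
                     const IntegerVector& col_totals) {
  const int S = row_totals.size(), T = col_totals.size();
  long N = 0;
  for (int i = 0; i < S; ++i) N += row_totals[i];
  std::vector<double> rcum(S), ccum(T);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) { acc += row_totals[i]; rcum[i] = acc; }
  const double rsum = acc;
  acc = 0.0;
  for (int k = 0; k < T; ++k) { acc += col_totals[k]; ccum[k] = acc; }
  const double csum = acc;
  IntegerMatrix out(S, T);
  for (long n = 0; n < N; ++n) {
    double u = R::unif_rand() * rsum;
    int i = int(std::lower_bound(rcum.begin(), rcum.end(), u) - rcum.begin());
    if (i >= S) i = S - 1;
    double v = R::unif_rand() * csum;
    int k = int(std::lower_bound(ccum.begin(), ccum.end(), v) - ccum.begin());
    if (k >= T) k = T - 1;
    ++out(i, k);
  }
  return out;
}

// ------------------------------------------------- quant null driver ----
// Null distributions of CA_ST, AA_ST, MA under IT or IA. Columns:
// CA_ST, AA_ST, MA (NA when not requested).
// [[Rcpp::export]]
NumericMatrix cpp_quant_null(const IntegerMatrix& m, std::string algorithm,
                             LogicalVector want, int n_sim, int max_restarts) {
  const int S = m.nrow(), T = m.ncol();
  IntegerVector rt(S), ct(T);
  for (int i = 0; i < S; ++i)
    for (int k = 0; k < T; ++k) { rt[i] += m(i, k); ct[k] += m(i, k); }
  const bool it = (algorithm == "IT");
  NumericMatrix out(n_sim, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  const bool need_caaa = want[0] || want[1];
  for (int s = 0; s < n_sim; ++s) {
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
    IntegerMatrix null_m = it ? cpp_it(rt, ct, max_restarts) : cpp_ia(rt, ct);
    NumericMatrix nm(S, T);
    for (int i = 0; i < S; ++i)
      for (int k = 0; k < T; ++k) nm(i, k) = null_m(i, k);
    if (need_caaa) {
      NumericVector caaa = cpp_ca_aa(nm);
      if (want[0]) out(s, 0) = caaa[0];
      if (want[1]) out(s, 1) = caaa[1];
    }
    if (want[2]) out(s, 2) = cpp_ma(nm);
  }
  return out;
}
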