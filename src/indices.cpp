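#include <Rcpp.h>
using namespace Rcpp;

// Binary co-occurrence indices operate on species-by-year 0/1 matrices.
// All pair loops run over unordered species pairs i < j.

// [[Rcpp::export]]
int cpp_checker(const IntegerMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  int count = 0;
  for (int i = 0; i < S - 1; ++i) {
    for (int j = i + 1; j < S; ++j) {
      int shared = 0;
      for (int k = 0; k < T; ++k) shared += m(i, k) & m(j, k);
      if (shared == 0) ++count;
    }
  }
  return count;
}

// C-score: mean over pairs of (r_i - S_ij)(r_j - S_ij), r = row totals,
// S_ij = number of shared presences.
// [[Rcpp::export]]
double cpp_cscore(const IntegerMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  std::vector<int> rt(S, 0);
  for (int i = 0; i < S; ++i)
    for (int k = 0; k < T; ++k) rt[i] += m(i, k);
  double sum = 0.0;
  for (int i = 0; i < S - 1; ++i) {
    for (int j = i + 1; j < S; ++j) {
      int shared = 0;
      for (int k = 0; k < T; ++k) shared += m(i, k) & m(j, k);
      sum += double(rt[i] - shared) * double(rt[j] - shared);
    }
  }
  return sum / (double(S) * (S - 1) / 2.0);
}

// V-ratio: Var(column sums) / sum of per-row variances, population variances.
// [[Rcpp::export]]
double cpp_vratio(const IntegerMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  double denom = 0.0;
  for (int i = 0; i < S; ++i) {
    double r = 0.0;
    for (int k = 0; k < T; ++k) r += m(i, k);
    double p = r / T;
    denom += p * (1.0 - p);  // population variance of a 0/1 row
  }
  double mean_cs = 0.0;
  std::vector<double> cs(T, 0.0);
  for (int k = 0; k < T; ++k) {
    for (int i = 0; i < S; ++i) cs[k] += m(i, k);
    mean_cs += cs[k];
  }
  mean_cs /= T;
  double num = 0.0;
  for (int k = 0; k < T; ++k) num += (cs[k] - mean_cs) * (cs[k] - mean_cs);
  num /= T;
  if (denom <= 0.0) return NA_REAL;  // all rows constant; caller errors
  return num / denom;
}

// Standardized abundance checkerboards (CA) and aggregations (AA):
// over all 2x2 species-by-year submatrices, count opposing vs concordant
// abundance differences; ties (either difference zero) count to neither.
// Returns c(CA_ST, AA_ST) = counts / (C(S,2) * C(T,2)).
// [[Rcpp::export]]
NumericVector cpp_ca_aa(const NumericMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  double ca = 0.0, aa = 0.0;
  // Only the signs of the within-species differences matter: for a year
  // pair with p species increasing and n decreasing, the opposing pairs
  // number p*n and the concordant ones C(p,2)+C(n,2).
  for (int k = 0; k < T - 1; ++k) {
    for (int l = k + 1; l < T; ++l) {
      long p = 0, n = 0;
      for (int i = 0; i < S; ++i) {
        const double d = m(i, k) - m(i, l);
        if (d > 0.0) ++p; else if (d < 0.0) ++n;
      }
      ca += double(p) * double(n);
      aa += double(p) * (p - 1) / 2.0 + double(n) * (n - 1) / 2.0;
    }
  }
  const double denom = (double(S) * (S - 1) / 2.0) * (double(T) * (T - 1) / 2.0);
  return NumericVector::create(ca / denom, aa / denom);
}

// Multi-community Morisita-Horn similarity across year columns.
// p_ik = relative abundance of species i in year k (columns normalized);
// MA = sum_i[(sum_k p_ik)^2 - sum_k p_ik^2] / [(T_eff - 1) * sum_ik p_ik^2].
// All-zero columns are skipped (T_eff = number of non-empty columns); the
// caller enforces non-empty columns for observed matrices.
// [[Rcpp::export]]
double cpp_ma(const NumericMatrix& m) {
  const int S = m.nrow(), T = m.ncol();
  std::vector<double> colsum(T, 0.0);
  int t_eff = 0;
  for (int k = 0; k < T; ++k) {
    for (int i = 0; i < S; ++i) colsum[k] += m(i, k);
    if (colsum[k] > 0.0) ++t_eff;
  }
  if (t_eff < 2) return NA_REAL;
  double num = 0.0, den = 0.0;
  for (int i = 0; i < S; ++i) {
    double sp = 0.0, sp2 = 0.0;
    for (int k = 0; k < T; ++k) {
      if (colsum[k] <= 0.0) continue;
      const double p = m(i, k) / colsum[k];
      sp += p;
      sp2 += p * p;
    }
    num += sp * sp - sp2;
    den += sp2;
  }
  if (den <= 0.0) return NA_REAL;
  return num / ((t_eff - 1.0) * den);
}
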