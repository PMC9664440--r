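#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pair-HMM state indexing used throughout this file:
//   0 = S (start; occupied only at cell (0,0)),
//   1 = M, 2 = Ix, 3 = Iy, 4 = Jx, 5 = Jy.
// The R side passes a 6x6 log-transition matrix T (T[s][d] = log P(s -> d),
// -Inf where the topology has no edge) and a length-6 log-termination vector
// E (E[s] = log P(s -> end)).  Emissions are passed as log matrices/vectors.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse_acc(double acc, double x) { return lse2(acc, x); }

struct Grid {
  // (n+1) x (m+1) x 6 array of log-probabilities
  int n, m;
  std::vector<double> v;
  Grid(int n_, int m_) : n(n_), m(m_), v((size_t)(n_ + 1) * (m_ + 1) * 6, NEG_INF) {}
  double &at(int i, int j, int k) { return v[((size_t)i * (m + 1) + j) * 6 + k]; }
};

// Forward pass. x, y are 0-based integer encodings of the sequences.
// lem: AxA log joint emission matrix (M state); lins: length-A log marginals.
static void forward_fill(Grid &F, const IntegerVector &x, const IntegerVector &y,
                         const NumericMatrix &T, const NumericMatrix &lem,
                         const NumericVector &lins) {
  int n = F.n, m = F.m;
  F.at(0, 0, 0) = 0.0;  // start state
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      // M consumes (x_i, y_j)
      if (i >= 1 && j >= 1) {
        double acc = NEG_INF;
        for (int k = 0; k < 6; ++k) {
          double p = F.at(i - 1, j - 1, k);
          if (p != NEG_INF && T(k, 1) != NEG_INF) acc = lse_acc(acc, p + T(k, 1));
        }
        if (acc != NEG_INF) F.at(i, j, 1) = acc + lem(x[i - 1], y[j - 1]);
      }
      // Ix (state 2) and Jx (state 4) consume x_i
      if (i >= 1) {
        for (int s : {2, 4}) {
          double acc = NEG_INF;
          for (int k = 0; k < 6; ++k) {
            double p = F.at(i - 1, j, k);
            if (p != NEG_INF && T(k, s) != NEG_INF) acc = lse_acc(acc, p + T(k, s));
          }
          if (acc != NEG_INF) F.at(i, j, s) = acc + lins[x[i - 1]];
        }
      }
      // Iy (state 3) and Jy (state 5) consume y_j
      if (j >= 1) {
        for (int s : {3, 5}) {
          double acc = NEG_INF;
          for (int k = 0; k < 6; ++k) {
            double p = F.at(i, j - 1, k);
            if (p != NEG_INF && T(k, s) != NEG_INF) acc = lse_acc(acc, p + T(k, s));
          }
          if (acc != NEG_INF) F.at(i, j, s) = acc + lins[y[j - 1]];
        }
      }
    }
  }
}

static void backward_fill(Grid &B, const IntegerVector &x, const IntegerVector &y,
                          const NumericMatrix &T, const NumericMatrix &lem,
                          const NumericVector &lins, const NumericVector &E) {
  int n = B.n, m = B.m;
  for (int k = 0; k < 6; ++k) B.at(n, m, k) = E[k];
  for (int i = n; i >= 0; --i) {
    for (int j = m; j >= 0; --j) {
      if (i == n && j == m) continue;
      for (int k = 0; k < 6; ++k) {
        double acc = NEG_INF;
        if (i < n && j < m && T(k, 1) != NEG_INF) {
          double b = B.at(i + 1, j + 1, 1);
          if (b != NEG_INF) acc = lse_acc(acc, T(k, 1) + lem(x[i], y[j]) + b);
        }
        if (i < n) {
          for (int s : {2, 4}) {
            if (T(k, s) == NEG_INF) continue;
            double b = B.at(i + 1, j, s);
            if (b != NEG_INF) acc = lse_acc(acc, T(k, s) + lins[x[i]] + b);
          }
        }
        if (j < m) {
          for (int s : {3, 5}) {
            if (T(k, s) == NEG_INF) continue;
            double b = B.at(i, j + 1, s);
            if (b != NEG_INF) acc = lse_acc(acc, T(k, s) + lins[y[j]] + b);
          }
        }
        B.at(i, j, k) = acc;
      }
    }
  }
}

// [[Rcpp::export]]
double pairhmm_forward_total(IntegerVector x, IntegerVector y,
                             NumericMatrix T, NumericVector E,
                             NumericMatrix lem, NumericVector lins) {
  int n = x.size(), m = y.size();
  Grid F(n, m);
  forward_fill(F, x, y, T, lem, lins);
  double tot = NEG_INF;
  for (int k = 0; k < 6; ++k) {
    double p = F.at(n, m, k);
    if (p != NEG_INF && E[k] != NEG_INF) tot = lse_acc(tot, p + E[k]);
  }
  return tot;
}

// Posterior match probabilities P(x_i ~ y_j | x, y).  Returns a dense n x m
// matrix; the sparsity cutoff is applied on the R side.
// [[Rcpp::export]]
NumericMatrix pairhmm_posterior(IntegerVector x, IntegerVector y,
                                NumericMatrix T, NumericVector E,
                                NumericMatrix lem, NumericVector lins) {
  int n = x.size(), m = y.size();
  Grid F(n, m), B(n, m);
  forward_fill(F, x, y, T, lem, lins);
  backward_fill(B, x, y, T, lem, lins, E);
  double tot = NEG_INF;
  for (int k = 0; k < 6; ++k) {
    double p = F.at(n, m, k);
    if (p != NEG_INF && E[k] != NEG_INF) tot = lse_acc(tot, p + E[k]);
  }
  NumericMatrix P(n, m);
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double f = F.at(i, j, 1), b = B.at(i, j, 1);
      P(i - 1, j - 1) = (f == NEG_INF || b == NEG_INF) ? 0.0 : std::exp(f + b - tot);
    }
  return P;
}

// Maximum expected accuracy DP over a non-negative score matrix S: find the
// monotone alignment maximising the sum of S over matched pairs (gaps score
// 0).  Traceback tie-break: match, then gap in x (consume y), then gap in y.
// Returns list(ix, iy, score): ix/iy are 1-based indices, 0 = gap.
// [[Rcpp::export]]
List mea_dp(NumericMatrix S) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> D((size_t)(n + 1) * (m + 1), 0.0);
  auto at = [&](int i, int j) -> double & { return D[(size_t)i * (m + 1) + j]; };
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double best = at(i - 1, j - 1) + S(i - 1, j - 1);
      if (at(i - 1, j) > best) best = at(i - 1, j);
      if (at(i, j - 1) > best) best = at(i, j - 1);
      at(i, j) = best;
    }
  std::vector<int> rx, ry;
  int i = n, j = m;
  const double eps = 1e-12;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && std::fabs(at(i, j) - (at(i - 1, j - 1) + S(i - 1, j - 1))) <= eps) {
      rx.push_back(i); ry.push_back(j); --i; --j;
    } else if (j > 0 && std::fabs(at(i, j) - at(i, j - 1)) <= eps) {
      rx.push_back(0); ry.push_back(j); --j;
    } else {
      rx.push_back(i); ry.push_back(0); --i;
    }
  }
  std::reverse(rx.begin(), rx.end());
  std::reverse(ry.begin(), ry.end());
  return List::create(_["ix"] = IntegerVector(rx.begin(), rx.end()),
                      _["iy"] = IntegerVector(ry.begin(), ry.end()),
                      _["score"] = at(n, m));
}
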