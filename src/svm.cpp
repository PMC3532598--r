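// Dual solver for the C-SVC linear soft-margin classifier, operating on
// precomputed Gram matrices. Sequential minimal optimization with
// maximal-violating-pair working-set selection (the libsvm formulation):
//   min_a  0.5 a'Qa - e'a   s.t. 0 <= a_i <= C,  y'a = 0,
// with Q_ij = y_i y_j K_ij. Deterministic: ties in working-set selection
// resolve to the lowest index. The decode path (nested leave-one-trial-out
// selection of C inside each leave-one-session-out fold) lives here because
// permutation inference re-runs it tens of thousands of times.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double TAU = 1e-12;

struct SmoFit {
  std::vector<double> alpha;
  double rho;      // decision f(x) = sum_i alpha_i y_i K(x_i, x) - rho
  int iter;
  bool converged;
};

// K: n x n Gram (row-major access via lambda), y in {-1,+1}.
// a_init, if given, must be feasible for (C, y) — used to warm-start the
// solver, e.g. from the solution at a smaller C.
SmoFit smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                 int n, double C, double eps, int max_iter,
                 const std::vector<double>* a_init = nullptr) {
  std::vector<double> a(n, 0.0), G(n, -1.0);
  auto Q = [&](int i, int j) { return y[i] * y[j] * K[(size_t)i * n + j]; };
  if (a_init) {
    a = *a_init;
    for (int t = 0; t < n; ++t) {
      double g = -1.0;
      for (int s = 0; s < n; ++s)
        if (a[s] != 0.0) g += Q(t, s) * a[s];
      G[t] = g;
    }
  }

  std::vector<double> QD(n);
  for (int t = 0; t < n; ++t) QD[t] = K[(size_t)t * n + t];

  int it = 0;
  bool converged = false;
  for (; it < max_iter; ++it) {
    // second-order working-set selection (maximal violating pair for i,
    // maximal objective decrease for j)
    int i = -1, j = -1;
    double m = -std::numeric_limits<double>::infinity();
    double M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && a[t] < C) || (y[t] == -1 && a[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > m) { m = v; i = t; }
    }
    if (i < 0) { converged = true; break; }
    double best_gain = 0.0;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] == -1 && a[t] < C) || (y[t] == 1 && a[t] > 0);
      if (!low) continue;
      double v = -y[t] * G[t];
      if (v < M) M = v;
      double diff = m - v;
      if (diff > 0) {
        double quad = QD[i] + QD[t] - 2.0 * y[i] * y[t] * K[(size_t)i * n + t];
        if (quad <= 0) quad = TAU;
        double gain = diff * diff / quad;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
    }
    if (j < 0 || m - M <= eps) { converged = true; break; }

    double ai_old = a[i], aj_old = a[j];
    if (y[i] != y[j]) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) { if (a[j] < 0) { a[j] = 0; a[i] = diff; } }
      else          { if (a[i] < 0) { a[i] = 0; a[j] = -diff; } }
      if (diff > 0) { if (a[i] > C) { a[i] = C; a[j] = C - diff; } }
      else          { if (a[j] > C) { a[j] = C; a[i] = C + diff; } }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) { if (a[i] > C) { a[i] = C; a[j] = sum - C; } }
      else         { if (a[j] < 0) { a[j] = 0; a[i] = sum; } }
      if (sum > C) { if (a[j] > C) { a[j] = C; a[i] = sum - C; } }
      else         { if (a[i] < 0) { a[i] = 0; a[j] = sum; } }
    }
    double di = a[i] - ai_old, dj = a[j] - aj_old;
    if (di == 0.0 && dj == 0.0) { converged = true; break; }
    for (int t = 0; t < n; ++t) G[t] += Q(t, i) * di + Q(t, j) * dj;
  }

  // rho from KKT conditions (libsvm calc_rho)
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (a[t] >= C) { if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else if (a[t] <= 0) { if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else { ++nfree; sum_free += yG; }
  }
  double rho = nfree > 0 ? sum_free / nfree : 0.5 * (ub + lb);
  SmoFit fit;
  fit.alpha = a; fit.rho = rho; fit.iter = it; fit.converged = converged;
  return fit;
}

// subset Gram: K[rows, rows] from full n x n K stored column-major (R layout)
std::vector<double> subset_gram(const NumericMatrix& K, const std::vector<int>& rows) {
  int m = (int)rows.size();
  std::vector<double> S((size_t)m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      S[(size_t)i * m + j] = K(rows[i], rows[j]);
  return S;
}

bool both_classes(const std::vector<int>& y) {
  bool pos = false, neg = false;
  for (int v : y) { if (v > 0) pos = true; else neg = true; }
  return pos && neg;
}

// decision values for rows `test` of K given a fit on rows `train`
double decision_value(const NumericMatrix& K, const std::vector<int>& train,
                      const std::vector<int>& ytr, const SmoFit& fit, int test_row) {
  double f = 0.0;
  for (size_t i = 0; i < train.size(); ++i)
    f += fit.alpha[i] * ytr[i] * K(train[i], test_row);
  return f - fit.rho;
}

// inner leave-one-trial-out accuracy on rows `train` for each C in grid;
// the C grid must be ascending so each solve can warm-start from the
// previous C's solution (which stays feasible as the box grows)
std::vector<double> inner_loto(const NumericMatrix& K, const std::vector<int>& train,
                               const std::vector<int>& ytr, const NumericVector& C_grid,
                               double eps, int max_iter) {
  int n = (int)train.size(), nc = C_grid.size();
  std::vector<double> correct(nc, 0.0);
  std::vector<int> counted(nc, 0);
  std::vector<int> sub; sub.reserve(n - 1);
  std::vector<int> ysub; ysub.reserve(n - 1);
  for (int t = 0; t < n; ++t) {
    sub.clear(); ysub.clear();
    for (int i = 0; i < n; ++i)
      if (i != t) { sub.push_back(train[i]); ysub.push_back(ytr[i]); }
    if (!both_classes(ysub)) continue;  // left-in set degenerate: fold skipped
    std::vector<double> Ksub = subset_gram(K, sub);
    std::vector<double> a_prev;
    for (int c = 0; c < nc; ++c) {
      SmoFit fit = smo_solve(Ksub, ysub, (int)sub.size(), C_grid[c], eps,
                             max_iter, c > 0 ? &a_prev : nullptr);
      a_prev = fit.alpha;
      double f = decision_value(K, sub, ysub, fit, train[t]);
      int pred = f > 0 ? 1 : -1;
      counted[c] += 1;
      if (pred == ytr[t]) correct[c] += 1.0;
    }
  }
  std::vector<double> acc(nc, NA_REAL);
  for (int c = 0; c < nc; ++c)
    if (counted[c] > 0) acc[c] = correct[c] / counted[c];
  return acc;
}

std::vector<int> as_index0(const IntegerVector& v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_smo")]]
List cpp_smo(NumericMatrix K, IntegerVector y, double C, double eps = 1e-6,
             int max_iter = 200000) {
  int n = K.nrow();
  std::vector<double> Kv((size_t)n * n);
  std::vector<int> yv(n);
  for (int i = 0; i < n; ++i) {
    yv[i] = y[i];
    for (int j = 0; j < n; ++j) Kv[(size_t)i * n + j] = K(i, j);
  }
  SmoFit fit = smo_solve(Kv, yv, n, C, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["rho"] = fit.rho, _["iterations"] = fit.iter,
                      _["converged"] = fit.converged);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_inner_loto")]]
NumericVector cpp_inner_loto(NumericMatrix K, IntegerVector y, NumericVector C_grid,
                             double eps = 1e-6, int max_iter = 200000) {
  int n = K.nrow();
  std::vector<int> train(n), ytr(n);
  for (int i = 0; i < n; ++i) { train[i] = i; ytr[i] = y[i]; }
  std::vector<double> acc = inner_loto(K, train, ytr, C_grid, eps, max_iter);
  return NumericVector(acc.begin(), acc.end());
}

// Decode one stratum: per leave-one-session-out fold, nested LOTO selection of
// C on the training rows, final fit, prediction of the test rows.
// K_folds[[f]] is the full stratum Gram computed under fold f's feature scaling;
// train_idx/test_idx are 1-based row indices into that Gram.
//' @noRd
// [[Rcpp::export(name = ".cpp_decode_stratum")]]
List cpp_decode_stratum(List K_folds, List train_idx, List test_idx,
                        IntegerVector y, NumericVector C_grid,
                        double eps = 1e-6, int max_iter = 200000,
                        bool details = false) {
  int nf = K_folds.size(), n = y.size();
  IntegerVector pred(n, NA_INTEGER);
  NumericVector decision(n, NA_REAL);
  NumericVector chosen_C(nf, NA_REAL);
  LogicalVector skipped(nf);
  List fold_fits(nf);

  for (int f = 0; f < nf; ++f) {
    NumericMatrix K = K_folds[f];
    std::vector<int> train = as_index0(train_idx[f]);
    std::vector<int> test = as_index0(test_idx[f]);
    std::vector<int> ytr(train.size());
    for (size_t i = 0; i < train.size(); ++i) ytr[i] = y[train[i]];
    if (!both_classes(ytr)) { skipped[f] = true; continue; }

    int best = 0;
    if (C_grid.size() > 1) {
      std::vector<double> acc = inner_loto(K, train, ytr, C_grid, eps, max_iter);
      double best_acc = -1.0;
      for (int c = 0; c < (int)acc.size(); ++c)   // ties: first (smallest C)
        if (!ISNA(acc[c]) && acc[c] > best_acc) { best_acc = acc[c]; best = c; }
    }
    chosen_C[f] = C_grid[best];

    std::vector<double> Ktr = subset_gram(K, train);
    SmoFit fit = smo_solve(Ktr, ytr, (int)train.size(), C_grid[best], eps, max_iter);
    for (int t : test) {
      double fv = decision_value(K, train, ytr, fit, t);
      decision[t] = fv;
      pred[t] = fv > 0 ? 1 : -1;
    }
    if (details) {
      fold_fits[f] = List::create(
        _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
        _["rho"] = fit.rho);
    }
  }
  List out = List::create(_["pred"] = pred, _["decision"] = decision,
                          _["chosen_C"] = chosen_C, _["skipped"] = skipped);
  if (details) out["fold_fits"] = fold_fits;
  return out;
}
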