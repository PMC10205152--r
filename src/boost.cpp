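// Core numerics: L1 coordinate-descent boosting with validation-based
// predictor freezing, and the max-cluster-mass statistic over sign-flip
// permutations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact change in sum |r - d*z| - sum |r| for one column.
static double l1_delta(const arma::vec& r, const arma::vec& z, double d) {
  double acc = 0.0;
  const arma::uword n = r.n_elem;
  for (arma::uword t = 0; t < n; ++t) {
    acc += std::abs(r[t] - d * z[t]) - std::abs(r[t]);
  }
  return acc;
}

// Boosting for one channel.
//
// Z_tr, Z_va: design matrices (time x coefficient), columns are
// basis-expanded predictor dimensions. group: 0-based predictor id per
// column; a whole predictor freezes as a unit. delta: step size. At each
// step the single (column, sign) update that most reduces the training L1
// error is applied (ties: lowest column index, + before -). If the update
// increases the validation L1 error it is reverted and the column's
// predictor is frozen. Fitting stops when all predictors are frozen, when no
// update reduces the training error, or at max_steps.
//
// The candidate scan uses the identity |r - a| - |r| = -sign(r) * a whenever
// |r| >= |a|; rows where any |delta * z| could exceed |r| are corrected
// exactly, so the selection equals a brute-force scan.
//
// [[Rcpp::export]]
List boost_channel_cpp(const arma::mat& Z_tr, const arma::vec& y_tr,
                       const arma::mat& Z_va, const arma::vec& y_va,
                       const arma::ivec& group, double delta, int max_steps) {
  const arma::uword Tt = Z_tr.n_rows, J = Z_tr.n_cols;
  const int n_groups = group.max() + 1;

  arma::vec coef(J, arma::fill::zeros);
  arma::vec r_tr = y_tr;
  arma::vec r_va = y_va;
  double train_err = arma::accu(arma::abs(r_tr));
  double val_err = arma::accu(arma::abs(r_va));

  std::vector<bool> frozen(n_groups, false);
  IntegerVector freeze_step(n_groups, NA_INTEGER);
  std::vector<double> train_trace;
  train_trace.reserve(256);
  train_trace.push_back(train_err);

  // per-row bound for the linearization: delta * max_j |Z(t, j)|
  arma::vec rowmax = delta * arma::max(arma::abs(Z_tr), 1);

  int step = 0;
  int n_frozen = 0;
  while (step < max_steps && n_frozen < n_groups) {
    ++step;
    // linear part of the error change for a +delta step on each column
    arma::vec s = arma::sign(r_tr);
    arma::vec lin = Z_tr.t() * s; // Delta+(j) ~ -delta * lin[j]

    // exact corrections where the linearization can fail
    arma::uvec S = arma::find(arma::abs(r_tr) < rowmax);
    arma::vec corr_p(J, arma::fill::zeros), corr_m(J, arma::fill::zeros);
    for (arma::uword si = 0; si < S.n_elem; ++si) {
      const arma::uword t = S[si];
      const double r = r_tr[t], st = s[t];
      for (arma::uword j = 0; j < J; ++j) {
        const double a = delta * Z_tr(t, j);
        corr_p[j] += std::abs(r - a) - std::abs(r) + st * a;
        corr_m[j] += std::abs(r + a) - std::abs(r) - st * a;
      }
    }

    // best (column, sign) among unfrozen predictors
    int best_j = -1;
    double best_sign = 1.0, best_delta_err = 0.0;
    for (arma::uword j = 0; j < J; ++j) {
      if (frozen[group[j]]) continue;
      const double dp = -delta * lin[j] + corr_p[j];
      const double dm = delta * lin[j] + corr_m[j];
      if (best_j < 0 || dp < best_delta_err) {
        best_j = j; best_sign = 1.0; best_delta_err = dp;
      }
      if (dm < best_delta_err) {
        best_j = j; best_sign = -1.0; best_delta_err = dm;
      }
    }
    if (best_j < 0 || best_delta_err >= 0.0) break; // no improving step

    const double d = best_sign * delta;
    const double dval = l1_delta(r_va, Z_va.col(best_j), d);
    if (dval > 0.0) {
      // revert (nothing applied yet) and freeze the offending predictor
      frozen[group[best_j]] = true;
      freeze_step[group[best_j]] = step;
      ++n_frozen;
      continue;
    }
    coef[best_j] += d;
    r_tr -= d * Z_tr.col(best_j);
    r_va -= d * Z_va.col(best_j);
    train_err += best_delta_err;
    val_err += dval;
    train_trace.push_back(train_err);
  }

  return List::create(
    _["coef"] = NumericVector(coef.begin(), coef.end()),
    _["n_steps"] = step,
    _["freeze_step"] = freeze_step,
    _["train_trace"] = NumericVector(train_trace.begin(), train_trace.end()),
    _["train_err"] = train_err,
    _["val_err"] = val_err);
}

// Max cluster-mass statistic per permutation.
//
// tmat: permutations x channels matrix of t values. thr: cluster-forming
// threshold (> 0). adj: adjacency as a list of 1-based integer neighbor
// vectors. two_sided: also cluster t < -thr and take the max of |mass|.
//
// [[Rcpp::export]]
NumericVector max_cluster_mass_cpp(const NumericMatrix& tmat, double thr,
                                   const List& adj, bool two_sided) {
  const int P = tmat.nrow(), C = tmat.ncol();
  std::vector<std::vector<int>> nb(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector v = adj[c];
    for (int i = 0; i < v.size(); ++i) nb[c].push_back(v[i] - 1);
  }
  NumericVector out(P);
  std::vector<int> stack;
  std::vector<bool> seen(C);
  for (int p = 0; p < P; ++p) {
    double best = 0.0;
    for (int sign = 0; sign < (two_sided ? 2 : 1); ++sign) {
      std::fill(seen.begin(), seen.end(), false);
      for (int c0 = 0; c0 < C; ++c0) {
        double t0 = sign ? -tmat(p, c0) : tmat(p, c0);
        if (seen[c0] || t0 < thr) continue;
        double mass = 0.0;
        stack.clear(); stack.push_back(c0); seen[c0] = true;
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          mass += sign ? -tmat(p, c) : tmat(p, c);
          for (int k : nb[c]) {
            double tk = sign ? -tmat(p, k) : tmat(p, k);
            if (!seen[k] && tk >= thr) { seen[k] = true; stack.push_back(k); }
          }
        }
        if (mass > best) best = mass;
      }
    }
    out[p] = best;
  }
  return out;
}
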