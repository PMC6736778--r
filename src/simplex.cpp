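// Dense two-phase primal simplex used as the LP backend for flux balance
// analysis.  Problems are small (tens to a few hundred variables) and are
// solved to a fixed deterministic vertex: entering variable = most negative
// reduced cost with smallest-index tie-break, switching to Bland's rule when
// an iteration budget is exceeded so cycling cannot occur.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double EPS_FEAS = 1e-9;   // feasibility / pivot tolerance
static const double EPS_OPT = 1e-7;    // reduced-cost optimality tolerance

// Solve: min c'x  s.t.  A x (dir) b,  x >= 0
//   dir[i]: -1 => <=, 0 => ==, +1 => >=
// Returns list(status, x, objective).  status: 0 optimal, 1 infeasible,
// 2 unbounded (entering_index names the unbounded column, 1-based).
// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix A, NumericVector b, NumericVector c,
                  IntegerVector dir, int max_iter = 100000) {
  const int m = A.nrow();
  const int n = A.ncol();

  // Normalise rows so that b >= 0.
  std::vector<std::vector<double>> Aw(m, std::vector<double>(n));
  std::vector<double> bw(m);
  std::vector<int> dw(m);
  for (int i = 0; i < m; ++i) {
    double s = (b[i] < 0.0) ? -1.0 : 1.0;
    bw[i] = s * b[i];
    dw[i] = (s < 0.0) ? -dir[i] : dir[i];
    for (int j = 0; j < n; ++j) Aw[i][j] = s * A(i, j);
  }

  // Column layout: [structural | slack/surplus | artificial]
  int n_slack = 0, n_art = 0;
  for (int i = 0; i < m; ++i) {
    if (dw[i] != 0) ++n_slack;
    if (dw[i] != -1) ++n_art;  // >= and == rows need an artificial
  }
  const int ncol = n + n_slack + n_art;

  // Tableau: m rows x (ncol + 1), last column = rhs.
  std::vector<std::vector<double>> T(m, std::vector<double>(ncol + 1, 0.0));
  std::vector<int> basis(m, -1);
  std::vector<bool> is_art(ncol, false);

  int js = n, ja = n + n_slack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = Aw[i][j];
    T[i][ncol] = bw[i];
    if (dw[i] == -1) {            // <= : slack, basic
      T[i][js] = 1.0;
      basis[i] = js++;
    } else if (dw[i] == 1) {      // >= : surplus + artificial
      T[i][js] = -1.0;
      ++js;
      T[i][ja] = 1.0;
      is_art[ja] = true;
      basis[i] = ja++;
    } else {                      // == : artificial
      T[i][ja] = 1.0;
      is_art[ja] = true;
      basis[i] = ja++;
    }
  }

  // Reduced-cost row z and objective value held separately.
  std::vector<double> z(ncol, 0.0);
  double zval = 0.0;

  std::vector<bool> banned(ncol, false);  // artificials banned in phase 2

  auto pivot = [&](int pr, int pc) {
    double piv = T[pr][pc];
    for (int j = 0; j <= ncol; ++j) T[pr][j] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == pr) continue;
      double f = T[i][pc];
      if (f != 0.0) {
        for (int j = 0; j <= ncol; ++j) T[i][j] -= f * T[pr][j];
        T[i][pc] = 0.0;
      }
    }
    double f = z[pc];
    if (f != 0.0) {
      for (int j = 0; j < ncol; ++j) z[j] -= f * T[pr][j];
      zval -= f * T[pr][ncol];
      z[pc] = 0.0;
    }
    basis[pr] = pc;
  };

  int iter = 0;
  int unbounded_col = -1;

  // run one simplex phase on the current z row; returns 0 ok, 2 unbounded
  auto run = [&]() -> int {
    const int bland_after = 50 * (m + ncol);
    while (true) {
      if (++iter > max_iter) stop("simplex iteration limit exceeded");
      bool bland = iter > bland_after;
      int pc = -1;
      double best = -EPS_OPT;
      for (int j = 0; j < ncol; ++j) {
        if (banned[j]) continue;
        double rc = z[j];
        if (bland) {
          if (rc < -EPS_OPT) { pc = j; break; }
        } else if (rc < best) {
          best = rc;
          pc = j;
        }
      }
      if (pc < 0) return 0;  // optimal for this phase
      // ratio test, smallest ratio; ties -> smallest basis index (Bland-safe)
      int pr = -1;
      double best_ratio = std::numeric_limits<double>::infinity();
      for (int i = 0; i < m; ++i) {
        double a = T[i][pc];
        if (a > EPS_FEAS) {
          double ratio = T[i][ncol] / a;
          if (ratio < best_ratio - EPS_FEAS ||
              (ratio < best_ratio + EPS_FEAS && pr >= 0 &&
               basis[i] < basis[pr])) {
            best_ratio = ratio;
            pr = i;
          }
        }
      }
      if (pr < 0) {
        unbounded_col = pc;
        return 2;
      }
      pivot(pr, pc);
    }
  };

  // ---- Phase 1: minimise the sum of artificials
  if (n_art > 0) {
    for (int j = 0; j < ncol; ++j) z[j] = is_art[j] ? 1.0 : 0.0;
    zval = 0.0;
    for (int i = 0; i < m; ++i) {
      if (is_art[basis[i]]) {  // price out basic artificials
        for (int j = 0; j < ncol; ++j) z[j] -= T[i][j];
        zval -= T[i][ncol];
      }
    }
    int st = run();
    if (st == 2) stop("internal error: phase-1 objective unbounded");
    if (-zval > 1e-7) {  // residual infeasibility (zval accumulates -obj)
      return List::create(_["status"] = 1, _["x"] = NumericVector(n),
                          _["objective"] = NA_REAL,
                          _["entering_index"] = NA_INTEGER);
    }
    // Drive remaining artificials out of the basis where possible.
    for (int i = 0; i < m; ++i) {
      if (!is_art[basis[i]]) continue;
      int pc = -1;
      for (int j = 0; j < n + n_slack; ++j) {
        if (std::fabs(T[i][j]) > 1e-7) { pc = j; break; }
      }
      if (pc >= 0) pivot(i, pc);
      // else: redundant row; artificial stays basic at value ~0
    }
    for (int j = 0; j < ncol; ++j) banned[j] = is_art[j];
  }

  // ---- Phase 2: minimise c'x
  for (int j = 0; j < ncol; ++j) z[j] = (j < n) ? c[j] : 0.0;
  zval = 0.0;
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    double cb = (bj < n) ? c[bj] : 0.0;
    if (cb != 0.0) {
      for (int j = 0; j < ncol; ++j) z[j] -= cb * T[i][j];
      zval -= cb * T[i][ncol];
      z[bj] = 0.0;
    }
  }
  int st = run();
  if (st == 2) {
    return List::create(_["status"] = 2, _["x"] = NumericVector(n),
                        _["objective"] = NA_REAL,
                        _["entering_index"] = unbounded_col + 1);
  }

  NumericVector x(n);
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n) x[basis[i]] = T[i][ncol];
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj,
                      _["entering_index"] = NA_INTEGER);
}
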