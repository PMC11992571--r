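#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Dense two-phase primal simplex for bounded variables:
//   maximize c'x  subject to  A x = b,  l <= x <= u  (finite l, u).
// Phase 1 introduces one artificial per row; Bland's rule engages after a
// run of degenerate pivots to guarantee termination on the highly
// degenerate LPs that stoichiometric models produce.

namespace {

const double kInf = std::numeric_limits<double>::infinity();

struct LpResult {
  int status;                 // 0 optimal, 1 infeasible, 2 iteration limit
  double obj;
  std::vector<double> x;
};

class BoundedSimplex {
public:
  BoundedSimplex(const std::vector<double>& A, int m, int n,
                 const std::vector<double>& b,
                 const std::vector<double>& l,
                 const std::vector<double>& u)
      : m_(m), n_(n), N_(n + m), A_(A), b_(b), l_(l), u_(u) {
    l_.resize(N_, 0.0);
    u_.resize(N_, kInf);   // artificial bounds set during phase 1
    feas_tol_ = 1e-9;
    piv_tol_ = 1e-10;
    dj_tol_ = 1e-9;
  }

  // Column j of the full (structural + artificial) matrix, entry i.
  double aij(int i, int j) const {
    if (j < n_) return A_[static_cast<size_t>(j) * m_ + i];
    return (j - n_ == i) ? art_sign_[i] : 0.0;
  }

  LpResult solve(const std::vector<double>& c) {
    // ---- phase 1: start from all structural vars at a finite bound ----
    x_.assign(N_, 0.0);
    vstat_.assign(N_, 0);         // 0 at lower, 1 at upper, 2 basic
    for (int j = 0; j < n_; ++j) {
      if (std::isfinite(l_[j])) { x_[j] = l_[j]; vstat_[j] = 0; }
      else { x_[j] = u_[j]; vstat_[j] = 1; }
    }
    std::vector<double> resid(b_);
    for (int j = 0; j < n_; ++j) {
      if (x_[j] != 0.0)
        for (int i = 0; i < m_; ++i) resid[i] -= A_[static_cast<size_t>(j) * m_ + i] * x_[j];
    }
    art_sign_.assign(m_, 1.0);
    basis_.resize(m_);
    Binv_.assign(static_cast<size_t>(m_) * m_, 0.0);
    for (int i = 0; i < m_; ++i) {
      art_sign_[i] = (resid[i] < 0.0) ? -1.0 : 1.0;
      int aj = n_ + i;
      basis_[i] = aj;
      vstat_[aj] = 2;
      x_[aj] = std::fabs(resid[i]);
      l_[aj] = 0.0;
      u_[aj] = kInf;
      Binv_[static_cast<size_t>(i) * m_ + i] = art_sign_[i]; // B = diag(sign), Binv likewise
    }

    std::vector<double> c1(N_, 0.0);
    for (int i = 0; i < m_; ++i) c1[n_ + i] = -1.0;
    int st = iterate(c1);
    if (st == 2) return {2, 0.0, {}};
    double infeas = 0.0;
    for (int i = 0; i < m_; ++i) infeas += x_[n_ + i];
    double scale = 1.0;
    for (int i = 0; i < m_; ++i) scale = std::max(scale, std::fabs(b_[i]));
    if (infeas > 1e-7 * scale) return {1, 0.0, {}};

    // Freeze artificials at zero for phase 2.
    for (int i = 0; i < m_; ++i) { l_[n_ + i] = 0.0; u_[n_ + i] = 0.0; }
    drive_out_artificials();

    // ---- phase 2 ----
    std::vector<double> c2(N_, 0.0);
    for (int j = 0; j < n_; ++j) c2[j] = c[j];
    st = iterate(c2);
    if (st == 2) return {2, 0.0, {}};

    double obj = 0.0;
    std::vector<double> xs(n_);
    for (int j = 0; j < n_; ++j) {
      double v = x_[j];
      if (std::isfinite(l_[j]) && v < l_[j]) v = l_[j];
      if (std::isfinite(u_[j]) && v > u_[j]) v = u_[j];
      xs[j] = v;
      obj += c[j] * v;
    }
    return {0, obj, xs};
  }

private:
  int m_, n_, N_;
  std::vector<double> A_, b_, l_, u_;
  std::vector<double> x_, Binv_, art_sign_;
  std::vector<int> basis_, vstat_;
  double feas_tol_, piv_tol_, dj_tol_;

  // w = Binv * A_j
  void ftran(int j, std::vector<double>& w) const {
    w.assign(m_, 0.0);
    if (j >= n_) {
      int r = j - n_;
      for (int i = 0; i < m_; ++i) w[i] = Binv_[static_cast<size_t>(i) * m_ + r] * art_sign_[r];
      return;
    }
    const double* col = &A_[static_cast<size_t>(j) * m_];
    for (int k = 0; k < m_; ++k) {
      double a = col[k];
      if (a == 0.0) continue;
      for (int i = 0; i < m_; ++i) w[i] += Binv_[static_cast<size_t>(i) * m_ + k] * a;
    }
  }

  void pivot_update(int r, const std::vector<double>& w) {
    double wr = w[r];
    double* rowr = &Binv_[static_cast<size_t>(r) * m_];
    for (int k = 0; k < m_; ++k) rowr[k] /= wr;
    for (int i = 0; i < m_; ++i) {
      if (i == r) continue;
      double wi = w[i];
      if (wi == 0.0) continue;
      double* rowi = &Binv_[static_cast<size_t>(i) * m_];
      for (int k = 0; k < m_; ++k) rowi[k] -= wi * rowr[k];
    }
  }

  void drive_out_artificials() {
    std::vector<double> w(m_);
    for (int i = 0; i < m_; ++i) {
      if (basis_[i] < n_) continue;
      // try to replace the basic artificial with a structural column
      int enter = -1;
      for (int j = 0; j < n_; ++j) {
        if (vstat_[j] == 2) continue;
        ftran(j, w);
        if (std::fabs(w[i]) > 1e-7) { enter = j; break; }
      }
      if (enter < 0) continue;   // redundant row; artificial stays pinned at 0
      ftran(enter, w);
      int leave = basis_[i];
      vstat_[leave] = 0;
      x_[leave] = 0.0;
      basis_[i] = enter;
      vstat_[enter] = 2;
      pivot_update(i, w);
      recompute_basics();
    }
  }

  void recompute_basics() {
    std::vector<double> r(b_);
    for (int j = 0; j < N_; ++j) {
      if (vstat_[j] == 2 || x_[j] == 0.0) continue;
      for (int i = 0; i < m_; ++i) r[i] -= aij(i, j) * x_[j];
    }
    for (int i = 0; i < m_; ++i) {
      double xb = 0.0;
      for (int k = 0; k < m_; ++k) xb += Binv_[static_cast<size_t>(i) * m_ + k] * r[k];
      x_[basis_[i]] = xb;
    }
  }

  int iterate(const std::vector<double>& c) {
    std::vector<double> y(m_), w(m_);
    bool bland = false;
    int stall = 0;
    long max_iter = 20000L + 50L * static_cast<long>(N_);
    for (long it = 0; it < max_iter; ++it) {
      // y' = c_B' Binv
      std::fill(y.begin(), y.end(), 0.0);
      for (int i = 0; i < m_; ++i) {
        double cb = c[basis_[i]];
        if (cb == 0.0) continue;
        const double* rowi = &Binv_[static_cast<size_t>(i) * m_];
        for (int k = 0; k < m_; ++k) y[k] += cb * rowi[k];
      }
      // pricing
      int enter = -1;
      double best = dj_tol_;
      for (int j = 0; j < N_; ++j) {
        if (vstat_[j] == 2) continue;
        if (l_[j] == u_[j]) continue;             // fixed
        double dj = c[j];
        if (j < n_) {
          const double* col = &A_[static_cast<size_t>(j) * m_];
          for (int i = 0; i < m_; ++i) dj -= y[i] * col[i];
        } else {
          dj -= y[j - n_] * art_sign_[j - n_];
        }
        double gain = (vstat_[j] == 0) ? dj : -dj;  // improvement rate
        if (gain > (bland ? dj_tol_ : best)) {
          enter = j;
          best = gain;
          if (bland) break;
        }
      }
      if (enter < 0) return 0;   // optimal

      ftran(enter, w);
      double sigma = (vstat_[enter] == 0) ? 1.0 : -1.0;
      double t_max = u_[enter] - l_[enter];   // may be Inf
      int leave_row = -1;
      int leave_col = -1;
      for (int i = 0; i < m_; ++i) {
        double delta = -sigma * w[i];         // d x_B[i] / dt
        int bj = basis_[i];
        double ti = kInf;
        if (delta < -piv_tol_) {
          if (std::isfinite(l_[bj])) ti = (x_[bj] - l_[bj]) / (-delta);
        } else if (delta > piv_tol_) {
          if (std::isfinite(u_[bj])) ti = (u_[bj] - x_[bj]) / delta;
        }
        if (ti < 0) ti = 0;
        if (ti < t_max - 1e-12) {
          t_max = ti; leave_row = i; leave_col = bj;
        } else if (leave_row >= 0 && ti <= t_max + 1e-12 && bland && bj < leave_col) {
          leave_row = i; leave_col = bj;   // Bland tie-break on smallest column index
        }
      }
      if (!std::isfinite(t_max)) return 0;    // unbounded direction cannot occur with finite structural bounds; treat as optimal ray cap
      if (t_max < 0) t_max = 0;

      // track degeneracy
      if (t_max < 1e-11) { if (++stall > 100) bland = true; }
      else { stall = 0; bland = false; }

      // apply step
      x_[enter] += sigma * t_max;
      if (t_max > 0) {
        for (int i = 0; i < m_; ++i) x_[basis_[i]] -= sigma * t_max * w[i];
      }
      if (leave_row < 0) {
        // bound flip
        vstat_[enter] = (vstat_[enter] == 0) ? 1 : 0;
        continue;
      }
      int out = basis_[leave_row];
      double delta_out = -sigma * w[leave_row];
      vstat_[out] = (delta_out < 0) ? 0 : 1;        // hit lower : hit upper
      x_[out] = (vstat_[out] == 0) ? l_[out] : u_[out];
      basis_[leave_row] = enter;
      vstat_[enter] = 2;
      pivot_update(leave_row, w);
      if ((it + 1) % 512 == 0) recompute_basics();
    }
    return 2;
  }
};

LpResult lp_max(const std::vector<double>& A, int m, int n,
                const std::vector<double>& b,
                const std::vector<double>& l,
                const std::vector<double>& u,
                const std::vector<double>& c) {
  BoundedSimplex sx(A, m, n, b, l, u);
  return sx.solve(c);
}

} // namespace

// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(Rcpp::NumericMatrix A, Rcpp::NumericVector b,
                        Rcpp::NumericVector lb, Rcpp::NumericVector ub,
                        Rcpp::NumericVector obj, bool maximize) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> Av(A.begin(), A.end());
  std::vector<double> bv(b.begin(), b.end());
  std::vector<double> lv(lb.begin(), lb.end());
  std::vector<double> uv(ub.begin(), ub.end());
  std::vector<double> cv(obj.begin(), obj.end());
  if (!maximize) for (auto& v : cv) v = -v;
  LpResult r = lp_max(Av, m, n, bv, lv, uv, cv);
  double o = maximize ? r.obj : -r.obj;
  Rcpp::NumericVector x(n);
  if (r.status == 0) for (int j = 0; j < n; ++j) x[j] = r.x[j];
  return Rcpp::List::create(Rcpp::Named("status") = r.status,
                            Rcpp::Named("objective") = (r.status == 0 ? o : NA_REAL),
                            Rcpp::Named("x") = x);
}

// Flux variability: min and max of each requested column subject to the
// same constraint system. cols is 1-based. Returns an (length(cols) x 2)
// matrix [min, max]; status 0 if feasible, 1 if the system is infeasible.
// [[Rcpp::export(name = ".fva_cpp")]]
Rcpp::List fva_cpp(Rcpp::NumericMatrix A, Rcpp::NumericVector b,
                   Rcpp::NumericVector lb, Rcpp::NumericVector ub,
                   Rcpp::IntegerVector cols) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> Av(A.begin(), A.end());
  std::vector<double> bv(b.begin(), b.end());
  std::vector<double> lv(lb.begin(), lb.end());
  std::vector<double> uv(ub.begin(), ub.end());
  std::vector<double> c0(n, 0.0);

  LpResult feas = lp_max(Av, m, n, bv, lv, uv, c0);
  if (feas.status != 0) {
    return Rcpp::List::create(Rcpp::Named("status") = feas.status,
                              Rcpp::Named("range") = R_NilValue);
  }
  int k = cols.size();
  Rcpp::NumericMatrix range(k, 2);
  std::vector<double> c(n, 0.0);
  for (int q = 0; q < k; ++q) {
    int j = cols[q] - 1;
    c[j] = -1.0;  // minimize
    LpResult lo = lp_max(Av, m, n, bv, lv, uv, c);
    c[j] = 1.0;   // maximize
    LpResult hi = lp_max(Av, m, n, bv, lv, uv, c);
    c[j] = 0.0;
    range(q, 0) = (lo.status == 0) ? -lo.obj : NA_REAL;
    range(q, 1) = (hi.status == 0) ? hi.obj : NA_REAL;
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("range") = range);
}
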