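#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Log-domain Sinkhorn solver for discrete entropic-regularized optimal
// transport. Works at very small regularization (slide-scale reg around 1e-3
// of typical spot distances) where the naive kernel exp(-C/reg) underflows.
// Epsilon scaling anneals the temperature from max(C)/2 down to the target
// reg, warm-starting the dual potentials at each stage. All quantities are
// kept in eps-scaled form (potential/eps, cost/eps) so the inner loops are
// subtraction + exp only; the matrix is stored twice (column-major both
// ways) so each update walks contiguous memory.

namespace {

struct ScaledProblem {
  int m, n;
  std::vector<double> Ct;   // Ct[j*m + i] = C(i,j)/eps   (for g update, walks i)
  std::vector<double> Cr;   // Cr[i*n + j] = C(i,j)/eps   (for f update, walks j)
  std::vector<double> loga, logb;
};

// log sum_j exp(g[j] - Cr[i*n + j] + logb[j])
inline double lse_over_cols(const ScaledProblem &P, const std::vector<double> &g,
                            int i, std::vector<double> &buf) {
  const double *crow = &P.Cr[(size_t)i * P.n];
  double mx = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < P.n; ++j) {
    double v = g[j] - crow[j] + P.logb[j];
    buf[j] = v;
    if (v > mx) mx = v;
  }
  double s = 0.0;
  for (int j = 0; j < P.n; ++j) s += std::exp(buf[j] - mx);
  return mx + std::log(s);
}

// log sum_i exp(f[i] - Ct[j*m + i] + loga[i])
inline double lse_over_rows(const ScaledProblem &P, const std::vector<double> &f,
                            int j, std::vector<double> &buf) {
  const double *ccol = &P.Ct[(size_t)j * P.m];
  double mx = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < P.m; ++i) {
    double v = f[i] - ccol[i] + P.loga[i];
    buf[i] = v;
    if (v > mx) mx = v;
  }
  double s = 0.0;
  for (int i = 0; i < P.m; ++i) s += std::exp(buf[i] - mx);
  return mx + std::log(s);
}

// core solve on a raw column-major cost matrix
List solve_sinkhorn(const double *C, int m, int n, const double *a,
                    const double *b, double reg, int max_iter, double tol,
                    int scaling_steps) {
  if (reg <= 0) stop("reg must be positive");
  if (m == 1 && n == 1)
    return List::create(_["cost"] = C[0], _["iterations"] = 0,
                        _["converged"] = true);
  double cmax = 0.0;
  for (size_t k = 0; k < (size_t)m * n; ++k)
    if (C[k] > cmax) cmax = C[k];
  if (cmax == 0.0)
    return List::create(_["cost"] = 0.0, _["iterations"] = 0,
                        _["converged"] = true);

  ScaledProblem P;
  P.m = m;
  P.n = n;
  P.Ct.resize((size_t)m * n);
  P.Cr.resize((size_t)m * n);
  P.loga.resize(m);
  P.logb.resize(n);
  for (int i = 0; i < m; ++i) P.loga[i] = std::log(a[i]);
  for (int j = 0; j < n; ++j) P.logb[j] = std::log(b[j]);

  // scaled potentials f/eps, g/eps; rescaled between annealing stages
  std::vector<double> f(m, 0.0), g(n, 0.0), bufm(m), bufn(n);
  double eps0 = std::max(cmax / 2.0, reg);
  int nsteps = (eps0 > reg) ? scaling_steps : 1;
  int total_it = 0;
  bool converged = false;
  double eps_prev = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    double eps = (nsteps == 1)
                     ? reg
                     : eps0 * std::pow(reg / eps0, (double)s / (nsteps - 1));
    for (size_t k = 0; k < (size_t)m * n; ++k) {
      P.Ct[k] = C[k] / eps;
    }
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j)
        P.Cr[(size_t)i * n + j] = P.Ct[(size_t)j * m + i];
    if (s > 0) {
      // carry potentials (in unscaled units) to the new temperature
      double ratio = eps_prev / eps;
      for (int i = 0; i < m; ++i) f[i] *= ratio;
      for (int j = 0; j < n; ++j) g[j] *= ratio;
    }
    eps_prev = eps;
    int iters = (s == nsteps - 1) ? max_iter : 10;
    // stop when the sup-norm change of the scaled potential implies a
    // relative marginal violation below tol
    for (int it = 0; it < iters; ++it) {
      double df = 0.0;
      for (int i = 0; i < m; ++i) {
        double fn = -lse_over_cols(P, g, i, bufn);
        double d = std::fabs(fn - f[i]);
        if (d > df) df = d;
        f[i] = fn;
      }
      for (int j = 0; j < n; ++j) g[j] = -lse_over_rows(P, f, j, bufm);
      ++total_it;
      if (s == nsteps - 1 && df < tol) {
        converged = true;
        break;
      }
    }
  }

  // transport cost <P, C>, log P_ij = f_i + g_j - C_ij/eps + log a_i b_j
  double cost = 0.0;
  for (int j = 0; j < n; ++j) {
    const double *ccol = &P.Ct[(size_t)j * m];
    for (int i = 0; i < m; ++i) {
      double lp = f[i] + g[j] - ccol[i] + P.loga[i] + P.logb[j];
      if (lp > -745.0) cost += std::exp(lp) * C[(size_t)j * m + i];
    }
  }
  return List::create(_["cost"] = cost, _["iterations"] = total_it,
                      _["converged"] = converged);
}

} // namespace

// [[Rcpp::export(name = ".sinkhorn_cost_cpp")]]
List sinkhorn_cost_cpp(NumericVector a, NumericVector b, NumericMatrix C,
                       double reg, int max_iter = 300, double tol = 1e-4,
                       int scaling_steps = 30) {
  if (C.nrow() != a.size() || C.ncol() != b.size())
    stop("cost matrix dimensions do not match the marginals");
  return solve_sinkhorn(C.begin(), a.size(), b.size(), a.begin(), b.begin(),
                        reg, max_iter, tol, scaling_steps);
}

// Euclidean cost matrix between two weighted point sets, then symmetrized
// Sinkhorn distance (mean of both transport directions). Keeping the whole
// evaluation in C++ makes the permutation-null loop cheap.
// [[Rcpp::export(name = ".wasserstein_points_cpp")]]
double wasserstein_points_cpp(NumericVector ax, NumericVector ay,
                              NumericVector aw, NumericVector bx,
                              NumericVector by, NumericVector bw, double reg,
                              int max_iter = 150, double tol = 1e-4) {
  int m = ax.size(), n = bx.size();
  std::vector<double> C((size_t)m * n), Ctr((size_t)m * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d = std::sqrt(dx * dx + dy * dy);
      C[(size_t)j * m + i] = d;
      Ctr[(size_t)i * n + j] = d;
    }
  List r1 = solve_sinkhorn(C.data(), m, n, aw.begin(), bw.begin(), reg,
                           max_iter, tol, 30);
  List r2 = solve_sinkhorn(Ctr.data(), n, m, bw.begin(), aw.begin(), reg,
                           max_iter, tol, 30);
  return (as<double>(r1["cost"]) + as<double>(r2["cost"])) / 2.0;
}
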