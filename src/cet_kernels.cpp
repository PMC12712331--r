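// Core numerical kernels: tridiagonal theta-scheme marchers for the
// drift-diffusion operators in log-tempo, a Strang-split solver for the
// nonlinear generating-function equation, and the Monte Carlo clade
// simulator. Everything here is single-threaded and uses R's RNG so that
// set.seed() controls all randomness.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Precomputed Thomas (tridiagonal LU) factorisation of (I - c*L) where L is
// given by its three diagonals. sub[0] and sup[n-1] are ignored.
struct TriFactor {
  arma::vec w;     // elimination multipliers
  arma::vec diag;  // pivots
  arma::vec sup;   // superdiagonal of the factored matrix
};

TriFactor tri_factor(const arma::vec& sub, const arma::vec& dia,
                     const arma::vec& sup, double c) {
  const arma::uword n = dia.n_elem;
  TriFactor f;
  f.w.set_size(n);
  f.diag.set_size(n);
  f.sup.set_size(n);
  for (arma::uword i = 0; i < n; ++i) {
    f.sup(i) = -c * sup(i);
    f.diag(i) = 1.0 - c * dia(i);
    f.w(i) = 0.0;
  }
  for (arma::uword i = 1; i < n; ++i) {
    double a = -c * sub(i);
    double w = a / f.diag(i - 1);
    f.w(i) = w;
    f.diag(i) -= w * f.sup(i - 1);
  }
  return f;
}

template <typename VecT>
void tri_solve_inplace(const TriFactor& f, VecT& d) {
  const arma::uword n = f.diag.n_elem;
  for (arma::uword i = 1; i < n; ++i) d(i) -= f.w(i) * d(i - 1);
  d(n - 1) /= f.diag(n - 1);
  for (arma::uword i = n - 1; i-- > 0;)
    d(i) = (d(i) - f.sup(i) * d(i + 1)) / f.diag(i);
}

// y = (I + c*L) x for tridiagonal L.
template <typename MatT>
void tri_apply(const arma::vec& sub, const arma::vec& dia,
               const arma::vec& sup, double c, const MatT& x, MatT& y) {
  const arma::uword n = dia.n_elem;
  const arma::uword k = x.n_cols;
  for (arma::uword j = 0; j < k; ++j) {
    y(0, j) = x(0, j) + c * (dia(0) * x(0, j) + sup(0) * x(1, j));
    for (arma::uword i = 1; i + 1 < n; ++i) {
      y(i, j) = x(i, j) + c * (sub(i) * x(i - 1, j) + dia(i) * x(i, j) +
                               sup(i) * x(i + 1, j));
    }
    y(n - 1, j) = x(n - 1, j) +
      c * (sub(n - 1) * x(n - 2, j) + dia(n - 1) * x(n - 1, j));
  }
}

}  // namespace

// Theta-scheme march of d(field)/dt = L field for a real tridiagonal L
// (already including any exp(x) scaling and diagonal reaction terms).
// Optionally the first `n_implicit` steps use backward Euler (useful to damp
// point-mass initial data), optionally each column is renormalised to unit
// L1 mass (times dx) after every step, and, when `stop_tol > 0` and
// renormalisation is on, the march stops early once the per-myr L1 change of
// the normalised field drops below `stop_tol`.
// [[Rcpp::export]]
List cpp_march_tridiag(const arma::mat& field0, const arma::vec& sub,
                       const arma::vec& dia, const arma::vec& sup, double dt,
                       int n_steps, double theta, int n_implicit,
                       bool renorm, double dx, double stop_tol) {
  arma::mat f = field0;
  arma::mat rhs(f.n_rows, f.n_cols);
  TriFactor fac_theta = tri_factor(sub, dia, sup, theta * dt);
  TriFactor fac_impl = tri_factor(sub, dia, sup, dt);
  arma::mat prev;
  int steps_done = 0;
  double resid = NA_REAL;
  for (int step = 0; step < n_steps; ++step) {
    bool implicit = step < n_implicit;
    if (renorm && stop_tol > 0) prev = f;
    if (implicit) {
      rhs = f;
      for (arma::uword j = 0; j < f.n_cols; ++j) {
        arma::vec col = rhs.col(j);
        tri_solve_inplace(fac_impl, col);
        f.col(j) = col;
      }
    } else {
      tri_apply(sub, dia, sup, (1.0 - theta) * dt, f, rhs);
      for (arma::uword j = 0; j < f.n_cols; ++j) {
        arma::vec col = rhs.col(j);
        tri_solve_inplace(fac_theta, col);
        f.col(j) = col;
      }
    }
    if (renorm) {
      for (arma::uword j = 0; j < f.n_cols; ++j) {
        double m = arma::accu(f.col(j)) * dx;
        if (m <= 0 || !std::isfinite(m))
          stop("field mass became non-positive or non-finite at step %d", step + 1);
        f.col(j) /= m;
      }
      if (stop_tol > 0) {
        resid = arma::accu(arma::abs(f - prev)) * dx / dt;
        steps_done = step + 1;
        if (resid < stop_tol) break;
      }
    }
    steps_done = step + 1;
    if (!f.is_finite())
      stop("non-finite field values at step %d (t = %g)", step + 1,
           dt * (step + 1));
  }
  return List::create(_["field"] = f, _["steps"] = steps_done,
                      _["residual"] = resid);
}

namespace {

// Exact flow of dG/ds = (lambda*G - mu)(G - 1) for duration tau, i.e. the
// generating-function composition of a constant-rate birth-death process.
// Maps the closed unit disk into itself, so it is unconditionally stable.
// `E` carries the precomputed exponential factor: exp(-|r| tau) for
// non-critical rates, lambda * tau for the critical case.
inline std::complex<double> bd_flow_pre(std::complex<double> g, double lambda,
                                        double mu, double r, double E) {
  if (r == 0.0) {
    std::complex<double> one_m = 1.0 - g;
    return 1.0 - one_m / (1.0 + E * one_m);
  }
  if (r > 0.0) {
    std::complex<double> num = mu * (1.0 - g) - (mu - lambda * g) * E;
    std::complex<double> den = lambda * (1.0 - g) - (mu - lambda * g) * E;
    return num / den;
  }
  std::complex<double> num = mu * (1.0 - g) * E - (mu - lambda * g);
  std::complex<double> den = lambda * (1.0 - g) * E - (mu - lambda * g);
  return num / den;
}

}  // namespace

// Strang-split solver for the generating-function equation
//   dG/dt = exp(x) * ( (lambda G - mu)(G - 1) ) + exp(x) * D G,
// where D is the tridiagonal drift-diffusion operator (sub/dia/sup, without
// the exp(x) factor). Initial condition G(0, z) = z for every grid point.
// Each step applies the exact reaction flow for dt/2, a theta-scheme step of
// the linear part, and the reaction flow for dt/2 again. Returns the full
// grid-by-z complex field at t = n_steps * dt.
// [[Rcpp::export]]
arma::cx_mat cpp_solve_gf(const arma::cx_rowvec& z, const arma::vec& sub,
                          const arma::vec& dia, const arma::vec& sup,
                          const arma::vec& ex, double lambda, double mu,
                          double dt, int n_steps, double theta,
                          int check_every) {
  const arma::uword n = ex.n_elem;
  const arma::uword k = z.n_elem;
  // Full linear operator: rows of D scaled by exp(x).
  arma::vec lsub = sub % ex, ldia = dia % ex, lsup = sup % ex;
  TriFactor fac = tri_factor(lsub, ldia, lsup, theta * dt);
  arma::cx_mat G(n, k);
  for (arma::uword j = 0; j < k; ++j) G.col(j).fill(z(j));
  arma::cx_mat rhs(n, k);
  const double r = lambda - mu;
  // precomputed reaction factor per grid row for a half step
  arma::vec Efac(n);
  for (arma::uword i = 0; i < n; ++i) {
    double tau = 0.5 * dt * ex(i);
    Efac(i) = (r == 0.0) ? lambda * tau : std::exp(-std::fabs(r) * tau);
  }
  bool linear_on = arma::any(arma::abs(dia) > 0);
  auto react_half = [&]() {
    for (arma::uword j = 0; j < k; ++j) {
      std::complex<double>* col = G.colptr(j);
      for (arma::uword i = 0; i < n; ++i)
        col[i] = bd_flow_pre(col[i], lambda, mu, r, Efac(i));
    }
  };
  for (int step = 0; step < n_steps; ++step) {
    react_half();
    if (linear_on) {
      tri_apply(lsub, ldia, lsup, (1.0 - theta) * dt, G, rhs);
      for (arma::uword j = 0; j < k; ++j) {
        std::complex<double>* col = rhs.colptr(j);
        for (arma::uword i = 1; i < n; ++i) col[i] -= fac.w(i) * col[i - 1];
        col[n - 1] /= fac.diag(n - 1);
        for (arma::uword i = n - 1; i-- > 0;)
          col[i] = (col[i] - fac.sup(i) * col[i + 1]) / fac.diag(i);
      }
      G.swap(rhs);
    }
    react_half();
    if ((step + 1) % check_every == 0 || step + 1 == n_steps) {
      double m2 = 0.0;
      const std::complex<double>* ptr = G.memptr();
      for (arma::uword q = 0; q < G.n_elem; ++q) {
        double v = std::norm(ptr[q]);
        if (v > m2) m2 = v;
      }
      double m = std::sqrt(m2);
      if (!std::isfinite(m))
        stop("generating-function solve produced non-finite values at t = %g",
             dt * (step + 1));
      if (m > 1.0 + 1e-4)
        stop("generating-function solve left the unit disk (|G| = %g at t = %g); reduce dt",
             m, dt * (step + 1));
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Monte Carlo simulator
// ---------------------------------------------------------------------------

// Simulates one clade of the covariant-tempo birth-death process. Log-tempo
// follows dx = -theta_ou e^x x dt + sqrt(2 theta_ou s^2 e^x) dW
// (Euler-Maruyama with an adaptive step, reflected at +/- xbound), and branch
// terminations are sampled exactly in molecular time: conditional on the
// tempo path, events form a Poisson process of constant rate (lambda + mu)
// in w = integral of e^x dt, so each branch draws w* ~ Exp(lambda + mu) and
// terminates when its accumulated molecular length reaches w*. Termination
// is a speciation with probability lambda / (lambda + mu); daughters inherit
// the parental log-tempo. Processing is depth-first, so `stop_at_survivor`
// can abandon the simulation as soon as one lineage is known to reach T.
// [[Rcpp::export]]
List cpp_simulate_clade(double lambda, double mu, double theta_ou, double s,
                        double x0, double T, double dt, int cap,
                        double xbound, bool stop_at_survivor,
                        const arma::vec& snapshot_times) {
  const double rate_tot = lambda + mu;
  std::vector<int> parent;
  std::vector<double> t_birth, t_end, x_birth, x_end, w_len;
  std::vector<int> status;  // 0 extinct, 1 speciated, 2 extant, -1 pending
  std::vector<int> snap_node, snap_id;
  std::vector<double> snap_x;
  std::vector<int> stack;
  bool truncated = false, early_stop = false;

  auto new_node = [&](int par, double tb, double xb) {
    parent.push_back(par);
    t_birth.push_back(tb);
    t_end.push_back(NA_REAL);
    x_birth.push_back(xb);
    x_end.push_back(NA_REAL);
    w_len.push_back(0.0);
    status.push_back(-1);
    return static_cast<int>(parent.size()) - 1;
  };
  const int max_nodes = cap > (INT_MAX - 1) / 2 ? INT_MAX - 1 : 2 * cap + 1;

  stack.push_back(new_node(NA_INTEGER, 0.0, x0));
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    double t = t_birth[id];
    double x = x_birth[id];
    double w = 0.0;
    // first snapshot index not yet passed for this branch
    arma::uword si = 0;
    while (si < snapshot_times.n_elem && snapshot_times(si) <= t) ++si;
    double w_target = rate_tot > 0 ? R::exp_rand() / rate_tot : R_PosInf;
    int st = -1;
    while (true) {
      double ex = std::exp(x);
      double h = dt;
      if (theta_ou > 0) {
        double hmax = 0.05 / (theta_ou * ex * (s * s + std::fabs(x) + 1.0));
        if (hmax < h) h = hmax;
      }
      if (t + h >= T) h = T - t;
      double dw = ex * h;
      if (w_target <= dw) {  // event within this step at (frozen) tempo
        double delta = w_target / ex;
        while (si < snapshot_times.n_elem && snapshot_times(si) <= t + delta) {
          snap_node.push_back(id);
          snap_id.push_back(static_cast<int>(si));
          snap_x.push_back(x);
          ++si;
        }
        t += delta;
        w += w_target;
        st = (R::unif_rand() * rate_tot < lambda) ? 1 : 0;
        break;
      }
      while (si < snapshot_times.n_elem && snapshot_times(si) <= t + h) {
        snap_node.push_back(id);
        snap_id.push_back(static_cast<int>(si));
        snap_x.push_back(x);
        ++si;
      }
      w += dw;
      w_target -= dw;
      t += h;
      if (t >= T * (1.0 - 1e-15)) {
        t = T;
        st = 2;
        break;
      }
      // Euler-Maruyama tempo update, reflected at +/- xbound
      x += -theta_ou * ex * x * h +
           std::sqrt(2.0 * theta_ou * s * s * ex * h) * R::norm_rand();
      if (x > xbound) x = 2.0 * xbound - x;
      if (x < -xbound) x = -2.0 * xbound - x;
      if (x > xbound) x = xbound;
      if (x < -xbound) x = -xbound;
      if (!std::isfinite(x))
        stop("log-tempo became non-finite during simulation");
    }
    t_end[id] = t;
    x_end[id] = x;
    w_len[id] = w;
    status[id] = st;
    if (st == 1) {
      if (static_cast<int>(parent.size()) + 2 > max_nodes) {
        truncated = true;
        break;
      }
      stack.push_back(new_node(id, t, x));
      stack.push_back(new_node(id, t, x));
    }
    if (st == 2 && stop_at_survivor) {
      early_stop = true;
      break;
    }
  }

  int n_extant = 0;
  for (size_t i = 0; i < status.size(); ++i)
    if (status[i] == 2) ++n_extant;
  return List::create(
      _["parent"] = IntegerVector(parent.begin(), parent.end()),
      _["t_birth"] = NumericVector(t_birth.begin(), t_birth.end()),
      _["t_end"] = NumericVector(t_end.begin(), t_end.end()),
      _["x_birth"] = NumericVector(x_birth.begin(), x_birth.end()),
      _["x_end"] = NumericVector(x_end.begin(), x_end.end()),
      _["w"] = NumericVector(w_len.begin(), w_len.end()),
      _["status"] = IntegerVector(status.begin(), status.end()),
      _["snap_node"] = IntegerVector(snap_node.begin(), snap_node.end()),
      _["snap_id"] = IntegerVector(snap_id.begin(), snap_id.end()),
      _["snap_x"] = NumericVector(snap_x.begin(), snap_x.end()),
      _["n_extant"] = n_extant, _["truncated"] = truncated,
      _["early_stop"] = early_stop,
      _["survived"] = n_extant > 0);
}
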