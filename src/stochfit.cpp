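// Compiled kernels: exact stochastic simulation (direct method) and
// multi-start damped-Newton steady-state location with eigenvalue
// classification.  Both consume the same compact reaction-network
// representation built on the R side (integer stoichiometry + typed
// rate laws referencing species/parameter indices).
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 seeding + xoshiro256++ streams.  Member j of
// an ensemble gets an independent stream derived from (base_seed, j), so
// results do not depend on execution order.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in the open interval (0,1)
  inline double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

static inline uint64_t member_seed(uint64_t base, uint64_t j) {
  return splitmix64(base ^ splitmix64(j + 1));
}

// ---------------------------------------------------------------------------
// Network representation.  Rate-law types:
//   1 mass action:        k * prod(x[sp])                (sp may repeat)
//   2 Hill activation:    V * x^n / (K^n + x^n)          par = (V, K, n), sp = (x)
//   3 gated zeroth order: k * (1 - x[gate])              par = (k), sp = (gate)
//   4 promoter activation:
//     kon * A*B / (kaA*kaB + kaA*A + kaB*B + A*B) * (1 - x[gate])
//                                                        par = (kon, kaA, kaB),
//                                                        sp  = (A, B, gate)
// ---------------------------------------------------------------------------
struct Net {
  int nsp, nrx;
  arma::imat stoich;                      // nsp x nrx
  std::vector<int> type;
  std::vector<std::vector<int> > sp, par; // 0-based indices
};

static Net parse_net(const List& net) {
  Net N;
  IntegerMatrix S = net["stoich"];
  N.nsp = S.nrow(); N.nrx = S.ncol();
  N.stoich.set_size(N.nsp, N.nrx);
  for (int i = 0; i < N.nsp; ++i)
    for (int j = 0; j < N.nrx; ++j) N.stoich(i, j) = S(i, j);
  IntegerVector ty = net["type"];
  N.type.assign(ty.begin(), ty.end());
  List spl = net["sp"], pal = net["par"];
  for (int j = 0; j < N.nrx; ++j) {
    IntegerVector a = spl[j], b = pal[j];
    N.sp.push_back(std::vector<int>(a.begin(), a.end()));
    N.par.push_back(std::vector<int>(b.begin(), b.end()));
  }
  return N;
}

static inline double propensity_one(const Net& N, int j, const double* x,
                                    const double* p) {
  switch (N.type[j]) {
  case 1: {
    double a = p[N.par[j][0]];
    for (size_t i = 0; i < N.sp[j].size(); ++i) a *= x[N.sp[j][i]];
    return a;
  }
  case 2: {
    const double V = p[N.par[j][0]], K = p[N.par[j][1]], n = p[N.par[j][2]];
    // even extension |x|^n keeps the law defined for the transient
    // negative excursions of root finding and finite differencing and
    // makes the central-difference derivative exact at x = 0
    const double xv = std::fabs(x[N.sp[j][0]]);
    if (xv == 0.0) return 0.0;
    const double xn = std::pow(xv, n);
    return V * xn / (std::pow(K, n) + xn);
  }
  case 3:
    return p[N.par[j][0]] * (1.0 - x[N.sp[j][0]]);
  case 4: {
    const double kon = p[N.par[j][0]], kaA = p[N.par[j][1]], kaB = p[N.par[j][2]];
    const double A = x[N.sp[j][0]], B = x[N.sp[j][1]], g = x[N.sp[j][2]];
    const double den = kaA * kaB + kaA * A + kaB * B + A * B;
    if (den == 0.0) return 0.0;
    return kon * (A * B / den) * (1.0 - g);
  }
  }
  return 0.0;
}

// [[Rcpp::export(name = ".propensities_cpp")]]
NumericVector propensities_cpp(List net, NumericVector state, NumericVector params) {
  Net N = parse_net(net);
  NumericVector a(N.nrx);
  for (int j = 0; j < N.nrx; ++j)
    a[j] = propensity_one(N, j, state.begin(), params.begin());
  return a;
}

// [[Rcpp::export(name = ".ode_rhs_cpp")]]
NumericVector ode_rhs_cpp(List net, NumericVector state, NumericVector params) {
  Net N = parse_net(net);
  NumericVector d(N.nsp);
  for (int j = 0; j < N.nrx; ++j) {
    const double a = propensity_one(N, j, state.begin(), params.begin());
    for (int i = 0; i < N.nsp; ++i)
      if (N.stoich(i, j) != 0) d[i] += N.stoich(i, j) * a;
  }
  return d;
}

// ---------------------------------------------------------------------------
// Stochastic simulation: direct method.  State recorded as the value holding
// immediately before/at each requested time (piecewise-constant sampling).
// A reaction whose firing would drive any copy number negative is given zero
// propensity: the bundled rate laws are evaluated exactly as printed, and the
// x*x dimerization form is positive at x=1 even though two molecules are
// required.
// ---------------------------------------------------------------------------
// Per-simulation static structure: which species a reaction consumes
// (for the feasibility guard), which species it changes, and the
// dependency lists telling which propensities must be refreshed after a
// firing.
struct SimPlan {
  std::vector<std::vector<int> > consumed;   // species with negative change
  std::vector<std::vector<int> > changes;    // (species, delta) pairs flattened
  std::vector<std::vector<int> > depends;    // reactions to refresh after j fires
};

static SimPlan make_plan(const Net& N) {
  SimPlan P;
  P.consumed.resize(N.nrx);
  P.changes.resize(N.nrx);
  std::vector<std::vector<char> > reads(N.nrx, std::vector<char>(N.nsp, 0));
  for (int j = 0; j < N.nrx; ++j) {
    for (int i = 0; i < N.nsp; ++i) {
      if (N.stoich(i, j) < 0) { P.consumed[j].push_back(i); reads[j][i] = 1; }
      if (N.stoich(i, j) != 0) {
        P.changes[j].push_back(i);
        P.changes[j].push_back(N.stoich(i, j));
      }
    }
    for (size_t s = 0; s < N.sp[j].size(); ++s) reads[j][N.sp[j][s]] = 1;
  }
  P.depends.resize(N.nrx);
  for (int r = 0; r < N.nrx; ++r)
    for (int j = 0; j < N.nrx; ++j)
      for (size_t c = 0; c < P.changes[r].size(); c += 2)
        if (reads[j][P.changes[r][c]]) { P.depends[r].push_back(j); break; }
  return P;
}

static inline double guarded_propensity(const Net& N, const SimPlan& P, int j,
                                        const double* x, const double* p) {
  for (size_t c = 0; c < P.consumed[j].size(); ++c) {
    const int i = P.consumed[j][c];
    if (x[i] + N.stoich(i, j) < 0.0) return 0.0;
  }
  double aj = propensity_one(N, j, x, p);
  if (!std::isfinite(aj))
    stop("non-finite propensity in reaction %d", j + 1);
  return aj < 0.0 ? 0.0 : aj;
}

static void simulate_one(const Net& N, const SimPlan& P, const double* p,
                         const arma::vec& init, const NumericVector& times,
                         uint64_t seed,
                         double* out /* ntimes x nsp, column-major by species */,
                         int ntimes) {
  Xoshiro rng(seed);
  const int nsp = N.nsp, nrx = N.nrx;
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(nrx);
  double t = 0.0, a0 = 0.0;
  int k = 0;
  long refresh = 0;
  for (int j = 0; j < nrx; ++j) {
    a[j] = guarded_propensity(N, P, j, x.data(), p);
    a0 += a[j];
  }
  while (k < ntimes) {
    if (a0 <= 0.0) {
      for (; k < ntimes; ++k)
        for (int i = 0; i < nsp; ++i) out[k + i * ntimes] = x[i];
      break;
    }
    const double tau = -std::log(rng.unif()) / a0;
    const double t2 = t + tau;
    while (k < ntimes && times[k] < t2) {
      for (int i = 0; i < nsp; ++i) out[k + i * ntimes] = x[i];
      ++k;
    }
    if (k >= ntimes) break;
    double u = rng.unif() * a0, c = 0.0;
    int r = nrx - 1;
    for (int j = 0; j < nrx; ++j) { c += a[j]; if (u <= c) { r = j; break; } }
    for (size_t s = 0; s < P.changes[r].size(); s += 2)
      x[P.changes[r][s]] += P.changes[r][s + 1];
    t = t2;
    // refresh only the propensities that read a changed species; rebuild
    // the total periodically to cap floating-point drift
    if (((++refresh) & 0xFFFF) == 0) {
      a0 = 0.0;
      for (int j = 0; j < nrx; ++j) {
        a[j] = guarded_propensity(N, P, j, x.data(), p);
        a0 += a[j];
      }
    } else {
      const std::vector<int>& dep = P.depends[r];
      for (size_t d = 0; d < dep.size(); ++d) {
        const int j = dep[d];
        const double aj = guarded_propensity(N, P, j, x.data(), p);
        a0 += aj - a[j];
        a[j] = aj;
      }
      if (a0 < 0.0) a0 = 0.0;
    }
  }
}

// [[Rcpp::export(name = ".simulate_trajectory_cpp")]]
NumericMatrix simulate_trajectory_cpp(List net, NumericVector params,
                                      NumericVector init, NumericVector times,
                                      double seed) {
  Net N = parse_net(net);
  SimPlan P = make_plan(N);
  const int ntimes = times.size();
  NumericMatrix out(ntimes, N.nsp);
  arma::vec x0(init.begin(), init.size());
  simulate_one(N, P, params.begin(), x0, times, (uint64_t)seed, out.begin(),
               ntimes);
  return out;
}

// [[Rcpp::export(name = ".simulate_ensemble_cpp")]]
NumericVector simulate_ensemble_cpp(List net, NumericVector params,
                                    NumericVector init, NumericVector times,
                                    int ns, double base_seed) {
  Net N = parse_net(net);
  SimPlan P = make_plan(N);
  const int ntimes = times.size();
  NumericVector out(Dimension(ntimes, N.nsp, ns));
  arma::vec x0(init.begin(), init.size());
  const size_t block = (size_t)ntimes * N.nsp;
  for (int j = 0; j < ns; ++j) {
    simulate_one(N, P, params.begin(), x0, times,
                 member_seed((uint64_t)base_seed, (uint64_t)j),
                 out.begin() + block * j, ntimes);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic analysis: central-difference Jacobian, damped Newton with a
// Levenberg fallback for (near-)singular Jacobians, post-convergence polish,
// and the maximal real part of the Jacobian eigenvalues for stability.
// ---------------------------------------------------------------------------
static arma::vec rhs_vec(const Net& N, const double* p, const arma::vec& x) {
  arma::vec d(N.nsp, arma::fill::zeros);
  for (int j = 0; j < N.nrx; ++j) {
    const double a = propensity_one(N, j, x.memptr(), p);
    for (int i = 0; i < N.nsp; ++i)
      if (N.stoich(i, j) != 0) d[i] += N.stoich(i, j) * a;
  }
  return d;
}

static arma::mat jac_fd(const Net& N, const double* p, const arma::vec& x) {
  const int n = N.nsp;
  arma::mat J(n, n);
  arma::vec xp = x, xm = x;
  for (int j = 0; j < n; ++j) {
    const double h = 1e-6 * (std::fabs(x[j]) + 1.0);
    xp[j] = x[j] + h; xm[j] = x[j] - h;
    J.col(j) = (rhs_vec(N, p, xp) - rhs_vec(N, p, xm)) / (2.0 * h);
    xp[j] = x[j]; xm[j] = x[j];
  }
  return J;
}

// [[Rcpp::export(name = ".ode_jac_cpp")]]
NumericMatrix ode_jac_cpp(List net, NumericVector state, NumericVector params) {
  Net N = parse_net(net);
  arma::vec x(state.begin(), state.size());
  arma::mat J = jac_fd(N, params.begin(), x);
  return wrap(J);
}

// [[Rcpp::export(name = ".eig_max_real_cpp")]]
double eig_max_real_cpp(List net, NumericVector state, NumericVector params) {
  Net N = parse_net(net);
  arma::vec x(state.begin(), state.size());
  arma::mat J = jac_fd(N, params.begin(), x);
  if (!J.is_finite()) return R_PosInf;
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, J)) return R_PosInf;
  return arma::real(ev).max();
}

static bool newton_solve(const Net& N, const double* p, arma::vec x,
                         double tol, int max_iter, arma::vec& root,
                         double& resid) {
  const int n = N.nsp;
  arma::vec f = rhs_vec(N, p, x);
  double nf = arma::norm(f, "inf");
  for (int it = 0; it < max_iter; ++it) {
    if (!std::isfinite(nf) || arma::norm(x, "inf") > 1e12) return false;
    if (nf < tol) break;
    arma::mat J = jac_fd(N, p, x);
    arma::vec dx;
    bool ok = J.is_finite() && arma::solve(dx, J, -f, arma::solve_opts::no_approx);
    if (!ok) {
      arma::mat Jr = J;
      if (!Jr.is_finite()) return false;
      Jr.diag() -= 1e-6 * (1.0 + arma::norm(J, "inf"));
      if (!arma::solve(dx, Jr, -f, arma::solve_opts::no_approx)) return false;
    }
    double tstep = 1.0, nfn = nf;
    arma::vec xn = x, fn = f;
    for (int ls = 0; ls < 40; ++ls) {
      xn = x + tstep * dx;
      fn = rhs_vec(N, p, xn);
      nfn = arma::norm(fn, "inf");
      if (std::isfinite(nfn) && nfn < nf * (1.0 - 1e-4 * tstep)) break;
      tstep *= 0.5;
      if (tstep < 1e-10) break;
    }
    if (!(std::isfinite(nfn) && nfn < nf)) return false;  // stagnation
    x = xn; f = fn; nf = nfn;
  }
  if (!(nf < tol)) return false;
  // polish: full Newton steps tighten the root well below the residual
  // tolerance so that duplicates from different starts coincide bitwise-near
  for (int k = 0; k < 3; ++k) {
    arma::mat J = jac_fd(N, p, x);
    arma::vec dx;
    if (!J.is_finite() ||
        !arma::solve(dx, J, -f, arma::solve_opts::no_approx)) break;
    arma::vec xn = x + dx;
    arma::vec fn = rhs_vec(N, p, xn);
    const double nfn = arma::norm(fn, "inf");
    if (std::isfinite(nfn) && nfn <= nf) { x = xn; f = fn; nf = nfn; } else break;
  }
  root = x; resid = nf;
  return true;
}

// [[Rcpp::export(name = ".newton_multistart_cpp")]]
List newton_multistart_cpp(List net, NumericVector params, NumericMatrix starts,
                           double tol, int max_iter) {
  Net N = parse_net(net);
  const int ns = starts.nrow();
  NumericMatrix roots(ns, N.nsp);
  NumericVector resid(ns);
  LogicalVector conv(ns);
  for (int s = 0; s < ns; ++s) {
    arma::vec x0(N.nsp);
    for (int i = 0; i < N.nsp; ++i) x0[i] = starts(s, i);
    arma::vec root;
    double r = NA_REAL;
    const bool ok = newton_solve(N, params.begin(), x0, tol, max_iter, root, r);
    conv[s] = ok;
    resid[s] = r;
    if (ok) for (int i = 0; i < N.nsp; ++i) roots(s, i) = root[i];
  }
  return List::create(_["roots"] = roots, _["resid"] = resid, _["conv"] = conv);
}
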