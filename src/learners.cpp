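// Fast inner loops for the trial-by-trial learners and the shifted
// log-normal sequence likelihood. Node indices arriving here are 0-based
// (converted at the R boundary; R-level code is 1-based).
//
// Model codes shared with R/models.R:
//   0 baseline, 1 recency, 2 onestep, 3 sr_td, 4 sr_static,
//   5 combined_onestep, 6 combined_sr_td, 7 combined_sr_static,
//   8 hebbian_trace (simulation agent only), 9 combined_hebbian (agent only)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;
// |M| beyond this is treated as diverged learning; the likelihood at such a
// parameter point is +inf so the optimizer rejects it.
static const double M_DIVERGE = 1e3;

// Recency learner W (unconditional expectancy); predictor at trial t is
// W[s_t] *before* the trial-t update.
static arma::vec recency_series(const arma::ivec& nodes, int n, double alpha) {
  int T = nodes.n_elem;
  arma::vec out(T);
  arma::vec W(n, arma::fill::value(1.0 / n));
  for (int t = 0; t < T; ++t) {
    int st = nodes[t];
    out[t] = W[st];
    W *= (1.0 - alpha);
    W[st] += alpha;
  }
  return out;
}

// One-step transition learner T; predictor is T[s_{t-1}, s_t] before update.
static arma::vec onestep_series(const arma::ivec& nodes, int n, double alpha) {
  int T = nodes.n_elem;
  arma::vec out(T);
  arma::mat Tm(n, n, arma::fill::value(1.0 / n));
  out[0] = 1.0 / n;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    out[t] = Tm(sp, st);
    Tm.row(sp) *= (1.0 - alpha);
    Tm(sp, st) += alpha;
  }
  return out;
}

// SR-TD(lambda) with a dutch eligibility trace. Predictor is the
// row-normalized M[s_{t-1}, s_t] before the trial-t update.
static arma::vec sr_td_series(const arma::ivec& nodes, int n, double alpha,
                              double gamma, double lam, bool& diverged) {
  int T = nodes.n_elem;
  arma::vec out(T);
  arma::mat M(n, n, arma::fill::value(1.0 / (n * (1.0 - gamma))));
  arma::vec e(n, arma::fill::zeros);
  out[0] = 1.0 / n;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    double rs = arma::accu(M.row(sp));
    if (rs <= 0) { diverged = true; return out; }
    out[t] = M(sp, st) / rs;
    e[sp] = (1.0 - alpha) * e[sp] + 1.0;
    arma::rowvec delta = gamma * M.row(st) - M.row(sp);
    delta[st] += 1.0;
    M += alpha * (e * delta);
    e *= gamma * lam;
    if (t % 64 == 0 && arma::abs(M).max() > M_DIVERGE) { diverged = true; return out; }
  }
  if (arma::abs(M).max() > M_DIVERGE) diverged = true;
  return out;
}

// Trace-only Hebbian SR learner (TD(1)-like, bootstrap-free): presynaptic
// dutch eligibility with one-hot targets and a local forgetting term applied
// to each state's own row when its trace is refreshed.
static arma::vec hebbian_series(const arma::ivec& nodes, int n, double alpha,
                                double gamma) {
  int T = nodes.n_elem;
  arma::vec out(T);
  arma::mat M(n, n, arma::fill::value(1.0 / (n * (1.0 - gamma))));
  arma::vec e(n, arma::fill::zeros);
  out[0] = 1.0 / n;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    double rs = arma::accu(M.row(sp));
    out[t] = rs > 0 ? M(sp, st) / rs : 1.0 / n;
    double v = e[sp];
    double u = 1.0 - alpha * v;   // fresh dutch increment
    e[sp] = (1.0 - alpha) * v + 1.0;
    M.row(sp) -= alpha * u * M.row(sp);
    M.col(st) += alpha * e;
    e *= gamma;
  }
  return out;
}

// Static SR predictor from an empirical transition matrix:
// M = That (I - gamma That)^{-1}, read out row-normalized.
static arma::vec static_sr_series(const arma::ivec& nodes, int n, double gamma,
                                  const arma::mat& That) {
  int T = nodes.n_elem;
  arma::vec out(T);
  arma::mat M = That * arma::inv(arma::eye(n, n) - gamma * That);
  arma::vec rs = arma::sum(M, 1);
  out[0] = 1.0 / n;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    out[t] = rs[sp] > 0 ? M(sp, st) / rs[sp] : 1.0 / n;
  }
  return out;
}

struct Predictors {
  arma::vec A;
  arma::vec W;
  bool hasA = false, hasW = false, diverged = false;
};

static Predictors make_predictors(const arma::ivec& nodes, int n, int code,
                                  double alpha_A, double alpha_W, double gamma,
                                  double lam, const arma::mat& That) {
  Predictors p;
  switch (code) {
    case 0: break;
    case 1: p.A = recency_series(nodes, n, alpha_A); p.hasA = true; break;
    case 2: p.A = onestep_series(nodes, n, alpha_A); p.hasA = true; break;
    case 3: p.A = sr_td_series(nodes, n, alpha_A, gamma, lam, p.diverged); p.hasA = true; break;
    case 4: p.A = static_sr_series(nodes, n, gamma, That); p.hasA = true; break;
    case 5: p.A = onestep_series(nodes, n, alpha_A); p.hasA = true;
            p.W = recency_series(nodes, n, alpha_W); p.hasW = true; break;
    case 6: p.A = sr_td_series(nodes, n, alpha_A, gamma, lam, p.diverged); p.hasA = true;
            p.W = recency_series(nodes, n, alpha_W); p.hasW = true; break;
    case 7: p.A = static_sr_series(nodes, n, gamma, That); p.hasA = true;
            p.W = recency_series(nodes, n, alpha_W); p.hasW = true; break;
    case 8: p.A = hebbian_series(nodes, n, alpha_A, gamma); p.hasA = true; break;
    case 9: p.A = hebbian_series(nodes, n, alpha_A, gamma); p.hasA = true;
            p.W = recency_series(nodes, n, alpha_W); p.hasW = true; break;
    default: stop("unknown model code");
  }
  return p;
}

// [[Rcpp::export]]
List cpp_predictor_series(IntegerVector nodes0, int n, int code,
                          double alpha_A, double alpha_W, double gamma,
                          double lam, NumericMatrix Tstatic) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  arma::mat That = as<arma::mat>(Tstatic);
  Predictors p = make_predictors(nodes, n, code, alpha_A, alpha_W, gamma, lam, That);
  SEXP A = R_NilValue, W = R_NilValue;
  if (p.hasA) A = NumericVector(p.A.begin(), p.A.end());
  if (p.hasW) W = NumericVector(p.W.begin(), p.W.end());
  return List::create(_["A"] = A, _["W"] = W, _["diverged"] = p.diverged);
}

// Full sequence negative log likelihood (no prior) under the shifted
// log-normal observation model, summed over included trials.
// [[Rcpp::export]]
double cpp_seq_nll(IntegerVector nodes0, NumericVector rt, LogicalVector include,
                   NumericMatrix Xfixed, int code, int n, NumericVector b,
                   double beta_A, double beta_W,
                   double alpha_A, double alpha_W, double gamma, double lam,
                   double shift_frac, double sigma, double rt_min,
                   NumericMatrix Tstatic) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  arma::mat X = as<arma::mat>(Xfixed);
  arma::vec bb = as<arma::vec>(b);
  arma::mat That = as<arma::mat>(Tstatic);
  Predictors p = make_predictors(nodes, n, code, alpha_A, alpha_W, gamma, lam, That);
  if (p.diverged) return R_PosInf;
  arma::vec mu = X * bb;
  if (p.hasA) mu += beta_A * p.A;
  if (p.hasW) mu += beta_W * p.W;
  double shift = shift_frac * rt_min;
  double nll = 0.0;
  int T = rt.size();
  for (int t = 0; t < T; ++t) {
    if (!include[t]) continue;
    double r = rt[t] - shift;
    if (r <= 0) return R_PosInf;
    double y = std::log(r);
    double z = (y - mu[t]) / sigma;
    nll += std::log(sigma) + 0.5 * LOG2PI + y + 0.5 * z * z;
  }
  return nll;
}

// Profiled MAP objective for one session. Given the nonlinear parameters
// (shift_frac and learner rates on the natural scale), the linear
// coefficients b (fixed regressors plus beta_A/beta_W) and log(sigma) have a
// ridge / 1-d Newton solution under the identity Gaussian prior; this
// routine alternates the two to convergence and returns the minimized
// penalized NLL together with the minimizing b and log(sigma).
// [[Rcpp::export]]
List cpp_profile_map(IntegerVector nodes0, NumericVector rt, LogicalVector include,
                     NumericMatrix Xfixed, int code, int n,
                     double shift_frac, double alpha_A, double alpha_W,
                     double gamma, double lam,
                     NumericVector prior_mean_b, double prior_mean_logsigma,
                     double rt_min, NumericMatrix Tstatic) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  arma::mat Xf = as<arma::mat>(Xfixed);
  arma::vec mb = as<arma::vec>(prior_mean_b);
  arma::mat That = as<arma::mat>(Tstatic);

  Predictors p = make_predictors(nodes, n, code, alpha_A, alpha_W, gamma, lam, That);
  if (p.diverged)
    return List::create(_["obj"] = R_PosInf, _["b"] = R_NilValue,
                        _["logsigma"] = NA_REAL, _["diverged"] = true);

  int T = rt.size();
  arma::uvec idx(T);
  int N = 0;
  for (int t = 0; t < T; ++t) if (include[t]) idx[N++] = t;
  idx.resize(N);

  int pA = p.hasA ? 1 : 0, pW = p.hasW ? 1 : 0;
  int P = Xf.n_cols + pA + pW;
  arma::mat X(N, P);
  X.cols(0, Xf.n_cols - 1) = Xf.rows(idx);
  if (p.hasA) X.col(Xf.n_cols) = p.A.elem(idx);
  if (p.hasW) X.col(Xf.n_cols + pA) = p.W.elem(idx);

  double shift = shift_frac * rt_min;
  arma::vec y(N);
  double sumlog = 0.0;
  for (int i = 0; i < N; ++i) {
    double r = rt[idx[i]] - shift;
    if (r <= 0)
      return List::create(_["obj"] = R_PosInf, _["b"] = R_NilValue,
                          _["logsigma"] = NA_REAL, _["diverged"] = false);
    y[i] = std::log(r);
    sumlog += y[i];
  }

  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  double yty = arma::dot(y, y);
  const arma::mat I = arma::eye(P, P);

  double ls = std::log(std::max(1e-4, arma::stddev(y)));
  arma::vec b = mb;
  double obj = R_PosInf, ssr = 0.0;
  for (int it = 0; it < 200; ++it) {
    double s2 = std::exp(2.0 * ls);
    arma::vec rhs = Xty / s2 + mb;
    arma::mat A = XtX / s2 + I;
    b = arma::solve(A, rhs, arma::solve_opts::likely_sympd);
    ssr = yty - 2.0 * arma::dot(b, Xty) + arma::as_scalar(b.t() * XtX * b);
    if (ssr < 1e-12) ssr = 1e-12;
    for (int k = 0; k < 30; ++k) {  // Newton on log(sigma)
      double e2 = std::exp(-2.0 * ls);
      double g = N - ssr * e2 + (ls - prior_mean_logsigma);
      double h = 2.0 * ssr * e2 + 1.0;
      double step = g / h;
      if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
      ls -= step;
      if (ls < -10.0) ls = -10.0; else if (ls > 10.0) ls = 10.0;
      if (std::fabs(step) < 1e-12) break;
    }
    double s2n = std::exp(2.0 * ls);
    double newobj = N * ls + 0.5 * N * LOG2PI + sumlog + ssr / (2.0 * s2n) +
      0.5 * arma::dot(b - mb, b - mb) +
      0.5 * (ls - prior_mean_logsigma) * (ls - prior_mean_logsigma);
    if (std::fabs(obj - newobj) < 1e-10) { obj = newobj; break; }
    obj = newobj;
  }
  return List::create(_["obj"] = obj, _["b"] = b, _["logsigma"] = ls,
                      _["diverged"] = false);
}

// Run SR-TD(lambda) along a node sequence; optionally track, over the last
// `tail` transitions, the running max-abs deviation from a reference matrix
// (the analytic SR fixed point). Used by the convergence oracles.
// [[Rcpp::export]]
List cpp_run_sr_td(IntegerVector nodes0, int n, double alpha, double gamma,
                   double lam, Nullable<NumericMatrix> Mref = R_NilValue,
                   int tail = 0) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  int T = nodes.n_elem;
  arma::mat M(n, n, arma::fill::value(1.0 / (n * (1.0 - gamma))));
  arma::vec e(n, arma::fill::zeros);
  arma::mat R;
  bool track = tail > 0;
  bool haveref = Mref.isNotNull();
  if (haveref) R = as<arma::mat>(Mref.get());
  arma::mat Msum(n, n, arma::fill::zeros);
  double errsum = 0.0;
  int errn = 0;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    e[sp] = (1.0 - alpha) * e[sp] + 1.0;
    arma::rowvec delta = gamma * M.row(st) - M.row(sp);
    delta[st] += 1.0;
    M += alpha * (e * delta);
    e *= gamma * lam;
    if (track && t >= T - tail) {
      Msum += M;
      ++errn;
      if (haveref) errsum += arma::abs(M - R).max();
    }
  }
  arma::mat Mbar = errn > 0 ? arma::mat(Msum / errn) : M;
  return List::create(_["M"] = M, _["e"] = e, _["M_tail_mean"] = Mbar,
                      _["mean_err"] = (errn > 0 && haveref) ? errsum / errn : NA_REAL,
                      _["tail_mean_err"] = (errn > 0 && haveref)
                        ? arma::abs(Mbar - R).max() : NA_REAL);
}

// Run the trace-only Hebbian SR learner along a node sequence.
// [[Rcpp::export]]
List cpp_run_hebbian(IntegerVector nodes0, int n, double alpha, double gamma) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  int T = nodes.n_elem;
  arma::mat M(n, n, arma::fill::value(1.0 / (n * (1.0 - gamma))));
  arma::vec e(n, arma::fill::zeros);
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    double v = e[sp];
    double u = 1.0 - alpha * v;
    e[sp] = (1.0 - alpha) * v + 1.0;
    M.row(sp) -= alpha * u * M.row(sp);
    M.col(st) += alpha * e;
    e *= gamma;
  }
  return List::create(_["M"] = M, _["e"] = e);
}

// Entrywise time-averaged absolute deviation from a reference over the
// final `tail` transitions: mean_t |M_t - Mref| per entry, then its max.
// [[Rcpp::export]]
double cpp_sr_td_tracking_err(IntegerVector nodes0, int n, double alpha,
                              double gamma, double lam, NumericMatrix Mref,
                              int tail) {
  arma::ivec nodes = as<arma::ivec>(nodes0);
  int T = nodes.n_elem;
  arma::mat M(n, n, arma::fill::value(1.0 / (n * (1.0 - gamma))));
  arma::vec e(n, arma::fill::zeros);
  arma::mat R = as<arma::mat>(Mref);
  arma::mat Esum(n, n, arma::fill::zeros);
  int cnt = 0;
  for (int t = 1; t < T; ++t) {
    int sp = nodes[t - 1], st = nodes[t];
    e[sp] = (1.0 - alpha) * e[sp] + 1.0;
    arma::rowvec delta = gamma * M.row(st) - M.row(sp);
    delta[st] += 1.0;
    M += alpha * (e * delta);
    e *= gamma * lam;
    if (t >= T - tail) { Esum += arma::abs(M - R); ++cnt; }
  }
  return cnt > 0 ? (Esum / cnt).max() : NA_REAL;
}
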