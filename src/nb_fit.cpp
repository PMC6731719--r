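// Negative-binomial (NB2) regression core: IRLS for the regression
// coefficients alternating with a safeguarded Newton update of the
// dispersion theta on the log scale, with theta profiled over
// [1e-2, 1e4]: the upper bound is numerically Poisson for catch-sized
// means, the lower one the coarsest dispersion estimable from a
// campaign of this size (and a guard against the degenerate resamples
// an unbounded theta-hat would generate).  Coefficients are constrained to
// [-cap, cap]; a coefficient pinned at the cap with the score still
// pushing outward is reported as separated (complete separation, e.g. a
// forest type with no catches at all).
//
// Counts are small integers, so lgamma(y + theta), digamma(y + theta)
// and trigamma(y + theta) are built by recurrence over 0..max(y) once
// per theta value; a likelihood evaluation then costs one exp and one
// log per observation.  This matters: the resampling tests refit the
// model hundreds of thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct NbData {
  arma::vec y;          // counts (integer-valued)
  arma::uvec yi;        // counts as indices into the value tables
  int ymax;             // capped so table sizes stay bounded
  double const_term;    // -sum lgamma(y+1), parameter-free
};

static NbData make_data(const arma::vec& y) {
  NbData d;
  d.y = y;
  double ym = y.max();
  d.ymax = (ym > 2e9) ? 2000000000 : (int) ym;
  d.yi = arma::conv_to<arma::uvec>::from(y);
  d.const_term = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    d.const_term -= std::lgamma(y[i] + 1.0);
  return d;
}

// lgamma(v + th) - lgamma(th) for v = 0..min(ymax, TAB_MAX) by
// recurrence; counts beyond the table (only seen in extreme resamples)
// fall back to direct lgamma
static const int TAB_MAX = 4096;
static arma::vec lg_table(double th, int ymax) {
  int m = std::min(ymax, TAB_MAX);
  arma::vec t(m + 1);
  t[0] = 0.0;
  for (int v = 1; v <= m; ++v) t[v] = t[v - 1] + std::log(th + v - 1.0);
  return t;
}

// full normalised log-likelihood given eta (mu = exp(eta)) and theta
static double nb_ll(const NbData& d, const arma::vec& eta, double th,
                    const arma::vec& lgt) {
  double lth = std::log(th);
  double lgth = (d.ymax > TAB_MAX) ? std::lgamma(th) : 0.0;
  double ll = d.const_term;
  for (arma::uword i = 0; i < d.y.n_elem; ++i) {
    int yi = d.yi[i];
    double mu = std::exp(eta[i]);
    double ltm = std::log(th + mu);
    double lgy = (yi < (int) lgt.n_elem) ? lgt[yi]
                 : std::lgamma(d.y[i] + th) - lgth;
    ll += lgy + th * (lth - ltm) + d.y[i] * (eta[i] - ltm);
  }
  return ll;
}

static arma::vec clamp_eta(const arma::mat& X, const arma::vec& off,
                           const arma::vec& beta) {
  return arma::clamp(off + X * beta, -700.0, 700.0);
}

// score and observed hessian of ll wrt theta at fixed eta
static void dg_tables(double th, int ymax, arma::vec& dg, arma::vec& tg) {
  int m = std::min(ymax, TAB_MAX);
  dg.set_size(m + 1); tg.set_size(m + 1);
  dg[0] = 0.0; tg[0] = 0.0;
  for (int v = 1; v <= m; ++v) {
    double a = th + v - 1.0;
    dg[v] = dg[v - 1] + 1.0 / a;
    tg[v] = tg[v - 1] - 1.0 / (a * a);
  }
}

static void theta_derivs(const NbData& d, const arma::vec& eta, double th,
                         double& score, double& hess) {
  arma::vec dg, tg;
  dg_tables(th, d.ymax, dg, tg);
  double dgth = R::digamma(th), tgth = R::trigamma(th);
  double lth = std::log(th);
  score = 0.0; hess = 0.0;
  for (arma::uword i = 0; i < d.y.n_elem; ++i) {
    int yi = d.yi[i];
    double mu = std::exp(eta[i]);
    double tm = th + mu;
    double dgy = (yi < (int) dg.n_elem) ? dg[yi]
                 : R::digamma(d.y[i] + th) - dgth;
    double tgy = (yi < (int) tg.n_elem) ? tg[yi]
                 : R::trigamma(d.y[i] + th) - tgth;
    score += dgy + lth + 1.0 - std::log(tm) - (d.y[i] + th) / tm;
    hess  += tgy + 1.0 / th - 2.0 / tm + (d.y[i] + th) / (tm * tm);
  }
}

// one profile update of theta (Newton on log theta, step-halved on the
// likelihood), bounded as above
static double update_theta(const NbData& d, const arma::vec& eta, double th,
                           int max_steps) {
  const double lt_lo = std::log(1e-2), lt_hi = std::log(1e4);
  double lt = std::log(th);
  double ll = nb_ll(d, eta, th, lg_table(th, d.ymax));
  for (int s = 0; s < max_steps; ++s) {
    double sc, he;
    double thc = std::exp(lt);
    theta_derivs(d, eta, thc, sc, he);
    double g = thc * sc;
    double h = thc * sc + thc * thc * he;
    if (std::fabs(g) < 1e-9 * (std::fabs(ll) + 1.0)) break;
    double step = (h < 0) ? (-g / h) : ((g > 0) ? 1.0 : -1.0);
    if (step > 4.0) step = 4.0;
    if (step < -4.0) step = -4.0;
    double lt_new = std::min(std::max(lt + step, lt_lo), lt_hi);
    double ll_new = nb_ll(d, eta, std::exp(lt_new), lg_table(std::exp(lt_new), d.ymax));
    int halve = 0;
    while (ll_new < ll - 1e-12 && halve < 20) {
      lt_new = 0.5 * (lt + lt_new);
      ll_new = nb_ll(d, eta, std::exp(lt_new), lg_table(std::exp(lt_new), d.ymax));
      ++halve;
    }
    if (std::fabs(lt_new - lt) < 1e-9 || ll_new - ll < 1e-11) {
      lt = lt_new;
      break;
    }
    lt = lt_new; ll = ll_new;
  }
  return std::exp(lt);
}

// IRLS for beta at fixed theta, box-constrained, step-halved
static double update_beta(const arma::mat& X, const NbData& d,
                          const arma::vec& off, double th, arma::vec& beta,
                          double cap, int max_iter) {
  arma::vec lgt = lg_table(th, d.ymax);
  arma::vec eta = clamp_eta(X, off, beta);
  double ll = nb_ll(d, eta, th, lgt);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec mu = arma::exp(eta);
    arma::vec w = mu / (1.0 + mu / th);
    arma::vec z = (eta - off) + (d.y - mu) / mu;
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * z;
    A.diag() += 1e-10;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, A, b, arma::solve_opts::no_approx);
    if (!ok) break;
    beta_new = arma::clamp(beta_new, -cap, cap);
    arma::vec eta_new = clamp_eta(X, off, beta_new);
    double ll_new = nb_ll(d, eta_new, th, lgt);
    int halve = 0;
    while (ll_new < ll - 1e-12 && halve < 30) {
      beta_new = arma::clamp(0.5 * (beta + beta_new), -cap, cap);
      eta_new = clamp_eta(X, off, beta_new);
      ll_new = nb_ll(d, eta_new, th, lgt);
      ++halve;
    }
    double delta = arma::abs(beta_new - beta).max();
    double gain = ll_new - ll;
    beta = beta_new; eta = eta_new; ll = ll_new;
    if (delta < 1e-9 || gain < 1e-11) break;   // converged or stalled
  }
  return ll;
}

// one joint Newton step on (beta, log theta) with an active set for
// coefficients pinned at the cap and theta pinned at its bounds.
// Gradient, Hessian and log-likelihood come from a single fused pass
// over the data; the step is trust-capped and step-halved so the
// likelihood never decreases.
static double newton_joint(const arma::mat& X, const NbData& d,
                           const arma::vec& off, arma::vec& beta, double& lt,
                           double cap, bool& moved, double& decrement) {
  const double lt_lo = std::log(1e-2), lt_hi = std::log(1e4);
  const arma::uword p = beta.n_elem;
  const arma::uword n = d.y.n_elem;
  double th = std::exp(lt);
  arma::vec eta = clamp_eta(X, off, beta);

  // tables over count values for lgamma/digamma/trigamma sums
  arma::vec lgt = lg_table(th, d.ymax);
  arma::vec dg, tg;
  dg_tables(th, d.ymax, dg, tg);
  double lgth = std::lgamma(th), dgth = R::digamma(th), tgth = R::trigamma(th);

  double lth = std::log(th);
  double ll = d.const_term, sc = 0.0, he = 0.0;
  arma::vec g(p + 1, arma::fill::zeros);
  arma::mat H(p + 1, p + 1, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double yv = d.y[i];
    int yi = d.yi[i];
    double mu = std::exp(eta[i]);
    double tm = th + mu;
    double ltm = std::log(tm);
    double lgy = (yi < (int) lgt.n_elem) ? lgt[yi] : std::lgamma(yv + th) - lgth;
    double dgy = (yi < (int) dg.n_elem) ? dg[yi] : R::digamma(yv + th) - dgth;
    double tgy = (yi < (int) tg.n_elem) ? tg[yi] : R::trigamma(yv + th) - tgth;
    ll += lgy + th * (lth - ltm) + yv * (eta[i] - ltm);
    double geta = th * (yv - mu) / tm;
    double wbb = th * mu * (th + yv) / (tm * tm);
    double ceta = th * mu * (yv - mu) / (tm * tm);
    sc += dgy + lth + 1.0 - ltm - (yv + th) / tm;
    he += tgy + 1.0 / th - 2.0 / tm + (yv + th) / (tm * tm);
    const double* xi = X.colptr(0);  // column-major: index j*n + i
    for (arma::uword j = 0; j < p; ++j) {
      double xij = X(i, j);
      g[j] += xij * geta;
      H(j, p) += xij * ceta;
      for (arma::uword k = 0; k <= j; ++k)
        H(j, k) -= xij * X(i, k) * wbb;
    }
    (void) xi;
  }
  g[p] = th * sc;
  H(p, p) = th * sc + th * th * he;
  for (arma::uword j = 0; j < p; ++j) {
    H(p, j) = H(j, p);
    for (arma::uword k = 0; k < j; ++k) H(k, j) = H(j, k);
  }

  // active set: parameters pinned at a bound with the score outward
  std::vector<arma::uword> free_ix;
  for (arma::uword j = 0; j < p; ++j) {
    bool pinned = (beta[j] >= cap - 1e-8 && g[j] > 0) ||
                  (beta[j] <= -cap + 1e-8 && g[j] < 0);
    if (!pinned) free_ix.push_back(j);
  }
  bool lt_free = !((lt >= lt_hi - 1e-8 && g[p] > 0) ||
                   (lt <= lt_lo + 1e-8 && g[p] < 0));
  if (lt_free) free_ix.push_back(p);
  moved = false;
  decrement = 0.0;
  if (free_ix.empty()) return ll;
  arma::uvec fi(free_ix);
  arma::mat Hr = -H.submat(fi, fi);       // positive definite near optimum
  // drop unidentifiable directions (e.g. an all-zero dummy column)
  // whose curvature is numerically zero, then add a relative ridge
  arma::vec hd = Hr.diag();
  double hmax = std::max(hd.max(), 1.0);
  arma::uvec ok = arma::find(hd > 1e-10 * hmax);
  if (ok.n_elem == 0) return ll;
  fi = fi.elem(ok);
  Hr = -H.submat(fi, fi);
  Hr.diag() += 1e-10 * (1.0 + Hr.diag());
  arma::vec dr;
  if (!arma::solve(dr, Hr, g.elem(fi), arma::solve_opts::no_approx))
    return ll;
  decrement = 0.5 * arma::dot(dr, g.elem(fi));   // expected gain
  if (decrement <= 0) return ll;                 // not an ascent direction
  arma::vec full_d(p + 1, arma::fill::zeros);
  full_d.elem(fi) = dr;
  // trust region: long ridge steps overshoot badly, cap the step
  double dmax = arma::abs(full_d).max();
  if (dmax > 10.0) full_d *= 10.0 / dmax;

  arma::vec deta = X * full_d.head(p);
  double t = 1.0;
  for (int halve = 0; halve < 30; ++halve, t *= 0.5) {
    arma::vec beta_new = arma::clamp(beta + t * full_d.head(p), -cap, cap);
    double lt_new = std::min(std::max(lt + t * full_d[p], lt_lo), lt_hi);
    double ll_new = nb_ll(d, clamp_eta(X, off, beta_new), std::exp(lt_new),
                          lg_table(std::exp(lt_new), d.ymax));
    if (ll_new >= ll - 1e-12) {
      moved = (arma::abs(beta_new - beta).max() > 1e-12 ||
               std::fabs(lt_new - lt) > 1e-12);
      beta = beta_new; lt = lt_new;
      return ll_new;
    }
  }
  (void) deta;
  return ll;
}

// [[Rcpp::export(name = ".nb_fit_core")]]
List nb_fit_core(const arma::mat& X, const arma::vec& y, const arma::vec& off,
                 arma::vec beta, double theta, double cap = 15.0,
                 double tol = 1e-8, int max_outer = 200, bool warm = false) {
  beta = arma::clamp(beta, -cap, cap);
  if (theta <= 0) theta = 1.0;
  NbData d = make_data(y);
  bool converged = false;
  int outer = 0;
  if (d.ymax == 0) {
    // all-zero counts: the intercept diverges to -inf; pin it at -cap
    beta.zeros();
    beta[0] = -cap;
    double ll = nb_ll(d, clamp_eta(X, off, beta), theta,
                      lg_table(theta, d.ymax));
    LogicalVector sep(beta.n_elem, false);
    sep[0] = true;
    return List::create(_["beta"] = beta, _["theta"] = theta,
                        _["loglik"] = ll, _["converged"] = true,
                        _["separated"] = sep, _["iter"] = 0);
  }
  double ll = nb_ll(d, clamp_eta(X, off, beta), theta,
                    lg_table(theta, d.ymax));
  double lt = std::log(theta);
  // cold starts get two alternation passes to stabilise the crude
  // Poisson initialisation; warm starts go straight to Newton
  int n_stab = warm ? 0 : 2;
  for (outer = 1; outer <= max_outer; ++outer) {
    if (outer <= n_stab) {
      // a couple of alternation passes stabilise crude starting values
      update_beta(X, d, off, theta, beta, cap, 25);
      arma::vec eta = clamp_eta(X, off, beta);
      theta = update_theta(d, eta, theta, 10);
      lt = std::log(theta);
      ll = nb_ll(d, eta, theta, lg_table(theta, d.ymax));
      continue;
    }
    // quadratic joint Newton on (beta, log theta); convergence is
    // decided by the Newton decrement (the attainable remaining gain),
    // never by a stalled step's small likelihood change
    bool moved;
    double decr;
    ll = newton_joint(X, d, off, beta, lt, cap, moved, decr);
    theta = std::exp(lt);
    if (decr >= 0 && decr < tol * (std::fabs(ll) + 1.0)) {
      converged = true;
      break;
    }
    if (!moved) {
      // Newton blocked (indefinite curvature or failed line search):
      // fall back to one alternation pass and keep iterating
      update_beta(X, d, off, theta, beta, cap, 25);
      arma::vec eta = clamp_eta(X, off, beta);
      theta = update_theta(d, eta, theta, 10);
      lt = std::log(theta);
      ll = nb_ll(d, eta, theta, lg_table(theta, d.ymax));
    }
  }
  // separation: pinned at the cap with the score still pushing outward
  arma::vec mu = arma::exp(clamp_eta(X, off, beta));
  arma::vec u = (y - mu) % (theta / (theta + mu));
  arma::vec g = X.t() * u;
  LogicalVector sep(beta.n_elem);
  // a pinned coefficient whose score does not substantially pull it
  // back inside is separated: either the score pushes outward (true
  // separation; it can be vanishingly small when the fitted mean is
  // ~exp(-cap)) or the surface is flat at the box (quasi-separation)
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    sep[j] = (beta[j] >= cap - 1e-6 && g[j] > -1e-6) ||
             (beta[j] <= -cap + 1e-6 && g[j] < 1e-6);
  return List::create(_["beta"] = beta, _["theta"] = theta,
                      _["loglik"] = ll, _["converged"] = converged,
                      _["separated"] = sep, _["iter"] = outer);
}
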