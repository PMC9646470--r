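// Weighted random-intercept linear mixed model engine.
//
// Model, per gene: y = X beta + Z b + eps, one random intercept per patient,
//   b_p ~ N(0, tau2), eps_i ~ N(0, sigma2 / w_i), w_i known precision weights.
// REML estimation profiles sigma2 out and optimises theta = tau2/sigma2 on
// [0, theta_max] by Brent's method, followed by a safeguarded secant polish of
// the analytic profile gradient so the optimum is located to near machine
// precision. Satterthwaite degrees of freedom use the analytic gradient of
// se^2 with respect to (tau2, sigma2) and the analytic observed information
// of the REML surface; at a clamped tau2 = 0 boundary (strictly negative REML
// gradient in tau2) the df fall back to the OLS residual df n - rank(X).
//
// All per-evaluation algebra uses the Sherman-Morrison structure of the
// block-diagonal marginal covariance, so one evaluation costs O(n p^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Blocks {
  int n = 0, p = 0, B = 0;
  arma::mat X;                         // n x p
  std::vector<std::vector<int>> idx;   // sample indices per group
};

Blocks make_blocks(const arma::mat& X, const IntegerVector& grp) {
  Blocks bl;
  bl.X = X;
  bl.n = X.n_rows;
  bl.p = X.n_cols;
  int B = 0;
  for (int i = 0; i < grp.size(); ++i) B = std::max(B, grp[i] + 1);
  bl.B = B;
  bl.idx.assign(B, {});
  for (int i = 0; i < grp.size(); ++i) bl.idx[grp[i]].push_back(i);
  return bl;
}

// per-gene sufficient statistics that do not depend on theta
struct GeneStats {
  arma::vec y, w;
  arma::mat XtWX;            // p x p
  arma::vec XtWy;            // p
  double ytWy = 0.0, sumlogw = 0.0;
  arma::mat U;               // p x B, U.col(b) = X_b' w_b
  arma::vec vy;              // B, w_b' y_b
  arma::vec sw;              // B, sum of w in block
};

GeneStats gene_stats(const Blocks& bl, const arma::vec& y, const arma::vec& w) {
  GeneStats st;
  st.y = y; st.w = w;
  st.XtWX.zeros(bl.p, bl.p);
  st.XtWy.zeros(bl.p);
  st.U.zeros(bl.p, bl.B);
  st.vy.zeros(bl.B);
  st.sw.zeros(bl.B);
  for (int b = 0; b < bl.B; ++b) {
    for (int i : bl.idx[b]) {
      const double wi = w[i];
      st.sw[b] += wi;
      st.vy[b] += wi * y[i];
      for (int j = 0; j < bl.p; ++j) st.U(j, b) += wi * bl.X(i, j);
    }
  }
  for (int i = 0; i < bl.n; ++i) {
    const double wi = w[i];
    st.ytWy += wi * y[i] * y[i];
    st.sumlogw += std::log(wi);
    for (int j = 0; j < bl.p; ++j) {
      st.XtWy[j] += wi * y[i] * bl.X(i, j);
      for (int k = j; k < bl.p; ++k) st.XtWX(j, k) += wi * bl.X(i, j) * bl.X(i, k);
    }
  }
  st.XtWX = arma::symmatu(st.XtWX);
  return st;
}

// state of one profile evaluation at a given theta (phi2-free scale:
// Sigma(theta) = W^{-1} + theta Z Z', S = Sigma^{-1})
struct ProfileEval {
  double theta = 0.0;
  arma::mat Atheta;   // X' S X
  arma::mat Ainv_t;   // Atheta^{-1}
  arma::vec beta;
  double q = 0.0;     // r' S r
  double sigma2 = 0.0;
  double ldSigma = 0.0, ldA = 0.0;
  double loglik = 0.0;
  bool ok = false;
};

ProfileEval profile_eval(const Blocks& bl, const GeneStats& st, double theta) {
  ProfileEval ev;
  ev.theta = theta;
  const int n = bl.n, p = bl.p, B = bl.B;
  arma::mat A = st.XtWX;
  arma::vec c = st.XtWy;
  double yy = st.ytWy;
  double ldS = -st.sumlogw;
  for (int b = 0; b < B; ++b) {
    const double d = 1.0 + theta * st.sw[b];
    const double kb = theta / d;
    A -= kb * (st.U.col(b) * st.U.col(b).t());
    c -= kb * st.vy[b] * st.U.col(b);
    yy -= kb * st.vy[b] * st.vy[b];
    ldS += std::log(d);
  }
  arma::mat R;
  if (!arma::chol(R, arma::symmatu(A))) return ev;
  ev.Atheta = arma::symmatu(A);
  ev.Ainv_t = arma::inv_sympd(ev.Atheta);
  ev.beta = ev.Ainv_t * c;
  ev.q = yy - arma::dot(c, ev.beta);
  if (!(ev.q > 0) || !std::isfinite(ev.q)) return ev;
  const double df = n - p;
  ev.sigma2 = ev.q / df;
  ev.ldSigma = ldS;
  ev.ldA = 2.0 * arma::sum(arma::log(R.diag()));
  ev.loglik = -0.5 * (df * (std::log(2.0 * M_PI * ev.sigma2) + 1.0) + ev.ldSigma + ev.ldA);
  ev.ok = std::isfinite(ev.loglik);
  return ev;
}

// analytic derivative of the profile REML log-likelihood w.r.t. theta
double profile_grad(const Blocks& bl, const GeneStats& st, const ProfileEval& ev) {
  const int n = bl.n, p = bl.p, B = bl.B;
  const double theta = ev.theta;
  // GLS residual pushed through Sigma^{-1}: e = S r (phi2-free scale)
  arma::vec r = st.y - bl.X * ev.beta;
  arma::vec e(n);
  std::vector<double> wr(B, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int i : bl.idx[b]) wr[b] += st.w[i] * r[i];
  }
  double dq = 0.0, trSZ = 0.0, trAT = 0.0;
  for (int b = 0; b < B; ++b) {
    const double d = 1.0 + theta * st.sw[b];
    const double kb = theta / d, al = 1.0 / d;
    double esum = 0.0;
    for (int i : bl.idx[b]) {
      e[i] = st.w[i] * r[i] - kb * st.w[i] * wr[b];
      esum += e[i];
    }
    dq -= esum * esum;                       // dq/dtheta = -e' ZZ' e
    trSZ += al * st.sw[b];                   // tr(S ZZ')
    trAT += al * al * arma::as_scalar(st.U.col(b).t() * ev.Ainv_t * st.U.col(b));
  }
  return -0.5 * ((n - p) * dq / ev.q + trSZ - trAT);
}

struct SattOut {
  arma::vec df;          // per requested coefficient
  bool info_ok = true;
};

// Satterthwaite df at (tau2, sigma2) = (theta*sigma2, sigma2) via analytic
// gradient of g = se_j^2 and the analytic observed REML information in the
// variance scale (tau2, sigma2).
SattOut satterthwaite(const Blocks& bl, const GeneStats& st, const ProfileEval& ev,
                      const std::vector<int>& coefs) {
  const int n = bl.n, p = bl.p, B = bl.B;
  const double theta = ev.theta, phi2 = ev.sigma2;
  SattOut out;
  out.df.set_size(coefs.size());
  out.df.fill(arma::datum::nan);

  // block constants
  arma::vec alpha(B), kb(B);
  for (int b = 0; b < B; ++b) {
    const double d = 1.0 + theta * st.sw[b];
    alpha[b] = 1.0 / d;
    kb[b] = theta / d;
  }

  // e = P y = V^{-1} (y - X beta) ; V = phi2 * Sigma(theta)
  arma::vec r = st.y - bl.X * ev.beta;
  arma::vec e(n);
  std::vector<double> wr(B, 0.0);
  for (int b = 0; b < B; ++b) for (int i : bl.idx[b]) wr[b] += st.w[i] * r[i];
  for (int b = 0; b < B; ++b)
    for (int i : bl.idx[b]) e[i] = (st.w[i] * r[i] - kb[b] * st.w[i] * wr[b]) / phi2;

  // applies S = V^{-1} to a vector
  auto applyS = [&](const arma::vec& x) {
    arma::vec out_v(n);
    for (int b = 0; b < B; ++b) {
      double wx = 0.0;
      for (int i : bl.idx[b]) wx += st.w[i] * x[i];
      for (int i : bl.idx[b]) out_v[i] = (st.w[i] * x[i] - kb[b] * st.w[i] * wx) / phi2;
    }
    return out_v;
  };
  // applies P = S - S X A^{-1} X' S with A = X'V^{-1}X = Atheta/phi2
  arma::mat Ainv = phi2 * ev.Ainv_t;
  auto applyP = [&](const arma::vec& x) {
    arma::vec Sx = applyS(x);
    arma::vec h = bl.X.t() * Sx;
    arma::vec v = bl.X * (Ainv * h);
    return arma::vec(Sx - applyS(v));
  };

  // c_k = V_k e  (V_1 = ZZ', V_2 = diag(1/w))
  arma::vec c1(n), c2(n);
  for (int b = 0; b < B; ++b) {
    double esum = 0.0;
    for (int i : bl.idx[b]) esum += e[i];
    for (int i : bl.idx[b]) c1[i] = esum;
  }
  for (int i = 0; i < n; ++i) c2[i] = e[i] / st.w[i];

  arma::vec f1 = applyP(c1), f2 = applyP(c2);
  const double s11 = arma::dot(c1, f1);
  const double s12 = arma::dot(c1, f2);
  const double s22 = arma::dot(c2, f2);

  // traces tr(P V_k P V_l)
  const double phi2sq = phi2 * phi2;
  double trS11 = 0.0, trS12 = 0.0, trS22 = 0.0;
  arma::mat T1(p, p, arma::fill::zeros), T2 = st.XtWX;
  arma::mat N11(p, p, arma::fill::zeros), N12(p, p, arma::fill::zeros), N22 = st.XtWX;
  for (int b = 0; b < B; ++b) {
    const double al = alpha[b], k = kb[b], swb = st.sw[b];
    const double mb = (double) bl.idx[b].size();
    trS11 += (al * swb) * (al * swb);
    trS12 += al * al * swb;
    trS22 += mb - 2.0 * k * swb + k * k * swb * swb;
    arma::mat uu = st.U.col(b) * st.U.col(b).t();
    T1 += (al * al) * uu;
    T2 -= (2.0 * k - k * k * swb) * uu;
    N11 += (al * al * al * swb) * uu;
    N12 += (al * al * al) * uu;
    N22 -= (2.0 * k - k * k * swb + k * al * al) * uu;
  }
  trS11 /= phi2sq; trS12 /= phi2sq; trS22 /= phi2sq;
  T1 /= phi2sq; T2 /= phi2sq;
  const double phi2cb = phi2sq * phi2;
  N11 /= phi2cb; N12 /= phi2cb; N22 /= phi2cb;

  arma::mat AinvT1 = Ainv * T1, AinvT2 = Ainv * T2;
  const double tr11 = trS11 - 2.0 * arma::trace(Ainv * N11) + arma::trace(AinvT1 * AinvT1);
  const double tr12 = trS12 - 2.0 * arma::trace(Ainv * N12) + arma::trace(AinvT1 * AinvT2);
  const double tr22 = trS22 - 2.0 * arma::trace(Ainv * N22) + arma::trace(AinvT2 * AinvT2);

  arma::mat H(2, 2);
  H(0, 0) = s11 - 0.5 * tr11;
  H(0, 1) = H(1, 0) = s12 - 0.5 * tr12;
  H(1, 1) = s22 - 0.5 * tr22;

  arma::mat C;
  if (!arma::inv(C, H)) { out.info_ok = false; return out; }

  for (size_t m = 0; m < coefs.size(); ++m) {
    const int j = coefs[m];
    const double g = Ainv(j, j);                 // se_j^2
    arma::vec aj = applyS(bl.X * Ainv.col(j));   // V^{-1} X A^{-1} e_j
    double dg1 = 0.0, dg2 = 0.0;
    for (int b = 0; b < B; ++b) {
      double asum = 0.0;
      for (int i : bl.idx[b]) asum += aj[i];
      dg1 += asum * asum;
    }
    for (int i = 0; i < n; ++i) dg2 += aj[i] * aj[i] / st.w[i];
    arma::vec dg = {dg1, dg2};
    const double den = arma::as_scalar(dg.t() * C * dg);
    if (den > 0 && std::isfinite(den)) out.df[m] = 2.0 * g * g / den;
    else out.info_ok = false;
  }
  return out;
}

// Brent minimisation of -profile loglik on [0, theta_max], then a safeguarded
// secant refinement of the analytic gradient root.
struct OptOut {
  ProfileEval ev;
  bool boundary = false, converged = false;
  double grad_at_zero = 0.0;
};

OptOut optimise_theta(const Blocks& bl, const GeneStats& st, double theta_max) {
  OptOut res;
  auto nll = [&](double th, ProfileEval& hold) {
    hold = profile_eval(bl, st, th);
    return hold.ok ? -hold.loglik : arma::datum::inf;
  };

  const double gold = 0.5 * (3.0 - std::sqrt(5.0));
  double a = 0.0, b = theta_max;
  ProfileEval evx, evtmp;
  double x = a + gold * (b - a), wv = x, v = x;
  double fx = nll(x, evx), fw = fx, fv = fx;
  if (!std::isfinite(fx)) return res;
  double d = 0.0, eprev = 0.0;
  const double eps = std::sqrt(std::numeric_limits<double>::epsilon());
  for (int iter = 0; iter < 300; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = eps * std::fabs(x) + 1e-12;
    const double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(eprev) > tol1) {
      const double rr = (x - wv) * (fx - fv);
      double qq = (x - v) * (fx - fw);
      double pp = (x - v) * qq - (x - wv) * rr;
      qq = 2.0 * (qq - rr);
      if (qq > 0.0) pp = -pp;
      qq = std::fabs(qq);
      const double etemp = eprev;
      eprev = d;
      if (std::fabs(pp) < std::fabs(0.5 * qq * etemp) && pp > qq * (a - x) && pp < qq * (b - x)) {
        d = pp / qq;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      eprev = (x >= xm) ? a - x : b - x;
      d = gold * eprev;
    }
    const double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    const double fu = nll(u, evtmp);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = wv; fv = fw; wv = x; fw = fx; x = u; fx = fu; evx = evtmp;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wv == x) { v = wv; fv = fw; wv = u; fw = fu; }
      else if (fu <= fv || v == x || v == wv) { v = u; fv = fu; }
    }
  }

  // gradient at zero decides boundary behaviour
  ProfileEval ev0 = profile_eval(bl, st, 0.0);
  if (!ev0.ok) return res;
  res.grad_at_zero = profile_grad(bl, st, ev0);

  if (res.grad_at_zero <= 0.0 && (x <= 1e-8 || -ev0.loglik <= fx)) {
    // optimum clamped at (or indistinguishable from) theta = 0
    res.ev = ev0;
    const double scale = std::fabs(res.grad_at_zero) * ev0.sigma2 / std::max(1, bl.n - bl.p);
    res.boundary = scale > 1e-8;   // knife-edge stationary optima are interior
    res.converged = true;
    return res;
  }

  // polish: bracket the root of the analytic profile gradient around Brent's
  // minimiser (the numerically flat likelihood can leave Brent's interval
  // slightly off the true stationary point), then Illinois false position.
  auto grad_at = [&](double th, ProfileEval& hold) {
    hold = profile_eval(bl, st, th);
    return hold.ok ? profile_grad(bl, st, hold) : arma::datum::nan;
  };
  double cur = x;
  ProfileEval evcur = evx;
  double gcur = profile_grad(bl, st, evcur);
  double lo, hi, glo, ghi;
  ProfileEval evside;
  bool bracket = false;
  double step = std::max(1e-6 * (1.0 + x), 1e-9);
  if (gcur > 0) {
    lo = x; glo = gcur;
    hi = x;
    for (int it = 0; it < 80; ++it) {
      hi = std::min(theta_max, hi + step);
      step *= 4.0;
      ghi = grad_at(hi, evside);
      if (!std::isfinite(ghi)) break;
      if (ghi <= 0) { bracket = true; break; }
      lo = hi; glo = ghi;
      if (hi >= theta_max) break;
    }
  } else {
    hi = x; ghi = gcur;
    lo = x;
    for (int it = 0; it < 80; ++it) {
      lo = std::max(0.0, lo - step);
      step *= 4.0;
      glo = grad_at(lo, evside);
      if (!std::isfinite(glo)) break;
      if (glo >= 0) { bracket = true; break; }
      hi = lo; ghi = glo;
      if (lo <= 0.0) break;
    }
  }
  if (bracket) {
    int side = 0;
    for (int it = 0; it < 200; ++it) {
      if (hi - lo < 1e-15 * (1.0 + hi)) break;
      double nxt = (ghi != glo) ? lo + (hi - lo) * glo / (glo - ghi)
                                : 0.5 * (lo + hi);
      if (!(nxt > lo && nxt < hi)) nxt = 0.5 * (lo + hi);
      ProfileEval evn;
      double gn = grad_at(nxt, evn);
      if (!std::isfinite(gn)) break;
      if (std::fabs(gn) < std::fabs(gcur)) { cur = nxt; evcur = evn; gcur = gn; }
      if (gn == 0.0) break;
      if (gn > 0) {
        lo = nxt; glo = gn;
        if (side == 1) ghi *= 0.5;   // Illinois modification
        side = 1;
      } else {
        hi = nxt; ghi = gn;
        if (side == -1) glo *= 0.5;
        side = -1;
      }
    }
    if (evcur.loglik >= evx.loglik - 1e-10 * (1.0 + std::fabs(evx.loglik))) evx = evcur;
  }
  res.ev = evx;
  res.converged = true;
  res.boundary = false;
  return res;
}

} // namespace

// [[Rcpp::export]]
NumericVector lmm_profile_loglik_cpp(NumericVector y, NumericVector w,
                                     NumericMatrix X, IntegerVector grp,
                                     NumericVector thetas) {
  Blocks bl = make_blocks(as<arma::mat>(X), grp);
  GeneStats st = gene_stats(bl, as<arma::vec>(y), as<arma::vec>(w));
  NumericVector out(thetas.size());
  for (int i = 0; i < thetas.size(); ++i) {
    ProfileEval ev = profile_eval(bl, st, thetas[i]);
    out[i] = ev.ok ? ev.loglik : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
List lmm_fit_one_cpp(NumericVector y, NumericVector w, NumericMatrix X,
                     IntegerVector grp, double theta_max) {
  Blocks bl = make_blocks(as<arma::mat>(X), grp);
  GeneStats st = gene_stats(bl, as<arma::vec>(y), as<arma::vec>(w));
  OptOut opt = optimise_theta(bl, st, theta_max);
  const int p = bl.p;
  if (!opt.converged) {
    return List::create(_["converged"] = false);
  }
  const ProfileEval& ev = opt.ev;
  arma::mat covb = ev.sigma2 * ev.Ainv_t;
  std::vector<int> coefs(p);
  for (int j = 0; j < p; ++j) coefs[j] = j;
  arma::vec dfs(p);
  bool info_ok = true;
  if (opt.boundary) {
    dfs.fill((double)(bl.n - p));
  } else {
    SattOut so = satterthwaite(bl, st, ev, coefs);
    dfs = so.df;
    info_ok = so.info_ok;
    if (!info_ok) for (int j = 0; j < p; ++j) if (!std::isfinite(dfs[j])) dfs[j] = bl.n - p;
  }
  arma::vec se = arma::sqrt(covb.diag());
  arma::vec tv = ev.beta / se, pv(p);
  for (int j = 0; j < p; ++j) pv[j] = 2.0 * R::pt(-std::fabs(tv[j]), dfs[j], 1, 0);

  // BLUPs and conditional residuals
  arma::vec r = st.y - bl.X * ev.beta;
  arma::vec blup(bl.B, arma::fill::zeros);
  for (int b = 0; b < bl.B; ++b) {
    double wr = 0.0;
    for (int i : bl.idx[b]) wr += st.w[i] * r[i];
    blup[b] = ev.theta / (1.0 + ev.theta * st.sw[b]) * wr;
  }
  arma::vec rcond(bl.n);
  for (int b = 0; b < bl.B; ++b) for (int i : bl.idx[b]) rcond[i] = r[i] - blup[b];

  return List::create(
    _["beta"] = ev.beta, _["cov_beta"] = covb, _["se"] = se, _["t"] = tv,
    _["df"] = dfs, _["p"] = pv, _["sigma2"] = ev.sigma2,
    _["tau2"] = ev.theta * ev.sigma2, _["theta"] = ev.theta,
    _["reml_loglik"] = ev.loglik, _["boundary"] = opt.boundary,
    _["converged"] = true, _["info_ok"] = info_ok,
    _["grad_at_zero"] = opt.grad_at_zero,
    _["blup"] = blup, _["resid_conditional"] = rcond,
    _["n_obs"] = bl.n, _["n_groups"] = bl.B);
}

// [[Rcpp::export]]
List lmm_fit_batch_cpp(NumericMatrix Y, NumericMatrix W, NumericMatrix X,
                       IntegerVector grp, int coef, double theta_max,
                       bool want_resid) {
  const int G = Y.nrow(), n = Y.ncol();
  Blocks bl = make_blocks(as<arma::mat>(X), grp);
  const int p = bl.p;
  NumericVector beta(G, NA_REAL), se(G, NA_REAL), tv(G, NA_REAL), dfv(G, NA_REAL),
      pv(G, NA_REAL), sig2(G, NA_REAL), tau2(G, NA_REAL), ll(G, NA_REAL);
  LogicalVector conv(G), bound(G);
  NumericMatrix rcond;
  if (want_resid) rcond = NumericMatrix(G, n);
  std::vector<int> coefs = {coef};

  arma::vec y(n), w(n);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) { y[i] = Y(g, i); w[i] = W(g, i); }
    GeneStats st = gene_stats(bl, y, w);
    OptOut opt = optimise_theta(bl, st, theta_max);
    conv[g] = opt.converged;
    if (!opt.converged) continue;
    const ProfileEval& ev = opt.ev;
    bound[g] = opt.boundary;
    const double sej = std::sqrt(ev.sigma2 * ev.Ainv_t(coef, coef));
    double dfj;
    if (opt.boundary) dfj = n - p;
    else {
      SattOut so = satterthwaite(bl, st, ev, coefs);
      dfj = std::isfinite(so.df[0]) ? so.df[0] : (double)(n - p);
    }
    beta[g] = ev.beta[coef];
    se[g] = sej;
    tv[g] = ev.beta[coef] / sej;
    dfv[g] = dfj;
    pv[g] = 2.0 * R::pt(-std::fabs(tv[g]), dfj, 1, 0);
    sig2[g] = ev.sigma2;
    tau2[g] = ev.theta * ev.sigma2;
    ll[g] = ev.loglik;
    if (want_resid) {
      arma::vec r = y - bl.X * ev.beta;
      for (int b = 0; b < bl.B; ++b) {
        double wr = 0.0;
        for (int i : bl.idx[b]) wr += w[i] * r[i];
        const double blup = ev.theta / (1.0 + ev.theta * st.sw[b]) * wr;
        for (int i : bl.idx[b]) rcond(g, i) = r[i] - blup;
      }
    }
  }
  List out = List::create(
    _["coef"] = beta, _["se"] = se, _["t"] = tv, _["df"] = dfv, _["p"] = pv,
    _["sigma2"] = sig2, _["tau2"] = tau2, _["reml_loglik"] = ll,
    _["converged"] = conv, _["boundary"] = bound);
  if (want_resid) out["resid_conditional"] = rcond;
  return out;
}
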