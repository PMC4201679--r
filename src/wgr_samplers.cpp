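// Single-site Gibbs samplers for whole-genome regression:
//  - Bayesian LASSO via the exponential scale-mixture representation of the
//    double-exponential prior (per-marker latent variances with
//    inverse-Gaussian full conditionals; rate parameter lambda with a
//    uniform prior sampled from its truncated-Gamma full conditional);
//  - four-component normal-mixture prior with fixed mixing proportions,
//    component indicators drawn from their collapsed multinomial
//    conditionals and component variances from scaled-inverse-chi-square
//    conditionals, order-enforced each cycle.
// Fixed effects get flat priors; the residual variance a flat
// scaled-inverse-chi-square (nu = -2, scale 0). All randomness comes from
// R's RNG so set.seed() governs the chains.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (!(x > 0.0)) x = std::numeric_limits<double>::min();
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gamma(shape, rate) truncated to (0, upper], by inverse CDF.
static double rtgamma_upper(double shape, double rate, double upper) {
  double pu = R::pgamma(upper, shape, 1.0 / rate, 1, 0);
  if (pu <= 0.0) return upper;
  double x = R::qgamma(unif_rand() * pu, shape, 1.0 / rate, 1, 0);
  if (!(x > 0.0)) x = std::numeric_limits<double>::min();
  if (x > upper) x = upper;
  return x;
}

// [[Rcpp::export]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                   std::string model, int n_iter, int burnin, int thin,
                   List ctrl) {
  const int n = y.size();
  const int p = X.ncol();
  const int k = M.ncol();
  if (M.nrow() != n || (p > 0 && X.nrow() != n))
    stop("design dimensions do not match y");
  if (burnin >= n_iter || thin < 1) stop("invalid chain schedule");
  const bool lasso = (model == "lasso");
  if (!lasso && model != "mix4") stop("unknown model kind");

  RNGScope rng;

  // precomputed cross-products
  std::vector<double> xtx(p), mtm(k);
  for (int l = 0; l < p; ++l) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, l) * X(i, l);
    xtx[l] = s;
  }
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    const double *mj = &M(0, j);
    for (int i = 0; i < n; ++i) s += mj[i] * mj[i];
    mtm[j] = s;
  }

  // state
  std::vector<double> b(p, 0.0), q(k, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);

  double se2 = as<double>(ctrl["sigma_e2_init"]);
  const bool upd_se2 = as<bool>(ctrl["update_sigma_e2"]);

  // lasso state
  double lambda = 0.0, lambda_max = 0.0;
  bool upd_lambda = true;
  int lambda_freeze = 0;
  std::vector<double> tau2;
  // mix4 state
  NumericVector pi4, scale4;
  double df0 = 4.2;
  bool upd_vars = true;
  std::vector<double> v4(4, 0.0);
  std::vector<int> comp;
  if (lasso) {
    lambda = as<double>(ctrl["lambda_init"]);
    lambda_max = as<double>(ctrl["lambda_max"]);
    upd_lambda = as<bool>(ctrl["update_lambda"]);
    lambda_freeze = as<int>(ctrl["lambda_freeze"]);
    tau2.assign(k, 1.0 / std::max(lambda * lambda, 1e-12));
  } else {
    pi4 = as<NumericVector>(ctrl["pi"]);
    scale4 = as<NumericVector>(ctrl["scale"]);
    df0 = as<double>(ctrl["df0"]);
    upd_vars = as<bool>(ctrl["update_component_vars"]);
    NumericVector v0 = as<NumericVector>(ctrl["var_init"]);
    for (int c = 0; c < 4; ++c) v4[c] = v0[c];
    comp.assign(k, 0);
  }

  // accumulators over saved samples
  const int n_saved_exp = (n_iter - burnin) / thin;
  std::vector<double> q_sum(k, 0.0), b_sum(p, 0.0);
  NumericVector se2_trace(n_saved_exp);
  NumericVector lambda_trace(lasso ? n_saved_exp : 0);
  NumericMatrix v4_trace(lasso ? 0 : n_saved_exp, lasso ? 0 : 4);
  NumericMatrix comp_count(lasso ? 0 : k, lasso ? 0 : 4);
  int n_saved = 0;

  for (int cyc = 1; cyc <= n_iter; ++cyc) {
    // fixed effects, coordinate-wise, flat prior
    for (int l = 0; l < p; ++l) {
      if (xtx[l] <= 0.0) continue;
      const double *xl = &X(0, l);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xl[i] * e[i];
      rhs += xtx[l] * b[l];
      double bn = rhs / xtx[l] + std::sqrt(se2 / xtx[l]) * norm_rand();
      double d = bn - b[l];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= xl[i] * d;
      b[l] = bn;
    }

    // marker effects
    if (lasso) {
      for (int j = 0; j < k; ++j) {
        if (mtm[j] <= 0.0) continue;
        const double *mj = &M(0, j);
        double rhs = 0.0;
        for (int i = 0; i < n; ++i) rhs += mj[i] * e[i];
        rhs += mtm[j] * q[j];
        double cc = mtm[j] + se2 / tau2[j];
        double qn = rhs / cc + std::sqrt(se2 / cc) * norm_rand();
        double d = qn - q[j];
        if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= mj[i] * d;
        q[j] = qn;
        // latent variance: 1/tau2 | q ~ InvGauss(lambda/|q|, lambda^2)
        double aq = std::fabs(q[j]);
        double mu = lambda / std::max(aq, 1e-12);
        if (mu > 1e10) mu = 1e10;
        tau2[j] = 1.0 / rinvgauss(mu, lambda * lambda);
      }
      // lambda is held at its start value for the first lambda_freeze
      // cycles (a warm start: effects grow to data-supported magnitudes
      // before the rate parameter is released, keeping the chain out of
      // the degenerate all-shrunk regime of the uniform-prior
      // parameterisation, where the marginal posterior of lambda is flat)
      if (upd_lambda && cyc > lambda_freeze) {
        double sabs = 0.0;
        for (int j = 0; j < k; ++j) sabs += std::fabs(q[j]);
        lambda = rtgamma_upper(k + 1.0, std::max(sabs, 1e-12), lambda_max);
        // joint rescaling Metropolis move (q, tau2, lambda) ->
        // (c q, c^2 tau2, lambda / c), c = e^z with z symmetric about 0.
        // The posterior-times-Jacobian ratio reduces to exp(dloglik - z).
        // Single-site updates mix very slowly along this scale direction
        // (the treadmill between the data-supported and the all-shrunk
        // regime); this move crosses it in one step and leaves the
        // stationary distribution unchanged.
        double z = (unif_rand() * 2.0 - 1.0) * 1.5;
        double c = std::exp(z);
        if (lambda / c <= lambda_max) {
          // genomic part g = M q = y - X b - e, so e' = e - (c - 1) g
          double sse_old = 0.0, sse_new = 0.0;
          std::vector<double> xb(n, 0.0);
          for (int l = 0; l < p; ++l) {
            const double *xl = &X(0, l);
            for (int i = 0; i < n; ++i) xb[i] += xl[i] * b[l];
          }
          for (int i = 0; i < n; ++i) {
            double g = y[i] - xb[i] - e[i];
            double en = e[i] - (c - 1.0) * g;
            sse_old += e[i] * e[i];
            sse_new += en * en;
          }
          double dll = -(sse_new - sse_old) / (2.0 * se2);
          if (std::log(unif_rand()) < dll - z) {
            for (int j = 0; j < k; ++j) {
              q[j] *= c;
              tau2[j] *= c * c;
            }
            lambda /= c;
            for (int i = 0; i < n; ++i) {
              double g = y[i] - xb[i] - e[i];
              e[i] -= (c - 1.0) * g;
            }
          }
        }
      }
    } else {
      for (int j = 0; j < k; ++j) {
        if (mtm[j] <= 0.0) continue;
        const double *mj = &M(0, j);
        double rhs = 0.0;
        for (int i = 0; i < n; ++i) rhs += mj[i] * e[i];
        rhs += mtm[j] * q[j];
        // collapsed indicator draw: rhs | comp ~ N(0, mtm^2 v_c + mtm se2)
        double logw[4], mx = -INFINITY;
        for (int c = 0; c < 4; ++c) {
          double w = mtm[j] * mtm[j] * v4[c] + mtm[j] * se2;
          logw[c] = std::log(pi4[c]) - 0.5 * std::log(w) -
                    0.5 * rhs * rhs / w;
          if (logw[c] > mx) mx = logw[c];
        }
        double tot = 0.0, pr[4];
        for (int c = 0; c < 4; ++c) { pr[c] = std::exp(logw[c] - mx); tot += pr[c]; }
        double u = unif_rand() * tot, acc = 0.0;
        int cj = 3;
        for (int c = 0; c < 4; ++c) { acc += pr[c]; if (u <= acc) { cj = c; break; } }
        comp[j] = cj;
        double cc = mtm[j] + se2 / v4[cj];
        double qn = rhs / cc + std::sqrt(se2 / cc) * norm_rand();
        double d = qn - q[j];
        if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= mj[i] * d;
        q[j] = qn;
      }
      if (upd_vars) {
        double ssq[4] = {0, 0, 0, 0};
        int cnt[4] = {0, 0, 0, 0};
        for (int j = 0; j < k; ++j) {
          if (mtm[j] <= 0.0) continue;
          ssq[comp[j]] += q[j] * q[j];
          ++cnt[comp[j]];
        }
        for (int c = 0; c < 4; ++c) {
          double df = df0 + cnt[c];
          double sc = df0 * scale4[c] + ssq[c];
          v4[c] = sc / R::rchisq(df);
        }
        // enforce the ordering pi1 <-> smallest variance by sorting and
        // remapping indicators
        int ord[4] = {0, 1, 2, 3};
        std::sort(ord, ord + 4, [&](int a, int bb) { return v4[a] < v4[bb]; });
        double vs[4]; int rank[4];
        for (int r = 0; r < 4; ++r) { vs[r] = v4[ord[r]]; rank[ord[r]] = r; }
        for (int c = 0; c < 4; ++c) v4[c] = vs[c];
        for (int j = 0; j < k; ++j) comp[j] = rank[comp[j]];
      }
    }

    // residual variance: flat scaled-inv-chi-square (nu = -2, S = 0)
    if (upd_se2) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      se2 = sse / R::rchisq((double)(n - 2));
    }
    if (!R_finite(se2) || se2 > 1e12 * std::max(vy, 1e-300)) {
      stop("residual variance diverged at cycle %d (sigma_e2 = %g)", cyc, se2);
    }

    // save
    if (cyc > burnin && (cyc - burnin) % thin == 0) {
      for (int j = 0; j < k; ++j) q_sum[j] += q[j];
      for (int l = 0; l < p; ++l) b_sum[l] += b[l];
      se2_trace[n_saved] = se2;
      if (lasso) {
        lambda_trace[n_saved] = lambda;
      } else {
        for (int c = 0; c < 4; ++c) v4_trace(n_saved, c) = v4[c];
        for (int j = 0; j < k; ++j) comp_count(j, comp[j]) += 1.0;
      }
      ++n_saved;
    }
  }

  NumericVector qhat(k), bhat(p);
  for (int j = 0; j < k; ++j) qhat[j] = q_sum[j] / std::max(n_saved, 1);
  for (int l = 0; l < p; ++l) bhat[l] = b_sum[l] / std::max(n_saved, 1);

  List out = List::create(
      _["qhat"] = qhat, _["bhat"] = bhat, _["sigma_e2_trace"] = se2_trace,
      _["n_saved"] = n_saved);
  if (lasso) {
    out["lambda_trace"] = lambda_trace;
  } else {
    out["component_var_trace"] = v4_trace;
    NumericMatrix cp(k, 4);
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < 4; ++c)
        cp(j, c) = comp_count(j, c) / std::max(n_saved, 1);
    out["component_prob"] = cp;
  }
  return out;
}
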