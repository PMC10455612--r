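// Core numerical kernels and the MCMC chain runner for the MGGUM.
//
// All category-probability work is done in log space with max-subtraction so
// that |alpha * (theta - delta)| up to ~50 stays finite.  The sampler is an
// adaptive Metropolis-within-Gibbs scheme: random-walk updates for person
// traits, item parameters and trait correlations, and a conjugate Gibbs draw
// for the latent-regression coefficients.  All randomness comes from R's RNG
// (norm_rand / unif_rand), so set.seed() in R makes a chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int MAX_CAT = 16; // categories 0..C, C < MAX_CAT

static inline double lse2(double a, double b) {
  double m = (a > b) ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log P[Z = z | .] for z = 0..C of the unidimensional graded unfolding kernel.
// u = theta - delta; ct[z] = sum_{k=1}^{z} tau_k (ct[0] = 0).
static void ggum_logprobs_u(double alpha, double u, const double *ct, int C,
                            double *out) {
  const int M = 2 * C + 1;
  double mx = -std::numeric_limits<double>::infinity();
  for (int z = 0; z <= C; ++z) {
    double l1 = alpha * (z * u - ct[z]);
    double l2 = alpha * ((M - z) * u - ct[z]);
    out[z] = lse2(l1, l2);
    if (out[z] > mx) mx = out[z];
  }
  double s = 0.0;
  for (int z = 0; z <= C; ++z) s += std::exp(out[z] - mx);
  const double ld = mx + std::log(s);
  for (int z = 0; z <= C; ++z) out[z] -= ld;
}

// log P[Z = z_obs | .] for a single observed category.
static inline double cell_ll(double alpha, double u, const double *ct, int C,
                             int z_obs) {
  double buf[MAX_CAT];
  ggum_logprobs_u(alpha, u, ct, C, buf);
  return buf[z_obs];
}

// [[Rcpp::export]]
NumericVector cpp_ggum_probs(double theta, double alpha, double delta,
                             NumericVector tau) {
  const int C = tau.size();
  if (C >= MAX_CAT) stop("too many response categories");
  double ct[MAX_CAT + 1];
  ct[0] = 0.0;
  for (int k = 1; k <= C; ++k) ct[k] = ct[k - 1] + tau[k - 1];
  double buf[MAX_CAT];
  ggum_logprobs_u(alpha, theta - delta, ct, C, buf);
  NumericVector out(C + 1);
  for (int z = 0; z <= C; ++z) out[z] = std::exp(buf[z]);
  return out;
}

// Pointwise log-likelihood over all non-missing cells (row-major cell order:
// person 1 items, person 2 items, ...).  Z uses NA_INTEGER for missing.
// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(IntegerMatrix Z, NumericMatrix theta,
                                   IntegerVector item_dim, NumericVector alpha,
                                   NumericVector delta, NumericMatrix tau) {
  const int J = Z.nrow(), I = Z.ncol(), C = tau.ncol();
  std::vector<double> ct(I * (C + 1));
  for (int i = 0; i < I; ++i) {
    ct[i * (C + 1)] = 0.0;
    for (int k = 1; k <= C; ++k)
      ct[i * (C + 1) + k] = ct[i * (C + 1) + k - 1] + tau(i, k - 1);
  }
  std::vector<double> out;
  out.reserve((size_t)J * I);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) {
      int z = Z(j, i);
      if (z == NA_INTEGER) continue;
      double u = theta(j, item_dim[i]) - delta[i];
      out.push_back(cell_ll(alpha[i], u, &ct[i * (C + 1)], C, z));
    }
  return wrap(out);
}

// Draw one response matrix given persons and items (uses R's RNG).
// [[Rcpp::export]]
IntegerMatrix cpp_generate_responses(NumericMatrix theta, IntegerVector item_dim,
                                     NumericVector alpha, NumericVector delta,
                                     NumericMatrix tau) {
  const int J = theta.nrow(), I = alpha.size(), C = tau.ncol();
  IntegerMatrix Z(J, I);
  double ct[MAX_CAT + 1], buf[MAX_CAT];
  for (int i = 0; i < I; ++i) {
    ct[0] = 0.0;
    for (int k = 1; k <= C; ++k) ct[k] = ct[k - 1] + tau(i, k - 1);
    for (int j = 0; j < J; ++j) {
      double u = theta(j, item_dim[i]) - delta[i];
      ggum_logprobs_u(alpha[i], u, ct, C, buf);
      double r = unif_rand(), acc = 0.0;
      int z = C;
      for (int w = 0; w <= C; ++w) {
        acc += std::exp(buf[w]);
        if (r <= acc) { z = w; break; }
      }
      Z(j, i) = z;
    }
  }
  return Z;
}

// ---------------------------------------------------------------------------
// MCMC chain runner
// ---------------------------------------------------------------------------

struct AdaptStep {
  double ls;      // log step size
  int n_prop, n_acc;
  double target;
  AdaptStep(double step = 0.2, double target_ = 0.44)
      : ls(std::log(step)), n_prop(0), n_acc(0), target(target_) {}
  double step() const { return std::exp(ls); }
  void tally(bool acc) { ++n_prop; if (acc) ++n_acc; }
  void adapt() {
    if (n_prop == 0) return;
    double rate = (double)n_acc / n_prop;
    double d = rate - target;
    if (d > 0.5) d = 0.5;
    if (d < -0.5) d = -0.5;
    ls += d;
    if (ls < -6.0) ls = -6.0;
    if (ls > 3.0) ls = 3.0;
    n_prop = n_acc = 0;
  }
};

// Haario-style adaptive state for one item's joint parameter block
// x = (log alpha, delta, tau_1..tau_C).  During burn-in the empirical
// covariance of the visited states is accumulated and used (scaled by
// 2.38^2/q and an adapted log scale factor) as the random-walk proposal
// covariance; adaptation is frozen at the end of burn-in.
struct BlockAdapt {
  int q, n;
  arma::vec mean, diag0;
  arma::mat M2, L;
  double lsc;
  int n_prop, n_acc;
  bool use_cov;
  void init(int q_, const arma::vec &diag_steps) {
    q = q_; n = 0; mean.zeros(q); M2.zeros(q, q);
    diag0 = diag_steps; lsc = 0.0; n_prop = n_acc = 0; use_cov = false;
  }
  void accumulate(const arma::vec &x) {
    ++n;
    arma::vec d = x - mean;
    mean += d / n;
    M2 += d * (x - mean).t();
  }
  void refresh_chol() {
    if (n < 50) return;
    arma::mat S = M2 / (n - 1);
    S.diag() += 1e-8;
    arma::mat Lc;
    if (arma::chol(Lc, S, "lower")) { L = Lc; use_cov = true; }
  }
  arma::vec propose(const arma::vec &x) {
    arma::vec z(q);
    for (int k = 0; k < q; ++k) z(k) = norm_rand();
    double sc = std::exp(lsc);
    double u = unif_rand();
    // mode-jumping reflection through the running mean: if the block
    // posterior is bimodal the reflection maps one mode near the other,
    // and the move is symmetric because the reflection is an involution
    if (u < 0.05 && n >= 100)
      return 2.0 * mean - x + 0.3 * sc * (diag0 % z);
    // occasional over-dispersed proposal to traverse between local modes
    if (u < 0.15) sc *= 3.0;
    if (use_cov) return x + sc * (2.38 / std::sqrt((double)q)) * (L * z);
    return x + sc * (diag0 % z);
  }
  void tally(bool acc) { ++n_prop; if (acc) ++n_acc; }
  void adapt_scale(double target) {
    if (n_prop == 0) return;
    double d = (double)n_acc / n_prop - target;
    if (d > 0.5) d = 0.5;
    if (d < -0.5) d = -0.5;
    lsc += d;
    if (lsc < -4.0) lsc = -4.0;
    if (lsc > 2.0) lsc = 2.0;
    n_prop = n_acc = 0;
    refresh_chol();
  }
};

// [[Rcpp::export]]
List cpp_run_chain(IntegerMatrix Z, IntegerVector item_dim,
                   IntegerVector direction, arma::mat X, int C,
                   int n_iter, int n_burn,
                   NumericVector tau_prior_mean, double tau_prior_sd,
                   double alpha_logmean, double alpha_logsd,
                   NumericVector delta_prior_mean, double delta_prior_sd,
                   double beta_prior_sd,
                   arma::vec alpha0, arma::vec delta0, arma::mat tau0,
                   arma::mat theta0, arma::mat beta0, arma::mat omega0,
                   int n_person_scans, int n_item_scans, int n_warmup_extra,
                   bool store_loglik) {
  RNGScope scope;
  const int J = Z.nrow(), I = Z.ncol(), D = omega0.n_rows;
  const int P = X.n_cols;
  const bool has_cov = (P > 0);
  const int S = n_iter - n_burn;
  const int burn_total = n_burn + n_warmup_extra;   // adaptation window
  const int iter_total = n_iter + n_warmup_extra;
  if (C >= MAX_CAT) stop("too many response categories");

  std::vector<std::vector<int>> by_item(I), by_person(J);
  int n_cells = 0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i)
      if (Z(j, i) != NA_INTEGER) {
        by_item[i].push_back(j);
        by_person[j].push_back(i);
        ++n_cells;
      }

  // state
  arma::vec alpha = alpha0, delta = delta0;
  arma::mat tau = tau0;     // I x C
  arma::mat theta = theta0; // J x D
  arma::mat beta = beta0;   // P x D
  arma::mat omega = omega0; // D x D correlation
  arma::mat omega_inv = arma::inv_sympd(omega);
  double omega_logdet = std::log(arma::det(omega));
  arma::mat mu(J, D, arma::fill::zeros);
  if (has_cov) mu = X * beta;
  arma::mat XtX;
  if (has_cov) XtX = X.t() * X;

  // cumulative thresholds, contiguous per item
  std::vector<double> ctv(I * (C + 1));
  auto refresh_ct = [&](int i) {
    ctv[i * (C + 1)] = 0.0;
    for (int k = 1; k <= C; ++k)
      ctv[i * (C + 1) + k] = ctv[i * (C + 1) + k - 1] + tau(i, k - 1);
  };
  for (int i = 0; i < I; ++i) refresh_ct(i);

  // cached per-cell log-likelihood under the current state
  arma::mat llcell(J, I, arma::fill::zeros);
  for (int i = 0; i < I; ++i)
    for (int j : by_item[i])
      llcell(j, i) = cell_ll(alpha[i], theta(j, item_dim[i]) - delta[i],
                             &ctv[i * (C + 1)], C, Z(j, i));

  // adaptation state
  const int q = 2 + C;
  arma::vec diag_steps(q);
  diag_steps(0) = 0.10; diag_steps(1) = 0.15;
  for (int k = 0; k < C; ++k) diag_steps(2 + k) = 0.20;
  std::vector<BlockAdapt> st_item(I);
  for (int i = 0; i < I; ++i) st_item[i].init(q, diag_steps);
  const int n_pair = D * (D - 1) / 2;
  std::vector<AdaptStep> st_omega(n_pair, AdaptStep(0.10, 0.30));

  // draw storage
  arma::mat d_alpha(S, I), d_delta(S, I), d_tau(S, I * C);
  arma::mat d_theta(S, J * D);
  arma::mat d_beta(S, has_cov ? P * D : 1, arma::fill::zeros);
  arma::mat d_omega(S, n_pair > 0 ? n_pair : 1, arma::fill::zeros);
  arma::mat d_ll;
  if (store_loglik) d_ll.set_size(S, n_cells);

  std::vector<double> rowbuf(I), colbuf_v(J);

  for (int it = 0; it < iter_total; ++it) {
    const bool burn = (it < burn_total);

    // --- persons: coordinate-wise slice sampling ----------------------------
    // Conditional on everything else, theta_jd has a log-concave-ish target:
    // the likelihood of that dimension's observed items plus the normal
    // conditional prior given the other coordinates.  Slice sampling with
    // stepping-out needs no tuning and yields nearly uncorrelated draws.
    for (int scan = 0; scan < n_person_scans; ++scan) {
      for (int j = 0; j < J; ++j) {
        for (int d = 0; d < D; ++d) {
          const double prec = omega_inv(d, d);
          double shift = 0.0;
          for (int e = 0; e < D; ++e)
            if (e != d) shift += omega_inv(d, e) * (theta(j, e) - mu(j, e));
          const double cmean = mu(j, d) - shift / prec;
          auto f = [&](double t) {
            double s = -0.5 * prec * (t - cmean) * (t - cmean);
            for (int i : by_person[j]) {
              if (item_dim[i] != d) continue;
              s += cell_ll(alpha[i], t - delta[i], &ctv[i * (C + 1)], C,
                           Z(j, i));
            }
            return s;
          };
          const double x0 = theta(j, d);
          const double logy = f(x0) - (-std::log(unif_rand()));
          const double w = 0.9;
          double Lb = x0 - w * unif_rand(), Rb = Lb + w;
          for (int s = 0; s < 8 && f(Lb) > logy; ++s) Lb -= w;
          for (int s = 0; s < 8 && f(Rb) > logy; ++s) Rb += w;
          double t = x0;
          for (int s = 0; s < 100; ++s) {
            t = Lb + unif_rand() * (Rb - Lb);
            if (f(t) > logy) break;
            if (t < x0) Lb = t; else Rb = t;
            if (s == 99) t = x0; // numerically stuck: keep current value
          }
          if (t != x0) {
            theta(j, d) = t;
            for (int i : by_person[j])
              if (item_dim[i] == d)
                llcell(j, i) = cell_ll(alpha[i], t - delta[i],
                                       &ctv[i * (C + 1)], C, Z(j, i));
          }
        }
      }
    }

    // --- persons: independence proposal from the trait prior ----------------
    // The posterior of a single theta_j can be bimodal (a low-agreement
    // response pattern fits on either side of the item locations), which a
    // local random walk cannot traverse.  Proposing from MVN(mu_j, omega)
    // makes the prior cancel in the Metropolis ratio, so acceptance depends
    // on the data term alone and distant modes remain reachable.
    {
      arma::mat Lom = arma::chol(omega, "lower");
      for (int j = 0; j < J; ++j) {
        arma::vec z(D);
        for (int d = 0; d < D; ++d) z(d) = norm_rand();
        arma::vec tp = Lom * z;
        for (int d = 0; d < D; ++d) tp(d) += mu(j, d);
        double ll_new = 0.0, ll_cur = 0.0;
        for (int i : by_person[j]) {
          rowbuf[i] = cell_ll(alpha[i], tp(item_dim[i]) - delta[i],
                              &ctv[i * (C + 1)], C, Z(j, i));
          ll_new += rowbuf[i];
          ll_cur += llcell(j, i);
        }
        double la = ll_new - ll_cur;
        if (la >= 0.0 || std::log(unif_rand()) < la) {
          for (int d = 0; d < D; ++d) theta(j, d) = tp(d);
          for (int i : by_person[j]) llcell(j, i) = rowbuf[i];
        }
      }
    }

    // --- items: joint adaptive block over (log alpha, delta, psi) -----------
    // psi_k = alpha * tau_k is the natural threshold parameter of the
    // kernel's exponent; in (alpha, tau) the posterior lies on a hyperbolic
    // ridge (tau ~ 1/alpha) that defeats Gaussian proposals, while in
    // (log alpha, delta, psi) it is close to elliptical.  The tau priors are
    // evaluated at tau = psi / alpha with the change-of-variables term
    // -C log alpha.
    for (int scan = 0; scan < n_item_scans; ++scan) {
      for (int i = 0; i < I; ++i) {
        arma::vec x(q);
        x(0) = std::log(alpha[i]);
        x(1) = delta[i];
        for (int k = 0; k < C; ++k) x(2 + k) = alpha[i] * tau(i, k);
        arma::vec xp = st_item[i].propose(x);
        bool ok = !((direction[i] > 0 && xp(1) < 0.0) ||
                    (direction[i] < 0 && xp(1) > 0.0));
        bool acc = false;
        if (ok) {
          double ap = std::exp(xp(0)), dp = xp(1);
          double tp[MAX_CAT], ctp[MAX_CAT + 1];
          ctp[0] = 0.0;
          for (int k = 0; k < C; ++k) {
            tp[k] = xp(2 + k) / ap;
            ctp[k + 1] = ctp[k] + tp[k];
          }
          const int dim = item_dim[i];
          double ll_new = 0.0, ll_cur = 0.0;
          for (int j : by_item[i]) {
            colbuf_v[j] = cell_ll(ap, theta(j, dim) - dp, ctp, C, Z(j, i));
            ll_new += colbuf_v[j];
            ll_cur += llcell(j, i);
          }
          double lpr = 0.0;
          lpr += (std::pow(x(0) - alpha_logmean, 2) -
                  std::pow(xp(0) - alpha_logmean, 2)) /
                 (2.0 * alpha_logsd * alpha_logsd);
          lpr += (std::pow(x(1) - delta_prior_mean[i], 2) -
                  std::pow(xp(1) - delta_prior_mean[i], 2)) /
                 (2.0 * delta_prior_sd * delta_prior_sd);
          for (int k = 0; k < C; ++k)
            lpr += (std::pow(tau(i, k) - tau_prior_mean[k], 2) -
                    std::pow(tp[k] - tau_prior_mean[k], 2)) /
                   (2.0 * tau_prior_sd * tau_prior_sd);
          lpr += C * (x(0) - xp(0)); // Jacobian of psi -> tau at each state
          double lr = ll_new - ll_cur + lpr;
          acc = (lr >= 0.0) || (std::log(unif_rand()) < lr);
          if (acc) {
            alpha[i] = ap;
            delta[i] = dp;
            for (int k = 0; k < C; ++k) tau(i, k) = tp[k];
            refresh_ct(i);
            for (int j : by_item[i]) llcell(j, i) = colbuf_v[j];
          }
        }
        if (burn) {
          st_item[i].tally(acc);
          if (scan == 0) {
            arma::vec xc(q);
            xc(0) = std::log(alpha[i]);
            xc(1) = delta[i];
            for (int k = 0; k < C; ++k) xc(2 + k) = alpha[i] * tau(i, k);
            st_item[i].accumulate(xc);
          }
        }
      }
    }

    // --- items: coordinate-wise slice sampling in (log alpha, delta, psi) ---
    // Binary and extreme-location items have long flat ridges in the item
    // posterior that random-walk proposals cross slowly; stepping-out slice
    // sampling expands to the ridge length automatically.  Run on alternate
    // iterations: the adaptive block updates cover the intervening ones.
    if (it % 2 == 0)
    for (int i = 0; i < I; ++i) {
      const int dim = item_dim[i];
      arma::vec x(q);
      x(0) = std::log(alpha[i]);
      x(1) = delta[i];
      for (int k = 0; k < C; ++k) x(2 + k) = alpha[i] * tau(i, k);
      auto g = [&](const arma::vec &xv) {
        if ((direction[i] > 0 && xv(1) < 0.0) ||
            (direction[i] < 0 && xv(1) > 0.0))
          return -std::numeric_limits<double>::infinity();
        double a = std::exp(xv(0)), dl = xv(1);
        double tv[MAX_CAT], ctp[MAX_CAT + 1];
        ctp[0] = 0.0;
        for (int k = 0; k < C; ++k) {
          tv[k] = xv(2 + k) / a;
          ctp[k + 1] = ctp[k] + tv[k];
        }
        double s = 0.0;
        for (int j : by_item[i])
          s += cell_ll(a, theta(j, dim) - dl, ctp, C, Z(j, i));
        s -= std::pow(xv(0) - alpha_logmean, 2) /
             (2.0 * alpha_logsd * alpha_logsd);
        s -= std::pow(xv(1) - delta_prior_mean[i], 2) /
             (2.0 * delta_prior_sd * delta_prior_sd);
        for (int k = 0; k < C; ++k)
          s -= std::pow(tv[k] - tau_prior_mean[k], 2) /
               (2.0 * tau_prior_sd * tau_prior_sd);
        s -= C * xv(0); // psi -> tau Jacobian
        return s;
      };
      double gcur = g(x); // carried across coordinates
      for (int c = 0; c < q; ++c) {
        const double x0 = x(c);
        const double logy = gcur + std::log(unif_rand());
        const double w = (c == 0) ? 0.5 : 0.8;
        arma::vec xt = x;
        double Lb = x0 - w * unif_rand(), Rb = Lb + w;
        for (int s = 0; s < 5; ++s) {
          xt(c) = Lb;
          if (!(g(xt) > logy)) break;
          Lb -= w;
        }
        for (int s = 0; s < 5; ++s) {
          xt(c) = Rb;
          if (!(g(xt) > logy)) break;
          Rb += w;
        }
        for (int s = 0; s < 100; ++s) {
          double t = Lb + unif_rand() * (Rb - Lb);
          xt(c) = t;
          double gt = g(xt);
          if (gt > logy) { x(c) = t; gcur = gt; break; }
          if (t < x0) Lb = t; else Rb = t;
          if (s == 99) xt(c) = x0;
        }
      }
      // write back and refresh caches
      alpha[i] = std::exp(x(0));
      delta[i] = x(1);
      for (int k = 0; k < C; ++k) tau(i, k) = x(2 + k) / alpha[i];
      refresh_ct(i);
      for (int j : by_item[i])
        llcell(j, i) = cell_ll(alpha[i], theta(j, dim) - delta[i],
                               &ctv[i * (C + 1)], C, Z(j, i));
    }

    // --- threshold swap moves -----------------------------------------------
    // Swapping two adjacent thresholds changes only one cumulative sum, so
    // distinct tau orderings can fit almost equally well (a label-switching
    // near-symmetry).  An explicit swap proposal (a symmetric involution)
    // lets the chain hop between those configurations.
    if (C > 1) {
      for (int i = 0; i < I; ++i) {
        int k = (int)(unif_rand() * (C - 1));
        if (k > C - 2) k = C - 2;
        double t1 = tau(i, k), t2 = tau(i, k + 1);
        if (t1 == t2) continue;
        tau(i, k) = t2; tau(i, k + 1) = t1;
        refresh_ct(i);
        double ll_new = 0.0, ll_cur = 0.0;
        const int dim = item_dim[i];
        for (int j : by_item[i]) {
          colbuf_v[j] = cell_ll(alpha[i], theta(j, dim) - delta[i],
                                &ctv[i * (C + 1)], C, Z(j, i));
          ll_new += colbuf_v[j];
          ll_cur += llcell(j, i);
        }
        double lpr = (std::pow(t1 - tau_prior_mean[k], 2) -
                      std::pow(t2 - tau_prior_mean[k], 2) +
                      std::pow(t2 - tau_prior_mean[k + 1], 2) -
                      std::pow(t1 - tau_prior_mean[k + 1], 2)) /
                     (2.0 * tau_prior_sd * tau_prior_sd);
        double lr = ll_new - ll_cur + lpr;
        if (lr >= 0.0 || std::log(unif_rand()) < lr) {
          for (int j : by_item[i]) llcell(j, i) = colbuf_v[j];
        } else {
          tau(i, k) = t1; tau(i, k + 1) = t2;
          refresh_ct(i);
        }
      }
    }

    // --- reflection moves ---------------------------------------------------
    // The unfolding kernel is symmetric in theta - delta, so a neutral item's
    // location is sign-ambiguous when the rest of the model only weakly pins
    // it.  A sign-flip proposal lets a chain escape the minor mirror mode.
    for (int i = 0; i < I; ++i) {
      if (direction[i] != 0 || delta[i] == 0.0) continue;
      double dp = -delta[i];
      const int dim = item_dim[i];
      double ll_new = 0.0, ll_cur = 0.0;
      for (int j : by_item[i]) {
        colbuf_v[j] = cell_ll(alpha[i], theta(j, dim) - dp,
                              &ctv[i * (C + 1)], C, Z(j, i));
        ll_new += colbuf_v[j];
        ll_cur += llcell(j, i);
      }
      // delta prior is N(0, sd) for neutral items: symmetric, cancels
      double lr = ll_new - ll_cur;
      if (lr >= 0.0 || std::log(unif_rand()) < lr) {
        delta[i] = dp;
        for (int j : by_item[i]) llcell(j, i) = colbuf_v[j];
      }
    }
    // Dimension reflection: propose flipping the sign of theta_d together
    // with the locations of that dimension's neutral items, the d-th
    // row/column of omega and the d-th beta column.  Every prior involved is
    // symmetric and neutral-item likelihoods depend on |theta - delta|, so
    // only the dimension's sign-bounded (directional) items contribute to
    // the Metropolis ratio; with no directional items the move is an exact
    // symmetry and always accepted.  This lets a chain escape a mirrored
    // mode that single-parameter updates cannot leave.
    for (int d = 0; d < D; ++d) {
      if (unif_rand() < 0.5) continue;
      double lr = 0.0;
      for (int i = 0; i < I; ++i) {
        if (item_dim[i] != d || direction[i] == 0) continue;
        for (int j : by_item[i])
          lr += cell_ll(alpha[i], -theta(j, d) - delta[i], &ctv[i * (C + 1)],
                        C, Z(j, i)) -
                llcell(j, i);
      }
      if (lr < 0.0 && std::log(unif_rand()) >= lr) continue;
      for (int i = 0; i < I; ++i) {
        if (item_dim[i] != d) continue;
        if (direction[i] == 0) {
          delta[i] = -delta[i];
        } else {
          for (int j : by_item[i])
            llcell(j, i) = cell_ll(alpha[i], -theta(j, d) - delta[i],
                                   &ctv[i * (C + 1)], C, Z(j, i));
        }
      }
      theta.col(d) *= -1.0;
      for (int e = 0; e < D; ++e)
        if (e != d) { omega(d, e) *= -1.0; omega(e, d) *= -1.0; }
      if (has_cov) { beta.col(d) *= -1.0; mu = X * beta; }
      omega_inv = arma::inv_sympd(omega); // logdet unchanged by the flip
    }

    // --- latent regression coefficients (conjugate Gibbs) -------------------
    if (has_cov) {
      arma::mat Q = arma::kron(omega_inv, XtX);
      Q.diag() += 1.0 / (beta_prior_sd * beta_prior_sd);
      arma::vec rhs = arma::vectorise(X.t() * theta * omega_inv);
      arma::mat R = arma::chol(Q); // upper
      arma::vec mean_b = arma::solve(Q, rhs);
      arma::vec zv(P * D);
      for (int m = 0; m < P * D; ++m) zv(m) = norm_rand();
      arma::vec b = mean_b + arma::solve(arma::trimatu(R), zv);
      beta = arma::reshape(b, P, D);
      mu = X * beta;
    }

    // --- trait correlations (LKJ(1) prior = flat over correlation matrices) -
    if (n_pair > 0) {
      arma::mat Rres = theta - mu;
      arma::mat Ssum = Rres.t() * Rres;
      for (int round = 0; round < 5; ++round) {
      int pair = 0;
      for (int a = 0; a < D; ++a)
        for (int b = a + 1; b < D; ++b, ++pair) {
          // random walk on the Fisher-z scale: steps stay efficient when the
          // posterior concentrates near |omega| = 1 (highly correlated
          // traits); the tanh Jacobian (1 - omega^2) enters the ratio
          double cur = omega(a, b);
          double prop = std::tanh(std::atanh(cur) +
                                  st_omega[pair].step() * norm_rand());
          bool acc = false;
          if (std::abs(prop) < 0.9999) {
            arma::mat om_p = omega;
            om_p(a, b) = om_p(b, a) = prop;
            arma::mat om_p_inv;
            bool pd = arma::inv_sympd(om_p_inv, om_p);
            if (pd) {
              double ld_p = std::log(arma::det(om_p));
              double lp = -0.5 * (J * ld_p + arma::trace(om_p_inv * Ssum));
              double lc =
                  -0.5 * (J * omega_logdet + arma::trace(omega_inv * Ssum));
              double lr = lp - lc + std::log1p(-prop * prop) -
                          std::log1p(-cur * cur);
              acc = (lr >= 0.0) || (std::log(unif_rand()) < lr);
              if (acc) {
                omega = om_p;
                omega_inv = om_p_inv;
                omega_logdet = ld_p;
              }
            }
          }
          if (burn) st_omega[pair].tally(acc);
        }
      }
    }

    // --- adaptation (burn-in only) ------------------------------------------
    if (burn && ((it + 1) % ((it < 300) ? 25 : 50) == 0)) {
      for (auto &a : st_item) a.adapt_scale(0.30);
      for (auto &a : st_omega) a.adapt();
    }

    // --- record --------------------------------------------------------------
    if (!burn) {
      const int s = it - burn_total;
      for (int i = 0; i < I; ++i) {
        d_alpha(s, i) = alpha[i];
        d_delta(s, i) = delta[i];
        for (int k = 0; k < C; ++k) d_tau(s, i * C + k) = tau(i, k);
      }
      for (int d = 0; d < D; ++d)
        for (int j = 0; j < J; ++j) d_theta(s, d * J + j) = theta(j, d);
      if (has_cov)
        for (int d = 0; d < D; ++d)
          for (int p = 0; p < P; ++p) d_beta(s, d * P + p) = beta(p, d);
      int pair = 0;
      for (int a = 0; a < D; ++a)
        for (int b = a + 1; b < D; ++b, ++pair) d_omega(s, pair) = omega(a, b);
      if (store_loglik) {
        int c = 0;
        for (int j = 0; j < J; ++j)
          for (int i : by_person[j]) d_ll(s, c++) = llcell(j, i);
      }
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      Named("alpha") = d_alpha, Named("delta") = d_delta, Named("tau") = d_tau,
      Named("theta") = d_theta, Named("beta") = d_beta,
      Named("omega") = d_omega, Named("n_cells") = n_cells);
  if (store_loglik) out["loglik"] = d_ll;
  return out;
}
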