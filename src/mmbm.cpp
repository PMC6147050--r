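// Multilevel multinomial logit posterior (noncentred Cholesky random effects)
// and a No-U-Turn sampler over its unconstrained parameterization.
//
// Parameter vector layout (all unconstrained):
//   alpha[K-1]                      category intercepts (reference fixed at 0)
//   beta[P*(K-1)]                   vec of P x (K-1) matrix, column-major
//   then per random-effect level l:
//     log_sigma[K-1]
//     y[(K-1)(K-2)/2]               canonical partial correlations, only if
//                                   the level is correlated
//     z[(K-1)*n_units]              standard-normal innovations, unit-major
//
// Observations are aggregated cells: one row per (unit combination x covariate
// row) with multinomial counts over the K categories.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

constexpr double kMinOneMinusS = 1e-12;

struct Level {
  arma::uvec uidx;      // cell -> unit (0-based)
  arma::uword n_units;
  bool correlated;
};

struct Priors {
  double intercept_scale;
  double beta_scale;
  double sd_rate;       // exponential rate for random-effect SDs
  double lkj_eta;
};

// Builds a correlation Cholesky factor from canonical partial correlations
// (tanh of the unconstrained values), row-wise lower triangle, and accumulates
// the log-Jacobian of the transform plus the LKJ(eta) log-density.
// Backprop through the same recursion gives d(lp)/d(y).
class CholCorr {
 public:
  explicit CholCorr(int K) : K_(K), L(K, K, arma::fill::zeros), zc_(K, K), tj_(K, K) {}

  // y: length K(K-1)/2; returns log-prior + log-Jacobian contribution
  double forward(const arma::vec& y, double eta) {
    double lp = 0.0;
    int idx = 0;
    L(0, 0) = 1.0;
    for (int i = 1; i < K_; ++i) {
      double s = 0.0;
      for (int j = 0; j < i; ++j) {
        double zc = std::tanh(y[idx++]);
        double oms = std::max(1.0 - s, kMinOneMinusS);
        double t = std::sqrt(oms);
        zc_(i, j) = zc;
        tj_(i, j) = t;
        L(i, j) = zc * t;
        lp += std::log1p(-zc * zc) + 0.5 * std::log(oms);
        s += L(i, j) * L(i, j);
      }
      double omsd = std::max(1.0 - s, kMinOneMinusS);
      L(i, i) = std::sqrt(omsd);
      // LKJ Cholesky log-density (unnormalized): (K - r + 2 eta - 2) log L_rr
      lp += (K_ - (i + 1) + 2.0 * eta - 2.0) * std::log(L(i, i));
    }
    return lp;
  }

  // dL: gradient wrt entries of L (lower triangle incl. diagonal) from the
  // likelihood side; LKJ diagonal term is added here. Writes d(lp)/dy.
  void backward(const arma::mat& dL_in, double eta, arma::vec& dy) const {
    arma::mat dL = dL_in;
    for (int i = 1; i < K_; ++i)
      dL(i, i) += (K_ - (i + 1) + 2.0 * eta - 2.0) / L(i, i);

    int base = 0;  // index of (i,0) within y for row i
    for (int i = 1; i < K_; ++i) {
      // ds = d lp / d s_{j+1} accumulator, starting from L_ii = sqrt(1-s_i)
      double ds = dL(i, i) * (-0.5 / L(i, i));
      for (int j = i - 1; j >= 0; --j) {
        double Lij = L(i, j), zc = zc_(i, j), t = tj_(i, j);
        double dLij = dL(i, j) + ds * 2.0 * Lij;
        // Jacobian term 0.5*log(1 - s_j) differentiates to -0.5/(1-s_j)
        double ds_j = ds + dLij * zc * (-0.5 / t) + (-0.5 / (t * t));
        double dzc = dLij * t - 2.0 * zc / (1.0 - zc * zc);
        dy[base + j] = dzc * (1.0 - zc * zc);
        ds = ds_j;
      }
      base += i;
    }
  }

  arma::mat L;

 private:
  int K_;
  arma::mat zc_, tj_;
};

class Posterior {
 public:
  Posterior(const arma::mat& Ynr, const arma::vec& yref, const arma::mat& X,
            const std::vector<Level>& levels, const Priors& priors)
      : Ynr_(Ynr), X_(X), levels_(levels), pr_(priors) {
    n_ = Ynr.n_rows;
    Km1_ = Ynr.n_cols;
    P_ = X.n_cols;
    ntot_ = yref + arma::sum(Ynr, 1);
    ncorr_ = Km1_ * (Km1_ - 1) / 2;
    dim_ = Km1_ + P_ * Km1_;
    for (const Level& l : levels_) {
      dim_ += Km1_;                       // log_sigma
      if (l.correlated) dim_ += ncorr_;   // y
      dim_ += Km1_ * l.n_units;           // z
    }
  }

  arma::uword dim() const { return dim_; }

  // log posterior density (unnormalized) and its gradient
  double lp_grad(const arma::vec& th, arma::vec& grad) const {
    grad.zeros(dim_);
    arma::uword off = 0;
    const arma::vec alpha = th.subvec(off, off + Km1_ - 1);
    off += Km1_;
    arma::mat B;
    if (P_ > 0) {
      B = arma::reshape(th.subvec(off, off + P_ * Km1_ - 1), P_, Km1_);
      off += P_ * Km1_;
    }

    struct LevelState {
      arma::vec sigma;
      std::unique_ptr<CholCorr> chol;
      arma::mat M;   // diag(sigma) * L
      arma::mat Z;   // Km1 x n_units
      arma::uword off_ls, off_y, off_z;
    };
    std::vector<LevelState> st(levels_.size());

    double lp = 0.0;
    for (size_t l = 0; l < levels_.size(); ++l) {
      LevelState& s = st[l];
      s.off_ls = off;
      arma::vec log_sigma = th.subvec(off, off + Km1_ - 1);
      off += Km1_;
      s.sigma = arma::exp(log_sigma);
      // Exponential(rate) prior on sigma plus log|d sigma / d log_sigma|
      lp += arma::sum(-pr_.sd_rate * s.sigma + log_sigma);

      if (levels_[l].correlated) {
        s.off_y = off;
        s.chol.reset(new CholCorr(Km1_));
        lp += s.chol->forward(th.subvec(off, off + ncorr_ - 1), pr_.lkj_eta);
        off += ncorr_;
        s.M = arma::diagmat(s.sigma) * s.chol->L;
      } else {
        s.M = arma::diagmat(s.sigma);
      }
      s.off_z = off;
      s.Z = arma::reshape(th.subvec(off, off + Km1_ * levels_[l].n_units - 1),
                          Km1_, levels_[l].n_units);
      off += Km1_ * levels_[l].n_units;
      lp += -0.5 * arma::accu(arma::square(s.Z));
    }

    // Linear predictors
    arma::mat Eta(n_, Km1_);
    Eta.each_row() = alpha.t();
    if (P_ > 0) Eta += X_ * B;
    for (size_t l = 0; l < levels_.size(); ++l) {
      const arma::mat U = st[l].M * st[l].Z;  // Km1 x n_units
      const arma::uvec& idx = levels_[l].uidx;
      for (arma::uword i = 0; i < n_; ++i) Eta.row(i) += U.col(idx[i]).t();
    }

    // Multinomial log likelihood with reference eta = 0, log-sum-exp stable
    arma::mat G(n_, Km1_);  // d loglik / d Eta
    for (arma::uword i = 0; i < n_; ++i) {
      double m = 0.0;
      for (arma::uword k = 0; k < Km1_; ++k) m = std::max(m, Eta(i, k));
      double se = std::exp(-m);
      for (arma::uword k = 0; k < Km1_; ++k) se += std::exp(Eta(i, k) - m);
      double lse = m + std::log(se);
      double li = -ntot_[i] * lse;
      for (arma::uword k = 0; k < Km1_; ++k) {
        li += Ynr_(i, k) * Eta(i, k);
        G(i, k) = Ynr_(i, k) - ntot_[i] * std::exp(Eta(i, k) - lse);
      }
      lp += li;
    }

    // Fixed-effect gradients and Gaussian priors
    const double ivar_a = 1.0 / (pr_.intercept_scale * pr_.intercept_scale);
    lp += -0.5 * ivar_a * arma::dot(alpha, alpha);
    grad.subvec(0, Km1_ - 1) = arma::sum(G, 0).t() - ivar_a * alpha;
    if (P_ > 0) {
      const double ivar_b = 1.0 / (pr_.beta_scale * pr_.beta_scale);
      lp += -0.5 * ivar_b * arma::accu(arma::square(B));
      arma::mat dB = X_.t() * G - ivar_b * B;
      grad.subvec(Km1_, Km1_ + P_ * Km1_ - 1) = arma::vectorise(dB);
    }

    // Random-effect gradients
    for (size_t l = 0; l < levels_.size(); ++l) {
      LevelState& s = st[l];
      const arma::uvec& idx = levels_[l].uidx;
      arma::mat A(Km1_, levels_[l].n_units, arma::fill::zeros);
      for (arma::uword i = 0; i < n_; ++i) A.col(idx[i]) += G.row(i).t();

      arma::mat dZ = s.M.t() * A - s.Z;
      grad.subvec(s.off_z, s.off_z + Km1_ * levels_[l].n_units - 1) =
          arma::vectorise(dZ);

      arma::mat dM = A * s.Z.t();  // Km1 x Km1; only lower triangle used
      if (levels_[l].correlated) {
        const arma::mat& L = s.chol->L;
        arma::vec dsig(Km1_, arma::fill::zeros);
        arma::mat dL(Km1_, Km1_, arma::fill::zeros);
        for (arma::uword k = 0; k < Km1_; ++k)
          for (arma::uword j = 0; j <= k; ++j) {
            dsig[k] += dM(k, j) * L(k, j);
            dL(k, j) = s.sigma[k] * dM(k, j);
          }
        grad.subvec(s.off_ls, s.off_ls + Km1_ - 1) =
            dsig % s.sigma - pr_.sd_rate * s.sigma + 1.0;
        arma::vec dy(ncorr_, arma::fill::zeros);
        s.chol->backward(dL, pr_.lkj_eta, dy);
        grad.subvec(s.off_y, s.off_y + ncorr_ - 1) = dy;
      } else {
        arma::vec dsig(Km1_);
        for (arma::uword k = 0; k < Km1_; ++k) dsig[k] = dM(k, k);
        grad.subvec(s.off_ls, s.off_ls + Km1_ - 1) =
            dsig % s.sigma - pr_.sd_rate * s.sigma + 1.0;
      }
    }
    return lp;
  }

 private:
  arma::mat Ynr_;
  arma::mat X_;
  std::vector<Level> levels_;
  Priors pr_;
  arma::vec ntot_;
  arma::uword n_, Km1_, P_, ncorr_, dim_;
};

std::vector<Level> parse_levels(const List& levels_in) {
  std::vector<Level> levels;
  for (R_xlen_t l = 0; l < levels_in.size(); ++l) {
    List li = levels_in[l];
    Level lev;
    IntegerVector u = li["uidx"];
    lev.uidx = arma::conv_to<arma::uvec>::from(
        arma::Col<int>(u.begin(), u.size(), false));
    lev.n_units = as<int>(li["n_units"]);
    lev.correlated = as<bool>(li["correlated"]);
    levels.push_back(lev);
  }
  return levels;
}

Priors parse_priors(const List& pr) {
  Priors p;
  p.intercept_scale = as<double>(pr["intercept_scale"]);
  p.beta_scale = as<double>(pr["beta_scale"]);
  p.sd_rate = as<double>(pr["sd_rate"]);
  p.lkj_eta = as<double>(pr["lkj_eta"]);
  return p;
}

// ---------------------------------------------------------------------------
// NUTS (slice variant) with diagonal mass-matrix and dual-averaging step-size
// adaptation.

struct Tree {
  arma::vec th_minus, r_minus, g_minus;
  arma::vec th_plus, r_plus, g_plus;
  arma::vec th_prop, g_prop;
  double lp_prop;
  double n;      // number of valid states in slice
  bool s;        // no U-turn / no divergence
  double alpha;  // sum of acceptance probabilities
  double n_alpha;
  bool divergent;
};

class Nuts {
 public:
  Nuts(const Posterior& post, double delta_max = 1000.0)
      : post_(post), delta_max_(delta_max) {}

  void leapfrog(arma::vec& th, arma::vec& r, arma::vec& g, double& lp,
                double eps, const arma::vec& inv_mass) const {
    r += 0.5 * eps * g;
    th += eps * (inv_mass % r);
    lp = post_.lp_grad(th, g);
    r += 0.5 * eps * g;
  }

  double joint(double lp, const arma::vec& r, const arma::vec& inv_mass) const {
    return lp - 0.5 * arma::dot(r, inv_mass % r);
  }

  void build_tree(const arma::vec& th, const arma::vec& r, const arma::vec& g,
                  double lp, double log_u, int v, int j, double eps,
                  double joint0, const arma::vec& inv_mass, Tree& out) const {
    if (j == 0) {
      arma::vec th1 = th, r1 = r, g1 = g;
      double lp1 = lp;
      leapfrog(th1, r1, g1, lp1, v * eps, inv_mass);
      double jt = joint(lp1, r1, inv_mass);
      if (!std::isfinite(jt)) jt = -std::numeric_limits<double>::infinity();
      out.th_minus = th1; out.r_minus = r1; out.g_minus = g1;
      out.th_plus = th1; out.r_plus = r1; out.g_plus = g1;
      out.th_prop = th1; out.g_prop = g1; out.lp_prop = lp1;
      out.n = (log_u <= jt) ? 1.0 : 0.0;
      out.divergent = (log_u - delta_max_) > jt;
      out.s = !out.divergent;
      out.alpha = std::min(1.0, std::exp(jt - joint0));
      out.n_alpha = 1.0;
      return;
    }
    Tree first;
    build_tree(th, r, g, lp, log_u, v, j - 1, eps, joint0, inv_mass, first);
    out = first;
    if (first.s) {
      Tree second;
      if (v == -1) {
        build_tree(first.th_minus, first.r_minus, first.g_minus, 0.0, log_u, v,
                   j - 1, eps, joint0, inv_mass, second);
        out.th_minus = second.th_minus; out.r_minus = second.r_minus;
        out.g_minus = second.g_minus;
      } else {
        build_tree(first.th_plus, first.r_plus, first.g_plus, 0.0, log_u, v,
                   j - 1, eps, joint0, inv_mass, second);
        out.th_plus = second.th_plus; out.r_plus = second.r_plus;
        out.g_plus = second.g_plus;
      }
      double ntot = first.n + second.n;
      if (ntot > 0.0 && R::unif_rand() < second.n / ntot) {
        out.th_prop = second.th_prop; out.g_prop = second.g_prop;
        out.lp_prop = second.lp_prop;
      }
      out.n = ntot;
      out.alpha = first.alpha + second.alpha;
      out.n_alpha = first.n_alpha + second.n_alpha;
      out.divergent = first.divergent || second.divergent;
      arma::vec dth = out.th_plus - out.th_minus;
      bool uturn_ok = arma::dot(dth, inv_mass % out.r_minus) >= 0.0 &&
                      arma::dot(dth, inv_mass % out.r_plus) >= 0.0;
      out.s = second.s && !out.divergent && uturn_ok;
    }
  }

  double find_epsilon(const arma::vec& th0, const arma::vec& inv_mass) const {
    arma::vec g(post_.dim());
    double lp = post_.lp_grad(th0, g);
    arma::vec r(post_.dim());
    for (arma::uword i = 0; i < r.n_elem; ++i)
      r[i] = R::norm_rand() / std::sqrt(inv_mass[i]);
    double eps = 0.1;
    double j0 = joint(lp, r, inv_mass);
    arma::vec th1 = th0, r1 = r, g1 = g;
    double lp1 = lp;
    leapfrog(th1, r1, g1, lp1, eps, inv_mass);
    double j1 = joint(lp1, r1, inv_mass);
    if (!std::isfinite(j1)) j1 = -std::numeric_limits<double>::infinity();
    double a = (j1 - j0 > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      if (a * (j1 - j0) <= -a * std::log(2.0)) break;
      eps *= std::pow(2.0, a);
      th1 = th0; r1 = r; g1 = g; lp1 = lp;
      leapfrog(th1, r1, g1, lp1, eps, inv_mass);
      j1 = joint(lp1, r1, inv_mass);
      if (!std::isfinite(j1)) j1 = -std::numeric_limits<double>::infinity();
    }
    return eps;
  }

 private:
  const Posterior& post_;
  double delta_max_;
};

}  // namespace

// [[Rcpp::export(name = ".mmbm_lp_grad")]]
List mmbm_lp_grad_cpp(const arma::vec& theta, const arma::mat& Ynr,
                      const arma::vec& yref, const arma::mat& X,
                      const List& levels, const List& priors) {
  Posterior post(Ynr, yref, X, parse_levels(levels), parse_priors(priors));
  if (theta.n_elem != post.dim())
    stop("theta has length %d, expected %d", (int)theta.n_elem, (int)post.dim());
  arma::vec grad;
  double lp = post.lp_grad(theta, grad);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export(name = ".mmbm_nuts_chain")]]
List mmbm_nuts_chain_cpp(const arma::mat& Ynr, const arma::vec& yref,
                         const arma::mat& X, const List& levels,
                         const List& priors, int iter, int warmup,
                         double adapt_delta, int max_depth,
                         double init_scale) {
  Posterior post(Ynr, yref, X, parse_levels(levels), parse_priors(priors));
  Nuts nuts(post);
  const arma::uword D = post.dim();

  arma::vec th(D);
  for (arma::uword i = 0; i < D; ++i) th[i] = init_scale * R::norm_rand();
  arma::vec inv_mass(D, arma::fill::ones);

  double eps = nuts.find_epsilon(th, inv_mass);
  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_count = 0;

  const int n_save = iter - warmup;
  arma::mat draws(n_save, D);
  arma::vec lp_save(n_save);
  IntegerVector treedepth(n_save);
  int divergences = 0;
  double accept_sum = 0.0;

  // mass-matrix estimation window inside warmup
  const int win_lo = warmup / 4, win_hi = (3 * warmup) / 4;
  const bool adapt_mass = warmup >= 80;
  arma::running_stat_vec<arma::vec> var_acc;

  arma::vec g(D);
  double lp = post.lp_grad(th, g);

  for (int it = 1; it <= iter; ++it) {
    arma::vec r0(D);
    for (arma::uword i = 0; i < D; ++i)
      r0[i] = R::norm_rand() / std::sqrt(inv_mass[i]);
    double joint0 = nuts.joint(lp, r0, inv_mass);
    double log_u = joint0 - R::exp_rand();

    arma::vec th_minus = th, th_plus = th, r_minus = r0, r_plus = r0;
    arma::vec g_minus = g, g_plus = g;
    arma::vec th_new = th, g_new = g;
    double lp_new = lp;
    double n = 1.0;
    bool s = true;
    int j = 0;
    double alpha = 0.0, n_alpha = 1.0;
    bool divergent = false;

    while (s && j < max_depth) {
      Tree t;
      int v = (R::unif_rand() < 0.5) ? -1 : 1;
      if (v == -1) {
        nuts.build_tree(th_minus, r_minus, g_minus, 0.0, log_u, v, j, eps,
                        joint0, inv_mass, t);
        th_minus = t.th_minus; r_minus = t.r_minus; g_minus = t.g_minus;
      } else {
        nuts.build_tree(th_plus, r_plus, g_plus, 0.0, log_u, v, j, eps,
                        joint0, inv_mass, t);
        th_plus = t.th_plus; r_plus = t.r_plus; g_plus = t.g_plus;
      }
      if (t.s && R::unif_rand() < t.n / n) {
        th_new = t.th_prop; g_new = t.g_prop; lp_new = t.lp_prop;
      }
      n += t.n;
      alpha = t.alpha; n_alpha = t.n_alpha;
      divergent = divergent || t.divergent;
      arma::vec dth = th_plus - th_minus;
      s = t.s && arma::dot(dth, inv_mass % r_minus) >= 0.0 &&
          arma::dot(dth, inv_mass % r_plus) >= 0.0;
      ++j;
    }
    th = th_new; g = g_new; lp = lp_new;
    double accept_stat = (n_alpha > 0) ? alpha / n_alpha : 0.0;

    if (it <= warmup) {
      // dual averaging toward target acceptance
      ++adapt_count;
      double frac = 1.0 / (adapt_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (adapt_delta - accept_stat);
      double log_eps = mu - std::sqrt((double)adapt_count) / gamma * h_bar;
      double w = std::pow((double)adapt_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);

      if (adapt_mass && it > win_lo && it <= win_hi) var_acc(th);
      if (adapt_mass && it == win_hi) {
        arma::vec v = var_acc.var();
        double nw = (double)var_acc.count();
        inv_mass = (nw / (nw + 5.0)) * v + (5.0 / (nw + 5.0)) * 1e-3;
        inv_mass.transform([](double x) { return std::max(x, 1e-8); });
        eps = nuts.find_epsilon(th, inv_mass);
        mu = std::log(10.0 * eps);
        log_eps_bar = 0.0; h_bar = 0.0; adapt_count = 0;
      }
      if (it == warmup) eps = std::exp(log_eps_bar);
    } else {
      if (divergent) ++divergences;
      accept_sum += accept_stat;
      int k = it - warmup - 1;
      draws.row(k) = th.t();
      lp_save[k] = lp;
      treedepth[k] = j;
    }
    if (it % 100 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lp_save, _["divergences"] = divergences,
      _["step_size"] = eps, _["treedepth"] = treedepth,
      _["mean_accept"] = n_save > 0 ? accept_sum / n_save : NA_REAL);
}
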