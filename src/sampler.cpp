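// MCMC sampler for the joint (multi-species) hierarchical count model.
//
// Target: Y_ivj ~ F(exp(M_ij + site_i + observer_o(i,v) + log npoints_iv),
// theta_j) with M_i ~ MVN(X_i B, Sigma), hierarchical B_kj ~ N(mu_k,
// sigma_B(k)^2), and the prior constructions for Sigma described in the R
// documentation (IW / SIW / SSIW / SSLKJ).
//
// Sampling scheme (one sweep):
//   * B[k,j]: random-walk Metropolis against the count likelihood, holding
//     the whitened residuals zM fixed (non-centered in Sigma).
//   * mu_B[k]: exact conjugate Gibbs given B, sigma_B.
//   * sigma_B[k]: slice sampling of the centered conditional given B, mu_B.
//   * zM[i,l] (whitened latent residuals): scalar random walk.
//   * Sigma parameters (Cholesky / partial-correlation / scale components):
//     random walk with zM held fixed; the MVN prior is exactly the standard
//     normal on zM so only the likelihood and the Sigma prior enter.
//   * site/observer effects: non-centered scalar random walks; their SDs get
//     both a non-centered likelihood move and an interweaved centered slice
//     move (ASIS), which decorrelates the scale from the effects.
//   * log theta_j: random walk (negative binomial only).
// Proposal scales adapt toward 44% acceptance during warm-up only.
//
// Randomness comes from R's RNG, so set.seed() makes chains reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double TARGET_ACC = 0.44;

struct Config {
  int family;        // 0 poisson, 1 negbinomial
  int flavor;        // 0 IW, 1 SIW, 2 SSIW, 3 SSLKJ
  double scale_mu, scale_sigma_b, scale_sigma_j, theta_rate;
  double scale_sS, scale_sO, lkj_shape;
  bool latent, ranef;
};

struct State;

// ---------- small density helpers -------------------------------------

static inline double log_half_cauchy(double x, double s) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0) - std::log(M_PI * s) - std::log1p((x / s) * (x / s));
}
static inline double log_half_normal(double x, double s) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0) - 0.5 * std::log(2.0 * M_PI) - std::log(s)
       - 0.5 * x * x / (s * s);
}
// density of theta when 1/theta ~ Exp(rate)
static inline double log_theta_prior(double th, double rate) {
  if (th <= 0) return R_NegInf;
  return std::log(rate) - rate / th - 2.0 * std::log(th);
}

// ---------- model ------------------------------------------------------

struct Model {
  arma::mat X;            // n x K
  arma::vec y, lognp;     // length R
  arma::uvec si, sp, ob;  // 0-based indices, length R
  int n, J, K, nO, R;
  Config cfg;
  // row index lists
  std::vector<std::vector<arma::uword>> rows_ij;   // (i*J+j) -> rows
  std::vector<std::vector<arma::uword>> rows_sp;   // j -> rows
  std::vector<std::vector<arma::uword>> rows_site; // i -> rows
  std::vector<std::vector<arma::uword>> rows_obs;  // o -> rows

  int n_sv() const {
    int Jt = J * (J + 1) / 2, Jp = J * (J - 1) / 2;
    switch (cfg.flavor) {
      case 0: return Jt;          // IW: chol of Sigma
      case 1: return Jt + J;      // SIW: chol of Q + log xi
      case 2: return Jt + J;      // SSIW: chol of Q + log sigma_j
      default: return Jp + J;     // SSLKJ: atanh partials + log sigma_j
    }
  }

  void index_rows() {
    rows_ij.assign((size_t)n * J, {});
    rows_sp.assign(J, {});
    rows_site.assign(n, {});
    rows_obs.assign(nO, {});
    for (int r = 0; r < R; ++r) {
      rows_ij[si[r] * J + sp[r]].push_back(r);
      rows_sp[sp[r]].push_back(r);
      rows_site[si[r]].push_back(r);
      rows_obs[ob[r]].push_back(r);
    }
  }
};

struct State {
  arma::vec mu_B, sigma_B;   // K
  arma::mat B;               // K x J
  arma::mat zM;              // n x J whitened latent residuals
  arma::vec sv;              // Sigma parameters (flavor-specific)
  arma::vec zs, zo;          // whitened random effects
  double sigma_S, sigma_O;
  arma::vec log_theta;       // J
  // caches
  arma::mat eta, M;          // n x J
  arma::mat L;               // lower chol of Sigma
  arma::vec site_eff, obs_eff;
  arma::vec ll;              // per-row log likelihood
  double sv_lp;              // log prior of sv (with Jacobians)
};

// lower-triangular index helpers for sv cholesky block
static inline int tri_index(int i, int j) { return i * (i + 1) / 2 + j; }

// Build L_Sigma (lower) from sv; also return the log prior of sv including
// all transform Jacobians. Returns false if numerically invalid.
static bool build_L(const Model& m, const arma::vec& sv, arma::mat& L,
                    double& lp) {
  const int J = m.J;
  const double df = J + 1.0;
  lp = 0.0;
  if (m.cfg.flavor == 3) { // SSLKJ
    const int Jp = J * (J - 1) / 2;
    arma::mat W(J, J, arma::fill::zeros);
    W(0, 0) = 1.0;
    // partial correlations via tanh transform, C-vine order
    int idx = 0;
    arma::mat pr(J, J, arma::fill::zeros);
    for (int k = 0; k < J - 1; ++k) {
      double a = m.cfg.lkj_shape + (J - 2 - k) / 2.0;
      for (int j = k + 1; j < J; ++j, ++idx) {
        double p = std::tanh(sv[idx]);
        pr(k, j) = p;
        double pc = 0.5 * (p + 1.0);
        lp += R::dbeta(pc, a, a, 1) + std::log(0.5) + std::log1p(-p * p);
      }
    }
    for (int j = 1; j < J; ++j) {
      double cum = 1.0;
      W(j, 0) = pr(0, j);
      cum *= std::sqrt(1.0 - pr(0, j) * pr(0, j));
      for (int k = 1; k < j; ++k) {
        W(j, k) = pr(k, j) * cum;
        cum *= std::sqrt(1.0 - pr(k, j) * pr(k, j));
      }
      W(j, j) = cum;
    }
    L = W;
    for (int j = 0; j < J; ++j) {
      double s = std::exp(sv[Jp + j]);
      if (!std::isfinite(s) || s <= 0) return false;
      lp += log_half_cauchy(s, m.cfg.scale_sigma_j) + sv[Jp + j];
      L.row(j) *= s;
    }
    return true;
  }
  // flavors with a cholesky block: reconstruct Lq
  const int Jt = J * (J + 1) / 2;
  arma::mat Lq(J, J, arma::fill::zeros);
  for (int i = 0; i < J; ++i)
    for (int j = 0; j <= i; ++j) {
      double v = sv[tri_index(i, j)];
      Lq(i, j) = (i == j) ? std::exp(v) : v;
      if (!std::isfinite(Lq(i, j))) return false;
    }
  // inverse-Wishart(df, I) prior on Q = Lq Lq', in chol coordinates:
  //   log IW(Q) + sum_i (J - i + 1) log Lq_ii  [chol Jacobian, i 1-based]
  //   + sum_i log Lq_ii                        [log-diagonal transform]
  double ldet = 0.0;
  for (int i = 0; i < J; ++i) ldet += 2.0 * std::log(Lq(i, i));
  arma::mat Linv;
  if (!arma::inv(Linv, arma::trimatl(Lq))) return false;
  double tr_qinv = arma::accu(arma::square(Linv));
  lp += -0.5 * (df + J + 1.0) * ldet - 0.5 * tr_qinv;
  for (int i = 0; i < J; ++i) lp += (J - i + 1.0) * std::log(Lq(i, i));
  if (m.cfg.flavor == 0) { // IW on Sigma itself
    L = Lq;
    return true;
  }
  if (m.cfg.flavor == 1) { // SIW: Sigma = D_xi Q D_xi
    L = Lq;
    for (int j = 0; j < J; ++j) {
      double xi = std::exp(sv[Jt + j]);
      if (!std::isfinite(xi) || xi <= 0) return false;
      lp += log_half_normal(xi, 1.0) + sv[Jt + j];
      L.row(j) *= xi;
    }
    return true;
  }
  // SSIW: R = Dq^-1 Q Dq^-1, Sigma = D_s R D_s  =>  L = D_s Dq^-1 Lq
  L = Lq;
  for (int j = 0; j < J; ++j) {
    double qjj = arma::norm(Lq.row(j).head(j + 1), 2);
    double s = std::exp(sv[Jt + j]);
    if (!std::isfinite(s) || s <= 0 || qjj <= 0) return false;
    lp += log_half_cauchy(s, m.cfg.scale_sigma_j) + sv[Jt + j];
    L.row(j) *= s / qjj;
  }
  return true;
}

// per-row observation log likelihood
static inline double row_ll(const Model& m, const State& st, int r,
                            double Mval) {
  double lmu = Mval + st.site_eff[m.si[r]] + st.obs_eff[m.ob[r]] + m.lognp[r];
  double yv = m.y[r];
  if (m.cfg.family == 0) { // poisson
    double mu = std::exp(lmu);
    if (!std::isfinite(mu)) return R_NegInf;
    return -mu + yv * lmu - std::lgamma(yv + 1.0);
  }
  double th = std::exp(st.log_theta[m.sp[r]]);
  double mu = std::exp(lmu);
  if (!std::isfinite(mu)) return R_NegInf;
  // NB with mean mu, shape th: Var = mu + mu^2/th
  return std::lgamma(yv + th) - std::lgamma(th) - std::lgamma(yv + 1.0)
       + th * std::log(th / (th + mu)) + yv * std::log(mu / (th + mu));
}

static void refresh_caches(const Model& m, State& st) {
  st.eta = m.X * st.B;
  if (m.cfg.latent) st.M = st.eta + st.zM * st.L.t();
  else st.M = st.eta;
  st.site_eff = m.cfg.ranef ? arma::vec(st.sigma_S * st.zs)
                            : arma::vec(m.n, arma::fill::zeros);
  st.obs_eff = m.cfg.ranef ? arma::vec(st.sigma_O * st.zo)
                           : arma::vec(m.nO, arma::fill::zeros);
  st.ll.set_size(m.R);
  for (int r = 0; r < m.R; ++r)
    st.ll[r] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
}

// adaptive step bookkeeping
struct Adapt {
  arma::vec step;
  arma::vec acc, tries;
  void init(int k, double s0) {
    step.set_size(k); step.fill(s0);
    acc.zeros(k); tries.zeros(k);
  }
  void update(int batch) {
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
    for (arma::uword i = 0; i < step.n_elem; ++i) {
      if (tries[i] > 0) {
        double rate = acc[i] / tries[i];
        step[i] *= std::exp(rate > TARGET_ACC ? delta : -delta);
      }
      acc[i] = tries[i] = 0;
    }
  }
};

// generic 1-D slice sampler (stepping out + shrinkage) on an unbounded scale
template <typename F>
static double slice_1d(double x0, double f0, F logf, double w = 1.0,
                       int maxstep = 50) {
  double logy = f0 + std::log(unif_rand());
  double u = unif_rand();
  double lo = x0 - w * u, hi = lo + w;
  int k = maxstep;
  while (k-- > 0 && logf(lo) > logy) lo -= w;
  k = maxstep;
  while (k-- > 0 && logf(hi) > logy) hi += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = lo + unif_rand() * (hi - lo);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) lo = x1; else hi = x1;
  }
  return x0;
}

// [[Rcpp::export(name = ".run_jsdm_chain")]]
List run_jsdm_chain(List data, List config, int n_iter, int n_warmup,
                    List init) {
  Model m;
  m.X = as<arma::mat>(data["X"]);
  m.y = as<arma::vec>(data["y"]);
  m.si = as<arma::uvec>(data["site"]);
  m.sp = as<arma::uvec>(data["species"]);
  m.ob = as<arma::uvec>(data["observer"]);
  m.lognp = as<arma::vec>(data["log_np"]);
  m.n = as<int>(data["n"]); m.J = as<int>(data["J"]);
  m.K = m.X.n_cols; m.nO = as<int>(data["n_observers"]);
  m.R = m.y.n_elem;
  m.cfg.family = as<int>(config["family_code"]);
  m.cfg.flavor = as<int>(config["flavor_code"]);
  m.cfg.scale_mu = as<double>(config["scale_mu"]);
  m.cfg.scale_sigma_b = as<double>(config["scale_sigma_b"]);
  m.cfg.scale_sigma_j = as<double>(config["scale_sigma_j"]);
  m.cfg.theta_rate = as<double>(config["theta_rate"]);
  m.cfg.scale_sS = as<double>(config["scale_sigma_s"]);
  m.cfg.scale_sO = as<double>(config["scale_sigma_o"]);
  m.cfg.lkj_shape = as<double>(config["lkj_shape"]);
  m.cfg.latent = as<bool>(config["latent_residual"]);
  m.cfg.ranef = as<bool>(config["include_ranef"]);
  m.index_rows();

  State st;
  st.mu_B = as<arma::vec>(init["mu_B"]);
  st.sigma_B = as<arma::vec>(init["sigma_B"]);
  st.B = as<arma::mat>(init["B"]);
  st.zM = as<arma::mat>(init["zM"]);
  st.sv = as<arma::vec>(init["sv"]);
  st.zs = as<arma::vec>(init["zs"]);
  st.zo = as<arma::vec>(init["zo"]);
  st.sigma_S = as<double>(init["sigma_S"]);
  st.sigma_O = as<double>(init["sigma_O"]);
  st.log_theta = as<arma::vec>(init["log_theta"]);

  const int J = m.J, K = m.K, n = m.n, nO = m.nO;
  const bool nb = m.cfg.family == 1;
  const int nsv = m.cfg.latent ? m.n_sv() : 0;

  if (m.cfg.latent) {
    if (!build_L(m, st.sv, st.L, st.sv_lp))
      stop("invalid initial Sigma parameters");
  } else {
    st.L.eye(J, J);
    st.sv_lp = 0.0;
  }
  refresh_caches(m, st);

  Adapt aB, aZM, aSV, aSVc, aZS, aZO, aTH, aSS, aSO;
  Adapt aShift, aRotO, aRotS, aRotM;
  aB.init(K * J, 0.1);
  aZM.init(n * J, 0.5);
  aSV.init(std::max(nsv, 1), 0.1);
  aSVc.init(std::max(nsv, 1), 0.1);
  aZS.init(n, 0.5); aZO.init(nO, 0.5);
  aTH.init(J, 0.3);
  aSS.init(1, 0.3); aSO.init(1, 0.3);
  aShift.init(K, 0.2);
  aRotO.init(1, 0.2); aRotS.init(1, 0.2); aRotM.init(n, 0.3);
  // the intercept-rotation moves assume X[,1] == 1
  bool has_intercept = arma::all(arma::abs(m.X.col(0) - 1.0) < 1e-12);

  // output layout
  const int n_keep = n_iter - n_warmup;
  const int P = 2 * K + K * J + 2 + n + nO + J + J + 2 * J * J + n * J;
  arma::mat out(n_keep, P);

  arma::vec newll;
  arma::mat Mprop;
  int batch = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool warm = iter < n_warmup;

    // --- B[k,j] random walk (zM fixed; likelihood over species j) -------
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < J; ++j) {
        int id = k * J + j;
        double d = aB.step[id] * norm_rand();
        double bnew = st.B(k, j) + d;
        double dprior =
          R::dnorm(bnew, st.mu_B[k], st.sigma_B[k], 1)
        - R::dnorm(st.B(k, j), st.mu_B[k], st.sigma_B[k], 1);
        const std::vector<arma::uword>& rows = m.rows_sp[j];
        double dll = 0.0;
        newll.set_size(rows.size());
        for (size_t t = 0; t < rows.size(); ++t) {
          int r = rows[t];
          double Mv = st.M(m.si[r], j) + d * m.X(m.si[r], k);
          newll[t] = row_ll(m, st, r, Mv);
          dll += newll[t] - st.ll[r];
        }
        aB.tries[id]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aB.acc[id]++;
          st.B(k, j) = bnew;
          st.eta.col(j) += d * m.X.col(k);
          st.M.col(j) += d * m.X.col(k);
          for (size_t t = 0; t < rows.size(); ++t) st.ll[rows[t]] = newll[t];
        }
      }
    }

    // --- joint shift of (mu_B[k], whole row B[k, ]) ---------------------
    // moves the species-common component of column k against the data;
    // B - mu differences (and hence the hierarchical prior) are unchanged
    for (int k = 0; k < K; ++k) {
      double d = aShift.step[k] * norm_rand();
      double dprior = R::dnorm(st.mu_B[k] + d, 0.0, m.cfg.scale_mu, 1)
                    - R::dnorm(st.mu_B[k], 0.0, m.cfg.scale_mu, 1);
      double dll = 0.0;
      newll.set_size(m.R);
      bool bad = false;
      for (int r = 0; r < m.R; ++r) {
        double Mv = st.M(m.si[r], m.sp[r]) + d * m.X(m.si[r], k);
        newll[r] = row_ll(m, st, r, Mv);
        if (newll[r] == R_NegInf) { bad = true; break; }
        dll += newll[r] - st.ll[r];
      }
      aShift.tries[k]++;
      if (!bad && std::log(unif_rand()) < dprior + dll) {
        aShift.acc[k]++;
        st.mu_B[k] += d;
        st.B.row(k) += d;
        for (int j = 0; j < J; ++j) {
          st.eta.col(j) += d * m.X.col(k);
          st.M.col(j) += d * m.X.col(k);
        }
        st.ll = newll;
      }
    }

    // --- mu_B conjugate Gibbs given B, sigma_B --------------------------
    for (int k = 0; k < K; ++k) {
      double prec = J / (st.sigma_B[k] * st.sigma_B[k])
                  + 1.0 / (m.cfg.scale_mu * m.cfg.scale_mu);
      double mean = arma::accu(st.B.row(k))
                  / (st.sigma_B[k] * st.sigma_B[k]) / prec;
      st.mu_B[k] = mean + norm_rand() / std::sqrt(prec);
    }

    // --- sigma_B slice given B, mu_B (centered conditional) -------------
    for (int k = 0; k < K; ++k) {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) {
        double e = st.B(k, j) - st.mu_B[k];
        ss += e * e;
      }
      double sb = m.cfg.scale_sigma_b;
      auto logf = [&](double x) {
        double s = std::exp(x);
        return -(double)J * x - 0.5 * ss / (s * s)
             + log_half_cauchy(s, sb) + x;
      };
      double x0 = std::log(st.sigma_B[k]);
      st.sigma_B[k] = std::exp(slice_1d(x0, logf(x0), logf));
    }

    if (m.cfg.latent) {
      // --- zM scalar random walks ---------------------------------------
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < J; ++l) {
          int id = i * J + l;
          double d = aZM.step[id] * norm_rand();
          double znew = st.zM(i, l) + d;
          double dprior = -0.5 * (znew * znew - st.zM(i, l) * st.zM(i, l));
          double dll = 0.0;
          // affects M(i, j) for j >= l
          static thread_local std::vector<double> nl;
          nl.clear();
          for (int j = l; j < J; ++j) {
            if (st.L(j, l) == 0.0) { continue; }
            double Mv = st.M(i, j) + d * st.L(j, l);
            for (arma::uword r : m.rows_ij[(size_t)i * J + j]) {
              double v = row_ll(m, st, r, Mv);
              nl.push_back(v);
              dll += v - st.ll[r];
            }
          }
          aZM.tries[id]++;
          if (std::log(unif_rand()) < dprior + dll) {
            aZM.acc[id]++;
            st.zM(i, l) = znew;
            int t = 0;
            for (int j = l; j < J; ++j) {
              if (st.L(j, l) == 0.0) continue;
              st.M(i, j) += d * st.L(j, l);
              for (arma::uword r : m.rows_ij[(size_t)i * J + j])
                st.ll[r] = nl[t++];
            }
          }
        }
      }

      // --- Sigma parameters (zM fixed) ----------------------------------
      for (int q = 0; q < nsv; ++q) {
        double d = aSV.step[q] * norm_rand();
        arma::vec svn = st.sv;
        svn[q] += d;
        arma::mat Lnew;
        double lpnew;
        aSV.tries[q]++;
        if (!build_L(m, svn, Lnew, lpnew)) continue;
        Mprop = st.eta + st.zM * Lnew.t();
        double dll = 0.0;
        newll.set_size(m.R);
        bool bad = false;
        for (int r = 0; r < m.R; ++r) {
          newll[r] = row_ll(m, st, r, Mprop(m.si[r], m.sp[r]));
          if (newll[r] == R_NegInf) { bad = true; break; }
          dll += newll[r] - st.ll[r];
        }
        if (bad) continue;
        if (std::log(unif_rand()) < dll + lpnew - st.sv_lp) {
          aSV.acc[q]++;
          st.sv = svn; st.L = Lnew; st.sv_lp = lpnew;
          st.M = Mprop; st.ll = newll;
        }
      }

      // --- interweaved centered Sigma sweep (M fixed; no likelihood) ----
      // conditional of the Sigma parameters given the residuals E = M - eta
      // is MVN(E; 0, Sigma) x prior; this decorrelates the residual scales
      // from the whitened latents (funnel)
      {
        arma::mat E = st.M - st.eta;
        arma::mat Et = E.t();
        auto mvn_term = [&](const arma::mat& Lc) -> double {
          arma::mat Z;
          if (!arma::solve(Z, arma::trimatl(Lc), Et)) return R_NegInf;
          double ld = 0.0;
          for (int j = 0; j < J; ++j) ld += std::log(Lc(j, j));
          return -n * ld - 0.5 * arma::accu(arma::square(Z));
        };
        double cur_mvn = mvn_term(st.L);
        for (int q = 0; q < nsv; ++q) {
          double d = aSVc.step[q] * norm_rand();
          arma::vec svn = st.sv;
          svn[q] += d;
          arma::mat Lnew;
          double lpnew;
          aSVc.tries[q]++;
          if (!build_L(m, svn, Lnew, lpnew)) continue;
          double new_mvn = mvn_term(Lnew);
          if (new_mvn == R_NegInf) continue;
          if (std::log(unif_rand()) <
              new_mvn - cur_mvn + lpnew - st.sv_lp) {
            aSVc.acc[q]++;
            st.sv = svn; st.L = Lnew; st.sv_lp = lpnew;
            cur_mvn = new_mvn;
          }
        }
        // re-whiten the latents under the (possibly) updated Sigma
        arma::mat Z;
        if (arma::solve(Z, arma::trimatl(st.L), Et)) st.zM = Z.t();
      }

      // --- per-site rotation: site effect vs latent row (likelihood
      // invariant; reallocates the site-common signal) -------------------
      if (m.cfg.ranef) {
        arma::vec u;
        bool oku = arma::solve(u, arma::trimatl(st.L),
                               arma::vec(J, arma::fill::ones));
        if (oku) {
          for (int i = 0; i < n; ++i) {
            double d = aRotM.step[i] * norm_rand();
            // site_i += d, M[i, ] -= d  =>  zs_i += d/sigma_S,
            // zM[i, ] -= d * u'
            double zs_new = st.zs[i] + d / st.sigma_S;
            arma::rowvec zrow = st.zM.row(i) - d * u.t();
            double dprior =
              -0.5 * (zs_new * zs_new - st.zs[i] * st.zs[i])
              - 0.5 * (arma::dot(zrow, zrow)
                       - arma::dot(st.zM.row(i), st.zM.row(i)));
            aRotM.tries[i]++;
            if (std::log(unif_rand()) < dprior) {
              aRotM.acc[i]++;
              st.zs[i] = zs_new;
              st.site_eff[i] += d;
              st.zM.row(i) = zrow;
              st.M.row(i) -= d;
            }
          }
        }
      }
    }

    // --- likelihood-invariant rotations against the intercept row -------
    if (m.cfg.ranef && has_intercept) {
      { // all observer effects vs intercept
        double d = aRotO.step[0] * norm_rand();
        double dzo = d / st.sigma_O;
        double dprior = 0.0;
        for (int o = 0; o < nO; ++o)
          dprior += -0.5 * ((st.zo[o] + dzo) * (st.zo[o] + dzo)
                            - st.zo[o] * st.zo[o]);
        dprior += R::dnorm(st.mu_B[0] - d, 0.0, m.cfg.scale_mu, 1)
                - R::dnorm(st.mu_B[0], 0.0, m.cfg.scale_mu, 1);
        aRotO.tries[0]++;
        if (std::log(unif_rand()) < dprior) {
          aRotO.acc[0]++;
          st.zo += dzo; st.obs_eff += d;
          st.mu_B[0] -= d; st.B.row(0) -= d;
          st.eta -= d; st.M -= d;
        }
      }
      { // all site effects vs intercept
        double d = aRotS.step[0] * norm_rand();
        double dzs = d / st.sigma_S;
        double dprior = 0.0;
        for (int i = 0; i < n; ++i)
          dprior += -0.5 * ((st.zs[i] + dzs) * (st.zs[i] + dzs)
                            - st.zs[i] * st.zs[i]);
        dprior += R::dnorm(st.mu_B[0] - d, 0.0, m.cfg.scale_mu, 1)
                - R::dnorm(st.mu_B[0], 0.0, m.cfg.scale_mu, 1);
        aRotS.tries[0]++;
        if (std::log(unif_rand()) < dprior) {
          aRotS.acc[0]++;
          st.zs += dzs; st.site_eff += d;
          st.mu_B[0] -= d; st.B.row(0) -= d;
          st.eta -= d; st.M -= d;
        }
      }
    }

    if (m.cfg.ranef) {
      // --- site effects (non-centered) ----------------------------------
      for (int i = 0; i < n; ++i) {
        double d = aZS.step[i] * norm_rand();
        double znew = st.zs[i] + d;
        double dprior = -0.5 * (znew * znew - st.zs[i] * st.zs[i]);
        double senew = st.sigma_S * znew;
        double dll = 0.0;
        const std::vector<arma::uword>& rows = m.rows_site[i];
        newll.set_size(rows.size());
        double old_se = st.site_eff[i];
        st.site_eff[i] = senew;
        for (size_t t = 0; t < rows.size(); ++t) {
          int r = rows[t];
          newll[t] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
          dll += newll[t] - st.ll[r];
        }
        st.site_eff[i] = old_se;
        aZS.tries[i]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aZS.acc[i]++;
          st.zs[i] = znew; st.site_eff[i] = senew;
          for (size_t t = 0; t < rows.size(); ++t) st.ll[rows[t]] = newll[t];
        }
      }
      // sigma_S: non-centered likelihood move ...
      {
        double d = aSS.step[0] * norm_rand();
        double snew = st.sigma_S * std::exp(d);
        double dprior = log_half_cauchy(snew, m.cfg.scale_sS)
                      - log_half_cauchy(st.sigma_S, m.cfg.scale_sS) + d;
        arma::vec se_new = snew * st.zs;
        arma::vec se_old = st.site_eff;
        st.site_eff = se_new;
        double dll = 0.0;
        newll.set_size(m.R);
        for (int r = 0; r < m.R; ++r) {
          newll[r] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
          dll += newll[r] - st.ll[r];
        }
        aSS.tries[0]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aSS.acc[0]++;
          st.sigma_S = snew; st.ll = newll;
        } else st.site_eff = se_old;
      }
      // ... and interweaved centered slice move (site_eff fixed)
      {
        arma::vec site = st.site_eff;
        double ss = arma::dot(site, site);
        double sc = m.cfg.scale_sS;
        auto logf = [&](double x) {
          double s = std::exp(x);
          return -(double)n * x - 0.5 * ss / (s * s)
               + log_half_cauchy(s, sc) + x;
        };
        double x0 = std::log(st.sigma_S);
        st.sigma_S = std::exp(slice_1d(x0, logf(x0), logf));
        st.zs = site / st.sigma_S;
      }

      // --- observer effects ----------------------------------------------
      for (int o = 0; o < nO; ++o) {
        double d = aZO.step[o] * norm_rand();
        double znew = st.zo[o] + d;
        double dprior = -0.5 * (znew * znew - st.zo[o] * st.zo[o]);
        double oenew = st.sigma_O * znew;
        const std::vector<arma::uword>& rows = m.rows_obs[o];
        newll.set_size(rows.size());
        double old_oe = st.obs_eff[o];
        st.obs_eff[o] = oenew;
        double dll = 0.0;
        for (size_t t = 0; t < rows.size(); ++t) {
          int r = rows[t];
          newll[t] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
          dll += newll[t] - st.ll[r];
        }
        st.obs_eff[o] = old_oe;
        aZO.tries[o]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aZO.acc[o]++;
          st.zo[o] = znew; st.obs_eff[o] = oenew;
          for (size_t t = 0; t < rows.size(); ++t) st.ll[rows[t]] = newll[t];
        }
      }
      {
        double d = aSO.step[0] * norm_rand();
        double snew = st.sigma_O * std::exp(d);
        double dprior = log_half_cauchy(snew, m.cfg.scale_sO)
                      - log_half_cauchy(st.sigma_O, m.cfg.scale_sO) + d;
        arma::vec oe_new = snew * st.zo;
        arma::vec oe_old = st.obs_eff;
        st.obs_eff = oe_new;
        double dll = 0.0;
        newll.set_size(m.R);
        for (int r = 0; r < m.R; ++r) {
          newll[r] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
          dll += newll[r] - st.ll[r];
        }
        aSO.tries[0]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aSO.acc[0]++;
          st.sigma_O = snew; st.ll = newll;
        } else st.obs_eff = oe_old;
      }
      {
        arma::vec oe = st.obs_eff;
        double ss = arma::dot(oe, oe);
        double sc = m.cfg.scale_sO;
        auto logf = [&](double x) {
          double s = std::exp(x);
          return -(double)nO * x - 0.5 * ss / (s * s)
               + log_half_cauchy(s, sc) + x;
        };
        double x0 = std::log(st.sigma_O);
        st.sigma_O = std::exp(slice_1d(x0, logf(x0), logf));
        st.zo = oe / st.sigma_O;
      }
    }

    // --- dispersion -----------------------------------------------------
    if (nb) {
      for (int j = 0; j < J; ++j) {
        double d = aTH.step[j] * norm_rand();
        double ltnew = st.log_theta[j] + d;
        double thnew = std::exp(ltnew), thold = std::exp(st.log_theta[j]);
        double dprior = log_theta_prior(thnew, m.cfg.theta_rate)
                      - log_theta_prior(thold, m.cfg.theta_rate) + d;
        double old_lt = st.log_theta[j];
        st.log_theta[j] = ltnew;
        const std::vector<arma::uword>& rows = m.rows_sp[j];
        newll.set_size(rows.size());
        double dll = 0.0;
        for (size_t t = 0; t < rows.size(); ++t) {
          int r = rows[t];
          newll[t] = row_ll(m, st, r, st.M(m.si[r], m.sp[r]));
          dll += newll[t] - st.ll[r];
        }
        st.log_theta[j] = old_lt;
        aTH.tries[j]++;
        if (std::log(unif_rand()) < dprior + dll) {
          aTH.acc[j]++;
          st.log_theta[j] = ltnew;
          for (size_t t = 0; t < rows.size(); ++t) st.ll[rows[t]] = newll[t];
        }
      }
    }

    // --- adaptation (warm-up only) --------------------------------------
    if (warm && (iter + 1) % 50 == 0) {
      ++batch;
      aB.update(batch); aZM.update(batch); aSV.update(batch);
      aSVc.update(batch); aZS.update(batch); aZO.update(batch);
      aTH.update(batch); aSS.update(batch); aSO.update(batch);
      aShift.update(batch); aRotO.update(batch); aRotS.update(batch);
      aRotM.update(batch);
    }

    // --- periodic cache resync (guards against float drift) -------------
    if ((iter + 1) % 500 == 0) {
      State chk = st;
      refresh_caches(m, chk);
      double dmax = arma::abs(chk.ll - st.ll).max();
      if (dmax > 1e-5) stop("internal cache inconsistency (%g)", dmax);
      st = chk;
    }

    // --- record ----------------------------------------------------------
    if (!warm) {
      int row = iter - n_warmup, c = 0;
      arma::mat Sigma = st.L * st.L.t();
      arma::vec sj = arma::sqrt(Sigma.diag());
      arma::mat Rm = Sigma / (sj * sj.t());
      Rm.diag().ones();
      for (int k = 0; k < K; ++k) out(row, c++) = st.mu_B[k];
      for (int k = 0; k < K; ++k) out(row, c++) = st.sigma_B[k];
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k) out(row, c++) = st.B(k, j);
      out(row, c++) = st.sigma_S;
      out(row, c++) = st.sigma_O;
      for (int i = 0; i < n; ++i) out(row, c++) = st.site_eff[i];
      for (int o = 0; o < nO; ++o) out(row, c++) = st.obs_eff[o];
      for (int j = 0; j < J; ++j)
        out(row, c++) = nb ? std::exp(st.log_theta[j]) : NA_REAL;
      for (int j = 0; j < J; ++j)
        out(row, c++) = m.cfg.latent ? sj[j] : NA_REAL;
      for (int j2 = 0; j2 < J; ++j2)
        for (int j1 = 0; j1 < J; ++j1)
          out(row, c++) = m.cfg.latent ? Sigma(j1, j2) : NA_REAL;
      for (int j2 = 0; j2 < J; ++j2)
        for (int j1 = 0; j1 < J; ++j1)
          out(row, c++) = m.cfg.latent ? Rm(j1, j2) : NA_REAL;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < n; ++i) out(row, c++) = st.M(i, j);
    }
    if ((iter + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  double accB = arma::accu(aB.step) / aB.step.n_elem; // summary only
  return List::create(
    _["draws"] = out,
    _["mean_step_B"] = accB);
}
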