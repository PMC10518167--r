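// Metropolis-within-Gibbs sampler for the data-augmented Jolly-Seber model
// of dive-state transitions over forward-distance bins.
//
// Latent structure per individual i (of M = n observed + M-n augmented):
//   path (b_i, e_i): in the vocal/foraging state for bins b..e, with no
//   re-entry once exited; b_i = -1 encodes "never in state within the grid".
//   entry_time_i: time already in state when entering bin 1 (only relevant
//   when b_i = bin 1), Uniform(0, maxTime) prior.
//   perp_i: perpendicular distance; data for observed individuals,
//   Uniform(0, W) latent for augmented pseudo-individuals.
//   w_i: superpopulation inclusion (Bernoulli(psi)).
//
// Transition kernel: entry with probability gamma_j per bin while never yet
// entered; persistence phi(t) = invlogit(alpha0 + alphaT * t) where t is
// the time already spent in state; exit is absorbing. Detection:
// Y_ij ~ Bernoulli(p_ij z_ij), logit(p_ij) = beta0 + beta1 * R_ij.
// Entry-rate structure (gamma_model): 0 = one shared rate; 1 = separate
// rate for bin 1 (initial presence) vs a shared rate for later bins;
// 2 = a free rate per bin. All rates get Uniform(0,1) priors and conjugate
// Beta Gibbs updates.
//
// The per-individual path update enumerates all (b, e) pairs (O(J^2), with
// O(1) per pair via prefix sums), which mixes far better than single-site
// flips on z.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_invlogit(double x) {
  if (x > 0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}
static inline double log1m_invlogit(double x) { return log_invlogit(-x); }
static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".cmr_mcmc_cpp")]]
List cmr_mcmc_cpp(IntegerMatrix Y,        // n x J observed histories
                  NumericVector perp_obs, // n observed perpendicular dists
                  NumericVector midpoints,// J signed forward midpoints
                  int M, double W, double T, double maxTime,
                  IntegerVector zone,     // nb_lo, nb_hi, f_lo, f_hi, s_lo, s_hi (1-based, 0 = empty)
                  int n_burn, int n_iter, int thin,
                  NumericVector init,     // gamma1, gamma, psi, alpha0, alphaT, beta0, beta1
                  LogicalVector fix,      // same order
                  int gamma_model,
                  double prior_sd) {
  const int n = Y.nrow();
  const int J = Y.ncol();
  const int n_aug = M - n;
  if (n_aug < 0) stop("M must be >= n");

  RNGScope scope;

  std::vector<double> gam(J);
  gam[0] = init[0];
  for (int j = 1; j < J; ++j) gam[j] = init[1];
  double psi = init[2], alpha0 = init[3], alphaT = init[4],
         beta0 = init[5], beta1 = init[6];
  const bool fix_g1 = fix[0], fix_g = fix[1], fix_psi = fix[2],
             fix_alpha = fix[3] && fix[4], fix_beta = fix[5] && fix[6];

  std::vector<double> lgam(J), cg(J + 1);  // cg[j] = sum_{k<j} log(1-gam_k)
  auto refresh_gamma_logs = [&]() {
    cg[0] = 0.0;
    for (int j = 0; j < J; ++j) {
      lgam[j] = std::log(gam[j]);
      cg[j + 1] = cg[j] + std::log1p(-gam[j]);
    }
  };

  // latent state
  std::vector<int> b(M), e(M), w(M, 1);
  std::vector<double> entry(M), perp(M);
  std::vector<int> first1(n), last1(n);
  for (int i = 0; i < n; ++i) {
    int f = -1, l = -1;
    for (int j = 0; j < J; ++j)
      if (Y(i, j) == 1) { if (f < 0) f = j; l = j; }
    if (f < 0) stop("observed history with no detection");
    first1[i] = f; last1[i] = l;
    b[i] = f; e[i] = l;
    perp[i] = perp_obs[i];
    entry[i] = 0.5 * maxTime;
  }
  for (int i = n; i < M; ++i) {
    b[i] = -1; e[i] = -1; w[i] = 0;
    perp[i] = R::runif(0.0, W);
    entry[i] = R::runif(0.0, maxTime);
  }

  // radial distances: observed fixed, augmented depend on latent perp
  std::vector<double> radial((size_t)M * J);
  auto set_radial = [&](int i) {
    for (int j = 0; j < J; ++j)
      radial[(size_t)i * J + j] =
        std::sqrt(perp[i] * perp[i] + midpoints[j] * midpoints[j]);
  };
  for (int i = 0; i < M; ++i) set_radial(i);

  // persistence log-prob tables for paths entering at bins >= 2 (offset 0):
  // P2[d] = sum_{m=1..d} log phi(m T); E2[d] = log(1 - phi(d T))
  std::vector<double> P2(J + 1, 0.0), E2(J + 1, 0.0);
  auto refresh_P2 = [&]() {
    for (int d = 1; d <= J; ++d) {
      double x = alpha0 + alphaT * (d * T);
      P2[d] = P2[d - 1] + log_invlogit(x);
      E2[d] = log1m_invlogit(x);
    }
  };

  // per-individual tables for paths entering at bin 1 (offset entry[i])
  std::vector<double> P1((size_t)M * (J + 1)), E1((size_t)M * (J + 1));
  auto refresh_P1_i = [&](int i) {
    double *p1 = &P1[(size_t)i * (J + 1)], *e1 = &E1[(size_t)i * (J + 1)];
    p1[0] = 0.0; e1[0] = 0.0;
    for (int d = 1; d <= J; ++d) {
      double x = alpha0 + alphaT * (entry[i] + d * T);
      p1[d] = p1[d - 1] + log_invlogit(x);
      e1[d] = log1m_invlogit(x);
    }
  };

  // persistence + exit log-probability of an active path (b, e), 0-based
  auto path_state_ll = [&](int i, int bb, int ee) {
    int d = ee - bb;
    if (bb == 0) {
      const double *p1 = &P1[(size_t)i * (J + 1)],
                   *e1 = &E1[(size_t)i * (J + 1)];
      double ll = p1[d];
      if (ee < J - 1) ll += e1[d + 1];
      return ll;
    }
    double ll = P2[d];
    if (ee < J - 1) ll += E2[d + 1];
    return ll;
  };

  std::vector<double> llin(J), C(J + 1), logw(J * J + 2);
  std::vector<int> cand_b(J * J + 2), cand_e(J * J + 2);

  auto fill_obs_prefix = [&](int i) {
    C[0] = 0.0;
    const double *rad = &radial[(size_t)i * J];
    for (int j = 0; j < J; ++j) {
      double x = beta0 + beta1 * rad[j];
      double ll = (i < n && Y(i, j) == 1) ? log_invlogit(x)
                                          : log1m_invlogit(x);
      llin[j] = ll;
      C[j + 1] = C[j] + ll;
    }
  };

  // alpha-dependent part of the state log-likelihood given current paths
  auto state_ll_all = [&](double a0, double aT) {
    double ll = 0.0;
    for (int i = 0; i < M; ++i) {
      if (b[i] < 0) continue;
      int d = e[i] - b[i];
      double off = (b[i] == 0) ? entry[i] : 0.0;
      for (int m = 1; m <= d; ++m)
        ll += log_invlogit(a0 + aT * (off + m * T));
      if (e[i] < J - 1)
        ll += log1m_invlogit(a0 + aT * (off + (d + 1) * T));
    }
    return ll;
  };
  auto obs_ll_all = [&](double b0, double b1) {
    double ll = 0.0;
    for (int i = 0; i < M; ++i) {
      if (b[i] < 0) continue;
      const double *rad = &radial[(size_t)i * J];
      for (int j = b[i]; j <= e[i]; ++j) {
        double x = b0 + b1 * rad[j];
        ll += (i < n && Y(i, j) == 1) ? log_invlogit(x) : log1m_invlogit(x);
      }
    }
    return ll;
  };

  refresh_gamma_logs();
  refresh_P2();
  for (int i = 0; i < M; ++i) refresh_P1_i(i);

  double step_a0 = 0.4, step_aT = 3e-4, step_b0 = 0.3, step_b1 = 1e-4;
  double step_ridge = 1.0, step_bridge = 0.5;
  double step_entry = 0.2 * maxTime, step_perp = 0.2 * W;

  const int n_keep = (n_iter + thin - 1) / thin;
  NumericMatrix par_draws(n_keep, 7);
  colnames(par_draws) = CharacterVector::create(
    "gamma1", "gamma", "psi", "alpha0", "alphaT", "beta0", "beta1");
  IntegerMatrix Fj_draws(n_keep, J), Sj_draws(n_keep, J);
  IntegerMatrix count_draws(n_keep, 4);
  colnames(count_draws) = CharacterVector::create("F_T", "S_T", "N_B",
                                                  "N_B_full");
  NumericMatrix disc_draws(n_keep, 2);
  colnames(disc_draws) = CharacterVector::create("D_obs", "D_rep");

  std::vector<double> obs_count(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) obs_count[j] += Y(i, j);

  int kept = 0;
  double acc_a = 0, acc_bp = 0, try_a = 0, try_bp = 0;
  std::vector<double> succ(J), fail(J);

  for (int it = 0; it < n_burn + n_iter; ++it) {
    bool burning = it < n_burn;

    // ---- 1. per-individual path update by enumeration ----
    double log_psi = std::log(psi);
    double p_never_w1 = psi * std::exp(cg[J]);
    for (int i = 0; i < M; ++i) {
      fill_obs_prefix(i);
      int ncand = 0;
      int bmax = (i < n) ? first1[i] : J - 1;
      for (int bb = 0; bb <= bmax; ++bb) {
        int emin = (i < n) ? std::max(bb, last1[i]) : bb;
        double entry_ll = cg[bb] + lgam[bb];
        for (int ee = emin; ee < J; ++ee) {
          cand_b[ncand] = bb; cand_e[ncand] = ee;
          logw[ncand++] = log_psi + entry_ll +
            path_state_ll(i, bb, ee) + (C[ee + 1] - C[bb]);
        }
      }
      if (i >= n) {  // never-in-state candidate (absorbs w = 0)
        cand_b[ncand] = -1; cand_e[ncand] = -1;
        logw[ncand++] = std::log((1.0 - psi) + p_never_w1);
      }
      double mx = logw[0];
      for (int k = 1; k < ncand; ++k) mx = std::max(mx, logw[k]);
      double tot = 0.0;
      for (int k = 0; k < ncand; ++k) {
        logw[k] = std::exp(logw[k] - mx);
        tot += logw[k];
      }
      double u = R::unif_rand() * tot, cum = 0.0;
      int pick = ncand - 1;
      for (int k = 0; k < ncand; ++k) {
        cum += logw[k];
        if (u <= cum) { pick = k; break; }
      }
      b[i] = cand_b[pick]; e[i] = cand_e[pick];
      if (b[i] < 0)
        w[i] = (R::unif_rand() < p_never_w1 / (p_never_w1 + 1.0 - psi)) ? 1 : 0;
      else w[i] = 1;
    }

    // ---- 2. entry_time update ----
    for (int i = 0; i < M; ++i) {
      if (b[i] == 0) {
        double prop = entry[i] + R::norm_rand() * step_entry;
        if (prop > 0 && prop < maxTime) {
          double cur_ll = path_state_ll(i, 0, e[i]);
          double saved = entry[i];
          entry[i] = prop;
          refresh_P1_i(i);
          double new_ll = path_state_ll(i, 0, e[i]);
          if (std::log(R::unif_rand()) >= new_ll - cur_ll) {
            entry[i] = saved;
            refresh_P1_i(i);
          }
        }
      } else {
        entry[i] = R::runif(0.0, maxTime);
        refresh_P1_i(i);
      }
    }

    // ---- 3. latent perpendicular distance (augmented only) ----
    for (int i = n; i < M; ++i) {
      if (b[i] < 0) {
        perp[i] = R::runif(0.0, W);
        set_radial(i);
        continue;
      }
      double prop = perp[i] + R::norm_rand() * step_perp;
      if (prop < 0) prop = -prop;
      if (prop > W) prop = 2 * W - prop;
      if (prop < 0 || prop > W) continue;
      double cur_ll = 0.0, new_ll = 0.0;
      for (int j = b[i]; j <= e[i]; ++j) {
        double rc = radial[(size_t)i * J + j];
        double rp = std::sqrt(prop * prop + midpoints[j] * midpoints[j]);
        cur_ll += log1m_invlogit(beta0 + beta1 * rc);
        new_ll += log1m_invlogit(beta0 + beta1 * rp);
      }
      if (std::log(R::unif_rand()) < new_ll - cur_ll) {
        perp[i] = prop;
        set_radial(i);
      }
    }

    // ---- 4. entry rates (Gibbs, Beta(1,1) priors) ----
    if (!(fix_g1 && fix_g)) {
      std::fill(succ.begin(), succ.end(), 0.0);
      std::fill(fail.begin(), fail.end(), 0.0);
      for (int i = 0; i < M; ++i) {
        if (!w[i]) continue;
        int upto = (b[i] < 0) ? J : b[i];
        for (int j = 0; j < upto; ++j) fail[j] += 1.0;
        if (b[i] >= 0) succ[b[i]] += 1.0;
      }
      if (gamma_model == 0) {          // one shared rate
        if (!fix_g) {
          double s = 0, f = 0;
          for (int j = 0; j < J; ++j) { s += succ[j]; f += fail[j]; }
          double g = R::rbeta(1.0 + s, 1.0 + f);
          for (int j = 0; j < J; ++j) gam[j] = g;
        }
      } else if (gamma_model == 1) {   // bin 1 vs later bins
        if (!fix_g1) gam[0] = R::rbeta(1.0 + succ[0], 1.0 + fail[0]);
        if (!fix_g) {
          double s = 0, f = 0;
          for (int j = 1; j < J; ++j) { s += succ[j]; f += fail[j]; }
          double g = R::rbeta(1.0 + s, 1.0 + f);
          for (int j = 1; j < J; ++j) gam[j] = g;
        }
      } else {                         // free rate per bin
        for (int j = 0; j < J; ++j) {
          if (j == 0 ? fix_g1 : fix_g) continue;
          gam[j] = R::rbeta(1.0 + succ[j], 1.0 + fail[j]);
        }
      }
      refresh_gamma_logs();
    }

    // ---- 5. psi (Gibbs, Beta(1,1) prior) ----
    if (!fix_psi) {
      double sw = 0;
      for (int i = 0; i < M; ++i) sw += w[i];
      psi = R::rbeta(1.0 + sw, 1.0 + M - sw);
    }

    // ---- 6. persistence coefficients ----
    // univariate walks plus a joint move along the (alpha0, alphaT) ridge
    // (shift the intercept, counter-shift the slope so phi at the typical
    // in-state time is preserved) -- the ridge is long and thin, and the
    // joint move is what gives the intercept a usable effective sample size
    if (!fix_alpha) {
      double t_typ = 0.0; int n_act = 0;
      for (int i = 0; i < M; ++i) {
        if (b[i] < 0) continue;
        double off = (b[i] == 0) ? entry[i] : 0.0;
        t_typ += off + 0.5 * (e[i] - b[i] + 1) * T;
        n_act++;
      }
      t_typ = (n_act > 0) ? t_typ / n_act : maxTime / 2;
      double cur_ll = state_ll_all(alpha0, alphaT) +
        R::dnorm(alpha0, 0.0, prior_sd, 1) +
        R::dnorm(alphaT, 0.0, prior_sd, 1);
      for (int rep = 0; rep < 3; ++rep) {
        double a0 = alpha0, aT = alphaT;
        if (rep == 0) a0 += R::norm_rand() * step_a0;
        else if (rep == 1) aT += R::norm_rand() * step_aT;
        else {
          double d = R::norm_rand() * step_ridge;
          a0 += d; aT -= d / t_typ;
        }
        double new_ll = state_ll_all(a0, aT) +
          R::dnorm(a0, 0.0, prior_sd, 1) + R::dnorm(aT, 0.0, prior_sd, 1);
        bool a = std::log(R::unif_rand()) < new_ll - cur_ll;
        if (a) { alpha0 = a0; alphaT = aT; cur_ll = new_ll; }
        if (burning) {
          double f = std::exp(((a ? 1.0 : 0.0) - 0.35) / std::sqrt(it + 1.0));
          if (rep == 0) step_a0 *= f;
          else if (rep == 1) step_aT *= f;
          else step_ridge *= f;
        } else { try_a += 1; acc_a += a; }
      }
      refresh_P2();
      for (int i = 0; i < M; ++i) refresh_P1_i(i);
    }

    // ---- 7. detection coefficients (same move structure) ----
    if (!fix_beta) {
      double r_typ = 0.0; int n_r = 0;
      for (int i = 0; i < M; ++i) {
        if (b[i] < 0) continue;
        for (int j = b[i]; j <= e[i]; ++j) {
          r_typ += radial[(size_t)i * J + j];
          n_r++;
        }
      }
      r_typ = (n_r > 0) ? r_typ / n_r : W;
      double cur_ll = obs_ll_all(beta0, beta1) +
        R::dnorm(beta0, 0.0, prior_sd, 1) +
        R::dnorm(beta1, 0.0, prior_sd, 1);
      for (int rep = 0; rep < 3; ++rep) {
        double b0 = beta0, b1 = beta1;
        if (rep == 0) b0 += R::norm_rand() * step_b0;
        else if (rep == 1) b1 += R::norm_rand() * step_b1;
        else {
          double d = R::norm_rand() * step_bridge;
          b0 += d; b1 -= d / r_typ;
        }
        double new_ll = obs_ll_all(b0, b1) +
          R::dnorm(b0, 0.0, prior_sd, 1) + R::dnorm(b1, 0.0, prior_sd, 1);
        bool a = std::log(R::unif_rand()) < new_ll - cur_ll;
        if (a) { beta0 = b0; beta1 = b1; cur_ll = new_ll; }
        if (burning) {
          double f = std::exp(((a ? 1.0 : 0.0) - 0.35) / std::sqrt(it + 1.0));
          if (rep == 0) step_b0 *= f;
          else if (rep == 1) step_b1 *= f;
          else step_bridge *= f;
        } else { try_bp += 1; acc_bp += a; }
      }
    }

    // ---- record ----
    if (!burning && ((it - n_burn) % thin == 0)) {
      double gmean = 0.0;
      for (int j = 1; j < J; ++j) gmean += gam[j];
      par_draws(kept, 0) = gam[0];
      par_draws(kept, 1) = gmean / (J - 1);
      par_draws(kept, 2) = psi;
      par_draws(kept, 3) = alpha0;
      par_draws(kept, 4) = alphaT;
      par_draws(kept, 5) = beta0;
      par_draws(kept, 6) = beta1;
      std::vector<int> Fj(J, 0), Sj(J, 0);
      int nb_zone = 0, nb_full = 0;
      for (int i = 0; i < M; ++i) {
        if (b[i] < 0) continue;
        nb_full++;
        Fj[b[i]]++;
        if (e[i] < J - 1) Sj[e[i] + 1]++;
        if (zone[0] > 0 && b[i] + 1 <= zone[1] && e[i] + 1 >= zone[0])
          nb_zone++;
      }
      int FT = 0, ST = 0;
      if (zone[2] > 0)
        for (int j = zone[2]; j <= zone[3]; ++j) FT += Fj[j - 1];
      if (zone[4] > 0)
        for (int j = zone[4]; j <= zone[5]; ++j) ST += Sj[j - 1];
      for (int j = 0; j < J; ++j) {
        Fj_draws(kept, j) = Fj[j];
        Sj_draws(kept, j) = Sj[j];
      }
      count_draws(kept, 0) = FT;
      count_draws(kept, 1) = ST;
      count_draws(kept, 2) = nb_zone;
      count_draws(kept, 3) = nb_full;

      // Freeman-Tukey discrepancy on per-bin detection counts (observed
      // individuals), observed vs replicated under the current draw
      double D_obs = 0.0, D_rep = 0.0;
      for (int j = 0; j < J; ++j) {
        double expct = 0.0; int repc = 0;
        for (int i = 0; i < n; ++i) {
          if (b[i] >= 0 && j >= b[i] && j <= e[i]) {
            double p = invlogit(beta0 + beta1 * radial[(size_t)i * J + j]);
            expct += p;
            if (R::unif_rand() < p) repc++;
          }
        }
        double so = std::sqrt(obs_count[j]) - std::sqrt(expct);
        double sr = std::sqrt((double)repc) - std::sqrt(expct);
        D_obs += so * so;
        D_rep += sr * sr;
      }
      disc_draws(kept, 0) = D_obs;
      disc_draws(kept, 1) = D_rep;
      kept++;
    }
  }

  return List::create(
    _["params"] = par_draws,
    _["Fj"] = Fj_draws,
    _["Sj"] = Sj_draws,
    _["counts"] = count_draws,
    _["discrepancy"] = disc_draws,
    _["acceptance"] = NumericVector::create(
      _["persistence"] = try_a > 0 ? acc_a / try_a : NA_REAL,
      _["detection"] = try_bp > 0 ? acc_bp / try_bp : NA_REAL)
  );
}
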