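test_that("time in state accumulates entry time plus whole bins", {
  expect_equal(time_in_state(c(1, 1, 1), 600, 60, 3), 720)
  expect_equal(time_in_state(c(0, 1, 1), 600, 60, 3), 60)
  expect_equal(time_in_state(c(0, 0, 0), 600, 60, 2), 0)
  expect_equal(time_in_state(c(1, 1, 1), 600, 60, 1), 600)
})

test_that("persistence and detection are inverse-logit linear", {
  expect_equal(persistence_prob(0, 0, 1000), 0.5)
  expect_equal(persistence_prob(2, -0.05, 40), 0.5)
  expect_equal(detection_prob(0, 0, 500), 0.5)
  expect_equal(detection_prob(0, -1 / 1000, 0), 0.5)
  expect_lt(detection_prob(0, -1 / 1000, 1e7), 1e-6)
  tgrid <- seq(0, 3000, by = 50)
  expect_true(all(diff(persistence_prob(1, -0.002, tgrid)) < 0))
  expect_true(all(diff(detection_prob(1, -0.001, tgrid)) < 0))
  expect_error(persistence_prob(0, 0, -5), "non-negative")
  expect_error(detection_prob(0, 0, -5), "non-negative")
})

test_that("state path log-likelihoods match direct substitution", {
  pars <- list(gamma = 0.3, alpha0 = 1, alphaT = -0.001)
  Td <- 60
  # J = 2, in state both bins: entry at bin 1, persist once
  phi2 <- persistence_prob(1, -0.001, 600 + 60)
  expect_equal(state_loglik(c(1, 1), pars, Td, entry_time = 600),
               log(0.3) + log(phi2))
  # never in state
  expect_equal(state_loglik(c(0, 0), pars, Td), 2 * log(0.7))
  # re-entry is invalid
  expect_error(state_loglik(c(1, 0, 1), pars, Td), "re-entry")
})

test_that("path probabilities sum to one over all valid paths", {
  for (J in 3:4) {
    z_all <- list(rep(0, J))
    for (b in 1:J) for (e in b:J) {
      z <- rep(0, J); z[b:e] <- 1
      z_all[[length(z_all) + 1]] <- z
    }
    for (pars in list(list(gamma = 0.3, alpha0 = 1, alphaT = 0),
                      list(gamma = 0.55, alpha0 = 2, alphaT = -0.002),
                      list(gamma = c(0.5, rep(0.1, J - 1)), alpha0 = 0.5,
                           alphaT = -0.01))) {
      tot <- sum(vapply(z_all, function(z)
        exp(state_loglik(z, pars, 60, entry_time = 300)), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("derived counts match hand counts on a small state matrix", {
  z <- rbind(c(0, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 0))
  zone_all <- zone_of_overlap(c(1, 4), c(1, 4), c(1, 4), 4)
  d <- derived_counts(z, zone_all)
  expect_equal(d$F_j, c(1, 1, 0, 0))
  expect_equal(d$S_j, c(0, 0, 1, 1))
  expect_equal(d$F_T, 2)
  expect_equal(d$S_T, 2)
  expect_equal(d$N_B, 2)

  zone_mid <- zone_of_overlap(c(1, 4), c(2, 3), c(2, 3), 4)
  d2 <- derived_counts(z, zone_mid)
  expect_equal(d2$F_T, 1)
  expect_equal(d2$S_T, 1)

  d0 <- derived_counts(matrix(0L, 3, 4), zone_all)
  expect_equal(unlist(d0[c("F_T", "S_T", "N_B")]), c(F_T = 0, S_T = 0, N_B = 0))

  expect_error(zone_of_overlap(c(1, 5), c(1, 4), c(1, 4), 4), "within 1..4")
  expect_error(zone_of_overlap(c(3, 2), c(1, 4), c(1, 4), 4), "within 1..4")
})

test_that("zone construction shifts the visual window by the silent phases", {
  cfg <- tiny_cfg(ahead = 1500, behind = 750, width = 150, speed = 2.5)
  J <- cfg$n_bins  # 15 bins, midpoints 1425 ... -675

  # zero silent durations: both zones are the visual window bins
  z0 <- make_zone(cfg, 0, 0, visual_window = c(0, 750))
  win_bins <- range(which(cfg$midpoints >= 0 & cfg$midpoints <= 750))
  expect_equal(z0$f, win_bins)
  expect_equal(z0$s, win_bins)

  # 5-minute silent ascent at 2.5 m/s = 750 m = 5 bins ahead
  z1 <- make_zone(cfg, 0, 300, visual_window = c(0, 750))
  expect_equal(z1$s, win_bins - 5L)

  # silent descent shifts the entry zone aft by the same amount
  z2 <- make_zone(cfg, 300, 0, visual_window = c(0, 750))
  expect_equal(z2$f, win_bins + 5L)

  # a shift beyond the grid empties the zone with a warning
  expect_warning(z3 <- make_zone(cfg, 2000, 0, visual_window = c(0, 750)),
                 "empty zone")
  expect_null(z3$f)

  # an empty transition zone gives zero duplicate counts downstream
  z <- rbind(c(0, 1, 1, 0))
  zone_empty <- zone_of_overlap(c(1, 4), NULL, NULL, 4)
  d <- derived_counts(z, zone_empty)
  expect_equal(d$F_T, 0)
  expect_equal(d$S_T, 0)
})

test_that("capture-recapture fit validates its inputs", {
  cfg <- tiny_cfg(ahead = 400, behind = 0, width = 100)
  zone <- full_zone(cfg)
  Y <- rbind(c(0, 1, 1, 0))
  expect_error(fit_cmr(Y[0, , drop = FALSE], numeric(0), cfg, zone, M = 5),
               "no acoustic events")
  expect_error(fit_cmr(Y, 100, cfg, zone, M = 1), "must exceed")
  expect_error(fit_cmr(cbind(Y, 0), c(100, NA), cfg, zone, M = 5),
               "per bin")
  expect_error(fit_cmr(rbind(c(0, 0, 0, 0)), 100, cfg, zone, M = 5),
               "at least one detection")
})

test_that("sampler path posterior matches exhaustive enumeration", {
  cfg <- tiny_cfg(ahead = 400, behind = 0, width = 100)  # J = 4
  J <- cfg$n_bins
  pars <- list(gamma = 0.3, psi = 0.7, alpha0 = 1.2, alphaT = 0,
               beta0 = 0.5, beta1 = -4e-4)
  Y <- rbind(c(0, 1, 1, 0),
             c(1, 0, 1, 0))
  perp <- c(800, 1500)

  # exact per-individual posteriors (2 observed + 1 augmented)
  o1 <- oracle_posterior(Y[1, ], perp[1], pars, cfg)
  o2 <- oracle_posterior(Y[2, ], perp[2], pars, cfg)
  oA <- oracle_posterior_aug(pars, cfg)
  EF <- oracle_EF(o1, J) + oracle_EF(o2, J) + oracle_EF(oA, J)
  ES <- oracle_ES(o1, J) + oracle_ES(o2, J) + oracle_ES(oA, J)
  ENB <- oracle_ENB(o1) + oracle_ENB(o2) + oracle_ENB(oA)

  set.seed(7)
  fit <- fit_cmr(Y, perp, cfg, full_zone(cfg, from = 1), M = 3,
                 mcmc = list(burn = 1000, iter = 20000, thin = 1,
                             chains = 1),
                 gamma_model = "constant",
                 fix = list(gamma = pars$gamma, psi = pars$psi,
                            alpha0 = pars$alpha0, alphaT = pars$alphaT,
                            beta0 = pars$beta0, beta1 = pars$beta1))
  expect_equal(colMeans(fit$Fj_draws), EF, tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(colMeans(fit$Sj_draws), ES, tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(mean(fit$draws$N_B_full), ENB, tolerance = 0.01)
})

test_that("perfect detection collapses the superpopulation to the events", {
  cfg <- recovery_cfg()
  set.seed(13)
  truth <- default_truth()
  d <- sim_cmr_model(40, truth, cfg)
  f <- fit_cmr(d$hist, d$perp, cfg, full_zone(cfg), M = 2 * nrow(d$hist),
               mcmc = list(burn = 300, iter = 600, thin = 1, chains = 1),
               fix = list(beta0 = 15, beta1 = 0))
  expect_true(mean(f$draws$N_B_full == nrow(d$hist)) > 0.99)
})

test_that("duplicate transitions are bounded by twice the superpopulation", {
  cfg <- recovery_cfg()
  set.seed(14)
  d <- sim_cmr_model(80, default_truth(), cfg)
  zone <- full_zone(cfg)   # all three zones identical
  f <- fit_cmr(d$hist, d$perp, cfg, zone, M = 2 * nrow(d$hist),
               mcmc = list(burn = 400, iter = 800, thin = 1, chains = 1))
  expect_true(all(f$draws$F_T + f$draws$S_T <= 2 * f$draws$N_B))
  expect_true(all(f$draws$N_B_full >= f$n))
})

test_that("augmentation size does not drive the superpopulation estimate", {
  cfg <- recovery_cfg()
  set.seed(15)
  d <- sim_cmr_model(60, default_truth(), cfg)
  post_mean <- function(mf, s) {
    set.seed(100 + s)
    f <- fit_cmr(d$hist, d$perp, cfg, full_zone(cfg),
                 M = ceiling(mf * nrow(d$hist)),
                 mcmc = list(burn = 600, iter = 1500, thin = 1, chains = 1))
    mean(f$draws$N_B_full)
  }
  m1 <- vapply(1:3, function(s) post_mean(2, s), numeric(1))
  m2 <- vapply(1:3, function(s) post_mean(3.5, s), numeric(1))
  se_diff <- sqrt(stats::var(m1) / 3 + stats::var(m2) / 3)
  expect_lt(abs(mean(m1) - mean(m2)), 4 * se_diff + 0.02 * mean(m1))
})

test_that("multi-chain fits report convergence diagnostics", {
  cfg <- recovery_cfg()
  set.seed(16)
  d <- sim_cmr_model(50, default_truth(), cfg)
  f <- fit_cmr(d$hist, d$perp, cfg, full_zone(cfg), M = 2 * nrow(d$hist),
               mcmc = list(burn = 500, iter = 1000, thin = 2, chains = 2))
  expect_false(is.null(f$rhat))
  expect_true(all(is.finite(f$rhat)))
  expect_named(f$rhat)
})
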