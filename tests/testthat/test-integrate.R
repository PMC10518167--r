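test_that("DS-DS sums the platform posteriors with zero duplicates", {
  e <- estimate_dsds(fake_ds_fit(rep(306, 100)), fake_ds_fit(rep(289, 100)))
  expect_equal(unique(e$draws$n_t), 595)
  expect_equal(unique(e$draws$n_d), 0)
  expect_identical(e$method, "DS-DS")

  e0 <- estimate_dsds(fake_ds_fit(rep(306, 100)), fake_ds_fit(rep(0, 100)))
  expect_equal(unique(e0$draws$n_t), 306)

  # for independent positive posteriors the summed CV cannot exceed the
  # larger component CV
  set.seed(50)
  a <- rlnorm(5000, log(200), 0.3)
  b <- rlnorm(5000, log(150), 0.15)
  es <- estimate_dsds(fake_ds_fit(a), fake_ds_fit(b))
  expect_lte(posterior_cv(es$draws$n_t),
             max(posterior_cv(a), posterior_cv(b)))
})

test_that("CMR-DS subtracts zone-restricted transitions as duplicates", {
  ns <- fake_ds_fit(rep(100, 200))
  cmr <- fake_cmr_fit(N_B = rep(80, 200), F_T = rep(20, 200),
                      S_T = rep(10, 200))
  e <- estimate_cmrds(ns, cmr)
  expect_equal(unique(e$draws$n_t), 150)
  expect_equal(unique(e$draws$n_d), 30)

  # no transitions reduces exactly to DS-DS
  cmr0 <- fake_cmr_fit(N_B = rep(80, 200), F_T = rep(0, 200),
                       S_T = rep(0, 200))
  e0 <- estimate_cmrds(ns, cmr0)
  expect_equal(e0$draws$n_t, estimate_dsds(ns, fake_ds_fit(rep(80, 200)))$draws$n_t)

  # draws where duplicates exceed all detections are flagged
  bad <- fake_cmr_fit(N_B = rep(10, 100), F_T = rep(80, 100),
                      S_T = rep(80, 100))
  expect_warning(estimate_cmrds(ns, bad), "duplicates")
})

test_that("hybrid rates are per-capita per-bin transition rates", {
  k <- 300
  zone <- zone_of_overlap(c(1, 12), c(3, 12), c(1, 10), 12)
  Fj <- matrix(2, k, 12)   # 2 entries per bin in every draw
  Sj <- matrix(2, k, 12)
  fit <- fake_cmr_fit(N_B = rep(40, k), F_T = rep(20, k), S_T = rep(20, k),
                      Fj = Fj, Sj = Sj, zone = zone)
  r <- hybrid_rates(fit)
  expect_equal(r$sbar, 2)
  expect_equal(mean(r$p_s), 0.05)   # 2 / 40
  expect_equal(r$zone_f, 10)
  expect_equal(r$zone_s, 10)
})

test_that("hybrid estimator scales DS abundance by the subset rates", {
  k <- 100
  ns <- fake_ds_fit(rep(306, k))
  nb <- fake_ds_fit(rep(100, k))
  zone <- zone_of_overlap(c(1, 12), c(1, 10), c(1, 10), 12)
  # rates chosen so F_j^(H) = 100 * 0.02 = 2 per bin -> F_T^(H) = 20
  fit <- fake_cmr_fit(N_B = rep(50, k), F_T = rep(10, k), S_T = rep(10, k),
                      Fj = matrix(1, k, 12), Sj = matrix(0, k, 12),
                      zone = zone)
  r <- hybrid_rates(fit)
  expect_equal(mean(r$p_f), 0.02)
  e <- estimate_hybrid(ns, nb, r)
  expect_equal(unique(e$draws$n_d), 20)
  expect_equal(unique(e$draws$n_t), 306 + 100 - 20)

  # zero rates reduce to DS-DS
  fit0 <- fake_cmr_fit(N_B = rep(50, k), F_T = rep(0, k), S_T = rep(0, k),
                       Fj = matrix(0, k, 12), Sj = matrix(0, k, 12),
                       zone = zone)
  e0 <- estimate_hybrid(ns, nb, hybrid_rates(fit0))
  expect_equal(unique(e0$draws$n_t), 406)
})

test_that("availability is the draw-wise surface share", {
  # printed point values: N_S = 306, N_T = 426
  av <- availability(abundance_estimate(306, 120, 0, 426))
  expect_equal(round(av$summary[["mean"]], 2), 0.72)
  expect_equal(availability(abundance_estimate(5, 0, 0, 5))$summary[["mean"]], 1)
  expect_equal(availability(abundance_estimate(0, 10, 0, 10))$summary[["mean"]], 0)

  # scale invariance: multiplying all abundances leaves a_S unchanged
  set.seed(51)
  ns <- rlnorm(1000, 5, 0.2); nb <- rlnorm(1000, 5, 0.2)
  nd <- 0.3 * nb
  a1 <- availability(abundance_estimate(ns, nb, nd))$draws
  a2 <- availability(abundance_estimate(7 * ns, 7 * nb, 7 * nd))$draws
  expect_equal(a1, a2)
})

test_that("the N_T identity holds exactly in stored draws", {
  set.seed(52)
  ns <- rlnorm(500, 4, 0.3); nb <- rlnorm(500, 4, 0.3); nd <- runif(500, 0, 30)
  for (e in list(abundance_estimate(ns, nb, nd),
                 estimate_dsds(fake_ds_fit(ns), fake_ds_fit(nb)))) {
    expect_equal(e$draws$n_t, e$draws$n_s + e$draws$n_b - e$draws$n_d)
  }
  expect_error(abundance_estimate(ns, nb, nd, n_t = ns), "identity")
})

test_that("negative-total draws are retained but flagged", {
  ns <- c(10, 10); nb <- c(5, 5); nd <- c(30, 0)
  expect_warning(e <- abundance_estimate(ns, nb, nd), "non-positive")
  expect_equal(e$draws$n_t, c(-15, 15))
  expect_equal(e$frac_nonpositive, 0.5)
  expect_warning(av <- availability(e), "dropped")
  expect_equal(length(av$draws), 1)
})

test_that("mismatched draw counts are resampled with a warning", {
  expect_warning(
    e <- estimate_dsds(fake_ds_fit(rep(10, 100)), fake_ds_fit(rep(5, 60))),
    "resampling")
  expect_equal(nrow(e$draws), 100)
})
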