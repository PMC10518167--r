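test_that("dive timelines partition time with no gaps or overlaps", {
  set.seed(60)
  p <- dive_cycle_params()
  tl <- simulate_timeline(p, duration = 50000)
  expect_true(all(diff(tl$start) > 0))
  expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  expect_lte(tl$start[1], 0)
  expect_gte(tl$end[nrow(tl)], 50000)
  expect_true(all(tl$end > tl$start))
  expect_setequal(unique(tl$phase),
                  c("surface", "descent", "vocal", "ascent"))
})

test_that("zero silent phases leave only surface and vocal states", {
  set.seed(61)
  p <- dive_cycle_params(descent_mean = 0, ascent_mean = 0)
  tl <- simulate_timeline(p, duration = 30000)
  expect_setequal(unique(tl$phase), c("surface", "vocal"))
})

test_that("long-run surface fraction matches the renewal expectation", {
  set.seed(62)
  p <- dive_cycle_params(individual_cv = 0)
  cycle <- with(p, surface_mean + descent_mean + vocal_mean + ascent_mean)
  dur <- 1e4 * cycle
  tl <- simulate_timeline(p, duration = dur)
  tl$start <- pmax(tl$start, 0)
  tl$end <- pmin(tl$end, dur)
  frac <- sum((tl$end - tl$start)[tl$phase == "surface"]) / dur
  expect_equal(frac, p$surface_mean / cycle, tolerance = 0.02)
})

test_that("whale placement is reproducible and validated", {
  cfg <- scenario_config()$survey
  p <- dive_cycle_params()
  s1 <- simulate_whales(2e-8, 50000, cfg, p, seed = 63)
  s2 <- simulate_whales(2e-8, 50000, cfg, p, seed = 63)
  expect_equal(s1$whales, s2$whales)
  expect_equal(s1$timelines, s2$timelines)
  expect_true(all(s1$whales$perp <= cfg$truncation_perp_acoustic))
  expect_error(simulate_whales(0, 1000, cfg, p), "positive")
  expect_error(simulate_whales(1e-8, -5, cfg, p), "empty strip")
})

test_that("identical seeds give identical datasets; seeds differ data", {
  scn <- scenario_config(density = 6e-8, transect_length = 60000)
  d1 <- simulate_dataset(scn, seed = 64)
  d2 <- simulate_dataset(scn, seed = 64)
  d3 <- simulate_dataset(scn, seed = 65)
  expect_equal(d1$sightings, d2$sightings)
  expect_equal(d1$histories, d2$histories)
  expect_equal(d1$truth$n_true, d2$truth$n_true)
  expect_false(isTRUE(all.equal(d1$events, d3$events)))
})

test_that("per-bin acoustic detection frequency follows the half-normal", {
  # whales that never stop vocalizing: every grid bin is a detection trial
  # with probability exp(-R^2 / (2 sigma^2))
  scn <- scenario_config(
    density = 4e-7, transect_length = 60000,
    dive = dive_cycle_params(surface_mean = 0, descent_mean = 0,
                             ascent_mean = 0, individual_cv = 0),
    acoustic_sigma = 2500, annotated_fraction = 1)
  set.seed(66)
  sim <- simulate_whales(scn$density, scn$transect_length, scn$survey,
                         scn$dive)
  det <- simulate_detections(sim, scn$survey, visual_sigma = 2500,
                             acoustic_sigma = scn$acoustic_sigma,
                             visual_window = scn$visual_window)
  hm <- history_matrix(det$histories)
  perp <- det$events$perp_distance_m
  pred <- t(vapply(perp, function(x)
    exp(-(x^2 + scn$survey$midpoints^2) / (2 * 2500^2)),
    numeric(scn$survey$n_bins)))
  # aggregate over all whale-bin trials (every bin is vocal here);
  # undetected whales are missing, so condition on detected events and
  # compare within them
  obs_total <- sum(hm)
  exp_total <- sum(pred)
  se <- sqrt(sum(pred * (1 - pred)))
  expect_lt(abs(obs_total - exp_total), 4 * se + 2)
})

test_that("doubling density doubles the expected event count", {
  scn1 <- scenario_config(density = 5e-8, transect_length = 80000)
  scn2 <- scenario_config(density = 1e-7, transect_length = 80000)
  n1 <- vapply(1:12, function(s)
    nrow(simulate_dataset(scn1, seed = 700 + s)$events), numeric(1))
  n2 <- vapply(1:12, function(s)
    nrow(simulate_dataset(scn2, seed = 900 + s)$events), numeric(1))
  # Poisson thinning: ratio of means near 2 within 3 sd
  se <- sqrt(mean(n1) / 12 + mean(n2) / 12)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * 2 * se + 2)
})

test_that("true availability matches the deterministic renewal window", {
  # with cv = 0 the surface interval overlaps the visual pass iff the
  # cycle phase falls in a window of length (surface + pass) out of the
  # cycle, truncated by the submerged duration
  scn <- scenario_config(
    density = 3e-7, transect_length = 80000,
    dive = dive_cycle_params(individual_cv = 0, within_cv = 0))
  d <- simulate_dataset(scn, seed = 67)
  p <- scn$dive
  cycle <- p$surface_mean + p$descent_mean + p$vocal_mean + p$ascent_mean
  pass <- diff(scn$visual_window) / scn$survey$ship_speed
  p_avail <- min(1, (p$surface_mean + pass) / cycle)
  n <- d$truth$n_true
  se <- sqrt(p_avail * (1 - p_avail) / n)
  expect_lt(abs(d$truth$a_true - p_avail), 4 * se + 0.01)
})

test_that("the simulated bundle round-trips through the survey files", {
  dir <- withr::local_tempdir()
  scn <- scenario_config(density = 6e-8, transect_length = 50000)
  d <- simulate_dataset(scn, seed = 68, out_dir = dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_survey(dir)
  expect_equal(nrow(back$events), nrow(d$events))
  expect_equal(history_matrix(back$histories), history_matrix(d$histories))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$n_true, d$truth$n_true)
  expect_equal(tr$seed, 68)
  # annotated subset is a proper, seeded subset
  expect_equal(sum(d$events$fully_annotated),
               max(1, round(0.3 * nrow(d$events))))
})
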