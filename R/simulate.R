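#' Dive-cycle parameters
#'
#' Mean durations of the four phases of a deep foraging dive cycle --
#' surface interval, silent descent, acoustically active foraging phase,
#' silent ascent -- with individual variation (per-whale mean multipliers)
#' and cycle-to-cycle variation. Defaults describe sperm whales: a ~35 min
#' vocal foraging phase within a ~48 min dive followed by a ~9 min surface
#' interval, with silent descent (~5 min) and ascent (~8 min) phases.
#' Maximum dive depth is drawn per whale for bookkeeping but does not
#' affect detection.
#'
#' @param surface_mean,descent_mean,vocal_mean,ascent_mean Mean phase
#'   durations, seconds.
#' @param individual_cv CV of the per-whale lognormal multipliers applied
#'   to each phase mean (drawn once per whale).
#' @param within_cv CV of the gamma-distributed cycle-to-cycle durations
#'   around the whale's own means.
#' @param max_depth_mean,max_depth_cv Per-whale maximum dive depth,
#'   lognormal, metres.
#' @return List of class `dive_cycle_params`.
#' @export
dive_cycle_params <- function(surface_mean = 540, descent_mean = 300,
                              vocal_mean = 2100, ascent_mean = 480,
                              individual_cv = 0.15, within_cv = 0.1,
                              max_depth_mean = 800, max_depth_cv = 0.2) {
  stopifnot(surface_mean >= 0, descent_mean >= 0, vocal_mean > 0,
            ascent_mean >= 0, individual_cv >= 0, within_cv >= 0)
  structure(as.list(environment()), class = "dive_cycle_params")
}

# lognormal multiplier with mean 1 and given cv
rlnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# gamma duration with given mean and cv (degenerate when cv = 0 or mean = 0)
rdur <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate one whale's dive-phase timeline
#'
#' Alternating-renewal simulation of the phase sequence
#' surface -> silent descent -> vocal foraging -> silent ascent, covering
#' `[0, duration]`. The timeline starts several cycles before time zero
#' with a uniformly random offset, so the phase occupied at any fixed time
#' is approximately stationary. Phases of zero mean duration are skipped.
#'
#' @param params A [dive_cycle_params()].
#' @param duration Length of the window to cover, seconds.
#' @param multipliers Optional named per-whale multipliers for
#'   `surface`, `descent`, `vocal`, `ascent` (default all 1).
#' @return Data frame with columns `phase` (factor-like character),
#'   `start`, `end` (seconds); intervals partition the covered span with
#'   no gaps or overlaps.
#' @export
simulate_timeline <- function(params, duration,
                              multipliers = c(surface = 1, descent = 1,
                                              vocal = 1, ascent = 1)) {
  stopifnot(inherits(params, "dive_cycle_params"), duration > 0)
  means <- c(surface = params$surface_mean * multipliers[["surface"]],
             descent = params$descent_mean * multipliers[["descent"]],
             vocal = params$vocal_mean * multipliers[["vocal"]],
             ascent = params$ascent_mean * multipliers[["ascent"]])
  cycle <- sum(means)
  t0 <- -3 * cycle - stats::runif(1, 0, cycle)
  phases <- character(0)
  starts <- numeric(0)
  t <- t0
  repeat {
    for (ph in c("surface", "descent", "vocal", "ascent")) {
      if (means[[ph]] == 0) next
      d <- rdur(1, means[[ph]], params$within_cv)
      phases <- c(phases, ph)
      starts <- c(starts, t)
      t <- t + d
    }
    if (t > duration) break
  }
  ends <- c(starts[-1], t)
  # merge consecutive identical phases (arises when phases have zero mean:
  # e.g. with no silent phases a dive is one uninterrupted vocal interval)
  same <- c(FALSE, phases[-1] == phases[-length(phases)])
  grp <- cumsum(!same)
  starts <- tapply(starts, grp, min)
  ends <- tapply(ends, grp, max)
  phases <- phases[!same]
  keep <- ends > 0 & starts < duration
  data.frame(phase = phases[keep], start = as.numeric(starts[keep]),
             end = as.numeric(ends[keep]))
}

#' Place whales in the surveyed strip and simulate their dive cycles
#'
#' Whale count is Poisson with mean `density * transect_length * W`
#' (one-sided strip of width equal to the acoustic truncation distance);
#' positions are uniform in the strip and fixed for the whole survey
#' (whales are treated as horizontally stationary). Each whale receives
#' per-phase mean-duration multipliers (individual variation), a maximum
#' dive depth, and a phase timeline covering the ship's transit.
#'
#' @param density Whales per square metre.
#' @param transect_length Trackline length, metres.
#' @param config A [survey_config()]; the strip width is
#'   `truncation_perp_acoustic` and the transit covers the grid passing
#'   over every whale.
#' @param params A [dive_cycle_params()].
#' @param seed Optional integer seed.
#' @return List with `whales` (data frame: `whale_id`, `along`, `perp`,
#'   `max_depth`), `timelines` (list of timelines, seconds on the ship
#'   clock), and `t_total` (transit duration, seconds).
#' @export
simulate_whales <- function(density, transect_length, config, params,
                            seed = NULL) {
  stopifnot(inherits(config, "survey_config"),
            inherits(params, "dive_cycle_params"))
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  if (transect_length <= 0) stop("empty strip", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W <- config$truncation_perp_acoustic
  n <- stats::rpois(1, density * transect_length * W)
  # ship reference point travels from -max_forward_ahead to L + behind,
  # so the grid passes completely over every whale in [0, L]
  t_total <- (transect_length + config$max_forward_ahead +
                config$max_forward_behind) / config$ship_speed
  whales <- data.frame(
    whale_id = seq_len(n),
    along = stats::runif(n, 0, transect_length),
    perp = stats::runif(n, 0, W),
    max_depth = params$max_depth_mean * rlnorm_mult(n, params$max_depth_cv)
  )
  timelines <- lapply(seq_len(n), function(i) {
    m <- c(surface = 1, descent = 1, vocal = 1, ascent = 1) *
      rlnorm_mult(4, params$individual_cv)
    simulate_timeline(params, t_total, m)
  })
  list(whales = whales, timelines = timelines, t_total = t_total)
}

# half-normal detection probability, tolerating sigma = 0 and sigma = Inf
hn_prob <- function(dist, sigma) {
  if (sigma <= 0) return(rep(0, length(dist)))
  exp(-dist^2 / (2 * sigma^2))
}

interval_overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1

#' Simulate dual-platform detection of the whales
#'
#' Runs the ship along the trackline and applies half-normal detection to
#' both platforms. A whale surfacing while inside the visual forward window
#' is detected by team k with probability
#' `g0_k * exp(-perp^2 / (2 visual_sigma^2))` (one trial per team per
#' surfacing; a surfacing seen by both teams is a linked duplicate
#' sighting). A whale vocal during any part of forward-distance bin j is
#' detected in that bin with probability
#' `exp(-R_j^2 / (2 acoustic_sigma^2))`, where `R_j` is the radial
#' distance; each vocal phase that is detected in at least one bin becomes
#' one acoustic event, so a whale whose vocal phase is interrupted and
#' resumed inside the grid yields two events (a "double diver").
#'
#' The truth ledger records, per whale, availability to each platform, and
#' overall: the availability-unit counts (surfacings inside the visual
#' window, vocal phases inside the grid), the dive/surfacing links between
#' them (the true duplicates), and the resulting true availability.
#'
#' @param sim Output of [simulate_whales()].
#' @param config A [survey_config()].
#' @param visual_sigma,acoustic_sigma Half-normal scales, metres.
#' @param visual_g0 Length-2 vector of team trackline intercepts.
#' @param visual_window Forward-distance interval `c(lo, hi)` searched by
#'   the visual teams, metres.
#' @param seed Optional integer seed.
#' @return List with `sightings`, `events`, `histories` (data frames in
#'   the package CSV schemas) and `truth` (class `sim_truth`).
#' @export
simulate_detections <- function(sim, config, visual_sigma, acoustic_sigma,
                                visual_g0 = c(1, 1),
                                visual_window = c(0, 5000),
                                seed = NULL) {
  stopifnot(inherits(config, "survey_config"))
  if (visual_sigma <= 0) stop("`visual_sigma` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- config$ship_speed
  p0 <- -config$max_forward_ahead   # ship reference position at t = 0
  J <- config$n_bins
  upper <- config$max_forward_ahead - (seq_len(J) - 1) * config$bin_width
  lower <- upper - config$bin_width
  n <- nrow(sim$whales)

  sightings <- list()
  events <- list()
  hist_rows <- list()
  truth_whale <- data.frame(whale_id = sim$whales$whale_id,
                            surf_avail = FALSE, vocal_avail = FALSE)
  n_s_units <- 0L; n_b_units <- 0L; f_links <- 0L; s_links <- 0L
  sid <- 0L; eid <- 0L; dup <- 0L

  for (i in seq_len(n)) {
    u <- sim$whales$along[i]
    x <- sim$whales$perp[i]
    tl <- sim$timelines[[i]]
    # whale's relative forward distance y(t) = u - p0 - v t; time at which
    # the whale sits at relative position c:
    t_at <- function(cc) (u - p0 - cc) / v
    # time windows during which the whale occupies each forward bin
    t_bin0 <- t_at(upper)  # enters bin j
    t_bin1 <- t_at(lower)  # leaves bin j
    t_grid0 <- t_bin0[1]
    t_grid1 <- t_bin1[J]
    t_win0 <- t_at(visual_window[2])
    t_win1 <- t_at(visual_window[1])

    vocal <- tl[tl$phase == "vocal", , drop = FALSE]
    surf <- tl[tl$phase == "surface", , drop = FALSE]

    # --- visual platform ---
    vis <- interval_overlaps(surf$start, surf$end, t_win0, t_win1)
    if (any(vis)) {
      truth_whale$surf_avail[i] <- TRUE
      n_s_units <- n_s_units + sum(vis)
    }
    for (k in which(vis)) {
      pk <- visual_g0 * hn_prob(x, visual_sigma)
      seen <- stats::runif(2) < pk
      if (!any(seen)) next
      dup_id <- if (all(seen)) {dup <- dup + 1L; sprintf("D%04d", dup)} else NA
      for (team in which(seen)) {
        sid <- sid + 1L
        sightings[[length(sightings) + 1L]] <- data.frame(
          sighting_id = sprintf("S%04d", sid), team = team,
          perp_distance_m = x, group_size = 1L, duplicate_id = dup_id,
          whale_id = sim$whales$whale_id[i])
      }
    }

    # --- acoustic platform, one candidate event per vocal phase ---
    in_grid <- interval_overlaps(vocal$start, vocal$end, t_grid0, t_grid1)
    if (any(in_grid)) truth_whale$vocal_avail[i] <- TRUE
    for (k in which(in_grid)) {
      n_b_units <- n_b_units + 1L
      # true duplicate links: preceding / following surfacing visible
      prev_surf <- surf$end <= vocal$start[k] + 1e-9
      if (any(prev_surf)) {
        ks <- which(prev_surf)[sum(prev_surf)]
        if (interval_overlaps(surf$start[ks], surf$end[ks], t_win0, t_win1))
          f_links <- f_links + 1L
      }
      next_surf <- surf$start >= vocal$end[k] - 1e-9
      if (any(next_surf)) {
        ks <- which(next_surf)[1]
        if (interval_overlaps(surf$start[ks], surf$end[ks], t_win0, t_win1))
          s_links <- s_links + 1L
      }
      z_true <- as.integer(interval_overlaps(vocal$start[k], vocal$end[k],
                                             t_bin0, t_bin1))
      R <- sqrt(x^2 + config$midpoints^2)
      y_obs <- as.integer(z_true == 1L &
                            stats::runif(J) < hn_prob(R, acoustic_sigma))
      if (sum(y_obs) == 0L) next
      eid <- eid + 1L
      events[[length(events) + 1L]] <- data.frame(
        event_id = sprintf("E%04d", eid), perp_distance_m = x,
        fully_annotated = TRUE, whale_id = sim$whales$whale_id[i])
      hist_rows[[length(hist_rows) + 1L]] <- y_obs
    }
  }

  sightings <- if (length(sightings)) do.call(rbind, sightings) else
    data.frame(sighting_id = character(0), team = integer(0),
               perp_distance_m = numeric(0), group_size = integer(0),
               duplicate_id = character(0), whale_id = integer(0))
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0), perp_distance_m = numeric(0),
               fully_annotated = logical(0), whale_id = integer(0))
  histories <- if (length(hist_rows)) {
    h <- do.call(rbind, hist_rows)
    colnames(h) <- paste0("bin_", seq_len(J))
    cbind(data.frame(event_id = events$event_id), as.data.frame(h))
  } else NULL

  n_t_units <- n_s_units + n_b_units - f_links - s_links
  truth <- structure(list(
    n_true = n,
    a_true = if (n > 0) mean(truth_whale$surf_avail) else NA_real_,
    n_surf_avail = sum(truth_whale$surf_avail),
    n_vocal_avail = sum(truth_whale$vocal_avail),
    n_s_units = n_s_units, n_b_units = n_b_units,
    f_links = f_links, s_links = s_links,
    n_t_units = n_t_units,
    per_whale = truth_whale
  ), class = "sim_truth")

  list(sightings = sightings, events = events, histories = histories,
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth\n")
  cat(sprintf("  whales in strip:      %d\n", x$n_true))
  cat(sprintf("  surface-available:    %d (a_true = %.3f)\n",
              x$n_surf_avail, x$a_true))
  cat(sprintf("  vocal-available:      %d (%d vocal phases in grid)\n",
              x$n_vocal_avail, x$n_b_units))
  cat(sprintf("  duplicate links:      %d dives + %d surfacings\n",
              x$f_links, x$s_links))
  invisible(x)
}

#' Scenario configuration for the simulator
#'
#' Bundles the survey geometry, dive-cycle parameters, whale density and
#' detection parameters into one scenario. The defaults describe a
#' sperm-whale shipboard survey: 10-knot ship, one-minute bins, acoustic
#' grid from 6 km ahead to 1.5 km astern, 4 km perpendicular truncation on
#' both platforms, a 0-5 km visual search window, and a density/transect
#' length giving on the order of 150 acoustic events.
#'
#' @param density Whales per square metre of strip.
#' @param transect_length Trackline length, metres.
#' @param survey A [survey_config()].
#' @param dive A [dive_cycle_params()].
#' @param visual_window Forward interval searched visually, metres.
#' @param visual_sigma,acoustic_sigma Half-normal detection scales, metres.
#' @param visual_g0 Team trackline intercepts (length 2).
#' @param annotated_fraction Fraction of events fully annotated into
#'   capture histories (simple random subset).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(density = 1.8e-7,
                            transect_length = 220000,
                            survey = survey_config(
                              truncation_perp_visual = 4000,
                              truncation_perp_acoustic = 4000,
                              max_forward_ahead = 6000,
                              max_forward_behind = 1500,
                              bin_width = 308.4,
                              ship_speed = 5.14),
                            dive = dive_cycle_params(),
                            visual_window = c(0, 5000),
                            visual_sigma = 2500,
                            acoustic_sigma = 2500,
                            visual_g0 = c(0.9, 0.85),
                            annotated_fraction = 0.3) {
  stopifnot(inherits(survey, "survey_config"),
            inherits(dive, "dive_cycle_params"),
            length(visual_g0) == 2L,
            annotated_fraction > 0, annotated_fraction <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Zone of overlap implied by a scenario
#'
#' Builds the [zone_of_overlap()] from the scenario's own dive timing and
#' visual window: entries shifted aft by the silent-descent distance,
#' exits shifted ahead by the silent-ascent distance, each widened by the
#' surface-interval drift.
#'
#' @param scenario A [scenario_config()].
#' @return A [zone_of_overlap()].
#' @export
scenario_zone <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  make_zone(scenario$survey,
            silent_descent = scenario$dive$descent_mean,
            silent_ascent = scenario$dive$ascent_mean,
            visual_window = scenario$visual_window,
            surface_duration = scenario$dive$surface_mean)
}

#' Simulate one complete dual-platform survey dataset
#'
#' Places whales, simulates their dive cycles and both detection
#' processes, marks a seeded random subset of events as fully annotated,
#' and optionally writes the survey bundle (`sightings.csv`, `events.csv`,
#' `histories.csv`, `config.yaml`, `truth.json`) to a directory in the
#' package's CSV schemas, so the estimators run on simulated and field
#' data alike.
#'
#' @param scenario A [scenario_config()].
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param out_dir Optional output directory.
#' @return List with `sightings`, `events`, `histories`, `truth`,
#'   `scenario` and `seed` (invisibly writes files when `out_dir` given).
#' @export
simulate_dataset <- function(scenario, seed, out_dir = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(seed)
  sim <- simulate_whales(scenario$density, scenario$transect_length,
                         scenario$survey, scenario$dive)
  det <- simulate_detections(sim, scenario$survey,
                             visual_sigma = scenario$visual_sigma,
                             acoustic_sigma = scenario$acoustic_sigma,
                             visual_g0 = scenario$visual_g0,
                             visual_window = scenario$visual_window)
  ne <- nrow(det$events)
  if (ne > 0 && scenario$annotated_fraction < 1) {
    keep <- sample.int(ne, max(1L, round(scenario$annotated_fraction * ne)))
    det$events$fully_annotated <- seq_len(ne) %in% keep
  }
  out <- list(sightings = det$sightings, events = det$events,
              histories = det$histories, truth = det$truth,
              scenario = scenario, seed = seed)
  if (!is.null(out_dir)) {
    write_survey(list(sightings = det$sightings, events = det$events,
                      histories = det$histories, config = scenario$survey),
                 out_dir)
    tr <- det$truth
    tr$per_whale <- NULL
    jsonlite::write_json(c(tr, list(seed = seed)),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
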