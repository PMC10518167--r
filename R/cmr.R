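#' Cumulative time in the foraging state
#'
#' The time a whale has already spent in the vocal foraging state when it
#' enters bin `j`: its (latent) time-in-state on entering bin 1 if it was
#' in state there, plus one bin duration for every in-state bin strictly
#' before `j`. Because the ship moves at a constant rate every bin
#' represents the same unit of time.
#'
#' @param z_row Integer 0/1 state vector over bins (no re-entry).
#' @param entry_time Time already in state when entering bin 1, seconds
#'   (counted only if `z_row[1] == 1`).
#' @param bin_duration Seconds per bin.
#' @param j Bin index.
#' @return Time in state on entering bin `j`, seconds.
#' @examples
#' time_in_state(c(1, 1, 1), 600, 60, 3) # 720
#' @export
time_in_state <- function(z_row, entry_time, bin_duration, j) {
  stopifnot(j >= 1, j <= length(z_row))
  before <- if (j > 1) sum(z_row[seq_len(j - 1)]) else 0
  entry_time * z_row[1] + bin_duration * before
}

#' Persistence probability in the foraging state
#'
#' `logit(phi) = alpha0 + alphaT * time`: the probability of remaining in
#' the foraging state for one more bin, declining with time already spent
#' in the state when `alphaT < 0`.
#'
#' @param alpha0,alphaT Persistence coefficients (intercept; per-second
#'   slope).
#' @param time Time already in state, seconds (>= 0).
#' @return Probability.
#' @export
persistence_prob <- function(alpha0, alphaT, time) {
  if (any(time < 0)) stop("`time` must be non-negative", call. = FALSE)
  stats::plogis(alpha0 + alphaT * time)
}

#' Acoustic detection probability
#'
#' `logit(p) = beta0 + beta1 * radial`: per-bin probability of detecting a
#' vocalizing whale at a given radial distance from the array.
#'
#' @param beta0,beta1 Detection coefficients (intercept; per-metre slope).
#' @param radial Radial distance(s), metres (>= 0).
#' @return Probability/probabilities.
#' @export
detection_prob <- function(beta0, beta1, radial) {
  if (any(radial < 0)) stop("`radial` must be non-negative", call. = FALSE)
  stats::plogis(beta0 + beta1 * radial)
}

# no-re-entry check: TRUE when the 1s (if any) form a single contiguous run
single_run <- function(z_row) {
  ones <- which(z_row == 1)
  length(ones) == 0L || all(diff(ones) == 1L)
}

#' Log-probability of a latent state path
#'
#' The transition-kernel log-probability of one whale's 0/1 state path over
#' the bins: entry with probability `gamma` per bin while the whale has
#' never yet been in state, persistence `phi` evaluated at the cumulative
#' time in state, and an absorbing exit (no re-entry within the survey
#' window). Summing `exp(state_loglik(...))` over all valid paths gives 1
#' for any parameter values.
#'
#' @param z_row Integer 0/1 state vector (single contiguous run of 1s).
#' @param params List with `gamma` (scalar or per-bin vector), `alpha0`,
#'   `alphaT`.
#' @param bin_duration Seconds per bin.
#' @param entry_time Time in state on entering bin 1 (used only when
#'   `z_row[1] == 1`), seconds.
#' @return Log-probability of the path.
#' @export
state_loglik <- function(z_row, params, bin_duration, entry_time = 0) {
  J <- length(z_row)
  if (!single_run(z_row))
    stop("invalid state path: re-entry after exit is not allowed",
         call. = FALSE)
  gamma <- rep_len(params$gamma, J)
  ones <- which(z_row == 1)
  if (length(ones) == 0L) return(sum(log1p(-gamma)))
  b <- ones[1]
  e <- ones[length(ones)]
  ll <- sum(log1p(-gamma[seq_len(b - 1)])) + log(gamma[b])
  if (e > b) {
    tt <- vapply(seq(b + 1, e), function(j)
      time_in_state(z_row, entry_time, bin_duration, j), numeric(1))
    ll <- ll + sum(log(persistence_prob(params$alpha0, params$alphaT, tt)))
  }
  if (e < J) {
    t_exit <- time_in_state(z_row, entry_time, bin_duration, e) + bin_duration
    ll <- ll + log1p(-persistence_prob(params$alpha0, params$alphaT, t_exit))
  }
  ll
}

#' Zone of overlap between the visual and acoustic platforms
#'
#' Bin-index bounds restricting which dive-state transitions count as
#' duplicates, and which individuals count toward the subsurface
#' superpopulation. Each zone is a pair `c(lo, hi)` of bin indices
#' (`lo <= hi`, bin 1 farthest ahead), or `NULL` when empty.
#'
#' @param nb Bin-index bounds for the superpopulation count.
#' @param f Bin-index bounds for entries (dives) that are duplicates.
#' @param s Bin-index bounds for exits (surfacings) that are duplicates.
#' @param n_bins Total number of bins J (for validation).
#' @return An object of class `zone_of_overlap`.
#' @export
zone_of_overlap <- function(nb, f, s, n_bins) {
  chk <- function(z, name) {
    if (is.null(z)) return(NULL)
    z <- as.integer(z)
    if (length(z) != 2L || z[1] > z[2] || z[1] < 1L || z[2] > n_bins)
      stop("zone `", name, "` must be bin-index bounds within 1..", n_bins,
           call. = FALSE)
    z
  }
  structure(list(nb = chk(nb, "nb"), f = chk(f, "f"), s = chk(s, "s"),
                 n_bins = as.integer(n_bins)),
            class = "zone_of_overlap")
}

#' @export
print.zone_of_overlap <- function(x, ...) {
  fmt <- function(z) if (is.null(z)) "empty" else sprintf("bins %d..%d", z[1], z[2])
  cat("Zone of overlap (", x$n_bins, " bins):\n", sep = "")
  cat("  superpopulation: ", fmt(x$nb), "\n", sep = "")
  cat("  entries (F):     ", fmt(x$f), "\n", sep = "")
  cat("  exits (S):       ", fmt(x$s), "\n", sep = "")
  invisible(x)
}

#' Derive the zone of overlap from dive timing and the visual window
#'
#' Maps the visual platform's forward search window into the bins where a
#' dive-state transition implies a whale was also available visually. A
#' whale sighted at the surface dives and, after the silent descent, starts
#' clicking once the ship has advanced by the descent distance, so entries
#' corresponding to visually available whales lie AFT of the visual window
#' by `silent_descent * ship_speed`. Symmetrically, a whale that stops
#' clicking surfaces after the silent ascent, so qualifying exits lie AHEAD
#' of the window by `silent_ascent * ship_speed`. Because a surfacing
#' lasts a while and the ship keeps moving, each zone is additionally
#' widened on one side by the surface-interval drift
#' (`surface_duration * ship_speed`). Bounds are clipped to the grid; a
#' shift beyond the grid yields an empty zone with a warning.
#'
#' @param config A [survey_config()].
#' @param silent_descent,silent_ascent Durations of the silent descent and
#'   ascent phases, seconds.
#' @param visual_window Forward-distance interval `c(lo, hi)` searched by
#'   the visual teams, metres (signed, relative to the ship).
#' @param surface_duration Mean surface-interval duration, seconds
#'   (default 0: zones are pure shifts of the window).
#' @param nb_window Forward-distance interval for the superpopulation
#'   count; default the whole grid.
#' @return A [zone_of_overlap()].
#' @export
make_zone <- function(config, silent_descent, silent_ascent,
                      visual_window, surface_duration = 0,
                      nb_window = NULL) {
  stopifnot(inherits(config, "survey_config"),
            silent_descent >= 0, silent_ascent >= 0, surface_duration >= 0,
            length(visual_window) == 2L)
  v <- config$ship_speed
  d_desc <- silent_descent * v
  d_asc <- silent_ascent * v
  drift <- surface_duration * v
  mid <- config$midpoints
  interval_to_bins <- function(lo, hi, name) {
    idx <- which(mid >= lo & mid <= hi)
    if (!length(idx)) {
      warning("zone `", name, "` falls entirely outside the grid; empty zone",
              call. = FALSE)
      return(NULL)
    }
    range(idx)
  }
  f <- interval_to_bins(visual_window[1] - d_desc - drift,
                        visual_window[2] - d_desc, "f")
  s <- interval_to_bins(visual_window[1] + d_asc,
                        visual_window[2] + d_asc + drift, "s")
  nb <- if (is.null(nb_window)) c(1L, config$n_bins)
        else interval_to_bins(nb_window[1], nb_window[2], "nb")
  zone_of_overlap(nb = nb, f = f, s = s, n_bins = config$n_bins)
}

#' Derived transition and superpopulation counts from a state matrix
#'
#' Hand-countable summaries of one latent-state draw: per-bin entries
#' `F_j = sum_i (1 - z_{i,j-1}) z_{i,j}` and exits
#' `S_j = sum_i z_{i,j-1} (1 - z_{i,j})` (with the convention `z_{i,0} = 0`,
#' so presence in bin 1 counts as an entry), zone-restricted totals `F_T`
#' and `S_T`, and the superpopulation `N_B` (individuals ever in state
#' within the superpopulation zone).
#'
#' @param z Integer 0/1 matrix, individuals x bins.
#' @param zone A [zone_of_overlap()].
#' @return List with `F_j`, `S_j` (length-J vectors), `F_T`, `S_T`, `N_B`.
#' @export
derived_counts <- function(z, zone) {
  stopifnot(is.matrix(z), inherits(zone, "zone_of_overlap"))
  J <- ncol(z)
  if (J != zone$n_bins)
    stop("state matrix and zone disagree on the number of bins",
         call. = FALSE)
  zprev <- cbind(0L, z[, -J, drop = FALSE])
  F_j <- colSums((1L - zprev) * z)
  S_j <- colSums(zprev * (1L - z))
  span <- function(zz) if (is.null(zz)) integer(0) else seq(zz[1], zz[2])
  nb_span <- span(zone$nb)
  N_B <- if (length(nb_span))
    sum(rowSums(z[, nb_span, drop = FALSE]) > 0) else 0L
  list(F_j = F_j, S_j = S_j,
       F_T = sum(F_j[span(zone$f)]), S_T = sum(S_j[span(zone$s)]),
       N_B = N_B)
}

#' Fit the state-space Jolly-Seber model to acoustic capture histories
#'
#' Fits the data-augmented capture-recapture model of dive-state
#' transitions to the binary capture histories of localized acoustic
#' events. The latent 0/1 state of each of `M` individuals (the `n`
#' observed events plus `M - n` all-zero pseudo-individuals) over the
#' forward-distance bins follows an entry/persistence/absorbing-exit
#' kernel; detection is Bernoulli with a logit-linear effect of radial
#' distance. The sampler is Metropolis-within-Gibbs with the per-individual
#' state path updated by enumeration over (entry bin, exit bin) pairs;
#' pseudo-individuals carry a latent perpendicular distance with a
#' `Uniform(0, W_acoustic)` prior.
#'
#' Priors: `gamma, psi ~ Uniform(0, 1)` (Gibbs via Beta conjugacy),
#' `alpha0, alphaT, beta0, beta1 ~ Normal(0, 10^2)`,
#' `Time_1 ~ Uniform(0, maxTime)`.
#'
#' @param histories Integer 0/1 matrix, events x bins (J columns).
#' @param perp_distance Localized perpendicular distances, one per event,
#'   metres.
#' @param config A [survey_config()].
#' @param zone A [zone_of_overlap()]; the derived counts `F_T`, `S_T` and
#'   `N_B` are restricted to it.
#' @param M Augmented size (> number of events); default twice the number
#'   of events.
#' @param max_time Upper bound of the uniform prior on the time already
#'   spent in state when entering bin 1, seconds. Default 2100 s (35 min,
#'   the length of the vocal foraging phase).
#' @param mcmc List with `burn`, `iter`, `thin`, `chains`. Defaults follow
#'   the usual practice for this model: burn-in 10000, 15000 further
#'   iterations thinned by 15, 3 chains.
#' @param gamma_model Structure of the per-bin entry rates: `"two_rate"`
#'   (default; one rate for already being in state at bin 1, one shared
#'   rate for entering at later bins -- under stationary dive cycling the
#'   initial-presence probability is much larger than the per-bin entry
#'   rate), `"constant"` (one shared rate for all bins) or `"by_bin"`
#'   (a free rate per bin).
#' @param fix Optional named list of parameter values to hold fixed
#'   (any of `gamma1`, `gamma`, `psi`, `alpha0`, `alphaT`, `beta0`,
#'   `beta1`; fixing `gamma` under `"constant"` fixes every bin);
#'   used mainly for validation against exhaustive enumeration.
#' @return A `cmr_fit`: posterior draws of the parameters and of the
#'   derived counts (`F_j`, `S_j`, `F_T`, `S_T`, `N_B`, `N_B_full`),
#'   Gelman-Rubin statistics when `chains >= 2` (with a warning when any
#'   R-hat >= 1.1), and Freeman-Tukey discrepancies for posterior
#'   predictive checking.
#' @export
fit_cmr <- function(histories, perp_distance, config, zone,
                    M = 2L * nrow(histories),
                    max_time = 2100,
                    mcmc = list(burn = 10000, iter = 15000, thin = 15,
                                chains = 3),
                    gamma_model = c("two_rate", "constant", "by_bin"),
                    fix = NULL) {
  gamma_model <- match.arg(gamma_model)
  stopifnot(inherits(config, "survey_config"),
            inherits(zone, "zone_of_overlap"))
  histories <- as.matrix(histories)
  storage.mode(histories) <- "integer"
  n <- nrow(histories)
  if (n < 1) stop("no acoustic events: nothing to fit", call. = FALSE)
  if (ncol(histories) != config$n_bins)
    stop("histories must have one column per bin (", config$n_bins, ")",
         call. = FALSE)
  if (!all(histories %in% c(0L, 1L)))
    stop("histories must be 0/1", call. = FALSE)
  if (any(rowSums(histories) < 1))
    stop("every observed history needs at least one detection", call. = FALSE)
  if (length(perp_distance) != n)
    stop("one perpendicular distance per event is required", call. = FALSE)
  if (M <= n)
    stop("augmented size M must exceed the number of observed events (",
         n, ")", call. = FALSE)
  mcmc <- utils::modifyList(list(burn = 10000, iter = 15000, thin = 15,
                                 chains = 3), as.list(mcmc))
  zone_vec <- unlist(lapply(list(zone$nb, zone$f, zone$s), function(z)
    if (is.null(z)) c(0L, 0L) else z))

  par_names <- c("gamma1", "gamma", "psi", "alpha0", "alphaT", "beta0",
                 "beta1")
  if (gamma_model == "constant" && "gamma" %in% names(fix) &&
      !"gamma1" %in% names(fix))
    fix$gamma1 <- fix$gamma
  fix_flags <- par_names %in% names(fix)
  base_init <- c(gamma1 = 0.5, gamma = 0.05,
                 psi = min(0.9, max(0.2, n / M)),
                 alpha0 = 2, alphaT = -0.001, beta0 = 0, beta1 = -5e-4)
  if (gamma_model == "constant") base_init["gamma1"] <- base_init["gamma"]
  if (!is.null(fix)) base_init[names(fix)] <- unlist(fix)
  gm_code <- match(gamma_model, c("constant", "two_rate", "by_bin")) - 1L

  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    init <- base_init
    if (ch > 1) {  # overdispersed starts for the free parameters
      jit <- c(gamma1 = stats::runif(1, 0.2, 0.8),
               gamma = stats::runif(1, 0.02, 0.2),
               psi = stats::runif(1, 0.3, 0.9),
               alpha0 = stats::rnorm(1, 2, 1),
               alphaT = -abs(stats::rnorm(1, 1e-3, 5e-4)),
               beta0 = stats::rnorm(1, 0, 1),
               beta1 = -abs(stats::rnorm(1, 5e-4, 3e-4)))
      init[!fix_flags] <- jit[!fix_flags]
    }
    chains[[ch]] <- .cmr_mcmc_cpp(
      histories, as.numeric(perp_distance), config$midpoints,
      as.integer(M), config$truncation_perp_acoustic,
      config$bin_duration, max_time, as.integer(zone_vec),
      as.integer(mcmc$burn), as.integer(mcmc$iter), as.integer(mcmc$thin),
      init, fix_flags, gm_code, 10.0)
  }

  params <- do.call(rbind, lapply(chains, `[[`, "params"))
  counts <- do.call(rbind, lapply(chains, `[[`, "counts"))
  Fj <- do.call(rbind, lapply(chains, `[[`, "Fj"))
  Sj <- do.call(rbind, lapply(chains, `[[`, "Sj"))
  disc <- do.call(rbind, lapply(chains, `[[`, "discrepancy"))

  rhat <- NULL
  if (mcmc$chains >= 2) {
    free <- par_names[!fix_flags]
    rhat <- vapply(free, function(p)
      gelman_rubin(lapply(chains, function(c) c$params[, p])), numeric(1))
    high <- rhat[!is.na(rhat) & rhat >= 1.1]
    if (length(high))
      warning("convergence not reached (R-hat >= 1.1) for: ",
              paste(names(high), collapse = ", "), call. = FALSE)
  }

  out <- list(
    draws = data.frame(params, counts, check.names = FALSE),
    Fj_draws = Fj, Sj_draws = Sj,
    discrepancy = data.frame(disc, check.names = FALSE),
    n = n, M = M, config = config, zone = zone,
    max_time = max_time, mcmc = mcmc, gamma_model = gamma_model, fix = fix,
    rhat = rhat,
    acceptance = colMeans(do.call(rbind,
      lapply(chains, `[[`, "acceptance")), na.rm = TRUE)
  )
  class(out) <- "cmr_fit"
  out
}

#' @export
print.cmr_fit <- function(x, ...) {
  cat(sprintf(
    "State-space Jolly-Seber fit: %d events augmented to M = %d, %d bins\n",
    x$n, x$M, x$config$n_bins))
  s <- rbind(
    N_B = summarize_draws(x$draws$N_B),
    F_T = summarize_draws(x$draws$F_T),
    S_T = summarize_draws(x$draws$S_T),
    gamma1 = summarize_draws(x$draws$gamma1),
    gamma = summarize_draws(x$draws$gamma),
    alpha0 = summarize_draws(x$draws$alpha0),
    alphaT = summarize_draws(x$draws$alphaT),
    beta0 = summarize_draws(x$draws$beta0),
    beta1 = summarize_draws(x$draws$beta1)
  )
  print(signif(s, 4))
  if (!is.null(x$rhat)) {
    flag <- if (any(x$rhat >= 1.1, na.rm = TRUE)) " [NOT CONVERGED]" else ""
    cat(sprintf("max R-hat: %.3f%s\n", max(x$rhat, na.rm = TRUE), flag))
  }
  invisible(x)
}
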