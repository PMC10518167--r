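# Shared fixtures: small survey configurations, a generator that simulates
# capture histories from the capture-recapture model itself (for
# parameter-recovery checks), an exhaustive-enumeration oracle for the
# latent-path posterior, and minimal fit objects for draw-arithmetic tests.

tiny_cfg <- function(ahead = 400, behind = 0, width = 100, speed = 5,
                     W = 4000) {
  survey_config(truncation_perp_visual = W, truncation_perp_acoustic = W,
                max_forward_ahead = ahead, max_forward_behind = behind,
                bin_width = width, ship_speed = speed)
}

# J = 20 configuration used by the recovery and diagnostic tests
recovery_cfg <- function() tiny_cfg(ahead = 4000, behind = 1000, width = 250)

full_zone <- function(cfg, from = 2) {
  J <- cfg$n_bins
  zone_of_overlap(c(1, J), c(from, J), c(from, J), J)
}

# simulate capture histories from the fitted model's own data-generating
# process (entry/persistence kernel + logit-linear detection)
sim_cmr_model <- function(N_super, truth, cfg) {
  J <- cfg$n_bins
  T <- cfg$bin_duration
  hist <- NULL
  perp <- c()
  nb_real <- 0
  for (i in seq_len(N_super)) {
    b <- NA
    if (stats::runif(1) < truth$gamma1) b <- 1
    else for (j in 2:J) if (stats::runif(1) < truth$gamma) { b <- j; break }
    if (is.na(b)) next
    et <- if (b == 1) stats::runif(1, 0, truth$maxTime) else 0
    e <- b
    while (e < J) {
      tt <- et + (e - b + 1) * T
      if (stats::runif(1) < stats::plogis(truth$alpha0 + truth$alphaT * tt))
        e <- e + 1
      else break
    }
    nb_real <- nb_real + 1
    x <- stats::runif(1, 0, cfg$truncation_perp_acoustic)
    R <- sqrt(x^2 + cfg$midpoints^2)
    y <- integer(J)
    idx <- b:e
    y[idx] <- as.integer(stats::runif(length(idx)) <
                           stats::plogis(truth$beta0 + truth$beta1 * R[idx]))
    if (sum(y) == 0) next
    hist <- rbind(hist, y)
    perp <- c(perp, x)
  }
  list(hist = hist, perp = perp, nb_real = nb_real)
}

default_truth <- function() {
  list(gamma1 = 0.45, gamma = 0.06, alpha0 = 4, alphaT = -0.0015,
       beta0 = 1.5, beta1 = -8e-4, maxTime = 2100)
}

# ---- exhaustive enumeration oracle for the latent-path posterior ----
# all paths: "never" (NA, NA) and every (entry bin, exit bin) pair
all_paths <- function(J) {
  rbind(c(NA, NA), do.call(rbind, lapply(seq_len(J), function(b)
    cbind(b, b:J))))
}

# prior probability of one path under fixed parameters, psi marginalized in
# (alphaT must be 0 so that the latent entry time is irrelevant)
oracle_path_prior <- function(b, e, pars, J) {
  stopifnot(pars$alphaT == 0)
  phi <- stats::plogis(pars$alpha0)
  if (is.na(b)) return((1 - pars$psi) + pars$psi * (1 - pars$gamma)^J)
  pars$psi * (1 - pars$gamma)^(b - 1) * pars$gamma *
    phi^(e - b) * (if (e < J) 1 - phi else 1)
}

oracle_obs_lik <- function(b, e, y, p) {
  J <- length(y)
  if (is.na(b)) return(if (sum(y) == 0) 1 else 0)
  out <- seq_len(J)[-(b:e)]
  if (length(out) && any(y[out] == 1)) return(0)
  prod(ifelse(y[b:e] == 1, p[b:e], 1 - p[b:e]))
}

# exact per-individual path posterior for an observed event
oracle_posterior <- function(y, perp, pars, cfg) {
  J <- cfg$n_bins
  p <- stats::plogis(pars$beta0 + pars$beta1 *
                       sqrt(perp^2 + cfg$midpoints^2))
  paths <- all_paths(J)
  w <- apply(paths, 1, function(pe)
    oracle_path_prior(pe[1], pe[2], pars, J) *
      oracle_obs_lik(pe[1], pe[2], y, p))
  list(paths = paths, post = w / sum(w))
}

# exact path posterior for an augmented pseudo-individual (all-zero history,
# perpendicular distance integrated over its uniform prior)
oracle_posterior_aug <- function(pars, cfg, n_grid = 400) {
  J <- cfg$n_bins
  W <- cfg$truncation_perp_acoustic
  paths <- all_paths(J)
  pgrid <- seq(W / (2 * n_grid), W - W / (2 * n_grid), length.out = n_grid)
  w <- rowMeans(sapply(pgrid, function(px) {
    p <- stats::plogis(pars$beta0 + pars$beta1 *
                         sqrt(px^2 + cfg$midpoints^2))
    apply(paths, 1, function(pe)
      oracle_path_prior(pe[1], pe[2], pars, J) *
        oracle_obs_lik(pe[1], pe[2], rep(0, J), p))
  }))
  list(paths = paths, post = w / sum(w))
}

oracle_EF <- function(or, J) vapply(seq_len(J), function(j)
  sum(or$post[which(or$paths[, 1] %in% j)]), numeric(1))
oracle_ES <- function(or, J) vapply(seq_len(J), function(j)
  sum(or$post[which(or$paths[, 2] %in% (j - 1))]), numeric(1))
oracle_ENB <- function(or) sum(or$post[!is.na(or$paths[, 1])])

# ---- minimal fit objects for draw-wise arithmetic tests ----
fake_ds_fit <- function(N_draws, g0_draws = rep(1, length(N_draws))) {
  structure(list(
    draws = data.frame(scale = NA_real_, shape = NA_real_, g0 = g0_draws,
                       esw = NA_real_, p_hat = NA_real_,
                       N = N_draws, N_animals = N_draws),
    n = NA_integer_, W = NA_real_, form = "half_normal", g0_fixed = TRUE,
    group_size_mean = 1, acceptance = NA_real_,
    esw = NA_real_, p_hat = NA_real_), class = "ds_fit")
}

fake_cmr_fit <- function(N_B, F_T, S_T, Fj = NULL, Sj = NULL, zone = NULL) {
  k <- length(N_B)
  structure(list(
    draws = data.frame(N_B = N_B, F_T = F_T, S_T = S_T, N_B_full = N_B),
    Fj_draws = Fj, Sj_draws = Sj, zone = zone, n = NA_integer_,
    M = NA_integer_), class = "cmr_fit")
}
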