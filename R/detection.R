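#' Detection functions
#'
#' Perpendicular-distance detection functions with unit intercept:
#' half-normal `g(y) = exp(-y^2 / (2 sigma^2))` and hazard-rate
#' `g(y) = 1 - exp(-(y / sigma)^(-shape))`. Both equal 1 at `y = 0` (the
#' hazard-rate in the limit) and are non-increasing on `[0, W]` for
#' `shape > 1`.
#'
#' @param distance Non-negative distance(s), metres.
#' @param form `"half_normal"` or `"hazard_rate"`.
#' @param scale Scale parameter sigma, metres (> 0).
#' @param shape Hazard-rate shape (> 0; > 1 for a shoulder), ignored for
#'   the half-normal.
#' @return Detection probabilities in `[0, 1]`.
#' @examples
#' gfun(0, "half_normal", scale = 100)    # 1
#' gfun(100, "half_normal", scale = 100)  # exp(-0.5)
#' @export
gfun <- function(distance, form = c("half_normal", "hazard_rate"),
                 scale, shape = NULL) {
  form <- match.arg(form)
  if (any(distance < 0))
    stop("distances must be non-negative", call. = FALSE)
  if (scale <= 0)
    stop("`scale` must be positive", call. = FALSE)
  if (form == "half_normal") {
    exp(-distance^2 / (2 * scale^2))
  } else {
    if (is.null(shape) || shape <= 0)
      stop("hazard-rate `shape` must be positive", call. = FALSE)
    out <- 1 - exp(-(distance / scale)^(-shape))
    out[distance == 0] <- 1
    out
  }
}

#' Effective strip width and average detection probability
#'
#' `esw = integral of g(y) dy over [0, W]` and `p_hat = esw / W`, the
#' average probability of detecting an animal in the covered strip. The
#' half-normal integral is evaluated in closed form via the normal CDF;
#' the hazard-rate by adaptive quadrature.
#'
#' @inheritParams gfun
#' @param W Truncation distance, metres (> 0).
#' @return List with elements `esw` (metres) and `p_hat`.
#' @export
esw_phat <- function(form = c("half_normal", "hazard_rate"),
                     scale, shape = NULL, W) {
  form <- match.arg(form)
  if (W <= 0) stop("`W` must be positive", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (form == "half_normal") {
    esw <- scale * sqrt(2 * pi) * (stats::pnorm(W / scale) - 0.5)
  } else {
    if (is.null(shape) || shape <= 0)
      stop("hazard-rate `shape` must be positive", call. = FALSE)
    q <- stats::integrate(function(y) gfun(y, form, scale, shape), 0, W,
                          rel.tol = 1e-8)
    if (q$message != "OK")
      stop("quadrature failed: ", q$message, call. = FALSE)
    esw <- q$value
  }
  list(esw = esw, p_hat = esw / W)
}

# fixed-grid Simpson ESW used inside samplers (201 nodes; the detection
# functions are smooth, so this agrees with adaptive quadrature to ~1e-9)
simpson_esw <- function(form, scale, shape, W) {
  y <- seq(0, W, length.out = 201L)
  wts <- c(1, rep(c(4, 2), 100L))[1:201]
  wts[201] <- 1
  sum(wts * gfun(y, form, scale, shape)) * (W / 200) / 3
}

summarize_draws <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), cv = stats::sd(x) / mean(x),
    lo95 = q[1], hi95 = q[2])
}

# N - n | p ~ NegBinomial(n + 1, p): exact posterior of binomial N under a
# flat prior on N. Draws are truncated at nmax (20 * n / p plug-in).
draw_abundance <- function(n, p_draws, nmax = NULL) {
  if (is.null(nmax)) nmax <- ceiling(20 * n / mean(p_draws))
  N <- n + stats::rnbinom(length(p_draws), size = n + 1, prob = p_draws)
  pmin(N, nmax)
}

# shared adaptive random-walk scaling (burn-in only)
adapt_step <- function(step, accepted, it, target = 0.35) {
  step * exp((accepted - target) / sqrt(it + 1))
}

#' Bayesian distance-sampling fit
#'
#' Fits a single-platform detection function to perpendicular distances by
#' random-walk Metropolis and converts it to a posterior for abundance in
#' the covered strip. Detection on the trackline is assumed certain
#' (`g(0) = 1`), as is standard for acoustic data. The abundance likelihood
#' is `n ~ Binomial(N, p_hat)` with a flat prior on `N`, which gives the
#' exact draw `N = n + NegBinomial(n + 1, p_hat)` per posterior draw of the
#' detection parameters, so credible intervals and CVs propagate detection
#' uncertainty.
#'
#' Priors: `sigma ~ Uniform(0, 5W)` (wide enough that a nearly flat
#' detection curve is representable); hazard-rate `shape ~ Uniform(1, 50)`.
#'
#' @param distances Perpendicular distances in `[0, W]`, metres.
#' @param W Truncation distance, metres.
#' @param form Detection function form, see [gfun()].
#' @param group_size Optional vector of observed group sizes (one per
#'   detection); when supplied, abundance is expanded by the mean group
#'   size into `N_animals`.
#' @param mcmc List with `burn`, `iter` (post burn-in iterations kept
#'   before thinning) and `thin`.
#' @return A `ds_fit` object: posterior draws of `scale` (and `shape`),
#'   `esw`, `p_hat`, `N` (groups) and `N_animals`, with acceptance rate and
#'   summaries.
#' @export
fit_ds <- function(distances, W, form = c("half_normal", "hazard_rate"),
                   group_size = NULL,
                   mcmc = list(burn = 1000, iter = 2000, thin = 1)) {
  form <- match.arg(form)
  n <- length(distances)
  if (n < 1) stop("no detections: cannot fit a detection function",
                  call. = FALSE)
  if (any(distances < 0)) stop("negative distances", call. = FALSE)
  if (any(distances > W))
    stop("distances beyond the truncation distance W; truncate first",
         call. = FALSE)
  if (!is.null(group_size) && length(group_size) != n)
    stop("`group_size` must have one entry per detection", call. = FALSE)

  esw_fun <- function(scale, shape) {
    if (form == "half_normal")
      scale * sqrt(2 * pi) * (stats::pnorm(W / scale) - 0.5)
    else simpson_esw(form, scale, shape, W)
  }
  loglik <- function(scale, shape) {
    sum(log(pmax(gfun(distances, form, scale, shape), 1e-300))) -
      n * log(esw_fun(scale, shape))
  }
  shape_bounds <- c(1, 50)
  scale0 <- max(stats::sd(distances), W / 50)
  shape0 <- 2.5
  cur <- list(scale = min(scale0, 0.9 * W), shape = shape0)  # start inside [0, 5W]
  cur_ll <- loglik(cur$scale, cur$shape)
  step <- c(scale = W / 20, shape = 0.3)

  n_keep <- ceiling(mcmc$iter / mcmc$thin)
  draws <- matrix(NA_real_, n_keep, 2, dimnames = list(NULL, c("scale", "shape")))
  acc <- 0L
  kept <- 0L
  total <- mcmc$burn + mcmc$iter
  for (it in seq_len(total)) {
    prop <- cur
    prop$scale <- cur$scale + stats::rnorm(1, 0, step["scale"])
    ok <- prop$scale > 0 && prop$scale < 5 * W
    if (ok && form == "hazard_rate") {
      prop$shape <- cur$shape + stats::rnorm(1, 0, step["shape"])
      ok <- prop$shape > shape_bounds[1] && prop$shape < shape_bounds[2]
    }
    a <- FALSE
    if (ok) {
      prop_ll <- loglik(prop$scale, prop$shape)
      if (is.finite(prop_ll) && log(stats::runif(1)) < prop_ll - cur_ll) {
        cur <- prop
        cur_ll <- prop_ll
        a <- TRUE
      }
    }
    if (it <= mcmc$burn) {
      step <- adapt_step(step, as.numeric(a), it)
    } else {
      acc <- acc + a
      k <- it - mcmc$burn
      if (k %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- c(cur$scale, cur$shape)
      }
    }
  }
  draws <- draws[seq_len(kept), , drop = FALSE]

  esw <- vapply(seq_len(kept), function(i)
    esw_fun(draws[i, "scale"], draws[i, "shape"]), numeric(1))
  p_hat <- esw / W
  N <- draw_abundance(n, p_hat)
  gs_mean <- if (is.null(group_size)) 1 else mean(group_size)
  out <- list(
    draws = data.frame(scale = draws[, "scale"],
                       shape = if (form == "hazard_rate") draws[, "shape"] else NA_real_,
                       esw = esw, p_hat = p_hat, g0 = 1,
                       N = N, N_animals = N * gs_mean),
    n = n, W = W, form = form, g0_fixed = TRUE,
    group_size_mean = gs_mean,
    acceptance = acc / mcmc$iter,
    esw = mean(esw), p_hat = mean(p_hat)
  )
  class(out) <- "ds_fit"
  out
}

#' Bayesian mark-recapture distance-sampling fit (two visual teams)
#'
#' Full-independence two-team model: both teams share a half-normal
#' detection shape with scale `sigma`, and each team has its own trackline
#' intercept `delta_k`, so team k detects a group at perpendicular distance
#' `y` with probability `delta_k * exp(-y^2 / (2 sigma^2))`. Duplicate
#' links between teams provide the mark-recapture information: the
#' likelihood of each detected group's capture history `(omega_1, omega_2)`
#' is conditional on detection by at least one team. The pooled trackline
#' detection probability is `g(0) = 1 - (1 - delta_1)(1 - delta_2)` and the
#' pooled `p_hat` integrates the pooled detection curve over `[0, W]`.
#'
#' @param sightings Data frame in the `sightings.csv` schema (columns
#'   `sighting_id`, `team`, `perp_distance_m`, `group_size`,
#'   `duplicate_id`). Two sightings with the same non-missing
#'   `duplicate_id` are the same group seen by both teams.
#' @param W Truncation distance, metres.
#' @param group_expand Multiply abundance by the mean observed group size
#'   (default `TRUE`).
#' @inheritParams fit_ds
#' @return A `ds_fit` object with additional draws of `delta1`, `delta2`
#'   and `g0`, fitted to the pooled detections.
#' @export
fit_mrds <- function(sightings, W, group_expand = TRUE,
                     mcmc = list(burn = 1000, iter = 2000, thin = 1)) {
  need <- c("team", "perp_distance_m", "duplicate_id")
  miss <- setdiff(need, names(sightings))
  if (length(miss))
    stop("`sightings` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sightings <- sightings[sightings$perp_distance_m <= W, , drop = FALSE]
  if (!all(c(1, 2) %in% sightings$team))
    stop("both visual teams must be present to estimate g(0)", call. = FALSE)

  dup <- sightings$duplicate_id
  dup[dup %in% c("", NA)] <- NA
  linked <- !is.na(dup)
  # one row per detected group: capture history over the two teams
  groups <- list()
  for (id in unique(dup[linked])) {
    rows <- sightings[which(dup == id), , drop = FALSE]
    groups[[length(groups) + 1L]] <- data.frame(
      y = mean(rows$perp_distance_m),
      w1 = as.integer(any(rows$team == 1)),
      w2 = as.integer(any(rows$team == 2)),
      size = mean(rows$group_size)
    )
  }
  solo <- sightings[!linked, , drop = FALSE]
  if (nrow(solo))
    groups[[length(groups) + 1L]] <- data.frame(
      y = solo$perp_distance_m,
      w1 = as.integer(solo$team == 1),
      w2 = as.integer(solo$team == 2),
      size = solo$group_size
    )
  cap <- do.call(rbind, groups)
  n <- nrow(cap)
  n_dup <- sum(cap$w1 & cap$w2)
  if (n_dup == 0L)
    stop("no duplicate sightings between the two teams: g(0) is not ",
         "identifiable from these data", call. = FALSE)

  ygrid <- seq(0, W, length.out = 201)  # Simpson nodes for the pooled ESW
  simpson_w <- c(1, rep(c(4, 2), 100))[1:201]
  simpson_w[201] <- 1
  simpson_w <- simpson_w * (W / 200) / 3

  loglik <- function(sigma, d1, d2) {
    shp <- exp(-cap$y^2 / (2 * sigma^2))
    p1 <- d1 * shp
    p2 <- d2 * shp
    ll <- sum(ifelse(cap$w1 == 1, log(p1), log1p(-p1))) +
      sum(ifelse(cap$w2 == 1, log(p2), log1p(-p2)))
    shp_g <- exp(-ygrid^2 / (2 * sigma^2))
    esw_pool <- sum(simpson_w * (1 - (1 - d1 * shp_g) * (1 - d2 * shp_g)))
    ll - n * log(esw_pool)
  }
  esw_pool_fun <- function(sigma, d1, d2) {
    shp_g <- exp(-ygrid^2 / (2 * sigma^2))
    sum(simpson_w * (1 - (1 - d1 * shp_g) * (1 - d2 * shp_g)))
  }

  cur <- c(sigma = min(max(stats::sd(cap$y), W / 50), 0.9 * W),
           l1 = 1.5, l2 = 1.5)  # logit team intercepts
  cur_ll <- loglik(cur["sigma"], stats::plogis(cur["l1"]), stats::plogis(cur["l2"]))
  step <- c(sigma = W / 20, l1 = 0.5, l2 = 0.5)
  n_keep <- ceiling(mcmc$iter / mcmc$thin)
  draws <- matrix(NA_real_, n_keep, 3,
                  dimnames = list(NULL, c("sigma", "l1", "l2")))
  acc <- 0L
  kept <- 0L
  for (it in seq_len(mcmc$burn + mcmc$iter)) {
    prop <- cur + stats::rnorm(3, 0, step)
    a <- FALSE
    if (prop["sigma"] > 0 && prop["sigma"] < 5 * W) {
      prop_ll <- loglik(prop["sigma"], stats::plogis(prop["l1"]),
                        stats::plogis(prop["l2"])) +
        sum(stats::dnorm(prop[c("l1", "l2")], 0, 10, log = TRUE))
      cur_post <- cur_ll + sum(stats::dnorm(cur[c("l1", "l2")], 0, 10, log = TRUE))
      if (is.finite(prop_ll) && log(stats::runif(1)) < prop_ll - cur_post) {
        cur <- prop
        cur_ll <- loglik(cur["sigma"], stats::plogis(cur["l1"]),
                         stats::plogis(cur["l2"]))
        a <- TRUE
      }
    }
    if (it <= mcmc$burn) {
      step <- adapt_step(step, as.numeric(a), it)
    } else {
      acc <- acc + a
      k <- it - mcmc$burn
      if (k %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- cur
      }
    }
  }
  draws <- draws[seq_len(kept), , drop = FALSE]
  d1 <- stats::plogis(draws[, "l1"])
  d2 <- stats::plogis(draws[, "l2"])
  g0 <- 1 - (1 - d1) * (1 - d2)
  esw <- vapply(seq_len(kept), function(i)
    esw_pool_fun(draws[i, "sigma"], d1[i], d2[i]), numeric(1))
  p_hat <- esw / W
  N <- draw_abundance(n, p_hat)
  gs_mean <- if (group_expand) mean(cap$size) else 1
  out <- list(
    draws = data.frame(scale = draws[, "sigma"], shape = NA_real_,
                       delta1 = d1, delta2 = d2, g0 = g0,
                       esw = esw, p_hat = p_hat,
                       N = N, N_animals = N * gs_mean),
    n = n, n_duplicates = n_dup, W = W, form = "half_normal",
    g0_fixed = FALSE, group_size_mean = gs_mean,
    acceptance = acc / mcmc$iter,
    esw = mean(esw), p_hat = mean(p_hat)
  )
  class(out) <- c("mrds_fit", "ds_fit")
  out
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s), n = %d detections, W = %g m\n",
              if (inherits(x, "mrds_fit")) "MRDS" else "Distance-sampling",
              x$form, x$n, x$W))
  s <- rbind(
    esw = summarize_draws(x$draws$esw),
    p_hat = summarize_draws(x$draws$p_hat),
    N = summarize_draws(x$draws$N),
    N_animals = summarize_draws(x$draws$N_animals)
  )
  if (!x$g0_fixed) s <- rbind(g0 = summarize_draws(x$draws$g0), s)
  print(round(s, 3))
  invisible(x)
}

#' Availability-bias correction of a distance-sampling abundance
#'
#' Divides the abundance posterior by an externally estimated surface
#' availability, propagating the availability uncertainty draw by draw
#' (the MRDS_AV estimator). Draws of `a_hat` outside `(0, 1]` are rejected
#' with a warning.
#'
#' @param ds_fit A `ds_fit` (or `mrds_fit`) object.
#' @param a_hat Numeric vector of posterior draws of surface availability,
#'   or a single point value.
#' @return An `abundance_estimate` with method label `"MRDS_AV"`; the
#'   corrected abundance is `N_animals / a_hat`.
#' @export
apply_availability <- function(ds_fit, a_hat) {
  stopifnot(inherits(ds_fit, "ds_fit"))
  bad <- a_hat <= 0 | a_hat > 1
  if (any(bad)) {
    warning(sum(bad), " availability draw(s) outside (0, 1] rejected",
            call. = FALSE)
    a_hat <- a_hat[!bad]
  }
  if (!length(a_hat)) stop("no valid availability draws", call. = FALSE)
  ns <- ds_fit$draws$N_animals
  a <- resample_to(a_hat, length(ns))
  n_t <- ns / a
  # the implied subsurface component keeps the N_T identity exact
  abundance_estimate(n_s = ns, n_b = n_t - ns, n_d = rep(0, length(ns)),
                     n_t = n_t, a_s = a, method = "MRDS_AV")
}
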