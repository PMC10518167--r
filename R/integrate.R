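# draw-wise combination of independently fitted posteriors: resample with
# replacement to a common length when chains differ
resample_to <- function(x, len) {
  if (length(x) == len) return(x)
  x[sample.int(length(x), len, replace = TRUE)]
}

align_draws <- function(...) {
  draws <- list(...)
  lens <- vapply(draws, length, integer(1))
  len <- max(lens)
  if (length(unique(lens)) > 1L)
    warning("posterior draw counts differ (", paste(lens, collapse = ", "),
            "); resampling to ", len, " draws", call. = FALSE)
  lapply(draws, resample_to, len = len)
}

#' Combined abundance estimate
#'
#' Container for draw-wise combined posteriors of surface abundance `N_S`,
#' subsurface abundance `N_B`, duplicates `N_D`, total abundance
#' `N_T = N_S + N_B - N_D` and surface availability `a_S = N_S / N_T`.
#' The identity `n_t = n_s + n_b - n_d` holds exactly in the stored draws.
#' Draws with non-positive `N_T` are retained in the abundance summaries
#' (so bias diagnostics stay honest) but dropped, with a warning, from the
#' availability ratio; the fraction of such draws is reported.
#'
#' @param n_s,n_b,n_d,n_t Numeric draw vectors (equal length).
#' @param a_s Optional availability draws; computed from `n_s / n_t` when
#'   omitted.
#' @param method Label: `"DS-DS"`, `"CMR-DS"`, `"Hybrid"` or `"MRDS_AV"`.
#' @return An object of class `abundance_estimate`.
#' @export
abundance_estimate <- function(n_s, n_b, n_d, n_t = n_s + n_b - n_d,
                               a_s = NULL, method = "custom") {
  stopifnot(length(n_s) == length(n_b), length(n_b) == length(n_d),
            length(n_d) == length(n_t))
  if (max(abs(n_t - (n_s + n_b - n_d))) > 1e-8)
    stop("draw-wise identity N_T = N_S + N_B - N_D violated", call. = FALSE)
  nonpos <- n_t <= 0
  if (is.null(a_s)) {
    a_s <- rep(NA_real_, length(n_t))
    if (any(nonpos))
      warning(sum(nonpos), " draw(s) with non-positive N_T dropped from ",
              "the availability ratio", call. = FALSE)
    a_s[!nonpos] <- n_s[!nonpos] / n_t[!nonpos]
  }
  structure(
    list(draws = data.frame(n_s = n_s, n_b = n_b, n_d = n_d, n_t = n_t,
                            a_s = a_s),
         method = method, frac_nonpositive = mean(nonpos)),
    class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance estimate (%s method)\n", x$method))
  print(round(summary_table(x)[, -1], 3))
  if (x$frac_nonpositive > 0)
    cat(sprintf("  (%.1f%% of draws had non-positive N_T)\n",
                100 * x$frac_nonpositive))
  invisible(x)
}

#' Posterior summary table of a combined estimate
#'
#' @param estimate An [abundance_estimate()].
#' @return Data frame with one row per quantity (`N_S`, `N_B`, `N_D`,
#'   `N_T`, `a_S`): mean, sd, cv, and 95% credible bounds.
#' @export
summary_table <- function(estimate) {
  stopifnot(inherits(estimate, "abundance_estimate"))
  rows <- lapply(c(n_s = "N_S", n_b = "N_B", n_d = "N_D", n_t = "N_T",
                   a_s = "a_S"), identity)
  out <- do.call(rbind, lapply(names(rows), function(col) {
    s <- summarize_draws(estimate$draws[[col]])
    data.frame(quantity = rows[[col]], mean = s["mean"], sd = s["sd"],
               cv = s["cv"], lo95 = s["lo95"], hi95 = s["hi95"],
               row.names = rows[[col]])
  }))
  out
}

#' DS-DS estimator: independent surface and subsurface distance sampling
#'
#' The simplest combination: sum the surface and subsurface abundance
#' posteriors draw-wise and assume there are no duplicates (`N_D = 0`).
#' Biased upward whenever whales transition between states within the zone
#' of overlap.
#'
#' @param ns_fit `ds_fit`/`mrds_fit` for the visual (surface) platform.
#' @param nb_fit `ds_fit` for the acoustic (subsurface) platform.
#' @return An [abundance_estimate()] labelled `"DS-DS"`.
#' @export
estimate_dsds <- function(ns_fit, nb_fit) {
  stopifnot(inherits(ns_fit, "ds_fit"), inherits(nb_fit, "ds_fit"))
  d <- align_draws(ns_fit$draws$N_animals, nb_fit$draws$N_animals)
  abundance_estimate(n_s = d[[1]], n_b = d[[2]], n_d = rep(0, length(d[[1]])),
                     method = "DS-DS")
}

#' CMR-DS estimator: capture-recapture correction for duplicates
#'
#' Combines the visual abundance posterior with the Jolly-Seber
#' superpopulation estimate of subsurface abundance, subtracting the
#' zone-restricted transition counts as duplicates:
#' `N_T = N_S + N_B^(CMR) - (F_T + S_T)`.
#'
#' @param ns_fit `ds_fit`/`mrds_fit` for the visual platform.
#' @param cmr_fit A [fit_cmr()] result with zone-restricted counts.
#' @return An [abundance_estimate()] labelled `"CMR-DS"`.
#' @export
estimate_cmrds <- function(ns_fit, cmr_fit) {
  stopifnot(inherits(ns_fit, "ds_fit"), inherits(cmr_fit, "cmr_fit"))
  d <- align_draws(ns_fit$draws$N_animals, cmr_fit$draws$N_B,
                   cmr_fit$draws$F_T, cmr_fit$draws$S_T)
  n_d <- d[[3]] + d[[4]]
  flagged <- n_d > d[[1]] + d[[2]]
  if (mean(flagged) > 0.01)
    warning(sprintf(
      "%.1f%% of draws have more duplicates than detections (N_D > N_S + N_B)",
      100 * mean(flagged)), call. = FALSE)
  abundance_estimate(n_s = d[[1]], n_b = d[[2]], n_d = n_d,
                     method = "CMR-DS")
}

#' Per-capita transition rates from an annotated subset
#'
#' Estimates the per-capita, per-bin rates of entering the foraging state
#' (`P_F`) and surfacing (`P_S`) from a capture-recapture fit to the subset
#' of fully annotated click trains: the posterior per-bin entry and exit
#' counts are averaged over the bins fully inside the respective zones and
#' normalized, draw-wise, by the subset superpopulation.
#'
#' @param subset_cmr_fit A [fit_cmr()] result fitted to the fully annotated
#'   events only.
#' @param zone Optional [zone_of_overlap()]; defaults to the zone stored in
#'   the fit.
#' @return An object of class `hybrid_rates`: draw vectors `p_f`, `p_s`,
#'   the posterior means `fbar`, `sbar`, `n_b_subset`, and the zone bin
#'   counts `zone_f`, `zone_s`.
#' @export
hybrid_rates <- function(subset_cmr_fit, zone = NULL) {
  stopifnot(inherits(subset_cmr_fit, "cmr_fit"))
  if (is.null(zone)) zone <- subset_cmr_fit$zone
  if (is.null(zone$f) || is.null(zone$s))
    stop("empty transition zone: cannot form per-bin rates", call. = FALSE)
  nb <- subset_cmr_fit$draws$N_B
  if (stats::quantile(nb, 0.01) <= 0)
    stop("subset superpopulation posterior has mass at zero; the annotated ",
         "subset is too small to estimate transition rates", call. = FALSE)
  f_span <- seq(zone$f[1], zone$f[2])
  s_span <- seq(zone$s[1], zone$s[2])
  fbar <- rowMeans(subset_cmr_fit$Fj_draws[, f_span, drop = FALSE])
  sbar <- rowMeans(subset_cmr_fit$Sj_draws[, s_span, drop = FALSE])
  keep <- nb > 0
  structure(
    list(p_f = fbar[keep] / nb[keep], p_s = sbar[keep] / nb[keep],
         fbar = mean(fbar), sbar = mean(sbar), n_b_subset = mean(nb),
         zone_f = length(f_span), zone_s = length(s_span)),
    class = "hybrid_rates")
}

#' @export
print.hybrid_rates <- function(x, ...) {
  cat("Per-capita per-bin transition rates (annotated subset)\n")
  cat(sprintf("  P_F = %.4f (fbar %.2f / n_B %.1f), zone of %d bins\n",
              mean(x$p_f), x$fbar, x$n_b_subset, x$zone_f))
  cat(sprintf("  P_S = %.4f (sbar %.2f / n_B %.1f), zone of %d bins\n",
              mean(x$p_s), x$sbar, x$n_b_subset, x$zone_s))
  invisible(x)
}

#' Hybrid estimator: DS subsurface abundance with subset transition rates
#'
#' Scales the distance-sampling estimate of subsurface abundance (fitted to
#' ALL localized events, annotated or not) by the per-capita transition
#' rates from the annotated subset to predict the duplicate counts:
#' `F_T^(H) = N_B^(DS) * P_F * Zone_F` and
#' `S_T^(H) = N_B^(DS) * P_S * Zone_S`, then
#' `N_T = N_S + N_B^(DS) - (F_T^(H) + S_T^(H))`.
#'
#' @param ns_fit `ds_fit`/`mrds_fit` for the visual platform.
#' @param nb_ds_fit `ds_fit` for all localized acoustic events.
#' @param rates A [hybrid_rates()].
#' @return An [abundance_estimate()] labelled `"Hybrid"`.
#' @export
estimate_hybrid <- function(ns_fit, nb_ds_fit, rates) {
  stopifnot(inherits(ns_fit, "ds_fit"), inherits(nb_ds_fit, "ds_fit"),
            inherits(rates, "hybrid_rates"))
  if (rates$zone_f <= 0 || rates$zone_s <= 0)
    stop("zone bin counts must be positive", call. = FALSE)
  d <- align_draws(ns_fit$draws$N_animals, nb_ds_fit$draws$N_animals,
                   rates$p_f, rates$p_s)
  n_d <- d[[2]] * d[[3]] * rates$zone_f + d[[2]] * d[[4]] * rates$zone_s
  abundance_estimate(n_s = d[[1]], n_b = d[[2]], n_d = n_d,
                     method = "Hybrid")
}

#' Surface availability from a combined estimate
#'
#' The proportion of whales available at the surface, `a_S = N_S / N_T`,
#' as a draw-wise ratio with summary CV. Draws with non-positive `N_T` are
#' dropped with a warning.
#'
#' @param estimate An [abundance_estimate()].
#' @return List with `draws` (availability draws) and `summary`
#'   (mean, sd, cv, credible bounds).
#' @examples
#' # point values: N_S = 306, N_T = 426 -> a_S = 0.72
#' availability(abundance_estimate(306, 120, 0, 426))$summary[["mean"]]
#' @export
availability <- function(estimate) {
  stopifnot(inherits(estimate, "abundance_estimate"))
  a <- estimate$draws$a_s
  bad <- is.na(a)
  if (any(bad))
    warning(sum(bad), " draw(s) without a valid availability ratio dropped",
            call. = FALSE)
  a <- a[!bad]
  if (!length(a)) stop("no draws with positive N_T", call. = FALSE)
  list(draws = a, summary = summarize_draws(a))
}
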