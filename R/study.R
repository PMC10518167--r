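#' Relative bias of an estimate
#'
#' `(estimate - truth) / truth`, the signed relative error used to score
#' the estimators in simulation studies.
#'
#' @param estimate,truth Numeric (vectorized); `truth` must be non-zero.
#' @return Signed relative bias.
#' @examples
#' relative_bias(55, 50) # 0.10
#' @export
relative_bias <- function(estimate, truth) {
  if (any(truth == 0)) stop("`truth` must be non-zero", call. = FALSE)
  (estimate - truth) / truth
}

#' Posterior coefficient of variation
#'
#' `sd / mean` of a vector of posterior draws.
#'
#' @param draws Numeric vector, at least 2 draws, non-zero mean.
#' @return CV (dimensionless).
#' @export
posterior_cv <- function(draws) {
  if (length(draws) < 2L)
    stop("at least 2 draws are needed for a CV", call. = FALSE)
  m <- mean(draws)
  if (m == 0) stop("degenerate draws: mean is zero", call. = FALSE)
  stats::sd(draws) / m
}

#' Gelman-Rubin potential scale reduction
#'
#' The classic between/within-chain variance ratio; values near 1 indicate
#' the chains agree, and convergence is presumed when R-hat < 1.1.
#'
#' @param chains List of numeric vectors (>= 2 chains of equal length).
#' @return R-hat (scalar). `NA` when the parameter is constant across all
#'   chains.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2L) stop("at least 2 chains are required", call. = FALSE)
  len <- vapply(chains, length, integer(1))
  if (length(unique(len)) != 1L)
    stop("chains must have equal length", call. = FALSE)
  nn <- len[1]
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0) return(if (stats::var(means) == 0) NA_real_ else Inf)
  B <- nn * stats::var(means)
  v_hat <- (nn - 1) / nn * W + B / nn
  sqrt(v_hat / W)
}

#' Posterior predictive p-value of a capture-recapture fit
#'
#' The probability that data replicated from the fitted model are at least
#' as discrepant as the observed data,
#' `P(D(rep) >= D(obs) | data)`, using a Freeman-Tukey discrepancy on the
#' per-bin detection counts of the observed events (computed draw-wise
#' during sampling). Values near 0 or 1 indicate misfit; ties count toward
#' the p-value, so identical discrepancies give 1.
#'
#' @param fit A [fit_cmr()] result.
#' @return p-value in `[0, 1]`.
#' @export
bayesian_pvalue <- function(fit) {
  stopifnot(inherits(fit, "cmr_fit"))
  mean(fit$discrepancy$D_rep >= fit$discrepancy$D_obs)
}

#' Apply the three estimators to one simulated dataset
#'
#' Fits the visual MRDS, the acoustic distance-sampling fit to all
#' localized events, the capture-recapture model to all histories (for
#' CMR-DS) and to the annotated subset (for Hybrid), then combines them
#' into the three abundance estimates.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param methods Character subset of `c("dsds", "cmrds", "hybrid")`.
#' @param ds_mcmc,cmr_mcmc MCMC settings for the detection and
#'   capture-recapture fits.
#' @param acoustic_form Detection-function form for the acoustic distance
#'   sampling fit (default hazard-rate, which accommodates the flat
#'   shoulder of event-level detection).
#' @param M_factor Augmented size as a multiple of the event count.
#' @return Named list of [abundance_estimate()]s plus the component fits.
#' @export
analyze_dataset <- function(dataset,
                            methods = c("dsds", "cmrds", "hybrid"),
                            ds_mcmc = list(burn = 600, iter = 1200, thin = 1),
                            cmr_mcmc = list(burn = 600, iter = 1200,
                                            thin = 1, chains = 1),
                            acoustic_form = "hazard_rate",
                            M_factor = 2) {
  methods <- match.arg(methods, c("dsds", "cmrds", "hybrid"),
                       several.ok = TRUE)
  scn <- dataset$scenario
  cfg <- scn$survey
  zone <- scenario_zone(scn)
  if (nrow(dataset$sightings) == 0L || nrow(dataset$events) == 0L)
    stop("dataset has no detections on one of the platforms", call. = FALSE)

  ns_fit <- fit_mrds(dataset$sightings, W = cfg$truncation_perp_visual,
                     mcmc = ds_mcmc)
  nb_ds <- fit_ds(dataset$events$perp_distance_m,
                  W = cfg$truncation_perp_acoustic,
                  form = acoustic_form, mcmc = ds_mcmc)
  hist_mat <- history_matrix(dataset$histories)

  out <- list(fits = list(ns = ns_fit, nb_ds = nb_ds))
  if ("dsds" %in% methods)
    out$dsds <- estimate_dsds(ns_fit, nb_ds)
  if ("cmrds" %in% methods) {
    cmr_full <- fit_cmr(hist_mat, dataset$events$perp_distance_m, cfg, zone,
                        M = ceiling(M_factor * nrow(hist_mat)),
                        mcmc = cmr_mcmc)
    out$fits$cmr_full <- cmr_full
    out$cmrds <- estimate_cmrds(ns_fit, cmr_full)
  }
  if ("hybrid" %in% methods) {
    ann <- dataset$events$fully_annotated
    if (!any(ann))
      stop("no annotated events: cannot run the hybrid method", call. = FALSE)
    cmr_sub <- fit_cmr(hist_mat[ann, , drop = FALSE],
                       dataset$events$perp_distance_m[ann], cfg, zone,
                       M = ceiling(M_factor * sum(ann)),
                       mcmc = cmr_mcmc)
    out$fits$cmr_subset <- cmr_sub
    out$hybrid <- estimate_hybrid(ns_fit, nb_ds, hybrid_rates(cmr_sub))
  }
  out
}

method_label <- c(dsds = "DS-DS", cmrds = "CMR-DS", hybrid = "Hybrid")

#' Run a simulation study of the three estimators
#'
#' Simulates `n_replicates` independent datasets from a scenario and
#' applies the requested estimators to each, recording posterior means and
#' CVs for total abundance and surface availability next to the simulation
#' truth. Replicate seeds are drawn once from the study seed, so each
#' replicate is reproducible in isolation and the output does not depend
#' on execution order.
#'
#' @param scenario A [scenario_config()].
#' @param n_replicates Number of simulated datasets.
#' @param methods Character subset of `c("dsds", "cmrds", "hybrid")`.
#' @param seed Integer study seed.
#' @inheritParams analyze_dataset
#' @return A `study_result`: `replicates` (one row per method per
#'   replicate: estimates, CVs, truth, a convergence flag) and `summary`
#'   (via [study_summary()]).
#' @export
run_study <- function(scenario, n_replicates,
                      methods = c("dsds", "cmrds", "hybrid"), seed = 1,
                      ds_mcmc = list(burn = 600, iter = 1200, thin = 1),
                      cmr_mcmc = list(burn = 600, iter = 1200, thin = 1,
                                      chains = 1)) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    ds <- simulate_dataset(scenario, seed = rep_seeds[r])
    set.seed(rep_seeds[r] %% 1000003L + 7L)  # fitting stream
    est <- tryCatch(
      analyze_dataset(ds, methods = methods, ds_mcmc = ds_mcmc,
                      cmr_mcmc = cmr_mcmc),
      error = function(e) e)
    if (inherits(est, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(est),
              call. = FALSE)
      next
    }
    for (m in methods) {
      d <- est[[m]]$draws
      a <- availability(est[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = method_label[[m]],
        n_t_hat = mean(d$n_t), n_t_cv = posterior_cv(d$n_t),
        a_s_hat = a$summary[["mean"]], a_s_cv = a$summary[["cv"]],
        n_true = ds$truth$n_true, a_true = ds$truth$a_true,
        n_events = nrow(ds$events), n_sightings = nrow(ds$sightings),
        seed = rep_seeds[r],
        converged = TRUE)
    }
  }
  if (!length(rows)) stop("no replicate completed", call. = FALSE)
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  structure(list(replicates = replicates,
                 summary = study_summary(replicates),
                 scenario = scenario, seed = seed),
            class = "study_result")
}

#' Summarize a simulation study
#'
#' A pure function of the per-replicate table: mean relative bias of total
#' abundance and surface availability per method (estimate vs truth,
#' averaged over replicates) and the across-replicate range of posterior
#' CVs.
#'
#' @param replicates Per-replicate table from [run_study()] (or its
#'   `study_result`).
#' @return Data frame, one row per method.
#' @export
study_summary <- function(replicates) {
  if (inherits(replicates, "study_result"))
    replicates <- replicates$replicates
  out <- do.call(rbind, lapply(split(replicates, replicates$method),
    function(d) data.frame(
      method = d$method[1],
      n_replicates = nrow(d),
      bias_n_t = mean(relative_bias(d$n_t_hat, d$n_true)),
      bias_a_s = mean(relative_bias(d$a_s_hat, d$a_true)),
      cv_n_t_lo = min(d$n_t_cv), cv_n_t_hi = max(d$n_t_cv),
      cv_a_s_lo = min(d$a_s_cv), cv_a_s_hi = max(d$a_s_cv))))
  rownames(out) <- NULL
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicate(s)\n",
              max(x$replicates$replicate)))
  print(transform(x$summary,
                  bias_n_t = sprintf("%+.1f%%", 100 * bias_n_t),
                  bias_a_s = sprintf("%+.1f%%", 100 * bias_a_s),
                  cv_n_t_lo = round(cv_n_t_lo, 3),
                  cv_n_t_hi = round(cv_n_t_hi, 3),
                  cv_a_s_lo = round(cv_a_s_lo, 3),
                  cv_a_s_hi = round(cv_a_s_hi, 3)))
  invisible(x)
}

#' Bar chart of relative bias by method and quantity
#'
#' @param study A `study_result` (or its per-replicate table).
#' @return A ggplot object.
#' @export
plot_study <- function(study) {
  s <- study_summary(study)
  df <- rbind(
    data.frame(method = s$method, quantity = "Total abundance",
               bias = 100 * s$bias_n_t),
    data.frame(method = s$method, quantity = "Surface availability",
               bias = 100 * s$bias_a_s))
  ggplot2::ggplot(df, ggplot2::aes(x = method, y = bias, fill = method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = NULL, y = "Relative bias (%)") +
    ggplot2::theme_minimal()
}
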