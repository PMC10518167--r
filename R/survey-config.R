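#' Survey and binning configuration
#'
#' Describes the geometry shared by the visual and acoustic platforms: the
#' perpendicular truncation distances, the forward-distance extent of the
#' acoustic detection grid, the bin width and the ship speed. Because the
#' ship moves at a constant rate, each forward-distance bin also represents
#' a fixed unit of time (`bin_duration = bin_width / ship_speed`), which is
#' what lets click trains recorded in time be analysed as capture histories
#' over forward-distance bins.
#'
#' The forward coordinate is signed: positive ahead of the ship, zero at the
#' array reference point, negative aft. Bin 1 is the farthest-ahead bin (at
#' `max_forward_ahead`, the maximum distance at which whales are detected by
#' the towed array) and indices increase toward and past the ship. When
#' `max_forward_ahead + max_forward_behind` is not a multiple of
#' `bin_width`, the number of bins is rounded up (`ceiling`), so the last
#' bin may extend slightly beyond `-max_forward_behind`.
#'
#' @param truncation_perp_visual Perpendicular truncation distance W for the
#'   visual platform, metres.
#' @param truncation_perp_acoustic Perpendicular truncation distance for the
#'   acoustic platform, metres.
#' @param max_forward_ahead Farthest forward distance (ahead of the ship) of
#'   the acoustic grid, metres.
#' @param max_forward_behind Farthest distance aft of the ship covered by
#'   the grid, metres (non-negative; the towed array hears behind the ship).
#' @param bin_width Width of one forward-distance bin, metres.
#' @param ship_speed Ship speed, metres per second.
#'
#' @return An object of class `survey_config`: a list with the input fields
#'   plus `bin_duration` (seconds per bin), `n_bins` (J) and `midpoints`
#'   (signed forward distances of bin midpoints, farthest-ahead first).
#' @examples
#' cfg <- survey_config(
#'   truncation_perp_visual = 4000, truncation_perp_acoustic = 4000,
#'   max_forward_ahead = 300, max_forward_behind = 0,
#'   bin_width = 100, ship_speed = 5
#' )
#' build_bin_grid(cfg) # 250 150 50
#' @export
survey_config <- function(truncation_perp_visual,
                          truncation_perp_acoustic,
                          max_forward_ahead,
                          max_forward_behind,
                          bin_width,
                          ship_speed) {
  stopifnot(
    is.numeric(truncation_perp_visual), length(truncation_perp_visual) == 1L,
    is.numeric(truncation_perp_acoustic), length(truncation_perp_acoustic) == 1L,
    is.numeric(max_forward_ahead), length(max_forward_ahead) == 1L,
    is.numeric(max_forward_behind), length(max_forward_behind) == 1L,
    is.numeric(bin_width), length(bin_width) == 1L,
    is.numeric(ship_speed), length(ship_speed) == 1L
  )
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  if (!is.finite(ship_speed) || ship_speed <= 0)
    stop("`ship_speed` must be positive", call. = FALSE)
  if (truncation_perp_visual <= 0 || truncation_perp_acoustic <= 0)
    stop("perpendicular truncation distances must be positive", call. = FALSE)
  if (max_forward_behind < 0)
    stop("`max_forward_behind` is a distance aft of the ship and must be >= 0",
         call. = FALSE)
  span <- max_forward_ahead + max_forward_behind
  if (span <= 0)
    stop("the forward grid has non-positive extent", call. = FALSE)
  n_bins <- as.integer(ceiling(span / bin_width))
  if (n_bins < 2L)
    stop("the grid must contain at least 2 bins; widen the forward extent ",
         "or narrow `bin_width`", call. = FALSE)
  midpoints <- max_forward_ahead - (seq_len(n_bins) - 0.5) * bin_width
  out <- list(
    truncation_perp_visual = truncation_perp_visual,
    truncation_perp_acoustic = truncation_perp_acoustic,
    max_forward_ahead = max_forward_ahead,
    max_forward_behind = max_forward_behind,
    bin_width = bin_width,
    ship_speed = ship_speed,
    bin_duration = bin_width / ship_speed,
    n_bins = n_bins,
    midpoints = midpoints
  )
  class(out) <- "survey_config"
  out
}

#' @export
print.survey_config <- function(x, ...) {
  cat("Survey configuration\n")
  cat(sprintf("  perpendicular truncation: visual %g m, acoustic %g m\n",
              x$truncation_perp_visual, x$truncation_perp_acoustic))
  cat(sprintf("  forward grid: +%g m ahead to -%g m aft, %d bins of %g m\n",
              x$max_forward_ahead, x$max_forward_behind, x$n_bins,
              x$bin_width))
  cat(sprintf("  ship speed %g m/s (%.1f s per bin)\n",
              x$ship_speed, x$bin_duration))
  invisible(x)
}

#' Forward-distance bin midpoints
#'
#' Ordered bin midpoints of the acoustic grid, farthest-ahead bin first
#' (signed forward distance, positive ahead of the ship).
#'
#' @param config A [survey_config()].
#' @return Numeric vector of length `config$n_bins`.
#' @export
build_bin_grid <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  config$midpoints
}

#' Radial distance from perpendicular and forward distance
#'
#' The Euclidean combination of a whale's localized perpendicular distance
#' from the trackline and the (signed) forward distance of a bin midpoint.
#' Symmetric in the sign of the forward distance: a bin aft of the ship is
#' as far away as the mirrored bin ahead.
#'
#' @param perp Perpendicular distance(s), metres, non-negative.
#' @param forward_midpoint Signed forward distance(s), metres.
#' @return Radial distance(s), metres.
#' @examples
#' radial_distance(3, 4) # 5
#' @export
radial_distance <- function(perp, forward_midpoint) {
  if (any(perp < 0))
    stop("perpendicular distance must be non-negative", call. = FALSE)
  sqrt(perp^2 + forward_midpoint^2)
}

#' Construct an acoustic event
#'
#' One localized click train: its perpendicular distance, its binary capture
#' history over the forward-distance bins and the per-bin radial distances
#' (derived from the perpendicular distance and the bin midpoints).
#'
#' @param event_id Identifier (scalar).
#' @param perp_distance Localized perpendicular distance, metres.
#' @param history Integer 0/1 vector of length `config$n_bins`; at least one
#'   bin must be 1 for an observed event.
#' @param config A [survey_config()].
#' @param fully_annotated Logical flag: whether every click of the event was
#'   annotated (events with `FALSE` enter the distance-sampling estimate of
#'   subsurface abundance but not the capture-recapture fit).
#' @return An object of class `acoustic_event`.
#' @export
acoustic_event <- function(event_id, perp_distance, history, config,
                           fully_annotated = TRUE) {
  stopifnot(inherits(config, "survey_config"))
  if (perp_distance < 0)
    stop("perpendicular distance must be non-negative", call. = FALSE)
  history <- as.integer(history)
  if (length(history) != config$n_bins)
    stop("history must have one entry per bin (", config$n_bins, ")",
         call. = FALSE)
  if (!all(history %in% c(0L, 1L)))
    stop("history entries must be 0 or 1", call. = FALSE)
  if (sum(history) < 1L)
    stop("an observed event must be detected in at least one bin",
         call. = FALSE)
  structure(
    list(
      event_id = event_id,
      perp_distance = perp_distance,
      history = history,
      radial = radial_distance(perp_distance, config$midpoints),
      fully_annotated = isTRUE(fully_annotated)
    ),
    class = "acoustic_event"
  )
}
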