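#' Bin a click train into a forward-distance capture history
#'
#' Converts the raw click record of one acoustic event into the binary
#' capture history used by the capture-recapture model. Click times are
#' converted to forward distances by anchoring on the forward distance of
#' the first recorded click and assuming the ship moves at a constant
#' speed (so the whale's forward distance relative to the ship decreases at
#' `ship_speed` while it remains horizontally stationary). A bin scores 1
#' if at least one click falls in it, 0 otherwise.
#'
#' Clicks that convert to positions outside the grid are dropped with a
#' warning; the number dropped is returned in the `n_dropped` attribute.
#' A click exactly on a bin boundary is assigned to the farther-ahead bin.
#'
#' @param clicks A data frame with columns `time_s` (non-decreasing within
#'   the event) and `forward_distance_m` (signed, negative aft). Only the
#'   first click's `forward_distance_m` is used as the anchor.
#' @param config A [survey_config()].
#' @return Integer 0/1 vector of length `config$n_bins`, with attribute
#'   `n_dropped` counting clicks that fell outside the grid.
#' @export
bin_click_train <- function(clicks, config) {
  stopifnot(inherits(config, "survey_config"))
  if (!is.data.frame(clicks) || nrow(clicks) == 0L)
    stop("`clicks` must be a data frame with at least one click",
         call. = FALSE)
  need <- c("time_s", "forward_distance_m")
  miss <- setdiff(need, names(clicks))
  if (length(miss))
    stop("`clicks` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tt <- clicks$time_s
  if (is.unsorted(tt))
    stop("click times within an event must be non-decreasing", call. = FALSE)
  y <- clicks$forward_distance_m[1L] - config$ship_speed * (tt - tt[1L])
  j <- forward_to_bin(y, config)
  dropped <- sum(is.na(j))
  if (dropped > 0L)
    warning(dropped, " click(s) fell outside the forward grid and were dropped",
            call. = FALSE)
  history <- integer(config$n_bins)
  history[unique(j[!is.na(j)])] <- 1L
  attr(history, "n_dropped") <- dropped
  history
}

#' Map signed forward distances to bin indices
#'
#' Bin j covers the half-open interval
#' `(max_forward_ahead - j*bin_width, max_forward_ahead - (j-1)*bin_width]`,
#' so a position exactly on a boundary belongs to the farther-ahead bin.
#' Positions outside the grid map to `NA`.
#'
#' @param y Signed forward distance(s), metres.
#' @param config A [survey_config()].
#' @return Integer bin indices (1 = farthest ahead), `NA` outside the grid.
#' @export
forward_to_bin <- function(y, config) {
  stopifnot(inherits(config, "survey_config"))
  j <- ceiling((config$max_forward_ahead - y) / config$bin_width)
  j[y == config$max_forward_ahead] <- 1L  # top edge belongs to bin 1
  j[j < 1L | j > config$n_bins] <- NA_integer_
  as.integer(j)
}
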