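#' Read and write survey data bundles
#'
#' Plain-CSV interchange for the four survey tables, plus a YAML survey
#' configuration. Schemas (header row required, UTF-8):
#'
#' * `sightings.csv`: `sighting_id, team, perp_distance_m, group_size,
#'   duplicate_id` (empty `duplicate_id` = no linked duplicate).
#' * `events.csv`: `event_id, perp_distance_m, fully_annotated`.
#' * `clicks.csv`: `event_id, time_s, forward_distance_m`.
#' * `histories.csv`: wide, `event_id, bin_1 ... bin_J`.
#' * `config.yaml`: fields mirroring [survey_config()].
#'
#' Unknown extra columns are preserved on read and written back on write.
#'
#' @param path Directory containing (or to contain) the files.
#' @param survey For `write_survey`, a list with any of `sightings`,
#'   `events`, `clicks`, `histories` (data frames) and `config`
#'   (a [survey_config()]).
#' @return `read_survey` returns a list with the tables present in `path`
#'   (and `config` if `config.yaml` exists); `write_survey` returns `path`
#'   invisibly.
#' @name survey_io
NULL

check_columns <- function(df, need, file) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file '", file, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a sightings table
#' @param file Path to a `sightings.csv`-schema file.
#' @return Data frame of visual sightings.
#' @export
read_sightings <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, c("sighting_id", "team", "perp_distance_m", "group_size"),
                file)
  if (!"duplicate_id" %in% names(df)) df$duplicate_id <- NA
  df$duplicate_id[df$duplicate_id %in% ""] <- NA
  if (anyDuplicated(df$sighting_id))
    stop("duplicate sighting_id rows in '", file, "'", call. = FALSE)
  if (!all(df$team %in% c(1L, 2L)))
    stop("'team' must be 1 or 2 in '", file, "'", call. = FALSE)
  if (any(df$perp_distance_m < 0))
    stop("negative perpendicular distance in '", file, "'", call. = FALSE)
  if (any(df$group_size < 1))
    stop("group_size must be >= 1 in '", file, "'", call. = FALSE)
  df
}

#' Read an acoustic events table
#' @param file Path to an `events.csv`-schema file.
#' @return Data frame of localized acoustic events.
#' @export
read_events <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, c("event_id", "perp_distance_m"), file)
  if (!"fully_annotated" %in% names(df)) df$fully_annotated <- TRUE
  df$fully_annotated <- as.logical(df$fully_annotated)
  if (anyDuplicated(df$event_id))
    stop("duplicate event_id rows in '", file, "'", call. = FALSE)
  if (any(df$perp_distance_m < 0))
    stop("negative perpendicular distance in '", file, "'", call. = FALSE)
  df
}

#' Read a raw click table
#' @param file Path to a `clicks.csv`-schema file.
#' @return Data frame of clicks (times non-decreasing within each event).
#' @export
read_clicks <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, c("event_id", "time_s", "forward_distance_m"), file)
  df
}

#' Read a wide capture-history table
#' @param file Path to a `histories.csv`-schema file (`event_id`,
#'   `bin_1`..`bin_J`).
#' @return Data frame; bin columns are integer 0/1.
#' @export
read_histories <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, "event_id", file)
  bins <- grep("^bin_\\d+$", names(df), value = TRUE)
  if (length(bins) < 2L)
    stop("file '", file, "' has no bin_1..bin_J history columns",
         call. = FALSE)
  if (anyDuplicated(df$event_id))
    stop("duplicate event_id rows in '", file, "'", call. = FALSE)
  vals <- as.matrix(df[bins])
  if (!all(vals %in% c(0L, 1L)))
    stop("history entries must be 0 or 1 in '", file, "'", call. = FALSE)
  df[bins] <- lapply(df[bins], as.integer)
  df
}

#' Extract the history matrix from a wide histories table
#' @param histories Data frame from [read_histories()].
#' @return Integer matrix (events x bins), rownames = event_id, columns in
#'   bin order.
#' @export
history_matrix <- function(histories) {
  bins <- grep("^bin_\\d+$", names(histories), value = TRUE)
  bins <- bins[order(as.integer(sub("^bin_", "", bins)))]
  m <- as.matrix(histories[bins])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(histories$event_id)
  m
}

#' Read a survey configuration from YAML
#' @param file Path to a YAML file with [survey_config()] fields.
#' @return A [survey_config()].
#' @export
read_survey_config <- function(file) {
  cf <- yaml::read_yaml(file)
  need <- c("truncation_perp_visual", "truncation_perp_acoustic",
            "max_forward_ahead", "max_forward_behind", "bin_width",
            "ship_speed")
  miss <- setdiff(need, names(cf))
  if (length(miss))
    stop("config '", file, "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  do.call(survey_config, cf[need])
}

#' Write a survey configuration to YAML
#' @param config A [survey_config()].
#' @param file Output path.
#' @export
write_survey_config <- function(config, file) {
  stopifnot(inherits(config, "survey_config"))
  fields <- config[c("truncation_perp_visual", "truncation_perp_acoustic",
                     "max_forward_ahead", "max_forward_behind", "bin_width",
                     "ship_speed")]
  yaml::write_yaml(fields, file)
  invisible(file)
}

#' @rdname survey_io
#' @export
read_survey <- function(path) {
  out <- list()
  f <- function(name) file.path(path, name)
  if (file.exists(f("config.yaml"))) out$config <- read_survey_config(f("config.yaml"))
  if (file.exists(f("sightings.csv"))) out$sightings <- read_sightings(f("sightings.csv"))
  if (file.exists(f("events.csv"))) out$events <- read_events(f("events.csv"))
  if (file.exists(f("clicks.csv"))) out$clicks <- read_clicks(f("clicks.csv"))
  if (file.exists(f("histories.csv"))) out$histories <- read_histories(f("histories.csv"))
  if (!length(out))
    stop("no survey files found under '", path, "'", call. = FALSE)
  out
}

#' @rdname survey_io
#' @export
write_survey <- function(survey, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(path, name), row.names = FALSE, na = "")
  if (!is.null(survey$sightings)) wr(survey$sightings, "sightings.csv")
  if (!is.null(survey$events)) wr(survey$events, "events.csv")
  if (!is.null(survey$clicks)) wr(survey$clicks, "clicks.csv")
  if (!is.null(survey$histories)) wr(survey$histories, "histories.csv")
  if (!is.null(survey$config))
    write_survey_config(survey$config, file.path(path, "config.yaml"))
  invisible(path)
}
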