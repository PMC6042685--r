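#' Construct a thermocouple temperature log
#'
#' @param times seconds, strictly increasing after duplicate collapse.
#' @param temps degrees C, one per time point.
#' @return A `temperature_log` (data.frame with columns `time_s`, `temp_C`).
#' @export
temperature_log <- function(times, temps) {
  if (length(times) != length(temps)) {
    stop_format("times and temps must have equal length")
  }
  if (anyNA(times) || anyNA(temps)) stop_format("log must not contain NA")
  ord <- order(times)
  times <- times[ord]; temps <- temps[ord]
  if (anyDuplicated(times)) {
    temps <- as.numeric(tapply(temps, times, mean))
    times <- sort(unique(times))
  }
  if (length(times) < 2L) {
    stop_format("a temperature log needs at least 2 distinct time points")
  }
  if (any(diff(times) <= 0)) {
    stop_format("log times must be strictly increasing")
  }
  structure(data.frame(time_s = times, temp_C = temps),
            class = c("temperature_log", "data.frame"))
}

#' Read a thermocouple log from CSV
#'
#' Expects header columns `time_s` and `temp_C` (a ~4 Hz probe reading).
#' Rows are sorted by time and duplicate timestamps collapsed to their mean
#' temperature.
#'
#' @param path CSV file.
#' @return A [temperature_log()].
#' @export
load_temperature_log <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- tryCatch(read.csv(path),
                 error = function(e) stop_io("cannot read '", path, "': ",
                                             conditionMessage(e)))
  if (!all(c("time_s", "temp_C") %in% names(df))) {
    stop_format("temperature log must have columns time_s, temp_C")
  }
  temperature_log(as.numeric(df$time_s), as.numeric(df$temp_C))
}

#' The latency censoring cap (seconds)
#'
#' Thermal stimulation is ceased at 11 s; animals that have not shown
#' nocifensive escape locomotion by then carry the cap value and are flagged
#' censored.
#' @export
LATENCY_CAP_S <- 11

#' Construct a per-animal behavior table
#'
#' Each row is one animal with a genotype label and at least one outcome:
#' `latency_s` (seconds to nocifensive escape locomotion, censored at the
#' 11 s cap) and/or `responded` (binary response to a fixed stimulus).
#' Latencies exactly at the cap are flagged `censored`.
#'
#' @param df data.frame with columns `genotype` and `latency_s` and/or
#'   `responded`; optional `animal_id`, `sex`.
#' @return A validated `behavior_table` (data.frame).
#' @export
behavior_table <- function(df) {
  if (!"genotype" %in% names(df)) stop_format("missing 'genotype' column")
  has_lat <- "latency_s" %in% names(df)
  has_resp <- "responded" %in% names(df)
  if (!has_lat && !has_resp) {
    stop_format("need at least one of 'latency_s' / 'responded'")
  }
  if (!"animal_id" %in% names(df)) df$animal_id <- seq_len(nrow(df))
  if (has_lat) {
    lat <- as.numeric(df$latency_s)
    bad <- !is.na(lat) & (lat <= 0 | lat > LATENCY_CAP_S)
    if (any(bad)) {
      stop_validation("latency_s outside (0, ", LATENCY_CAP_S,
                      "]: censoring cap violated")
    }
    df$latency_s <- lat
    df$censored <- !is.na(lat) & lat == LATENCY_CAP_S
  }
  if (has_resp) {
    df$responded <- as.logical(df$responded)
  }
  some <- rep(FALSE, nrow(df))
  if (has_lat) some <- some | !is.na(df$latency_s)
  if (has_resp) some <- some | !is.na(df$responded)
  if (!all(some)) stop_format("every row needs at least one outcome value")
  df$genotype <- as.character(df$genotype)
  structure(df, class = c("behavior_table", "data.frame"))
}

#' Read a behavior table from CSV
#'
#' @param path CSV with a `genotype` column and `latency_s` and/or
#'   `responded` columns.
#' @return A [behavior_table()].
#' @export
load_behavior_table <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- tryCatch(read.csv(path),
                 error = function(e) stop_io("cannot read '", path, "': ",
                                             conditionMessage(e)))
  behavior_table(df)
}

#' Resolved run configuration
#'
#' Reads a YAML configuration, fills defaults, and validates. Any value in
#' `overrides` (e.g. parsed command-line flags) takes precedence over the
#' file; the resolved configuration carries the seed used by every
#' stochastic step.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list overriding config keys.
#' @return A list with elements `seed`, `bin_width_C`, `baseline_frames`,
#'   `roi_diameter_px`, `corner_margin_px`, `output_dir`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(seed = 1L, bin_width_C = 1, baseline_frames = 30L,
              roi_diameter_px = 6L, corner_margin_px = 2L,
              output_dir = ".")
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io("no such config: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  if (cfg$bin_width_C <= 0) stop_validation("bin_width_C must be > 0")
  if (cfg$baseline_frames < 1) stop_validation("baseline_frames must be >= 1")
  if (cfg$roi_diameter_px < 1) stop_validation("roi_diameter_px must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
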