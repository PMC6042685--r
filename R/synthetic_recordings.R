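#' Gaussian temperature-response profile
#'
#' Returns the mapping from probe temperature to true fractional fluorescence
#' increase used by the GCaMP generator: a Gaussian bump
#' `amplitude * exp(-(T - center_C)^2 / (2 width_C^2))`.
#'
#' @param center_C peak temperature in degrees C.
#' @param width_C Gaussian SD in degrees C.
#' @param amplitude peak fractional increase (0.2 = a 20% peak
#'   \eqn{\Delta F/F_0}).
#' @return A function of temperature (degrees C).
#' @export
gaussian_response <- function(center_C, width_C, amplitude) {
  stopifnot(amplitude >= 0, width_C > 0)
  force(center_C); force(width_C); force(amplitude)
  function(temp_C) amplitude * exp(-(temp_C - center_C)^2 / (2 * width_C^2))
}

#' Ground truth for a synthetic GCaMP heat-ramp recording
#'
#' Emulates an axon-terminal calcium recording during a slow local heat
#' ramp: the probe holds ambient temperature, then ramps at `ramp_rate`
#' (0.1 degrees C/s by default) to `max_C`. Camera frames (~4 Hz, jittered)
#' and the thermocouple log (4 Hz) run on deliberately unsynchronized
#' clocks, the log's timestamps shifted by `clock_offset_s`. Fluorescence
#' follows `f0_true * (1 + response_curve(T(t)))` plus per-pixel noise.
#'
#' The control profile defaults peak mid-way through the 43 degree C bin
#' (43.5 degrees C), i.e. within the 1-degree bin labelled 43.
#'
#' @param response_curve function mapping degrees C to fractional
#'   \eqn{\Delta F/F_0}; see [gaussian_response()].
#' @param ramp_rate degrees C per second during the ramp.
#' @param f0_true baseline fluorescence intensity of the terminal.
#' @param frame_rate camera frames per second.
#' @param clock_offset_s thermocouple-clock minus camera-clock offset.
#' @param ambient_C bath temperature before the ramp.
#' @param max_C temperature at which the ramp stops (held afterwards).
#' @param baseline_hold_s seconds of ambient hold before the ramp (long
#'   enough to cover the 30-frame F0 baseline at 4 Hz).
#' @param noise_sd per-pixel Gaussian noise SD per slice.
#' @param frame_jitter_s SD of frame-timestamp jitter.
#' @param ny,nx,nz frame geometry (desk-scale default; set to the
#'   acquisition geometry of a real rig if desired).
#' @param bit_depth 8 or 16.
#' @return A `recording_truth` list.
#' @export
recording_truth <- function(response_curve = gaussian_response(43.5, 2, 0.2),
                            ramp_rate = 0.1, f0_true = 1000,
                            frame_rate = 4, clock_offset_s = 0.3,
                            ambient_C = 25, max_C = 50,
                            baseline_hold_s = 10,
                            noise_sd = 20, frame_jitter_s = 0.02,
                            ny = 32L, nx = 64L, nz = 3L, bit_depth = 16L) {
  stopifnot(ramp_rate > 0, f0_true > 0, frame_rate > 0, max_C > ambient_C)
  structure(
    list(response_curve = response_curve, ramp_rate = ramp_rate,
         f0_true = f0_true, frame_rate = frame_rate,
         clock_offset_s = clock_offset_s, ambient_C = ambient_C,
         max_C = max_C, baseline_hold_s = baseline_hold_s,
         noise_sd = noise_sd, frame_jitter_s = frame_jitter_s,
         ny = as.integer(ny), nx = as.integer(nx), nz = as.integer(nz),
         bit_depth = as.integer(bit_depth)),
    class = "recording_truth"
  )
}

# Probe temperature at true time t under the hold-ramp-hold protocol.
.probe_temp <- function(truth, t) {
  ramped <- pmax(0, t - truth$baseline_hold_s)
  pmin(truth$ambient_C + truth$ramp_rate * ramped, truth$max_C)
}

#' Total duration needed to complete the ramp
#' @param truth a [recording_truth()].
#' @param tail_s seconds recorded after the ramp tops out.
#' @return Duration in seconds.
#' @export
ramp_duration_s <- function(truth, tail_s = 5) {
  truth$baseline_hold_s +
    (truth$max_C - truth$ambient_C) / truth$ramp_rate + tail_s
}

#' Generate a synthetic GCaMP heat-ramp recording
#'
#' Produces a single-channel time series of Z-stacks: a bright terminal
#' disc (radius 8 px) centered in the frame whose intensity tracks
#' `f0_true * (1 + response_curve(T))`, over a dim background, with i.i.d.
#' Gaussian pixel noise per slice, plus the asynchronous thermocouple log.
#' Deterministic given `(truth, seed)`.
#'
#' @param truth a [recording_truth()].
#' @param duration_s recording length in seconds (default: long enough to
#'   complete the ramp, [ramp_duration_s()]).
#' @param seed integer seed.
#' @return List with `recording` (a `calcium_recording`: field `frames` is a
#'   `(nz, ny, nx, n_frames)` array, plus `frame_times`, `log`,
#'   `roi_center`, `roi_diameter_px`) and `truth`.
#' @export
generate_gcamp_recording <- function(truth, duration_s = NULL, seed = 1L) {
  stopifnot(inherits(truth, "recording_truth"))
  if (is.null(duration_s)) duration_s <- ramp_duration_s(truth)
  stopifnot(duration_s > 0)
  with_seed(seed, {
    n_frames <- floor(duration_s * truth$frame_rate)
    frame_times <- (seq_len(n_frames) - 1L) / truth$frame_rate +
      rnorm(n_frames, 0, truth$frame_jitter_s)
    frame_times <- cummax(pmax(frame_times, 0))  # keep increasing
    frame_times <- frame_times + seq_len(n_frames) * 1e-9
    log_times <- seq(0, duration_s, by = 0.25)
    log_temps <- .probe_temp(truth, log_times)
    log <- temperature_log(log_times + truth$clock_offset_s, log_temps)

    cy <- (truth$ny - 1) / 2; cx <- (truth$nx - 1) / 2
    disc <- ellipse_mask(truth$ny, truth$nx, cy, cx, 8, 8)
    f_t <- truth$f0_true *
      (1 + truth$response_curve(.probe_temp(truth, frame_times)))
    npx <- truth$ny * truth$nx
    mean_px <- matrix(100, npx, n_frames)
    mean_px[as.vector(disc), ] <- rep(f_t, each = sum(disc))
    mean_yxt <- array(mean_px, c(truth$ny, truth$nx, n_frames))
    frames <- array(0, dim = c(truth$nz, truth$ny, truth$nx, n_frames))
    for (z in seq_len(truth$nz)) {
      sl <- mean_yxt
      if (truth$noise_sd > 0) {
        sl <- sl + rnorm(length(sl), 0, truth$noise_sd)
      }
      frames[z, , , ] <- round(.clip_intensity(sl, truth$bit_depth))
    }
  })
  rec <- structure(
    list(frames = frames, frame_times = frame_times, log = log,
         roi_center = c(cy, cx), roi_diameter_px = 6,
         bit_depth = truth$bit_depth),
    class = "calcium_recording"
  )
  list(recording = rec, truth = truth)
}

#' Ground truth for a synthetic behavior dataset
#'
#' One row per genotype: latencies are drawn from a lognormal family (the
#' default positive right-skewed choice) and censored at the 11 s cap;
#' binary responses are Bernoulli.
#'
#' @param groups data.frame with columns `genotype`, `n`, and any of
#'   `meanlog`, `sdlog` (latency family parameters) and `response_prob`.
#' @return A `behavior_truth` list.
#' @export
behavior_truth <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("genotype", "n") %in% names(groups)))
  if (!"meanlog" %in% names(groups)) groups$meanlog <- NA_real_
  if (!"sdlog" %in% names(groups)) groups$sdlog <- NA_real_
  if (!"response_prob" %in% names(groups)) groups$response_prob <- NA_real_
  stopifnot(all(groups$n >= 1))
  pr <- groups$response_prob
  stopifnot(all(is.na(pr) | (pr >= 0 & pr <= 1)))
  structure(list(groups = groups, family = "lognormal"),
            class = "behavior_truth")
}

#' Generate a synthetic behavior table
#'
#' Latencies above the 11 s cap are recorded as 11 and flagged censored.
#' Deterministic given `(truth, seed)`.
#'
#' @param truth a [behavior_truth()].
#' @param seed integer seed.
#' @return A [behavior_table()].
#' @export
generate_behavior_dataset <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "behavior_truth"))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth$groups)), function(i) {
      g <- truth$groups[i, ]
      lat <- if (!is.na(g$meanlog)) {
        pmin(rlnorm(g$n, g$meanlog, g$sdlog), LATENCY_CAP_S)
      } else {
        rep(NA_real_, g$n)
      }
      resp <- if (!is.na(g$response_prob)) {
        as.logical(rbinom(g$n, 1L, g$response_prob))
      } else {
        rep(NA, g$n)
      }
      data.frame(genotype = g$genotype, latency_s = lat, responded = resp)
    })
  })
  df <- do.call(rbind, rows)
  df$animal_id <- seq_len(nrow(df))
  keep <- c("animal_id", "genotype")
  if (!all(is.na(df$latency_s))) keep <- c(keep, "latency_s")
  if (!all(is.na(df$responded))) keep <- c(keep, "responded")
  behavior_table(df[, keep, drop = FALSE])
}
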