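#' Construct a calcium recording
#'
#' @param frames numeric `(z, y, x, frame)` array of single-channel
#'   fluorescence Z-stacks.
#' @param frame_times seconds, one per frame, increasing (camera clock).
#' @param log a [temperature_log()] on the thermocouple's own clock.
#' @param roi_center 0-based `(y, x)` center of the measurement ROI (the
#'   centroid of the target neuromere).
#' @param roi_diameter_px ROI diameter in pixels (default 6).
#' @return A `calcium_recording`.
#' @export
calcium_recording <- function(frames, frame_times, log, roi_center,
                              roi_diameter_px = 6) {
  stopifnot(length(dim(frames)) == 4L,
            length(frame_times) == dim(frames)[4L],
            inherits(log, "temperature_log"))
  if (any(diff(frame_times) <= 0)) {
    stop_format("frame_times must be strictly increasing")
  }
  structure(list(frames = frames, frame_times = frame_times, log = log,
                 roi_center = as.numeric(roi_center),
                 roi_diameter_px = roi_diameter_px),
            class = "calcium_recording")
}

# Logical (ny x nx) disc: pixel centers strictly within radius of center.
.roi_disc <- function(ny, nx, center, diameter_px) {
  r <- diameter_px / 2
  cy <- center[1L]; cx <- center[2L]
  if (cy - r < -0.5 || cy + r > ny - 0.5 ||
      cx - r < -0.5 || cx + r > nx - 0.5) {
    stop_geometry("ROI disc extends beyond the image")
  }
  yy <- matrix(seq_len(ny) - 1L, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  (yy - cy)^2 + (xx - cx)^2 < r^2
}

#' Per-frame ROI fluorescence trace
#'
#' For each frame, max-projects the Z-stack and averages intensity over the
#' circular ROI (pixels whose centers lie strictly within `diameter / 2` of
#' the ROI center).
#'
#' @param recording a [calcium_recording()] (or the `recording` element of
#'   [generate_gcamp_recording()]).
#' @return Numeric vector `f`, one mean intensity per frame.
#' @export
roi_trace <- function(recording) {
  stopifnot(inherits(recording, "calcium_recording"))
  d <- dim(recording$frames)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]; nt <- d[4L]
  mask <- .roi_disc(ny, nx, recording$roi_center,
                    recording$roi_diameter_px)
  if (!any(mask)) stop_geometry("ROI contains no pixel centers")
  m <- matrix(recording$frames, nrow = nz)
  proj <- do.call(pmax, lapply(seq_len(nz), function(z) m[z, ]))
  proj <- matrix(proj, ny * nx, nt)
  colMeans(proj[as.vector(mask), , drop = FALSE])
}

#' Percent fluorescence change from baseline
#'
#' \eqn{F_0} is the mean of the first `n_baseline` frames (30 by default);
#' \eqn{\Delta F/F_0 = 100 (F - F_0)/F_0} per frame.
#'
#' @param f per-frame fluorescence (from [roi_trace()]).
#' @param n_baseline number of baseline frames.
#' @return List with `f0` (scalar) and `dff` (percent per frame).
#' @export
dff <- function(f, n_baseline = 30L) {
  if (length(f) < n_baseline) {
    stop_format("need at least ", n_baseline, " frames for the baseline")
  }
  f0 <- mean(f[seq_len(n_baseline)])
  if (!is.finite(f0) || f0 <= 0) {
    stop_validation("baseline F0 must be positive")
  }
  list(f0 = f0, dff = 100 * (f - f0) / f0)
}

#' Interpolate probe temperature at frame times
#'
#' Camera and thermocouple are not synchronized; each frame's temperature
#' is estimated by linear interpolation between the bracketing log samples.
#' Frames before the first (after the last) log sample take the first
#' (last) logged temperature (endpoint hold; the ramp is slow, so edges are
#' brief).
#'
#' @param log a [temperature_log()].
#' @param frame_times seconds on the log's clock (or close enough that the
#'   offset is negligible relative to the ramp rate).
#' @return Degrees C per frame.
#' @export
interpolate_temperature <- function(log, frame_times) {
  stopifnot(inherits(log, "temperature_log"))
  approx(log$time_s, log$temp_C, xout = frame_times, rule = 2)$y
}

#' Bin a dF/F0 trace by probe temperature
#'
#' Bins are `[k, k + bin_width)` degrees C anchored at integer multiples of
#' `bin_width` and labelled by the anchor `k`; each bin's value is the mean
#' dF/F0 over frames whose temperature falls in it. Empty bins are missing
#' (absent rows), never zero.
#'
#' @param dff percent dF/F0 per frame.
#' @param temps degrees C per frame.
#' @param bin_width bin width in degrees C (default 1).
#' @param animal_id,group labels carried into the result.
#' @return A `binned_response` data.frame with columns `bin_temp`,
#'   `mean_dff`, `n_frames`, `animal_id`, `group`.
#' @export
bin_by_temperature <- function(dff, temps, bin_width = 1,
                               animal_id = NA, group = NA) {
  stopifnot(length(dff) == length(temps), bin_width > 0)
  k <- floor(temps / bin_width) * bin_width
  mean_dff <- tapply(dff, k, mean)
  n_frames <- tapply(dff, k, length)
  out <- data.frame(bin_temp = as.numeric(names(mean_dff)),
                    mean_dff = as.numeric(mean_dff),
                    n_frames = as.integer(n_frames),
                    animal_id = animal_id, group = group)
  out <- out[order(out$bin_temp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binned_response", "data.frame"))
}

#' Full per-animal calcium analysis
#'
#' [roi_trace()] then [dff()] then [interpolate_temperature()] then
#' [bin_by_temperature()].
#'
#' @param recording a [calcium_recording()].
#' @param n_baseline baseline frames for F0.
#' @param bin_width degrees C per bin.
#' @param animal_id,group labels.
#' @return A [bin_by_temperature()] result.
#' @export
analyze_recording <- function(recording, n_baseline = 30L, bin_width = 1,
                              animal_id = NA, group = NA) {
  f <- roi_trace(recording)
  d <- dff(f, n_baseline)
  temps <- interpolate_temperature(recording$log, recording$frame_times)
  bin_by_temperature(d$dff, temps, bin_width,
                     animal_id = animal_id, group = group)
}

#' Per-bin group comparison of binned responses
#'
#' For each temperature bin, compares the per-animal mean dF/F0 values of
#' two groups with a two-sided Mann-Whitney U test ([mann_whitney_u()]);
#' animals missing a bin are excluded for that bin, and bins with fewer
#' than 2 animals per group are flagged untestable. `adjust = "bonferroni"`
#' controls the familywise error across the tested bins, which is the
#' appropriate form for claims about where a response differs.
#'
#' @param groupA,groupB lists of [bin_by_temperature()] results (one per
#'   animal).
#' @param adjust `"none"` (per-bin p, as figures typically annotate) or
#'   `"bonferroni"`.
#' @return Data.frame with `bin_temp`, `n_a`, `n_b`, `statistic`,
#'   `p_value`, `p_adjusted`, `testable`.
#' @export
compare_binned_groups <- function(groupA, groupB,
                                  adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  pull <- function(group, bin) {
    v <- vapply(group, function(b) {
      hit <- b$bin_temp == bin
      if (any(hit)) b$mean_dff[hit][1L] else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  }
  bins <- sort(unique(unlist(lapply(c(groupA, groupB), `[[`, "bin_temp"))))
  rows <- lapply(bins, function(bin) {
    a <- pull(groupA, bin); b <- pull(groupB, bin)
    if (length(a) >= 2L && length(b) >= 2L) {
      r <- mann_whitney_u(a, b)
      data.frame(bin_temp = bin, n_a = length(a), n_b = length(b),
                 statistic = r$statistic, p_value = r$p_value,
                 testable = TRUE)
    } else {
      data.frame(bin_temp = bin, n_a = length(a), n_b = length(b),
                 statistic = NA_real_, p_value = NA_real_, testable = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  m <- sum(out$testable)
  out$p_adjusted <- if (adjust == "bonferroni") {
    ifelse(out$testable, pmin(1, out$p_value * m), NA_real_)
  } else {
    out$p_value
  }
  out
}

#' Group-mean binned response curve
#'
#' Mean and standard error of per-animal binned dF/F0 at each bin (animals
#' missing a bin are excluded there).
#'
#' @param group list of [bin_by_temperature()] results.
#' @return Data.frame with `bin_temp`, `mean_dff`, `se`, `n_animals`.
#' @export
group_binned_mean <- function(group) {
  df <- do.call(rbind, lapply(group, function(b) {
    data.frame(bin_temp = b$bin_temp, mean_dff = b$mean_dff)
  }))
  agg_m <- tapply(df$mean_dff, df$bin_temp, mean)
  agg_s <- tapply(df$mean_dff, df$bin_temp, function(v) {
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  })
  agg_n <- tapply(df$mean_dff, df$bin_temp, length)
  out <- data.frame(bin_temp = as.numeric(names(agg_m)),
                    mean_dff = as.numeric(agg_m), se = as.numeric(agg_s),
                    n_animals = as.integer(agg_n))
  out[order(out$bin_temp), , drop = FALSE]
}

#' Plot group-mean binned response curves
#'
#' Mean plus/minus SE dF/F0 versus binned probe temperature, one curve per
#' group.
#'
#' @param groups named list of group lists (each a list of
#'   [bin_by_temperature()] results).
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics plot lines arrows legend
#' @export
plot_binned_response <- function(groups, ...) {
  curves <- lapply(groups, group_binned_mean)
  xr <- range(unlist(lapply(curves, `[[`, "bin_temp")))
  yr <- range(unlist(lapply(curves, function(cv) {
    c(cv$mean_dff - cv$se, cv$mean_dff + cv$se, cv$mean_dff)
  })), na.rm = TRUE)
  plot(NA, xlim = xr, ylim = yr, xlab = "probe temperature (binned, deg C)",
       ylab = expression(Delta * F / F[0] ~ "(%)"), ...)
  cols <- seq_along(curves)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    lines(cv$bin_temp, cv$mean_dff, col = cols[i], type = "b", pch = 16)
    ok <- !is.na(cv$se) & cv$se > 0
    if (any(ok)) {
      arrows(cv$bin_temp[ok], cv$mean_dff[ok] - cv$se[ok],
             cv$bin_temp[ok], cv$mean_dff[ok] + cv$se[ok],
             angle = 90, code = 3, length = 0.02, col = cols[i])
    }
  }
  legend("topleft", legend = names(curves), col = cols, lty = 1, pch = 16,
         bty = "n")
  invisible(curves)
}
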