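#' Maximum intensity projection
#'
#' Collapses the z axis of every channel by the pixelwise maximum, the
#' standard reduction applied to confocal Z-stacks before quantification.
#' A 2D stack is returned unchanged.
#'
#' @param stack an [image_stack()].
#' @return An [image_stack()] whose channels are `(y, x)` matrices.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  if (length(d) == 2L) return(stack)
  if (d[1L] < 1L) stop_format("empty stack")
  channels <- lapply(stack$channels, function(arr) {
    nz <- dim(arr)[1L]
    m <- matrix(arr, nrow = nz)
    proj <- do.call(pmax, lapply(seq_len(nz), function(z) m[z, ]))
    matrix(proj, dim(arr)[2L], dim(arr)[3L])
  })
  image_stack(channels, bit_depth = stack$bit_depth,
              pixel_size = stack$pixel_size)
}

#' Nucleus region of interest
#'
#' @param mask logical `(y, x)` matrix delineating the nucleus.
#' @return A `nucleus_roi` with the mask, its centroid (0-based `(y, x)`)
#'   and pixel area.
#' @export
nucleus_roi <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop_format("nucleus mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  structure(
    list(mask = mask,
         centroid = c(mean(idx[, 1L]) - 1, mean(idx[, 2L]) - 1),
         area_px = nrow(idx)),
    class = "nucleus_roi"
  )
}

#' Segment the GFP-negative nucleus of a labelled soma
#'
#' Nociceptor nuclei are located as the GFP-negative hole enclosed by
#' cytoplasmic GFP: the GFP projection is Otsu-thresholded, background
#' pixels are labelled into connected components, and the component that is
#' fully enclosed by GFP foreground (not touching the image border) is
#' returned — the largest such component, or the one containing
#' `seed_point`. Supplying `mask` bypasses segmentation entirely and wraps
#' the manual ROI verbatim, which is the mode recovery analyses use to
#' decouple segmentation error from quantification error.
#'
#' @param gfp_projection `(y, x)` matrix (GFP channel of a max projection).
#' @param seed_point optional 0-based `(y, x)` hint inside the nucleus.
#' @param mask optional logical matrix: manual-ROI mode, returned verbatim.
#' @return A [nucleus_roi()].
#' @export
segment_nucleus <- function(gfp_projection, seed_point = NULL, mask = NULL) {
  if (!is.null(mask)) return(nucleus_roi(mask))
  stopifnot(is.matrix(gfp_projection))
  if (length(unique(as.vector(gfp_projection))) < 2L) {
    stop_segmentation("uniform GFP image: supply a manual mask")
  }
  t <- otsu_threshold(gfp_projection)
  fg <- gfp_projection > t
  labels <- EBImage::bwlabel(!fg)
  n_lab <- max(labels)
  if (n_lab < 1L) {
    stop_segmentation("no GFP-negative region found: supply a manual mask")
  }
  border_labels <- unique(c(labels[1L, ], labels[nrow(labels), ],
                            labels[, 1L], labels[, ncol(labels)]))
  enclosed <- setdiff(seq_len(n_lab), border_labels)
  if (length(enclosed) == 0L) {
    stop_segmentation("no enclosed GFP-negative hole found: ",
                      "supply a manual mask")
  }
  pick <- if (!is.null(seed_point)) {
    lab <- labels[round(seed_point[1L]) + 1L, round(seed_point[2L]) + 1L]
    if (!lab %in% enclosed) {
      stop_segmentation("seed_point is not inside an enclosed hole")
    }
    lab
  } else {
    sizes <- tabulate(labels[labels > 0L], nbins = n_lab)
    enclosed[which.max(sizes[enclosed])]
  }
  nucleus_roi(labels == pick)
}

# Translate a mask so its bounding box abuts the given corner at margin_px.
.corner_mask <- function(mask, corner, margin_px) {
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  y0 <- min(idx[, 1L]); y1 <- max(idx[, 1L])
  x0 <- min(idx[, 2L]); x1 <- max(idx[, 2L])
  h <- y1 - y0 + 1L; w <- x1 - x0 + 1L
  ty <- switch(corner, tl = , tr = margin_px + 1L - y0,
               bl = , br = ny - margin_px - y1)
  tx <- switch(corner, tl = , bl = margin_px + 1L - x0,
               tr = , br = nx - margin_px - x1)
  out <- matrix(FALSE, ny, nx)
  out[cbind(idx[, 1L] + ty, idx[, 2L] + tx)] <- TRUE
  out
}

#' Four-corner background estimate
#'
#' Estimates the image background as the mean of four corner-ROI means,
#' each corner ROI being the nucleus mask translated (shape and size
#' preserved) so its bounding box sits `margin_px` pixels from that corner.
#'
#' @param projection `(y, x)` intensity matrix.
#' @param roi a [nucleus_roi()].
#' @param margin_px pixels between each corner and the translated ROI's
#'   bounding box (default 2).
#' @return Scalar background intensity.
#' @export
corner_background <- function(projection, roi, margin_px = 2L) {
  stopifnot(is.matrix(projection), inherits(roi, "nucleus_roi"))
  ny <- nrow(projection); nx <- ncol(projection)
  idx <- which(roi$mask, arr.ind = TRUE)
  h <- diff(range(idx[, 1L])) + 1L
  w <- diff(range(idx[, 2L])) + 1L
  if (h > ny %/% 2L || w > nx %/% 2L) {
    stop_geometry("ROI bounding box exceeds half the image; corner ROIs ",
                  "would overlap")
  }
  if (h + margin_px > ny || w + margin_px > nx) {
    stop_geometry("ROI does not fit in a corner at this margin")
  }
  corners <- c("tl", "tr", "bl", "br")
  means <- vapply(corners, function(cn) {
    mean(projection[.corner_mask(roi$mask, cn, as.integer(margin_px))])
  }, numeric(1))
  mean(means)
}

#' Per-neuron nuclear pMad measurement
#'
#' Computes the mean pMad intensity over the nucleus ROI and subtracts the
#' four-corner background estimate. The corrected value may be negative and
#' is recorded as-is.
#'
#' @param projection `(y, x)` pMad intensity matrix (max projection).
#' @param roi a [nucleus_roi()].
#' @param margin_px corner margin, see [corner_background()].
#' @param specimen_id,batch_id identifiers carried into the result
#'   (`batch_id` names the co-processed staining batch).
#' @return A one-row data.frame of class `pmad_measurement` with columns
#'   `specimen_id`, `batch_id`, `raw_nuclear_mean`, `background_mean`,
#'   `corrected`.
#' @export
nuclear_pmad <- function(projection, roi, margin_px = 2L,
                         specimen_id = NA_character_,
                         batch_id = NA_character_) {
  stopifnot(is.matrix(projection), inherits(roi, "nucleus_roi"))
  raw <- mean(projection[roi$mask])
  bg <- corner_background(projection, roi, margin_px)
  structure(
    data.frame(specimen_id = as.character(specimen_id),
               batch_id = as.character(batch_id),
               raw_nuclear_mean = raw, background_mean = bg,
               corrected = raw - bg),
    class = c("pmad_measurement", "data.frame")
  )
}

#' Normalize pMad measurements to co-processed controls
#'
#' Expresses an experimental group's mean corrected nuclear pMad as a
#' percent change relative to the mean of control specimens processed
#' side-by-side in the same staining solutions (same `batch_id`).
#'
#' @param experimental,control data.frames of [nuclear_pmad()] rows (or any
#'   data.frame with `corrected` and `batch_id` columns).
#' @return A one-row data.frame with `percent_change`, `n_experimental`,
#'   `n_control`, `batch_id`.
#' @export
normalize_to_control <- function(experimental, control) {
  stopifnot(nrow(experimental) >= 1L, nrow(control) >= 1L)
  batches <- unique(c(experimental$batch_id, control$batch_id))
  if (length(batches) != 1L) {
    stop_validation("experimental and control must share one batch_id ",
                    "(co-processed specimens); got: ",
                    paste(batches, collapse = ", "))
  }
  mc <- mean(control$corrected)
  if (!is.finite(mc) || mc <= 0) {
    stop_validation("control mean corrected signal must be > 0 for ",
                    "normalization")
  }
  me <- mean(experimental$corrected)
  data.frame(percent_change = 100 * (me - mc) / mc,
             n_experimental = nrow(experimental),
             n_control = nrow(control),
             batch_id = batches)
}

#' Average neurons within animals
#'
#' The imaging design measures three ddaC neurons (segments A4-A6) per
#' animal; averaging within an animal before group statistics avoids
#' pseudo-replication. With `unit = "neuron"`, rows pass through unchanged
#' (matching per-neuron n as printed in figure legends).
#'
#' @param measurements data.frame of [nuclear_pmad()] rows with an
#'   `animal_id` column.
#' @param unit `"animal"` (default: average neurons within `animal_id`) or
#'   `"neuron"`.
#' @return A data.frame with one row per statistical unit.
#' @export
aggregate_by_animal <- function(measurements, unit = c("animal", "neuron")) {
  unit <- match.arg(unit)
  if (unit == "neuron") return(measurements)
  if (!"animal_id" %in% names(measurements)) {
    stop_format("unit = 'animal' requires an animal_id column")
  }
  agg <- aggregate(corrected ~ animal_id + batch_id, data = measurements,
                   FUN = mean)
  agg
}
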