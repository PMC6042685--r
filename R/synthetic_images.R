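#' @title Synthetic microscopy ground truth
#' @description Helpers building elliptical masks on a pixel grid.
#' @param ny,nx image height/width in pixels.
#' @param cy,cx ellipse center (0-based pixel coordinates, y downward).
#' @param ry,rx ellipse semi-axes in pixels.
#' @return Logical `(ny, nx)` matrix, `TRUE` inside the ellipse.
#' @export
ellipse_mask <- function(ny, nx, cy, cx, ry, rx) {
  yy <- matrix(seq_len(ny) - 1L, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Ground truth for a synthetic nociceptor soma image
#'
#' Describes a cell body expressing a membrane GFP marker with a GFP-negative
#' nucleus, over a sloped additive background, as imaged for nuclear pMad
#' quantification. Geometry defaults place an elliptical cytoplasm centered
#' in the frame with an interior elliptical nucleus, leaving the image
#' corners as pure background so the four-corner background estimator is
#' well-posed, and a linear background gradient whose four-corner mean
#' equals its value at the (centered) nucleus.
#'
#' @param ny,nx image size in pixels.
#' @param nucleus_mean true mean nuclear pMad intensity (above background).
#' @param cytoplasm_mean true mean cytoplasmic pMad intensity.
#' @param gfp_level cytoplasmic GFP intensity.
#' @param background baseline additive background intensity.
#' @param gradient peak-to-trough amplitude of a linear background ramp
#'   along x (0 for a flat field).
#' @param noise_sd per-pixel Gaussian noise SD (per z-slice).
#' @param nz number of z-slices (structure constant across z, noise i.i.d.).
#' @param bit_depth 8 or 16.
#' @return A `soma_truth` list with masks, the background field, and the
#'   programmed intensities.
#' @export
soma_truth <- function(ny = 96L, nx = 96L,
                       nucleus_mean = 1000, cytoplasm_mean = 400,
                       gfp_level = 5000, background = 200, gradient = 100,
                       noise_sd = 50, nz = 3L, bit_depth = 16L) {
  stopifnot(nucleus_mean >= 0, cytoplasm_mean >= 0, noise_sd >= 0)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  cell <- ellipse_mask(ny, nx, cy, cx, ry = ny * 0.28, rx = nx * 0.28)
  nucleus <- ellipse_mask(ny, nx, cy, cx, ry = ny * 0.13, rx = nx * 0.13)
  cytoplasm <- cell & !nucleus
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  background_field <- background + gradient * xx / max(nx - 1, 1)
  structure(
    list(nucleus_mask = nucleus, cytoplasm_mask = cytoplasm,
         true_nuclear_mean = nucleus_mean,
         true_cytoplasmic_mean = cytoplasm_mean,
         gfp_level = gfp_level, background_field = background_field,
         noise_sd = noise_sd, nz = as.integer(nz),
         bit_depth = as.integer(bit_depth)),
    class = "soma_truth"
  )
}

.clip_intensity <- function(x, bit_depth) {
  ceiling_val <- 2^bit_depth - 1
  n_clip <- sum(x < 0 | x > ceiling_val)
  pmin(pmax(x, 0), ceiling_val)
}

# Expand a 2D mean image into a (nz, ny, nx) stack with i.i.d. Gaussian
# noise per slice, clipped to the bit-depth range.
.noisy_stack <- function(mean2d, nz, noise_sd, bit_depth) {
  ny <- nrow(mean2d); nx <- ncol(mean2d)
  arr <- array(rep(as.numeric(mean2d), times = nz), dim = c(ny, nx, nz))
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
  # detectors record integer counts; rounding also keeps TIFF round trips
  # bit-exact
  arr <- round(.clip_intensity(arr, bit_depth))
  aperm(arr, c(3L, 1L, 2L))
}

#' Generate a synthetic soma image for pMad quantification
#'
#' The GFP channel is bright on the cytoplasm and ~0 in the nucleus (the
#' GFP-negative hole used to locate nociceptor nuclei) and outside the cell;
#' the pMad channel is the programmed nuclear/cytoplasmic means plus the
#' additive background field, with i.i.d. Gaussian noise per z-slice clipped
#' to the bit-depth range. Deterministic given `(truth, seed)`.
#'
#' @param truth a [soma_truth()].
#' @param seed integer seed.
#' @return A list with elements `stack` (an [image_stack()] with channels
#'   `"GFP"` and `"pMad"`) and `truth` (the input truth, with a
#'   `clipped_fraction` field reporting pixels clipped at the bit ceiling).
#' @export
generate_soma_image <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "soma_truth"))
  ceiling_val <- 2^truth$bit_depth - 1
  pmad_mean <- truth$background_field +
    truth$true_nuclear_mean * truth$nucleus_mask +
    truth$true_cytoplasmic_mean * truth$cytoplasm_mask
  if (max(pmad_mean) > ceiling_val) {
    warning("programmed pMad means exceed the bit-depth ceiling; clipping")
  }
  gfp_mean <- truth$gfp_level * truth$cytoplasm_mask
  with_seed(seed, {
    gfp <- .noisy_stack(gfp_mean, truth$nz, truth$noise_sd, truth$bit_depth)
    pmad <- .noisy_stack(pmad_mean, truth$nz, truth$noise_sd, truth$bit_depth)
  })
  truth$clipped_fraction <- mean(pmad_mean > ceiling_val)
  list(stack = image_stack(list(GFP = gfp, pMad = pmad),
                           bit_depth = truth$bit_depth),
       truth = truth)
}

#' Ground truth for a synthetic flip-out clone image
#'
#' Emulates a ventral-nerve-cord field of view: the CD2 channel labels the
#' whole neuropil (a ladder of `n_neuromeres` segmental blocks), the GFP
#' channel labels a single nociceptor clone's axon terminal arbor occupying
#' a known subset of the neuropil. Pixel counts of both masks are exact, so
#' the normalized terminal area (GFP pixels per average neuromere) is known
#' in closed form.
#'
#' @param ny,nx image size in pixels.
#' @param n_neuromeres number of segmental units covered by the neuropil.
#' @param entry_index neuromere (0-based) where the clone's axon enters.
#' @param clone_span number of neuromeres the arbor spans from the entry.
#' @param fg_level,bg_level foreground/background mean intensities for both
#'   channels (must be separable for Otsu binarization).
#' @param noise_sd per-pixel Gaussian noise SD.
#' @param nz z-slices.
#' @param bit_depth 8 or 16.
#' @return A `clone_truth` list; `separability_warning` is `TRUE` when the
#'   foreground/background contrast falls below 4 noise SDs.
#' @export
clone_truth <- function(ny = 120L, nx = 60L, n_neuromeres = 8L,
                        entry_index = 2L, clone_span = 3L,
                        fg_level = 5000, bg_level = 400, noise_sd = 100,
                        nz = 3L, bit_depth = 16L) {
  stopifnot(n_neuromeres >= 1L, entry_index >= 0L,
            entry_index < n_neuromeres, clone_span >= 1L)
  margin_y <- max(4L, round(ny * 0.05))
  margin_x <- max(4L, round(nx * 0.2))
  neuromere_h <- (ny - 2L * margin_y) %/% n_neuromeres
  neuropil <- matrix(FALSE, ny, nx)
  neuropil[(margin_y + 1L):(margin_y + neuromere_h * n_neuromeres),
           (margin_x + 1L):(nx - margin_x)] <- TRUE
  span_end <- min(entry_index + clone_span, n_neuromeres)
  y0 <- margin_y + entry_index * neuromere_h + 1L
  y1 <- margin_y + span_end * neuromere_h
  # clone occupies the medial half-width of the neuropil over its span
  x_mid <- (margin_x + 1L + nx - margin_x) %/% 2L
  clone <- matrix(FALSE, ny, nx)
  clone[y0:y1, (margin_x + 1L):x_mid] <- TRUE
  clone <- clone & neuropil
  structure(
    list(clone_mask = clone, neuropil_mask = neuropil,
         n_neuromeres = as.integer(n_neuromeres),
         entry_index = as.integer(entry_index),
         fg_level = fg_level, bg_level = bg_level, noise_sd = noise_sd,
         nz = as.integer(nz), bit_depth = as.integer(bit_depth),
         separability_warning = (fg_level - bg_level) < 4 * noise_sd),
    class = "clone_truth"
  )
}

#' Generate a synthetic two-channel clone/neuropil image
#'
#' GFP is bright on the clone arbor, CD2 bright on the whole neuropil, both
#' over a noisy background, giving each channel the bimodal intensity
#' histogram Otsu thresholding expects. Deterministic given `(truth, seed)`.
#'
#' @param truth a [clone_truth()].
#' @param seed integer seed.
#' @return List with `stack` (channels `"GFP"`, `"CD2"`) and `truth`.
#' @export
generate_clone_image <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "clone_truth"))
  if (truth$separability_warning) {
    warning("foreground/background contrast below the separability floor")
  }
  gfp_mean <- truth$bg_level +
    (truth$fg_level - truth$bg_level) * truth$clone_mask
  cd2_mean <- truth$bg_level +
    (truth$fg_level - truth$bg_level) * truth$neuropil_mask
  with_seed(seed, {
    gfp <- .noisy_stack(gfp_mean, truth$nz, truth$noise_sd, truth$bit_depth)
    cd2 <- .noisy_stack(cd2_mean, truth$nz, truth$noise_sd, truth$bit_depth)
  })
  list(stack = image_stack(list(GFP = gfp, CD2 = cd2),
                           bit_depth = truth$bit_depth),
       truth = truth)
}
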