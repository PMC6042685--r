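#' Otsu threshold of an intensity image
#'
#' Classic histogram thresholding: over a 256-bin intensity histogram
#' (16-bit data are rescaled into 256 bins, which keeps sparse 16-bit
#' histograms stable), returns the threshold maximizing the between-class
#' variance. Foreground is defined as strictly greater than the returned
#' threshold; ties are broken toward the smallest threshold.
#'
#' @param image_channel numeric matrix or array of intensities.
#' @param bit_depth 8 or 16; inferred from the intensity range if `NULL`.
#' @return Threshold in intensity units (the top intensity of the last
#'   background bin), with attribute `"bin"` giving the 0-based bin index.
#' @export
otsu_threshold <- function(image_channel, bit_depth = NULL) {
  v <- as.vector(image_channel)
  if (anyNA(v)) stop_format("image contains NA")
  if (is.null(bit_depth)) bit_depth <- if (max(v) > 255) 16L else 8L
  step <- 2^(as.integer(bit_depth) - 8L)
  bins <- pmin(v %/% step, 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    stop(errorCondition(
      "image not binarizable: fewer than 2 occupied histogram bins",
      class = c("nociquant_otsu_error", "nociquant_error")))
  }
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * levels)
  mu_t <- mu[256L]
  mu0 <- mu[1:255]
  # between-class variance for thresholds t = 0..254 (class0 = bins <= t)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, 255L)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_bin <- which.max(bcv) - 1L
  t_int <- (t_bin + 1L) * step - 1
  structure(t_int, bin = t_bin)
}

#' Upper-decile mean intensity
#'
#' The matching statistic used for linear enhancement: the mean of pixels at
#' or above the 90th intensity percentile.
#'
#' @param image_channel numeric matrix or array.
#' @return Scalar intensity.
#' @export
upper_decile_mean <- function(image_channel) {
  v <- as.vector(image_channel)
  q <- quantile(v, 0.9, names = FALSE)
  mean(v[v >= q])
}

#' Linearly enhance a channel to match reference statistics
#'
#' Applies a pure gain (offset 0) so the source's upper-decile mean equals
#' the reference's — the compensation applied when marker expression is too
#' low to binarize on the same footing as controls. A pure gain is monotone,
#' so relative pixel ordering is preserved.
#'
#' @param image_channel numeric matrix or array.
#' @param reference_stats scalar target upper-decile mean (as from
#'   [upper_decile_mean()] of a control image).
#' @return The enhanced channel with attribute `"gain"`.
#' @export
match_enhance <- function(image_channel, reference_stats) {
  src <- upper_decile_mean(image_channel)
  if (!is.finite(src) || src <= 0) {
    stop(errorCondition(
      "zero-intensity source: not enhanceable",
      class = c("nociquant_enhance_error", "nociquant_error")))
  }
  g <- as.numeric(reference_stats) / src
  structure(image_channel * g, gain = g)
}

#' Neuromere-normalized terminal area of a flip-out clone
#'
#' Max-projects the clone stack, Otsu-binarizes the GFP (clone arbor) and
#' CD2 (neuropil) channels independently, counts foreground pixels, and
#' normalizes the GFP count to the average size of a single neuromere
#' (CD2 pixels divided by the neuromere count). Clones whose signal cannot
#' be binarized (even after optional linear enhancement) are marked
#' excluded rather than quantified.
#'
#' @param clone an [image_stack()] with `"GFP"` and `"CD2"` channels.
#' @param n_neuromeres number of neuromeres in the (cropped) field.
#' @param enhance_ref optional list with elements `GFP` and `CD2` giving
#'   reference upper-decile means for [match_enhance()].
#' @param clone_id identifier carried into the result.
#' @return One-row data.frame with `clone_id`, `gfp_pixels`, `cd2_pixels`,
#'   `n_neuromeres`, `normalized_area`, `gfp_threshold`, `cd2_threshold`,
#'   `excluded`, `exclusion_reason`.
#' @export
terminal_area <- function(clone, n_neuromeres, enhance_ref = NULL,
                          clone_id = NA_character_) {
  stopifnot(inherits(clone, "image_stack"), n_neuromeres >= 1L)
  missing <- setdiff(c("GFP", "CD2"), channel_names(clone))
  if (length(missing)) {
    stop_format("missing channel(s): ", paste(missing, collapse = ", "))
  }
  proj <- max_project(clone)
  res <- data.frame(clone_id = as.character(clone_id),
                    gfp_pixels = NA_integer_, cd2_pixels = NA_integer_,
                    n_neuromeres = as.integer(n_neuromeres),
                    normalized_area = NA_real_,
                    gfp_threshold = NA_real_, cd2_threshold = NA_real_,
                    excluded = FALSE, exclusion_reason = NA_character_)
  counts <- list()
  for (ch in c("GFP", "CD2")) {
    img <- get_channel(proj, ch)
    if (!is.null(enhance_ref)) {
      img <- tryCatch(match_enhance(img, enhance_ref[[ch]]),
                      nociquant_enhance_error = function(e) NULL)
      if (is.null(img)) {
        res$excluded <- TRUE
        res$exclusion_reason <- paste0(ch, " not enhanceable")
        return(res)
      }
    }
    if (ch == "GFP" && all(img == 0)) {
      # an empty clone channel is a valid measurement of zero area
      counts[[ch]] <- 0L
      next
    }
    t <- tryCatch(otsu_threshold(img, bit_depth = clone$bit_depth),
                  nociquant_otsu_error = function(e) NULL)
    if (is.null(t)) {
      res$excluded <- TRUE
      res$exclusion_reason <- paste0(
        ch, " signal too low to be binarized by Otsu's method")
      return(res)
    }
    counts[[ch]] <- sum(img > t)
    res[[paste0(tolower(ch), "_threshold")]] <- as.numeric(t)
  }
  res$gfp_pixels <- counts$GFP
  res$cd2_pixels <- counts$CD2
  if (counts$CD2 == 0L) {
    res$excluded <- TRUE
    res$exclusion_reason <- "no CD2 foreground (neuromere size undefined)"
    return(res)
  }
  res$normalized_area <- counts$GFP / (counts$CD2 / n_neuromeres)
  res
}

#' Per-clone axonal projection profile
#'
#' Wraps the manual presence/absence annotation of terminal branches per
#' neuromere and longitudinal tract.
#'
#' @param presence logical matrix; rownames are neuromere indices
#'   (integers), columns are tract labels.
#' @param entry_index neuromere index where the axon enters the CNS.
#' @param clone_id identifier.
#' @return A `projection_profile`.
#' @export
projection_profile <- function(presence, entry_index, clone_id = NA) {
  stopifnot(is.matrix(presence), is.logical(presence))
  if (is.null(rownames(presence))) {
    stop_format("presence rownames must give neuromere indices")
  }
  neuromeres <- as.integer(rownames(presence))
  if (anyNA(neuromeres)) stop_format("non-integer neuromere rownames")
  if (!entry_index %in% neuromeres ||
      !any(presence[as.character(entry_index), ])) {
    stop_validation("presence must be TRUE somewhere at the entry neuromere")
  }
  structure(list(presence = presence, entry_index = as.integer(entry_index),
                 clone_id = clone_id),
            class = "projection_profile")
}

#' Align projection profiles on their entry neuromere
#'
#' Re-indexes each clone's presence annotation by the offset from its entry
#' neuromere (offset 0 = entry), so clones entering at different segments
#' become comparable; offsets a clone does not cover are padded absent.
#'
#' @param profiles list of [projection_profile()] objects.
#' @return An `aligned_profiles` list: `presence` is a logical
#'   `(clone, offset, tract)` array, plus `offsets`, `tracts`, `clone_ids`.
#' @export
align_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  stopifnot(all(vapply(profiles, inherits, logical(1), "projection_profile")))
  offs <- lapply(profiles, function(p) {
    as.integer(rownames(p$presence)) - p$entry_index
  })
  offsets <- seq(min(unlist(offs)), max(unlist(offs)))
  tracts <- unique(unlist(lapply(profiles, function(p) colnames(p$presence))))
  arr <- array(FALSE,
               dim = c(length(profiles), length(offsets), length(tracts)),
               dimnames = list(NULL, as.character(offsets), tracts))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    arr[i, as.character(offs[[i]]), colnames(p$presence)] <- p$presence
  }
  structure(list(presence = arr, offsets = offsets, tracts = tracts,
                 clone_ids = lapply(profiles, `[[`, "clone_id")),
            class = "aligned_profiles")
}

#' Projection heat map
#'
#' For each (relative neuromere offset, longitudinal tract) position, the
#' percentage of aligned clones with a terminal branch there.
#'
#' @param aligned an [align_profiles()] result.
#' @return A `projection_heatmap`: `percent` matrix (offset x tract) and
#'   `n_clones`.
#' @export
projection_heatmap <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_profiles"))
  n <- dim(aligned$presence)[1L]
  percent <- 100 * apply(aligned$presence, c(2L, 3L), mean)
  structure(list(percent = percent, n_clones = n), class = "projection_heatmap")
}

#' Render a projection heat map
#'
#' @param x a [projection_heatmap()].
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image axis box title
#' @importFrom grDevices colorRampPalette
#' @export
plot.projection_heatmap <- function(x, ...) {
  pct <- x$percent
  pal <- colorRampPalette(c("white", "gold", "red"))(100)
  image(x = seq_len(ncol(pct)), y = seq_len(nrow(pct)),
        z = t(pct)[, rev(seq_len(nrow(pct))), drop = FALSE],
        col = pal, zlim = c(0, 100), axes = FALSE,
        xlab = "longitudinal tract", ylab = "neuromere offset from entry",
        ...)
  axis(1, at = seq_len(ncol(pct)), labels = colnames(pct))
  axis(2, at = seq_len(nrow(pct)), labels = rev(rownames(pct)), las = 1)
  box()
  title(main = sprintf("axonal projection (%% of %d clones)", x$n_clones))
  invisible(x)
}
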