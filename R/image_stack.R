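#' Multi-channel intensity image stack
#'
#' The container consumed by every imaging pipeline in the package. Pixels
#' are stored per channel as arrays indexed `(z, y, x)` (or matrices `(y, x)`
#' for single-plane images), 0-based coordinates in all user-facing
#' geometry, with `y` increasing downward. Intensities are integer-valued
#' and bounded by the declared bit depth.
#'
#' @param channels named list of numeric arrays, one per channel, all with
#'   identical dimensions; either `(y, x)` matrices or `(z, y, x)` arrays.
#' @param bit_depth integer, 8 or 16.
#' @param pixel_size microns per pixel, or `NA` if unknown.
#' @return An object of class `image_stack`.
#' @examples
#' px <- matrix(0:15, 4, 4)
#' stk <- image_stack(list(GFP = px), bit_depth = 8)
#' dim(stk)
#' @export
image_stack <- function(channels, bit_depth = 16L, pixel_size = NA_real_) {
  if (!is.list(channels) || length(channels) < 1L) {
    stop_format("an image stack needs at least one channel")
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop_format("every channel must be named")
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop_format("bit_depth must be 8 or 16")
  }
  dims <- lapply(channels, function(ch) dim(as.array(ch)))
  if (length(unique(lapply(dims, identity))) != 1L) {
    stop_format("all channels must share identical dimensions")
  }
  nd <- length(dims[[1L]])
  if (!nd %in% c(2L, 3L)) {
    stop_format("channels must be (y, x) or (z, y, x) arrays")
  }
  ceiling_val <- 2^bit_depth - 1
  channels <- lapply(channels, function(ch) {
    ch <- as.array(ch)
    if (anyNA(ch)) stop_format("pixel intensities must not be NA")
    if (min(ch) < 0 || max(ch) > ceiling_val) {
      stop_format("intensities must lie within [0, 2^bit_depth - 1]")
    }
    ch
  })
  structure(
    list(channels = channels, bit_depth = bit_depth,
         pixel_size = pixel_size),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

#' Channel labels of an image stack
#' @param stack an [image_stack()].
#' @return Character vector of channel names.
#' @export
channel_names <- function(stack) names(stack$channels)

#' Extract one channel's pixel array
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @return The pixel array for that channel.
#' @export
get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels)) {
    stop_format("channel '", channel, "' not present (have: ",
                paste(names(stack$channels), collapse = ", "), ")")
  }
  stack$channels[[channel]]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  geom <- if (length(d) == 3L) {
    sprintf("%d z-slices of %d x %d (y x x)", d[1L], d[2L], d[3L])
  } else {
    sprintf("%d x %d (y x x)", d[1L], d[2L])
  }
  cat(sprintf("<image_stack> %s, %d-bit, channels: %s\n",
              geom, x$bit_depth, paste(channel_names(x), collapse = ", ")))
  invisible(x)
}

# tiff stores a page as (y, x); our z-stacks are (z, y, x).
.slice_list <- function(arr) {
  if (length(dim(arr)) == 2L) return(list(arr))
  lapply(seq_len(dim(arr)[1L]), function(z) arr[z, , ])
}

.stack_slices <- function(pages) {
  if (length(pages) == 1L) return(pages[[1L]])
  out <- array(0, dim = c(length(pages), dim(pages[[1L]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  out
}

#' Save an image stack to disk
#'
#' Writes one single-sample multi-page TIFF per channel (pages are z-slices)
#' plus a YAML manifest binding the channels together. This dialect
#' round-trips 8- and 16-bit data bit-exactly through [load_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path path of the manifest to write; must end in `.yaml`/`.yml`.
#'   Channel TIFFs are written next to it as `<stem>_<channel>.tif`.
#' @return `path`, invisibly.
#' @export
save_image_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop_format("not an image_stack")
  if (!grepl("\\.ya?ml$", path)) {
    stop_format("save path must be a .yaml manifest")
  }
  stem <- sub("\\.ya?ml$", "", path)
  scale <- 2^stack$bit_depth - 1
  files <- character(0)
  for (ch in channel_names(stack)) {
    f <- paste0(stem, "_", gsub("[^A-Za-z0-9]", "_", ch), ".tif")
    pages <- lapply(.slice_list(get_channel(stack, ch)), function(p) p / scale)
    tiff::writeTIFF(pages, f, bits.per.sample = stack$bit_depth)
    files <- c(files, basename(f))
  }
  manifest <- list(
    channels = as.list(setNames(files, channel_names(stack))),
    bit_depth = stack$bit_depth,
    pixel_size = if (is.na(stack$pixel_size)) NULL else stack$pixel_size
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.read_channel_tiff <- function(file, bit_depth) {
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(file, all = TRUE, as.is = TRUE)),
    error = function(e) stop_io("cannot read TIFF '", file, "': ",
                                conditionMessage(e))
  )
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      stop_format("per-channel TIFF pages must be single-sample")
    }
    storage.mode(p) <- "double"
    p
  })
  .stack_slices(pages)
}

#' Load an image stack
#'
#' Accepts either a YAML manifest (as written by [save_image_stack()], one
#' single-sample TIFF per channel) or a bare TIFF. A bare single-sample TIFF
#' is read as one channel named `"ch1"` with pages as z-slices; a bare
#' interleaved TIFF with 2 samples per pixel is read as two channels
#' (`"ch1"`, `"ch2"`), intensities rescaled back to the declared bit depth.
#'
#' @param path a `.yaml`/`.yml` manifest or a `.tif`/`.tiff` file.
#' @param bit_depth bit depth assumed for bare TIFFs (default 16).
#' @return An [image_stack()].
#' @export
load_image_stack <- function(path, bit_depth = 16L) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  if (grepl("\\.ya?ml$", path)) {
    manifest <- tryCatch(yaml::read_yaml(path),
                         error = function(e) stop_format(
                           "unreadable manifest: ", conditionMessage(e)))
    if (is.null(manifest$channels) || length(manifest$channels) < 1L) {
      stop_format("manifest declares no channels")
    }
    bd <- as.integer(manifest$bit_depth %||% bit_depth)
    dirn <- dirname(path)
    channels <- lapply(manifest$channels, function(f) {
      fp <- if (file.exists(f)) f else file.path(dirn, f)
      if (!file.exists(fp)) stop_format("manifest names missing file: ", f)
      .read_channel_tiff(fp, bd)
    })
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1L) {
      stop_format("manifest channels disagree in dimensions")
    }
    ps <- manifest$pixel_size %||% NA_real_
    return(image_stack(channels, bit_depth = bd, pixel_size = as.numeric(ps)))
  }
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
    error = function(e) stop_io("cannot read TIFF '", path, "': ",
                                conditionMessage(e))
  )
  scale <- 2^as.integer(bit_depth) - 1
  nd <- length(dim(pages[[1L]]))
  if (nd == 2L) {
    arr <- .stack_slices(lapply(pages, function(p) {
      storage.mode(p) <- "double"; p
    }))
    return(image_stack(list(ch1 = arr), bit_depth = bit_depth))
  }
  # interleaved multi-sample: readTIFF rescales to [0, 1]; undo it
  nsamp <- dim(pages[[1L]])[3L]
  channels <- lapply(seq_len(nsamp), function(s) {
    .stack_slices(lapply(pages, function(p) round(p[, , s] * scale)))
  })
  names(channels) <- paste0("ch", seq_len(nsamp))
  image_stack(channels, bit_depth = bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
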