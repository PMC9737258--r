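#' Multichannel image stacks
#'
#' A `multichannel_stack` holds a non-negative fluorescence image as a 4-D
#' array indexed `[y, x, z, channel]`, together with its scale (um per pixel),
#' channel names, and optionally the z step in micrometres. All channels share
#' the same spatial dimensions.
#'
#' @param pixels Numeric array: `y, x` matrix, `y, x, z` array, or
#'   `y, x, z, channel` array. Intensities must be >= 0.
#' @param channel_names Character vector naming the channels (unique, one per
#'   channel slab).
#' @param um_per_px Image scale in micrometres per pixel.
#' @param z_step_um Optional z spacing in micrometres.
#' @return An object of class `multichannel_stack`.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 5] <- 1
#' multichannel_stack(m, channel_names = "red")
#' @export
multichannel_stack <- function(pixels, channel_names, um_per_px = 1,
                               z_step_um = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 4L) {
    abort("`pixels` must be a matrix or a 3-D/4-D array [y, x, z, channel].")
  }
  if (any(pixels < 0)) abort("`pixels` intensities must be >= 0.")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[4L]) {
    abort(sprintf("`channel_names` has %d names but `pixels` has %d channels.",
                  length(channel_names), dim(pixels)[4L]))
  }
  if (anyDuplicated(channel_names)) abort("`channel_names` must be unique.")
  stopifnot_scalar_number(um_per_px, "um_per_px", min = 0, strict_min = TRUE)
  dimnames(pixels) <- list(NULL, NULL, NULL, channel_names)
  structure(
    list(pixels = pixels, channel_names = channel_names,
         um_per_px = um_per_px, z_step_um = z_step_um),
    class = "multichannel_stack"
  )
}

#' @export
print.multichannel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multichannel_stack> %d x %d px, %d z-slice(s), %g um/px\n",
              d[1], d[2], d[3], x$um_per_px))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multichannel_stack <- function(x) dim(x$pixels)

channel_slab <- function(stack, channel) {
  if (!channel %in% stack$channel_names) {
    abort(sprintf("channel '%s' not present (have: %s).", channel,
                  paste(stack$channel_names, collapse = ", ")))
  }
  stack$pixels[, , , channel, drop = FALSE][, , , 1L]
}

# Max-intensity projection over z for one channel -> matrix [y, x].
max_projection <- function(stack, channel) {
  slab <- channel_slab(stack, channel)
  if (length(dim(slab)) == 2L) return(slab)
  apply(slab, c(1L, 2L), max)
}

#' Write and read image stacks as multi-page TIFF
#'
#' Stacks are written as plain multi-page TIFF (16-bit, channel-major page
#' order: all z slices of channel 1, then channel 2, ...) with a JSON sidecar
#' (`<path>.json`) recording channel names, z count, scale, and z step.
#' Intensities are clamped to \[0, 1\] on write and quantised to 16 bits.
#' `read_stack_tiff()` restores the stack from the sidecar; without a sidecar,
#' `channels` and `um_per_px` must be supplied and the page count must be a
#' multiple of the channel count.
#'
#' @param stack A [multichannel_stack()].
#' @param path TIFF file path.
#' @param channels Optional character vector of channel names (required when
#'   the sidecar is absent).
#' @param um_per_px Optional scale override (required when the sidecar is
#'   absent).
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   returns a [multichannel_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$pixels)
  pages <- list()
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- pmin(pmax(stack$pixels[, , z, ch], 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = stack$channel_names, z_slices = d[3],
               um_per_px = stack$um_per_px, z_step_um = stack$z_step_um,
               dim_yx = d[1:2])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, channels = NULL, um_per_px = NULL) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- channels %||% meta$channels
    um_per_px <- um_per_px %||% meta$um_per_px
    z_step_um <- meta$z_step_um
  } else {
    if (is.null(channels)) {
      abort(paste0("no metadata sidecar found for ", path,
                   "; supply `channels` (and `um_per_px`) explicitly."))
    }
    z_step_um <- NULL
  }
  if (is.null(um_per_px)) um_per_px <- 1
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0L) {
    abort(sprintf("%d TIFF pages are not divisible by %d channels.",
                  length(pages), n_ch))
  }
  nz <- length(pages) %/% n_ch
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], nz, n_ch))
  k <- 1L
  for (ch in seq_len(n_ch)) {
    for (z in seq_len(nz)) {
      arr[, , z, ch] <- pages[[k]]
      k <- k + 1L
    }
  }
  multichannel_stack(arr, channel_names = channels, um_per_px = um_per_px,
                     z_step_um = z_step_um)
}
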