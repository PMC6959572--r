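#' Multi-channel 3-D image stack with physical geometry
#'
#' Container for confocal voxel data. Voxels are stored as a 4-D numeric
#' array indexed `[y, x, z, channel]` (image convention: y increases
#' downward). All physical sizes derive from the attached geometry, never
#' from hard-coded constants.
#'
#' @param voxels 4-D numeric array `[y, x, z, channel]`. A 2-D matrix or a
#'   3-D `[y, x, z]` array is promoted to a single-channel stack.
#' @param pixel_size_um in-plane sampling (micrometres per pixel), > 0.
#' @param z_step_um axial step between planes (micrometres), > 0.
#' @param channel_names character vector, one unique name per channel.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um = pixel_size_um,
                        channel_names = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 2-D, 3-D or 4-D array")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0")
  }
  if (!is.numeric(z_step_um) || z_step_um <= 0) stop("`z_step_um` must be > 0")
  nch <- dim(voxels)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch || anyDuplicated(channel_names)) {
    stop("`channel_names` must be unique and match the channel axis")
  }
  structure(
    list(voxels = voxels,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um),
         channel_names = as.character(channel_names)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack: %d x %d px, %d plane(s), %d channel(s) [%s]\n",
              d[2L], d[1L], d[3L], d[4L],
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel %.4g um, z-step %.4g um (%.4g x %.4g um field)\n",
              x$pixel_size_um, x$z_step_um,
              d[2L] * x$pixel_size_um, d[1L] * x$pixel_size_um))
  invisible(x)
}

#' Pixel geometry
#'
#' Physical sampling of an image: in-plane pixel size and z-step, both in
#' micrometres. Houses all pixel/micrometre unit conversions.
#'
#' @param pixel_size_um in-plane pixel size (um), > 0.
#' @param z_step_um axial step (um), > 0.
#' @return An object of class `PixelGeometry`.
#' @export
pixel_geometry <- function(pixel_size_um, z_step_um = pixel_size_um) {
  if (pixel_size_um <= 0 || z_step_um <= 0) {
    stop("pixel sizes must be positive")
  }
  structure(list(pixel_size_um = as.numeric(pixel_size_um),
                 z_step_um = as.numeric(z_step_um)),
            class = "PixelGeometry")
}

#' @export
print.PixelGeometry <- function(x, ...) {
  cat(sprintf("PixelGeometry: %.4g um/px in-plane, %.4g um z-step\n",
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Geometry of a stack
#' @param stack an `ImageStack`.
#' @return the stack's `PixelGeometry`.
#' @export
stack_geometry <- function(stack) {
  pixel_geometry(stack$pixel_size_um, stack$z_step_um)
}

#' Extract one channel of a stack
#'
#' @param stack an `ImageStack`.
#' @param channel channel name or index.
#' @param z optional plane index; if given a 2-D matrix is returned.
#' @return a 3-D `[y, x, z]` array, or a matrix when `z` is given.
#' @export
get_channel <- function(stack, channel, z = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("unknown channel: ", channel)
  } else ci <- as.integer(channel)
  if (is.null(z)) {
    stack$voxels[, , , ci, drop = FALSE][, , , 1L]
  } else {
    stack$voxels[, , z, ci]
  }
}

#' Write / read an image stack as multi-page TIFF with a YAML sidecar
#'
#' Planes are written channel-major (all z of channel 1, then channel 2,
#' ...) as 32-bit float TIFF; `pixel_size_um`, `z_step_um` and
#' `channel_names` travel in a `.yaml` sidecar next to the TIFF so physical
#' geometry survives the round trip.
#'
#' @param stack an `ImageStack`.
#' @param path output `.tif` path; the sidecar is `<path>.yaml`.
#' @return `write_image_stack`: the path, invisibly. `read_image_stack`:
#'   an `ImageStack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  # tiff::writeTIFF float requires [0,1]; store a scale factor in the sidecar
  mx <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[3L] * d[4L])
  k <- 1L
  for (ci in seq_len(d[4L])) for (zi in seq_len(d[3L])) {
    pages[[k]] <- stack$voxels[, , zi, ci] / mx
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               channel_names = as.list(stack$channel_names),
               n_planes = d[3L], intensity_scale = mx)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_planes
  nch <- length(pages) / nz
  d <- dim(pages[[1L]])
  vox <- array(0, c(d[1L], d[2L], nz, nch))
  k <- 1L
  for (ci in seq_len(nch)) for (zi in seq_len(nz)) {
    vox[, , zi, ci] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  image_stack(vox, meta$pixel_size_um, meta$z_step_um,
              unlist(meta$channel_names))
}

# Run expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
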