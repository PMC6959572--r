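#' Binarize an intensity image
#'
#' Threshold a 2-D plane or 3-D `[y, x, z]` channel. The mask is TRUE where
#' intensity >= threshold. For condition comparisons the same threshold
#' must be applied to every member of a batch: compute it once (e.g. with
#' `method = "otsu"` on a reference stack, or a fixed value) and pass it as
#' `method = "fixed"` to the others.
#'
#' Sparse fluorescence channels (isolated puncta over a flat background)
#' make Otsu's bimodality assumption fail; `method = "background"`
#' thresholds at `median + value * MAD` of the whole channel instead, a
#' robust background-statistics rule that is stable when foreground
#' occupies a tiny pixel fraction.
#'
#' @param channel numeric matrix or 3-D array of intensities.
#' @param method one of `"fixed"`, `"otsu"`, `"percentile"`,
#'   `"background"`.
#' @param value fixed threshold; the percentile (0-100) for
#'   `method = "percentile"`; the number of MADs above the median for
#'   `method = "background"` (default 5).
#' @return A `BinaryMask`: logical array of the same shape with attributes
#'   `threshold` and `method` recording provenance.
#' @export
binarize <- function(channel,
                     method = c("otsu", "fixed", "percentile", "background"),
                     value = NULL) {
  method <- match.arg(method)
  if (method %in% c("fixed", "percentile") && is.null(value)) {
    stop("`value` is required for method '", method, "'")
  }
  thr <- switch(method,
    fixed = value,
    percentile = {
      if (value < 0 || value > 100) stop("percentile must be in [0, 100]")
      as.numeric(stats::quantile(channel, value / 100, type = 1))
    },
    background = {
      k <- if (is.null(value)) 5 else value
      x <- if (length(channel) > 2e6) {
        channel[seq(1L, length(channel), by = length(channel) %/% 1e6)]
      } else channel
      stats::median(x) + k * stats::mad(x)
    },
    otsu = {
      rng <- range(channel)
      if (rng[1L] == rng[2L]) {
        warning("constant image: otsu undefined, returning empty mask")
        Inf
      } else {
        # EBImage::otsu expects a matrix in [0,1]
        x01 <- (channel - rng[1L]) / (rng[2L] - rng[1L])
        if (length(dim(channel)) == 3L) dim(x01) <- c(dim(channel)[1L],
                                                      prod(dim(channel)[-1L]))
        EBImage::otsu(x01, range = c(0, 1)) * (rng[2L] - rng[1L]) + rng[1L]
      }
    })
  mask <- channel >= thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  class(mask) <- c("BinaryMask", class(mask))
  mask
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask: %s px, %d foreground (%.2f%%), %s threshold %.4g\n",
              paste(dim(x), collapse = " x "), sum(x),
              100 * mean(x), attr(x, "method"), attr(x, "threshold")))
  invisible(x)
}

# Neighbor offsets (dy, dx, dz) for the half neighborhood of a connectivity.
.half_offsets <- function(connectivity) {
  switch(as.character(connectivity),
    "4" = list(c(1L, 0L, 0L), c(0L, 1L, 0L)),
    "8" = list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(-1L, 1L, 0L)),
    "6" = list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
    "26" = {
      off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
      off <- off[off$dz > 0 | (off$dz == 0 & (off$dx > 0 |
               (off$dx == 0 & off$dy > 0))), ]
      lapply(seq_len(nrow(off)),
             function(i) as.integer(unlist(off[i, ])))
    },
    stop("connectivity must be 4, 8 (planar) or 6, 26 (volumetric)"))
}

#' Connected foreground regions with physical areas
#'
#' Label connected components of a binary mask (2-D with 4/8-connectivity,
#' 3-D with 6/26-connectivity), drop components smaller than `min_pixels`,
#' and report sizes in pixels and in physical units from `geom`.
#'
#' @param mask logical matrix or 3-D array (a `BinaryMask` or plain
#'   logical).
#' @param connectivity 4 or 8 for planes, 6 or 26 for volumes.
#' @param min_pixels components with fewer pixels are removed.
#' @param geom optional `PixelGeometry` for the um conversions.
#' @return list with `labels` (integer array, 0 = background, components
#'   renumbered 1..n after filtering) and `regions`, a data.frame with
#'   `label`, `n_pixels`, `area_um2` (2-D) or `volume_um3` (3-D).
#' @export
connected_regions <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L,
                              min_pixels = 1L, geom = NULL) {
  d <- dim(mask)
  is3d <- length(d) == 3L
  if (!is3d && !(connectivity %in% c(4L, 8L))) {
    stop("planar masks use connectivity 4 or 8")
  }
  if (is3d && !(connectivity %in% c(6L, 26L))) {
    stop("volumetric masks use connectivity 6 or 26")
  }
  fg <- which(mask)
  labels <- array(0L, d)
  if (length(fg) == 0L) {
    return(list(labels = labels,
                regions = .region_table(integer(0), geom, is3d)))
  }
  ny <- d[1L]; nx <- d[2L]; nz <- if (is3d) d[3L] else 1L
  idx0 <- fg - 1L
  y <- idx0 %% ny
  x <- (idx0 %/% ny) %% nx
  z <- idx0 %/% (ny * nx)
  pos <- integer(ny * nx * nz)    # map linear index -> rank among foreground
  pos[fg] <- seq_along(fg)
  edges <- integer(0)
  for (off in .half_offsets(connectivity)) {
    yn <- y + off[1L]; xn <- x + off[2L]; zn <- z + off[3L]
    ok <- yn >= 0L & yn < ny & xn >= 0L & xn < nx & zn >= 0L & zn < nz
    nb <- yn[ok] + ny * (xn[ok] + nx * zn[ok]) + 1L
    hit <- pos[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(pos[fg[ok]][hit], pos[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_pixels)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  labels[fg] <- remap[comp]
  list(labels = labels,
       regions = .region_table(sizes[keep], geom, is3d))
}

.region_table <- function(sizes, geom, is3d) {
  out <- data.frame(label = seq_along(sizes), n_pixels = as.integer(sizes))
  if (!is.null(geom)) {
    if (is3d) {
      out$volume_um3 <- sizes * geom$pixel_size_um^2 * geom$z_step_um
    } else {
      out$area_um2 <- sizes * geom$pixel_size_um^2
    }
  }
  out
}

#' Pixel / micrometre conversions
#'
#' Lengths convert as `n * pixel_size_um`, areas as
#' `n * pixel_size_um^2`. At the spine-imaging sampling of 0.12 um/px,
#' 3 px is 0.36 um; at the expansion-microscopy sampling of 0.155 um/px,
#' 9 px is 0.216 um2 and 4 px is 0.0961 um2.
#'
#' @param n_pixels pixel count (length for `pixels_to_um`, area for
#'   `pixels_to_um2`), >= 0.
#' @param geom a `PixelGeometry`.
#' @return micrometres (or square micrometres).
#' @export
pixels_to_um <- function(n_pixels, geom) {
  if (any(n_pixels < 0)) stop("`n_pixels` must be >= 0")
  n_pixels * geom$pixel_size_um
}

#' @rdname pixels_to_um
#' @export
pixels_to_um2 <- function(n_pixels, geom) {
  if (any(n_pixels < 0)) stop("`n_pixels` must be >= 0")
  n_pixels * geom$pixel_size_um^2
}

#' @rdname pixels_to_um
#' @param length_um physical length in micrometres.
#' @export
um_to_pixels <- function(length_um, geom) length_um / geom$pixel_size_um

#' Random cardinal pixel shift (chance-colocalization null)
#'
#' Translate a whole channel by `round(distance_um / pixel_size_um)` pixels
#' along one of +x, -x, +y, -y chosen uniformly at random. Each channel of
#' an analysis should be shifted with an independent draw. Edges wrap
#' around (toroidal), so total signal is conserved; `edge = "crop"`
#' zero-fills instead.
#'
#' @param channel matrix or 3-D `[y, x, z]` array (intensity or mask).
#' @param distance_um shift magnitude in micrometres, >= 0.
#' @param geom a `PixelGeometry`.
#' @param seed optional RNG seed for the direction draw.
#' @param direction force one of `"+x" "-x" "+y" "-y"` instead of drawing.
#' @param edge `"wrap"` (default) or `"crop"`.
#' @return the shifted array, with attributes `direction` and `shift_px`.
#' @export
pixel_shift <- function(channel, distance_um, geom, seed = NULL,
                        direction = NULL, edge = c("wrap", "crop")) {
  edge <- match.arg(edge)
  if (distance_um < 0) stop("`distance_um` must be >= 0")
  npx <- as.integer(round(distance_um / geom$pixel_size_um))
  d <- dim(channel)
  if (npx >= d[1L] || npx >= d[2L]) stop("shift exceeds image extent")
  if (is.null(direction)) {
    direction <- with_seed(seed, sample(c("+x", "-x", "+y", "-y"), 1L))
  }
  out <- channel
  if (npx > 0L) {
    roll <- function(n, k) {         # index vector shifting content by +k
      ((seq_len(n) - 1L - k) %% n) + 1L
    }
    is3d <- length(d) == 3L
    ix <- switch(direction,
      "+x" = list(seq_len(d[1L]), roll(d[2L], npx)),
      "-x" = list(seq_len(d[1L]), roll(d[2L], -npx)),
      "+y" = list(roll(d[1L], npx), seq_len(d[2L])),
      "-y" = list(roll(d[1L], -npx), seq_len(d[2L])),
      stop("bad direction"))
    if (is3d) out <- channel[ix[[1L]], ix[[2L]], , drop = FALSE]
    else out <- channel[ix[[1L]], ix[[2L]]]
    if (edge == "crop") {
      blank <- function(m, rows, cols) { m[rows, cols] <- 0; m }
      wiped <- switch(direction,
        "+x" = list(seq_len(d[1L]), seq_len(npx)),
        "-x" = list(seq_len(d[1L]), d[2L] - seq_len(npx) + 1L),
        "+y" = list(seq_len(npx), seq_len(d[2L])),
        "-y" = list(d[1L] - seq_len(npx) + 1L, seq_len(d[2L])))
      if (is3d) out[wiped[[1L]], wiped[[2L]], ] <- 0
      else out[wiped[[1L]], wiped[[2L]]] <- 0
    }
  }
  attr(out, "direction") <- direction
  attr(out, "shift_px") <- npx
  out
}

#' Rolling-ball style background subtraction
#'
#' Grayscale top-hat: the morphological opening with a disc of the given
#' physical radius is taken as background and subtracted. Applied per
#' plane.
#'
#' @param channel matrix or 3-D `[y, x, z]` array.
#' @param geom a `PixelGeometry`.
#' @param radius_um structuring-element radius (um), default 10.
#' @return array of the same shape, background removed (never negative).
#' @export
subtract_background <- function(channel, geom, radius_um = 10) {
  r <- max(1L, as.integer(round(radius_um / geom$pixel_size_um)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  op <- function(m) pmax(m - EBImage::opening(m, brush), 0)
  if (length(dim(channel)) == 2L) return(op(channel))
  out <- channel
  for (zi in seq_len(dim(channel)[3L])) out[, , zi] <- op(channel[, , zi])
  out
}
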