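#' Soma cross-section axes
#'
#' Long and short cross sections of a microglial cell body, measured on a
#' maximum-intensity projection.
#'
#' @param long_um,short_um axis lengths in um; `long >= short > 0`.
#' @return a `SomaAxes` object.
#' @export
soma_axes <- function(long_um, short_um) {
  if (short_um <= 0 || long_um < short_um) {
    stop("axes must satisfy long >= short > 0")
  }
  structure(list(long_um = long_um, short_um = short_um),
            class = "SomaAxes")
}

#' Measure soma axes from an image stack
#'
#' Binarizes the maximum-intensity projection of the given channel,
#' takes the connected component containing (or nearest to) the seed
#' point, and measures its extent along the principal axes of the
#' component's pixels (PCA): the long axis is the extent along the first
#' principal direction, the short axis along the second.
#'
#' @param stack an `ImageStack`.
#' @param center_um `(x, y)` seed near the soma center, in um.
#' @param channel channel to measure (default `"Iba1"`).
#' @param threshold_method passed to [binarize()].
#' @param search_radius_um how far from the seed to accept a component.
#' @return a `SomaAxes` object.
#' @export
measure_soma_axes <- function(stack, center_um, channel = "Iba1",
                              threshold_method = "background",
                              search_radius_um = 5) {
  ps <- stack$pixel_size_um
  mip <- apply(get_channel(stack, channel), c(1L, 2L), max)
  mask <- binarize(mip, threshold_method)
  lab <- connected_regions(mask, connectivity = 8L)$labels
  cx <- center_um[[1L]] / ps + 0.5
  cy <- center_um[[2L]] / ps + 0.5
  i0 <- as.integer(round(cy)); j0 <- as.integer(round(cx))
  r <- as.integer(ceiling(search_radius_um / ps))
  is <- max(1L, i0 - r):min(nrow(lab), i0 + r)
  js <- max(1L, j0 - r):min(ncol(lab), j0 + r)
  local <- lab[is, js]
  cand <- local[local > 0L]
  if (length(cand) == 0L) stop("no component near the seed point")
  id <- as.integer(names(which.max(table(cand))))
  px <- which(lab == id)
  i <- (px - 1L) %% nrow(lab) + 1L
  j <- (px - 1L) %/% nrow(lab) + 1L
  xy <- cbind(j, i)
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  ext <- apply(pc$x, 2L, function(u) diff(range(u)) + 1)
  soma_axes(long_um = max(ext) * ps, short_um = min(ext) * ps)
}

#' Per-cell linear expansion scaling factor
#'
#' Mean of the long-axis and short-axis post/pre ratios of the same
#' microglia soma. Post-expansion lengths divide by the factor, areas by
#' the factor squared, to recover pre-expansion sizes.
#'
#' @param pre,post `SomaAxes` for the same cell before and after
#'   expansion.
#' @return list with `factor`, `long_ratio`, `short_ratio`, `shrinkage`
#'   (flag, TRUE when factor < 1; the value is still returned).
#' @export
scaling_factor <- function(pre, post) {
  stopifnot(inherits(pre, "SomaAxes"), inherits(post, "SomaAxes"))
  lr <- post$long_um / pre$long_um
  sr <- post$short_um / pre$short_um
  f <- mean(c(lr, sr))
  if (f < 1) warning("scaling factor < 1: apparent shrinkage")
  list(factor = f, long_ratio = lr, short_ratio = sr, shrinkage = f < 1)
}

#' Rule-based lysosome detection in an expanded CD68 channel
#'
#' CD68 regions inside a cell footprint are scored as lysosomes when, at
#' their brightest z-plane (argmax of mean ROI intensity), they cover at
#' least `min_area_px` pixels (default 9 px = 0.216 um2 expanded at
#' 0.155 um/px), their mean intensity is at least `bg_factor` (default 2)
#' times the local background, and the region is present in two
#' consecutive z-planes (>= 1 px overlap with plane +-1, which is what a
#' 26-connected 3-D component spanning adjacent planes guarantees).
#'
#' Both thresholds are relative (background multiples), so detection is
#' invariant to global intensity scaling.
#'
#' @param cd68 3-D `[y, x, z]` CD68 intensity array.
#' @param cell_mask logical 2-D footprint of the cell (applied to every
#'   plane), or linear indices.
#' @param geom a `PixelGeometry` (post-expansion sampling).
#' @param min_area_px minimum area at the brightest plane (7-9 px per the
#'   scoring rule; default 9).
#' @param bg_factor intensity multiple over local background (default 2).
#' @return list of `Lysosome` records: `roi_idx` (brightest plane),
#'   `z`, `z_planes`, `area_px`, `area_um2_expanded`, `mean_intensity`,
#'   `background`.
#' @export
detect_lysosomes <- function(cd68, cell_mask, geom, min_area_px = 9L,
                             bg_factor = 2) {
  d <- dim(cd68)
  if (is.matrix(cell_mask) || is.array(cell_mask)) {
    cell_idx <- which(cell_mask)
  } else cell_idx <- as.integer(cell_mask)
  if (length(cell_idx) == 0L) stop("cell mask is empty")
  # work on the cell's bounding box only
  ci <- (cell_idx - 1L) %% d[1L] + 1L
  cj <- (cell_idx - 1L) %/% d[1L] + 1L
  is <- min(ci):max(ci); js <- min(cj):max(cj)
  sub <- cd68[is, js, , drop = FALSE]
  ds <- dim(sub)
  npl_s <- ds[1L] * ds[2L]
  idx_s <- (ci - min(ci) + 1L) + (cj - min(cj)) * ds[1L]
  in_cell <- rep(FALSE, npl_s); in_cell[idx_s] <- TRUE
  # local background: median CD68 over the cell footprint, all planes
  samp <- as.vector(vapply(seq_len(ds[3L]),
                           function(z) sub[idx_s + (z - 1L) * npl_s],
                           numeric(length(idx_s))))
  bg <- stats::median(samp)
  thr <- bg_factor * bg
  cand <- array(FALSE, ds)
  for (z in seq_len(ds[3L])) {
    pl <- sub[, , z] >= thr
    pl[!in_cell] <- FALSE
    cand[, , z] <- pl
  }
  cc <- connected_regions(cand, connectivity = 26L)
  # map a bbox plane index back to the full plane
  to_full <- function(k) {
    ii <- (k - 1L) %% ds[1L] + 1L + min(ci) - 1L
    jj <- (k - 1L) %/% ds[1L] + 1L + min(cj) - 1L
    ii + (jj - 1L) * d[1L]
  }
  out <- list()
  for (lb in cc$regions$label) {
    vox <- which(cc$labels == lb)
    z <- (vox - 1L) %/% npl_s + 1L
    zs <- sort(unique(z))
    if (!any(diff(zs) == 1L)) next            # two consecutive planes rule
    zmean <- vapply(zs, function(zz) mean(sub[vox[z == zz]]), numeric(1))
    zb <- zs[which.max(zmean)]
    roi_s <- (vox[z == zb] - 1L) %% npl_s + 1L
    if (length(roi_s) < min_area_px) next
    m <- mean(sub[roi_s + (zb - 1L) * npl_s])
    if (m < bg_factor * bg) next
    roi <- to_full(roi_s)
    npl <- d[1L] * d[2L]
    out[[length(out) + 1L]] <-
      structure(list(roi_idx = roi, z = zb, z_planes = zs,
                     area_px = length(roi),
                     area_um2_expanded = pixels_to_um2(length(roi), geom),
                     mean_intensity = m, background = bg),
                class = "Lysosome")
  }
  out
}

# Annulus of background pixels around a lysosome ROI: width twice the
# ROI-equivalent radius, excluding every detected lysosome ROI.
.background_annulus <- function(lys, exclude_idx, dim2) {
  ny <- dim2[1L]; nx <- dim2[2L]
  i <- (lys$roi_idx - 1L) %% ny + 1L
  j <- (lys$roi_idx - 1L) %/% ny + 1L
  r_eq <- sqrt(lys$area_px / pi)
  w <- 2 * r_eq
  is <- max(1L, floor(min(i) - w)):min(ny, ceiling(max(i) + w))
  js <- max(1L, floor(min(j) - w)):min(nx, ceiling(max(j) + w))
  sub_i <- rep(is, times = length(js))
  sub_j <- rep(js, each = length(is))
  dmin <- rep(Inf, length(sub_i))
  for (k in seq_along(i)) {
    dk <- sqrt((sub_i - i[k])^2 + (sub_j - j[k])^2)
    dmin <- pmin(dmin, dk)
  }
  ann <- sub_i[dmin > 0 & dmin <= w] + (sub_j[dmin > 0 & dmin <= w] - 1L) * ny
  setdiff(ann, exclude_idx)
}

#' Score a lysosome for engulfed PSD-95
#'
#' A lysosome is positive for synaptic engulfment when (a) the mean PSD
#' signal in its ROI exceeds the local background mean by two background
#' SDs, (b) a connected PSD region of at least `min_punctum_px` pixels
#' (default 4 px = 0.0961 um2 expanded) with mean intensity at least
#' twice the background lies within the ROI, and (c) the PSD and CD68
#' z-profiles over the ROI footprint peak in the same plane +- 1.
#' The local background is an annulus of width twice the ROI-equivalent
#' radius around the ROI, excluding all detected lysosome ROIs.
#'
#' @param lys a `Lysosome` from [detect_lysosomes()].
#' @param psd,cd68 3-D `[y, x, z]` intensity arrays.
#' @param all_lysosome_idx union of all detected lysosome ROI pixels in
#'   the plane (for annulus exclusion).
#' @param min_punctum_px minimum punctum size (4-5 px per the rule;
#'   default 4).
#' @param bg_factor punctum intensity multiple over background.
#' @return list with `positive`, the individual rule outcomes
#'   (`signal_over_bg`, `has_punctum`, `co_peaked`), `bg_mean`, `bg_sd`,
#'   `z_peak_psd`, `z_peak_cd68`.
#' @export
score_psd_positive <- function(lys, psd, cd68,
                               all_lysosome_idx = lys$roi_idx,
                               min_punctum_px = 4L, bg_factor = 2) {
  d <- dim(psd)
  npl <- d[1L] * d[2L]
  ann <- .background_annulus(lys, all_lysosome_idx, d[1:2])
  if (length(ann) == 0L) stop("background annulus is empty")
  off <- (lys$z - 1L) * npl
  bg_px <- psd[ann + off]
  bg_mean <- mean(bg_px); bg_sd <- stats::sd(bg_px)
  roi_mean <- mean(psd[lys$roi_idx + off])
  rule_a <- roi_mean >= bg_mean + 2 * bg_sd
  # (b) punctum of min size and 2x background inside the ROI
  pl <- psd[, , lys$z]
  sub <- rep(FALSE, npl); sub[lys$roi_idx] <- pl[lys$roi_idx] >= bg_factor * bg_mean
  sizes <- .component_sizes(which(sub), d[1L])
  rule_b <- any(sizes >= min_punctum_px)
  # (c) co-peaking z-profiles over the ROI footprint
  prof <- function(arr) vapply(seq_len(d[3L]),
                               function(z) mean(arr[lys$roi_idx + (z - 1L) * npl]),
                               numeric(1))
  zp <- which.max(prof(psd)); zc <- which.max(prof(cd68))
  rule_c <- abs(zp - zc) <= 1L
  list(positive = rule_a && rule_b && rule_c,
       signal_over_bg = rule_a, has_punctum = rule_b, co_peaked = rule_c,
       bg_mean = bg_mean, bg_sd = bg_sd, z_peak_psd = zp, z_peak_cd68 = zc)
}

#' Per-cell lysosome statistics with expansion correction
#'
#' Aggregates detected lysosomes per microglia: count, percent
#' PSD-95-positive, and mean cross-sectional sizes split by positivity,
#' both as measured in the expanded gel and rescaled to pre-expansion
#' units by dividing areas by the cell's squared linear scaling factor.
#'
#' @param cells list, one element per cell: `list(lysosomes = <list of
#'   Lysosome>, positive = <logical vector>, factor = <scaling factor>)`.
#' @return data.frame, one row per cell: `n_lysosomes`, `pct_positive`,
#'   `mean_size_pos_um2`, `mean_size_neg_um2` (expanded) and their
#'   `_scaled` counterparts.
#' @export
lysosome_stats <- function(cells) {
  rows <- lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    if (is.null(cl$factor)) stop("every cell needs a scaling factor")
    n <- length(cl$lysosomes)
    sizes <- vapply(cl$lysosomes, `[[`, 0, "area_um2_expanded")
    pos <- as.logical(cl$positive)
    msize <- function(sel) if (any(sel)) mean(sizes[sel]) else NA_real_
    data.frame(cell_id = i, n_lysosomes = n,
               pct_positive = if (n > 0) 100 * mean(pos) else NA_real_,
               mean_size_pos_um2 = msize(pos),
               mean_size_neg_um2 = msize(!pos),
               mean_size_pos_um2_scaled = msize(pos) / cl$factor^2,
               mean_size_neg_um2_scaled = msize(!pos) / cl$factor^2,
               factor = cl$factor)
  })
  do.call(rbind, rows)
}
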