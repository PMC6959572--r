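#' A traced microglia in a single analysis plane
#'
#' Analysis unit for colocalization/engulfment scoring. The mask is the
#' traced cell perimeter (soma plus proximal processes) in one z-plane,
#' held as linear pixel indices into that plane. Cortical depth is the
#' distance from the soma center to the pia.
#'
#' @param mask_idx integer linear indices of the cell's pixels within a
#'   `dim[1] x dim[2]` plane, or a logical matrix.
#' @param dim plane dimensions `c(ny, nx)` (ignored when `mask_idx` is a
#'   matrix).
#' @param z_plane the analyzed z-plane index.
#' @param soma_center_um `(x, y)` soma center in um.
#' @param cortical_depth_um distance from soma center to the pia (um),
#'   >= 0.
#' @param geom a `PixelGeometry`.
#' @param cell_id optional identifier.
#' @return A `MicrogliaCell` object.
#' @export
microglia_cell <- function(mask_idx, dim = NULL, z_plane = 1L,
                           soma_center_um = c(NA_real_, NA_real_),
                           cortical_depth_um = NA_real_, geom = NULL,
                           cell_id = NA) {
  if (is.matrix(mask_idx)) {
    dim <- base::dim(mask_idx)
    mask_idx <- which(mask_idx)
  }
  if (length(mask_idx) == 0L) stop("cell mask is empty")
  if (!is.na(cortical_depth_um) && cortical_depth_um < 0) {
    stop("`cortical_depth_um` must be >= 0")
  }
  structure(list(cell_id = cell_id, mask_idx = as.integer(mask_idx),
                 dim = as.integer(dim), z_plane = as.integer(z_plane),
                 soma_center_um = soma_center_um,
                 cortical_depth_um = cortical_depth_um,
                 area_px = length(mask_idx), geom = geom),
            class = "MicrogliaCell")
}

#' @export
print.MicrogliaCell <- function(x, ...) {
  cat(sprintf("MicrogliaCell %s: %d px @ z=%d, depth %.1f um\n",
              as.character(x$cell_id), x$area_px, x$z_plane,
              x$cortical_depth_um))
  invisible(x)
}

# Extract the cell's plane from a 2-D or 3-D mask/image.
.cell_plane <- function(x, cell) {
  if (length(dim(x)) == 3L) x[, , cell$z_plane] else x
}

# Sizes of 8-connected components of `idx` (linear indices into an
# ny x nx plane), computed on the tight bounding box.
.component_sizes <- function(idx, ny) {
  if (length(idx) == 0L) return(integer(0))
  i <- (idx - 1L) %% ny + 1L
  j <- (idx - 1L) %/% ny + 1L
  i0 <- i - min(i) + 1L; j0 <- j - min(j) + 1L
  sub <- matrix(FALSE, max(i0), max(j0))
  sub[cbind(i0, j0)] <- TRUE
  connected_regions(sub, connectivity = 8L)$regions$n_pixels
}

#' Fraction of a microglia colocalized with a signal
#'
#' Overlap of the cell mask with a binarized signal, after discarding
#' 8-connected overlap regions smaller than `min_pixels`. The cell is
#' scored positive when at least one region survives. This is the
#' GFP/Iba1 colocalization measure: colocalized area / total microglia
#' area, in percent.
#'
#' @param cell a `MicrogliaCell`.
#' @param signal_mask logical plane (or 3-D mask; the cell's plane is
#'   used).
#' @param min_pixels minimum overlap-region size in pixels (default 3).
#' @return list with `pct`, `positive`, `n_regions`, `region_px`.
#' @export
colocalization_fraction <- function(cell, signal_mask, min_pixels = 3L) {
  stopifnot(inherits(cell, "MicrogliaCell"))
  pl <- .cell_plane(signal_mask, cell)
  if (!identical(base::dim(pl), as.integer(cell$dim))) {
    stop("mask and cell geometry differ")
  }
  ov <- cell$mask_idx[pl[cell$mask_idx]]
  sizes <- .component_sizes(ov, cell$dim[1L])
  kept <- sizes[sizes >= min_pixels]
  list(pct = 100 * sum(kept) / cell$area_px,
       positive = length(kept) > 0L,
       n_regions = length(kept), region_px = kept)
}

#' Triple-channel engulfment score for one microglia
#'
#' Qualifying engulfed puncta are 8-connected regions of
#' PSD-95 AND CD68 AND cell mask of at least `min_pixels` pixels in the
#' cell's analysis plane. The engulfment area is their summed area as a
#' percentage of the microglia area; the cell is engulfment-positive when
#' at least one qualifying punctum exists.
#'
#' @param cell a `MicrogliaCell`.
#' @param psd_mask,cd68_mask binarized PSD-95 and CD68 channels (2-D plane
#'   or 3-D mask).
#' @param min_pixels minimum punctum size (default 3 px).
#' @param iba1_mask optional binarized Iba1 signal; when given, puncta
#'   must additionally overlap it (inside the traced cell this is
#'   normally a no-op, but in the pixel-shift control the Iba1 channel is
#'   displaced like the others and the constraint bites).
#' @return list with `engulf_area_pct`, `positive`, `n_puncta`,
#'   `punctum_px`.
#' @export
triple_engulfment <- function(cell, psd_mask, cd68_mask, min_pixels = 3L,
                              iba1_mask = NULL) {
  stopifnot(inherits(cell, "MicrogliaCell"))
  psd <- .cell_plane(psd_mask, cell)
  cd <- .cell_plane(cd68_mask, cell)
  if (!identical(base::dim(psd), as.integer(cell$dim)) ||
      !identical(base::dim(cd), as.integer(cell$dim))) {
    stop("mask and cell geometry differ")
  }
  .triple_on_planes(cell, psd, cd,
                    if (is.null(iba1_mask)) NULL
                    else .cell_plane(iba1_mask, cell), min_pixels)
}

.triple_on_planes <- function(cell, psd_pl, cd_pl, iba_pl, min_pixels) {
  hit <- psd_pl[cell$mask_idx] & cd_pl[cell$mask_idx]
  if (!is.null(iba_pl)) hit <- hit & iba_pl[cell$mask_idx]
  ov <- cell$mask_idx[hit]
  sizes <- .component_sizes(ov, cell$dim[1L])
  kept <- sizes[sizes >= min_pixels]
  list(engulf_area_pct = 100 * sum(kept) / cell$area_px,
       positive = length(kept) > 0L,
       n_puncta = length(kept), punctum_px = kept)
}

#' CD68 reactivity of one microglia
#'
#' Percent of the microglia area colocalized with CD68 signal (area of
#' CD68 / microglia area), the reactivity measure.
#'
#' @inheritParams triple_engulfment
#' @param min_pixels minimum region size (default 1: no size rule).
#' @return percent in \[0, 100\].
#' @export
cd68_reactivity <- function(cell, cd68_mask, min_pixels = 1L) {
  colocalization_fraction(cell, cd68_mask, min_pixels = min_pixels)$pct
}

#' Score a whole ROI for triple-channel engulfment
#'
#' Binarizes the PSD-95 and CD68 channels of a stack (robust
#' background-statistics threshold by default — both channels are sparse —
#' or fixed thresholds pinned across a batch, the same-settings mode used
#' for condition comparisons) and scores every supplied microglia with
#' [triple_engulfment()].
#'
#' @param stack an `ImageStack` with `PSD95` and `CD68` channels (names
#'   configurable).
#' @param cells list of `MicrogliaCell`.
#' @param channels named character vector mapping `psd` and `cd68` to
#'   channel names.
#' @param min_pixels minimum punctum size in px.
#' @param threshold_method,threshold_psd,threshold_cd68 binarization
#'   controls; fixed values enable the batch-pinned mode.
#' @return list with `cells` (per-cell data.frame: `cell_id`, `depth_um`,
#'   `engulf_area_pct`, `positive`, `n_puncta`, `cd68_area_pct`) and
#'   `summary` (n_microglia, pct_positive, mean_engulf_area_pct).
#' @export
score_engulfment_roi <- function(stack, cells,
                                 channels = c(psd = "PSD95", cd68 = "CD68",
                                              iba1 = "Iba1"),
                                 min_pixels = 3L,
                                 threshold_method = "background",
                                 threshold_psd = NULL,
                                 threshold_cd68 = NULL) {
  masks <- .engulfment_masks(stack, cells, channels, threshold_method,
                             threshold_psd, threshold_cd68)
  .score_cells_planes(cells, .static_plane_fn(masks), min_pixels)
}

.static_plane_fn <- function(masks) {
  pl <- function(m, z) if (is.null(m)) NULL
                       else if (length(dim(m)) == 3L) m[, , z] else m
  function(z) list(psd = pl(masks$psd, z), cd68 = pl(masks$cd68, z),
                   iba1 = pl(masks$iba1, z))
}

.engulfment_masks <- function(stack, cells, channels, threshold_method,
                              threshold_psd, threshold_cd68) {
  bin <- function(name, fixed) {
    ch <- get_channel(stack, name)
    if (is.null(fixed)) binarize(ch, threshold_method)
    else binarize(ch, "fixed", fixed)
  }
  list(psd = bin(channels[["psd"]], threshold_psd),
       cd68 = bin(channels[["cd68"]], threshold_cd68),
       iba1 = if ("iba1" %in% names(channels))
         bin(channels[["iba1"]], NULL) else NULL)
}

# Score a list of cells given a per-plane mask provider: plane_fn(z)
# returns list(psd, cd68, iba1-or-NULL) matrices for plane z.
.score_cells_planes <- function(cells, plane_fn, min_pixels = 3L) {
  cache <- new.env(parent = emptyenv())
  getpl <- function(z) {
    key <- as.character(z)
    if (!exists(key, envir = cache)) assign(key, plane_fn(z), envir = cache)
    get(key, envir = cache)
  }
  rows <- lapply(cells, function(cl) {
    pl <- getpl(cl$z_plane)
    tr <- .triple_on_planes(cl, pl$psd, pl$cd68, pl$iba1, min_pixels)
    cd_ov <- cl$mask_idx[pl$cd68[cl$mask_idx]]
    data.frame(cell_id = cl$cell_id, depth_um = cl$cortical_depth_um,
               engulf_area_pct = tr$engulf_area_pct, positive = tr$positive,
               n_puncta = tr$n_puncta,
               cd68_area_pct = 100 * length(cd_ov) / cl$area_px)
  })
  per_cell <- do.call(rbind, rows)
  list(cells = per_cell,
       summary = data.frame(
         n_microglia = nrow(per_cell),
         pct_positive = 100 * mean(per_cell$positive),
         mean_engulf_area_pct = mean(per_cell$engulf_area_pct)))
}

#' Pixel-shift chance-colocalization null for an ROI
#'
#' Per round, the binarized PSD-95, CD68 and Iba1 channels are each
#' shifted by `distance_um` along an independently drawn cardinal
#' direction ([pixel_shift()]) and triple engulfment (a qualifying
#' punctum must overlap all three shifted signals) is rescored against
#' the original, unshifted traced cell masks. The distribution of the
#' percent-positive statistic across rounds estimates the chance
#' colocalization level; in the original tissue analysis this control
#' fell below 3%.
#'
#' @inheritParams score_engulfment_roi
#' @param distance_um shift magnitude (default 12 um).
#' @param n_rounds number of independent shift rounds (default 100).
#' @param seed RNG seed for the direction draws.
#' @return list with `observed` (unshifted scores), `null_pct_positive`
#'   (length `n_rounds`), `null_mean_engulf_area_pct`, and
#'   `mean_null_pct_positive`.
#' @export
shifted_null <- function(stack, cells,
                         channels = c(psd = "PSD95", cd68 = "CD68",
                                      iba1 = "Iba1"),
                         distance_um = 12, n_rounds = 100L, seed = NULL,
                         min_pixels = 3L, threshold_method = "background",
                         threshold_psd = NULL, threshold_cd68 = NULL) {
  if (n_rounds < 1L) stop("`n_rounds` must be >= 1")
  geom <- stack_geometry(stack)
  masks <- .engulfment_masks(stack, cells, channels, threshold_method,
                             threshold_psd, threshold_cd68)
  observed <- .score_cells_planes(cells, .static_plane_fn(masks), min_pixels)
  null_pos <- numeric(n_rounds)
  null_area <- numeric(n_rounds)
  static <- .static_plane_fn(masks)
  with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      dirs <- sample(c("+x", "-x", "+y", "-y"), 3L, replace = TRUE)
      shifted_fn <- function(z) {
        pl <- static(z)
        list(psd = pixel_shift(pl$psd, distance_um, geom,
                               direction = dirs[1L]),
             cd68 = pixel_shift(pl$cd68, distance_um, geom,
                                direction = dirs[2L]),
             iba1 = if (is.null(pl$iba1)) NULL
                    else pixel_shift(pl$iba1, distance_um, geom,
                                     direction = dirs[3L]))
      }
      sc <- .score_cells_planes(cells, shifted_fn, min_pixels)
      null_pos[r] <- sc$summary$pct_positive
      null_area[r] <- sc$summary$mean_engulf_area_pct
    }
  })
  list(observed = observed, null_pct_positive = null_pos,
       null_mean_engulf_area_pct = null_area,
       mean_null_pct_positive = mean(null_pos))
}

#' Depth dependence of microglial engulfment
#'
#' Pearson correlation between cortical depth and engulfment area over
#' engulfment-positive microglia only, restricted to `depth <=
#' max_depth_um` (L1 and L2/3); cells without triple-stained puncta are
#' excluded.
#'
#' @param cells data.frame with columns `depth_um`, `engulf_area_pct`,
#'   `positive` (as produced by [score_engulfment_roi()]).
#' @param max_depth_um depth gate in um (default 300).
#' @return list with `r`, `p`, `conf_int`, `slope`, `intercept`, `n`.
#' @export
depth_correlation <- function(cells, max_depth_um = 300) {
  d <- cells[cells$positive & !is.na(cells$depth_um) &
               cells$depth_um <= max_depth_um, ]
  if (nrow(d) < 3L) stop("fewer than 3 engulfment-positive cells in range")
  if (stats::sd(d$engulf_area_pct) == 0 || stats::sd(d$depth_um) == 0) {
    return(list(r = NA_real_, p = NA_real_, conf_int = c(NA_real_, NA_real_),
                slope = NA_real_, intercept = NA_real_, n = nrow(d),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(d$depth_um, d$engulf_area_pct)
  fit <- stats::lm(engulf_area_pct ~ depth_um, data = d)
  list(r = unname(ct$estimate), p = ct$p.value,
       conf_int = as.numeric(ct$conf.int),
       slope = unname(stats::coef(fit)[2L]),
       slope_ci = as.numeric(stats::confint(fit)["depth_um", ]),
       intercept = unname(stats::coef(fit)[1L]), n = nrow(d),
       degenerate = FALSE)
}

#' Layer-resolved microglia density
#'
#' Assigns each cell to one cortical layer bin by soma depth (default
#' L1: 0-120 um with the 120 um boundary closed, L2/3: >120-300 um) and
#' divides counts by the supplied tissue volumes. Cells deeper than the
#' last bin are excluded with a message.
#'
#' @param depths_um numeric soma depths.
#' @param volumes_um3 named numeric, tissue volume per layer
#'   (same order as the bins).
#' @param breaks_um layer boundaries, default `c(0, 120, 300)`.
#' @param layer_names bin names, default `c("L1", "L2/3")`.
#' @return data.frame with `layer`, `n_cells`, `volume_um3`,
#'   `density_per_um3`.
#' @export
microglia_density <- function(depths_um, volumes_um3,
                              breaks_um = c(0, 120, 300),
                              layer_names = c("L1", "L2/3")) {
  if (any(volumes_um3 <= 0)) stop("volumes must be > 0")
  nbin <- length(breaks_um) - 1L
  stopifnot(length(layer_names) == nbin, length(volumes_um3) == nbin)
  deep <- depths_um > breaks_um[length(breaks_um)]
  if (any(deep)) {
    message(sum(deep), " cell(s) deeper than ", breaks_um[length(breaks_um)],
            " um excluded from density")
  }
  bin <- cut(depths_um, breaks_um, labels = layer_names,
             include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  data.frame(layer = layer_names, n_cells = counts,
             volume_um3 = as.numeric(volumes_um3),
             density_per_um3 = counts / as.numeric(volumes_um3))
}
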