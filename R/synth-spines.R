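#' Mixture specification for synthetic spine-head volumes
#'
#' Tri-modal mixture emulating thin/filopodia, medium, and mushroom/stubby
#' spine populations. Volumes are drawn from truncated-normal components
#' (um3); GFP brightness in the rendered image is proportional to the
#' drawn volume.
#'
#' @param means,sds,weights component parameters; weights are normalized.
#' @return a `SpineVolumeMixture` list.
#' @export
spine_volume_mixture <- function(means = c(0.06, 0.20, 0.55),
                                 sds = c(0.015, 0.05, 0.12),
                                 weights = c(0.25, 0.50, 0.25)) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            all(means > 0), all(sds >= 0), all(weights >= 0))
  structure(list(means = means, sds = sds,
                 weights = weights / sum(weights)),
            class = "SpineVolumeMixture")
}

.draw_volumes <- function(mix, n) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  v <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  bad <- v <= 0
  v[bad] <- mix$means[comp[bad]]
  list(volume = v, component = comp)
}

#' Generate a synthetic dendrite image with protrusions of graded brightness
#'
#' Renders one or more horizontal dendritic shafts with perpendicular
#' protrusions whose intensity is proportional to a drawn spine-head
#' volume, so that the brightness ratio (TIB) is monotonically related to
#' volume. When `n_spines` exceeds what one shaft can carry at a
#' realistic density, additional parallel shaft rows are added to the
#' same image (each an independent segment in the truth).
#'
#' @param n_spines number of protrusions (0 allowed).
#' @param volume_distribution a [spine_volume_mixture()].
#' @param shaft_length_um analyzed shaft length; must lie within
#'   `length_bounds` (default 50-80 um).
#' @param pixel_size_um sampling (default 0.12 um/px, the 40x spine
#'   imaging setup).
#' @param n_planes z planes (protrusions have a random brightest plane).
#' @param noise_sd additive Gaussian noise SD.
#' @param psf_sigma_um blur sigma.
#' @param seed RNG seed.
#' @param length_bounds admissible shaft lengths.
#' @return list with `stack` (single-channel `ImageStack`) and `truth`
#'   (shaft masks per segment, per-protrusion ROI, extent, volume,
#'   mixture component and volume-quantile class).
#' @export
generate_spine_image <- function(n_spines,
                                 volume_distribution = spine_volume_mixture(),
                                 shaft_length_um = 60,
                                 pixel_size_um = 0.12,
                                 n_planes = 3L,
                                 noise_sd = 2,
                                 psf_sigma_um = 0.15,
                                 seed = NULL,
                                 length_bounds = c(50, 80)) {
  if (shaft_length_um < length_bounds[1L] ||
      shaft_length_um > length_bounds[2L]) {
    stop("shaft length must be within [", length_bounds[1L], ", ",
         length_bounds[2L], "] um")
  }
  if (n_spines < 0) stop("`n_spines` must be >= 0")
  ps <- pixel_size_um
  margin <- 3
  spacing_um <- 1.0                      # min inter-protrusion spacing
  usable <- shaft_length_um - 2
  cap <- max(1L, floor(usable / spacing_um))
  n_rows <- max(1L, ceiling(n_spines / cap))
  row_pitch <- 14                        # um between shaft rows
  nx <- as.integer(round((shaft_length_um + 2 * margin) / ps))
  ny <- as.integer(round(row_pitch * n_rows / ps))
  bg <- 10; shaft_amp <- 60; vol_ref <- 0.20
  shaft_hw <- 0.35                       # um half-width
  with_seed(seed, {
    vol <- .draw_volumes(volume_distribution, n_spines)
    # assign protrusions to rows, positions on a jittered grid
    row_of <- rep(seq_len(n_rows), length.out = n_spines)
    prot <- vector("list", n_spines)
    counts <- table(factor(row_of, levels = seq_len(n_rows)))
    pos_in_row <- unlist(lapply(counts, function(k) {
      if (k == 0) return(numeric(0))
      grid <- seq(margin + 1, margin + 1 + usable, length.out = max(k, 2))[seq_len(k)]
      grid + stats::runif(k, -0.3, 0.3)
    }), use.names = FALSE)
    ord <- order(row_of)
    xs <- numeric(n_spines); xs[ord] <- pos_in_row
    planes <- array(0, c(ny, nx, n_planes))
    shaft_masks <- vector("list", n_rows)
    y_rows <- (seq_len(n_rows) - 0.5) * row_pitch
    pxc <- function(um) um / ps + 0.5
    for (r in seq_len(n_rows)) {
      for (z in seq_len(n_planes)) {
        planes[, , z] <- .add_capsule(planes[, , z], pxc(margin),
                                      pxc(y_rows[r]),
                                      pxc(margin + shaft_length_um),
                                      pxc(y_rows[r]), shaft_hw / ps,
                                      shaft_amp)
      }
      shaft_masks[[r]] <- .idx_capsule(ny, nx, pxc(margin), pxc(y_rows[r]),
                                       pxc(margin + shaft_length_um),
                                       pxc(y_rows[r]), shaft_hw / ps)
    }
    truth_prot <- vector("list", n_spines)
    for (i in seq_len(n_spines)) {
      r <- row_of[i]
      side <- sample(c(-1, 1), 1L)
      extent <- stats::runif(1, 0.6, 1.8)      # beyond shaft edge, um
      hw <- stats::runif(1, 0.22, 0.35)
      amp <- shaft_amp * vol$volume[i] / vol_ref
      y0 <- y_rows[r] + side * shaft_hw        # shaft edge
      y1 <- y_rows[r] + side * (shaft_hw + extent)
      zb <- sample.int(n_planes, 1L)
      for (z in seq_len(n_planes)) {
        w <- if (z == zb) 1 else if (abs(z - zb) == 1L) 0.5 else 0.15
        planes[, , z] <- .add_capsule(planes[, , z], pxc(xs[i]), pxc(y0),
                                      pxc(xs[i]), pxc(y1), hw / ps, amp * w)
      }
      roi <- .idx_capsule(ny, nx, pxc(xs[i]), pxc(y0), pxc(xs[i]), pxc(y1),
                          hw / ps)
      roi <- setdiff(roi, shaft_masks[[r]])
      # the protrusion tip reaches extent + cap radius beyond the shaft
      truth_prot[[i]] <- list(id = i, segment = r, x_um = xs[i],
                              side = side, extent_um = extent + hw,
                              extent_px = (extent + hw) / ps,
                              volume_um3 = vol$volume[i],
                              component = vol$component[i],
                              brightest_z = zb, roi_idx = roi)
    }
    # volume-quantile class truth (matches the percentile classifier's
    # convention: boundaries belong to the medium class)
    if (n_spines > 0L) {
      q <- stats::quantile(vol$volume, c(0.25, 0.75), type = 7)
      for (i in seq_len(n_spines)) {
        v <- vol$volume[i]
        truth_prot[[i]]$klass <- if (v < q[1L]) "thin_filopodia"
                                 else if (v > q[2L]) "mushroom_stubby"
                                 else "medium"
      }
    }
    for (z in seq_len(n_planes)) {
      pl <- .blur_plane(planes[, , z], psf_sigma_um / ps) + bg
      if (noise_sd > 0) pl <- pl + stats::rnorm(length(pl), 0, noise_sd)
      planes[, , z] <- pl
    }
    stack <- image_stack(array(planes, c(ny, nx, n_planes, 1L)), ps,
                         z_step_um = 0.3, channel_names = "GFP")
    list(stack = stack,
         truth = list(protrusions = truth_prot,
                      shaft_masks = shaft_masks,
                      shaft_y_um = y_rows,
                      segment_length_um = rep(shaft_length_um, n_rows),
                      dim = c(ny = ny, nx = nx, nz = n_planes),
                      pixel_size_um = ps))
  })
}
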