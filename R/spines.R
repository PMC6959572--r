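#' Protrusion inclusion rule
#'
#' A candidate dendritic protrusion is counted only if it clearly
#' protrudes out of the shaft: its farthest pixel must lie at least
#' `min_extent_px` pixels (default 3, ~0.36 um at 0.12 um/px) from the
#' shaft mask.
#'
#' @param candidate_idx linear pixel indices of the candidate ROI (or a
#'   logical matrix).
#' @param shaft_mask logical matrix of the shaft.
#' @param geom a `PixelGeometry` (used for the reported um extent).
#' @param min_extent_px inclusion threshold in pixels.
#' @param max_gap_px a candidate whose nearest pixel is farther than this
#'   from the shaft is rejected as disjoint.
#' @return list with `keep`, `extent_px`, `extent_um`, `reason`.
#' @export
protrusion_filter <- function(candidate_idx, shaft_mask, geom,
                              min_extent_px = 3, max_gap_px = 5) {
  if (is.matrix(candidate_idx)) candidate_idx <- which(candidate_idx)
  if (length(candidate_idx) == 0L) {
    return(list(keep = FALSE, extent_px = 0, extent_um = 0,
                reason = "empty candidate"))
  }
  # distance of every non-shaft pixel to the shaft
  dmap <- EBImage::distmap(!shaft_mask)
  d <- dmap[candidate_idx]
  if (min(d) > max_gap_px) {
    return(list(keep = FALSE, extent_px = max(d),
                extent_um = pixels_to_um(max(d), geom),
                reason = "disjoint from shaft neighborhood"))
  }
  ext <- max(d)
  list(keep = ext >= min_extent_px, extent_px = ext,
       extent_um = pixels_to_um(ext, geom),
       reason = if (ext >= min_extent_px) NA_character_
                else "below minimum extent")
}

#' Total integrated brightness (TIB) of a protrusion
#'
#' The mean gray value of the spine ROI at its brightest focal plane
#' (argmax over z of the ROI's mean intensity) divided by the mean
#' intensity of the adjacent shaft ROI at the same plane. The ratio is
#' invariant to global intensity scaling and normalizes for imaging
#' conditions; it is a monotone proxy for spine-head volume.
#'
#' @param spine_idx,shaft_idx linear pixel indices of the spine and
#'   adjacent-shaft ROIs in one plane.
#' @param image 3-D `[y, x, z]` intensity array (or a matrix for a single
#'   plane).
#' @return list with `tib`, `brightest_z`, `spine_mean`, `shaft_mean`;
#'   `tib` is `NA` with `undefined = TRUE` when the shaft mean is zero.
#' @export
compute_tib <- function(spine_idx, shaft_idx, image) {
  if (length(spine_idx) == 0L || length(shaft_idx) == 0L) {
    stop("spine and shaft ROIs must be non-empty")
  }
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  nz <- dim(image)[3L]
  npl <- prod(dim(image)[1:2])
  spine_means <- vapply(seq_len(nz),
                        function(z) mean(image[spine_idx + (z - 1L) * npl]),
                        numeric(1))
  zb <- which.max(spine_means)
  sh <- mean(image[shaft_idx + (zb - 1L) * npl])
  if (sh == 0) {
    return(list(tib = NA_real_, brightest_z = zb,
                spine_mean = spine_means[zb], shaft_mean = sh,
                undefined = TRUE))
  }
  list(tib = spine_means[zb] / sh, brightest_z = zb,
       spine_mean = spine_means[zb], shaft_mean = sh, undefined = FALSE)
}

#' Percentile-based spine-type classification
#'
#' Cutoffs are the 25th and 75th percentiles (linear interpolation
#' between order statistics) of a control-condition reference TIB sample;
#' the boundaries are inclusive to the medium class:
#' thin/filopodia below the 25th, mushroom/stubby above the 75th,
#' medium in between.
#'
#' @param tibs numeric TIB values to classify.
#' @param reference control-condition TIB sample defining the cutoffs
#'   (>= 20 values); defaults to `tibs` itself (self-referenced
#'   classification).
#' @return list with `klass` (character vector), `cutoffs`, and `counts`.
#' @export
classify_spines <- function(tibs, reference = tibs) {
  if (length(reference) == 0L) stop("reference sample is empty")
  if (length(reference) < 20L) {
    warning("reference sample smaller than 20; percentile cutoffs unstable")
  }
  q <- stats::quantile(reference, c(0.25, 0.75), type = 7, names = FALSE)
  klass <- ifelse(tibs < q[1L], "thin_filopodia",
                  ifelse(tibs > q[2L], "mushroom_stubby", "medium"))
  counts <- table(factor(klass, levels = c("thin_filopodia", "medium",
                                           "mushroom_stubby")))
  list(klass = klass, cutoffs = c(p25 = q[1L], p75 = q[2L]),
       counts = counts)
}

#' Spine density of a dendritic segment
#'
#' Count of protrusions divided by the analyzed dendritic length, overall
#' and per class; per-class densities sum to the overall density.
#'
#' @param n_spines protrusion count, or a vector of class labels.
#' @param length_um analyzed shaft length (> 0).
#' @return data.frame with `class` (including `"all"`) and
#'   `density_per_um`.
#' @export
spine_density <- function(n_spines, length_um) {
  if (length_um <= 0) stop("`length_um` must be > 0")
  if (is.character(n_spines) || is.factor(n_spines)) {
    tab <- table(n_spines)
    data.frame(class = c("all", names(tab)),
               density_per_um = c(length(n_spines), as.integer(tab)) /
                 length_um)
  } else {
    data.frame(class = "all", density_per_um = n_spines / length_um)
  }
}

#' Quantify protrusions of a synthetic or annotated dendrite image
#'
#' Runs the full spine pipeline on one image: re-checks the protrusion
#' inclusion rule against the shaft, computes TIB at the brightest plane
#' against the adjacent shaft (shaft pixels within `shaft_window_um` of
#' the protrusion base), and returns a tidy per-protrusion table.
#'
#' @param stack single-channel `ImageStack`.
#' @param protrusions list of protrusion records with `roi_idx`,
#'   `segment`, `x_um` (as in the generator truth).
#' @param shaft_masks list of per-segment shaft pixel indices.
#' @param min_extent_px inclusion rule (default 3 px).
#' @param shaft_window_um half-width of the adjacent-shaft window.
#' @return data.frame: `id`, `segment`, `keep`, `extent_px`, `tib`,
#'   `brightest_z`.
#' @export
measure_protrusions <- function(stack, protrusions, shaft_masks,
                                min_extent_px = 3, shaft_window_um = 2) {
  geom <- stack_geometry(stack)
  img <- get_channel(stack, 1L)
  ny <- dim(img)[1L]
  shaft_logical <- lapply(shaft_masks, function(idx) {
    m <- matrix(FALSE, ny, dim(img)[2L]); m[idx] <- TRUE; m
  })
  dmaps <- lapply(shaft_logical, function(m) EBImage::distmap(!m))
  rows <- lapply(protrusions, function(pr) {
    seg <- pr$segment
    d <- dmaps[[seg]][pr$roi_idx]
    ext <- if (length(d)) max(d) else 0
    keep <- length(d) > 0 && min(d) <= 5 && ext >= min_extent_px
    # adjacent shaft: pixels of this segment's shaft near the base x
    sx <- ((shaft_masks[[seg]] - 1L) %/% ny + 1L) * geom$pixel_size_um
    adj <- shaft_masks[[seg]][abs(sx - pr$x_um) <= shaft_window_um]
    tib <- compute_tib(pr$roi_idx, adj, img)
    data.frame(id = pr$id, segment = seg, keep = keep, extent_px = ext,
               tib = tib$tib, brightest_z = tib$brightest_z)
  })
  do.call(rbind, rows)
}
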