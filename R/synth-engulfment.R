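#' Parameters of a synthetic engulfment scene
#'
#' Describes one simulated confocal ROI of mPFC tissue: microglia
#' (Iba1 soma + processes, DAPI nucleus) containing CD68 lysosomes, a
#' fraction of which hold an engulfed PSD-95 punctum, plus free synaptic
#' puncta in the neuropil outside microglia. Defaults are the study
#' conditions: a 280 x 350 um transfected-region ROI sampled at
#' 0.27 um/px with ~14 microglia.
#'
#' @param roi_size_um numeric length-2, (x, y) extent in um.
#' @param n_planes number of z planes.
#' @param pixel_size_um in-plane sampling (um/px).
#' @param z_step_um axial step (um).
#' @param n_microglia microglia count per ROI.
#' @param lysosomes_per_microglia mean CD68 lysosome count per cell
#'   (Poisson).
#' @param engulfment_rate probability in \[0, 1\] that a microglia contains
#'   at least one engulfed postsynaptic punctum.
#' @param free_puncta_density free PSD-95 puncta per um2 of tissue outside
#'   microglia (per plane).
#' @param psf_sigma_um Gaussian blur sigma emulating the PSF (um).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param psd_lysosome_area_scale area factor applied to lysosomes that
#'   receive an engulfed punctum (PSD-95-positive lysosomes are ~1.5-fold
#'   larger than negative ones in tissue).
#' @param seed RNG seed; identical (params, seed) give bit-identical
#'   output.
#' @return An `EngulfmentSceneParams` object.
#' @export
engulfment_scene_params <- function(roi_size_um = c(280, 350),
                                    n_planes = 5L,
                                    pixel_size_um = 0.27,
                                    z_step_um = 0.3,
                                    n_microglia = 14L,
                                    lysosomes_per_microglia = 3,
                                    engulfment_rate = 0.30,
                                    free_puncta_density = 0.3,
                                    psf_sigma_um = 0.2,
                                    noise_sd = 4,
                                    psd_lysosome_area_scale = 1.5,
                                    seed = NULL) {
  stopifnot(length(roi_size_um) == 2L)
  if (any(roi_size_um <= 0) || n_planes < 1 || pixel_size_um <= 0 ||
      z_step_um <= 0) {
    stop("scene dimensions must be positive")
  }
  if (engulfment_rate < 0 || engulfment_rate > 1) {
    stop("`engulfment_rate` must be in [0, 1]")
  }
  if (free_puncta_density < 0 || lysosomes_per_microglia < 0 ||
      n_microglia < 0 || noise_sd < 0) {
    stop("rates, densities and counts must be >= 0")
  }
  structure(list(roi_size_um = roi_size_um, n_planes = as.integer(n_planes),
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 n_microglia = as.integer(n_microglia),
                 lysosomes_per_microglia = lysosomes_per_microglia,
                 engulfment_rate = engulfment_rate,
                 free_puncta_density = free_puncta_density,
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 psd_lysosome_area_scale = psd_lysosome_area_scale,
                 seed = seed),
            class = "EngulfmentSceneParams")
}

# Intensity model shared by the scene renderers. Object amplitudes are
# set so that the default analysis threshold (background median + 5 MAD
# = 30 at the default noise) sits near the half-maximum of blurred
# objects: the binarized footprint then matches the geometric ground
# truth instead of including the PSF skirt.
.scene_amps <- list(background = 10, dapi = 60, iba1 = 60, cd68 = 80,
                    psd95 = 80)

# Draw the geometric description of one scene (no rasterization). All
# coordinates in um. Returns list(cells, free_puncta).
.draw_engulfment_scene <- function(p) {
  X <- p$roi_size_um[1L]; Y <- p$roi_size_um[2L]; nz <- p$n_planes
  margin <- 12
  zc_pool <- if (nz >= 3L) 2:(nz - 1L) else seq_len(nz)
  cells <- vector("list", p$n_microglia)
  placed <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(p$n_microglia)) {
    a <- stats::runif(1, 4.5, 6.5)       # soma semi-axes, um
    b <- stats::runif(1, 3.5, 5.5)
    theta <- stats::runif(1, 0, pi)
    # microglia tile the parenchyma: enforce a minimum soma spacing
    for (try in 1:200) {
      cx <- stats::runif(1, margin, X - margin)
      cy <- stats::runif(1, margin, Y - margin)
      if (nrow(placed) == 0L ||
          min((placed[, 1L] - cx)^2 + (placed[, 2L] - cy)^2) > 25^2) break
    }
    placed <- rbind(placed, c(cx, cy))
    zc <- if (length(zc_pool) == 1L) zc_pool else sample(zc_pool, 1L)
    np <- sample(3:6, 1L)
    ang <- stats::runif(np, 0, 2 * pi)
    procs <- lapply(seq_len(np), function(k) {
      len <- stats::runif(1, 10, 25)
      hw <- stats::runif(1, 0.5, 0.9)
      # start on the soma boundary along the process direction
      er <- 1 / sqrt((cos(ang[k] - theta) / a)^2 + (sin(ang[k] - theta) / b)^2)
      list(x1 = cx + 0.9 * er * cos(ang[k]), y1 = cy + 0.9 * er * sin(ang[k]),
           x2 = cx + (er + len) * cos(ang[k]), y2 = cy + (er + len) * sin(ang[k]),
           halfwidth = hw)
    })
    engulfed <- stats::runif(1) < p$engulfment_rate
    n_lys <- stats::rpois(1, p$lysosomes_per_microglia)
    if (engulfed && n_lys == 0L) n_lys <- 1L
    grow <- if (is.null(p$psd_lysosome_area_scale)) 1
            else sqrt(p$psd_lysosome_area_scale)
    lys <- NULL
    if (n_lys > 0L) {
      lys <- list()
      for (k in seq_len(n_lys)) {
        r <- stats::runif(1, 0.55, 0.95)
        # lysosomes are solid organelles: resample until they clear each
        # other by a PSF-safe margin (allowing for later host growth);
        # a soma holds only as many discrete lysosomes as fit, so a
        # draw that finds no room is dropped
        found_room <- FALSE
        for (try in 1:40) {
          ctr <- .point_in_ellipse(cx, cy, a, b, theta, shrink = 0.55)
          clear <- all(vapply(lys, function(l) {
            sqrt((l$x - ctr[1L])^2 + (l$y - ctr[2L])^2) >
              (l$r + r) * grow + 0.8
          }, logical(1)))
          if (clear) { found_room <- TRUE; break }
        }
        if (found_room) lys[[length(lys) + 1L]] <-
          list(x = ctr[1L], y = ctr[2L], r = r)
      }
      n_lys <- length(lys)
    }
    puncta <- NULL
    if (engulfed) {
      npunc <- 1L + stats::rpois(1, 0.7)
      hosts <- sample.int(n_lys, npunc, replace = TRUE)
      # PSD-positive (host) lysosomes are larger than negative ones
      for (j in unique(hosts)) lys[[j]]$r <- lys[[j]]$r * grow
      # engulfed debris is an aggregate: sized relative to its host
      # lysosome and placed strictly inside it
      puncta <- lapply(seq_len(npunc), function(k) {
        j <- hosts[k]
        rl <- lys[[j]]$r
        rp <- rl * stats::runif(1, 0.45, 0.65)
        phi <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * max(rl - rp - 0.05, 0)
        list(x = lys[[j]]$x + rad * cos(phi),
             y = lys[[j]]$y + rad * sin(phi), r = rp, lysosome = j)
      })
    }
    cells[[i]] <- list(id = i, cx = cx, cy = cy, a = a, b = b, theta = theta,
                       z_plane = zc, processes = procs, lysosomes = lys,
                       engulfed = engulfed, puncta = puncta,
                       psd_positive_lys = if (engulfed)
                         unique(vapply(puncta, `[[`, 0, "lysosome"))
                       else integer(0))
  }
  n_free <- stats::rpois(1, p$free_puncta_density * X * Y)
  free <- data.frame(x = stats::runif(n_free, 0, X),
                     y = stats::runif(n_free, 0, Y),
                     r = stats::runif(n_free, 0.30, 0.40),
                     z_plane = sample.int(nz, n_free, replace = TRUE))
  list(cells = cells, free_puncta = free)
}

#' Generate a synthetic engulfment ROI stack with ground truth
#'
#' Renders the four analysis channels (DAPI, PSD95, Iba1, CD68) of one
#' simulated ROI. Engulfed PSD-95 puncta lie strictly inside a CD68
#' lysosome inside a microglia; free puncta lie outside microglia; the
#' whole scene is Gaussian-blurred and corrupted with additive Gaussian
#' noise on a constant background. The pia is the y = 0 edge, so a soma's
#' cortical depth equals its y coordinate.
#'
#' @param params an [engulfment_scene_params()] object.
#' @return list with `stack` (an `ImageStack`) and `truth`, a ground-truth
#'   list holding per-cell geometry, masks (`cells`, each with `mask_idx`
#'   at its analysis plane), lysosome and punctum tables, engulfed flags,
#'   and the free-puncta table.
#' @export
generate_engulfment_stack <- function(params) {
  stopifnot(inherits(params, "EngulfmentSceneParams"))
  with_seed(params$seed, {
    scene <- .draw_engulfment_scene(params)
    .render_engulfment_scene(scene, params)
  })
}

# Rasterize a drawn scene under the geometry in `p` (uses the RNG for
# noise only; callers manage seeding).
.render_engulfment_scene <- function(scene, p) {
  ps <- p$pixel_size_um
  nx <- as.integer(round(p$roi_size_um[1L] / ps))
  ny <- as.integer(round(p$roi_size_um[2L] / ps))
  nz <- p$n_planes
  {
    # drop free puncta whose center falls inside a cell footprint at its plane
    cell_masks <- lapply(scene$cells, function(cl) .cell_mask(cl, ny, nx, ps))
    if (nrow(scene$free_puncta) > 0L && length(scene$cells) > 0L) {
      keep <- rep(TRUE, nrow(scene$free_puncta))
      j <- pmin(pmax(ceiling(scene$free_puncta$x / ps), 1L), nx)
      i <- pmin(pmax(ceiling(scene$free_puncta$y / ps), 1L), ny)
      lin <- i + (j - 1L) * ny
      for (ci in seq_along(scene$cells)) {
        same_z <- scene$free_puncta$z_plane == scene$cells[[ci]]$z_plane
        keep[same_z & (lin %in% cell_masks[[ci]])] <- FALSE
      }
      scene$free_puncta <- scene$free_puncta[keep, , drop = FALSE]
    }
    vox <- array(0, c(ny, nx, nz, 4L))
    chn <- c("DAPI", "PSD95", "Iba1", "CD68")
    amps <- .scene_amps
    u <- function(um) um / ps          # um -> px scalar
    pxc <- function(um) um / ps + 0.5  # um -> px center coordinate
    zw <- function(zc, dz) if (dz == 0) 1 else 0.55
    for (cl in scene$cells) {
      for (dz in -1:1) {
        z <- cl$z_plane + dz
        if (z < 1L || z > nz) next
        w <- zw(cl$z_plane, dz)
        iba <- vox[, , z, 3L]
        iba <- .add_ellipse(iba, pxc(cl$cx), pxc(cl$cy), u(cl$a), u(cl$b),
                            cl$theta, amps$iba1 * w)
        for (pr in cl$processes) {
          iba <- .add_capsule(iba, pxc(pr$x1), pxc(pr$y1), pxc(pr$x2),
                              pxc(pr$y2), u(pr$halfwidth),
                              amps$iba1 * w * 0.9)
        }
        vox[, , z, 3L] <- iba
        vox[, , z, 1L] <- .add_ellipse(vox[, , z, 1L], pxc(cl$cx), pxc(cl$cy),
                                       u(0.65 * cl$a), u(0.65 * cl$b),
                                       cl$theta, amps$dapi * w)
        if (length(cl$lysosomes)) {
          lx <- vapply(cl$lysosomes, `[[`, 0, "x")
          ly <- vapply(cl$lysosomes, `[[`, 0, "y")
          lr <- vapply(cl$lysosomes, `[[`, 0, "r")
          vox[, , z, 4L] <- .add_discs(vox[, , z, 4L], pxc(lx), pxc(ly),
                                       u(lr), amps$cd68 * (if (dz == 0) 1 else 0.6))
        }
        if (length(cl$puncta)) {
          qx <- vapply(cl$puncta, `[[`, 0, "x")
          qy <- vapply(cl$puncta, `[[`, 0, "y")
          qr <- vapply(cl$puncta, `[[`, 0, "r")
          vox[, , z, 2L] <- .add_discs(vox[, , z, 2L], pxc(qx), pxc(qy),
                                       u(qr), amps$psd95 * (if (dz == 0) 1 else 0.5))
        }
      }
    }
    fp <- scene$free_puncta
    if (nrow(fp) > 0L) {
      for (z in sort(unique(fp$z_plane))) {
        sel <- fp$z_plane == z
        vox[, , z, 2L] <- .add_discs(vox[, , z, 2L], pxc(fp$x[sel]),
                                     pxc(fp$y[sel]), u(fp$r[sel]), amps$psd95)
      }
    }
    sig_px <- p$psf_sigma_um / ps
    for (ci in 1:4) for (z in seq_len(nz)) {
      pl <- .blur_plane(vox[, , z, ci], sig_px) + amps$background
      if (p$noise_sd > 0) pl <- pl + stats::rnorm(length(pl), 0, p$noise_sd)
      vox[, , z, ci] <- pl
    }
    truth_cells <- lapply(seq_along(scene$cells), function(i) {
      cl <- scene$cells[[i]]
      lys <- if (length(cl$lysosomes)) {
        data.frame(x_um = vapply(cl$lysosomes, `[[`, 0, "x"),
                   y_um = vapply(cl$lysosomes, `[[`, 0, "y"),
                   r_um = vapply(cl$lysosomes, `[[`, 0, "r"),
                   psd_positive = seq_along(cl$lysosomes) %in%
                     cl$psd_positive_lys)
      } else data.frame(x_um = numeric(0), y_um = numeric(0),
                        r_um = numeric(0), psd_positive = logical(0))
      pun <- if (length(cl$puncta)) {
        data.frame(x_um = vapply(cl$puncta, `[[`, 0, "x"),
                   y_um = vapply(cl$puncta, `[[`, 0, "y"),
                   r_um = vapply(cl$puncta, `[[`, 0, "r"),
                   lysosome = vapply(cl$puncta, `[[`, 0, "lysosome"),
                   engulfed = TRUE)
      } else NULL
      list(id = cl$id, soma_center_um = c(x = cl$cx, y = cl$cy),
           soma_axes_um = c(long = 2 * max(cl$a, cl$b),
                            short = 2 * min(cl$a, cl$b)),
           z_plane = cl$z_plane, depth_um = cl$cy,
           mask_idx = cell_masks[[i]], engulfed = cl$engulfed,
           lysosomes = lys, puncta = pun)
    })
    stack <- image_stack(vox, ps, p$z_step_um, chn)
    list(stack = stack,
         truth = list(cells = truth_cells, free_puncta = scene$free_puncta,
                      dim = c(ny = ny, nx = nx, nz = nz), params = p))
  }
}

# Scale all physical coordinates and object sizes of a drawn scene by a
# linear factor (isotropic in-plane expansion).
.scale_scene <- function(scene, f) {
  scene$cells <- lapply(scene$cells, function(cl) {
    cl$cx <- cl$cx * f; cl$cy <- cl$cy * f
    cl$a <- cl$a * f; cl$b <- cl$b * f
    cl$processes <- lapply(cl$processes, function(pr) {
      pr$x1 <- pr$x1 * f; pr$y1 <- pr$y1 * f
      pr$x2 <- pr$x2 * f; pr$y2 <- pr$y2 * f
      pr$halfwidth <- pr$halfwidth * f
      pr
    })
    cl$lysosomes <- lapply(cl$lysosomes, function(l) {
      l$x <- l$x * f; l$y <- l$y * f; l$r <- l$r * f; l
    })
    if (!is.null(cl$puncta)) {
      cl$puncta <- lapply(cl$puncta, function(q) {
        q$x <- q$x * f; q$y <- q$y * f; q$r <- q$r * f; q
      })
    }
    cl
  })
  if (nrow(scene$free_puncta) > 0L) {
    scene$free_puncta$x <- scene$free_puncta$x * f
    scene$free_puncta$y <- scene$free_puncta$y * f
    scene$free_puncta$r <- scene$free_puncta$r * f
  }
  scene
}

# Pixel-index footprint (soma + processes) of one drawn cell at its plane.
.cell_mask <- function(cl, ny, nx, ps) {
  pxc <- function(um) um / ps + 0.5
  idx <- .idx_ellipse(ny, nx, pxc(cl$cx), pxc(cl$cy), cl$a / ps, cl$b / ps,
                      cl$theta)
  for (pr in cl$processes) {
    idx <- c(idx, .idx_capsule(ny, nx, pxc(pr$x1), pxc(pr$y1), pxc(pr$x2),
                               pxc(pr$y2), pr$halfwidth / ps))
  }
  sort(unique(idx))
}

#' Microglia cell records from generator ground truth
#'
#' Convert the ground-truth cells of [generate_engulfment_stack()] into the
#' `MicrogliaCell` objects consumed by the engulfment scoring functions
#' (the analysis-side analogue of manual cell tracing).
#'
#' @param truth the `truth` element returned by the generator.
#' @return list of `MicrogliaCell` objects.
#' @export
microglia_cells_from_truth <- function(truth) {
  geom <- pixel_geometry(truth$params$pixel_size_um, truth$params$z_step_um)
  lapply(truth$cells, function(cl) {
    microglia_cell(mask_idx = cl$mask_idx,
                   dim = truth$dim[c("ny", "nx")],
                   z_plane = cl$z_plane,
                   soma_center_um = cl$soma_center_um,
                   cortical_depth_um = cl$depth_um,
                   geom = geom, cell_id = cl$id)
  })
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth a generator `truth` list.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  slim <- truth
  slim$cells <- lapply(truth$cells, function(cl) {
    cl$mask_idx <- NULL   # masks are reproducible from params + seed
    cl
  })
  slim$params <- unclass(slim$params)
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
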