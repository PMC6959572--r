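# Small scene used by several generator checks (not the study-scale ROI;
# the acceptance checks use the defaults).
small_scene <- function(...) {
  engulfment_scene_params(roi_size_um = c(80, 80), n_microglia = 3L, ...)
}

test_that("generators are deterministic given a seed", {
  a <- generate_engulfment_stack(small_scene(seed = 4))
  b <- generate_engulfment_stack(small_scene(seed = 4))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$free_puncta, b$truth$free_puncta)
  ta <- generate_mpsc_trace(3, duration_s = 5, seed = 9)
  tb <- generate_mpsc_trace(3, duration_s = 5, seed = 9)
  expect_identical(ta$trace$samples, tb$trace$samples)
  ar <- arena_config(50, 50, zones = list(
    z1 = list(type = "disc", center = c(10, 10), radius = 8)))
  wa <- generate_trajectory(ar, duration_s = 10, seed = 2)
  wb <- generate_trajectory(ar, duration_s = 10, seed = 2)
  expect_identical(wa$traj$x, wb$traj$x)
})

test_that("empty and saturated engulfment scenes behave as stated", {
  # no engulfment, no free puncta: PSD channel is pure background noise
  g0 <- generate_engulfment_stack(small_scene(engulfment_rate = 0,
                                              free_puncta_density = 0,
                                              seed = 1))
  psd <- get_channel(g0$stack, "PSD95")
  expect_lt(max(psd), 10 + 6 * 4)          # background + 6 SD
  cells <- microglia_cells_from_truth(g0$truth)
  sc <- score_engulfment_roi(g0$stack, cells)
  expect_equal(sc$summary$pct_positive, 0)
  # saturation: every microglia flagged engulfment-positive in truth
  g1 <- generate_engulfment_stack(small_scene(engulfment_rate = 1,
                                              seed = 2))
  expect_true(all(vapply(g1$truth$cells, `[[`, TRUE, "engulfed")))
})

test_that("ground-truth engulfment frequency follows the binomial draw", {
  g <- generate_engulfment_stack(
    engulfment_scene_params(n_microglia = 200L, engulfment_rate = 0.3,
                            seed = 1))
  frac <- mean(vapply(g$truth$cells, `[[`, TRUE, "engulfed"))
  ci <- 1.96 * sqrt(0.3 * 0.7 / 200)
  expect_gt(frac, 0.3 - ci)
  expect_lt(frac, 0.3 + ci)
})

test_that("rendered objects agree with ground truth at half-max threshold", {
  # thresholding each object's channel halfway between its own level
  # and the background floor (10) must recover >= 95% of the truth
  # pixels, pooled over cells and lysosomes
  g <- generate_engulfment_stack(small_scene(noise_sd = 0,
                                             engulfment_rate = 1,
                                             seed = 6))
  iba <- get_channel(g$stack, "Iba1")
  cd <- get_channel(g$stack, "CD68")
  ps <- g$stack$pixel_size_um
  ny <- dim(iba)[1]; nx <- dim(iba)[2]
  hit <- 0; tot <- 0
  for (cl in g$truth$cells) {
    pl <- iba[, , cl$z_plane]
    thr <- (stats::median(pl[cl$mask_idx]) + 10) / 2
    hit <- hit + sum(pl[cl$mask_idx] >= thr)
    tot <- tot + length(cl$mask_idx)
    cdp <- cd[, , cl$z_plane]
    for (k in seq_len(nrow(cl$lysosomes))) {
      idx <- synaptoglia:::.idx_ellipse(
        ny, nx, cl$lysosomes$x_um[k] / ps + 0.5,
        cl$lysosomes$y_um[k] / ps + 0.5,
        cl$lysosomes$r_um[k] / ps, cl$lysosomes$r_um[k] / ps)
      thr <- (max(cdp[idx]) + 10) / 2
      hit <- hit + sum(cdp[idx] >= thr)
      tot <- tot + length(idx)
    }
  }
  expect_gte(hit / tot, 0.95)
})

test_that("mPSC generator hits its Poisson event budget and noiseless peak", {
  g <- generate_mpsc_trace(5, duration_s = 60, seed = 3)
  expect_gt(nrow(g$truth), 300 - 1.96 * sqrt(300))
  expect_lt(nrow(g$truth), 300 + 1.96 * sqrt(300))
  # rate 0 -> pure noise, empty truth
  g0 <- generate_mpsc_trace(0, duration_s = 2, seed = 1)
  expect_equal(nrow(g0$truth), 0L)
  # a single noiseless event peaks at amp_mean at the kernel peak time
  g1 <- generate_mpsc_trace(1 / 50, amp_cv = 0, noise_sd_pA = 0,
                            duration_s = 50, fs_hz = 10000, seed = 15)
  stopifnot(nrow(g1$truth) >= 1)
  expect_equal(min(g1$trace$samples), -20, tolerance = 0.01)
  pk_idx <- which.min(g1$trace$samples)
  expect_lt(abs((pk_idx - 1) / 10000 - g1$truth$t_peak_s[1]), 2e-4)
  # unresolvable rise is refused
  expect_error(generate_mpsc_trace(1, rise_ms = 0.5, fs_hz = 2000),
               "rise")
})

test_that("test-pulse transients follow the RC circuit closed form", {
  tp <- generate_test_pulse(10, 150, 100, dV_mV = -5)
  w <- tp$step_window
  expect_equal(tp$samples[w[1]], -500)            # dV/Rs at t = 0
  expect_equal(tp$samples[w[2]], -5 / 160 * 1000, # dV/(Rs+Rm)
               tolerance = 1e-3)
  # decay constant: fit log-linear on the noiseless transient
  seg <- tp$samples[w[1]:w[2]] - tp$samples[w[2]]
  n <- sum(seg / seg[1] > 0.01)
  fit <- stats::lm(log(seg[1:n] / seg[1]) ~ I(0:(n - 1)))
  tau_ms <- unname(-1 / stats::coef(fit)[2] / 10000 * 1000)
  expect_equal(tau_ms, 0.9375, tolerance = 0.01)
  expect_error(generate_test_pulse(0, 150, 100), "> 0")
})

test_that("trajectory generator respects zone preferences and bounds", {
  ar <- arena_config(50, 50, fps = 30, zones = list(
    left = list(type = "rect", xmin = 0, xmax = 10, ymin = 20, ymax = 30),
    right = list(type = "rect", xmin = 40, xmax = 50, ymin = 20,
                 ymax = 30)))
  # uniform weights: equal-area zones get equal long-run occupancy
  g <- generate_trajectory(ar, duration_s = 600, seed = 8)
  occ <- g$truth
  p <- occ$proportion[match(c("left", "right"), occ$zone)]
  expect_lt(abs(p[1] - p[2]), 0.035)
  expect_true(all(g$traj$x >= 0 & g$traj$x <= 50))
  # locked preference: DI = 1 for the locked-vs-other pair
  gl <- generate_trajectory(ar, duration_s = 60, start = c(5, 25),
                            lock_zone = "left", seed = 3)
  t_in <- gl$truth$time_s[match(c("left", "right"), gl$truth$zone)]
  expect_equal(discrimination_index(t_in[1], t_in[2]), 1)
  # latency truth equals first frame in zone / fps by construction
  gs <- generate_trajectory(ar, duration_s = 60, start = c(25, 25),
                            seed = 5)
  am <- approach_metrics(gs$traj, ar)
  inz <- zone_of(gs$traj, ar)
  for (nm in c("left", "right")) {
    first <- which(inz == nm)[1]
    expect_equal(am$latency_s[[nm]],
                 if (is.na(first)) NA_real_ else gs$traj$t[first])
  }
})

test_that("spine generator degenerate cases: empty image and equal volumes", {
  g0 <- generate_spine_image(0, seed = 1)
  expect_length(g0$truth$protrusions, 0)
  # all volumes equal -> all TIB values equal within noise tolerance
  mix <- spine_volume_mixture(means = 0.2, sds = 0, weights = 1)
  ge <- generate_spine_image(30, volume_distribution = mix, seed = 4)
  m <- measure_protrusions(ge$stack, ge$truth$protrusions,
                           ge$truth$shaft_masks)
  expect_lt(stats::sd(m$tib) / mean(m$tib), 0.06)
})

test_that("ExM pair at factor 1 reproduces the pre-expansion scene", {
  pair <- generate_exm_pair(1, seed = 11,
    scene = engulfment_scene_params(roi_size_um = c(60, 60),
                                    n_microglia = 2L,
                                    free_puncta_density = 0.05,
                                    pixel_size_um = 0.155))
  ax <- pair$truth$soma_axes
  expect_equal(ax$post_long_um, ax$pre_long_um)
  expect_equal(ax$post_short_um, ax$pre_short_um)
  expect_error(generate_exm_pair(0.8), ">= 1")
})

test_that("ground truth can be written as a JSON sidecar", {
  g <- generate_engulfment_stack(small_scene(seed = 3))
  path <- file.path(tempdir(), "truth.json")
  write_ground_truth(g$truth, path)
  back <- jsonlite::read_json(path)
  expect_length(back$cells, length(g$truth$cells))
  unlink(path)
})
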