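test_that("passive properties recover the RC circuit parameters", {
  # noiseless: within 2% (and the Ohm's-law anchor Rs = dV/I_peak)
  pp <- passive_properties(generate_test_pulse(10, 150, 100))
  expect_equal(pp$Rs_MOhm, 10, tolerance = 0.02)
  expect_equal(pp$Rm_MOhm, 150, tolerance = 0.02)
  expect_equal(pp$Cm_pF, 100, tolerance = 0.02)
  expect_equal(pp$tau_ms, 0.9375, tolerance = 0.02)
  expect_equal(pp$I_peak_pA, -500, tolerance = 0.01)
  # 50-sweep average at 5 pA noise: within 5%
  sweeps <- lapply(1:50, function(s)
    generate_test_pulse(10, 150, 100, noise_sd_pA = 5, seed = 700 + s))
  avg <- sweeps[[1]]
  avg$samples <- rowMeans(vapply(sweeps, `[[`,
                                 numeric(length(avg$samples)), "samples"))
  ppn <- passive_properties(avg)
  expect_equal(ppn$Rs_MOhm, 10, tolerance = 0.05)
  expect_equal(ppn$Rm_MOhm, 150, tolerance = 0.05)
  expect_equal(ppn$Cm_pF, 100, tolerance = 0.05)
  expect_error(passive_properties(
    sweep_trace(numeric(100), 1e4, "voltage_clamp")), "window")
})

test_that("a single noiseless event is detected at its true peak", {
  g <- generate_mpsc_trace(0, noise_sd_pA = 0, duration_s = 3, seed = 1)
  tr <- g$trace
  ker <- -20 * synaptoglia:::.psc_kernel(0.5, 5, 10000)
  tr$samples[10001:(10000 + length(ker))] <- ker
  ev <- detect_mpsc(tr)
  expect_equal(nrow(ev), 1L)
  true_peak <- 1 + synaptoglia:::.psc_peak_delay(0.5, 5)
  expect_lt(abs(ev$t_peak_s - true_peak), 1.01e-4)   # +- 1 sample
  expect_equal(ev$amplitude_pA, 20, tolerance = 0.02)
  expect_equal(ev$decay_tau_ms, 5, tolerance = 0.05)
  expect_error(detect_mpsc(sweep_trace(numeric(10), 1e4,
                                       "voltage_clamp")), "longer")
})

test_that("detection achieves recall and precision >= 0.9 at SNR 5", {
  g <- generate_mpsc_trace(5, amp_mean_pA = 20, amp_cv = 0,
                           noise_sd_pA = 4, duration_s = 60, seed = 3)
  ev <- detect_mpsc(g$trace, with_kinetics = FALSE)
  tol <- 0.003
  recall <- mean(vapply(g$truth$t_peak_s, function(t)
    any(abs(ev$t_peak_s - t) < tol), logical(1)))
  precision <- mean(vapply(ev$t_peak_s, function(t)
    any(abs(g$truth$t_peak_s - t) < tol), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # frequency estimate within 10% of the generator rate at 120 s
  g2 <- generate_mpsc_trace(5, amp_mean_pA = 20, amp_cv = 0,
                            noise_sd_pA = 4, duration_s = 120, seed = 8)
  n2 <- nrow(detect_mpsc(g2$trace, with_kinetics = FALSE))
  expect_lt(abs(n2 / 120 - 5) / 5, 0.10)
})

test_that("false positives on pure noise stay below 0.2 events/s", {
  rates <- vapply(1:3, function(s) {
    g <- generate_mpsc_trace(0, noise_sd_pA = 4, duration_s = 30,
                             seed = 500 + s)
    nrow(detect_mpsc(g$trace, with_kinetics = FALSE)) / 30
  }, numeric(1))
  expect_lte(mean(rates), 0.2)
})

test_that("event kinetics scale linearly and flag edge events", {
  mk <- function(amp) {
    tr <- sweep_trace(numeric(30000), 10000, "voltage_clamp")
    ker <- -amp * synaptoglia:::.psc_kernel(0.5, 5, 10000)
    tr$samples[10001:(10000 + length(ker))] <- ker
    tr
  }
  t_pk <- 1 + synaptoglia:::.psc_peak_delay(0.5, 5)
  k1 <- event_kinetics(mk(20), t_pk)
  k2 <- event_kinetics(mk(40), t_pk)
  expect_equal(k2$amplitude_pA / k1$amplitude_pA, 2, tolerance = 0.01)
  expect_equal(k2$rise_10_90_ms, k1$rise_10_90_ms, tolerance = 0.02)
  expect_equal(k2$decay_tau_ms, k1$decay_tau_ms, tolerance = 0.02)
  # an event with its decay cut off at the trace edge is flagged
  tre <- mk(20)
  tre$samples <- tre$samples[1:10030]
  ke <- event_kinetics(tre, t_pk)
  expect_true(ke$flagged)
})

test_that("detection and kinetics are invariant to a DC offset", {
  g <- generate_mpsc_trace(4, amp_cv = 0, noise_sd_pA = 4,
                           duration_s = 20, seed = 17)
  ev0 <- detect_mpsc(g$trace)
  tr <- g$trace
  tr$samples <- tr$samples + 50
  ev1 <- detect_mpsc(tr)
  expect_equal(ev1$t_peak_s, ev0$t_peak_s)
  expect_equal(ev1$amplitude_pA, ev0$amplitude_pA, tolerance = 1e-9)
})

test_that("rheobase matches the analytic LIF threshold on the step grid", {
  grid <- seq(-200, 400, by = 15)
  sweeps <- lapply(grid, simulate_lif_sweep)
  fi <- fi_analysis(sweeps)
  analytic <- lif_analytic_rheobase()          # 200 pA
  expect_equal(fi$rheobase_pA, grid[grid > analytic][1])   # 205
  expect_true(all(fi$steps$n_ap[fi$steps$step_pA < analytic] == 0))
  # shuffled sweep order gives identical results
  set.seed(2)
  fi_sh <- fi_analysis(sample(sweeps))
  expect_equal(fi_sh$steps, fi$steps)
  expect_equal(fi_sh$rheobase_pA, fi$rheobase_pA)
  # all-subthreshold family: no APs, rheobase missing
  sub <- lapply(seq(-200, 100, by = 15), simulate_lif_sweep)
  fis <- fi_analysis(sub)
  expect_true(all(fis$steps$n_ap == 0))
  expect_true(is.na(fis$rheobase_pA))
})

test_that("distribution comparison flags a planted IEI shift and amplitude scale", {
  # identical samples: KS statistic 0
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  same <- distribution_compare(x, x, "iei")
  expect_equal(same$ks_statistic, 0)
  expect_error(distribution_compare(1:3, 1:10), "at least 5")
  # a 0.4x event-rate arm shifts the IEI distribution (KS significant)
  ga <- generate_mpsc_trace(5, amp_cv = 0, duration_s = 60, seed = 71)
  gb <- generate_mpsc_trace(2, amp_cv = 0, duration_s = 60, seed = 72)
  ea <- detect_mpsc(ga$trace, with_kinetics = FALSE)
  eb <- detect_mpsc(gb$trace, with_kinetics = FALSE)
  ks <- distribution_compare(ea$iei_s[-1], eb$iei_s[-1], "iei")
  expect_lt(ks$p_value, 0.01)
  expect_gt(ks$mean_b, ks$mean_a)
  # an 18% amplitude shift is recovered in the group means
  gc <- generate_mpsc_trace(5, amp_mean_pA = 23.6, amp_cv = 0,
                            duration_s = 60, seed = 73)
  ec <- detect_mpsc(gc$trace, with_kinetics = FALSE)
  cmp <- distribution_compare(ea$amplitude_pA, ec$amplitude_pA,
                              "amplitude")
  expect_equal(cmp$mean_b / cmp$mean_a, 1.18, tolerance = 0.05)
})

test_that("traces round-trip through the CSV interchange format", {
  g <- generate_mpsc_trace(2, duration_s = 2, seed = 5)
  path <- file.path(tempdir(), "trace.csv")
  write_trace_csv(g$trace, path)
  back <- read_trace_csv(path)
  expect_equal(back$samples, g$trace$samples, tolerance = 1e-6)
  expect_equal(back$fs_hz, 10000)
  expect_equal(back$mode, "voltage_clamp")
  unlink(path)
})
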