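#' Whole-cell sweep container
#'
#' A sampled current or voltage trace with acquisition metadata.
#'
#' @param samples numeric vector (pA in voltage clamp, mV in current
#'   clamp); must be finite.
#' @param fs_hz sampling rate, > 0.
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param holding_mV holding potential (voltage clamp).
#' @param step_pA command-step amplitude (current clamp).
#' @param step_window two sample indices `(on, off)` of the command step.
#' @return a `SweepTrace` object.
#' @export
sweep_trace <- function(samples, fs_hz,
                        mode = c("voltage_clamp", "current_clamp"),
                        holding_mV = NA_real_, step_pA = NA_real_,
                        step_window = NULL) {
  mode <- match.arg(mode)
  if (fs_hz <= 0) stop("`fs_hz` must be > 0")
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, mode = mode,
                 holding_mV = holding_mV, step_pA = step_pA,
                 step_window = step_window),
            class = "SweepTrace")
}

#' @export
print.SweepTrace <- function(x, ...) {
  cat(sprintf("SweepTrace (%s): %d samples @ %g kHz (%.3g s)\n",
              x$mode, length(x$samples), x$fs_hz / 1000,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

# Difference-of-exponentials synaptic kernel, normalized to unit peak.
# Returns the kernel sampled at fs from t = 0 with the given duration.
.psc_kernel <- function(rise_ms, decay_ms, fs_hz,
                        duration_ms = rise_ms + 5 * decay_ms) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  t <- seq(0, duration_ms / 1000, by = 1 / fs_hz)
  k <- exp(-t / td) - exp(-t / tr)
  k / max(k)
}

# Time of the kernel peak after onset, seconds.
.psc_peak_delay <- function(rise_ms, decay_ms) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  log(td / tr) * tr * td / (td - tr)
}

#' Generate a miniature-PSC train on a noisy baseline
#'
#' Poisson event train of difference-of-exponential synaptic currents on
#' Gaussian noise, emulating a voltage-clamp recording digitized at
#' 10 kHz. mEPSCs at -70 mV are inward, so events are negative-going by
#' default; amplitudes are reported as magnitudes in the ground truth.
#'
#' @param rate_hz mean event rate, >= 0.
#' @param amp_mean_pA mean event amplitude (magnitude).
#' @param amp_cv coefficient of variation of amplitudes (lognormal).
#' @param rise_ms,decay_ms kernel time constants; `decay > rise > 0`.
#' @param noise_sd_pA baseline Gaussian noise SD.
#' @param duration_s trace length.
#' @param fs_hz sampling rate (default 10 kHz); the rise time must span
#'   at least 2 samples.
#' @param polarity -1 for inward (default), +1 for outward events.
#' @param seed RNG seed.
#' @return list with `trace` (a `SweepTrace`) and `truth`
#'   (data.frame `t_onset_s`, `t_peak_s`, `amplitude_pA`).
#' @export
generate_mpsc_trace <- function(rate_hz, amp_mean_pA = 20, amp_cv = 0.3,
                                rise_ms = 0.5, decay_ms = 5,
                                noise_sd_pA = 4, duration_s = 60,
                                fs_hz = 10000, polarity = -1,
                                seed = NULL) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0")
  if (!(decay_ms > rise_ms && rise_ms > 0)) stop("need decay > rise > 0")
  if (rise_ms / 1000 * fs_hz < 2) {
    stop("sampling rate too low to resolve the rise time (< 2 samples)")
  }
  n <- as.integer(round(duration_s * fs_hz))
  with_seed(seed, {
    x <- if (noise_sd_pA > 0) stats::rnorm(n, 0, noise_sd_pA) else numeric(n)
    n_ev <- stats::rpois(1, rate_hz * duration_s)
    truth <- data.frame(t_onset_s = numeric(0), t_peak_s = numeric(0),
                        amplitude_pA = numeric(0))
    if (n_ev > 0) {
      ker <- .psc_kernel(rise_ms, decay_ms, fs_hz)
      t_on <- sort(stats::runif(n_ev, 0, duration_s))
      if (amp_cv > 0) {
        sdl <- sqrt(log(1 + amp_cv^2))
        amps <- stats::rlnorm(n_ev, log(amp_mean_pA) - sdl^2 / 2, sdl)
      } else amps <- rep(amp_mean_pA, n_ev)
      for (e in seq_len(n_ev)) {
        i0 <- as.integer(floor(t_on[e] * fs_hz)) + 1L
        idx <- i0:min(n, i0 + length(ker) - 1L)
        x[idx] <- x[idx] + polarity * amps[e] * ker[seq_along(idx)]
      }
      truth <- data.frame(
        t_onset_s = t_on,
        t_peak_s = t_on + .psc_peak_delay(rise_ms, decay_ms),
        amplitude_pA = amps)
    }
    list(trace = sweep_trace(x, fs_hz, "voltage_clamp", holding_mV = -70),
         truth = truth)
  })
}

#' Generate a seal-test current transient (-5 mV pulse)
#'
#' Current response of the series-resistance / parallel-RC pipette-cell
#' circuit to a voltage step dV: instantaneous peak `dV/Rs`, steady state
#' `dV/(Rs+Rm)`, and a single-exponential relaxation with
#' `tau = Cm * Rs*Rm/(Rs+Rm)`. Units: MOhm, pF, mV, pA, so
#' `I[pA] = 1000 * dV[mV] / R[MOhm]` and `tau[ms] = Cm[pF] *
#' R[MOhm] / 1000`.
#'
#' @param Rs_MOhm,Rm_MOhm,Cm_pF circuit parameters, all > 0.
#' @param dV_mV step amplitude (default -5 mV).
#' @param fs_hz sampling rate (default 10 kHz).
#' @param noise_sd_pA additive noise SD.
#' @param pre_s,pulse_s,post_s segment durations.
#' @param seed RNG seed.
#' @return a `SweepTrace` (voltage clamp) with `step_window` marking the
#'   pulse samples.
#' @export
generate_test_pulse <- function(Rs_MOhm, Rm_MOhm, Cm_pF, dV_mV = -5,
                                fs_hz = 10000, noise_sd_pA = 0,
                                pre_s = 0.02, pulse_s = 0.1, post_s = 0.02,
                                seed = NULL) {
  if (Rs_MOhm <= 0 || Rm_MOhm <= 0 || Cm_pF <= 0) {
    stop("RC parameters must be > 0")
  }
  n_pre <- round(pre_s * fs_hz); n_pulse <- round(pulse_s * fs_hz)
  n_post <- round(post_s * fs_hz)
  tau_s <- Cm_pF * (Rs_MOhm * Rm_MOhm / (Rs_MOhm + Rm_MOhm)) * 1e-6
  i_peak <- 1000 * dV_mV / Rs_MOhm                    # pA at t = 0+
  i_ss <- 1000 * dV_mV / (Rs_MOhm + Rm_MOhm)
  t <- (seq_len(n_pulse) - 1) / fs_hz                 # pulse onset at t = 0
  pulse <- i_ss + (i_peak - i_ss) * exp(-t / tau_s)
  # relaxation back to baseline after the step ends
  t2 <- (seq_len(n_post) - 1) / fs_hz
  post <- (i_ss - i_peak) * exp(-t2 / tau_s)
  x <- c(numeric(n_pre), pulse, post)
  with_seed(seed, {
    if (noise_sd_pA > 0) x <- x + stats::rnorm(length(x), 0, noise_sd_pA)
    sweep_trace(x, fs_hz, "voltage_clamp",
                step_window = c(n_pre + 1L, n_pre + n_pulse))
  })
}

#' Write / read a sweep as CSV with sampling-rate metadata
#'
#' Plain-text trace interchange: columns `time_s` and `value` with
#' header comment lines carrying `fs_hz` and `mode`.
#'
#' @param trace a `SweepTrace`.
#' @param path output `.csv` path.
#' @return `write_trace_csv`: the path, invisibly; `read_trace_csv`: a
#'   `SweepTrace`.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs_hz=%g", trace$fs_hz),
               sprintf("# mode=%s", trace$mode)), con)
  utils::write.table(
    data.frame(time_s = (seq_along(trace$samples) - 1) / trace$fs_hz,
               value = trace$samples),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  kv <- sub("^# *", "", meta)
  vals <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  sweep_trace(df$value, fs_hz = as.numeric(vals[["fs_hz"]]),
              mode = if ("mode" %in% names(vals)) vals[["mode"]]
                     else "voltage_clamp")
}
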