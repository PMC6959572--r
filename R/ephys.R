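#' Detect miniature postsynaptic currents by scaled-template matching
#'
#' Clements-Bekkers sliding template detection: at every offset the
#' difference-of-exponentials template is optimally scaled and offset to
#' the data, and the detection criterion is the scale divided by its
#' standard error. Detections above the criterion threshold are reduced
#' to local criterion maxima; maxima closer than one template
#' rise-to-peak are merged to the larger. Events are returned in time
#' order with inter-event intervals.
#'
#' @param trace a voltage-clamp `SweepTrace`.
#' @param rise_ms,decay_ms template time constants (defaults 0.5/5 ms,
#'   an EPSC-like template; use ~1/10 for IPSCs).
#' @param criterion_threshold detection criterion (default 3.5).
#' @param polarity -1 for inward events (default), +1 for outward.
#' @param with_kinetics also run [event_kinetics()] per event.
#' @return data.frame of events: `t_peak_s`, `criterion`,
#'   `amplitude_pA`, `iei_s` (NA for the first event), and kinetics
#'   columns when requested.
#' @export
detect_mpsc <- function(trace, rise_ms = 0.5, decay_ms = 5,
                        criterion_threshold = 3.5, polarity = -1,
                        with_kinetics = TRUE) {
  stopifnot(inherits(trace, "SweepTrace"))
  x <- trace$samples
  fs <- trace$fs_hz
  p <- polarity * .psc_kernel(rise_ms, decay_ms, fs,
                              duration_ms = rise_ms + 3 * decay_ms)
  L <- length(p)
  N <- length(x)
  if (L >= N) stop("template longer than trace")
  nw <- N - L + 1L
  # running sums over windows of length L, aligned to window start
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x * x))
  Sx <- cs[(L + 1L):(N + 1L)] - cs[1:nw]
  Sxx <- cs2[(L + 1L):(N + 1L)] - cs2[1:nw]
  f <- stats::filter(x, rev(p), method = "convolution", sides = 1)
  Spx <- as.numeric(f)[L:N]
  Sp <- sum(p); Spp <- sum(p * p)
  denom <- Spp - Sp * Sp / L
  scale <- (Spx - Sp * Sx / L) / denom
  offset <- (Sx - scale * Sp) / L
  sse <- Sxx + scale^2 * Spp + L * offset^2 -
    2 * (scale * Spx + offset * Sx - scale * offset * Sp)
  sse[sse < 0] <- 0
  se <- sqrt(sse / (L - 1))        # residual standard error of the fit
  crit <- scale / se
  crit[!is.finite(crit)] <- 0
  above <- crit > criterion_threshold
  if (!any(above)) {
    return(data.frame(t_peak_s = numeric(0), criterion = numeric(0),
                      amplitude_pA = numeric(0), iei_s = numeric(0)))
  }
  # local criterion maxima of above-threshold runs
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  onsets <- integer(0); crits <- numeric(0)
  for (k in which(runs$values)) {
    w <- starts[k]:ends[k]
    onsets <- c(onsets, w[which.max(crit[w])])
    crits <- c(crits, max(crit[w]))
  }
  # merge detections within one template rise-to-peak, keep the larger
  min_sep <- max(2L, as.integer(round(.psc_peak_delay(rise_ms, decay_ms) * fs)))
  keep <- logical(length(onsets))
  i <- 1L
  while (i <= length(onsets)) {
    j <- i
    while (j < length(onsets) && onsets[j + 1L] - onsets[j] < min_sep) j <- j + 1L
    grp <- i:j
    keep[grp[which.max(crits[grp])]] <- TRUE
    i <- j + 1L
  }
  onsets <- onsets[keep]
  crits <- crits[keep]
  # event peak: polarity extremum within two rise-to-peak delays of onset
  pk_win <- 2L * min_sep
  peaks <- vapply(onsets, function(o) {
    w <- o:min(N, o + pk_win)
    w[which.max(polarity * x[w])]
  }, integer(1))
  ord <- order(peaks)
  peaks <- peaks[ord]; crits <- crits[ord]
  # residual duplicates (criterion re-firing on the decay phase) resolve
  # to nearby peaks: keep the stronger of any pair closer than one
  # rise-to-peak plus a rise
  dd_win <- min_sep + as.integer(round(rise_ms / 1000 * fs))
  keep <- logical(length(peaks))
  i <- 1L
  while (i <= length(peaks)) {
    j <- i
    while (j < length(peaks) && peaks[j + 1L] - peaks[j] < dd_win) j <- j + 1L
    grp <- i:j
    keep[grp[which.max(crits[grp])]] <- TRUE
    i <- j + 1L
  }
  peaks <- peaks[keep]; crits <- crits[keep]
  out <- data.frame(t_peak_s = (peaks - 1L) / fs, criterion = crits)
  if (with_kinetics) {
    kin <- lapply(peaks, function(pk) {
      event_kinetics(trace, (pk - 1L) / fs, rise_ms = rise_ms,
                     decay_ms = decay_ms, polarity = polarity)
    })
    out$amplitude_pA <- vapply(kin, `[[`, 0, "amplitude_pA")
    out$rise_10_90_ms <- vapply(kin, `[[`, 0, "rise_10_90_ms")
    out$decay_tau_ms <- vapply(kin, `[[`, 0, "decay_tau_ms")
    out$flagged <- vapply(kin, `[[`, TRUE, "flagged")
  } else {
    out$amplitude_pA <- vapply(peaks, function(pk) {
      b0 <- max(1L, pk - as.integer(0.01 * fs) - min_sep)
      abs(x[pk] - stats::median(x[b0:max(b0, pk - min_sep)]))
    }, numeric(1))
  }
  out$iei_s <- c(NA, diff(out$t_peak_s))
  out
}

#' Amplitude and kinetics of one synaptic event
#'
#' Baseline is the median of the 10 ms preceding the event onset;
#' amplitude is baseline-to-peak (reported as a magnitude). The 10-90%
#' rise time is interpolated on the rising phase, and the decay time
#' constant comes from a single-exponential least-squares fit from the
#' peak toward baseline. Events too close to the trace edge for a full
#' decay window, or with a non-convergent fit, are flagged (excluded
#' from tau statistics by callers).
#'
#' @param trace a `SweepTrace`.
#' @param t_peak_s event peak time (s).
#' @param rise_ms,decay_ms kinetic guesses (onset/window geometry and
#'   fit start).
#' @param polarity -1 inward / +1 outward.
#' @param baseline_ms baseline window length before onset.
#' @return list with `amplitude_pA`, `rise_10_90_ms`, `decay_tau_ms`,
#'   `baseline_pA`, `flagged`.
#' @export
event_kinetics <- function(trace, t_peak_s, rise_ms = 0.5, decay_ms = 5,
                           polarity = -1, baseline_ms = 10) {
  x <- trace$samples; fs <- trace$fs_hz; N <- length(x)
  pk <- as.integer(round(t_peak_s * fs)) + 1L
  lead <- as.integer(ceiling((.psc_peak_delay(rise_ms, decay_ms) +
                                rise_ms / 1000) * fs)) + 1L
  onset <- max(1L, pk - lead)
  b0 <- max(1L, onset - as.integer(baseline_ms / 1000 * fs))
  flagged <- FALSE
  baseline <- stats::median(x[b0:max(b0, onset - 1L)])
  # peak on a 0.25 ms boxcar-smoothed copy: the raw argmax rides the
  # noise maximum and systematically overestimates the amplitude
  w <- max(1L, as.integer(round(0.00025 * fs)))
  sm_w <- (max(1L, pk - w):min(N, pk + w))
  amp <- polarity * (mean(x[sm_w]) - baseline)
  # 10-90% rise on the rising phase
  seg <- polarity * (x[onset:pk] - baseline)
  lv10 <- 0.1 * amp; lv90 <- 0.9 * amp
  cross <- function(lv) {
    idx <- which(seg[-length(seg)] < lv & seg[-1] >= lv)
    if (!length(idx)) return(NA_real_)
    i <- idx[length(idx)]
    i + (lv - seg[i]) / (seg[i + 1L] - seg[i])
  }
  t10 <- cross(lv10); t90 <- cross(lv90)
  rise <- if (is.na(t10) || is.na(t90)) {
    flagged <- TRUE; NA_real_
  } else (t90 - t10) / fs * 1000
  # single-exponential decay fit from the peak
  nfit <- as.integer(4 * decay_ms / 1000 * fs)
  tau <- NA_real_
  if (pk + nfit > N) {
    flagged <- TRUE                      # incomplete decay at trace edge
  } else {
    tt <- (0:nfit) / fs
    yy <- polarity * (x[pk:(pk + nfit)] - baseline)
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ A * exp(-tt / tau),
                        start = list(A = amp, tau = decay_ms / 1000),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || stats::coef(fit)[["tau"]] <= 0) {
      flagged <- TRUE
    } else tau <- stats::coef(fit)[["tau"]] * 1000
  }
  list(amplitude_pA = amp, rise_10_90_ms = rise, decay_tau_ms = tau,
       baseline_pA = baseline, flagged = flagged)
}

#' Passive membrane properties from a -5 mV test pulse
#'
#' From the capacitive transient and steady-state deflection of the
#' seal-test current: `Rs = dV / I_peak` (peak extrapolated to the step
#' onset from a single-exponential fit, so sampling does not clip the
#' transient), `Rm = dV / I_ss - Rs`, and `Cm = tau / (Rs || Rm)`.
#'
#' @param pulse a `SweepTrace` with `step_window` set.
#' @param dV_mV step amplitude (default -5).
#' @return list with `Rs_MOhm`, `Rm_MOhm`, `Cm_pF`, `tau_ms`,
#'   `I_peak_pA`, `I_ss_pA`, `flagged` (TRUE when `Rm <= 0`).
#' @export
passive_properties <- function(pulse, dV_mV = -5) {
  stopifnot(inherits(pulse, "SweepTrace"))
  if (is.null(pulse$step_window)) stop("pulse window not annotated")
  x <- pulse$samples; fs <- pulse$fs_hz
  on <- pulse$step_window[1L]; off <- pulse$step_window[2L]
  baseline <- if (on > 1L) mean(x[1:(on - 1L)]) else 0
  seg <- x[on:off] - baseline
  n <- length(seg)
  i_ss <- mean(seg[max(1L, floor(0.8 * n)):n])
  if (abs(i_ss) < 1e-9) stop("steady-state current is ~0")
  tt <- (seq_len(n) - 1) / fs
  dev0 <- seg[1L] - i_ss
  # crude tau guess: time to 1/e of the initial deviation
  below <- which(abs(seg - i_ss) <= abs(dev0) / exp(1))
  tau0 <- if (length(below)) max(tt[below[1L]], 1 / fs) else n / fs / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ iss + A * exp(-tt / tau),
                      start = list(iss = i_ss, A = dev0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("exponential fit of the transient failed")
  cf <- stats::coef(fit)
  i_ss <- cf[["iss"]]
  i_peak <- cf[["iss"]] + cf[["A"]]
  tau_ms <- cf[["tau"]] * 1000
  if (abs(i_peak) < 1e-9) stop("peak current is ~0")
  rs <- 1000 * dV_mV / i_peak
  rtot <- 1000 * dV_mV / i_ss
  rm <- rtot - rs
  flagged <- rm <= 0
  cm <- if (flagged) NA_real_ else tau_ms / (rs * rm / (rs + rm)) * 1000
  list(Rs_MOhm = rs, Rm_MOhm = rm, Cm_pF = cm, tau_ms = tau_ms,
       I_peak_pA = i_peak, I_ss_pA = i_ss, flagged = flagged)
}

#' Action-potential counts, rheobase and F-I relation
#'
#' An action potential is an upward crossing of 0 mV whose preceding
#' slope is at least 2 mV/ms. Counts and AP inter-event intervals are
#' computed within each sweep's current-step window; rheobase is the
#' smallest step amplitude eliciting at least one AP (missing when no
#' step does). Input sweeps may arrive in any order; results are sorted
#' by step amplitude.
#'
#' @param sweeps list of current-clamp `SweepTrace`s, each with `step_pA`
#'   and `step_window`.
#' @param slope_mV_ms minimum depolarization slope (default 2).
#' @param slope_window_ms lookback for the slope estimate.
#' @return list with `steps` (data.frame `step_pA`, `n_ap`), `ap_times`
#'   (list of AP times per step, s), `ap_iei` (list), `rheobase_pA`
#'   (NA when undefined).
#' @export
fi_analysis <- function(sweeps, slope_mV_ms = 2, slope_window_ms = 0.5) {
  stopifnot(length(sweeps) > 0L)
  steps <- vapply(sweeps, `[[`, 0, "step_pA")
  ord <- order(steps)
  sweeps <- sweeps[ord]; steps <- steps[ord]
  ap_times <- vector("list", length(sweeps))
  for (s in seq_along(sweeps)) {
    tr <- sweeps[[s]]
    v <- tr$samples; fs <- tr$fs_hz
    w <- tr$step_window
    k <- max(1L, as.integer(round(slope_window_ms / 1000 * fs)))
    idx <- which(v[-1] >= 0 & v[-length(v)] < 0) + 1L
    idx <- idx[idx > w[1L] & idx <= w[2L] & idx > k]
    slope <- (v[idx] - v[idx - k]) / (k / fs * 1000)
    idx <- idx[slope >= slope_mV_ms]
    ap_times[[s]] <- (idx - 1L) / fs
  }
  n_ap <- lengths(ap_times)
  rheo <- if (any(n_ap >= 1L)) steps[which(n_ap >= 1L)[1L]] else NA_real_
  list(steps = data.frame(step_pA = steps, n_ap = as.integer(n_ap)),
       ap_times = ap_times,
       ap_iei = lapply(ap_times, function(t) if (length(t) > 1L) diff(t)
                       else numeric(0)),
       rheobase_pA = rheo)
}

#' Compare mPSC metric distributions between two groups
#'
#' Two-sample Kolmogorov-Smirnov test on the pooled per-event metric
#' (amplitude or inter-event interval), plus per-cell means for the
#' cell-level comparison.
#'
#' @param events_a,events_b numeric vectors of the metric, or lists of
#'   per-cell numeric vectors.
#' @param metric label only (`"amplitude"` or `"iei"`).
#' @return list with `ks_statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `cell_means_a`, `cell_means_b`.
#' @export
distribution_compare <- function(events_a, events_b,
                                 metric = c("amplitude", "iei")) {
  metric <- match.arg(metric)
  pool <- function(e) if (is.list(e)) unlist(e, use.names = FALSE) else e
  a <- pool(events_a); b <- pool(events_b)
  if (length(a) < 5L || length(b) < 5L) {
    stop("need at least 5 events per group")
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(metric = metric,
       ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       mean_a = mean(a), mean_b = mean(b),
       cell_means_a = if (is.list(events_a))
         vapply(events_a, mean, numeric(1)) else NULL,
       cell_means_b = if (is.list(events_b))
         vapply(events_b, mean, numeric(1)) else NULL)
}
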