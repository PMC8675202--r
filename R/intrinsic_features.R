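# Current-clamp analysis: spike detection, F-I curve and rheobase, AP
# waveform features with the dV/dt threshold rule, the 16-18-spike
# adaptation ratio, and passive membrane properties from hyperpolarizing
# steps.

#' Configuration for current-clamp feature extraction
#'
#' @param peak_cutoff_mV Minimum absolute voltage of a spike peak (mV).
#' @param min_prominence_mV Minimum peak prominence (mV): height of the peak
#'   above the higher of the two flanking valleys.
#' @param refractory_ms Minimum separation between detected peaks (ms).
#' @param dvdt_criterion Threshold criterion on the first derivative
#'   (mV/ms): scanning backward in time from the upstroke, the AP threshold
#'   is the first sample whose dV/dt falls below this value.
#' @param adaptation_window Inclusive spike-count window selecting the sweep
#'   used for the adaptation ratio.
#' @param threshold_search_ms How far before the peak to search for the
#'   threshold (ms).
#' @param ap_window_ms Window after the peak over which decay slope and
#'   half-width recovery are evaluated (ms).
#' @param steady_state_ms Length of the pre-offset window used for
#'   steady-state voltage in passive fits (ms).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(peak_cutoff_mV = 0, min_prominence_mV = 20,
                           refractory_ms = 2, dvdt_criterion = 10,
                           adaptation_window = c(16L, 18L),
                           threshold_search_ms = 10, ap_window_ms = 10,
                           steady_state_ms = 100) {
  stopifnot(dvdt_criterion > 0, refractory_ms >= 0,
            length(adaptation_window) == 2L,
            adaptation_window[1] <= adaptation_window[2])
  structure(list(peak_cutoff_mV = peak_cutoff_mV,
                 min_prominence_mV = min_prominence_mV,
                 refractory_ms = refractory_ms,
                 dvdt_criterion = dvdt_criterion,
                 adaptation_window = as.integer(adaptation_window),
                 threshold_search_ms = threshold_search_ms,
                 ap_window_ms = ap_window_ms,
                 steady_state_ms = steady_state_ms),
            class = "feature_config")
}

#' Detect action-potential peaks in a voltage trace
#'
#' A sample is a candidate peak if it is a local maximum above the peak
#' cutoff whose prominence (height above the higher flanking valley, with
#' valleys delimited by neighbouring candidates or the trace ends) reaches
#' the configured minimum. Candidates closer than the refractory period are
#' resolved greedily in favour of the higher peak.
#'
#' @param v Numeric voltage trace (mV).
#' @param dt_ms Sampling interval (ms).
#' @param cfg A [feature_config()].
#' @return Sorted integer vector of peak sample indices (1-based).
#' @export
detect_spikes <- function(v, dt_ms, cfg = feature_config()) {
  if (any(!is.finite(v))) stop("non-finite samples in voltage trace")
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- v[2:(n - 1L)]
  is_max <- core > v[1:(n - 2L)] & core >= v[3:n] & core >= cfg$peak_cutoff_mV
  cand <- which(is_max) + 1L
  if (!length(cand)) return(integer(0))
  # prominence: lowest valley to the nearest higher ground on each side
  prom <- vapply(cand, function(i) {
    left <- v[max(1L, 1L):i]
    higher_l <- which(left > v[i])
    lo_l <- if (length(higher_l)) min(v[(max(higher_l) + 1L):i]) else min(left)
    right <- v[i:n]
    higher_r <- which(right > v[i])
    lo_r <- if (length(higher_r)) min(v[i:(i + min(higher_r) - 2L)]) else min(right)
    v[i] - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= cfg$min_prominence_mV]
  if (!length(cand)) return(integer(0))
  # refractory: greedy by descending height
  refr <- cfg$refractory_ms / dt_ms
  keep <- logical(length(cand))
  for (j in order(v[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < refr)) keep[j] <- TRUE
  }
  sort(cand[keep])
}

#' F-I curve and rheobase of a step family
#'
#' Counts spikes per sweep within the step window (spikes before onset or
#' after offset are ignored). The rheobase is the smallest injected current
#' whose sweep fires at least one spike; `NA` when no sweep fires.
#'
#' @param s Current-clamp [sweep_set()] with a step protocol.
#' @param cfg A [feature_config()].
#' @return A `fi_curve` object: data frame with `current_pA` and `n_spikes`,
#'   plus attributes `rheobase_pA` and `spike_times_ms` (list of per-sweep
#'   peak times, restricted to the step window).
#' @export
fi_curve <- function(s, cfg = feature_config()) {
  stopifnot(inherits(s, "sweep_set"))
  if (s$mode != "current_clamp") stop("fi_curve requires a current-clamp sweep set")
  if (is.null(s$protocol)) stop("fi_curve requires a step protocol")
  p <- s$protocol
  times <- sweep_times(s)
  in_step <- times >= p$pre_step_ms & times < p$pre_step_ms + p$step_duration_ms
  idx_sweeps <- seq_len(nrow(s$data))
  st <- lapply(idx_sweeps, function(k) {
    pk <- detect_spikes(s$data[k, ], s$dt_ms, cfg)
    pk <- pk[in_step[pk]]
    (pk - 1L) * s$dt_ms
  })
  counts <- lengths(st)
  current <- current_at(p, idx_sweeps - 1L)
  firing <- which(counts >= 1L)
  rheo <- if (length(firing)) min(current[firing]) else NA_real_
  out <- data.frame(current_pA = current, n_spikes = counts)
  attr(out, "rheobase_pA") <- rheo
  attr(out, "spike_times_ms") <- st
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Waveform features of one action potential
#'
#' The threshold follows the first-derivative rule: plot dV/dt (central
#' finite differences) and, scanning backward in time from the peak,
#' take the first sample where the derivative is lower than the criterion
#' (default 10 mV/ms); the voltage at that sample is the threshold.
#' Amplitude is peak minus threshold; the half-width is the width at the
#' voltage midway between threshold and peak, linearly interpolated on both
#' flanks; maximum rise and decay slopes are the extrema of dV/dt within
#' the AP window.
#'
#' @param v Voltage trace (mV).
#' @param peak_index Peak sample index from [detect_spikes()].
#' @param dt_ms Sampling interval (ms).
#' @param cfg A [feature_config()].
#' @return A list of class `ap_feature`: `peak_time_ms`, `peak_mV`,
#'   `threshold_mV`, `threshold_time_ms`, `threshold_index`,
#'   `amplitude_mV`, `halfwidth_ms`, `max_rise_mV_ms`, `max_decay_mV_ms`,
#'   `valid`, `reason`.
#' @export
ap_waveform_features <- function(v, peak_index, dt_ms, cfg = feature_config()) {
  n <- length(v)
  stopifnot(peak_index >= 2L, peak_index <= n - 1L)
  dvdt <- c(NA_real_, (v[3:n] - v[1:(n - 2L)]) / (2 * dt_ms), NA_real_)
  lo <- max(2L, peak_index - round(cfg$threshold_search_ms / dt_ms))
  thr_idx <- NA_integer_
  for (i in (peak_index - 1L):lo) {
    if (!is.na(dvdt[i]) && dvdt[i] < cfg$dvdt_criterion) { thr_idx <- i; break }
  }
  invalid <- function(reason) {
    structure(list(peak_time_ms = (peak_index - 1L) * dt_ms,
                   peak_mV = v[peak_index], threshold_mV = NA_real_,
                   threshold_time_ms = NA_real_, threshold_index = NA_integer_,
                   amplitude_mV = NA_real_, halfwidth_ms = NA_real_,
                   max_rise_mV_ms = NA_real_, max_decay_mV_ms = NA_real_,
                   valid = FALSE, reason = reason), class = "ap_feature")
  }
  if (is.na(thr_idx)) return(invalid("no sub-criterion dV/dt sample in search window"))
  thr <- v[thr_idx]
  amp <- v[peak_index] - thr
  if (amp <= 0) return(invalid("non-positive amplitude"))
  half <- thr + amp / 2
  # rising crossing between threshold and peak
  rise_seg <- thr_idx:peak_index
  above <- which(v[rise_seg] >= half)
  if (!length(above)) return(invalid("no half-amplitude crossing on rise"))
  iu <- rise_seg[min(above)]
  t_up <- if (iu == thr_idx) (iu - 1L) * dt_ms else
    ((iu - 2L) + (half - v[iu - 1L]) / (v[iu] - v[iu - 1L])) * dt_ms
  # falling crossing after the peak
  hi <- min(n, peak_index + round(cfg$ap_window_ms / dt_ms))
  fall_seg <- peak_index:hi
  below <- which(v[fall_seg] <= half)
  if (!length(below)) return(invalid("no half-amplitude recovery within AP window"))
  idn <- fall_seg[min(below)]
  t_dn <- ((idn - 2L) + (half - v[idn - 1L]) / (v[idn] - v[idn - 1L])) * dt_ms
  win <- max(2L, thr_idx):min(n - 1L, hi)
  structure(list(peak_time_ms = (peak_index - 1L) * dt_ms,
                 peak_mV = v[peak_index], threshold_mV = thr,
                 threshold_time_ms = (thr_idx - 1L) * dt_ms,
                 threshold_index = thr_idx,
                 amplitude_mV = amp, halfwidth_ms = t_dn - t_up,
                 max_rise_mV_ms = max(dvdt[win], na.rm = TRUE),
                 max_decay_mV_ms = min(dvdt[win], na.rm = TRUE),
                 valid = TRUE, reason = NA_character_), class = "ap_feature")
}

#' Features of the first action potential at rheobase
#'
#' Convenience wrapper: locates the rheobase sweep via [fi_curve()] and
#' extracts [ap_waveform_features()] of its first spike.
#'
#' @inheritParams fi_curve
#' @return An `ap_feature`, or `NULL` when no sweep fires.
#' @export
first_ap_at_rheobase <- function(s, cfg = feature_config()) {
  fi <- fi_curve(s, cfg)
  rheo <- attr(fi, "rheobase_pA")
  if (is.na(rheo)) return(NULL)
  k <- which(fi$current_pA == rheo)[1L]
  st <- attr(fi, "spike_times_ms")[[k]]
  peak_index <- round(st[1L] / s$dt_ms) + 1L
  ap_waveform_features(s$data[k, ], peak_index, s$dt_ms, cfg)
}

#' Spike-frequency adaptation ratio
#'
#' The ratio divides the time between the first two action potentials (T1)
#' by the time between the last two (T2) on the sweep firing 16-18 spikes
#' (the lowest-current such sweep when several qualify). A value near 1
#' means no adaptation; values toward 0 mean strong adaptation. Cells with
#' no sweep in the window are excluded, not errored.
#'
#' @inheritParams fi_curve
#' @return A list of class `adaptation_result`: `sweep_index` (1-based),
#'   `n_spikes`, `T1_ms`, `T2_ms`, `ratio`, `excluded`.
#' @export
adaptation_ratio <- function(s, cfg = feature_config()) {
  fi <- fi_curve(s, cfg)
  win <- cfg$adaptation_window
  ok <- which(fi$n_spikes >= win[1] & fi$n_spikes <= win[2])
  if (!length(ok)) {
    return(structure(list(sweep_index = NA_integer_, n_spikes = NA_integer_,
                          T1_ms = NA_real_, T2_ms = NA_real_, ratio = NA_real_,
                          excluded = TRUE), class = "adaptation_result"))
  }
  k <- ok[which.min(fi$current_pA[ok])]
  st <- attr(fi, "spike_times_ms")[[k]]
  m <- length(st)
  T1 <- st[2L] - st[1L]
  T2 <- st[m] - st[m - 1L]
  structure(list(sweep_index = k, n_spikes = m, T1_ms = T1, T2_ms = T2,
                 ratio = T1 / T2, excluded = FALSE),
            class = "adaptation_result")
}

#' Passive membrane properties from hyperpolarizing steps
#'
#' Resting potential is the mean pre-step baseline; input resistance is the
#' least-squares slope of steady-state voltage deflection against injected
#' current over the hyperpolarizing sweeps; the membrane time constant is a
#' single-exponential fit to the onset of the smallest hyperpolarizing step;
#' capacitance follows as `1000 * tau / Rin` (pF from ms and MOhm).
#'
#' @inheritParams fi_curve
#' @return A list of class `passive_properties`: `v_rest_mV`, `rin_mohm`,
#'   `tau_ms`, `capacitance_pF`, `valid`, `reason`.
#' @export
passive_properties <- function(s, cfg = feature_config()) {
  stopifnot(inherits(s, "sweep_set"))
  if (is.null(s$protocol)) stop("passive_properties requires a step protocol")
  p <- s$protocol
  current <- current_at(p, seq_len(nrow(s$data)) - 1L)
  hyp <- which(current < 0)
  if (length(hyp) < 2L) stop("need at least 2 hyperpolarizing sweeps")
  times <- sweep_times(s)
  base_idx <- times < p$pre_step_ms
  off <- p$pre_step_ms + p$step_duration_ms
  ss_idx <- times >= (off - cfg$steady_state_ms) & times < off
  v_rest <- mean(s$data[, base_idx])
  base_per <- rowMeans(s$data[hyp, base_idx, drop = FALSE])
  dv <- rowMeans(s$data[hyp, ss_idx, drop = FALSE]) - base_per
  fit <- stats::lm.fit(cbind(1, current[hyp]), dv)
  rin <- unname(fit$coefficients[2L]) * 1000  # mV/pA = GOhm -> MOhm
  if (!is.finite(rin) || rin <= 0) stop("non-positive input-resistance fit")
  # tau from the smallest (least negative) hyperpolarizing step onset
  k <- hyp[which.max(current[hyp])]
  on_idx <- which(times >= p$pre_step_ms & times < off)
  tt <- times[on_idx] - p$pre_step_ms
  vv <- s$data[k, on_idx]
  v0 <- base_per[match(k, hyp)]
  vss <- mean(vv[tt >= max(tt) - cfg$steady_state_ms])
  tau0 <- max(tt) / 10
  fit2 <- tryCatch(
    minpack.lm::nlsLM(vv ~ vss_f + (v0_f - vss_f) * exp(-tt / tau),
                      start = list(vss_f = vss, v0_f = v0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit2)) {
    return(structure(list(v_rest_mV = v_rest, rin_mohm = rin, tau_ms = NA_real_,
                          capacitance_pF = NA_real_, valid = FALSE,
                          reason = "exponential onset fit did not converge"),
                     class = "passive_properties"))
  }
  tau <- unname(stats::coef(fit2)["tau"])
  structure(list(v_rest_mV = v_rest, rin_mohm = rin, tau_ms = tau,
                 capacitance_pF = 1000 * tau / rin, valid = TRUE,
                 reason = NA_character_),
            class = "passive_properties")
}
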