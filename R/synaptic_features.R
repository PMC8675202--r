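# Voltage-clamp synaptic analysis: automatic PSC event detection by scaled
# template matching (Clements-Bekkers style: at each offset a difference-of-
# exponentials template is fitted with a free scale and offset, and the
# detection statistic is scale / SE of the fit), per-event kinetics, per-cell
# summaries with the >= 50-event inclusion rule, E/I ratios across paired
# mEPSC/mIPSC recordings of the same cell, and the NMDA/AMPA isolation
# procedure on paired evoked recordings at -70 and +40 mV.

#' Configuration for PSC event detection
#'
#' @param rise_tau_ms,decay_tau_ms Kinetics of the matching template.
#' @param criterion Detection criterion (dimensionless; template scale over
#'   the standard error of the local fit). Default 3.5.
#' @param min_amplitude_pA Minimum absolute fitted amplitude (pA).
#' @param polarity `"inward"` (negative events) or `"outward"`.
#' @param min_events Minimum number of events for a recording to enter
#'   kinetics-level analysis (default 50; recordings with fewer events are
#'   flagged excluded).
#' @param template_length_ms Template length; defaults to the template peak
#'   delay plus one decay time constant. A compact template keeps the
#'   matched filter local, so closely spaced events produce separate
#'   criterion crossings instead of being merged into one detection.
#' @param baseline_ms Pre-onset window for the local baseline (ms).
#' @param merge_gap_ms Super-threshold offsets closer than this are treated
#'   as one detection (best-scoring offset wins); offsets further apart
#'   remain separate events, so closely spaced but distinct events are not
#'   swallowed.
#' @param peak_smooth_ms Boxcar width used to smooth the event segment
#'   before locating the peak for the amplitude measure; damps the upward
#'   bias of a raw extremum under noise.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(rise_tau_ms = 0.5, decay_tau_ms = 5,
                             criterion = 3.5, min_amplitude_pA = 5,
                             polarity = c("inward", "outward"),
                             min_events = 50L, template_length_ms = NULL,
                             baseline_ms = 3, merge_gap_ms = 2,
                             peak_smooth_ms = 0.5) {
  polarity <- match.arg(polarity)
  stopifnot(criterion > 0, min_events >= 1, decay_tau_ms > rise_tau_ms,
            rise_tau_ms > 0, min_amplitude_pA >= 0, merge_gap_ms >= 0)
  structure(list(rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 criterion = criterion, min_amplitude_pA = min_amplitude_pA,
                 polarity = polarity, min_events = as.integer(min_events),
                 template_length_ms = template_length_ms,
                 baseline_ms = baseline_ms, merge_gap_ms = merge_gap_ms,
                 peak_smooth_ms = peak_smooth_ms),
            class = "detection_config")
}

# Running sums of x over windows of length L starting at each sample
# (position i covers x[i..i+L-1]); returns a vector of length n - L + 1.
run_sum <- function(x, L) {
  cs <- cumsum(x)
  cs[L:length(x)] - c(0, cs[seq_len(length(x) - L)])
}

# Sliding cross-product of the trace with the template at every offset i:
# sum(x[i..i+L-1] * tmpl). Computed as an FFT cross-correlation padded to a
# 2-3-5-smooth length (R's mixed-radix FFT degrades to quadratic cost on
# lengths with large prime factors).
slide_prod <- function(x, tmpl) {
  n <- length(x)
  L <- length(tmpl)
  N <- stats::nextn(n, factors = c(2, 3, 5))
  X <- stats::fft(c(x, numeric(N - n)))
  TT <- stats::fft(c(tmpl, numeric(N - L)))
  cc <- Re(stats::fft(X * Conj(TT), inverse = TRUE)) / N
  cc[seq_len(n - L + 1L)]
}

#' Detect PSC events by scaled template matching
#'
#' At every offset the unit-peak difference-of-exponentials template is
#' fitted to the trace with a free scale and additive offset (closed-form
#' least squares); the detection statistic is the fitted scale divided by
#' the standard error of the residuals. Samples where the statistic exceeds
#' the criterion with the configured polarity and a fitted amplitude at
#' least `min_amplitude_pA` become detections; runs of super-threshold
#' offsets closer than one template length are merged to the best-scoring
#' offset.
#'
#' @param sweep Numeric current trace (pA), or a single-sweep
#'   [sweep_set()].
#' @param dt_ms Sampling interval (ms); taken from the sweep set when one is
#'   given.
#' @param cfg A [detection_config()].
#' @return A data frame of class `synaptic_events` with one row per event:
#'   `onset_ms`, `peak_ms`, `amplitude_pA` (signed), `rise_ms` (10-90%),
#'   `decay_tau_ms`, `kinetics_valid`, `score`.
#' @export
detect_events <- function(sweep, dt_ms = NULL, cfg = detection_config()) {
  if (inherits(sweep, "sweep_set")) {
    if (nrow(sweep$data) != 1L) stop("detect_events expects a single-sweep recording")
    dt_ms <- sweep$dt_ms
    sweep <- as.numeric(sweep$data[1L, ])
  }
  stopifnot(is.numeric(sweep), !is.null(dt_ms))
  tl <- cfg$template_length_ms
  ker <- psc_kernel(cfg$rise_tau_ms, cfg$decay_tau_ms, dt_ms,
                    length_ms = if (is.null(tl)) NULL else tl)
  tmpl <- ker$y
  if (is.null(tl)) {
    keep_ms <- ker$t_peak_ms + cfg$decay_tau_ms
    tmpl <- tmpl[seq_len(min(length(tmpl), floor(keep_ms / dt_ms) + 1L))]
  }
  L <- length(tmpl)
  n <- length(sweep)
  if (L >= n) stop("template longer than trace")
  sgn <- if (cfg$polarity == "inward") -1 else 1

  sum_t <- sum(tmpl)
  sum_t2 <- sum(tmpl^2)
  sum_d <- run_sum(sweep, L)
  sum_d2 <- run_sum(sweep^2, L)
  sum_td <- slide_prod(sweep, tmpl)
  denom <- sum_t2 - sum_t^2 / L
  scale <- (sum_td - sum_t * sum_d / L) / denom
  offset <- (sum_d - scale * sum_t) / L
  sse <- sum_d2 + scale^2 * sum_t2 + L * offset^2 -
    2 * (scale * sum_td + offset * sum_d - scale * offset * sum_t)
  sse[sse < 0] <- 0
  se <- sqrt(sse / (L - 1))
  crit <- scale / se
  crit[!is.finite(crit)] <- 0

  hits <- which(sgn * crit >= cfg$criterion &
                  abs(scale) >= cfg$min_amplitude_pA &
                  sign(scale) == sgn)
  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      amplitude_pA = numeric(0), rise_ms = numeric(0),
                      decay_tau_ms = numeric(0), kinetics_valid = logical(0),
                      score = numeric(0))
  class(empty) <- c("synaptic_events", "data.frame")
  if (!length(hits)) return(empty)
  # merge super-threshold offsets closer than the merge gap, keep the
  # best-scoring offset of each run
  gap <- max(1L, round(cfg$merge_gap_ms / dt_ms))
  grp <- cumsum(c(1L, as.integer(diff(hits) > gap)))
  onsets <- vapply(split(hits, grp), function(ii) ii[which.max(sgn * crit[ii])],
                   numeric(1))
  onsets <- as.integer(sort(onsets))
  # an event must deflect beyond the global trace baseline in its own
  # direction: rejects template matches on the recovery flank of
  # opposite-polarity deflections
  global_base <- stats::median(sweep)
  rows <- lapply(onsets, function(i0) {
    kin <- event_kinetics(sweep, i0, dt_ms, cfg)
    pk_idx <- round(kin$peak_ms / dt_ms) + 1L
    if (sgn * (sweep[pk_idx] - global_base) < 0.5 * cfg$min_amplitude_pA) {
      return(NULL)
    }
    data.frame(onset_ms = (i0 - 1L) * dt_ms, peak_ms = kin$peak_ms,
               amplitude_pA = kin$amplitude_pA, rise_ms = kin$rise_ms,
               decay_tau_ms = kin$decay_tau_ms,
               kinetics_valid = kin$valid, score = sgn * crit[i0])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("synaptic_events", "data.frame")
  out
}

#' Kinetics of one detected event
#'
#' Amplitude is the extremum within the event window minus the local
#' baseline (median of the pre-onset window); the 10-90% rise time is
#' linearly interpolated on the rising flank; the decay time constant is a
#' least-squares single-exponential fit from the peak to 90% recovery.
#'
#' @param sweep Numeric current trace (pA).
#' @param onset_index Onset sample (1-based) of the event.
#' @param dt_ms Sampling interval (ms).
#' @param cfg A [detection_config()] (supplies polarity, template length
#'   and baseline window).
#' @return List: `amplitude_pA` (signed), `rise_ms`, `decay_tau_ms`,
#'   `peak_ms`, `valid`, `reason`.
#' @export
event_kinetics <- function(sweep, onset_index, dt_ms, cfg = detection_config()) {
  n <- length(sweep)
  sgn <- if (cfg$polarity == "inward") -1 else 1
  t_pk <- psc_kernel(cfg$rise_tau_ms, cfg$decay_tau_ms, dt_ms)$t_peak_ms
  win_ms <- if (is.null(cfg$template_length_ms)) {
    t_pk + 4 * cfg$decay_tau_ms
  } else cfg$template_length_ms
  i1 <- min(n, onset_index + round(win_ms / dt_ms))
  b0 <- max(1L, onset_index - round(cfg$baseline_ms / dt_ms))
  base <- stats::median(sweep[b0:onset_index])
  # peak restricted to the expected rise region, on a lightly smoothed
  # segment so the amplitude is not the extremum of the noise
  i_pk_max <- min(n, onset_index + round((t_pk + 3 * cfg$rise_tau_ms) / dt_ms))
  seg <- sweep[onset_index:i_pk_max]
  sm_w <- max(1L, round(cfg$peak_smooth_ms / dt_ms))
  if (sm_w > 1L && length(seg) > sm_w) {
    seg_s <- as.numeric(stats::filter(seg, rep(1 / sm_w, sm_w), sides = 2))
    seg_s[is.na(seg_s)] <- seg[is.na(seg_s)]
  } else seg_s <- seg
  pk_rel <- if (sgn < 0) which.min(seg_s) else which.max(seg_s)
  pk <- onset_index + pk_rel - 1L
  amp <- seg_s[pk_rel] - base
  bad <- function(reason) list(amplitude_pA = amp, rise_ms = NA_real_,
                               decay_tau_ms = NA_real_,
                               peak_ms = (pk - 1L) * dt_ms,
                               valid = FALSE, reason = reason)
  if (sgn * amp <= 0) return(bad("amplitude has wrong polarity"))
  # 10-90% rise, interpolated on |V - base| normalised by |amp|
  rise_seg <- sgn * (sweep[onset_index:pk] - base) / abs(amp)
  t_at <- function(frac) {
    j <- which(rise_seg >= frac)
    if (!length(j)) return(NA_real_)
    j <- j[1L]
    if (j == 1L) return(0)
    (j - 2L + (frac - rise_seg[j - 1L]) / (rise_seg[j] - rise_seg[j - 1L])) * dt_ms
  }
  t10 <- t_at(0.1); t90 <- t_at(0.9)
  if (is.na(t10) || is.na(t90)) return(bad("rise crossings not found"))
  # decay: peak to 90% recovery (|deflection| down to 10% of amplitude);
  # the fit starts two rise time constants past the peak, where the
  # residual rising exponential no longer biases the decay constant
  pk_fit <- min(i1, pk + round(2 * cfg$rise_tau_ms / dt_ms))
  dec <- sgn * (sweep[pk_fit:i1] - base)
  stop_rel <- which(dec <= 0.1 * abs(amp))
  j_end <- if (length(stop_rel)) stop_rel[1L] else length(dec)
  if (j_end < 4L) return(bad("decay segment too short for fit"))
  tt <- (seq_len(j_end) - 1L) * dt_ms
  yy <- dec[seq_len(j_end)]
  pos <- yy > 0
  if (sum(pos) < 3L) return(bad("decay segment not positive"))
  ls <- stats::lm.fit(cbind(1, tt[pos]), log(yy[pos]))
  tau0 <- unname(-1 / ls$coefficients[2L])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- cfg$decay_tau_ms
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau),
                      start = list(A = max(yy), tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  tau_fit <- if (is.null(fit)) NA_real_ else unname(stats::coef(fit)["tau"])
  if (!is.finite(tau_fit) || tau_fit <= 0 || tau_fit > 5 * win_ms) {
    return(bad("decay fit did not converge"))
  }
  list(amplitude_pA = amp, rise_ms = t90 - t10,
       decay_tau_ms = tau_fit,
       peak_ms = (pk - 1L) * dt_ms, valid = TRUE, reason = NA_character_)
}

#' Per-cell summary of detected PSC events
#'
#' Applies the inclusion rule: a recording enters kinetics-level analysis
#' only when it holds at least `min_events` events (default 50); recordings
#' with fewer events are flagged `included = FALSE` but their frequency is
#' still reported.
#'
#' @param events A `synaptic_events` data frame from [detect_events()].
#' @param duration_s Analyzed trace duration (s).
#' @param cfg A [detection_config()].
#' @param cell_id Optional cell identifier carried into the summary.
#' @return A list of class `cell_synaptic_summary`: `n_events`,
#'   `frequency_hz`, `mean_amplitude_pA`, `mean_rise_ms`,
#'   `mean_decay_tau_ms`, `included`, `cell_id`.
#' @export
summarize_cell <- function(events, duration_s, cfg = detection_config(),
                           cell_id = NA_character_) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- nrow(events)
  ok <- events$kinetics_valid
  structure(list(
    n_events = n,
    frequency_hz = n / duration_s,
    mean_amplitude_pA = if (n) mean(events$amplitude_pA) else NA_real_,
    mean_rise_ms = if (any(ok)) mean(events$rise_ms[ok]) else NA_real_,
    mean_decay_tau_ms = if (any(ok)) mean(events$decay_tau_ms[ok]) else NA_real_,
    included = n >= cfg$min_events,
    cell_id = cell_id
  ), class = "cell_synaptic_summary")
}

#' Excitation/inhibition ratio of one cell
#'
#' mEPSC and mIPSC recordings of the same cell are summarized separately;
#' the E/I ratio divides the excitatory by the inhibitory frequency (and
#' mean absolute amplitude). The ratio is only defined when both summaries
#' pass the inclusion rule and the mIPSC frequency is positive; otherwise
#' the result is flagged excluded with a reason.
#'
#' @param epsc,ipsc `cell_synaptic_summary` objects for the mEPSC and mIPSC
#'   recordings of one cell.
#' @return A list of class `ei_ratio`: `frequency_ratio`,
#'   `amplitude_ratio`, `cell_id`, `excluded`, `reason`.
#' @export
ei_ratio <- function(epsc, ipsc) {
  stopifnot(inherits(epsc, "cell_synaptic_summary"),
            inherits(ipsc, "cell_synaptic_summary"))
  if (!is.na(epsc$cell_id) && !is.na(ipsc$cell_id) &&
      epsc$cell_id != ipsc$cell_id) {
    stop("E/I ratio requires recordings from the same cell (got '",
         epsc$cell_id, "' vs '", ipsc$cell_id, "')")
  }
  excl <- function(reason) structure(
    list(frequency_ratio = NA_real_, amplitude_ratio = NA_real_,
         cell_id = epsc$cell_id, excluded = TRUE, reason = reason),
    class = "ei_ratio")
  if (!epsc$included || !ipsc$included) return(excl("insufficient events"))
  if (ipsc$frequency_hz <= 0) return(excl("undefined ratio"))
  structure(list(
    frequency_ratio = epsc$frequency_hz / ipsc$frequency_hz,
    amplitude_ratio = abs(epsc$mean_amplitude_pA) / abs(ipsc$mean_amplitude_pA),
    cell_id = epsc$cell_id, excluded = FALSE, reason = NA_character_
  ), class = "ei_ratio")
}

#' NMDA/AMPA ratio from paired evoked recordings
#'
#' Sweeps at each holding potential are averaged; the stimulus artifact
#' window is blanked (replaced by the pre-stimulus baseline). The AMPA peak
#' is the extremum of the baseline-subtracted -70 mV average after the
#' stimulus. The NMDA measurement time t10 is the first post-peak time at
#' which the -70 mV AMPA current has decayed below 10% of its peak; the
#' NMDA amplitude is the mean of the baseline-subtracted +40 mV average
#' over a 5-ms window centered on t10. The ratio is |NMDA| / |AMPA|.
#'
#' @param neg70,pos40 Voltage-clamp [sweep_set()]s at -70 and +40 mV from
#'   one cell; `meta$stim_time_ms` (and optionally `meta$artifact_width_ms`)
#'   must be present on `neg70`.
#' @param nmda_window_ms Width of the averaging window at t10 (ms).
#' @param decay_fraction Residual fraction of the AMPA peak defining t10.
#' @return A list of class `evoked_ratio_result`: `ampa_peak_pA`, `t10_ms`
#'   (relative to the stimulus), `nmda_amp_pA`, `ratio`, `n_sweeps`.
#' @export
nmda_ampa_ratio <- function(neg70, pos40, nmda_window_ms = 5,
                            decay_fraction = 0.1) {
  stopifnot(inherits(neg70, "sweep_set"), inherits(pos40, "sweep_set"))
  if (neg70$mode != "voltage_clamp" || pos40$mode != "voltage_clamp") {
    stop("nmda_ampa_ratio requires voltage-clamp sweep sets")
  }
  stim <- neg70$meta$stim_time_ms
  if (is.null(stim)) stop("stimulus time missing from sweep metadata")
  art_w <- neg70$meta$artifact_width_ms
  if (is.null(art_w)) art_w <- 1
  if (nrow(neg70$data) != nrow(pos40$data)) {
    message("unequal sweep counts across holdings (",
            nrow(neg70$data), " vs ", nrow(pos40$data), "); averaging each")
  }
  dt <- neg70$dt_ms
  stopifnot(isTRUE(all.equal(dt, pos40$dt_ms)))
  prep <- function(s) {
    avg <- colMeans(s$data)
    times <- sweep_times(s)
    base <- mean(avg[times < stim])
    # blank the artifact with a small settle margin
    blank <- times >= stim & times < stim + art_w + 2 * dt
    avg[blank] <- base
    avg - base
  }
  a <- prep(neg70)
  p <- prep(pos40)
  times <- sweep_times(neg70)
  post <- which(times >= stim)
  pk_rel <- which.max(abs(a[post]))
  pk <- post[pk_rel]
  ampa_peak <- a[pk]
  after <- post[post > pk]
  dec <- which(abs(a[after]) < decay_fraction * abs(ampa_peak))
  if (!length(dec)) stop("AMPA decay incomplete before sweep end")
  t10_idx <- after[dec[1L]]
  t10 <- times[t10_idx] - stim
  win <- abs(times - times[t10_idx]) <= nmda_window_ms / 2
  nmda <- mean(p[win])
  structure(list(ampa_peak_pA = ampa_peak, t10_ms = t10, nmda_amp_pA = nmda,
                 ratio = abs(nmda) / abs(ampa_peak),
                 n_sweeps = c(neg70 = nrow(neg70$data), pos40 = nrow(pos40$data))),
            class = "evoked_ratio_result")
}
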