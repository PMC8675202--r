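# Ground-truth simulators. Each generator returns both a sweep_set (what an
# analysis stage sees) and a ground_truth list (what it should recover), so
# every downstream extractor is testable without real recordings.
#
# The current-clamp generator is an adaptive exponential integrate-and-fire
# (AdEx) neuron: its spike-triggered adaptation increment b and subthreshold
# coupling a directly control the spike-frequency-adaptation phenotype the
# analysis measures (T1/T2 ratio), so lowering b/a emulates the mutant
# phenotype (more spikes, ratio nearer 1). Model spikes are truncated at a
# cut potential; a stereotyped triangular AP waveform with a smooth onset
# foot is superimposed at each spike so waveform features (threshold,
# amplitude, half-width) have a known shape. This insertion is a stylization
# for testability, not a biophysical claim.

#' AdEx neuron parameters
#'
#' Defaults are generic values for a cortical/hippocampal pyramidal cell:
#' 150 pF, 10 nS leak (100 MOhm input resistance), -70 mV rest, 2 mV slope
#' factor, -50 mV threshold parameter. Quantitative AP waveform values are
#' not constrained by any dataset; they are plain textbook magnitudes.
#'
#' @param C_pF Membrane capacitance (pF).
#' @param gL_nS Leak conductance (nS).
#' @param EL_mV Leak reversal / resting potential (mV).
#' @param deltaT_mV Slope factor of the exponential spike-initiation term (mV).
#' @param VT_mV Rheobase-setting spike threshold parameter (mV).
#' @param a_nS Subthreshold adaptation coupling (nS).
#' @param b_pA Spike-triggered adaptation increment (pA); 0 disables
#'   spike-frequency adaptation.
#' @param tau_w_ms Adaptation time constant (ms).
#' @param Vreset_mV Post-spike reset potential (mV).
#' @param ap_amplitude_mV,ap_halfwidth_ms Amplitude and full width at half
#'   maximum of the inserted stereotyped AP waveform.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C_pF = 150, gL_nS = 10, EL_mV = -70, deltaT_mV = 2,
                          VT_mV = -50, a_nS = 2, b_pA = 40, tau_w_ms = 120,
                          Vreset_mV = -58, ap_amplitude_mV = 100,
                          ap_halfwidth_ms = 1.0) {
  stopifnot(C_pF > 0, gL_nS > 0, tau_w_ms > 0, deltaT_mV > 0, b_pA >= 0,
            ap_amplitude_mV > 0, ap_halfwidth_ms > 0)
  structure(list(C_pF = C_pF, gL_nS = gL_nS, EL_mV = EL_mV,
                 deltaT_mV = deltaT_mV, VT_mV = VT_mV, a_nS = a_nS,
                 b_pA = b_pA, tau_w_ms = tau_w_ms, Vreset_mV = Vreset_mV,
                 ap_amplitude_mV = ap_amplitude_mV,
                 ap_halfwidth_ms = ap_halfwidth_ms),
            class = "neuron_params")
}

# Stereotyped AP waveform sampled at dt: smooth quadratic foot (10% of the
# amplitude), then linear rise to the peak and linear decay, FWHM equal to
# halfwidth_ms. Returns the deflection above the local membrane potential
# and the index of the peak sample.
ap_template <- function(amplitude, halfwidth_ms, dt_ms) {
  rise <- 0.6 * halfwidth_ms
  fall <- 1.4 * halfwidth_ms
  foot <- 0.5 * rise
  tt <- seq(0, foot + rise + fall, by = dt_ms)
  y <- numeric(length(tt))
  in_foot <- tt < foot
  y[in_foot] <- 0.1 * amplitude * (tt[in_foot] / foot)^2
  in_rise <- tt >= foot & tt < foot + rise
  y[in_rise] <- amplitude * (0.1 + 0.9 * (tt[in_rise] - foot) / rise)
  in_fall <- tt >= foot + rise
  y[in_fall] <- pmax(0, amplitude * (1 - (tt[in_fall] - foot - rise) / fall))
  list(y = y, peak_index = which.max(y), peak_offset_ms = foot + rise)
}

#' Simulate a current-clamp step family with an AdEx neuron
#'
#' Integrates the AdEx equations (forward Euler, dt = 0.025 ms by default)
#' for every sweep of a square-step protocol, vectorized across sweeps.
#' Model spikes (cut at 0 mV) reset the membrane to `Vreset_mV` and
#' increment the adaptation current by `b_pA`; at each spike a stereotyped
#' AP waveform is superimposed on the trace. Gaussian current noise is
#' optional.
#'
#' @param np A [neuron_params()].
#' @param protocol A [step_protocol()].
#' @param seed Integer seed; fixes all randomness.
#' @param dt_ms Integration and output sampling interval (ms).
#' @param noise_sd_pA SD of white Gaussian current noise (pA).
#' @param meta Metadata list stored on the sweep set.
#' @return A list with `sweeps` (a [sweep_set()]) and `truth`
#'   (`spike_times_ms`: list of per-sweep vectors of AP peak times,
#'   `current_pA`: injected current per sweep).
#' @export
simulate_current_clamp <- function(np, protocol = step_protocol(), seed = 1,
                                   dt_ms = 0.025, noise_sd_pA = 0,
                                   meta = list()) {
  stopifnot(inherits(np, "neuron_params"), inherits(protocol, "step_protocol"))
  set.seed(as.integer(seed))
  n_sweeps <- protocol$n_sweeps
  t_total <- protocol$pre_step_ms + protocol$step_duration_ms + protocol$post_step_ms
  n_samp <- floor(t_total / dt_ms) + 1L
  times <- (seq_len(n_samp) - 1) * dt_ms
  on_step <- times >= protocol$pre_step_ms &
    times < protocol$pre_step_ms + protocol$step_duration_ms
  I_step <- current_at(protocol, seq_len(n_sweeps) - 1L)

  V <- rep(np$EL_mV, n_sweeps)
  w <- rep(0, n_sweeps)
  Vmat <- matrix(NA_real_, n_sweeps, n_samp)
  Vmat[, 1L] <- V
  v_cut <- 0  # truncation potential for model spikes
  spikes <- vector("list", n_sweeps)
  for (k in seq_len(n_sweeps)) spikes[[k]] <- numeric(0)
  noise <- if (noise_sd_pA > 0) {
    matrix(stats::rnorm(n_sweeps * (n_samp - 1L), 0, noise_sd_pA),
           n_sweeps, n_samp - 1L)
  } else NULL

  for (i in 2L:n_samp) {
    I <- if (on_step[i - 1L]) I_step else rep(0, n_sweeps)
    if (!is.null(noise)) I <- I + noise[, i - 1L]
    expo <- np$gL_nS * np$deltaT_mV * exp(pmin((V - np$VT_mV) / np$deltaT_mV, 20))
    dV <- (-np$gL_nS * (V - np$EL_mV) + expo + I - w) / np$C_pF
    dw <- (np$a_nS * (V - np$EL_mV) - w) / np$tau_w_ms
    V <- V + dt_ms * dV
    w <- w + dt_ms * dw
    if (anyNA(V) || any(!is.finite(V)) || any(V < -500)) {
      stop("AdEx integration diverged (membrane potential left the ",
           "physiological range); check C_pF/gL_nS/deltaT_mV or reduce dt_ms")
    }
    fired <- V >= v_cut
    if (any(fired)) {
      for (k in which(fired)) spikes[[k]] <- c(spikes[[k]], times[i])
      V[fired] <- np$Vreset_mV
      w[fired] <- w[fired] + np$b_pA
    }
    Vmat[, i] <- V
  }

  # superimpose the stereotyped AP waveform at each model-spike time
  tmpl <- ap_template(np$ap_amplitude_mV, np$ap_halfwidth_ms, dt_ms)
  L <- length(tmpl$y)
  peak_times <- vector("list", n_sweeps)
  for (k in seq_len(n_sweeps)) {
    pk <- numeric(0)
    for (ts in spikes[[k]]) {
      i0 <- round(ts / dt_ms) + 1L - (tmpl$peak_index - 1L)
      idx <- i0:(i0 + L - 1L)
      keep <- idx >= 1L & idx <= n_samp
      if (!any(keep)) next
      base <- Vmat[k, max(1L, i0)]
      seg <- base + tmpl$y[keep]
      Vmat[k, idx[keep]] <- pmax(Vmat[k, idx[keep]], seg)
      pk <- c(pk, (i0 + tmpl$peak_index - 2L) * dt_ms)
    }
    peak_times[[k]] <- pk[pk >= 0 & pk <= t_total]
  }

  sw <- sweep_set(Vmat, dt_ms = dt_ms, mode = "current_clamp",
                  protocol = protocol, meta = meta)
  list(sweeps = sw,
       truth = list(spike_times_ms = peak_times, current_pA = I_step))
}

#' Parameters of a miniature-PSC event train
#'
#' @param rate_hz Mean event rate (Hz, Poisson).
#' @param amp_mean_pA Mean absolute event amplitude (pA).
#' @param amp_cv Coefficient of variation of amplitudes (log-normal draw).
#' @param rise_tau_ms,decay_tau_ms Kinetics of the difference-of-exponentials
#'   event shape; `decay_tau_ms > rise_tau_ms > 0`.
#' @param polarity `"inward"` (negative-going, e.g. mEPSC at -70 mV) or
#'   `"outward"` (positive-going, e.g. mIPSC at 0 mV).
#' @param noise_sd_pA SD of additive white Gaussian noise (pA).
#' @param duration_s Trace duration (s).
#' @return An object of class `event_train_params`.
#' @export
event_train_params <- function(rate_hz = 5, amp_mean_pA = 30, amp_cv = 0.3,
                               rise_tau_ms = 0.5, decay_tau_ms = 5,
                               polarity = c("inward", "outward"),
                               noise_sd_pA = 3, duration_s = 120) {
  polarity <- match.arg(polarity)
  stopifnot(rate_hz >= 0, decay_tau_ms > rise_tau_ms, rise_tau_ms > 0,
            noise_sd_pA >= 0, duration_s > 0, amp_mean_pA >= 0, amp_cv >= 0)
  structure(list(rate_hz = rate_hz, amp_mean_pA = amp_mean_pA, amp_cv = amp_cv,
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 polarity = polarity, noise_sd_pA = noise_sd_pA,
                 duration_s = duration_s),
            class = "event_train_params")
}

# Unit-peak difference-of-exponentials kernel and its peak delay.
psc_kernel <- function(rise_tau, decay_tau, dt_ms, length_ms = NULL) {
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  if (is.null(length_ms)) length_ms <- t_peak + 8 * decay_tau
  tt <- seq(0, length_ms, by = dt_ms)
  y <- exp(-tt / decay_tau) - exp(-tt / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  list(y = y / peak, t_peak_ms = t_peak)
}

#' Simulate a miniature-PSC trace
#'
#' Event onsets form a homogeneous Poisson process (exponential inter-onset
#' intervals); each event is a difference-of-exponentials with the
#' configured taus, amplitude drawn log-normal at the stated mean and CV;
#' white Gaussian noise is added.
#'
#' @param p An [event_train_params()].
#' @param seed Integer seed.
#' @param dt_ms Sampling interval (ms).
#' @param holding_mV Holding potential stored on the sweep set (mV);
#'   defaults to -70 for inward and 0 for outward events.
#' @param meta Metadata list.
#' @return List with `sweeps` (single-sweep voltage-clamp [sweep_set()]) and
#'   `truth` (`onsets_ms`, `amplitudes_pA` signed, and `short_duration`
#'   warning flag when the duration does not accommodate one expected event).
#' @export
simulate_minis <- function(p, seed = 1, dt_ms = 0.1, holding_mV = NULL,
                           meta = list()) {
  stopifnot(inherits(p, "event_train_params"))
  set.seed(as.integer(seed))
  dur_ms <- p$duration_s * 1000
  short <- p$rate_hz > 0 && p$duration_s < 1 / p$rate_hz
  onsets <- numeric(0)
  if (p$rate_hz > 0) {
    # exponential gaps until past the end; expected count + 6 sd margin
    n_draw <- ceiling(p$rate_hz * p$duration_s + 6 * sqrt(p$rate_hz * p$duration_s) + 10)
    gaps <- stats::rexp(n_draw, rate = p$rate_hz / 1000)  # ms
    onsets <- cumsum(gaps)
    while (sum(gaps) < dur_ms) {
      gaps <- stats::rexp(n_draw, rate = p$rate_hz / 1000)
      onsets <- c(onsets, onsets[length(onsets)] + cumsum(gaps))
    }
    onsets <- onsets[onsets < dur_ms]
  }
  sgn <- if (p$polarity == "inward") -1 else 1
  amps <- numeric(0)
  n_samp <- floor(dur_ms / dt_ms) + 1L
  trace <- stats::rnorm(n_samp, 0, p$noise_sd_pA)
  if (length(onsets)) {
    if (p$amp_cv > 0) {
      sdlog <- sqrt(log(1 + p$amp_cv^2))
      amps <- sgn * stats::rlnorm(length(onsets),
                                  meanlog = log(p$amp_mean_pA) - sdlog^2 / 2,
                                  sdlog = sdlog)
    } else {
      amps <- rep(sgn * p$amp_mean_pA, length(onsets))
    }
    ker <- psc_kernel(p$rise_tau_ms, p$decay_tau_ms, dt_ms)$y
    L <- length(ker)
    for (j in seq_along(onsets)) {
      i0 <- floor(onsets[j] / dt_ms) + 1L
      idx <- i0:min(n_samp, i0 + L - 1L)
      trace[idx] <- trace[idx] + amps[j] * ker[seq_along(idx)]
    }
  }
  if (is.null(holding_mV)) holding_mV <- if (p$polarity == "inward") -70 else 0
  sw <- sweep_set(matrix(trace, nrow = 1L), dt_ms = dt_ms,
                  mode = "voltage_clamp", holding_mV = holding_mV, meta = meta)
  list(sweeps = sw,
       truth = list(onsets_ms = onsets, amplitudes_pA = amps,
                    short_duration = short))
}

#' Parameters of an evoked AMPA/NMDA recording pair
#'
#' @param ampa_amp_pA,nmda_amp_pA Component peak amplitudes (pA, magnitudes).
#' @param ampa_rise_ms,ampa_decay_ms,nmda_rise_ms,nmda_decay_ms Component
#'   kinetics; the NMDA decay must be at least 5x slower than the AMPA decay.
#' @param ampa_pos40_scale Relative amplitude of the AMPA component at
#'   +40 mV. The driving-force ratio for a 0 mV reversal would be 4/7;
#'   the default 0.4 additionally reflects the inward rectification of
#'   AMPA receptors at depolarized potentials (polyamine block), which
#'   shrinks the outward AMPA current below the ohmic prediction.
#' @param artifact_width_ms Width of the square stimulus artifact (ms).
#' @param artifact_amp_pA Artifact amplitude (pA).
#' @param stim_time_ms Stimulus time from sweep start (ms).
#' @param n_sweeps Sweeps per holding potential (default 10, the number
#'   averaged per cell).
#' @param noise_sd_pA Additive Gaussian noise SD (pA).
#' @param duration_ms Sweep duration (ms).
#' @return An object of class `evoked_params`.
#' @export
evoked_params <- function(ampa_amp_pA = 200, nmda_amp_pA = 150,
                          ampa_rise_ms = 0.5, ampa_decay_ms = 4,
                          nmda_rise_ms = 5, nmda_decay_ms = 80,
                          ampa_pos40_scale = 0.4,
                          artifact_width_ms = 1, artifact_amp_pA = 500,
                          stim_time_ms = 50, n_sweeps = 10,
                          noise_sd_pA = 3, duration_ms = 500) {
  stopifnot(ampa_amp_pA >= 0, nmda_amp_pA >= 0,
            nmda_decay_ms >= 5 * ampa_decay_ms,
            ampa_decay_ms > ampa_rise_ms, nmda_decay_ms > nmda_rise_ms,
            n_sweeps >= 1, duration_ms > stim_time_ms)
  structure(list(ampa_amp_pA = ampa_amp_pA, nmda_amp_pA = nmda_amp_pA,
                 ampa_rise_ms = ampa_rise_ms, ampa_decay_ms = ampa_decay_ms,
                 nmda_rise_ms = nmda_rise_ms, nmda_decay_ms = nmda_decay_ms,
                 ampa_pos40_scale = ampa_pos40_scale,
                 artifact_width_ms = artifact_width_ms,
                 artifact_amp_pA = artifact_amp_pA,
                 stim_time_ms = stim_time_ms, n_sweeps = as.integer(n_sweeps),
                 noise_sd_pA = noise_sd_pA, duration_ms = duration_ms),
            class = "evoked_params")
}

# Time (ms after stimulus) at which the unit-peak AMPA kernel first decays
# below `frac` of its peak, solved on the closed-form kernel.
ampa_decay_time <- function(e, frac = 0.1) {
  ker <- psc_kernel(e$ampa_rise_ms, e$ampa_decay_ms, dt_ms = 1e-3)
  f <- function(t) (exp(-t / e$ampa_decay_ms) - exp(-t / e$ampa_rise_ms)) /
    (exp(-ker$t_peak_ms / e$ampa_decay_ms) - exp(-ker$t_peak_ms / e$ampa_rise_ms)) - frac
  stats::uniroot(f, c(ker$t_peak_ms, 100 * e$ampa_decay_ms), tol = 1e-10)$root
}

#' Simulate paired evoked recordings at -70 and +40 mV
#'
#' At -70 mV the sweep contains only the (inward) AMPA component; at +40 mV
#' it contains the outward AMPA component (scaled by the driving-force
#' ratio) plus the (outward) NMDA component. Both holdings carry the same
#' square stimulus artifact at `stim_time_ms`, which the analysis blanks.
#'
#' @param e An [evoked_params()].
#' @param seed Integer seed.
#' @param dt_ms Sampling interval (ms).
#' @param meta Metadata list; `stim_time_ms` and `artifact_width_ms` are
#'   added so the analysis can blank the artifact.
#' @return List with `neg70` and `pos40` ([sweep_set()]s) and `truth`
#'   (component amplitudes, the analytic time `t10_ms` after the stimulus at
#'   which the AMPA component decays to 10% of its peak, and the closed-form
#'   NMDA/AMPA ratio measured at that time, `oracle_ratio`).
#' @export
simulate_evoked <- function(e, seed = 1, dt_ms = 0.05, meta = list()) {
  stopifnot(inherits(e, "evoked_params"))
  set.seed(as.integer(seed))
  n_samp <- floor(e$duration_ms / dt_ms) + 1L
  tt <- (seq_len(n_samp) - 1) * dt_ms
  rel <- tt - e$stim_time_ms
  ka <- psc_kernel(e$ampa_rise_ms, e$ampa_decay_ms, dt_ms,
                   length_ms = e$duration_ms)
  kn <- psc_kernel(e$nmda_rise_ms, e$nmda_decay_ms, dt_ms,
                   length_ms = e$duration_ms)
  shape_at <- function(ker) {
    y <- numeric(n_samp)
    pos <- rel >= 0
    y[pos] <- ker$y[seq_len(sum(pos))]
    y
  }
  a_shape <- shape_at(ka)
  n_shape <- shape_at(kn)
  artifact <- as.numeric(rel >= 0 & rel < e$artifact_width_ms) * e$artifact_amp_pA

  clean_neg <- -e$ampa_amp_pA * a_shape
  clean_pos <- e$ampa_pos40_scale * e$ampa_amp_pA * a_shape + e$nmda_amp_pA * n_shape
  mk <- function(clean, holding) {
    mat <- matrix(NA_real_, e$n_sweeps, n_samp)
    for (k in seq_len(e$n_sweeps)) {
      mat[k, ] <- clean + artifact + stats::rnorm(n_samp, 0, e$noise_sd_pA)
    }
    sweep_set(mat, dt_ms = dt_ms, mode = "voltage_clamp", holding_mV = holding,
              meta = c(meta, list(stim_time_ms = e$stim_time_ms,
                                  artifact_width_ms = e$artifact_width_ms)))
  }
  t10 <- ampa_decay_time(e, 0.1)
  # closed-form composite value at t10 relative to the AMPA peak at -70 mV
  a_at <- function(t) exp(-t / e$ampa_decay_ms) - exp(-t / e$ampa_rise_ms)
  n_at <- function(t) exp(-t / e$nmda_decay_ms) - exp(-t / e$nmda_rise_ms)
  a_pk <- a_at(psc_kernel(e$ampa_rise_ms, e$ampa_decay_ms, 1e-3)$t_peak_ms)
  n_pk <- n_at(psc_kernel(e$nmda_rise_ms, e$nmda_decay_ms, 1e-3)$t_peak_ms)
  comp_pos40 <- e$ampa_pos40_scale * e$ampa_amp_pA * a_at(t10) / a_pk +
    e$nmda_amp_pA * n_at(t10) / n_pk
  oracle_ratio <- if (e$ampa_amp_pA > 0) abs(comp_pos40) / e$ampa_amp_pA else NA_real_
  list(neg70 = mk(clean_neg, -70), pos40 = mk(clean_pos, 40),
       truth = list(ampa_amp_pA = e$ampa_amp_pA, nmda_amp_pA = e$nmda_amp_pA,
                    t10_ms = t10, oracle_ratio = oracle_ratio))
}
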