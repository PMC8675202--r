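test_that("spike detection finds inserted waveforms and honors the refractory rule", {
  cfg <- feature_config()
  dt <- 0.025
  # flat trace: nothing
  expect_identical(detect_spikes(rep(-70, 2000), dt, cfg), integer(0))
  expect_error(detect_spikes(c(-70, NA, -70), dt, cfg), "non-finite")

  # five inserted templates recovered within one sample of ground truth
  sim <- simulate_current_clamp(
    neuron_params(), step_protocol(step_start_pA = 220, step_increment_pA = 20,
                                   step_duration_ms = 500, pre_step_ms = 50,
                                   post_step_ms = 50, n_sweeps = 1),
    seed = 5)
  truth <- sim$truth$spike_times_ms[[1]]
  pk <- detect_spikes(sim$sweeps$data[1, ], dt, cfg)
  expect_equal(length(pk), length(truth))
  expect_true(all(abs((pk - 1) * dt - truth) <= dt))

  # two peaks 1 ms apart with a 2 ms refractory collapse to one detection
  v <- rep(-70, 4000)
  tri <- make_triangle_spike(dt = dt, amp = 95, slope = 120)
  ins <- function(v, at_ms, tri) {
    i0 <- round(at_ms / dt) + 1
    seg <- tri$v - tri$v[1]
    idx <- i0:(i0 + length(seg) - 1)
    v[idx] <- pmax(v[idx], -70 + seg)
    v
  }
  v <- ins(v, 40, tri)
  v <- ins(v, 41, tri)
  expect_length(detect_spikes(v, dt, cfg), 1L)
})

test_that("F-I curve counts match simulator truth and respect the step window", {
  p <- step_protocol(step_start_pA = -100, step_increment_pA = 50,
                     step_duration_ms = 400, pre_step_ms = 50,
                     post_step_ms = 100, n_sweeps = 10)
  sim <- simulate_current_clamp(neuron_params(), p, seed = 6)
  fi <- fi_curve(sim$sweeps)
  expect_equal(fi$n_spikes, lengths(sim$truth$spike_times_ms))
  expect_equal(attr(fi, "rheobase_pA"),
               min(fi$current_pA[fi$n_spikes > 0]))

  # all-subthreshold family: zero counts, absent rheobase
  p0 <- step_protocol(step_start_pA = -100, step_increment_pA = 20,
                      step_duration_ms = 300, pre_step_ms = 50,
                      post_step_ms = 50, n_sweeps = 5)
  sim0 <- simulate_current_clamp(neuron_params(), p0, seed = 1)
  fi0 <- fi_curve(sim0$sweeps)
  expect_true(all(fi0$n_spikes == 0))
  expect_true(is.na(attr(fi0, "rheobase_pA")))

  # a spike after step offset is not counted
  dt <- 0.025
  n <- round(500 / dt)
  v <- rep(-70, n)
  tri <- make_triangle_spike(dt = dt)
  late <- round(460 / dt)  # step ends at pre 50 + 400 = 450 ms
  seg <- tri$v - tri$v[1]
  v[late:(late + length(seg) - 1)] <- -70 + seg
  sw <- sweep_set(matrix(v[1:n], 1), dt_ms = dt, mode = "current_clamp",
                  protocol = step_protocol(step_start_pA = 100,
                                           step_increment_pA = 20,
                                           step_duration_ms = 400,
                                           pre_step_ms = 50, post_step_ms = 50,
                                           n_sweeps = 1))
  expect_equal(fi_curve(sw)$n_spikes, 0L)
})

test_that("AP threshold follows the dV/dt rule on constructed geometry", {
  cfg <- feature_config()
  # slow 5 mV/ms ramp then steep upstroke: threshold at the knee
  rs <- make_ramp_spike(slow_slope = 5, knee = -55, fast_slope = 200,
                        peak = 30)
  f <- ap_waveform_features(rs$v, rs$peak_index, rs$dt, cfg)
  expect_true(f$valid)
  expect_equal(f$threshold_mV, -55, tolerance = 0.01)
  expect_equal(f$amplitude_mV, 85, tolerance = 0.01)
  expect_gt(f$max_rise_mV_ms, 100)
  expect_lt(f$max_decay_mV_ms, 0)

  # a 9 mV/ms ramp is still below the 10 mV/ms criterion: the threshold
  # lands at the top of that ramp, not at its foot
  rs9 <- make_ramp_spike(slow_slope = 9, knee = -55, fast_slope = 200,
                         peak = 30)
  f9 <- ap_waveform_features(rs9$v, rs9$peak_index, rs9$dt, cfg)
  expect_equal(f9$threshold_mV, -55, tolerance = 0.15)

  # symmetric triangle: half-width equals amplitude / slope
  tri <- make_triangle_spike(amp = 100, slope = 100)
  ft <- ap_waveform_features(tri$v, tri$peak_index, tri$dt, cfg)
  expect_true(ft$valid)
  expect_equal(ft$halfwidth_ms, tri$amp / tri$slope, tolerance = 0.02)
})

test_that("threshold equals the exhaustive brute-force scan exactly", {
  cfg <- feature_config()
  # hand-constructed geometries
  for (sl in c(2, 5, 8)) for (fs in c(100, 250)) {
    rs <- make_ramp_spike(slow_slope = sl, fast_slope = fs)
    f <- ap_waveform_features(rs$v, rs$peak_index, rs$dt, cfg)
    expect_identical(f$threshold_index,
                     brute_force_threshold(rs$v, rs$peak_index, rs$dt, cfg))
  }
  # simulated APs
  sim <- simulate_current_clamp(
    neuron_params(), step_protocol(step_start_pA = 200, step_increment_pA = 40,
                                   step_duration_ms = 400, pre_step_ms = 50,
                                   post_step_ms = 50, n_sweeps = 4),
    seed = 7, noise_sd_pA = 5)
  for (k in 1:4) {
    v <- sim$sweeps$data[k, ]
    for (pk in detect_spikes(v, sim$sweeps$dt_ms, cfg)[1:2]) {
      if (is.na(pk)) next
      f <- ap_waveform_features(v, pk, sim$sweeps$dt_ms, cfg)
      expect_identical(f$threshold_index,
                       brute_force_threshold(v, pk, sim$sweeps$dt_ms, cfg))
    }
  }
})

test_that("adaptation ratio implements the 16-18-spike sweep rule", {
  dt <- 0.05
  # build a one-sweep family with spikes at prescribed times
  mk_train <- function(times_ms, dur_ms = 1500) {
    n <- round(dur_ms / dt)
    v <- rep(-70, n)
    tri <- make_triangle_spike(dt = dt)
    seg <- tri$v - tri$v[1]
    for (tm in times_ms) {
      i0 <- round((tm + 100) / dt) + 1
      idx <- i0:(i0 + length(seg) - 1)
      v[idx] <- pmax(v[idx], -70 + seg[seq_along(idx)])
    }
    sweep_set(matrix(v, 1), dt_ms = dt, mode = "current_clamp",
              protocol = step_protocol(step_start_pA = 200,
                                       step_increment_pA = 20,
                                       step_duration_ms = 1300,
                                       pre_step_ms = 100, post_step_ms = 100,
                                       n_sweeps = 1))
  }
  # 17 equally spaced spikes: ratio 1
  s_eq <- mk_train(seq(0, by = 40, length.out = 17))
  r_eq <- adaptation_ratio(s_eq)
  expect_false(r_eq$excluded)
  expect_equal(r_eq$n_spikes, 17L)
  expect_equal(r_eq$ratio, 1, tolerance = 1e-6)

  # T1 = 20 ms, T2 = 50 ms: ratio 0.4
  times <- cumsum(c(0, 20, rep(30, 13), 50))
  r_04 <- adaptation_ratio(mk_train(times))
  expect_equal(r_04$n_spikes, 16L)
  expect_equal(r_04$ratio, 0.4, tolerance = 1e-6)

  # a cell peaking at 14 spikes is excluded, not errored
  s_14 <- mk_train(seq(0, by = 40, length.out = 14))
  r_14 <- adaptation_ratio(s_14)
  expect_true(r_14$excluded)
  expect_true(is.na(r_14$ratio))

  # time rescaling leaves the ratio unchanged
  r_a <- adaptation_ratio(mk_train(cumsum(c(0, 20, rep(30, 14), 50))))
  r_b <- adaptation_ratio(mk_train(cumsum(c(0, 20, rep(30, 14), 50)) * 1.5))
  expect_equal(r_a$ratio, r_b$ratio, tolerance = 1e-6)
})

test_that("passive properties recover RC parameters", {
  cfg <- feature_config()
  dt <- 0.1
  # analytic RC cell: R = 100 MOhm, tau = 20 ms -> C = 200 pF
  p <- step_protocol(step_start_pA = -80, step_increment_pA = 20,
                     step_duration_ms = 500, pre_step_ms = 100,
                     post_step_ms = 100, n_sweeps = 4)
  times <- seq(0, 700, by = dt)
  mk <- function(I_pA) {
    v <- rep(-70, length(times))
    on <- times >= 100 & times < 600
    t_rel <- times[on] - 100
    v[on] <- -70 + I_pA * 0.1 * (1 - exp(-t_rel / 20))  # 0.1 GOhm
    off <- times >= 600
    v_off <- -70 + I_pA * 0.1 * (1 - exp(-500 / 20))
    v[off] <- -70 + (v_off - -70) * exp(-(times[off] - 600) / 20)
    v
  }
  mat <- t(vapply(current_at(p, 0:3), mk, numeric(length(times))))
  s <- sweep_set(mat[, 1:length(times)], dt_ms = dt, mode = "current_clamp",
                 protocol = p)
  pp <- passive_properties(s, cfg)
  expect_true(pp$valid)
  expect_equal(pp$v_rest_mV, -70, tolerance = 0.01)
  expect_equal(pp$rin_mohm, 100, tolerance = 1)
  expect_equal(pp$tau_ms, 20, tolerance = 0.5)
  expect_equal(pp$capacitance_pF, 200, tolerance = 5)
  # -20 pA step settles at -2 mV below rest (Ohm's law)
  ss <- mean(mat[which(current_at(p, 0:3) == -20),
                 times >= 500 & times < 600])
  expect_equal(ss - -70, -2, tolerance = 0.01)

  # simulated passive-regime neuron: R and tau within 5% of generative
  np <- neuron_params(a_nS = 0, b_pA = 0)
  sim <- simulate_current_clamp(np, p, seed = 3)
  pps <- passive_properties(sim$sweeps, cfg)
  expect_true(pps$valid)
  expect_lt(abs(pps$rin_mohm - 1000 / np$gL_nS) / (1000 / np$gL_nS), 0.05)
  expect_lt(abs(pps$tau_ms - np$C_pF / np$gL_nS) / (np$C_pF / np$gL_nS), 0.05)

  expect_error(passive_properties(
    sweep_set(matrix(-70, 2, 100), dt_ms = 0.1, mode = "current_clamp",
              protocol = step_protocol(step_start_pA = 0,
                                       step_increment_pA = 20,
                                       step_duration_ms = 5,
                                       pre_step_ms = 2, post_step_ms = 3,
                                       n_sweeps = 2))),
    "hyperpolarizing")
})
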