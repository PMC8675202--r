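test_that("template matching recovers planted events with accurate onsets", {
  cfg <- detection_config(polarity = "inward")
  p <- event_train_params(rate_hz = 100 / 60, amp_mean_pA = 30, amp_cv = 0,
                          noise_sd_pA = 3, duration_s = 60)
  sim <- simulate_minis(p, seed = 10)
  truth <- sim$truth
  ev <- detect_events(sim$sweeps, cfg = cfg)
  # >= 95% of planted events detected
  matched <- vapply(truth$onsets_ms, function(o)
    any(abs(ev$onset_ms - o) <= 2), logical(1))
  expect_gte(sum(matched), ceiling(0.95 * length(truth$onsets_ms)))
  # each detection lies within 2 ms of a true onset
  near <- vapply(ev$onset_ms, function(o)
    min(abs(truth$onsets_ms - o)), numeric(1))
  expect_lt(stats::quantile(near, 0.95), 2)

  # wrong polarity: nothing (noiseless trace isolates the polarity rule
  # from statistical false positives)
  p_clean <- event_train_params(rate_hz = 2, amp_mean_pA = 30, amp_cv = 0,
                                noise_sd_pA = 0, duration_s = 30)
  sim_clean <- simulate_minis(p_clean, seed = 11)
  ev_out <- detect_events(sim_clean$sweeps,
                          cfg = detection_config(polarity = "outward"))
  expect_equal(nrow(ev_out), 0L)

  # template longer than trace errors
  expect_error(detect_events(rnorm(50), 0.1, cfg), "longer than")
})

test_that("event kinetics match the generative curve on clean data", {
  cfg <- detection_config(polarity = "inward")
  dt <- 0.1
  ker <- epiphys:::psc_kernel(0.5, 5, dt)$y
  x <- numeric(4000)
  on <- 1500
  x[on:(on + length(ker) - 1)] <- -30 * ker
  k <- event_kinetics(x, on, dt, cfg)
  expect_true(k$valid)
  expect_equal(k$amplitude_pA, -30, tolerance = 0.01 * 30)
  expect_equal(k$decay_tau_ms, 5, tolerance = 0.02 * 5)

  # triangular event: 10-90% rise time is 0.8 of the total rise duration
  rise_ms <- 2
  n_r <- round(rise_ms / dt)
  y <- numeric(3000)
  o <- 1000
  y[o:(o + n_r)] <- -30 * (0:n_r) / n_r
  y[(o + n_r + 1):(o + n_r + 400)] <- -30 * exp(-(1:400) * dt / 8)
  kt <- event_kinetics(y, o, dt, detection_config(polarity = "inward",
                                                  peak_smooth_ms = 0))
  expect_equal(kt$rise_ms, 0.8 * rise_ms, tolerance = 0.05)
})

test_that("per-cell summaries apply the 50-event inclusion boundary exactly", {
  mk_events <- function(n) {
    data.frame(onset_ms = seq_len(n) * 100, peak_ms = seq_len(n) * 100 + 1,
               amplitude_pA = rep(-20, n), rise_ms = rep(0.6, n),
               decay_tau_ms = rep(5, n), kinetics_valid = rep(TRUE, n),
               score = rep(5, n))
  }
  expect_false(summarize_cell(mk_events(49), 120)$included)
  expect_true(summarize_cell(mk_events(50), 120)$included)
  expect_equal(summarize_cell(mk_events(600), 120)$frequency_hz, 5)
  expect_error(summarize_cell(mk_events(5), 0), "positive")
})

test_that("E/I ratios are guarded and correct", {
  mk_sum <- function(freq, amp, included = TRUE, id = "c1") {
    structure(list(n_events = 100, frequency_hz = freq,
                   mean_amplitude_pA = amp, mean_rise_ms = 0.6,
                   mean_decay_tau_ms = 5, included = included, cell_id = id),
              class = "cell_synaptic_summary")
  }
  r <- ei_ratio(mk_sum(4, -20), mk_sum(8, 30))
  expect_false(r$excluded)
  expect_equal(r$frequency_ratio, 0.5)
  expect_equal(r$amplitude_ratio, 20 / 30)

  expect_true(ei_ratio(mk_sum(4, -20), mk_sum(0, 30))$excluded)
  expect_true(ei_ratio(mk_sum(4, -20, included = FALSE),
                       mk_sum(8, 30))$excluded)
  expect_error(ei_ratio(mk_sum(4, -20, id = "a"), mk_sum(8, 30, id = "b")),
               "same cell")
})

test_that("end-to-end E/I recovery scales with the generative rate ratio", {
  run_pair <- function(re, ri, seed) {
    e <- simulate_minis(event_train_params(rate_hz = re, polarity = "inward",
                                           duration_s = 60), seed = seed)
    i <- simulate_minis(event_train_params(rate_hz = ri, polarity = "outward",
                                           duration_s = 60), seed = seed + 1000)
    ec <- detection_config(polarity = "inward", min_events = 50)
    ic <- detection_config(polarity = "outward", min_events = 50)
    ei_ratio(summarize_cell(detect_events(e$sweeps, cfg = ec), 60, ec),
             summarize_cell(detect_events(i$sweeps, cfg = ic), 60, ic))
  }
  r1 <- run_pair(5, 10, 21)
  expect_false(r1$excluded)
  expect_lt(abs(r1$frequency_ratio - 0.5) / 0.5, 0.15)
  # doubling the excitatory rate doubles the ratio (within 15%)
  r2 <- run_pair(10, 10, 23)
  expect_lt(abs(r2$frequency_ratio / r1$frequency_ratio - 2) / 2, 0.15)
})

test_that("NMDA/AMPA isolation matches the closed-form oracle", {
  e <- evoked_params()
  sim <- simulate_evoked(e, seed = 31)
  res <- nmda_ampa_ratio(sim$neg70, sim$pos40)
  expect_lt(abs(res$ratio - sim$truth$oracle_ratio) / sim$truth$oracle_ratio,
            0.1)
  expect_gt(res$t10_ms, 0)

  # zero NMDA component: ratio at the noise floor
  s0 <- simulate_evoked(evoked_params(nmda_amp_pA = 0), seed = 32)
  expect_lte(nmda_ampa_ratio(s0$neg70, s0$pos40)$ratio, 0.05)

  # uniform gain scaling of both holdings leaves the ratio unchanged
  sg <- simulate_evoked(e, seed = 33)
  scale_set <- function(s, g) {
    s$data <- s$data * g
    s
  }
  r1 <- nmda_ampa_ratio(sg$neg70, sg$pos40)
  r2 <- nmda_ampa_ratio(scale_set(sg$neg70, 2.5), scale_set(sg$pos40, 2.5))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-10)

  # unequal sweep counts are allowed (logged, not fatal)
  neg_sub <- sg$neg70
  neg_sub$data <- neg_sub$data[1:7, ]
  expect_message(nmda_ampa_ratio(neg_sub, sg$pos40), "unequal sweep counts")

  # AMPA decay that never completes raises the documented error
  slow <- simulate_evoked(evoked_params(ampa_decay_ms = 80,
                                        nmda_decay_ms = 400,
                                        duration_ms = 120,
                                        stim_time_ms = 50), seed = 34)
  expect_error(nmda_ampa_ratio(slow$neg70, slow$pos40), "decay incomplete")
})
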