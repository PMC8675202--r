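# Fixtures and independent oracles shared across test files. Everything is
# built in code at test time; oracles deliberately take a different route
# than the implementation they check.

# piecewise-linear voltage trace: baseline, slow ramp, fast upstroke to the
# peak, linear fall back; returns trace plus the analytically known
# threshold/peak geometry
make_ramp_spike <- function(dt = 0.025, baseline = -70, slow_slope = 5,
                            knee = -55, fast_slope = 200, peak = 30,
                            fall_slope = -100, pre_ms = 20, post_ms = 20) {
  t_slow <- (knee - baseline) / slow_slope
  t_fast <- (peak - knee) / fast_slope
  t_fall <- (baseline - peak) / fall_slope
  tt <- seq(0, pre_ms + t_slow + t_fast + t_fall + post_ms, by = dt)
  v <- numeric(length(tt))
  v[] <- baseline
  in_slow <- tt > pre_ms & tt <= pre_ms + t_slow
  v[in_slow] <- baseline + slow_slope * (tt[in_slow] - pre_ms)
  in_fast <- tt > pre_ms + t_slow & tt <= pre_ms + t_slow + t_fast
  v[in_fast] <- knee + fast_slope * (tt[in_fast] - pre_ms - t_slow)
  in_fall <- tt > pre_ms + t_slow + t_fast &
    tt <= pre_ms + t_slow + t_fast + t_fall
  v[in_fall] <- peak + fall_slope * (tt[in_fall] - pre_ms - t_slow - t_fast)
  list(v = v, dt = dt, threshold = knee, peak = peak,
       amplitude = peak - knee,
       peak_index = which.max(v))
}

# symmetric triangular spike riding on a flat baseline
make_triangle_spike <- function(dt = 0.025, baseline = -70, amp = 100,
                                slope = 100, pre_ms = 10, post_ms = 10) {
  t_side <- amp / slope
  tt <- seq(0, pre_ms + 2 * t_side + post_ms, by = dt)
  v <- rep(baseline, length(tt))
  up <- tt > pre_ms & tt <= pre_ms + t_side
  v[up] <- baseline + slope * (tt[up] - pre_ms)
  dn <- tt > pre_ms + t_side & tt <= pre_ms + 2 * t_side
  v[dn] <- baseline + amp - slope * (tt[dn] - pre_ms - t_side)
  list(v = v, dt = dt, amp = amp, slope = slope,
       peak_index = which.max(v))
}

# exhaustive brute-force threshold oracle: central-difference dV/dt over
# every sample, then the sample closest to the peak among all pre-peak
# samples inside the search window whose derivative is below the criterion
brute_force_threshold <- function(v, peak_index, dt, cfg = feature_config()) {
  n <- length(v)
  dvdt <- rep(NA_real_, n)
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  lo <- max(2L, peak_index - round(cfg$threshold_search_ms / dt))
  idx <- lo:(peak_index - 1L)
  sub <- idx[!is.na(dvdt[idx]) & dvdt[idx] < cfg$dvdt_criterion]
  if (!length(sub)) return(NA_integer_)
  max(sub)
}

# O(n^3) brute-force complete-linkage oracle: at every step recompute all
# inter-cluster distances directly as the maximum pairwise item distance
# (no Lance-Williams update), same smallest-index tie-break
brute_force_complete <- function(m) {
  n <- nrow(m)
  D0 <- as.matrix(stats::dist(m))
  clusters <- lapply(seq_len(n), identity)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    k <- length(clusters)
    best_d <- Inf; best <- NULL; best_key <- c(Inf, Inf)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- max(D0[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (d < best_d - 1e-12 ||
          (d < best_d + 1e-12 &&
           (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best_d <- d; best <- c(i, j); best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- c(codes[i], codes[j])
    height[s] <- best_d
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    codes[i] <- s
    clusters[[j]] <- NULL
    codes <- codes[-j]
  }
  list(merge = merge, height = height)
}

# canonical form of a merge table: sort children within rows (singletons
# by label, then internal by row), so structurally identical trees compare
# equal regardless of child order
canonical_merge <- function(merge) {
  t(apply(merge, 1L, sort))
}

# fixed small long-format table for RM-ANOVA oracle checks
fixture_rm_table <- function() {
  vals <- c(3.1, 4.0, 5.2,
            2.9, 4.4, 5.0,
            3.6, 4.1, 6.1,
            5.0, 6.2, 7.9,
            5.5, 6.0, 8.3,
            4.8, 6.6, 7.5,
            5.1, 6.9, 8.8)
  d <- expand.grid(within = c("w1", "w2", "w3"), subject = sprintf("s%d", 1:7))
  d$between <- ifelse(d$subject %in% c("s1", "s2", "s3"), "gA", "gB")
  d$value <- vals
  long_table(d$subject, d$between, d$within, d$value)
}
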