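# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (vectorized rules, findInterval,
# closed forms) in favor of transparent double loops and enumeration.

# Artifact rules applied literally, sample by sample.
oracle_artifacts <- function(t, mm, velocity_limit = 10, zero_tol = 1e-6) {
  n <- length(mm)
  v <- ifelse(is.na(mm), 0, mm)
  zero <- logical(n)
  vel <- logical(n)
  for (i in seq_len(n)) {
    if (abs(v[i]) <= zero_tol) zero[i] <- TRUE
  }
  for (i in seq_len(n - 1)) {
    if (abs((v[i + 1] - v[i]) / (t[i + 1] - t[i])) > velocity_limit) {
      vel[i] <- TRUE
      vel[i + 1] <- TRUE
    }
  }
  list(flag = zero | vel, zero = zero, velocity = vel)
}

# Linear scan over intervals (half-open), one time at a time.
oracle_labels <- function(timeline, times) {
  out <- character(length(times))
  for (k in seq_along(times)) {
    out[k] <- "outside"
    for (i in seq_len(nrow(timeline))) {
      if (times[k] >= timeline$start_s[i] && times[k] < timeline$end_s[i]) {
        out[k] <- paste(timeline$phase[i], timeline$luminance_state[i],
                        timeline$load[i], sep = "|")
        break
      }
    }
  }
  out
}

# Exact one-sided signed-rank p by enumerating all 2^n sign patterns.
oracle_wilcoxon_exact_p <- function(x, mu0) {
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 2^n
  count <- 0
  for (pattern in 0:(total - 1)) {
    signs <- bitwAnd(pattern, 2^(0:(n - 1))) > 0
    if (sum(r[signs]) >= w_obs) count <- count + 1
  }
  count / total
}

# Random jittered-timestamp trace with occasional zero dropouts and jumps.
random_trace <- function(n, rate = 90) {
  t <- cumsum(runif(n, 0.8 / rate, 1.2 / rate))
  mm <- 4.5 + cumsum(rnorm(n, 0, 0.02))
  mm[runif(n) < 0.05] <- 0
  jump <- runif(n) < 0.03
  mm[jump] <- mm[jump] + sample(c(-1, 1), sum(jump), TRUE) * runif(sum(jump), 0.5, 2)
  list(t = t, mm = mm)
}

# Short protocol for fast tests: 1 cycle x 2 s states, 4 s washout
# (last 2 s baseline), 5 s blocks, 2 s rests.
short_config <- function() {
  protocol_config(plr_cycles = 1, plr_state_s = 2, washout_s = 4,
                  baseline_s = 2, block_s = 5, rest_s = 2)
}

# Dense-grid filtering oracle: applies the same Butterworth cascade on a
# much finer grid directly to an analytic signal, bypassing the package's
# artifact/resampling path, to predict what a zero-phase low-pass does to
# a continuous-time waveform.
oracle_dense_filter <- function(fun, t_end, cutoff_hz, order = 4,
                                dense_rate = 900) {
  t <- seq(0, t_end, by = 1 / dense_rate)
  x <- fun(t)
  bf <- signal::butter(order, cutoff_hz / (dense_rate / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1, max(3 * (order + 1), ceiling(3 * dense_rate / cutoff_hz)))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))[(pad + 1):(pad + n)]
  data.frame(t = t, mm = y)
}
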