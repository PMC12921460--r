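test_that("artifact rules flag the hand-computed blink example", {
  t <- (0:3) / 90
  mask <- detect_artifacts(t, c(4.0, 4.0, 0.0, 4.0))
  expect_equal(mask$flag, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(mask$zero_rule, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(mask$velocity_rule, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(mask$reason, c("none", "velocity", "zero", "velocity"))
})

test_that("a constant trace and in-limit drift produce no flags", {
  t <- (0:99) / 90
  expect_false(any(detect_artifacts(t, rep(4.5, 100))$flag))
  drift <- 4 + 0.005 * seq_len(100)   # 0.45 mm/s, well under the limit
  expect_false(any(detect_artifacts(t, drift)$flag))
  expect_error(detect_artifacts(c(0, 0), c(4, 4)), "strictly increasing")
})

test_that("detection matches the brute-force oracle on random traces", {
  set.seed(101)
  for (rep in 1:40) {
    tr <- random_trace(sample(20:200, 1))
    mask <- detect_artifacts(tr$t, tr$mm)
    ora <- oracle_artifacts(tr$t, tr$mm)
    expect_identical(mask$flag, ora$flag)
    expect_identical(mask$zero_rule, ora$zero)
    expect_identical(mask$velocity_rule, ora$velocity)
  }
})

test_that("mask dilation reaches 50 ms in each direction, inclusive", {
  t <- (0:180) / 90
  mm <- rep(4.5, 181)
  mm[91] <- 0                       # flagged sample at exactly t = 1.0 s
  mask <- detect_artifacts(t, mm)
  dil <- dilate_mask(mask, t, radius_s = 0.050)
  # velocity rule already flagged 90:92; 50 ms at 1/90 s spacing adds 4
  # neighbours (4/90 = 44 ms, inclusive) on each side of that run
  expect_equal(which(mask$flag), 90:92)
  expect_equal(which(dil$flag), 86:96)
  expect_equal(dil$reason[c(86, 89, 93, 96)], rep("dilation", 4))
  expect_equal(dil$reason[91], "zero")
  expect_equal(dil$reason[c(90, 92)], rep("velocity", 2))
  expect_equal(dilate_mask(mask, t, radius_s = 0), mask)
  expect_error(dilate_mask(mask, t, radius_s = -0.01), "config error")
})

test_that("dilating twice with r is contained in dilating once with 2r", {
  set.seed(55)
  for (rep in 1:15) {
    tr <- random_trace(150)
    mask <- detect_artifacts(tr$t, tr$mm)
    twice <- dilate_mask(dilate_mask(mask, tr$t, 0.03), tr$t, 0.03)
    once <- dilate_mask(mask, tr$t, 0.06)
    expect_true(all(!twice$flag | once$flag))
  }
})

test_that("interpolation replaces flagged samples and nothing else", {
  t <- c(0, 0.01, 0.02)
  mm <- c(4.0, 99, 5.0)
  mask <- structure(data.frame(flag = c(FALSE, TRUE, FALSE),
                               reason = c("none", "velocity", "none"),
                               zero_rule = FALSE,
                               velocity_rule = c(FALSE, TRUE, FALSE)),
                    class = c("artifact_mask", "data.frame"))
  expect_equal(interpolate_artifacts(t, mm, mask), c(4.0, 4.5, 5.0))

  # empty mask: identity, bit for bit
  none <- detect_artifacts(c(0, 0.01, 0.02), c(4.4, 4.41, 4.42))
  expect_identical(interpolate_artifacts(t, c(4.4, 4.41, 4.42), none),
                   c(4.4, 4.41, 4.42))

  # leading flagged run takes the first valid value
  t5 <- (0:4) / 90
  mm5 <- c(0, 0, 4.2, 4.2, 4.2)
  m5 <- detect_artifacts(t5, mm5)
  expect_equal(interpolate_artifacts(t5, mm5, m5), rep(4.2, 5))

  all_bad <- detect_artifacts(t5, rep(0, 5))
  expect_error(interpolate_artifacts(t5, rep(0, 5), all_bad),
               "unrecoverable")
})

test_that("interpolation is idempotent and leaves clean samples identical", {
  set.seed(77)
  for (rep in 1:15) {
    tr <- random_trace(120)
    mask <- dilate_mask(detect_artifacts(tr$t, tr$mm), tr$t)
    if (all(mask$flag)) next
    once <- interpolate_artifacts(tr$t, tr$mm, mask)
    expect_identical(once[!mask$flag], tr$mm[!mask$flag])
    expect_identical(interpolate_artifacts(tr$t, once, mask), once)
  }
})

test_that("data loss fraction and the 15% exclusion rule", {
  mk <- function(flags) structure(
    data.frame(flag = flags, reason = ifelse(flags, "zero", "none"),
               zero_rule = flags, velocity_rule = FALSE),
    class = c("artifact_mask", "data.frame"))
  expect_equal(data_loss_fraction(mk(rep(c(TRUE, FALSE), c(10, 90)))), 0.10)
  expect_false(session_excluded(0.10))
  expect_equal(data_loss_fraction(mk(rep(c(TRUE, FALSE), c(16, 84)))), 0.16)
  expect_true(session_excluded(0.16))
  expect_equal(data_loss_fraction(mk(rep(FALSE, 50))), 0)
  expect_false(session_excluded(0.15))  # threshold is strict
})

test_that("uniform resampling is exact for uniform and affine inputs", {
  t <- (0:199) / 90
  mm <- 4 + 0.3 * sin(t)
  out <- resample_uniform(t, mm, 90)
  expect_equal(out$mm, mm, tolerance = 1e-9)
  expect_equal(out$t, t, tolerance = 1e-12)

  set.seed(9)
  tj <- cumsum(runif(300, 0.009, 0.013))
  ramp <- 2 + 1.0 * tj               # 1 mm/s affine signal
  r <- resample_uniform(tj, ramp, 90)
  expect_equal(r$mm, 2 + 1.0 * r$t, tolerance = 1e-9)
  expect_equal(unique(round(diff(r$t), 12)), 1 / 90)
  expect_error(resample_uniform(t, mm, 0), "config error")
})

test_that("zero-phase low-pass has unit DC gain and monotone attenuation", {
  rate <- 90
  t <- (0:(rate * 20)) / rate
  uni <- function(x) structure(data.frame(t = t, mm = x), rate_hz = rate)

  const <- lowpass(uni(rep(4.5, length(t))), cutoff_hz = 0.5)
  expect_equal(const$mm, rep(4.5, length(t)), tolerance = 1e-6)

  # attenuation measured mid-signal, increasing in frequency above cutoff
  gains <- vapply(c(1, 2, 5, 10, 20), function(f) {
    y <- lowpass(uni(sin(2 * pi * f * t)), cutoff_hz = 0.5)$mm
    mid <- t > 5 & t < 15
    max(abs(y[mid]))
  }, numeric(1))
  expect_true(all(diff(gains) < 0))
  expect_lt(gains[4], 0.01)          # 10 Hz through 0.5 Hz: < 1% passes

  expect_error(lowpass(uni(rep(1, length(t))), cutoff_hz = 45),
               "Nyquist")
  expect_error(lowpass(uni(rep(1, length(t))), cutoff_hz = 0), "config error")
})

test_that("no phase lag: a filtered pulse peaks where the input peaks", {
  rate <- 90
  t <- (0:(rate * 30)) / rate
  pulse <- exp(-((t - 15)^2) / (2 * 0.8^2))
  uni <- structure(data.frame(t = t, mm = pulse), rate_hz = rate)
  for (cutoff in c(4, 0.5)) {
    y <- lowpass(uni, cutoff_hz = cutoff)$mm
    expect_lt(abs(t[which.max(y)] - 15), 0.05)
  }
})

test_that("aggressive filtering lowers the peak speed of a reflex transient", {
  rate <- 90
  t <- (0:(rate * 20)) / rate
  step <- 4.75 - 1.5 * (1 - exp(-pmax(t - 10, 0) / 0.2))
  uni <- structure(data.frame(t = t, mm = step), rate_hz = rate)
  v4 <- trace_velocity(lowpass(uni, 4, pathway = "plr"))
  v05 <- trace_velocity(lowpass(uni, 0.5, pathway = "cognitive"))
  expect_lt(max(abs(v05)), max(abs(v4)))
})

test_that("the cleaning chain is a no-op on an artifact-free trace", {
  tl <- build_timeline()
  p <- simulation_params(seed = 31, noise_sd_mm = 0, blink_rate_hz = 0,
                         timestamp_jitter_s = 0)
  sim <- simulate_session(p, tl)
  mono <- combine_eyes(sim$trace)
  mask <- dilate_mask(detect_artifacts(mono$t, mono$mm), mono$t)
  expect_false(any(mask$flag))
  cleaned <- interpolate_artifacts(mono$t, mono$mm, mask)
  uni <- resample_uniform(mono$t, cleaned, attr(sim$trace, "nominal_rate_hz"))
  ref <- stats::approx(mono$t, mono$mm, xout = uni$t, rule = 2)$y
  rng <- diff(range(mono$mm))
  expect_lt(max(abs(uni$mm - ref)) / rng, 1e-6)

  # with timestamp jitter the resampling error stays under 1% of range
  pj <- simulation_params(seed = 31, noise_sd_mm = 0, blink_rate_hz = 0,
                          timestamp_jitter_s = 0.001)
  simj <- simulate_session(pj, tl)
  monoj <- combine_eyes(simj$trace)
  maskj <- dilate_mask(detect_artifacts(monoj$t, monoj$mm), monoj$t)
  cleanedj <- interpolate_artifacts(monoj$t, monoj$mm, maskj)
  unij <- resample_uniform(monoj$t, cleanedj, 90)
  refj <- stats::approx(monoj$t, monoj$mm, xout = unij$t, rule = 2)$y
  expect_lt(max(abs(unij$mm - refj)) / diff(range(monoj$mm)), 0.01)
})

test_that("preprocess_session assembles both pathways with QC accounting", {
  tl <- build_timeline()
  sim <- simulate_session(simulation_params(seed = 13), tl)
  prep <- preprocess_session(sim$trace)
  expect_equal(attr(prep$plr, "cutoff_hz"), 4)
  expect_equal(attr(prep$cognitive, "cutoff_hz"), 0.5)
  expect_equal(attr(prep$plr, "pathway"), "plr")
  expect_equal(nrow(prep$plr), nrow(prep$cognitive))
  expect_equal(prep$qc$n_zero + prep$qc$n_velocity + prep$qc$n_dilation,
               sum(prep$mask$flag))
  expect_equal(prep$data_loss_fraction, mean(prep$mask$flag))
  expect_false(prep$excluded)
})
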