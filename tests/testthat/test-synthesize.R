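test_that("null template with zero noise gives an all-zero session", {
  g <- test_grid()
  tp <- make_spatial_template(g, c(2, 3), spread = 1, peak = 0)
  proto <- contraction_protocol(n_repetitions = 1, fs = 1024)
  nm <- noise_model(baseline_sd = 0, powerline_amplitude = 0, seed = 1)
  s <- synthesize_session(tp, proto, nm, grid = g)
  expect_equal(max(abs(s$signals)), 0)
  expect_equal(dim(s$signals), c(64L, round(6 * 1024)))
})

test_that("sessions are reproducible from the seed and differ across seeds", {
  s1 <- quick_session(seed = 7)
  s2 <- quick_session(seed = 7)
  s3 <- quick_session(seed = 8)
  expect_identical(s1$signals, s2$signals)
  expect_gt(max(abs(s1$signals - s3$signals)), 1)
})

test_that("envelope pipeline recovers the planted amplitude within 15%", {
  # rectified-Gaussian mean factor sqrt(2/pi), peak channel during plateau
  s <- quick_session(peak = 50, baseline_sd = 1, seed = 3,
                     n_repetitions = 2, fs = 2048)
  env <- quick_envelope(s)
  peak_chan <- which.max(rowMeans(env$envelopes))
  fs <- s$fs
  plateau <- round((3.5 * fs):(5.5 * fs))  # middle of first contraction
  level <- mean(env$envelopes[peak_chan, plateau])
  expect_lt(abs(level - 50 * sqrt(2 / pi)), 0.15 * 50 * sqrt(2 / pi))
})

test_that("faulty channel modes leave the planted signatures", {
  faulty <- tibble::tibble(channel = c(5, 40), mode = c("dead", "saturated"))
  s <- quick_session(faulty = faulty, baseline_sd = 2, seed = 9)
  rms <- sqrt(rowMeans(s$signals^2))
  med <- median(rms)
  expect_lt(rms[5], 0.05 * med)
  expect_gt(rms[40], 5 * med)
})

test_that("ground truth records the planted structure", {
  s <- quick_session(center = c(1, 4), n_repetitions = 3, seed = 2,
                     rest_s = 3, contraction_s = 3)
  expect_equal(s$truth$onsets_s, c(3, 9, 15))
  expect_equal(s$truth$center, c(1, 4))
  expect_equal(s$truth$seed, 2)
})

test_that("protocol and noise invariants are enforced", {
  expect_error(contraction_protocol(n_repetitions = 0),
               class = "hdemg_parameter_error")
  expect_error(contraction_protocol(fs = 800), class = "hdemg_parameter_error")
  expect_error(contraction_protocol(contraction_s = -1),
               class = "hdemg_parameter_error")
  expect_error(noise_model(baseline_sd = -1), class = "hdemg_parameter_error")
  expect_error(noise_model(carrier_band = c(450, 20)),
               class = "hdemg_parameter_error")
  g <- test_grid()
  tp <- make_spatial_template(g, c(2, 3), spread = 1)
  expect_error(
    synthesize_session(tp, contraction_protocol(fs = 1024),
                       noise_model(carrier_band = c(20, 600))),
    class = "hdemg_parameter_error")
})

test_that("protocol envelope is trapezoidal with the planted timing", {
  proto <- contraction_protocol(n_repetitions = 2, fs = 1024, ramp_s = 0.25)
  env <- protocol_envelope(proto)
  t <- (seq_along(env) - 1) / 1024
  expect_equal(max(env), 1)
  expect_equal(env[t < 2.9], rep(0, sum(t < 2.9)))
  expect_equal(env[t > 3.3 & t < 5.9], rep(1, sum(t > 3.3 & t < 5.9)))
  # ramp midpoint
  expect_equal(env[which.min(abs(t - 3.125))], 0.5, tolerance = 0.01)
})
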