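make_concat <- function(n_seg = 10, fs = 2048, seg_s = 1, n_chan = 2,
                        seed = 1) {
  len <- round(seg_s * fs)
  withr::with_seed(seed, {
    segs <- lapply(seq_len(n_seg),
                   function(i) matrix(rnorm(n_chan * len), n_chan))
  })
  list(signals = do.call(cbind, segs), fs = fs,
       boundaries = cumsum(c(1L, rep(len, n_seg - 1L))),
       segment_length = rep(as.integer(len), n_seg),
       gesture_label = "g")
}

test_that("steady-state concatenation yields the expected 10-s vector", {
  s <- quick_session(n_repetitions = 2, seed = 51, fs = 1024)
  cc <- concatenate_steady_segments(s)
  expect_equal(ncol(cc$signals), 2 * 1024)
  expect_equal(cc$boundaries, c(1L, 1025L))
  # 10 x 1 s at 2048 Hz -> 20480 samples
  cc10 <- make_concat()
  expect_equal(ncol(cc10$signals), 20480)
  err <- tryCatch(
    concatenate_steady_segments(s, structure(list(steady_windows = NULL),
                                             class = "segmentation")),
    error = identity)
  expect_s3_class(err, "hdemg_parameter_error")
})

test_that("window counts: 9 per 1-s segment, 90 per gesture, 99 straddling", {
  cc <- make_concat()
  f <- feature_windows(cc)
  expect_equal(nrow(f), 90)
  expect_equal(sum(f$segment == 1), 9)
  f_str <- feature_windows(cc, straddle = TRUE)
  expect_equal(nrow(f_str), 99)
})

test_that("time-domain features match hand-computed values", {
  f <- extract_features(c(1, -1, 1, -1))
  expect_equal(unname(f["mav_c01"]), 1)
  expect_equal(unname(f["zc_c01"]), 3)
  expect_equal(unname(f["wl_c01"]), 6)
  expect_equal(unname(f["ssc_c01"]), 2)
  # constant signal
  fc <- extract_features(rep(2, 100))
  expect_equal(unname(fc[c("zc_c01", "ssc_c01", "wl_c01")]), c(0, 0, 0))
  expect_equal(unname(fc["mav_c01"]), 2)
  # strictly monotone ramp
  fr <- extract_features(seq(-1, 1, length.out = 50))
  expect_equal(unname(fr["ssc_c01"]), 0)
  expect_lte(unname(fr["zc_c01"]), 1)
})

test_that("feature vector is channel-major MAV, ZC, SSC, WL", {
  x <- matrix(c(1, -1, 1, -1, 2, 2, 2, 2), nrow = 2, byrow = TRUE)
  f <- extract_features(x)
  expect_equal(names(f)[1:8],
               c("mav_c01", "zc_c01", "ssc_c01", "wl_c01",
                 "mav_c02", "zc_c02", "ssc_c02", "wl_c02"))
  expect_equal(unname(f[5:8]), c(2, 0, 0, 0))
  expect_length(f, 8)
})

test_that("feature invariances: amplitude scaling", {
  x <- withr::with_seed(3, rnorm(400))
  f1 <- extract_features(x)
  f5 <- extract_features(5 * x)
  expect_equal(unname(f5["mav_c01"]), 5 * unname(f1["mav_c01"]))
  expect_equal(unname(f5["wl_c01"]), 5 * unname(f1["wl_c01"]))
  expect_equal(unname(f5[c("zc_c01", "ssc_c01")]),
               unname(f1[c("zc_c01", "ssc_c01")]))
})

test_that("dead-band suppresses small crossings", {
  x <- c(0.1, -0.1, 0.1, -0.1, 5, -5, 5)
  f0 <- extract_features(x, eps = 0)
  f1 <- extract_features(x, eps = 1)
  expect_lt(unname(f1["zc_c01"]), unname(f0["zc_c01"]))
})

test_that("degenerate feature inputs error", {
  expect_error(extract_features(c(1, 2)), class = "hdemg_parameter_error")
  cc <- make_concat(n_seg = 1, seg_s = 0.1)
  expect_error(feature_windows(cc), class = "hdemg_parameter_error")
})
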