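# Frequency-response oracles use signal::freqz on the designed coefficients,
# independently of the filtering code path. Zero-phase application squares
# the magnitude response.

mag_at <- function(filt, f, fs) {
  h <- signal::freqz(filt$b, filt$a, Fs = fs, n = 4096)
  abs(h$h[which.min(abs(h$f - f))])
}

test_that("band-pass magnitude response matches independent evaluation", {
  fs <- 2048
  bp <- design_bandpass(fs)
  expect_gte(mag_at(bp, 100, fs), 0.95)
  expect_lte(mag_at(bp, 100, fs), 1.0 + 1e-9)
  expect_lt(mag_at(bp, 5, fs), 0.05)
  expect_lt(mag_at(bp, 0, fs), 1e-6)   # DC is stopband
  expect_lt(mag_at(bp, 900, fs), 0.05)
})

test_that("band-pass on signals: DC rejected, passband sinusoid preserved", {
  fs <- 2048
  t <- seq(0, 3, by = 1 / fs)
  dc <- bandpass(matrix(1, 1, length(t)), fs)
  expect_lt(max(abs(dc[1, 2048:4096])), 1e-6)
  x <- sin(2 * pi * 100 * t)
  y <- bandpass(x, fs)
  amp <- max(abs(y[2048:4096]))
  expect_gte(amp, 0.95)
  expect_lte(amp, 1.0 + 1e-6)
  x5 <- sin(2 * pi * 5 * t)
  expect_lt(max(abs(bandpass(x5, fs)[2048:4096])), 0.05)
})

test_that("notch rejects 50 Hz by >= 30 dB and leaves 100 Hz within 1%", {
  fs <- 2048
  nt <- design_notch(fs)
  expect_lt(20 * log10(mag_at(nt, 50, fs)), -30)
  expect_lt(abs(mag_at(nt, 100, fs) - 1), 0.01)
  # on signals (zero-phase): pure 50 Hz attenuated, zero stays zero
  t <- seq(0, 3, by = 1 / fs)
  y <- notch(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y[3000:4000])), 10^(-30 / 20))
  expect_equal(notch(numeric(5000), fs), numeric(5000))
  y100 <- notch(sin(2 * pi * 100 * t), fs)
  expect_lt(abs(max(abs(y100[3000:4000])) - 1), 0.01)
})

test_that("envelope low-pass passes DC at unity", {
  lp <- design_lowpass(2048)
  expect_equal(sum(lp$b) / sum(lp$a), 1, tolerance = 1e-6)
})

test_that("designed filters are stable (impulse response decays)", {
  fs <- 2048
  for (filt in list(design_bandpass(fs), design_notch(fs),
                    design_lowpass(fs))) {
    imp <- matrix(c(1, numeric(8 * fs - 1)), 1)
    h <- hdemg:::.iir_rows(filt$b, filt$a, imp)[1, ]
    expect_lt(max(abs(tail(h, fs))), 1e-8 * max(abs(h)))
  }
})

test_that("invalid designs raise parameter errors", {
  expect_error(design_bandpass(800, 20, 450), class = "hdemg_parameter_error")
  expect_error(design_bandpass(2048, 500, 450), class = "hdemg_parameter_error")
  expect_error(design_notch(2048, f0 = 2000), class = "hdemg_parameter_error")
})

test_that("zero-phase kernel agrees with reference single-pass filtering", {
  fs <- 2048
  bp <- design_bandpass(fs)
  x <- matrix(rnorm(3 * 4000), nrow = 3)
  y1 <- hdemg:::.iir_rows(bp$b, bp$a, x)
  y2 <- t(apply(x, 1, function(v)
    as.numeric(signal::filter(signal::Arma(b = bp$b, a = bp$a), v))))
  expect_lt(max(abs(y1 - y2)), 1e-8)
})
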