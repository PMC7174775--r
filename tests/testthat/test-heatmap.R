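fake_env <- function(values_by_channel, fs = 1024, n = 2 * 1024) {
  structure(list(envelopes = matrix(values_by_channel, 64, n), fs = fs,
                 provenance = list()), class = "envelope_set")
}

test_that("repetition heatmaps average the steady window per electrode", {
  g <- test_grid()
  env <- fake_env(rep(0.5, 64))
  hm <- build_repetition_heatmap(env, c(1, 1024), g)
  expect_equal(hm$absolute$values, matrix(0.5, 8, 8))
  # single active channel maps to its grid cell
  v <- rep(0, 64)
  ch <- channel_of(g, 4, 6)
  v[ch] <- 2
  hm2 <- build_repetition_heatmap(fake_env(v), c(1, 512), g)
  expect_equal(hm2$absolute$values[5, 7], 2)
  expect_equal(sum(hm2$absolute$values > 0), 1)
  # normalized map divides by the per-channel factors
  f <- rep(4, 64)
  hm3 <- build_repetition_heatmap(fake_env(v), c(1, 512), g, factors = f)
  expect_equal(hm3$normalized$values[5, 7], 0.5)
})

test_that("heatmap recovers the planted template at high SNR", {
  s <- quick_session(center = c(3, 4), spread = 1, peak = 50,
                     baseline_sd = 1, n_repetitions = 1, seed = 41)
  env <- quick_envelope(s)
  seg <- detect_onsets(env, s$protocol)
  hm <- build_repetition_heatmap(
    env, c(seg$steady_windows$start[1], seg$steady_windows$end[1]),
    session_grid(s))
  r2 <- cor(as.vector(hm$absolute$values),
            as.vector(s$truth$templates[[1]]$amplitudes))^2
  expect_gte(r2, 0.95)
})

test_that("averaging heatmaps is the cell-wise mean", {
  maps1 <- replicate(10, random_heatmap(1), simplify = FALSE)
  expect_equal(average_heatmap(maps1)$values, maps1[[1]]$values)
  zeros <- emg_heatmap(matrix(0, 8, 8), "normalized")
  ones <- emg_heatmap(matrix(1, 8, 8), "normalized")
  avg <- average_heatmap(c(replicate(5, zeros, simplify = FALSE),
                           replicate(5, ones, simplify = FALSE)))
  expect_equal(avg$values, matrix(0.5, 8, 8))
  expect_equal(avg$repetition, "average")
  # cell identity against an independent mean
  maps <- lapply(1:10, random_heatmap)
  avg2 <- average_heatmap(maps)
  expect_equal(avg2$values[3, 5],
               mean(vapply(maps, function(m) m$values[3, 5], 0)))
  expect_error(average_heatmap(list(zeros, emg_heatmap(matrix(1, 8, 8), "absolute"))),
               class = "hdemg_parameter_error")
})

test_that("COG follows the thresholded amplitude-weighted centroid", {
  g <- test_grid()
  # single hot cell
  m <- matrix(0, 8, 8)
  m[3, 4] <- 1
  cog <- compute_cog(emg_heatmap(m, "normalized"), g)
  expect_equal(c(cog$row, cog$col), c(2, 3))
  expect_equal(cog$n_cells, 1L)
  expect_equal(cog$cog_x_pct, (2 + 0.5) / 8 * 100)
  expect_equal(cog$cog_y_pct, (0.2 * 26 + 3 * 2 + 1) / 26 * 100)
  # two equal maxima at the column extremes, rest below threshold
  m2 <- matrix(0.1, 8, 8)
  m2[1, 1] <- 1
  m2[1, 8] <- 1
  cog2 <- compute_cog(emg_heatmap(m2, "normalized"), g)
  expect_equal(cog2$col, 3.5)
  expect_equal(cog2$row, 0)
  expect_equal(cog2$n_cells, 2L)
  # uniform map: all 64 cells, center of the grid
  cog3 <- compute_cog(emg_heatmap(matrix(1, 8, 8), "normalized"), g,
                      circular = FALSE)
  expect_equal(c(cog3$row, cog3$col), c(3.5, 3.5))
  expect_equal(cog3$n_cells, 64L)
})

test_that("circular row centroid handles activity straddling the seam", {
  g <- test_grid()
  m <- matrix(0, 8, 8)
  m[1, 4] <- 1   # row 0
  m[8, 4] <- 1   # row 7
  cog <- compute_cog(emg_heatmap(m, "normalized"), g)
  # wrap-aware midpoint: -0.5 and 7.5 name the same seam point
  expect_lt(abs(((cog$row + 0.5 + 4) %% 8) - 4), 1e-9)
  lin <- compute_cog(emg_heatmap(m, "normalized"), g, circular = FALSE)
  expect_equal(lin$row, 3.5)  # planar fallback
})

test_that("COG is scale invariant and threshold-monotone", {
  g <- test_grid()
  for (seed in 1:20) {
    hm <- random_heatmap(seed)
    c1 <- compute_cog(hm, g)
    c2 <- compute_cog(emg_heatmap(hm$values * 7.3, hm$kind), g)
    expect_equal(c1$row, c2$row, tolerance = 1e-12)
    expect_equal(c1$col, c2$col, tolerance = 1e-12)
    n_cells <- vapply(c(0.5, 0.7, 0.8, 0.95),
                      function(th) compute_cog(hm, g, threshold = th)$n_cells,
                      integer(1))
    expect_true(all(diff(n_cells) <= 0))
  }
})

test_that("ties at exactly the threshold are included", {
  g <- test_grid()
  m <- matrix(0, 8, 8)
  m[3, 3] <- 1
  m[3, 5] <- 0.8
  cog <- compute_cog(emg_heatmap(m, "normalized"), g, threshold = 0.8)
  expect_equal(cog$n_cells, 2L)
})

test_that("an all-zero map has no COG", {
  g <- test_grid()
  expect_error(compute_cog(emg_heatmap(matrix(0, 8, 8), "normalized"), g),
               class = "hdemg_parameter_error")
})

test_that("max activation reads the cell-wise maxima", {
  z <- emg_heatmap(matrix(0, 8, 8), "normalized")
  za <- emg_heatmap(matrix(0, 8, 8), "absolute")
  expect_equal(unlist(max_activation(z, za)),
               c(max_normalized = 0, max_absolute = 0))
  m <- matrix(runif(64), 8, 8)
  m[2, 2] <- 1
  expect_equal(max_activation(emg_heatmap(m, "normalized"), za)$max_normalized, 1)
})
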