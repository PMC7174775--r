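test_that("repeatability of identical maps is perfect across all 45 pairs", {
  base <- random_heatmap(1)
  maps <- replicate(10, base, simplify = FALSE)
  sim <- repeatability(maps)
  expect_equal(sim$n_unique_pairs, 45)
  expect_equal(nrow(tidy(sim)), 45)
  expect_true(all(abs(tidy(sim)$r_squared - 1) < 1e-12))
  expect_equal(diag(sim$values), rep(1, 10), ignore_attr = TRUE)
  expect_equal(sim$values, t(sim$values))
})

test_that("squared Pearson correlation is shift invariant", {
  m <- random_heatmap(2)
  shifted <- emg_heatmap(m$values + 0.3, "normalized")
  sim <- repeatability(list(m, shifted))
  expect_equal(tidy(sim)$r_squared, 1, tolerance = 1e-12)
})

test_that("pair counts equal n choose 2", {
  for (n in 2:12) {
    maps <- lapply(seq_len(n), random_heatmap)
    sim <- repeatability(maps)
    expect_equal(sim$n_unique_pairs, choose(n, 2))
    expect_equal(nrow(tidy(sim)), choose(n, 2))
  }
})

test_that("zero-variance maps raise an error naming the repetition", {
  maps <- list(random_heatmap(1), emg_heatmap(matrix(0.5, 8, 8), "normalized"))
  err <- tryCatch(repeatability(maps), error = identity)
  expect_s3_class(err, "hdemg_parameter_error")
  expect_match(conditionMessage(err), "2")
})

test_that("gesture similarity separates orthogonal and duplicated gestures", {
  g <- test_grid()
  # disjoint-support templates: off-diagonal R^2 near zero
  centers <- list(c(0, 1), c(2, 4), c(4, 6), c(6, 2))
  maps <- lapply(seq_along(centers), function(i) {
    tp <- make_spatial_template(g, centers[[i]], spread = 0.4)
    emg_heatmap(tp$amplitudes, "normalized",
                gesture_label = paste0("g", i))
  })
  sim <- gesture_similarity(maps)
  expect_lt(max(tidy(sim)$r_squared), 0.05)
  expect_equal(sim$labels, paste0("g", 1:4))
  # 7 gestures give 21 unique pairs
  maps7 <- lapply(1:7, function(i) {
    m <- random_heatmap(100 + i)
    m$gesture_label <- paste0("g", i)
    m
  })
  expect_equal(gesture_similarity(maps7)$n_unique_pairs, 21)
  # a duplicated gesture pair correlates perfectly
  maps7[[2]] <- maps7[[1]]
  maps7[[2]]$gesture_label <- "g2"
  sim7 <- tidy(gesture_similarity(maps7))
  expect_equal(sim7$r_squared[sim7$item1 == "g1" & sim7$item2 == "g2"], 1,
               tolerance = 1e-12)
})

test_that("PCA dimensionality identifies planted structure", {
  # rank 1: 70 near-copies of one map
  base <- as.vector(random_heatmap(3)$values)
  x <- matrix(rep(base, 70), ncol = 70) +
    withr::with_seed(4, matrix(rnorm(64 * 70, sd = 1e-12), 64))
  pc <- pca_dimensionality(x)
  expect_equal(pc$n_pcs, 1L)
  expect_gt(pc$ve[1], 1 - 1e-9)
  # 5 orthogonal equal-power patterns (orthogonal also to the constant
  # vector, so centering is a no-op): 20% each, 5 PCs
  q <- withr::with_seed(7, qr.Q(qr(cbind(1, matrix(rnorm(64 * 5), 64)))))
  pats <- q[, 2:6]
  x5 <- pats[, rep(1:5, each = 14)]
  pc5 <- pca_dimensionality(x5)
  expect_equal(pc5$n_pcs, 5L)
  expect_equal(pc5$ve[1:5], rep(0.2, 5), tolerance = 1e-9)
  # noiseless planted rank k gives exactly k nonzero components
  expect_lt(sum(pc5$ve > 1e-12), 6)
})

test_that("variance explained is a normalized, monotone decomposition", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(runif(64 * 30), 64))
    pc <- pca_dimensionality(x)
    expect_true(all(pc$ve >= 0))
    expect_equal(sum(pc$ve), 1, tolerance = 1e-9)
    expect_true(all(diff(pc$cumulative_ve) >= -1e-12))
    expect_equal(tail(pc$cumulative_ve, 1), 1, tolerance = 1e-9)
    expect_true(all(diff(pc$ve) <= 1e-12))
  }
})

test_that("a centered 64-observation matrix has at most 63 components", {
  x <- withr::with_seed(9, matrix(runif(64 * 70), 64))
  pc <- pca_dimensionality(x)
  expect_lte(sum(pc$ve > 1e-12), 63)
})

test_that("activation summary reports group means and SDs", {
  one <- tibble::tibble(group = "dmd", max_normalized = 0.7,
                        max_absolute = 30)
  s1 <- activation_summary(one)
  expect_equal(s1$mean_normalized, 0.7)
  expect_equal(s1$sd_normalized, 0)
  # 3 participants x 7 gestures x 10 reps = 210 events
  tbl <- tidyr::expand_grid(participant = 1:3, gesture = 1:7, rep = 1:10)
  tbl$group <- "dmd"
  tbl$max_normalized <- withr::with_seed(1, runif(nrow(tbl)))
  tbl$max_absolute <- withr::with_seed(2, runif(nrow(tbl), 10, 40))
  s <- activation_summary(tbl)
  expect_equal(s$n, 210L)
})
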