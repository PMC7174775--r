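fast_protocol <- function(n_repetitions = 10) {
  contraction_protocol(n_repetitions = n_repetitions, fs = 1024)
}

test_that("cohort plans are deterministic and empty cohorts are allowed", {
  pr <- cohort_profile("dmd")
  c1 <- make_cohort(pr, 2, protocol = fast_protocol(), seed = 5)
  c2 <- make_cohort(pr, 2, protocol = fast_protocol(), seed = 5)
  expect_identical(cohort_truth(c1), cohort_truth(c2))
  expect_identical(c1$participants[[1]]$gestures$hand_open$rep_amplitudes,
                   c2$participants[[1]]$gestures$hand_open$rep_amplitudes)
  empty <- make_cohort(pr, 0, protocol = fast_protocol(), seed = 5)
  expect_length(empty$participants, 0)
  expect_error(make_cohort(pr, -1, protocol = fast_protocol()),
               class = "hdemg_parameter_error")
})

test_that("realized sessions are reproducible and carry ground truth", {
  pr <- cohort_profile("dmd")
  co <- make_cohort(pr, 1, protocol = fast_protocol(2), seed = 6)
  s1 <- cohort_session(co, 1, "hand_open")
  s2 <- cohort_session(co, "DP01", "hand_open")
  expect_identical(s1$signals, s2$signals)
  expect_equal(s1$truth$onsets_s, protocol_onsets(co$protocol))
  expect_equal(length(s1$truth$templates), 2)
})

test_that("profile defaults encode the planted group contrast", {
  h <- cohort_profile("healthy")
  d <- cohort_profile("dmd")
  expect_gt(d$normalized_activation_level, h$normalized_activation_level)
  expect_lt(d$absolute_scale, h$absolute_scale)
  expect_lt(d$n_templates_distinct, h$n_templates_distinct)
  expect_error(cohort_profile("dmd", n_templates_distinct = 8),
               class = "hdemg_parameter_error")
  expect_error(cohort_profile("dmd", normalized_activation_level = 1.5),
               class = "hdemg_parameter_error")
})

test_that("gesture blends reuse base patterns beyond the planted rank", {
  co <- make_cohort(rank_recovery_profile(3), 1, protocol = fast_protocol(1),
                    seed = 7)
  p <- co$participants[[1]]
  coeffs <- vapply(p$gestures, `[[`, numeric(3), "coeffs")
  expect_equal(coeffs[, 1:3], diag(3), ignore_attr = TRUE)
  expect_true(all(colSums(coeffs[, 4:7] > 0) >= 2))
  # every pattern lies in the span of the base templates: planted rank holds
  X <- sapply(unlist(lapply(p$gestures, function(g) g$rep_amplitudes),
                     recursive = FALSE), as.vector)
  expect_equal(qr(X)$rank, 3)
})

test_that("planted rank is recovered through the PCA (3, 5, 7)", {
  for (k in c(3, 5, 7)) {
    co <- make_cohort(rank_recovery_profile(k), 1,
                      protocol = fast_protocol(10), seed = 30 + k)
    p <- co$participants[[1]]
    X <- sapply(unlist(lapply(p$gestures, function(g) g$rep_amplitudes),
                       recursive = FALSE), as.vector)
    expect_equal(pca_dimensionality(X)$n_pcs, k)
  }
})

test_that("cohorts write to disk with a ground-truth sidecar", {
  co <- make_cohort(cohort_profile("dmd"), 1,
                    protocol = fast_protocol(1), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$planted_rank, 3)
  expect_equal(gt$onsets_s, 3)
  s <- read_session(file.path(dir, "DP01", "hand_open"))
  expect_equal(s$gesture_label, "hand_open")
  expect_true(file.exists(file.path(dir, "DP01", "mvc", "signals.dat")))
})
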