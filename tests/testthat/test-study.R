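# A miniature cohort keeps the end-to-end tests fast: 2 gestures x 3
# repetitions at 1024 Hz. The full-scale study conditions are exercised in
# the acceptance suite.
mini_cohorts <- function(seed = 1) {
  proto <- contraction_protocol(n_repetitions = 3, fs = 1024)
  gestures <- default_gestures()[1:2]
  list(
    make_cohort(cohort_profile("healthy", n_templates_distinct = 2), 1,
                gestures = gestures, protocol = proto, seed = seed),
    make_cohort(cohort_profile("dmd", n_templates_distinct = 2), 1,
                gestures = gestures, protocol = proto, seed = seed + 100)
  )
}

test_that("invalid configurations fail before any computation", {
  expect_error(study_config(cog_threshold = 1.5), class = "hdemg_config_error")
  expect_error(study_config(cog_threshold = 0), class = "hdemg_config_error")
  expect_error(study_config(ve_threshold = 1), class = "hdemg_config_error")
  expect_error(study_config(train_fraction = 1), class = "hdemg_config_error")
  expect_error(study_config(onset_k = -2), class = "hdemg_config_error")
  expect_error(study_config(overlap_s = 0.3), class = "hdemg_config_error")
})

test_that("the study pipeline produces consistent per-participant tables", {
  rep <- run_study(mini_cohorts(), study_config(seed = 2))
  expect_equal(rep$provenance$n_participants_ok, 2)
  expect_equal(nrow(rep$failures), 0)
  # 2 gestures x C(3,2) repetition pairs per participant
  expect_equal(nrow(rep$tables$repeatability), 2 * 2 * choose(3, 2))
  # C(2,2) gesture pair per participant
  expect_equal(nrow(rep$tables$similarity), 2)
  # activation events: 2 gestures x 3 reps per participant
  expect_equal(nrow(rep$tables$activation), 2 * 6)
  expect_equal(sort(unique(rep$tables$accuracy$k)), 2)
  # group statistic equals recomputation from the long table
  act <- rep$tables$activation
  expect_equal(
    rep$group$activation$mean_normalized[rep$group$activation$group == "dmd"],
    mean(act$max_normalized[act$group == "dmd"]))
  r2 <- rep$tables$repeatability
  expect_equal(
    rep$group$repeatability$mean_r2[rep$group$repeatability$group == "healthy"],
    mean(r2$r_squared[r2$group == "healthy"]))
})

test_that("a study run is deterministic: identical reports byte for byte", {
  r1 <- run_study(mini_cohorts(), study_config(seed = 3))
  r2 <- run_study(mini_cohorts(), study_config(seed = 3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_report(r1, d1)
  emit_report(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("emitted reports round-trip and summarize failures", {
  rep <- run_study(mini_cohorts(), study_config(seed = 4))
  out <- withr::local_tempdir()
  emit_report(rep, out)
  back <- readr::read_csv(file.path(out, "activation.csv"),
                          show_col_types = FALSE)
  expect_equal(back$max_normalized, rep$tables$activation$max_normalized)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(any(grepl("participants processed: 2",
                        readLines(file.path(out, "summary.txt")))))
})

test_that("an empty cohort yields an empty but valid report", {
  co <- make_cohort(cohort_profile("dmd"), 0,
                    protocol = contraction_protocol(fs = 1024), seed = 1)
  rep <- run_study(co, study_config(seed = 1))
  expect_equal(rep$provenance$n_participants_ok, 0)
  out <- withr::local_tempdir()
  emit_report(rep, out)
  expect_true(any(grepl("zero participants",
                        readLines(file.path(out, "summary.txt")))))
  expect_false(file.exists(file.path(out, "activation.csv")))
})

test_that("per-participant failures are collected without aborting the cohort", {
  cohorts <- mini_cohorts(seed = 7)
  # sabotage one participant: a noise model whose bursts cannot be detected
  dir <- withr::local_tempdir()
  write_cohort(cohorts[[1]], dir)
  # truncate one gesture's signals so segmentation fails
  bad <- file.path(dir, "HP01", "hand_open")
  meta <- jsonlite::read_json(file.path(bad, "metadata.json"),
                              simplifyVector = TRUE)
  n_keep <- round(4 * meta$fs)
  con <- file(file.path(bad, "signals.dat"), "rb")
  v <- readBin(con, "numeric", meta$n_channels * meta$n_samples, size = 4)
  close(con)
  m <- t(matrix(v, nrow = meta$n_samples))[, 1:n_keep]
  s_bad <- recording_session(
    m, meta$fs, meta$gesture_label, meta$participant_id,
    do.call(contraction_protocol,
            meta$protocol[c("n_repetitions", "contraction_s", "rest_s",
                            "fs", "ramp_s")]),
    as.list(meta$anthropometrics))
  write_session(s_bad, bad)
  rep <- run_study(dir, study_config(seed = 8))
  expect_equal(rep$provenance$n_participants_ok, 0)
  expect_equal(nrow(rep$failures), 1)
  expect_equal(rep$failures$participant, "HP01")
})

test_that("a cohort directory is a valid study input", {
  cohorts <- mini_cohorts(seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(cohorts[[2]], dir)
  rep <- run_study(dir, study_config(seed = 10), classify = FALSE)
  expect_equal(rep$tables$participants$participant, "DP01")
  expect_equal(rep$tables$participants$group, "dmd")
  expect_equal(nrow(rep$tables$dimensionality), 1)
})
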