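#' Study configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis with the
#' defaults of the acquisition study: 10-SD onset threshold, 80% COG
#' threshold, 90% variance-explained threshold, 200 ms / 100 ms feature
#' windows and three 70/30 Monte Carlo splits. Validation happens here, so
#' an invalid configuration fails before any computation.
#'
#' @param onset_k Onset threshold in baseline SDs.
#' @param cog_threshold COG inclusion threshold, fraction of map maximum in
#'   (0, 1].
#' @param ve_threshold Cumulative variance-explained threshold in (0, 1).
#' @param repair `"auto"`, `NULL`, or an integer vector of faulty channels.
#' @param window_s,overlap_s Feature window length and overlap (s).
#' @param n_splits,train_fraction Monte Carlo cross-validation settings.
#' @param accuracy_ks Gesture counts for the accuracy curve (`NULL` for 2
#'   up to the number of gestures).
#' @param straddle Allow feature windows across segment splices.
#' @param seed Master seed for all randomized stages.
#' @return A `study_config` list.
#' @export
study_config <- function(onset_k = 10, cog_threshold = 0.8,
                         ve_threshold = 0.9, repair = "auto",
                         window_s = 0.2, overlap_s = 0.1,
                         n_splits = 3, train_fraction = 0.7,
                         accuracy_ks = NULL, straddle = FALSE, seed = 1L) {
  err <- function(msg, ...) abort(sprintf(msg, ...), class = "hdemg_config_error")
  ok_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok_num(onset_k) || onset_k <= 0) err("onset_k must be > 0")
  if (!ok_num(cog_threshold) || cog_threshold <= 0 || cog_threshold > 1) {
    err("cog_threshold = %s must be in (0, 1]", format(cog_threshold))
  }
  if (!ok_num(ve_threshold) || ve_threshold <= 0 || ve_threshold >= 1) {
    err("ve_threshold must be in (0, 1)")
  }
  if (!ok_num(window_s) || window_s <= 0 || !ok_num(overlap_s) ||
      overlap_s < 0 || overlap_s >= window_s) {
    err("need 0 <= overlap_s < window_s")
  }
  if (!ok_num(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    err("train_fraction must be in (0, 1)")
  }
  if (!ok_num(n_splits) || n_splits < 1) err("n_splits must be >= 1")
  if (!ok_num(seed)) err("seed must be a number")
  structure(
    list(onset_k = onset_k, cog_threshold = cog_threshold,
         ve_threshold = ve_threshold, repair = repair,
         window_s = window_s, overlap_s = overlap_s,
         n_splits = as.integer(n_splits), train_fraction = train_fraction,
         accuracy_ks = accuracy_ks, straddle = straddle,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the end-to-end study analysis
#'
#' Executes the full chain for every participant — channel repair,
#' band-pass and notch filtering, envelope extraction, onset segmentation,
#' normalization, heatmaps — then the motor-control metrics (repeatability,
#' COG, maximum activations, similarity, PCA dimensionality) and the
#' offline myocontrol assessment (time-domain features, regularized LDA,
#' Monte Carlo cross-validation, accuracy-versus-gesture-count). The run is
#' deterministic given the input and `config$seed`. A participant whose
#' processing fails is reported in `failures` and excluded from group
#' summaries without aborting the cohort.
#'
#' @param x An `emg_cohort`, a list of cohorts (e.g. healthy plus DMD), or a
#'   directory written by [write_cohort()].
#' @param config A [study_config()].
#' @param classify Run the myocontrol stage (default `TRUE`; the spatial
#'   metrics alone are considerably faster).
#' @return A `study_report`: list of per-participant tables, group
#'   summaries, `failures`, and a provenance block.
#' @export
run_study <- function(x, config = study_config(), classify = TRUE) {
  stopifnot(inherits(config, "study_config"))
  loaders <- participant_loaders(x)
  part_seeds <- draw_seeds(max(1L, length(loaders)), config$seed)

  results <- list()
  failures <- list()
  for (i in seq_along(loaders)) {
    ld <- loaders[[i]]
    res <- tryCatch(
      process_participant(ld, config, part_seeds[i], classify),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(participant = ld$id, error = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  assemble_report(results, failures, config, n_input = length(loaders))
}

participant_loaders <- function(x) {
  if (inherits(x, "emg_cohort")) x <- list(x)
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    dirs <- list.dirs(x, recursive = FALSE)
    return(lapply(dirs, function(d) {
      gestures <- basename(list.dirs(d, recursive = FALSE))
      list(id = basename(d),
           group = id_group(basename(d)),
           gestures = setdiff(gestures, "mvc"),
           has_mvc = "mvc" %in% gestures,
           load = function(g) read_session(file.path(d, g)))
    }))
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "emg_cohort"))) {
    return(unlist(lapply(x, function(co) {
      lapply(seq_along(co$participants), function(p) {
        pid <- co$participants[[p]]$id
        list(id = pid, group = co$profile$group, gestures = co$gestures,
             has_mvc = !is.null(co$participants[[p]]$mvc),
             load = function(g) cohort_session(co, pid, g))
      })
    }), recursive = FALSE))
  }
  stop_param("`x` must be a cohort, a list of cohorts, or a cohort directory")
}

id_group <- function(id) {
  if (grepl("^HP", id)) "healthy" else if (grepl("^DP", id)) "dmd" else "unknown"
}

process_participant <- function(ld, config, seed, classify) {
  labels <- c(ld$gestures, if (ld$has_mvc) "mvc")
  per_session <- list()
  grid <- NULL
  for (g in labels) {
    s <- ld$load(g)
    if (is.null(grid)) grid <- session_grid(s)
    rest_win <- c(1L, max(2L, as.integer(round(s$protocol$rest_s * s$fs))))
    raw <- if (is.null(config$repair)) s$signals else
      repair_channels(s$signals, grid, faulty = config$repair,
                      diagnostic_window = rest_win)
    bp <- bandpass(raw, s$fs)
    env <- envelope(notch(bp, s$fs), s$fs)
    sm <- moving_average(env$envelopes, max(1L, as.integer(round(s$fs))))
    seg <- detect_onsets(env, s$protocol, k = config$onset_k)
    sw <- seg$steady_windows
    steady_means <- t(vapply(seq_len(nrow(sw)), function(j) {
      rowMeans(env$envelopes[, sw$start[j]:(sw$end[j] - 1L), drop = FALSE])
    }, numeric(nrow(env$envelopes))))
    per_session[[g]] <- list(
      smoothed_max = apply(sm, 1, max, na.rm = TRUE),
      steady_means = steady_means,  # reps x channels, uV
      steady_raw = if (classify && g != "mvc") {
        lapply(seq_len(nrow(sw)),
               function(j) bp[, sw$start[j]:(sw$end[j] - 1L), drop = FALSE])
      },
      fs = s$fs, n_reps = nrow(sw),
      repaired = attr(raw, "faulty") %||% integer(0)
    )
  }
  factors <- Reduce(pmax, lapply(per_session, `[[`, "smoothed_max"))
  if (any(factors <= 0)) stop_param("non-positive normalization factor")

  rep_maps_norm <- list()
  rep_maps_abs <- list()
  avg_maps <- list()
  for (g in ld$gestures) {
    ps <- per_session[[g]]
    rep_maps_norm[[g]] <- lapply(seq_len(ps$n_reps), function(j) {
      emg_heatmap(cells_from_channels(grid, ps$steady_means[j, ] / factors),
                  "normalized", gesture_label = g, repetition = j)
    })
    rep_maps_abs[[g]] <- lapply(seq_len(ps$n_reps), function(j) {
      emg_heatmap(cells_from_channels(grid, ps$steady_means[j, ]),
                  "absolute", gesture_label = g, repetition = j)
    })
    avg_maps[[g]] <- average_heatmap(rep_maps_norm[[g]])
  }

  repeat_tbl <- purrr::map_dfr(ld$gestures, function(g) {
    dplyr::mutate(tidy(repeatability(rep_maps_norm[[g]])), gesture = g,
                  .before = 1)
  })
  sim <- gesture_similarity(unname(avg_maps), labels = ld$gestures)
  cog_tbl <- purrr::map_dfr(ld$gestures, function(g) {
    dplyr::mutate(compute_cog(avg_maps[[g]], grid,
                              threshold = config$cog_threshold),
                  gesture = g, .before = 1)
  })
  act_tbl <- purrr::map_dfr(ld$gestures, function(g) {
    purrr::map_dfr(seq_len(per_session[[g]]$n_reps), function(j) {
      dplyr::mutate(max_activation(rep_maps_norm[[g]][[j]],
                                   rep_maps_abs[[g]][[j]]),
                    gesture = g, repetition = j, .before = 1)
    })
  })
  pca <- pca_dimensionality(unlist(rep_maps_norm, recursive = FALSE),
                            ve_threshold = config$ve_threshold)

  acc <- NULL
  cv7 <- NULL
  if (classify) {
    feats <- purrr::map_dfr(ld$gestures, function(g) {
      ps <- per_session[[g]]
      concat <- list(signals = do.call(cbind, ps$steady_raw), fs = ps$fs,
                     boundaries = cumsum(c(1L, head(vapply(ps$steady_raw, ncol, 0L), -1L))),
                     segment_length = vapply(ps$steady_raw, ncol, 0L),
                     gesture_label = g)
      feature_windows(concat, window_s = config$window_s,
                      overlap_s = config$overlap_s, straddle = config$straddle)
    })
    cv_seeds <- draw_seeds(2, seed)
    cv7 <- monte_carlo_cv(feats, n_splits = config$n_splits,
                          train_fraction = config$train_fraction,
                          seed = cv_seeds[1])
    acc <- accuracy_vs_gesture_count(feats, ks = config$accuracy_ks,
                                     gesture_order = ld$gestures,
                                     seed = cv_seeds[2],
                                     n_splits = config$n_splits,
                                     train_fraction = config$train_fraction)
  }

  list(id = ld$id, group = ld$group, grid = grid,
       repeatability = repeat_tbl, similarity = sim, cog = cog_tbl,
       activation = act_tbl, pca = pca, accuracy = acc, cv7 = cv7,
       repaired = lapply(per_session, `[[`, "repaired"))
}

assemble_report <- function(results, failures, config, n_input) {
  add_id <- function(res, tbl) {
    dplyr::mutate(tbl, participant = res$id, group = res$group, .before = 1)
  }
  tables <- list(
    participants = purrr::map_dfr(results, function(r) {
      tibble::tibble(participant = r$id, group = r$group,
                     forearm_length_cm = r$grid$length_cm,
                     circumference_cm = r$grid$circumference_cm)
    }),
    repeatability = purrr::map_dfr(results, function(r) add_id(r, r$repeatability)),
    similarity = purrr::map_dfr(results, function(r) add_id(r, tidy(r$similarity))),
    cog = purrr::map_dfr(results, function(r) add_id(r, r$cog)),
    activation = purrr::map_dfr(results, function(r) add_id(r, r$activation)),
    dimensionality = purrr::map_dfr(results, function(r) add_id(r, glance(r$pca))),
    ve_curves = purrr::map_dfr(results, function(r) add_id(r, tidy(r$pca))),
    accuracy = purrr::map_dfr(results, function(r) {
      if (is.null(r$accuracy)) tibble::tibble() else add_id(r, tidy(r$accuracy))
    })
  )

  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  group_summaries <- list()
  if (nrow(tables$participants)) {
    group_summaries$repeatability <- dplyr::summarise(
      dplyr::group_by(tables$repeatability, .data$group),
      mean_r2 = mean(.data$r_squared), sd_r2 = sd0(.data$r_squared),
      n = dplyr::n(), .groups = "drop")
    group_summaries$activation <- activation_summary(tables$activation)
    group_summaries$dimensionality <- dplyr::summarise(
      dplyr::group_by(tables$dimensionality, .data$group),
      mean_n_pcs = mean(.data$n_pcs), mean_pc1_ve = mean(.data$pc1_ve),
      n = dplyr::n(), .groups = "drop")
    group_summaries$similarity <- dplyr::summarise(
      dplyr::group_by(tables$similarity, .data$group, .data$item1, .data$item2),
      mean_r2 = mean(.data$r_squared), .groups = "drop")
    if (nrow(tables$accuracy)) {
      group_summaries$accuracy <- dplyr::summarise(
        dplyr::group_by(tables$accuracy, .data$group, .data$k),
        mean_accuracy = mean(.data$accuracy), sd_accuracy = sd0(.data$accuracy),
        .groups = "drop")
    }
  }

  structure(
    list(tables = tables, group = group_summaries,
         failures = if (length(failures)) dplyr::bind_rows(failures) else
           tibble::tibble(participant = character(), error = character()),
         provenance = list(
           config = unclass(config),
           n_participants_in = n_input,
           n_participants_ok = length(results),
           package_version = as.character(utils::packageVersion("hdemg"))
         )),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d/%d participants processed, %d failure(s)\n",
              x$provenance$n_participants_ok, x$provenance$n_participants_in,
              nrow(x$failures)))
  if (!is.null(x$group$activation)) {
    print(x$group$activation)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes every per-participant table as CSV, the group summaries and
#' provenance as `summary.json`, and a short human-readable `summary.txt`.
#' File names are stable: `participants.csv`, `repeatability.csv`,
#' `similarity.csv`, `cog.csv`, `activation.csv`, `dimensionality.csv`,
#' `ve_curves.csv`, `accuracy.csv`.
#'
#' @param report A `study_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    tbl <- report$tables[[nm]]
    if (nrow(tbl)) readr::write_csv(tbl, file.path(outdir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(
    list(group_summaries = report$group, failures = report$failures,
         provenance = report$provenance),
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)

  lines <- c("HD-sEMG study report",
             sprintf("participants processed: %d of %d",
                     report$provenance$n_participants_ok,
                     report$provenance$n_participants_in))
  if (report$provenance$n_participants_ok == 0) {
    lines <- c(lines, "zero participants: no tables written")
  } else {
    act <- report$group$activation
    lines <- c(lines, vapply(seq_len(nrow(act)), function(i) {
      sprintf("%s: normalized %.2f +/- %.2f, absolute %.1f +/- %.1f uV (n = %d)",
              act$group[i], act$mean_normalized[i], act$sd_normalized[i],
              act$mean_absolute[i], act$sd_absolute[i], act$n[i])
    }, ""))
  }
  if (nrow(report$failures)) {
    lines <- c(lines, sprintf("FAILED %s: %s", report$failures$participant,
                              report$failures$error))
  }
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(outdir)
}
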