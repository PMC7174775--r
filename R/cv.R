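#' Monte Carlo cross-validation of gesture classification
#'
#' Repeated random 70/30 train/test partitioning (3 splits by default), with
#' a fresh classifier per split and the mean test accuracy as the
#' performance metric. Splits are stratified by class so every gesture is
#' represented in both partitions.
#'
#' @param features Numeric matrix or tibble of features (e.g. from
#'   [feature_windows()]; non-feature columns `gesture`, `segment`,
#'   `window` are dropped automatically).
#' @param labels Class labels; defaults to the `gesture` column of
#'   `features` when present.
#' @param n_splits Number of Monte Carlo splits (default 3).
#' @param train_fraction Fraction of each class used for training (default
#'   0.7).
#' @param seed Integer seed making the splits reproducible.
#' @param ... Passed to [train_lda()].
#' @return An `mc_cv`: `splits` tibble (split, accuracy), `mean_accuracy`,
#'   `confusion` (list of per-split label x label count matrices, rows =
#'   truth), `train_fraction`, `seed`.
#' @export
monte_carlo_cv <- function(features, labels = NULL, n_splits = 3,
                           train_fraction = 0.7, seed = NULL, ...) {
  check_number(n_splits, "n_splits", lower = 1)
  check_number(train_fraction, "train_fraction", 0, 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  if (is.null(labels) && is.data.frame(features) && "gesture" %in% names(features)) {
    labels <- features$gesture
  }
  if (is.null(labels)) stop_param("`labels` required (or a `gesture` column)")
  x <- if (is.data.frame(features)) {
    feature_matrix(features[, setdiff(names(features), "gesture"), drop = FALSE])
  } else {
    as.matrix(features)
  }
  y <- factor(labels)
  if (nrow(x) != length(y)) stop_param("features and labels differ in length")

  splits <- with_seed_maybe(seed, {
    lapply(seq_len(n_splits), function(s) {
      train_idx <- unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        n_tr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
        sample(idx, n_tr)
      }), use.names = FALSE)
      train_idx
    })
  })

  results <- lapply(seq_along(splits), function(s) {
    tr <- splits[[s]]
    te <- setdiff(seq_along(y), tr)
    fit <- train_lda(x[tr, , drop = FALSE], y[tr], ...)
    pred <- predict(fit, x[te, , drop = FALSE])
    conf <- table(truth = factor(y[te], levels = levels(y)),
                  predicted = factor(pred, levels = levels(y)))
    list(accuracy = mean(pred == y[te]), confusion = unclass(conf))
  })

  acc <- vapply(results, `[[`, 0, "accuracy")
  structure(
    list(splits = tibble::tibble(split = seq_len(n_splits), accuracy = acc),
         mean_accuracy = mean(acc),
         confusion = lapply(results, `[[`, "confusion"),
         train_fraction = train_fraction,
         n_splits = as.integer(n_splits),
         seed = seed, levels = levels(y)),
    class = "mc_cv"
  )
}

#' @export
print.mc_cv <- function(x, ...) {
  cat(sprintf("<mc_cv> %d splits (train %g%%): mean accuracy %.3f [%s]\n",
              x$n_splits, 100 * x$train_fraction, x$mean_accuracy,
              paste(sprintf("%.3f", x$splits$accuracy), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.mc_cv <- function(x, ...) x$splits

#' @export
glance.mc_cv <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$splits$accuracy),
                 n_splits = x$n_splits,
                 train_fraction = x$train_fraction)
}

#' Accuracy as a function of the number of gestures
#'
#' Runs the Monte Carlo cross-validation on the first `k` gestures of
#' `gesture_order` for every `k`, tracing how classification accuracy decays
#' as the gesture set grows. `k = 1` is excluded as degenerate.
#'
#' @param features Feature tibble with a `gesture` column (or matrix with
#'   `labels`).
#' @param labels Optional label vector.
#' @param gesture_order Order in which gestures are added; defaults to
#'   [default_gestures()] filtered to the labels present.
#' @param ks Gesture counts to evaluate (default 2 up to the number of
#'   gestures).
#' @param seed Integer seed; each `k` uses a sub-seed drawn from it.
#' @param ... Passed to [monte_carlo_cv()].
#' @return An `accuracy_curve`: tibble `results` (k, split, accuracy) and
#'   `summary` (k, mean_accuracy, sd_accuracy).
#' @export
accuracy_vs_gesture_count <- function(features, labels = NULL,
                                      gesture_order = NULL, ks = NULL,
                                      seed = NULL, ...) {
  if (is.null(labels) && is.data.frame(features) && "gesture" %in% names(features)) {
    labels <- features$gesture
  }
  if (is.null(labels)) stop_param("`labels` required (or a `gesture` column)")
  labels <- as.character(labels)
  present <- unique(labels)
  gesture_order <- gesture_order %||% c(intersect(default_gestures(), present),
                                        setdiff(present, default_gestures()))
  if (!all(gesture_order %in% present)) {
    stop_param("gesture_order contains gestures absent from the data: %s",
               toString(setdiff(gesture_order, present)))
  }
  ks <- ks %||% (2:length(gesture_order))
  if (any(ks < 2)) stop_param("`ks` must be >= 2 (single-class runs are degenerate)")
  x <- if (is.data.frame(features)) {
    feature_matrix(features[, setdiff(names(features), "gesture"), drop = FALSE])
  } else {
    as.matrix(features)
  }
  sub_seeds <- draw_seeds(length(ks), seed)

  res <- purrr::map2_dfr(ks, sub_seeds, function(k, s) {
    keep <- labels %in% gesture_order[seq_len(k)]
    cv <- monte_carlo_cv(x[keep, , drop = FALSE], labels[keep], seed = s, ...)
    dplyr::mutate(cv$splits, k = k, .before = 1)
  })
  summary <- dplyr::summarise(dplyr::group_by(res, .data$k),
                              mean_accuracy = mean(.data$accuracy),
                              sd_accuracy = sd(.data$accuracy),
                              .groups = "drop")
  structure(list(results = res, summary = summary,
                 gesture_order = gesture_order, seed = seed),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("<accuracy_curve>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.accuracy_curve <- function(x, ...) x$results

#' @export
glance.accuracy_curve <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("k", "mean_accuracy")],
                     names_from = "k", values_from = "mean_accuracy",
                     names_prefix = "k")
}
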