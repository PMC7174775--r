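#' Detect contraction onsets and segment a recording
#'
#' An onset is the first sample at which a summary envelope trace exceeds the
#' baseline mean plus `k` baseline standard deviations (10 by default),
#' where the baseline is the initial rest period of the protocol after
#' discarding the first `settle_s` seconds of filter transient. Each onset
#' opens a contraction window of `contraction_s` seconds; the steady-state
#' window is that window shrunk by the transient fraction on each side (with
#' the defaults, the middle 1 s of a 3 s contraction).
#'
#' The summary trace aggregates channels: by default the mean of the raw
#' envelopes over channels whose normalization factor exceeds the 25th
#' percentile (amplitude-weighted, robust to dead channels); when
#' participant-wide `factors` are supplied the mean of the *normalized*
#' envelopes over those channels is used instead, and a single-channel mode
#' is available.
#'
#' Threshold crossings are cleaned by merging above-threshold runs separated
#' by less than `merge_gap_s` and dropping runs shorter than `min_burst_s`.
#' Finding a number of bursts different from `protocol$n_repetitions` is an
#' error: segmentation is not guessed.
#'
#' @param env An `envelope_set` from [envelope()].
#' @param protocol The [contraction_protocol()] of the recording.
#' @param k Threshold in baseline standard deviations (default 10).
#' @param factors Optional participant-wide [normalization_factors()].
#' @param aggregate `"auto"` (raw mean without factors, normalized mean with
#'   them), `"raw_mean"`, `"normalized_mean"`, or `"channel"`.
#' @param channel Channel number for `aggregate = "channel"`.
#' @param steady_fraction Fraction of the contraction trimmed from each side
#'   for the steady-state window (default 1/3).
#' @param settle_s Initial seconds of the baseline discarded (default 0.5).
#' @param min_burst_s,merge_gap_s Burst cleaning parameters in seconds.
#' @return A `segmentation`: list with `onsets` (sample indices),
#'   `contraction_windows` and `steady_windows` (tibbles with `start`,
#'   `end` sample indices, end exclusive), `threshold_used`,
#'   `baseline_stats`.
#' @export
detect_onsets <- function(env, protocol, k = 10, factors = NULL,
                          aggregate = c("auto", "raw_mean", "normalized_mean",
                                        "channel"),
                          channel = NULL, steady_fraction = 1 / 3,
                          settle_s = 0.5, min_burst_s = 0.25,
                          merge_gap_s = 0.25) {
  stopifnot(inherits(env, "envelope_set"),
            inherits(protocol, "contraction_protocol"))
  aggregate <- match.arg(aggregate)
  check_number(k, "k", lower = 0, allow_equal_lower = FALSE)
  check_number(steady_fraction, "steady_fraction", 0, 0.5)
  fs <- env$fs
  e <- env$envelopes
  n <- ncol(e)

  if (aggregate == "auto") {
    aggregate <- if (is.null(factors)) "raw_mean" else "normalized_mean"
  }
  summary_trace <- switch(
    aggregate,
    channel = {
      if (is.null(channel)) stop_param("`channel` required for single-channel mode")
      e[channel, ]
    },
    raw_mean = ,
    normalized_mean = {
      f <- factors %||% {
        w <- max(1L, as.integer(round(fs)))
        apply(moving_average(e, w), 1, max, na.rm = TRUE)
      }
      sel <- which(f > stats::quantile(f, 0.25))
      if (!length(sel)) sel <- seq_len(nrow(e))
      if (aggregate == "normalized_mean") {
        colMeans(e[sel, , drop = FALSE] / f[sel])
      } else {
        colMeans(e[sel, , drop = FALSE])
      }
    }
  )

  b0 <- max(1L, as.integer(round(settle_s * fs)) + 1L)
  b1 <- as.integer(round(protocol$rest_s * fs))
  if (b1 <= b0 + 10L) {
    stop_param("rest period too short for a baseline estimate (%.2g s after settling)",
               (b1 - b0) / fs)
  }
  baseline <- summary_trace[b0:b1]
  thr <- mean(baseline) + k * sd(baseline)

  above <- summary_trace >= thr
  runs <- run_bounds(above)
  runs <- merge_runs(runs, as.integer(round(merge_gap_s * fs)))
  runs <- runs[(runs[, 2] - runs[, 1] + 1L) >= as.integer(round(min_burst_s * fs)), ,
               drop = FALSE]
  # filter edge transients: a genuine burst cannot end inside the initial
  # rest period that defines the baseline
  runs <- runs[runs[, 2] > b1, , drop = FALSE]
  n_found <- nrow(runs)
  if (n_found == 0 || n_found != protocol$n_repetitions) {
    abort(sprintf("expected %d activity bursts but found %d (threshold %.4g)",
                  protocol$n_repetitions, n_found, thr),
          class = "hdemg_segmentation_error")
  }
  onsets <- runs[, 1]
  len_c <- as.integer(round(protocol$contraction_s * fs))
  trim <- as.integer(round(steady_fraction * protocol$contraction_s * fs))
  ends <- onsets + len_c
  if (onsets[n_found] + len_c - trim - 1L > n) {
    abort("last steady-state window extends past the end of the recording",
          class = "hdemg_segmentation_error")
  }
  # a detection-jitter overhang of the final contraction window is clipped
  ends <- pmin(ends, n + 1L)
  structure(
    list(
      onsets = onsets,
      contraction_windows = tibble::tibble(start = onsets, end = ends),
      steady_windows = tibble::tibble(start = onsets + trim,
                                      end = onsets + len_c - trim),
      threshold_used = thr,
      baseline_stats = c(mean = mean(baseline), sd = sd(baseline)),
      fs = fs, aggregate = aggregate, k = k
    ),
    class = "segmentation"
  )
}

run_bounds <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

merge_runs <- function(runs, max_gap) {
  if (nrow(runs) < 2) return(runs)
  keep <- list(runs[1, ])
  for (i in 2:nrow(runs)) {
    last <- keep[[length(keep)]]
    if (runs[i, 1] - last[2] <= max_gap) {
      keep[[length(keep)]] <- c(last[1], runs[i, 2])
    } else {
      keep[[length(keep) + 1L]] <- runs[i, ]
    }
  }
  do.call(rbind, keep)
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d contractions, threshold %.4g (baseline %.4g +/- %.4g)\n",
              length(x$onsets), x$threshold_used,
              x$baseline_stats["mean"], x$baseline_stats["sd"]))
  invisible(x)
}

#' @export
tidy.segmentation <- function(x, ...) {
  tibble::tibble(
    repetition = seq_along(x$onsets),
    onset_s = (x$onsets - 1) / x$fs,
    contraction_start_s = (x$contraction_windows$start - 1) / x$fs,
    contraction_end_s = (x$contraction_windows$end - 1) / x$fs,
    steady_start_s = (x$steady_windows$start - 1) / x$fs,
    steady_end_s = (x$steady_windows$end - 1) / x$fs
  )
}
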