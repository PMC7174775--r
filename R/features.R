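#' Concatenate steady-state segments of one gesture
#'
#' Band-pass filters the raw signals (20-450 Hz by default) and concatenates
#' the steady-state windows of all repetitions in repetition order, giving
#' the ~10 s per-gesture signal used for classifier training. Segment
#' boundaries are recorded so feature windows need not straddle a splice
#' between non-contiguous signal.
#'
#' @param session A [recording_session()].
#' @param segmentation A `segmentation` from [detect_onsets()], or `NULL` to
#'   detect onsets here.
#' @param low,high,order Band-pass parameters.
#' @param filtered Optional pre-filtered signal matrix (channels x samples)
#'   to reuse; when given, no filtering is done here.
#' @return List: `signals` (channels x total samples), `fs`, `boundaries`
#'   (start index of each segment, 1-based), `segment_length`,
#'   `gesture_label`.
#' @export
concatenate_steady_segments <- function(session, segmentation = NULL,
                                        low = 20, high = 450, order = 4,
                                        filtered = NULL) {
  stopifnot(inherits(session, "recording_session"))
  if (is.null(segmentation)) {
    env <- envelope(notch(bandpass(session$signals, session$fs, low, high, order),
                          session$fs),
                    session$fs)
    segmentation <- detect_onsets(env, session$protocol)
  }
  sw <- segmentation$steady_windows
  if (is.null(sw) || !nrow(sw)) stop_param("segmentation holds no steady windows")
  x <- filtered %||% bandpass(session$signals, session$fs, low, high, order)
  pieces <- lapply(seq_len(nrow(sw)),
                   function(i) x[, sw$start[i]:(sw$end[i] - 1L), drop = FALSE])
  lens <- vapply(pieces, ncol, 0L)
  list(
    signals = do.call(cbind, pieces),
    fs = session$fs,
    boundaries = cumsum(c(1L, lens[-length(lens)])),
    segment_length = lens,
    gesture_label = session$gesture_label
  )
}

#' Time-domain features of one analysis window
#'
#' The classical myocontrol feature set, per channel: mean absolute value
#' (MAV), zero crossings (ZC), slope-sign changes (SSC) and waveform length
#' (WL). ZC counts sign changes whose amplitude step exceeds the dead-band
#' `eps`; SSC counts slope-sign reversals exceeding `eps`. With `eps = 0`
#' both are scale invariant while MAV and WL scale linearly with amplitude.
#'
#' @param window Channels x samples matrix (or vector for one channel).
#' @param eps Dead-band threshold in uV (default 0).
#' @return Named numeric vector of length `4 * n_channels`, ordered
#'   channel-major: `mav_c01, zc_c01, ssc_c01, wl_c01, mav_c02, ...`.
#' @examples
#' extract_features(c(1, -1, 1, -1)) # MAV 1, ZC 3, SSC 2, WL 6
#' @export
extract_features <- function(window, eps = 0) {
  x <- as_signal_matrix(window, "window")
  n <- ncol(x)
  if (n < 3) stop_param("feature window must hold at least 3 samples")
  mav <- rowMeans(abs(x))
  d <- x[, -1, drop = FALSE] - x[, -n, drop = FALSE]
  wl <- rowSums(abs(d))
  prod_sign <- x[, -n, drop = FALSE] * x[, -1, drop = FALSE]
  zc <- rowSums(prod_sign < 0 & abs(d) >= eps)
  slope_rev <- d[, -(n - 1), drop = FALSE] * d[, -1, drop = FALSE]
  big <- pmax(abs(d[, -(n - 1), drop = FALSE]), abs(d[, -1, drop = FALSE]))
  ssc <- rowSums(slope_rev < 0 & big >= eps)
  feats <- rbind(mav, zc, ssc, wl)
  out <- as.vector(feats)
  names(out) <- paste0(rep(c("mav", "zc", "ssc", "wl"), nrow(x)), "_c",
                       sprintf("%02d", rep(seq_len(nrow(x)), each = 4)))
  out
}

#' Sliding feature windows over concatenated steady segments
#'
#' Cuts 200 ms windows with 100 ms overlap and extracts the time-domain
#' features of each. By default windows never span a segment boundary (each
#' 1 s steady segment at 2048 Hz yields 9 windows, 90 per gesture);
#' `straddle = TRUE` slides one window train across the whole concatenation
#' instead.
#'
#' @param concat Result of [concatenate_steady_segments()].
#' @param window_s,overlap_s Window length and overlap in seconds.
#' @param eps Dead-band for ZC/SSC.
#' @param straddle Allow windows to cross segment boundaries.
#' @return A tibble: `gesture`, `segment`, `window`, then one column per
#'   feature.
#' @export
feature_windows <- function(concat, window_s = 0.2, overlap_s = 0.1,
                            eps = 0, straddle = FALSE) {
  check_number(window_s, "window_s", lower = 0, allow_equal_lower = FALSE)
  check_number(overlap_s, "overlap_s", lower = 0, upper = window_s,
               allow_equal_upper = FALSE)
  fs <- concat$fs
  wlen <- as.integer(floor(window_s * fs))
  step <- as.integer(floor((window_s - overlap_s) * fs))
  x <- concat$signals
  ranges <- if (straddle) {
    window_starts(ncol(x), wlen, step, offset = 0L, segment = NA_integer_)
  } else {
    do.call(rbind, lapply(seq_along(concat$boundaries), function(i) {
      window_starts(concat$segment_length[i], wlen, step,
                    offset = concat$boundaries[i] - 1L, segment = i)
    }))
  }
  if (is.null(ranges) || !nrow(ranges)) {
    stop_param("segments shorter than one feature window")
  }
  feats <- t(vapply(seq_len(nrow(ranges)), function(i) {
    extract_features(x[, ranges[i, "start"]:(ranges[i, "start"] + wlen - 1L),
                       drop = FALSE], eps = eps)
  }, numeric(4L * nrow(x))))
  dplyr::bind_cols(
    tibble::tibble(gesture = concat$gesture_label,
                   segment = ranges[, "segment"],
                   window = seq_len(nrow(ranges))),
    tibble::as_tibble(feats)
  )
}

window_starts <- function(len, wlen, step, offset, segment) {
  if (len < wlen) return(NULL)
  n_win <- (len - wlen) %/% step + 1L
  cbind(start = offset + (seq_len(n_win) - 1L) * step + 1L,
        segment = rep(as.integer(segment), n_win))
}

feature_matrix <- function(features) {
  num <- vapply(features, is.numeric, TRUE) &
    !(names(features) %in% c("segment", "window"))
  as.matrix(features[, num, drop = FALSE])
}
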