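#' Repair faulty channels by grid-neighborhood interpolation
#'
#' Replaces each faulty channel, sample by sample, with the mean of its
#' available non-faulty neighbors in the electrode grid (8-neighborhood).
#' Rows wrap circumferentially around the forearm; cells at the longitudinal
#' extremes use their smaller neighborhoods. All replacements are computed
#' from the original non-faulty channels, so the result does not depend on
#' the order of the faulty list and repairing an already repaired matrix with
#' the same list changes nothing.
#'
#' With `faulty = "auto"` channels are flagged when their broadband RMS is
#' more than `rms_high` times, or less than `rms_low` times, the median
#' channel RMS — an explicit, reproducible stand-in for visual inspection of
#' dead or saturated electrodes. An explicit channel list always overrides
#' the automatic rule.
#'
#' @param x Channels x samples matrix or an `envelope_set`.
#' @param grid The [electrode_grid()] describing channel placement.
#' @param faulty Integer channel numbers, `"auto"`, or `NULL` for no repair.
#' @param rms_high,rms_low Outlier multipliers for the automatic rule.
#' @param diagnostic_window Optional `(start, end)` sample range over which
#'   the automatic rule measures RMS. Passing the initial rest period keeps
#'   genuine high-amplitude activity from being mistaken for a saturated
#'   electrode; the default uses the whole recording.
#' @return Same type as `x`, with attribute `faulty` listing the channels
#'   that were replaced.
#' @export
repair_channels <- function(x, grid, faulty = "auto",
                            rms_high = 5, rms_low = 0.05,
                            diagnostic_window = NULL) {
  if (inherits(x, "envelope_set")) {
    x$envelopes <- repair_channels(x$envelopes, grid, faulty, rms_high, rms_low,
                                   diagnostic_window)
    attr(x, "faulty") <- attr(x$envelopes, "faulty")
    return(x)
  }
  x <- as_signal_matrix(x)
  n_chan <- nrow(x)
  if (n_chan != grid$n_rows * grid$n_cols) {
    stop_format("matrix has %d channels but the grid defines %d",
                n_chan, grid$n_rows * grid$n_cols)
  }
  if (is.null(faulty)) {
    attr(x, "faulty") <- integer(0)
    return(x)
  }
  if (identical(faulty, "auto")) {
    xd <- if (is.null(diagnostic_window)) x else
      x[, diagnostic_window[1]:diagnostic_window[2], drop = FALSE]
    rms <- sqrt(rowMeans(xd^2))
    med <- median(rms)
    faulty <- which(rms > rms_high * med | rms < rms_low * med)
  }
  faulty <- sort(unique(as.integer(faulty)))
  if (any(faulty < 1 | faulty > n_chan)) {
    stop_param("faulty channel numbers must be in 1..%d", n_chan)
  }
  if (!length(faulty)) {
    attr(x, "faulty") <- integer(0)
    return(x)
  }
  cells <- cell_of(grid)
  out <- x
  for (ch in faulty) {
    cell <- cells[cells$channel == ch, ]
    nb <- grid_neighbors(grid, cell$row, cell$col)
    good <- setdiff(nb$channel, faulty)
    if (!length(good)) {
      abort(sprintf("channel %d cannot be repaired: all %d neighbors are faulty",
                    ch, nrow(nb)),
            class = "hdemg_channel_error")
    }
    out[ch, ] <- colMeans(x[good, , drop = FALSE])
  }
  attr(out, "faulty") <- faulty
  out
}
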