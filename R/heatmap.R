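#' Activation heatmaps
#'
#' An activation heatmap is the grid-shaped image of per-electrode mean
#' envelope amplitude over a steady-state contraction window: one heatmap per
#' repetition, averaged into one per gesture for spatial analysis.
#'
#' `build_repetition_heatmap()` averages each channel's envelope over one
#' steady window and arranges the 64 values on the grid, returning the
#' absolute map (uV) and, when normalization `factors` are given, the
#' normalized map (fraction of the per-channel dataset maximum).
#'
#' @param env An `envelope_set`.
#' @param steady_window Length-2 integer `(start, end)` sample window (end
#'   exclusive), e.g. one row of a `segmentation`'s `steady_windows`.
#' @param grid The [electrode_grid()].
#' @param factors Optional [normalization_factors()].
#' @param gesture_label,repetition Metadata stored in the heatmap.
#' @return A list with elements `absolute` and (if factors are supplied)
#'   `normalized`, each an `emg_heatmap`.
#' @export
build_repetition_heatmap <- function(env, steady_window, grid, factors = NULL,
                                     gesture_label = NULL, repetition = NULL) {
  stopifnot(inherits(env, "envelope_set"))
  w <- as.integer(unlist(steady_window)[1:2])
  if (w[1] < 1 || w[2] - 1L > ncol(env$envelopes) || w[2] <= w[1]) {
    stop_param("steady window [%d, %d) outside the envelope", w[1], w[2])
  }
  means <- rowMeans(env$envelopes[, w[1]:(w[2] - 1L), drop = FALSE])
  out <- list(absolute = emg_heatmap(cells_from_channels(grid, means),
                                     kind = "absolute",
                                     gesture_label = gesture_label,
                                     repetition = repetition))
  if (!is.null(factors)) {
    out$normalized <- emg_heatmap(cells_from_channels(grid, means / factors),
                                  kind = "normalized",
                                  gesture_label = gesture_label,
                                  repetition = repetition)
  }
  out
}

#' @rdname build_repetition_heatmap
#' @param values Non-negative n_rows x n_cols matrix.
#' @param kind `"absolute"` (uV) or `"normalized"`.
#' @export
emg_heatmap <- function(values, kind = c("normalized", "absolute"),
                        gesture_label = NULL, repetition = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || any(values < 0) || any(!is.finite(values))) {
    stop_param("heatmap values must be a finite non-negative matrix")
  }
  structure(
    list(values = values, kind = kind, gesture_label = gesture_label,
         repetition = repetition),
    class = "emg_heatmap"
  )
}

#' Average repetition heatmaps into a gesture heatmap
#'
#' @param maps List of `emg_heatmap`s of the same kind and shape.
#' @return An `emg_heatmap` with `repetition = "average"`.
#' @export
average_heatmap <- function(maps) {
  if (!length(maps) || !all(vapply(maps, inherits, TRUE, "emg_heatmap"))) {
    stop_param("`maps` must be a non-empty list of emg_heatmap objects")
  }
  kinds <- unique(vapply(maps, `[[`, "", "kind"))
  if (length(kinds) != 1) stop_param("cannot average heatmaps of mixed kind")
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  emg_heatmap(vals, kind = kinds,
              gesture_label = maps[[1]]$gesture_label, repetition = "average")
}

#' @export
print.emg_heatmap <- function(x, ...) {
  cat(sprintf("<emg_heatmap> %s%s%s, %d x %d, max %.4g\n", x$kind,
              if (!is.null(x$gesture_label)) paste0(" ", x$gesture_label) else "",
              if (!is.null(x$repetition)) paste0(" rep ", x$repetition) else "",
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' @export
tidy.emg_heatmap <- function(x, ...) {
  tibble::tibble(
    row = as.vector(row(x$values)) - 1L,
    col = as.vector(col(x$values)) - 1L,
    value = as.vector(x$values),
    kind = x$kind
  )
}

#' Thresholded center of gravity of a heatmap
#'
#' The COG is the amplitude-weighted centroid of the cells whose value is
#' equal to or larger than `threshold` times the map maximum (80% by
#' default), so only the cluster of high-amplitude electrodes defines the
#' gesture's location. The row (circumferential) coordinate is computed as a
#' circular mean by default, since the rows encircle the forearm and
#' activity may straddle the row seam; `circular = FALSE` gives the planar
#' centroid. Grid coordinates are mapped to anatomical percentages:
#' `cog_x_pct` of the circumference (dorsal start) and `cog_y_pct` of the
#' forearm length from the elbow, with the electrode array starting at 20%
#' of forearm length and cell centers offset by half an inter-electrode
#' pitch.
#'
#' @param map An `emg_heatmap` with a strictly positive maximum.
#' @param grid The [electrode_grid()] (supplies LID and, with
#'   `length_cm`, the anatomical scaling).
#' @param threshold Inclusion threshold as a fraction of the maximum
#'   (default 0.8); ties at exactly the threshold are included.
#' @param circular Circular (wrap-aware) row centroid (default `TRUE`).
#' @return A one-row tibble: `row`, `col` (zero-based grid coordinates),
#'   `cog_x_pct`, `cog_y_pct`, `threshold`, `n_cells`.
#' @export
compute_cog <- function(map, grid, threshold = 0.8, circular = TRUE) {
  stopifnot(inherits(map, "emg_heatmap"), inherits(grid, "electrode_grid"))
  check_number(threshold, "threshold", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  v <- map$values
  mx <- max(v)
  if (mx <= 0) {
    abort("COG undefined: heatmap has no positive values",
          class = "hdemg_parameter_error")
  }
  keep <- v >= threshold * mx
  w <- ifelse(keep, v, 0)
  cen <- template_centroid(w, circular_rows = circular)
  length_cm <- grid$length_cm
  cog_y <- if (is.na(length_cm)) NA_real_ else {
    (grid$start_offset_fraction * length_cm +
       cen[2] * grid$lid_cm + grid$lid_cm / 2) / length_cm * 100
  }
  tibble::tibble(
    row = cen[1], col = cen[2],
    cog_x_pct = (cen[1] + 0.5) / grid$n_rows * 100,
    cog_y_pct = cog_y,
    threshold = threshold,
    n_cells = sum(keep)
  )
}

#' Maximum activation of a repetition
#'
#' Cell-wise maxima of the normalized and absolute heatmaps of one
#' repetition.
#'
#' @param map_norm,map_abs Normalized and absolute `emg_heatmap`s.
#' @return One-row tibble: `max_normalized`, `max_absolute`.
#' @export
max_activation <- function(map_norm, map_abs) {
  stopifnot(inherits(map_norm, "emg_heatmap"), inherits(map_abs, "emg_heatmap"))
  tibble::tibble(max_normalized = max(map_norm$values),
                 max_absolute = max(map_abs$values))
}
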