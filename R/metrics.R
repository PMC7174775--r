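#' Repeatability of repetition heatmaps
#'
#' Squared Pearson correlation between every unordered pair of heatmaps,
#' each 8 x 8 map reshaped to a 64-vector first. For the standard 10
#' repetitions this yields 45 unique coefficients per gesture.
#'
#' @param maps List of `emg_heatmap`s (or matrices) of one gesture's
#'   repetitions.
#' @param labels Optional labels (default repetition numbers).
#' @return A `similarity_matrix`: symmetric matrix of R^2 with unit
#'   diagonal, plus `labels` and `n_unique_pairs`.
#' @export
repeatability <- function(maps, labels = NULL) {
  vecs <- maps_to_vectors(maps)
  labels <- labels %||% colnames(vecs) %||% as.character(seq_len(ncol(vecs)))
  zero_var <- which(apply(vecs, 2, var) <= 0)
  if (length(zero_var)) {
    stop_param("correlation undefined: map %s has zero variance across cells",
               toString(labels[zero_var]))
  }
  r2 <- cor(vecs)^2
  diag(r2) <- 1
  dimnames(r2) <- list(labels, labels)
  structure(
    list(values = r2, labels = labels,
         n_unique_pairs = choose(ncol(vecs), 2)),
    class = "similarity_matrix"
  )
}

#' Inter-gesture similarity
#'
#' Squared Pearson correlation between the average heatmaps of different
#' gestures of one participant: 21 unique coefficients for 7 gestures.
#'
#' @param avg_maps List of gesture-average `emg_heatmap`s (typically 7).
#' @param labels Gesture labels (defaults to the maps' `gesture_label`s).
#' @return A `similarity_matrix`.
#' @export
gesture_similarity <- function(avg_maps, labels = NULL) {
  labels <- labels %||% vapply(avg_maps, function(m) {
    if (inherits(m, "emg_heatmap") && !is.null(m$gesture_label))
      m$gesture_label else NA_character_
  }, "")
  if (anyNA(labels)) labels <- as.character(seq_along(avg_maps))
  repeatability(avg_maps, labels = labels)
}

maps_to_vectors <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (!length(maps) || length(maps) < 2) {
    stop_param("need at least two maps")
  }
  vapply(maps, function(m) {
    v <- if (inherits(m, "emg_heatmap")) m$values else m
    as.vector(v)
  }, numeric(length(if (inherits(maps[[1]], "emg_heatmap"))
    maps[[1]]$values else maps[[1]])))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d items, %d unique pairs, mean off-diagonal R^2 %.3f\n",
              length(x$labels), x$n_unique_pairs,
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    item1 = x$labels[ut[, 1]],
    item2 = x$labels[ut[, 2]],
    r_squared = x$values[ut]
  )
}

#' Activation-pattern dimensionality via PCA
#'
#' Concatenates all repetition heatmaps of one participant (64 electrodes x
#' 70 gesture-repetitions for the standard protocol), centers each
#' heatmap-vector (column), and measures how many principal components are
#' needed to explain more than `ve_threshold` of the total variance. The
#' heatmap vectors are the variables and the electrodes the observations, so
#' a centered 64-observation matrix has at most 63 components.
#'
#' @param maps List of `emg_heatmap`s (or a 64 x n matrix of reshaped maps).
#' @param ve_threshold Cumulative variance-explained threshold (default
#'   0.9).
#' @param electrodes_as `"observations"` (default) or `"variables"`
#'   (transposed mode).
#' @return A `pca_dim`: `ve` (per-component variance-explained fractions,
#'   summing to 1), `cumulative_ve`, `n_pcs` (smallest count whose
#'   cumulative VE exceeds the threshold).
#' @export
pca_dimensionality <- function(maps, ve_threshold = 0.9,
                               electrodes_as = c("observations", "variables")) {
  electrodes_as <- match.arg(electrodes_as)
  check_number(ve_threshold, "ve_threshold", 0, 1, allow_equal_lower = FALSE,
               allow_equal_upper = FALSE)
  x <- maps_to_vectors(maps)            # electrodes x maps
  if (ncol(x) < 2) stop_param("need at least two maps for a PCA")
  if (electrodes_as == "variables") x <- t(x)
  xc <- sweep(x, 2, colMeans(x))        # center each variable (column)
  d <- svd(xc, nu = 0, nv = 0)$d
  ev <- d^2
  total <- sum(ev)
  if (total <= 0) stop_param("PCA undefined: all maps are identical")
  ve <- ev / total
  cum <- cumsum(ve)
  structure(
    list(ve = ve, cumulative_ve = cum,
         n_pcs = which(cum > ve_threshold)[1],
         ve_threshold = ve_threshold,
         n_maps = ncol(x)),
    class = "pca_dim"
  )
}

#' @export
print.pca_dim <- function(x, ...) {
  cat(sprintf("<pca_dim> %d PCs explain > %g%% of variance (PC1: %.1f%%)\n",
              x$n_pcs, 100 * x$ve_threshold, 100 * x$ve[1]))
  invisible(x)
}

#' @export
tidy.pca_dim <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$ve),
    ve = x$ve,
    cumulative_ve = x$cumulative_ve
  )
}

#' @export
glance.pca_dim <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs, pc1_ve = x$ve[1],
                 ve_threshold = x$ve_threshold, n_maps = x$n_maps)
}

#' Group summary of maximum activations
#'
#' Mean and standard deviation of the per-repetition maximum normalized and
#' absolute activations, per group: the amplitude-distribution comparison
#' across cohorts.
#'
#' @param activations Tibble with columns `group`, `max_normalized`,
#'   `max_absolute` (one row per gesture x repetition, see
#'   [max_activation()]).
#' @return Tibble with one row per group: means, SDs and the event count.
#' @export
activation_summary <- function(activations) {
  req <- c("group", "max_normalized", "max_absolute")
  if (!all(req %in% names(activations))) {
    stop_param("`activations` needs columns %s", toString(req))
  }
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(activations), .data$group),
    mean_normalized = mean(.data$max_normalized),
    sd_normalized = sd0(.data$max_normalized),
    mean_absolute = mean(.data$max_absolute),
    sd_absolute = sd0(.data$max_absolute),
    n = dplyr::n(),
    .groups = "drop"
  )
}
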