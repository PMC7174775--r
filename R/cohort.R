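#' Synthesize a cohort plan with known ground truth
#'
#' Builds a cohort of synthetic participants whose gesture repertoire is
#' generated from `n_templates_distinct` base spatial patterns: the first
#' gestures get one base pattern each, and any further gestures are blends of
#' base patterns (correlated gestures, as co-contraction produces in
#' practice). Every repetition perturbs the gesture's pattern by mixing noise
#' in base-template space (`pattern_variability`) and by lognormal amplitude
#' jitter, and each participant additionally gets a maximal-effort reference
#' session (`"mvc"`) in which all base patterns are expressed at
#' `absolute_scale / normalized_activation_level` — the recording that
#' anchors per-channel normalization.
#'
#' The returned object is a *plan*: templates, seeds and ground truth for
#' every session, with signals synthesized on demand by [cohort_session()]
#' (a realized 64-channel session occupies ~60 MB, a full cohort would not
#' fit comfortably in memory). The plan is fully deterministic given
#' `(profile, n_participants, seed)`.
#'
#' @param profile A [cohort_profile()].
#' @param n_participants Number of participants (0 gives an empty cohort).
#' @param gestures Gesture labels (default the seven-gesture protocol set).
#' @param protocol A [contraction_protocol()].
#' @param noise A [noise_model()]; its seed field is ignored (session seeds
#'   are drawn from `seed`).
#' @param seed Integer master seed, or `NULL`.
#' @param include_mvc Include the maximal-effort reference session.
#' @return An `emg_cohort`: list with `participants` (each carrying base
#'   templates, per-repetition gesture patterns, session seeds and planted
#'   ground truth), `profile`, `protocol`, `noise`, `gestures`,
#'   `planted_rank`, `seed`.
#' @export
make_cohort <- function(profile, n_participants,
                        gestures = default_gestures(),
                        protocol = contraction_protocol(),
                        noise = noise_model(),
                        seed = NULL, include_mvc = TRUE) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(protocol, "contraction_protocol"),
            inherits(noise, "noise_model"))
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 0 || n_participants != round(n_participants)) {
    stop_param("`n_participants` must be a non-negative integer")
  }
  n_participants <- as.integer(n_participants)
  n_g <- length(gestures)
  k <- min(profile$n_templates_distinct, n_g)

  participants <- with_seed_maybe(seed, {
    lapply(seq_len(n_participants), function(p) {
      plan_participant(p, profile, k, gestures, protocol, include_mvc)
    })
  })

  structure(
    list(participants = participants, profile = profile, protocol = protocol,
         noise = noise, gestures = gestures, planted_rank = k,
         include_mvc = include_mvc, seed = seed),
    class = "emg_cohort"
  )
}

# All randomness for one participant; runs inside the cohort seed scope.
plan_participant <- function(p, profile, k, gestures, protocol, include_mvc) {
  group <- profile$group
  id <- sprintf("%s%02d", if (group == "healthy") "HP" else "DP", p)
  anthro <- if (group == "healthy") {
    list(forearm_length_cm = min(max(rnorm(1, 24.8, 1.8), 19), 32),
         circumference_cm = min(max(rnorm(1, 25.9, 1.8), 19), 34))
  } else {
    list(forearm_length_cm = min(max(rnorm(1, 24.2, 2.9), 19), 32),
         circumference_cm = min(max(rnorm(1, 25.5, 3.9), 19), 34))
  }
  anthro$handedness <- "right"
  grid <- grid_from_anthropometrics(anthro$forearm_length_cm,
                                    anthro$circumference_cm)

  centers <- base_center_layout(k, grid$n_rows, grid$n_cols)
  cj <- profile$center_jitter %||% 0.4
  jit <- matrix(runif(2 * k, -cj, cj), ncol = 2)
  centers[, 1] <- ((centers[, 1] + jit[, 1] + 0.5) %% grid$n_rows) - 0.5
  centers[, 2] <- pmin(pmax(centers[, 2] + jit[, 2], 0), grid$n_cols - 1)

  base_templates <- lapply(seq_len(k), function(i) {
    make_spatial_template(grid, centers[i, ], spread = profile$template_spread,
                          peak = 1, gesture_id = sprintf("base%d", i))
  })
  base_mats <- lapply(base_templates, function(tp) tp$amplitudes)

  # envelope amplitude giving a mean rectified-carrier steady level of
  # absolute_scale: carrier has unit variance, E|carrier| = sqrt(2/pi)
  amp <- profile$absolute_scale / sqrt(2 / pi)
  coeff_list <- gesture_mixing(k, length(gestures))

  gesture_plans <- lapply(seq_along(gestures), function(g) {
    coeffs <- coeff_list[[g]]
    jitter <- exp(rnorm(protocol$n_repetitions, 0, profile$rep_jitter_sd) -
                    profile$rep_jitter_sd^2 / 2)
    mixing <- matrix(rnorm(k * protocol$n_repetitions, 0,
                           profile$pattern_variability / sqrt(k)),
                     nrow = k)
    rep_amplitudes <- lapply(seq_len(protocol$n_repetitions), function(j) {
      cj <- coeffs + mixing[, j]
      m <- Reduce(`+`, Map(`*`, base_mats, cj))
      m[m < 0] <- 0
      mx <- max(m)
      if (mx > 0) m * (amp * jitter[j] / mx) else m
    })
    list(label = gestures[g], coeffs = coeffs, jitter = jitter,
         mixing = mixing, rep_amplitudes = rep_amplitudes,
         session_seed = sample.int(.Machine$integer.max, 1))
  })
  names(gesture_plans) <- gestures

  mvc <- NULL
  if (include_mvc) {
    m <- Reduce(pmax, base_mats)
    m <- pmax(m, profile$mvc_floor)
    mvc <- list(amplitudes = m * (amp / profile$normalized_activation_level),
                session_seed = sample.int(.Machine$integer.max, 1))
  }

  list(id = id, group = group, anthropometrics = anthro, grid = grid,
       base_centers = centers, base_templates = base_templates,
       gestures = gesture_plans, mvc = mvc)
}

# Deterministic greedy farthest-point layout of k base-pattern centers on
# the grid, with circular row distance. Columns are kept off the extreme
# longitudinal edges.
base_center_layout <- function(k, n_rows = 8, n_cols = 8) {
  cand <- as.matrix(expand.grid(row = 0:(n_rows - 1), col = 1:(n_cols - 2)))
  d2 <- function(a, b) {
    dr <- abs(a[1] - b[, 1])
    dr <- pmin(dr, n_rows - dr)
    dr^2 + (a[2] - b[, 2])^2
  }
  chosen <- matrix(c(2, 2), ncol = 2)
  while (nrow(chosen) < k) {
    mind <- apply(cand, 1, function(x) min(d2(x, chosen)))
    chosen <- rbind(chosen, cand[which.max(mind), ])
  }
  unname(chosen[seq_len(k), , drop = FALSE])
}

# Base-template coefficients per gesture: pure patterns first, then blends —
# disjoint pairs, then triples — with a dominant base (coefficient 1) and
# secondary bases at 2/3, modeling asymmetric co-activation. The dominant
# coefficient keeps every gesture's peak amplitude on the common scale, and
# the blend spectrum keeps the cumulative variance explained at (rank - 1)
# components comfortably below the 90% dimensionality threshold.
gesture_mixing <- function(k, n_g) {
  lapply(seq_len(n_g), function(g) {
    coeffs <- numeric(k)
    if (g <= k) {
      coeffs[g] <- 1
    } else {
      j <- g - k
      members <- if (j <= k) {
        unique(c((2 * j - 2) %% k + 1, (2 * j - 1) %% k + 1))
      } else {
        unique((j - k - 1 + 0:2) %% k + 1)
      }
      coeffs[members[1]] <- 1
      if (length(members) > 1) coeffs[members[-1]] <- 0.5
    }
    coeffs
  })
}

#' Realize one session of a cohort plan
#'
#' @param cohort An `emg_cohort` from [make_cohort()].
#' @param participant Participant index or id.
#' @param gesture Gesture label, or `"mvc"` for the maximal-effort reference
#'   session.
#' @return A [recording_session()].
#' @export
cohort_session <- function(cohort, participant, gesture) {
  stopifnot(inherits(cohort, "emg_cohort"))
  p <- resolve_participant(cohort, participant)
  meta <- list(id = p$id,
               forearm_length_cm = p$anthropometrics$forearm_length_cm,
               circumference_cm = p$anthropometrics$circumference_cm,
               handedness = p$anthropometrics$handedness)
  if (identical(gesture, "mvc")) {
    if (is.null(p$mvc)) stop_param("cohort was built without MVC sessions")
    proto <- cohort$protocol
    proto$n_repetitions <- 1L
    tp <- template_from_matrix(p$mvc$amplitudes, "mvc")
    return(synthesize_session(tp, proto, cohort$noise, participant = meta,
                              gesture_label = "mvc", grid = p$grid,
                              seed = p$mvc$session_seed))
  }
  gp <- p$gestures[[gesture]]
  if (is.null(gp)) stop_param("unknown gesture `%s`", gesture)
  templates <- lapply(gp$rep_amplitudes, template_from_matrix, gesture)
  synthesize_session(templates, cohort$protocol, cohort$noise,
                     participant = meta, gesture_label = gesture,
                     grid = p$grid, seed = gp$session_seed)
}

resolve_participant <- function(cohort, participant) {
  if (is.character(participant)) {
    ids <- vapply(cohort$participants, `[[`, "", "id")
    idx <- match(participant, ids)
    if (is.na(idx)) stop_param("unknown participant `%s`", participant)
    return(cohort$participants[[idx]])
  }
  if (participant < 1 || participant > length(cohort$participants)) {
    stop_param("participant index %s out of range", participant)
  }
  cohort$participants[[participant]]
}

template_from_matrix <- function(amplitudes, gesture_id = NULL) {
  structure(
    list(amplitudes = amplitudes,
         center = if (sum(amplitudes) > 0)
           template_centroid(amplitudes, circular_rows = TRUE) else c(NA_real_, NA_real_),
         spread = NA_real_, peak = max(amplitudes),
         wrap_circumferential = TRUE, gesture_id = gesture_id),
    class = "spatial_template"
  )
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d %s participant(s), %d gestures x %d repetitions, planted rank %d\n",
              length(x$participants), x$profile$group, length(x$gestures),
              x$protocol$n_repetitions, x$planted_rank))
  invisible(x)
}

#' Ground truth of a cohort plan
#'
#' @param cohort An `emg_cohort`.
#' @return A list (JSON-ready) with the planted rank, per-participant base
#'   pattern centers, onset times and session seeds.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "emg_cohort"))
  list(
    group = cohort$profile$group,
    planted_rank = cohort$planted_rank,
    onsets_s = protocol_onsets(cohort$protocol),
    seed = cohort$seed,
    participants = lapply(cohort$participants, function(p) {
      list(id = p$id,
           base_centers = p$base_centers,
           gesture_coeffs = lapply(p$gestures, `[[`, "coeffs"),
           session_seeds = vapply(p$gestures, `[[`, 1L, "session_seed"))
    })
  )
}

#' Write a cohort to disk as session bundles plus a ground-truth sidecar
#'
#' Realizes every session of the plan and writes it with [write_session()]
#' under `dir/<participant>/<gesture>/`, plus `ground_truth.json` holding the
#' planted centers, rank, onsets and seeds.
#'
#' @param cohort An `emg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    labels <- c(cohort$gestures, if (!is.null(p$mvc)) "mvc")
    for (g in labels) {
      s <- cohort_session(cohort, p$id, g)
      write_session(s, file.path(dir, p$id, g))
    }
  }
  jsonlite::write_json(cohort_truth(cohort),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
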