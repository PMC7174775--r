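# Shared fixtures: everything is generated in code at test time.

test_grid <- function(circumference_cm = 27, length_cm = 26, ...) {
  electrode_grid(circumference_cm = circumference_cm, length_cm = length_cm, ...)
}

# A short high-SNR single-template session. fs 1024 keeps tests fast; the
# carrier band still fits below Nyquist.
quick_session <- function(center = c(2, 5), spread = 1, peak = 50,
                          baseline_sd = 1, n_repetitions = 2, fs = 1024,
                          seed = 1, powerline = 10, faulty = NULL, ...) {
  g <- test_grid()
  tp <- make_spatial_template(g, center, spread = spread, peak = peak)
  proto <- contraction_protocol(n_repetitions = n_repetitions, fs = fs, ...)
  nm <- noise_model(baseline_sd = baseline_sd, powerline_amplitude = powerline,
                    faulty_channels = faulty, seed = seed)
  synthesize_session(tp, proto, nm, grid = g)
}

quick_envelope <- function(session) {
  envelope(notch(bandpass(session$signals, session$fs), session$fs),
           session$fs)
}

# Random positive heatmap with controllable seed.
random_heatmap <- function(seed, kind = "normalized", n = 8) {
  withr::with_seed(seed, {
    emg_heatmap(matrix(runif(n * n), n, n), kind = kind)
  })
}

# n repetition-like heatmaps correlated around one base pattern.
correlated_heatmaps <- function(n, seed, noise = 0.05) {
  withr::with_seed(seed, {
    base <- matrix(runif(64), 8, 8)
    lapply(seq_len(n), function(i) {
      emg_heatmap(pmax(base + matrix(rnorm(64, sd = noise), 8, 8), 0),
                  "normalized", repetition = i)
    })
  })
}

# Feature clusters: k well-separated classes in feature space.
separable_features <- function(k = 7, n_per = 30, p = 24, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * p), k, p) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(n_per * p), n_per, p) +
        matrix(centers[i, ], n_per, p, byrow = TRUE)
    }))
    list(x = x, y = rep(paste0("g", seq_len(k)), each = n_per))
  })
}

rank_recovery_profile <- function(k, group = "healthy") {
  cohort_profile(group, n_templates_distinct = k, template_spread = 0.3,
                 pattern_variability = 0, rep_jitter_sd = 0,
                 center_jitter = 0)
}
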