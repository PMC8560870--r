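# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_layout <- function() fixture("layout", build_layout)
test_map <- function() fixture("map", function() default_roi_map(test_layout()))

# A small but complete synthetic dataset: 3 participants/class, 60 s
# sessions (80 s for AD so central cropping is exercised), 200 Hz.
small_sim_config <- function(seed = 11, effect = 1, n = 3L,
                             session_seconds = c(AD = 80, MCI = 60, HC = 60),
                             ...) {
  sim_config(participants_per_class = n, session_seconds = session_seconds,
             seed = seed, effect = effect, ...)
}

small_features <- function() {
  fixture("small_features", function() {
    simulate_features(small_sim_config(), roi = "LF", layout = test_layout(),
                      map = test_map(), duration_s = 60)
  })
}

# Synthetic feature tables with controllable class structure, for classifier
# and cross-validation tests that do not need MEG signals at all.
# Participant-level random intercepts make epoch-level leakage detectable.
fake_features <- function(n_per_class = 7L, n_epochs = 18L, n_dim = 21L,
                          separation = 1, participant_sd = 0, seed = 1,
                          modalities = c("magnetometer", "gradiometer"),
                          modality_means = NULL) {
  class_means <- list(AD = separation * seq_len(n_dim) / n_dim,
                      MCI = separation * rev(seq_len(n_dim)) / n_dim,
                      HC = rep(0, n_dim))
  withr::with_seed(seed, {
    purrr::map_dfr(c("AD", "MCI", "HC"), function(cl) {
      purrr::map_dfr(seq_len(n_per_class), function(i) {
        shift <- stats::rnorm(n_dim, 0, participant_sd)
        purrr::map_dfr(modalities, function(mod) {
          mu <- if (is.null(modality_means)) class_means[[cl]]
                else modality_means[[mod]][[cl]]
          vals <- matrix(stats::rnorm(n_epochs * n_dim), n_epochs, n_dim)
          vals <- sweep(vals, 2, mu + shift, "+")
          colnames(vals) <- paste0("f", seq_len(n_dim))
          dplyr::bind_cols(
            tibble::tibble(participant = sprintf("%s%02d", cl, i), class = cl,
                           epoch = seq_len(n_epochs), modality = mod),
            tibble::as_tibble(vals)
          )
        })
      })
    })
  })
}
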