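#' Default class-dependent oscillation table
#'
#' One row per band-limited oscillatory component. Each component has a
#' nominal frequency band, a spatial focus (an ROI id from the gradiometer
#' map, or `"global"` for a diffuse component), a base amplitude (arbitrary
#' field units, relative to the unit-SD 1/f background components), and one
#' multiplicative power scale per class. The defaults emulate the
#' qualitative class structure of resting-state dementia MEG: slow (theta)
#' activity elevated in AD over frontal sensors, and beta/gamma activity
#' strongest in healthy controls — ordered HC > MCI > AD, with the HC gamma
#' scale 3x the AD scale in the left-frontal focus.
#'
#' @return A tibble with columns `band`, `lo`, `hi`, `roi`, `base_amp`,
#'   `AD`, `MCI`, `HC`.
#' @export
default_oscillations <- function() {
  tibble::tribble(
    ~band,    ~lo, ~hi, ~roi,     ~base_amp, ~AD, ~MCI, ~HC,
    "alpha",    8,  12, "LO",     1.0,       0.8, 0.9,  1.0,
    "theta",    4,   8, "LF",     0.9,       2.0, 1.3,  1.0,
    "beta",    13,  30, "LF",     0.7,       0.6, 0.8,  1.0,
    "gamma",   30,  80, "LF",     0.6,       0.4, 0.7,  1.2
  )
}

#' Simulation configuration
#'
#' Study conditions for the synthetic Elekta-306 resting-state generator.
#' Defaults mirror the packaged study design: 7 participants per class,
#' 5-minute AD sessions and 3-minute MCI/HC sessions, direct synthesis at
#' 200 Hz (1000 Hz available to exercise resampling), pink-noise background
#' with white sensor noise, and the class-dependent oscillation table of
#' [default_oscillations()].
#'
#' @param participants_per_class Participants per class (default 7).
#' @param session_seconds Named vector of session lengths in seconds
#'   (default AD 300, MCI 180, HC 180).
#' @param rate Sampling rate in Hz, 200 or 1000 (default 200).
#' @param background_alpha Spectral exponent of the 1/f^alpha background
#'   (default 1).
#' @param background_amp Amplitude of each latent background component
#'   (default 1).
#' @param n_background Number of spatially smooth latent background
#'   components (default 6).
#' @param sensor_noise_sd SD of per-channel white sensor noise (default 0.5).
#' @param oscillations Oscillation table, see [default_oscillations()].
#' @param effect Class-separation scaling: per-class power scales are
#'   `1 + effect * (scale - 1)`, so `effect = 0` removes all class
#'   differences (null configuration) and `effect = 1` is the default
#'   ("large") preset.
#' @param participant_gain_sd SD of the per-participant log-normal gain
#'   (default 0.2) — a participant-level confound that makes epoch-level
#'   train/test leakage detectable.
#' @param freq_jitter_sd SD (Hz) of per-participant band-edge jitter
#'   (default 0.5).
#' @param spatial_sigma Width of the Gaussian spatial profiles on the unit
#'   sphere (chord distance, default 0.6).
#' @param grad_delta Offset (sphere units) of the finite spatial differences
#'   that synthesize planar-gradiometer channels (default 0.02).
#' @param seed Master seed; every participant's generator seed derives
#'   deterministically from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(participants_per_class = 7L,
                       session_seconds = c(AD = 300, MCI = 180, HC = 180),
                       rate = 200,
                       background_alpha = 1,
                       background_amp = 1,
                       n_background = 6L,
                       sensor_noise_sd = 0.5,
                       oscillations = default_oscillations(),
                       effect = 1,
                       participant_gain_sd = 0.2,
                       freq_jitter_sd = 0.5,
                       spatial_sigma = 0.6,
                       grad_delta = 0.02,
                       seed = 1L) {
  stopifnot(participants_per_class >= 1L,
            all(session_seconds > 0),
            all(CLASS_LEVELS %in% names(session_seconds)),
            rate > 0,
            all(oscillations$base_amp >= 0),
            all(oscillations$AD >= 0), all(oscillations$MCI >= 0),
            all(oscillations$HC >= 0))
  structure(list(participants_per_class = as.integer(participants_per_class),
                 session_seconds = session_seconds, rate = rate,
                 background_alpha = background_alpha,
                 background_amp = background_amp,
                 n_background = as.integer(n_background),
                 sensor_noise_sd = sensor_noise_sd,
                 oscillations = oscillations, effect = effect,
                 participant_gain_sd = participant_gain_sd,
                 freq_jitter_sd = freq_jitter_sd,
                 spatial_sigma = spatial_sigma, grad_delta = grad_delta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Unit-SD 1/f^alpha noise via spectral shaping of white noise.
.noise_1f <- function(n, alpha, rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) * (rate / n) # bin frequencies, mirrored upper half
  fk[1] <- fk[2]                    # avoid the DC singularity
  shaped <- X * fk^(-alpha / 2)
  y <- Re(stats::fft(shaped, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

# Unit-SD band-limited noise: white noise with its spectrum zeroed outside
# [lo, hi] Hz.
.band_noise <- function(n, lo, hi, rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) * (rate / n)
  keep <- fk >= lo & fk <= hi
  if (!any(keep)) stop("band [", lo, ", ", hi, "] Hz empty at n = ", n)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

# Gaussian spatial profile on the unit sphere (chord distance).
.spatial_profile <- function(pos, center, sigma) {
  d2 <- rowSums((pos - matrix(center, nrow(pos), 3, byrow = TRUE))^2)
  exp(-d2 / (2 * sigma^2))
}

# Tangent-plane basis (latitude / longitude directions) at unit vectors p.
.tangent_dirs <- function(pos) {
  up <- c(0, 0, 1)
  e_lat <- t(apply(pos, 1, function(p) {
    v <- crossprod_vec(up, p)
    if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0) # at the vertex
    v / sqrt(sum(v^2))
  }))
  e_long <- t(vapply(seq_len(nrow(pos)), function(i) {
    v <- crossprod_vec(pos[i, ], e_lat[i, ])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  list(lat = e_lat, long = e_long)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ROI spatial centers: mean unit position of the gradiometer-map sites.
.roi_centers <- function(layout, map) {
  sapply(ROI_IDS, function(roi) {
    ch <- map$gradiometer[[roi]]
    idx <- match(ch, layout$channels$name)
    p <- colMeans(as.matrix(layout$channels[idx, c("x", "y", "z")]))
    p / sqrt(sum(p^2))
  })
}

#' Generate one synthetic resting-state MEG recording
#'
#' The signal model is a sum of latent components, each a time course times
#' a smooth spatial profile over the sensor array: `n_background` pink-noise
#' (1/f^alpha) components with random spatial foci, plus one band-limited
#' oscillatory component per row of the oscillation table, whose amplitude
#' is the base amplitude times the class power scale (moderated by the
#' `effect` parameter) times a per-participant log-normal gain, and whose
#' spatial profile is a Gaussian bump at the component's ROI center.
#' Magnetometer channels sample the latent field at the site position;
#' planar-gradiometer channels are finite spatial differences of the field
#' along the two tangential directions at the site. Independent white sensor
#' noise is added to every channel.
#'
#' @param label Class label: `"AD"`, `"MCI"` or `"HC"`.
#' @param pid Participant id.
#' @param cfg A [sim_config()].
#' @param layout A `meg_layout`.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @param map ROI map used to place oscillation foci (default packaged map).
#' @return A `meg_recording` with channels in layout order.
#' @export
generate_recording <- function(label, pid, cfg = sim_config(),
                               layout = build_layout(), seed = 1L,
                               map = default_roi_map(layout)) {
  label <- match.arg(label, CLASS_LEVELS)
  n <- as.integer(round(cfg$session_seconds[[label]] * cfg$rate))
  chan <- layout$channels
  pos <- as.matrix(chan[, c("x", "y", "z")])
  is_mag <- chan$kind == "magnetometer"
  is_lat <- chan$kind == "gradiometer_lat"
  is_long <- chan$kind == "gradiometer_long"
  tang <- .tangent_dirs(pos)
  centers <- .roi_centers(layout, map)

  .with_seed(seed, {
    # channel weights of one latent component: field value at magnetometers,
    # symmetric finite differences along the tangential directions at
    # gradiometer channels
    component_weights <- function(center, amp) {
      w <- numeric(nrow(chan))
      w[is_mag] <- .spatial_profile(pos[is_mag, , drop = FALSE], center,
                                    cfg$spatial_sigma)
      d <- cfg$grad_delta
      for (sel in list(list(is_lat, tang$lat), list(is_long, tang$long))) {
        ix <- sel[[1]]; e <- sel[[2]][ix, , drop = FALSE]
        p <- pos[ix, , drop = FALSE]
        wp <- .spatial_profile(p + d * e, center, cfg$spatial_sigma)
        wm <- .spatial_profile(p - d * e, center, cfg$spatial_sigma)
        w[ix] <- (wp - wm) / (2 * d)
      }
      amp * w
    }

    # participant-level confounds
    gain <- exp(stats::rnorm(1, 0, cfg$participant_gain_sd))
    jit <- stats::rnorm(nrow(cfg$oscillations), 0, cfg$freq_jitter_sd)

    W <- list() # channel weights per component
    TS <- list() # unit-SD time courses per component

    # diffuse 1/f background
    for (b in seq_len(cfg$n_background)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      u[3] <- abs(u[3]) # keep foci on the upper hemisphere
      W[[length(W) + 1L]] <- component_weights(u, cfg$background_amp)
      TS[[length(TS) + 1L]] <- .noise_1f(n, cfg$background_alpha, cfg$rate)
    }

    # class-scaled oscillations
    osc <- cfg$oscillations
    for (i in seq_len(nrow(osc))) {
      scale <- 1 + cfg$effect * (osc[[label]][i] - 1)
      lo <- max(0.5, osc$lo[i] + jit[i])
      hi <- min(cfg$rate / 2 - 1, osc$hi[i] + jit[i])
      center <- if (osc$roi[i] == "global") c(0, 0, 1) else centers[, osc$roi[i]]
      W[[length(W) + 1L]] <- component_weights(center,
                                               osc$base_amp[i] * scale * gain)
      TS[[length(TS) + 1L]] <- .band_noise(n, lo, hi, cfg$rate)
    }

    data <- do.call(cbind, W) %*% do.call(rbind, TS)
    data <- data + matrix(stats::rnorm(length(data), 0, cfg$sensor_noise_sd),
                          nrow(data), ncol(data))
    meg_recording(data, cfg$rate, pid, label, chan$name)
  })
}

#' Generate a full synthetic dataset
#'
#' One recording per participant, `participants_per_class` per class, with
#' class-appropriate session lengths and unique participant ids; every
#' participant's generator seed derives deterministically from the master
#' seed in `cfg`.
#'
#' @param cfg A [sim_config()].
#' @param layout A `meg_layout`.
#' @param map ROI map for oscillation foci.
#' @return List of `meg_recording` objects (AD first, then MCI, then HC).
#' @export
generate_dataset <- function(cfg = sim_config(), layout = build_layout(),
                             map = default_roi_map(layout)) {
  idx <- 0L
  out <- list()
  for (label in CLASS_LEVELS) {
    for (i in seq_len(cfg$participants_per_class)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", label, i)
      out[[pid]] <- generate_recording(label, pid, cfg, layout,
                                       seed = .child_seed(cfg$seed, idx),
                                       map = map)
    }
  }
  out
}

#' Map a function over a synthetic dataset without holding it in memory
#'
#' Generates each participant's recording, applies `f`, and discards the
#' recording before generating the next — the memory-friendly path for
#' full-size datasets.
#'
#' @param cfg A [sim_config()].
#' @param f Function of one `meg_recording`.
#' @param layout,map As in [generate_dataset()].
#' @return Named list of `f`'s results, one per participant.
#' @export
map_dataset <- function(cfg, f, layout = build_layout(),
                        map = default_roi_map(layout)) {
  idx <- 0L
  out <- list()
  for (label in CLASS_LEVELS) {
    for (i in seq_len(cfg$participants_per_class)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", label, i)
      rec <- generate_recording(label, pid, cfg, layout,
                                seed = .child_seed(cfg$seed, idx), map = map)
      out[[pid]] <- f(rec)
    }
  }
  out
}
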