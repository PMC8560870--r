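#' Default per-modality feature configurations
#'
#' @return Named list of [feature_config()] objects (magnetometer: mean of
#'   raw coefficients; gradiometer: population SD of the time-axis
#'   coefficient gradient).
#' @export
default_feature_configs <- function() {
  list(magnetometer = feature_config("magnetometer"),
       gradiometer = feature_config("gradiometer"))
}

# Decompose each epoch image once and evaluate one or more feature configs
# on the shared tree (configs must agree on wavelet/levels/transpose).
.features_from_epochs <- function(epochs, roi, modality, map, cfgs) {
  base <- cfgs[[1]]
  purrr::map_dfr(seq_along(epochs$epochs), function(ei) {
    img <- build_meg_image(epochs, roi, modality, map, ei)
    tree <- wpd_decompose(img, wavelet = base$wavelet, levels = base$levels,
                          transpose = base$transpose)
    purrr::imap_dfr(cfgs, function(cfg, cfg_name) {
      nodes <- wpd_terminal_nodes(tree, cfg$detail)
      vals <- vapply(nodes, function(coefs) {
        if (cfg$use_gradient) coefs <- wpd_gradient(coefs, cfg$gradient_mode)
        node_statistic(coefs, cfg$statistic)
      }, numeric(1))
      row <- tibble::tibble(participant = epochs$participant,
                            class = epochs$label, epoch = ei,
                            modality = modality, roi = roi)
      if (length(cfgs) > 1L) row$config <- cfg_name
      dplyr::bind_cols(row, tibble::as_tibble(as.list(vals)))
    })
  })
}

#' Extract marker vectors for a set of recordings
#'
#' Runs the standard preprocessing chain on each recording, assembles the
#' per-epoch ROI images for both modalities, and extracts one marker vector
#' per image. The result is a tidy wide table: one row per
#' (participant, epoch, modality), metadata columns followed by one column
#' per wavelet-packet node (21 at the defaults), named by node path.
#'
#' @param recordings List of `meg_recording` objects (or a single one).
#' @param roi ROI id (default `"LF"`, the most effective region).
#' @param map A `roi_map`.
#' @param configs Named list of per-modality [feature_config()]s; modalities
#'   are taken from its names.
#' @param preprocess Apply [preprocess_recording()] first (default TRUE;
#'   set FALSE if `recordings` are already `epoch_set`s).
#' @param duration_s,epoch_seconds,target_rate,low,high Preprocessing
#'   parameters.
#' @return A tibble of features.
#' @export
extract_features <- function(recordings, roi = "LF", map = default_roi_map(),
                             configs = default_feature_configs(),
                             preprocess = TRUE, duration_s = 180,
                             epoch_seconds = 10, target_rate = 200,
                             low = 0.5, high = 80) {
  if (inherits(recordings, "meg_recording") || inherits(recordings, "epoch_set"))
    recordings <- list(recordings)
  needed <- unique(unlist(lapply(names(configs), function(m) map[[m]][[roi]])))
  purrr::map_dfr(recordings, function(rec) {
    epochs <- if (preprocess) {
      # filtering cost scales with channel count, so preprocess only the
      # channels this ROI/modality combination will use
      rec <- subset_channels(rec, intersect(rec$channel_names, needed))
      preprocess_recording(rec, target_rate = target_rate, low = low,
                           high = high, duration_s = duration_s,
                           epoch_seconds = epoch_seconds)
    } else rec
    purrr::imap_dfr(configs, function(cfg, modality) {
      .features_from_epochs(epochs, roi, modality, map, list(cfg))
    })
  })
}

#' Extract features for a simulated dataset without materialising it
#'
#' Streams over the participants of a [sim_config()] — generate, preprocess,
#' extract, discard — so full-size datasets never sit in memory at once.
#'
#' @param cfg A [sim_config()].
#' @param roi,map,configs,duration_s,epoch_seconds As [extract_features()].
#' @param layout A `meg_layout`.
#' @return A tibble of features.
#' @export
simulate_features <- function(cfg = sim_config(), roi = "LF",
                              layout = build_layout(),
                              map = default_roi_map(layout),
                              configs = default_feature_configs(),
                              duration_s = NULL, epoch_seconds = 10) {
  if (is.null(duration_s)) duration_s <- min(cfg$session_seconds)
  res <- map_dataset(cfg, function(rec) {
    extract_features(list(rec), roi = roi, map = map, configs = configs,
                     duration_s = duration_s, epoch_seconds = epoch_seconds)
  }, layout = layout, map = map)
  dplyr::bind_rows(res)
}

#' Write / read a tidy feature CSV
#'
#' Long format: participant, class, epoch, modality, roi, node, value.
#'
#' @param features Wide feature tibble from [extract_features()].
#' @param path CSV path.
#' @return `path` invisibly (write); the wide tibble (read).
#' @export
write_features <- function(features, path) {
  long <- tidyr::pivot_longer(features, !dplyr::any_of(c("participant", "class",
                                                         "epoch", "modality",
                                                         "roi", "config")),
                              names_to = "node", values_to = "value")
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  long <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tidyr::pivot_wider(long, names_from = "node", values_from = "value")
}

#' Marker-grid experiment: node type x statistic, per modality
#'
#' Sweeps the terminal-node rule (A, H, V, D) against the summary statistic
#' (mean, SD) for each modality, evaluating every cell with the hybrid
#' LOO-MCRS scheme on that modality alone and reporting the mean accuracy —
#' the table used to pick the marker design (horizontal detail; mean for
#' magnetometers, SD for gradiometers).
#'
#' @param recordings List of `meg_recording`s (or `epoch_set`s with
#'   `preprocess = FALSE`).
#' @param roi ROI id.
#' @param map A `roi_map`.
#' @param config A [pipeline_config()].
#' @param repetitions Hybrid-CV repetitions per cell (default 20).
#' @param seed RNG seed for the CV repetitions.
#' @param ... Passed to [extract_features()].
#' @return Tibble with `modality`, `detail`, `statistic`, `mean_accuracy`.
#' @export
grid_experiment <- function(recordings, roi = "LF", map = default_roi_map(),
                            config = pipeline_config(), repetitions = 20L,
                            seed = 1L, ...) {
  cells <- expand.grid(detail = c("A", "H", "V", "D"),
                       statistic = c("mean", "sd"),
                       modality = c("magnetometer", "gradiometer"),
                       stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    cfg <- feature_config(cell$modality, detail = cell$detail,
                          statistic = cell$statistic)
    feats <- extract_features(recordings, roi = roi, map = map,
                              configs = stats::setNames(list(cfg), cell$modality),
                              ...)
    cv <- hybrid_loo_mcrs_run(feats, config, repetitions = repetitions,
                              seed = seed)
    acc_col <- if (cell$modality == "magnetometer") "acc_mag" else "acc_grad"
    tibble::tibble(modality = cell$modality, detail = cell$detail,
                   statistic = cell$statistic,
                   mean_accuracy = mean(cv$reps[[acc_col]]))
  })
}

#' ROI scan: fused accuracy per region
#'
#' Evaluates the default bimodal pipeline on each of the 10 ROIs with the
#' hybrid LOO-MCRS scheme and reports the mean fused accuracy per region.
#'
#' @param recordings List of `meg_recording`s (or `epoch_set`s with
#'   `preprocess = FALSE`).
#' @param map A `roi_map`.
#' @param config A [pipeline_config()].
#' @param repetitions Hybrid-CV repetitions per ROI (default 20).
#' @param seed RNG seed.
#' @param ... Passed to [extract_features()].
#' @return Tibble with `roi` and `mean_accuracy`.
#' @export
roi_scan <- function(recordings, map = default_roi_map(),
                     config = pipeline_config(), repetitions = 20L,
                     seed = 1L, ...) {
  purrr::map_dfr(ROI_IDS, function(roi) {
    feats <- extract_features(recordings, roi = roi, map = map, ...)
    cv <- hybrid_loo_mcrs_run(feats, config, repetitions = repetitions,
                              seed = seed)
    tibble::tibble(roi = roi, mean_accuracy = mean(cv$reps$acc_fused))
  })
}
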