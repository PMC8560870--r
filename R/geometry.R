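#' @keywords internal
ROI_IDS <- c("LF", "RF", "LT", "RT", "LC", "RC", "LP", "RP", "LO", "RO")

# Split one hemisphere's sites into frontal/occipital/temporal/central/parietal
# with forced group sizes. Heuristic, in order: the most anterior sites are
# frontal, the most posterior occipital, the most inferior of the remainder
# temporal, then central (anterior) vs parietal (posterior).
.assign_hemi <- function(sites, n) {
  stopifnot(nrow(sites) == sum(unlist(n)))
  ord_y <- sites[order(-sites$y, sites$site), ]
  frontal <- ord_y$site[seq_len(n$F)]
  rest <- ord_y[-seq_len(n$F), ]
  ord_back <- rest[order(rest$y, rest$site), ]
  occipital <- ord_back$site[seq_len(n$O)]
  rest <- ord_back[-seq_len(n$O), ]
  ord_z <- rest[order(rest$z, rest$site), ]
  temporal <- ord_z$site[seq_len(n$T)]
  rest <- ord_z[-seq_len(n$T), ]
  ord_y2 <- rest[order(-rest$y, rest$site), ]
  central <- ord_y2$site[seq_len(n$C)]
  parietal <- ord_y2$site[-seq_len(n$C)]
  list(F = sort(frontal), T = sort(temporal), C = sort(central),
       P = sort(parietal), O = sort(occipital))
}

.sites_to_channels <- function(layout, site_ids, modality) {
  site_ids <- sort(site_ids)
  if (modality == "magnetometer") {
    vapply(site_ids, function(s) {
      ch <- layout$channels
      ch$name[ch$site == s & ch$kind == "magnetometer"]
    }, character(1))
  } else {
    unlist(lapply(site_ids, function(s) {
      ch <- layout$channels
      c(ch$name[ch$site == s & ch$kind == "gradiometer_lat"],
        ch$name[ch$site == s & ch$kind == "gradiometer_long"])
    }))
  }
}

#' Default region-of-interest map
#'
#' Assigns every non-centerline channel to one of 10 scalp regions
#' (left/right x frontal, temporal, central, parietal, occipital), separately
#' per modality. The left-frontal (LF) listing holds 22 channels in each
#' modality: 22 magnetometer sites, or 11 gradiometer sites contributing a
#' latitude/longitude channel pair each (pairs interleaved as adjacent
#' entries). Membership is nominal — derived from the packaged geometry, and
#' user-overridable via [load_roi_map()]. Channel order within an ROI is
#' ascending site index.
#'
#' @param layout A `meg_layout`.
#' @return A `roi_map`: list with `magnetometer` and `gradiometer` (each a
#'   named list ROI id -> ordered channel names) and `excluded` (centerline
#'   channel names).
#' @export
default_roi_map <- function(layout = build_layout()) {
  sites <- layout$sites[!layout$sites$centerline, ]
  left <- sites[sites$x < 0, ]
  right <- sites[sites$x > 0, ]
  counts <- list(
    magnetometer = list(F = 22L, T = 7L, C = 7L, P = 6L, O = 6L),
    gradiometer  = list(F = 11L, T = 10L, C = 9L, P = 9L, O = 9L)
  )
  map <- list()
  for (mod in names(counts)) {
    asg_l <- .assign_hemi(left, counts[[mod]])
    asg_r <- .assign_hemi(right, counts[[mod]])
    rois <- list()
    for (part in c("F", "T", "C", "P", "O")) {
      rois[[paste0("L", part)]] <- .sites_to_channels(layout, asg_l[[part]], mod)
      rois[[paste0("R", part)]] <- .sites_to_channels(layout, asg_r[[part]], mod)
    }
    map[[mod]] <- rois[ROI_IDS]
  }
  center <- layout$channels$centerline
  map$excluded <- layout$channels$name[center]
  structure(map, class = "roi_map")
}

.validate_roi_map <- function(map, layout) {
  for (mod in c("magnetometer", "gradiometer")) {
    all_chan <- layout_channels(layout, if (mod == "magnetometer") "magnetometer" else "gradiometer")
    center <- layout$channels$name[layout$channels$centerline]
    expected <- setdiff(all_chan, center)
    got <- unlist(map[[mod]], use.names = FALSE)
    dup <- unique(got[duplicated(got)])
    if (length(dup))
      stop("ROI map (", mod, "): channel(s) assigned twice: ",
           paste(dup, collapse = ", "))
    missing <- setdiff(expected, got)
    if (length(missing))
      stop("ROI map (", mod, "): missing channel(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(got, expected)
    if (length(extra))
      stop("ROI map (", mod, "): unknown or centerline channel(s): ",
           paste(extra, collapse = ", "))
    if (!setequal(names(map[[mod]]), ROI_IDS))
      stop("ROI map (", mod, "): ROI ids must be ", paste(ROI_IDS, collapse = ","))
  }
  invisible(map)
}

#' Load a region-of-interest map from YAML
#'
#' The file holds `magnetometer:` and `gradiometer:` sections, each mapping
#' the 10 ROI ids (LF, RF, LT, RT, LC, RC, LP, RP, LO, RO) to ordered channel
#' name lists. Every non-centerline channel of a modality must appear exactly
#' once; violations raise an error naming the offending channels.
#'
#' @param path YAML file path; the packaged default is at
#'   `system.file("extdata", "roi_map.yaml", package = "megwave")`.
#' @param layout The `meg_layout` the map refers to.
#' @return A validated `roi_map`.
#' @export
load_roi_map <- function(path, layout = build_layout()) {
  raw <- yaml::read_yaml(path)
  map <- list(
    magnetometer = purrr::map(raw$magnetometer, as.character)[ROI_IDS],
    gradiometer = purrr::map(raw$gradiometer, as.character)[ROI_IDS],
    excluded = as.character(raw$excluded)
  )
  class(map) <- "roi_map"
  .validate_roi_map(map, layout)
  map
}

#' Write a region-of-interest map to YAML
#'
#' @param map A `roi_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_map <- function(map, path) {
  yaml::write_yaml(list(magnetometer = purrr::map(map$magnetometer, as.list),
                        gradiometer = purrr::map(map$gradiometer, as.list),
                        excluded = as.list(map$excluded)), path)
  invisible(path)
}

#' @export
print.roi_map <- function(x, ...) {
  cat("<roi_map> 10 ROIs;",
      length(unlist(x$magnetometer)), "magnetometer /",
      length(unlist(x$gradiometer)), "gradiometer channels;",
      length(x$excluded), "centerline channels excluded\n")
  cat("  LF:", length(x$magnetometer$LF), "mag,",
      length(x$gradiometer$LF), "grad channels\n")
  invisible(x)
}

#' Assemble one ROI's MEG image for one epoch
#'
#' Stacks the traces of one ROI's sensors (one modality) for a single epoch
#' into an M x N matrix: M time samples down the rows, N sensors across the
#' columns in the ROI map's fixed channel order. This matrix is the 2D "MEG
#' image" fed to the wavelet-packet decomposition.
#'
#' @param epochs An `epoch_set` (see [segment_epochs()]).
#' @param roi ROI id, one of LF, RF, LT, RT, LC, RC, LP, RP, LO, RO.
#' @param modality `"magnetometer"` or `"gradiometer"`.
#' @param map A `roi_map`.
#' @param epoch_index 1-based epoch number.
#' @return A `meg_image`: list with `data` (M x N matrix), `sensors`, `roi`,
#'   `modality`, `participant`, `label`, `epoch`.
#' @export
build_meg_image <- function(epochs, roi, modality = c("magnetometer", "gradiometer"),
                            map, epoch_index) {
  modality <- match.arg(modality)
  if (!roi %in% ROI_IDS) stop("unknown ROI id: ", roi)
  if (epoch_index < 1L || epoch_index > length(epochs$epochs))
    stop("epoch_index out of range")
  sensors <- map[[modality]][[roi]]
  if (!length(sensors)) stop("ROI ", roi, " is empty for modality ", modality)
  ep <- epochs$epochs[[epoch_index]]
  idx <- match(sensors, epochs$channel_names)
  if (anyNA(idx))
    stop("epoch set lacks channel(s): ",
         paste(sensors[is.na(idx)], collapse = ", "))
  img <- t(ep[idx, , drop = FALSE])
  dimnames(img) <- NULL
  structure(list(data = img, sensors = sensors, roi = roi, modality = modality,
                 participant = epochs$participant, label = epochs$label,
                 epoch = epoch_index),
            class = "meg_image")
}

#' @export
print.meg_image <- function(x, ...) {
  cat("<meg_image> ", nrow(x$data), " samples x ", ncol(x$data), " sensors (",
      x$roi, "/", x$modality, ", participant ", x$participant,
      ", epoch ", x$epoch, ")\n", sep = "")
  invisible(x)
}
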