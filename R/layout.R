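#' Elekta-306-style sensor layout
#'
#' A `meg_layout` describes the 306-channel sensor array used throughout the
#' package: 102 sites on the unit sphere, each carrying one magnetometer and
#' two orthogonal planar gradiometers (latitude- and longitude-oriented).
#' Six magnetometer sites lie on the head centerline and are excluded from
#' the symmetric region-of-interest analysis.
#'
#' @param spec A list of site records, one per site, each with fields
#'   `site` (integer 1..102), `label`, `pos` (length-3 unit vector; x = right,
#'   y = anterior, z = superior), `centerline` (logical) and `channels`
#'   (character vector: magnetometer name then the two gradiometer names,
#'   suffixes "1", "2", "3" in the Neuromag convention). Defaults to the
#'   packaged layout.
#' @return A `meg_layout` object: a list with `channels` (tibble: one row per
#'   channel with name, kind, site, position, centerline flag) and `sites`
#'   (tibble of site records).
#' @examples
#' lay <- build_layout()
#' nrow(lay$channels) # 306
#' @export
build_layout <- function(spec = default_layout_spec()) {
  if (!length(spec)) stop("empty layout spec")
  sites <- purrr::map_dfr(spec, function(s) {
    tibble::tibble(
      site = as.integer(s$site),
      label = as.character(s$label),
      x = s$pos[1], y = s$pos[2], z = s$pos[3],
      centerline = isTRUE(s$centerline),
      channels = list(as.character(s$channels))
    )
  })
  if (anyDuplicated(sites$site)) stop("duplicate site indices in layout spec")

  chan <- purrr::pmap_dfr(sites, function(site, label, x, y, z, centerline, channels) {
    kind <- dplyr::case_when(
      endsWith(channels, "1") ~ "magnetometer",
      endsWith(channels, "2") ~ "gradiometer_lat",
      endsWith(channels, "3") ~ "gradiometer_long",
      TRUE ~ NA_character_
    )
    tibble::tibble(
      name = channels, kind = kind, site = site,
      x = x, y = y, z = z, centerline = centerline
    )
  })
  if (anyDuplicated(chan$name))
    stop("duplicate sensor names: ",
         paste(unique(chan$name[duplicated(chan$name)]), collapse = ", "))
  if (any(is.na(chan$kind)))
    stop("channel names must end in 1 (magnetometer), 2 or 3 (gradiometers)")

  per_site <- dplyr::summarise(
    dplyr::group_by(chan, .data$site),
    n_mag = sum(.data$kind == "magnetometer"),
    n_grad = sum(.data$kind != "magnetometer"),
    .groups = "drop"
  )
  bad_grad <- per_site$site[per_site$n_grad != 2L]
  if (length(bad_grad))
    stop("site(s) without both gradiometers: ", paste(bad_grad, collapse = ", "))
  bad_mag <- per_site$site[per_site$n_mag != 1L]
  if (length(bad_mag))
    stop("site(s) without exactly one magnetometer: ", paste(bad_mag, collapse = ", "))

  n_mag <- sum(chan$kind == "magnetometer")
  n_grad <- sum(chan$kind != "magnetometer")
  if (n_mag != 102L)
    stop("layout must have 102 magnetometers, found ", n_mag)
  if (n_grad != 204L)
    stop("layout must have 204 gradiometer channels, found ", n_grad)
  n_center <- sum(sites$centerline)
  if (n_center != 6L)
    stop("layout must flag exactly 6 centerline sites, found ", n_center)

  structure(list(channels = chan, sites = sites), class = "meg_layout")
}

#' @export
print.meg_layout <- function(x, ...) {
  cat("<meg_layout> ", nrow(x$channels), " channels / ", nrow(x$sites),
      " sites (", sum(x$sites$centerline), " centerline)\n", sep = "")
  invisible(x)
}

#' Channel names of one modality, in layout order
#'
#' @param layout A `meg_layout`.
#' @param modality `"magnetometer"` or `"gradiometer"` (both planar
#'   gradiometer orientations).
#' @return Character vector of channel names.
#' @export
layout_channels <- function(layout, modality = c("magnetometer", "gradiometer")) {
  modality <- match.arg(modality)
  if (modality == "magnetometer") {
    layout$channels$name[layout$channels$kind == "magnetometer"]
  } else {
    layout$channels$name[layout$channels$kind != "magnetometer"]
  }
}

# Deterministic default site geometry: 6 centerline sites on the x = 0 arc and
# 48 sites per hemisphere arranged in 4 rings of colatitude, mirrored in x.
# Site numbering: centerline 1..6 (anterior to posterior), then left hemisphere
# 7..54 and right hemisphere 55..102, each ring front-to-back, rings from the
# vertex outwards.
default_layout_spec <- function() {
  deg <- pi / 180
  rows <- list()
  add <- function(pos, centerline) {
    rows[[length(rows) + 1L]] <<- list(pos = pos, centerline = centerline)
  }
  # centerline: colatitudes 24/48/72 deg, front (y > 0) then back
  for (th in c(24, 48, 72) * deg) add(c(0, sin(th), cos(th)), TRUE)
  for (th in c(24, 48, 72) * deg) add(c(0, -sin(th), cos(th)), TRUE)
  ring_n <- c(8L, 12L, 14L, 14L)
  ring_th <- c(20, 42, 64, 82) * deg
  hemi_rows <- function(sgn) {
    out <- list()
    for (r in seq_along(ring_n)) {
      az <- seq(15, 165, length.out = ring_n[r]) * deg # from anterior to posterior
      for (a in az) {
        th <- ring_th[r]
        out[[length(out) + 1L]] <-
          list(pos = c(sgn * sin(th) * sin(a), sin(th) * cos(a), cos(th)),
               centerline = FALSE)
      }
    }
    out
  }
  rows <- c(rows, hemi_rows(-1), hemi_rows(+1))
  purrr::imap(rows, function(r, i) {
    label <- sprintf("MEG%03d", i)
    list(site = i, label = label, pos = round(r$pos, 6), centerline = r$centerline,
         channels = paste0(label, 1:3))
  })
}

#' Read a sensor layout specification from YAML
#'
#' The file holds one record per site with fields `site`, `label`, `pos`,
#' `centerline` and `channels`; the packaged default is at
#' `system.file("extdata", "elekta306_layout.yaml", package = "megwave")`.
#'
#' @param path Path to the YAML file.
#' @return A list of site records suitable for [build_layout()].
#' @export
read_layout_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  purrr::map(spec, function(s) {
    s$pos <- as.numeric(s$pos)
    s
  })
}

#' Write a sensor layout specification to YAML
#'
#' @param spec A list of site records (see [build_layout()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}
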