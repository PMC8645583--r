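#' Standard 64-channel scalp montage
#'
#' Returns the 64 scalp positions of the extended 10--20 system used by the
#' benchmark, with approximate 2-D head-layout coordinates (unit-circle
#' convention, nose up: `y > 0` anterior, `x > 0` right) and a coarse region
#' tag per electrode.  Coordinates are derived from the electrode label: the
#' row prefix (Fp, AF, F, FC/FT, C/T, CP/TP, P, PO, O, M) fixes the
#' anterior--posterior position and the numeric suffix the lateral one
#' (odd = left, even = right, z = midline).  They are intended for layout and
#' region lookup, not for source modelling.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `region`
#'   (one of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`,
#'   `"temporal"`).
#' @examples
#' m <- standard_montage()
#' subset(m, region == "occipital")
#' @export
standard_montage <- function() {
  labels <- c(
    "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
    "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
    "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6", "CP3",
    "CPz", "CP4", "P5", "P1", "P2", "P6", "PO5", "PO3",
    "PO4", "PO6", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8"
  )
  info <- t(vapply(labels, parse_1020_label, c(x = 0, y = 0, region = 0)))
  regions <- c("frontal", "central", "parietal", "occipital", "temporal")
  data.frame(
    label = labels,
    x = as.numeric(info[, "x"]),
    y = as.numeric(info[, "y"]),
    region = regions[as.integer(info[, "region"])],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Decompose a 10-20 label into row prefix + lateral suffix and map to an
# approximate layout position.  Longest prefixes are matched first so that
# "FC5" parses as FC+5, not F+C5.
parse_1020_label <- function(label) {
  prefixes <- c("Fp", "AF", "FT", "FC", "TP", "CP", "PO",
                "F", "T", "C", "P", "O", "M")
  hit <- prefixes[startsWith(label, prefixes)][1]
  if (is.na(hit)) stop("not a 10-20 label: ", label, call. = FALSE)
  suffix <- substring(label, nchar(hit) + 1L)
  if (!grepl("^(z|[0-9]+)$", suffix)) {
    stop("not a 10-20 label: ", label, call. = FALSE)
  }

  y <- switch(hit,
    Fp = 0.9, AF = 0.7, F = 0.5, FT = 0.25, FC = 0.25,
    T = 0, C = 0, M = -0.15, TP = -0.25, CP = -0.25,
    P = -0.5, PO = -0.7, O = -0.9
  )
  if (suffix == "z") {
    mag <- 0
    side <- 0
  } else {
    d <- as.integer(suffix)
    mag <- c(0.25, 0.45, 0.65, 0.85)[min(ceiling(d / 2), 4L)]
    if (hit == "M") mag <- 1
    side <- if (d %% 2 == 1) -1 else 1
  }
  # keep lateral electrodes inside the head circle at every row
  x <- side * mag * sqrt(max(1 - y^2, 0.05))

  region <- switch(hit,
    Fp = 1, AF = 1, F = 1,
    FC = 2, C = 2,
    CP = 3, P = 3,
    PO = 4, O = 4,
    FT = 5, T = 5, TP = 5, M = 5
  )
  c(x = x, y = y, region = region)
}

#' Default channel exclusion set
#'
#' The benchmark excludes the frontal-most electrodes (`Fz`, `F1`, `F2`),
#' which cannot be recorded under a head-mounted display because of
#' mechanical interference, and the mastoid electrodes (`M1`, `M2`), which
#' are prone to chronically high impedances.
#'
#' @return Character vector of electrode labels.
#' @export
default_exclusions <- function() c("Fz", "F1", "F2", "M1", "M2")

#' Drop channels from a recording
#'
#' @param rec An [eeg_recording()] object.
#' @param labels Electrode labels to drop.  Labels must belong to the
#'   standard montage; labels not present in `rec` are ignored so that the
#'   same exclusion list can be applied to reduced channel sets.
#' @return The recording without the named channels.
#' @examples
#' rec <- simulate_berger_session(test_generator_config(seed = 1), "No-VR")
#' rec2 <- exclude_channels(rec, c("Fp1", "Fp2"))
#' @export
exclude_channels <- function(rec, labels = default_exclusions()) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- as.character(labels)
  unknown <- setdiff(labels, standard_montage()$label)
  if (length(unknown)) {
    stop("labels not in the standard montage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(rec$channels %in% labels)
  if (!any(keep)) stop("channel exclusion would remove all channels",
                       call. = FALSE)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channels <- rec$channels[keep]
  validate_recording(rec)
}

# region lookup for a channel vector; unknown labels get NA
channel_regions <- function(channels) {
  m <- standard_montage()
  m$region[match(channels, m$label)]
}
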