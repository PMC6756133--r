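# EEG container and the 64-channel BioSemi (10-10 subset) template layout.

#' Construct an EEG recording
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel names; defaults to the BioSemi-64 layout when the
#'   recording has 64 channels.
#' @param reference `"raw"` or `"average"`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, reference = "raw") {
  if (!is.matrix(data)) stop_invalid("`data` must be a channels x samples matrix")
  check_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(labels)) {
    labels <- if (nrow(data) == 64L) biosemi64_labels() else
      paste0("Ch", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) stop_invalid("one label per channel required")
  if (anyDuplicated(labels)) stop_invalid("channel labels must be unique")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 reference = match.arg(reference, c("raw", "average"))),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG: %d channels x %d samples @ %g Hz (%.2f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' BioSemi 64-channel labels
#'
#' Channel names of the BioSemi ActiveTwo 64-electrode cap in its standard
#' A1-A32 / B1-B32 ordering (10-10 subset).
#'
#' @return character vector of 64 labels.
#' @export
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

#' Frontal channels used for ocular-artifact detection
#' @return character vector of 8 frontal labels.
#' @export
frontal_labels <- function() {
  c("Fp1", "AF7", "AF3", "Fpz", "Fp2", "AF8", "AF4", "AFz")
}

# Spherical-head template positions. Electrodes are placed on an idealized
# sphere using the 10-10 angular construction: the circumferential ring sits
# 72 deg from the vertex, sagittal rows step by 18 deg along the midline, and
# intermediate electrodes divide each row arc evenly (great-circle
# interpolation). Below-ring positions (P9/P10/Iz) sit 90 deg from the vertex.
# Good enough as a template for neighbourhood structure and smooth
# topographic weight maps; it is not a digitised cap.

#' Template 3-D electrode positions for the BioSemi-64 layout
#'
#' @param radius head radius in cm (default 9).
#' @return data.frame with columns `label`, `x`, `y`, `z` (cm); x points to
#'   the right ear, y to the nasion, z to the vertex.
#' @export
biosemi64_positions <- function(radius = 9) {
  sph <- function(incl_deg, az_deg) {
    # inclination from vertex; azimuth measured from nasion, clockwise to the
    # right when seen from above
    i <- incl_deg * pi / 180
    a <- az_deg * pi / 180
    c(x = sin(i) * sin(a), y = sin(i) * cos(a), z = cos(i))
  }
  slerp <- function(u, v, f) {
    w <- acos(max(-1, min(1, sum(u * v))))
    if (w < 1e-12) return(u)
    (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
  }
  pos <- list()
  # circumferential ring (72 deg inclination), azimuth in 18-deg steps
  ring <- c(Fpz = 0, Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36,
            F7 = -54, F8 = 54, FT7 = -72, FT8 = 72, T7 = -90, T8 = 90,
            TP7 = -108, TP8 = 108, P7 = -126, P8 = 126,
            PO7 = -144, PO8 = 144, O1 = -162, O2 = 162, Oz = 180)
  for (nm in names(ring)) pos[[nm]] <- sph(72, ring[[nm]])
  # below-ring electrodes
  pos$P9 <- sph(90, -126); pos$P10 <- sph(90, 126); pos$Iz <- sph(90, 180)
  # midline electrodes between ring and vertex
  mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0, CPz = -18, Pz = -36,
           POz = -54)
  for (nm in names(mid)) {
    d <- mid[[nm]]
    pos[[nm]] <- if (d >= 0) sph(d, 0) else sph(-d, 180)
  }
  # rows: interpolate between the left ring end, the midline electrode and
  # the right ring end along great circles
  row_fill <- function(left, midl, right, names_l, names_r) {
    nl <- length(names_l)
    for (k in seq_len(nl)) {
      f <- k / (nl + 1)
      pos[[names_l[k]]] <<- slerp(pos[[left]], pos[[midl]], f)
      pos[[names_r[k]]] <<- slerp(pos[[right]], pos[[midl]], f)
    }
  }
  row_fill("AF7", "AFz", "AF8", "AF3", "AF4")
  row_fill("F7", "Fz", "F8", c("F5", "F3", "F1"), c("F6", "F4", "F2"))
  row_fill("FT7", "FCz", "FT8", c("FC5", "FC3", "FC1"), c("FC6", "FC4", "FC2"))
  row_fill("T7", "Cz", "T8", c("C5", "C3", "C1"), c("C6", "C4", "C2"))
  row_fill("TP7", "CPz", "TP8", c("CP5", "CP3", "CP1"), c("CP6", "CP4", "CP2"))
  row_fill("P7", "Pz", "P8", c("P5", "P3", "P1"), c("P6", "P4", "P2"))
  row_fill("PO7", "POz", "PO8", "PO3", "PO4")
  labs <- biosemi64_labels()
  m <- t(vapply(labs, function(l) pos[[l]], numeric(3))) * radius
  data.frame(label = labs, x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL)
}

#' Write or read a channel adjacency graph as an edge list
#'
#' @param adjacency a named neighbour list as from [channel_adjacency()].
#' @param path a two-column tab-separated edge-list file.
#' @return `write_adjacency()` returns `path`; `read_adjacency()` the
#'   neighbour list.
#' @export
write_adjacency <- function(adjacency, path) {
  edges <- do.call(rbind, lapply(names(adjacency), function(a) {
    b <- adjacency[[a]]
    if (length(b)) data.frame(from = a, to = b) else NULL
  }))
  edges <- edges[edges$from < edges$to, ] # undirected: keep each edge once
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  labs <- sort(unique(c(edges$from, edges$to)))
  out <- lapply(labs, function(l)
    sort(unique(c(edges$to[edges$from == l], edges$from[edges$to == l]))))
  names(out) <- labs
  out
}

#' Channel adjacency graph from template distances
#'
#' Two channels are neighbours when their straight-line template distance is
#' below `threshold_cm`. Returned as a named list of neighbour label vectors,
#' the form consumed by [cluster_permutation()].
#'
#' @param positions electrode positions as from [biosemi64_positions()].
#' @param threshold_cm neighbour distance threshold in cm (default 4).
#' @return named list: for each channel, the labels of its neighbours.
#' @export
channel_adjacency <- function(positions = biosemi64_positions(),
                              threshold_cm = 4) {
  m <- as.matrix(positions[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m))
  out <- lapply(seq_len(nrow(m)), function(i)
    positions$label[d[i, ] < threshold_cm & seq_len(nrow(m)) != i])
  names(out) <- positions$label
  out
}
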