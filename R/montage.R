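#' Electrode montage: idealized 10-10 layout with spatial adjacency
#'
#' Builds the 64-electrode montage used throughout the package. Electrode
#' positions are idealized 10-10 coordinates on the unit sphere (vertex at
#' Cz, the 10% ring through T7/T8/Oz at 90 degrees inclination, the
#' sub-ring FT9/TP9/PO9 and mirrors at 108 degrees); interior electrodes
#' are placed by spherical interpolation along the arc between their
#' midline anchor and their outer-ring counterpart. For display and export
#' the sphere is projected to the unit disc with an azimuthal-equidistant
#' projection (nose up, left hemisphere at negative x).
#'
#' Two electrodes are adjacent iff their chord distance on the unit sphere
#' is at most `neighbour_factor` times the median nearest-neighbour
#' distance of the layout. Distances are taken on the sphere rather than on
#' the projected disc because disc projections stretch the outer ring
#' tangentially, which would leave rim electrodes without neighbours; on
#' the sphere the idealized 10-10 arcs are nearly uniform (~18 degrees).
#'
#' The recording reference (FCz) is not a data channel and carries no
#' position in the montage.
#'
#' @param n_channels Number of channels; only 64 is supported.
#' @param neighbour_factor Multiple of the median nearest-neighbour
#'   distance below which two electrodes count as adjacent. Default 1.3.
#' @return An object of class `electrode_montage`: a list with `labels`
#'   (character), `positions` (data frame: label, x, y on the unit disc),
#'   `adjacency` (symmetric, irreflexive logical matrix with dimnames),
#'   `reference_label` ("FCz") and `neighbour_factor`.
#' @examples
#' mon <- build_standard_montage()
#' neighbours(mon, "Cz")
#' @export
build_standard_montage <- function(n_channels = 64, neighbour_factor = 1.3) {
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels != 64) {
    stop("only the 64-channel 10-10 montage is supported", call. = FALSE)
  }
  stopifnot(is.numeric(neighbour_factor), neighbour_factor > 0)

  lay <- ten_ten_layout()
  p3 <- as.matrix(lay[, c("sx", "sy", "sz")])
  d <- as.matrix(stats::dist(p3))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  thresh <- neighbour_factor * stats::median(nn)
  adjacency <- d <= thresh
  diag(adjacency) <- FALSE
  dimnames(adjacency) <- list(lay$label, lay$label)

  structure(
    list(
      labels = lay$label,
      positions = data.frame(label = lay$label, x = lay$x, y = lay$y,
                             stringsAsFactors = FALSE),
      adjacency = adjacency,
      reference_label = "FCz",
      neighbour_factor = neighbour_factor
    ),
    class = "electrode_montage"
  )
}

#' Neighbours of an electrode
#'
#' @param montage An `electrode_montage`.
#' @param label Electrode name present in the montage.
#' @return Character vector of adjacent electrode labels (never contains
#'   `label` itself).
#' @export
neighbours <- function(montage, label) {
  stopifnot(inherits(montage, "electrode_montage"))
  if (length(label) != 1L || !label %in% montage$labels) {
    stop("unknown electrode label: ", label, call. = FALSE)
  }
  montage$labels[montage$adjacency[label, ]]
}

#' @export
print.electrode_montage <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  cat(sprintf("<electrode_montage> %d channels (10-10), reference %s\n",
              length(x$labels), x$reference_label))
  cat(sprintf("  adjacency: %d edges, mean degree %.2f (factor %.2f)\n",
              sum(x$adjacency) / 2, mean(deg), x$neighbour_factor))
  invisible(x)
}

#' Export a montage as tab-separated text
#'
#' Writes the electrode coordinate table (`label`, `x`, `y`) and,
#' optionally, the adjacency relation as an edge list (`from`, `to`, each
#' undirected edge once).
#'
#' @param montage An `electrode_montage`.
#' @param path File path for the coordinate TSV.
#' @param edge_path Optional file path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
write_montage_tsv <- function(montage, path, edge_path = NULL) {
  stopifnot(inherits(montage, "electrode_montage"))
  utils::write.table(montage$positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(edge_path)) {
    idx <- which(montage$adjacency & upper.tri(montage$adjacency),
                 arr.ind = TRUE)
    edges <- data.frame(from = montage$labels[idx[, 1L]],
                        to = montage$labels[idx[, 2L]],
                        stringsAsFactors = FALSE)
    utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---- layout construction ---------------------------------------------------

# Unit vector on the scalp sphere. Inclination measured from the vertex,
# azimuth from the nose (positive towards the left ear).
sph_vec <- function(inclination_deg, azimuth_deg) {
  i <- inclination_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

# Great-circle interpolation between two unit vectors.
slerp <- function(a, b, t) {
  om <- acos(max(-1, min(1, sum(a * b))))
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

# Azimuthal-equidistant projection to the head plane, rescaled so the
# outermost (sub-ring) electrodes sit on the unit circle; nose up, left
# hemisphere at negative x.
disc_project <- function(v, max_inclination_deg = 108) {
  inclination <- acos(max(-1, min(1, v[3])))
  azimuth <- atan2(v[1], v[2])
  r <- inclination / (max_inclination_deg * pi / 180)
  c(-r * sin(azimuth), r * cos(azimuth))
}

# The 64 labelled positions: outer ring at 90 deg inclination, sub-ring at
# 108 deg, midline anchors every 18 deg, interior electrodes by slerp
# between the midline anchor and the same row's outer-ring electrode.
ten_ten_layout <- function() {
  pts <- list()
  add <- function(label, v) pts[[label]] <<- v

  ring_lab_l <- c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1")
  ring_lab_r <- c("Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2")
  ring_az <- c(18, 36, 54, 72, 90, 108, 126, 144, 162)
  for (k in seq_along(ring_az)) {
    add(ring_lab_l[k], sph_vec(90, ring_az[k]))
    add(ring_lab_r[k], sph_vec(90, -ring_az[k]))
  }
  add("Oz", sph_vec(90, 180))

  sub_lab_l <- c("FT9", "TP9", "PO9")
  sub_lab_r <- c("FT10", "TP10", "PO10")
  sub_az <- c(72, 108, 144)
  for (k in seq_along(sub_az)) {
    add(sub_lab_l[k], sph_vec(108, sub_az[k]))
    add(sub_lab_r[k], sph_vec(108, -sub_az[k]))
  }

  add("Fz", sph_vec(36, 0))
  add("Cz", sph_vec(0, 0))
  add("CPz", sph_vec(18, 180))
  add("Pz", sph_vec(36, 180))
  add("POz", sph_vec(54, 180))

  interp_row <- function(mid_inc, mid_az, ring_az,
                         labels_left, labels_right, ts) {
    m <- sph_vec(mid_inc, mid_az)
    for (k in seq_along(ts)) {
      add(labels_left[k], slerp(m, sph_vec(90, ring_az), ts[k]))
      add(labels_right[k], slerp(m, sph_vec(90, -ring_az), ts[k]))
    }
  }
  interp_row(54, 0, 36, "AF3", "AF4", 0.5)
  interp_row(36, 0, 54, c("F1", "F3", "F5"), c("F2", "F4", "F6"),
             c(0.25, 0.5, 0.75))
  interp_row(18, 0, 72, c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"),
             c(0.25, 0.5, 0.75))
  interp_row(0, 0, 90, c("C1", "C3", "C5"), c("C2", "C4", "C6"),
             c(0.25, 0.5, 0.75))
  interp_row(18, 180, 108, c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"),
             c(0.25, 0.5, 0.75))
  interp_row(36, 180, 126, c("P1", "P3", "P5"), c("P2", "P4", "P6"),
             c(0.25, 0.5, 0.75))
  interp_row(54, 180, 144, "PO3", "PO4", 0.5)

  labels <- names(pts)
  sphere <- do.call(rbind, pts)
  plane <- t(apply(sphere, 1L, disc_project))
  data.frame(label = labels,
             x = plane[, 1L], y = plane[, 2L],
             sx = sphere[, 1L], sy = sphere[, 2L], sz = sphere[, 3L],
             stringsAsFactors = FALSE)
}

#' Region-of-interest electrode sets
#'
#' The centro-parietal electrode sets over which alpha-band activity is
#' aggregated: a left-lateralized seven-electrode set and a midline
#' five-electrode set.
#'
#' @param side `"left"` or `"midline"`.
#' @return Character vector of electrode labels.
#' @export
roi_electrodes <- function(side = c("left", "midline")) {
  side <- match.arg(side)
  switch(side,
         left = c("CP1", "P3", "CP3", "P1", "P5", "PO7", "PO3"),
         midline = c("Pz", "CP2", "P1", "P2", "CPz"))
}
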