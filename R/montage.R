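# Electrode montages: labels + 3-D unit-sphere positions (head apex at z = +1),
# azimuthal equidistant projection to the plane, and the spatial profile used
# by the synthetic cohort generator.

new_montage <- function(labels, pos3d, pos2d = NULL) {
  labels <- as.character(labels)
  pos3d <- as.matrix(pos3d)
  if (nrow(pos3d) != length(labels) || ncol(pos3d) != 3L)
    stop_input("pos3d must be an n x 3 matrix matching labels")
  if (anyDuplicated(labels)) stop_input("montage labels must be unique")
  nrm <- sqrt(rowSums(pos3d^2))
  if (any(nrm < 1e-12)) stop_input("zero-norm electrode position")
  if (any(abs(nrm - 1) > 1e-6))
    stop_input("electrode positions must lie on the unit sphere (|p| == 1)")
  structure(list(labels = labels, pos3d = pos3d, pos2d = pos2d),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes%s\n", length(x$labels),
              if (is.null(x$pos2d)) "" else " (projected)"))
  invisible(x)
}

# spherical position from inclination (deg from vertex) and azimuth
# (deg, 0 = front/nasion, positive = left)
sph_pos <- function(inc_deg, az_deg) {
  t <- inc_deg * pi / 180; a <- az_deg * pi / 180
  c(sin(t) * cos(a), sin(t) * sin(a), cos(t))
}

slerp <- function(u, v, f) {
  o <- acos(max(-1, min(1, sum(u * v))))
  if (o < 1e-12) return(u)
  (sin((1 - f) * o) * u + sin(f * o) * v) / sin(o)
}

#' Template 60-channel montage
#'
#' A synthetic standard 10-10 style template for a 60-electrode cap:
#' midline row Fpz..Oz, a 10%-ring of lateral electrodes, and intermediate
#' electrodes placed by spherical interpolation along each coronal row.
#' Positions are unit vectors with the head apex (Cz) at z = +1 and the
#' nasion direction along +x.  It is a geometric template, not digitised
#' electrode positions; user montages can be supplied as JSON via
#' [read_montage()].
#'
#' @return an `eeg_montage` object with 60 electrodes.
#' @export
template_montage <- function() {
  pos <- list(); lab <- character(0)
  add <- function(label, p) { pos[[length(pos) + 1L]] <<- p; lab <<- c(lab, label) }

  mid <- list(Fpz = c(72, 0), AFz = c(54, 0), Fz = c(36, 0), Cz = c(0, 0),
              CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180), Oz = c(72, 180))
  for (nm in names(mid)) add(nm, sph_pos(mid[[nm]][1], mid[[nm]][2]))

  ring <- list(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
               TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  right_of <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
                TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2")
  for (nm in names(ring)) {
    add(nm, sph_pos(72, ring[[nm]]))
    add(right_of[[nm]], sph_pos(72, -ring[[nm]]))
  }

  # intermediate electrodes: slerp between the midline anchor of the row and
  # the 10%-ring electrode of the same row (left side; right is mirrored)
  rows <- list(
    AF = list(anchor = sph_pos(54, 0),   outer = 36,  inner = c(AF3 = 0.5)),
    F  = list(anchor = sph_pos(36, 0),   outer = 54,  inner = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    FC = list(anchor = sph_pos(18, 0),   outer = 72,  inner = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    C  = list(anchor = sph_pos(0, 0),    outer = 90,  inner = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    CP = list(anchor = sph_pos(18, 180), outer = 108, inner = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    P  = list(anchor = sph_pos(36, 180), outer = 126, inner = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    PO = list(anchor = sph_pos(54, 180), outer = 144, inner = c(PO3 = 0.5)))
  mirror_label <- function(l) {
    n <- as.integer(sub("^[A-Za-z]+", "", l))
    paste0(sub("[0-9]+$", "", l), n + 1L)
  }
  for (row in rows) {
    outerL <- sph_pos(72, row$outer); outerR <- sph_pos(72, -row$outer)
    for (nm in names(row$inner)) {
      f <- row$inner[[nm]]
      add(nm, slerp(row$anchor, outerL, f))
      add(mirror_label(nm), slerp(row$anchor, outerR, f))
    }
  }
  p <- do.call(rbind, pos)
  p <- p / sqrt(rowSums(p^2))
  new_montage(lab, p)
}

#' Channel labels of the raw 64-channel recording template
#'
#' The 60 scalp labels of [template_montage()] plus the four ocular channels
#' (HEOGL, HEOGR, VEOGL, VEOGU) that are removed during preprocessing.
#'
#' @return character vector of 64 labels.
#' @export
template_labels_64 <- function() {
  c(template_montage()$labels, ocular_labels())
}

#' The four ocular channel labels removed during preprocessing
#' @return character vector of 4 labels.
#' @export
ocular_labels <- function() c("HEOGL", "HEOGR", "VEOGL", "VEOGU")

#' Frontal-weighted spatial effect profile
#'
#' Maps channel labels to the spatial weight with which the synthetic
#' patient-class effect is applied: frontal labels (Fp/AF/F, incl. FT) get
#' weight 1.0, central labels (FC/C/T) 0.4, posterior labels (CP/TP/P/PO/O)
#' 0.1, anything else (e.g. ocular channels) 0.
#'
#' @param labels character vector of channel labels.
#' @return named numeric vector of weights in `[0, 1]`.
#' @export
frontal_weights <- function(labels) {
  w <- vapply(labels, function(l) {
    if (grepl("^(CP|TP|P|O)", l)) 0.1
    else if (grepl("^(FC|C|T)", l)) 0.4
    else if (grepl("^(Fp|AF|F)", l)) 1.0
    else 0.0
  }, numeric(1))
  names(w) <- labels
  w
}

#' Azimuthal equidistant projection of a montage
#'
#' Projects 3-D unit-sphere electrode positions onto the plane tangent at the
#' head apex (0, 0, 1).  An electrode with polar angle `theta = acos(z)` and
#' azimuth `phi = atan2(y, x)` maps to `(theta * cos(phi), theta * sin(phi))`,
#' so the planar distance from the origin equals the great-circle distance
#' from the apex (equidistant property).
#'
#' @param montage an `eeg_montage`.
#' @return the montage with `pos2d` filled (n x 2 matrix).
#' @export
aep_project <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  p <- montage$pos3d
  theta <- acos(pmin(1, pmax(-1, p[, 3])))
  phi <- atan2(p[, 2], p[, 1])
  montage$pos2d <- cbind(theta * cos(phi), theta * sin(phi))
  rownames(montage$pos2d) <- montage$labels
  montage
}

#' Read / write a montage as JSON
#'
#' The file is a JSON array of objects `{label, x, y, z}` with unit-sphere
#' coordinates.
#'
#' @param path file path.
#' @return `read_montage` returns an `eeg_montage`.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("montage file not found: %s", path))
  d <- jsonlite::fromJSON(path)
  new_montage(d$label, cbind(d$x, d$y, d$z))
}

#' @param montage an `eeg_montage`.
#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  d <- data.frame(label = montage$labels, x = montage$pos3d[, 1],
                  y = montage$pos3d[, 2], z = montage$pos3d[, 3])
  jsonlite::write_json(d, path, digits = NA)
  invisible(path)
}
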