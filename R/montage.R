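#' Standard 10-20 electrode template
#'
#' Spherical-head positions (unit radius) for the electrodes of the extended
#' 10-20 montage used throughout the package, given as signed inclination /
#' azimuth pairs (degrees) and converted to 3-D Cartesian coordinates.
#' Inclination is measured from the vertex and signed by hemisphere
#' (negative = left); azimuth rotates towards the front of the head.
#'
#' @return A data frame with columns `label`, `x`, `y`, `z` (x = right,
#'   y = anterior, z = superior; unit sphere).
#' @export
template_positions <- function() {
  # theta: signed inclination from Cz; phi: azimuth (front-positive on the
  # right, front-negative on the left, standard spherical-head convention)
  tab <- matrix(c(
    -92, -72,   # Fp1
     92,  72,   # Fp2
    -92, -36,   # F7
    -60, -51,   # F3
     46,  90,   # Fz
     60,  51,   # F4
     92,  36,   # F8
    -71, -21,   # FC5
    -32, -45,   # FC1
     32,  45,   # FC2
     71,  21,   # FC6
    -92,   0,   # T7
    -46,   0,   # C3
      0,   0,   # Cz
     46,   0,   # C4
     92,   0,   # T8
   -113,  18,   # TP9
    -71,  21,   # CP5
    -32,  45,   # CP1
     32, -45,   # CP2
     71, -21,   # CP6
    113, -18,   # TP10
    -92,  36,   # P7
    -60,  51,   # P3
     46, -90,   # Pz
     60, -51,   # P4
     92, -36    # P8
  ), ncol = 2, byrow = TRUE)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6",
              "T7", "C3", "Cz", "C4", "T8",
              "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
              "P7", "P3", "Pz", "P4", "P8")
  th <- tab[, 1] * pi / 180
  ph <- tab[, 2] * pi / 180
  data.frame(label = labels,
             x = sin(th) * cos(ph),
             y = sin(th) * sin(ph),
             z = cos(th),
             stringsAsFactors = FALSE)
}

#' Analysis channel set
#'
#' The 23 scalp channels retained for analysis: the recorded 10-20 montage
#' minus the two noisy posterior channels (P7, P8) and the two mastoids
#' (TP9, TP10), which are reserved for referencing.
#'
#' @return Character vector of 23 channel labels.
#' @export
analysis_channels <- function() {
  setdiff(template_positions()$label, c("P7", "P8", "TP9", "TP10"))
}

#' Build a channel layout
#'
#' @param labels Channel labels; all must be present in the template.
#' @return A `sbc_layout` object: data frame of labels and 3-D positions.
#' @export
channel_layout <- function(labels = analysis_channels()) {
  tmpl <- template_positions()
  miss <- setdiff(labels, tmpl$label)
  if (length(miss) > 0)
    stop("no template position for channel(s): ", paste(miss, collapse = ", "))
  out <- tmpl[match(labels, tmpl$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sbc_layout", "data.frame")
  out
}

layout_matrix <- function(layout) {
  m <- as.matrix(layout[, c("x", "y", "z")])
  rownames(m) <- layout$label
  m
}
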