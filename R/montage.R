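#' Standard 64-channel 10-10 scalp montage
#'
#' Returns unit-sphere electrode coordinates for a 64-channel
#' international 10-10 layout (the cap used for the recordings, nose
#' reference not included). Positions are generated from the schematic
#' grid of the 10-10 system: rows from frontal pole to inion at 10%
#' (18 degree) sagittal steps and lateral columns at 18 degree coronal
#' steps, projected onto the unit sphere. The geometry feeds neighbor
#' construction and the topography templates of the synthetic generator;
#' it is a schematic head, not digitized electrode positions.
#'
#' @return Data frame with `label`, `x`, `y`, `z` (unit vectors;
#'   x = right, y = anterior, z = up).
#' @examples
#' head(montage_1010())
#' @export
montage_1010 <- function() {
  rows <- list(
    Fp = list(y = 4, labs = c("Fp1" = -1, "Fpz" = 0, "Fp2" = 1)),
    AF = list(y = 3, labs = c("AF7" = -4, "AF3" = -2, "AFz" = 0, "AF4" = 2, "AF8" = 4)),
    F  = list(y = 2, labs = c("F7" = -4, "F5" = -3, "F3" = -2, "F1" = -1, "Fz" = 0,
                              "F2" = 1, "F4" = 2, "F6" = 3, "F8" = 4)),
    FC = list(y = 1, labs = c("FT7" = -4, "FC5" = -3, "FC3" = -2, "FC1" = -1, "FCz" = 0,
                              "FC2" = 1, "FC4" = 2, "FC6" = 3, "FT8" = 4)),
    C  = list(y = 0, labs = c("T7" = -4, "C5" = -3, "C3" = -2, "C1" = -1, "Cz" = 0,
                              "C2" = 1, "C4" = 2, "C6" = 3, "T8" = 4)),
    CP = list(y = -1, labs = c("TP7" = -4, "CP5" = -3, "CP3" = -2, "CP1" = -1, "CPz" = 0,
                               "CP2" = 1, "CP4" = 2, "CP6" = 3, "TP8" = 4)),
    P  = list(y = -2, labs = c("P7" = -4, "P5" = -3, "P3" = -2, "P1" = -1, "Pz" = 0,
                               "P2" = 1, "P4" = 2, "P6" = 3, "P8" = 4)),
    PO = list(y = -3, labs = c("PO7" = -4, "PO5" = -3, "PO3" = -2, "POz" = 0,
                               "PO4" = 2, "PO6" = 3, "PO8" = 4)),
    O  = list(y = -4, labs = c("O1" = -1, "Oz" = 0, "O2" = 1)),
    I  = list(y = -5, labs = c("Iz" = 0))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = names(r$labs), gx = unname(r$labs), gy = r$y)
  }))
  rownames(out) <- NULL
  # schematic grid -> sphere: 15 degrees of inclination per grid unit of
  # radial distance from the vertex (a cap reaching ~75 degrees, matching
  # the packing density of an elastic 64-channel cap)
  rho <- sqrt(out$gx^2 + out$gy^2)
  theta <- pmin(rho * 15, 90) * pi / 180       # inclination from vertex
  phi <- atan2(out$gx, out$gy)                 # azimuth, 0 = anterior
  data.frame(label = out$label,
             x = sin(theta) * sin(phi),
             y = sin(theta) * cos(phi),
             z = cos(theta))
}

#' Frontal channels excluded from the coarse artifact screen
#'
#' Frontmost rows of the montage, left in during epoch screening so
#' blink-dominated trials survive to the (out-of-scope) ICA stage.
#'
#' @return Character vector of channel labels.
#' @export
frontal_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8")
}

#' Build a channel adjacency graph from electrode geometry
#'
#' Two channels are neighbors when their 3D distance on the (unit) head
#' is at most `threshold`. The relation is symmetric and irreflexive;
#' it defines the spatial component of cluster adjacency.
#'
#' @param positions Data frame with `label`, `x`, `y`, `z` (see
#'   [montage_1010()]).
#' @param threshold Neighbor distance threshold (default 0.4 on a unit
#'   head).
#' @return An `adjacency` object: logical channel-by-channel matrix with
#'   dimnames, plus attribute `neighbors` (list of integer vectors).
#' @export
build_adjacency <- function(positions, threshold = 0.4) {
  if (nrow(positions) < 2) stopf("need at least 2 positioned channels")
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= threshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(positions$label, positions$label)
  if (any(rowSums(adj) == 0))
    warning("adjacency graph has isolated channels at threshold ", threshold)
  structure(adj, class = c("adjacency", "matrix"),
            neighbors = apply(adj, 1, which, simplify = FALSE))
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d channels, mean %.1f neighbors\n",
              nrow(x), mean(rowSums(unclass(x)))))
  invisible(x)
}
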