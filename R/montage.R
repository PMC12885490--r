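#' Idealized spherical 10-10 montage
#'
#' Returns unit-sphere Cartesian coordinates (x right, y anterior, z up) for a
#' subset of the extended 10-20 system. Positions are idealized: midline and
#' central rows are placed at exact 10-20 angles and intermediate rows
#' (FC/CP) by spherical interpolation between neighbours. The geometry is
#' used for Gaussian ground-truth topographies and the surface-Laplacian
#' (current source density) transform; it is not a digitized head model.
#'
#' @param channels character vector of channel names, or `NULL` for the
#'   default 14-channel montage (the frontocentral/central/centroparietal
#'   set, Fz, Pz, O1, O2 and T7).
#' @return data.frame with columns `channel`, `x`, `y`, `z` (unit sphere).
#' @export
#' @examples
#' montage_positions(c("C3", "Cz", "C4"))
montage_positions <- function(channels = NULL) {
  pos <- .montage_table()
  if (is.null(channels)) channels <- default_channels()
  missing <- setdiff(channels, pos$channel)
  if (length(missing) > 0) {
    stop("no montage position for channel(s): ", paste(missing, collapse = ", "))
  }
  pos[match(channels, pos$channel), , drop = FALSE]
}

#' Default 14-channel montage
#'
#' The nine sensorimotor channels used for steady-state movement-related
#' potential analysis (FC3, FCz, FC4, C3, Cz, C4, CP3, CPz, CP4), the three
#' occipito-parietal channels used for steady-state visual evoked potential
#' analysis (Pz, O1, O2), plus Fz and T7.
#'
#' @return character vector of channel names.
#' @export
default_channels <- function() {
  c("Fz", "FC3", "FCz", "FC4", "C3", "Cz", "C4",
    "CP3", "CPz", "CP4", "Pz", "O1", "O2", "T7")
}

#' Named channel sets for steady-state analyses
#'
#' @param name one of `"ssmrp"` (frontocentral/central/centroparietal) or
#'   `"ssvep"` (occipital/parietal).
#' @return character vector of channel names.
#' @export
channel_set <- function(name = c("ssmrp", "ssvep")) {
  name <- match.arg(name)
  switch(name,
    ssmrp = c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CPz", "CP4"),
    ssvep = c("Pz", "O1", "O2")
  )
}

# Spherical linear interpolation between two unit vectors.
.slerp <- function(a, b, t = 0.5) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

.montage_table <- function() {
  sph <- function(incl_deg, az_deg) {
    # inclination from vertex; azimuth 0 = anterior midline, positive to right
    th <- incl_deg * pi / 180
    ph <- az_deg * pi / 180
    c(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
  }
  p <- list(
    Cz  = sph(0, 0),
    Fz  = sph(45, 0),
    Pz  = sph(45, 180),
    C3  = sph(45, -90),
    C4  = sph(45, 90),
    T7  = sph(90, -90),
    T8  = sph(90, 90),
    Oz  = sph(90, 180),
    O1  = sph(90, 180 + 18),  # 18 deg off the posterior midline, left
    O2  = sph(90, 180 - 18),
    F3  = sph(62, -39),
    F4  = sph(62, 39),
    P3  = sph(62, 180 + 39),
    P4  = sph(62, 180 - 39),
    FCz = sph(22.5, 0),
    CPz = sph(22.5, 180)
  )
  p$FC3 <- .slerp(p$C3, p$F3)
  p$FC4 <- .slerp(p$C4, p$F4)
  p$CP3 <- .slerp(p$C3, p$P3)
  p$CP4 <- .slerp(p$C4, p$P4)
  nm <- names(p)
  m <- do.call(rbind, p)
  data.frame(channel = nm, x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gaussian scalp topography centred on a channel set
#'
#' Builds a smooth per-channel weight vector: a Gaussian bump (in great-circle
#' distance on the unit sphere) centred on the spherical centroid of
#' `center_channels`, evaluated at every channel of `channels` and scaled to a
#' maximum of 1.
#'
#' @param center_channels channels defining the bump centre.
#' @param channels full montage channel vector the weights are computed for.
#' @param width Gaussian width (radians of great-circle distance). Default
#'   0.6 gives substantial weight across a 9-channel sensorimotor patch while
#'   leaving distal sites near zero.
#' @return named numeric vector of weights in (0, 1], one per channel.
#' @export
gaussian_topography <- function(center_channels, channels = default_channels(),
                                width = 0.6) {
  stopifnot(width > 0)
  pos <- montage_positions(channels)
  cpos <- montage_positions(center_channels)
  centroid <- colMeans(as.matrix(cpos[, c("x", "y", "z")]))
  centroid <- centroid / sqrt(sum(centroid^2))
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  ang <- acos(pmax(-1, pmin(1, as.vector(xyz %*% centroid))))
  w <- exp(-ang^2 / (2 * width^2))
  w <- w / max(w)
  names(w) <- channels
  w
}
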