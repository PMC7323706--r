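#' Phantom configuration
#'
#' @param dim spatial grid in voxels (length 3, each >= 16).
#' @param voxel_mm isotropic voxel size in mm (default 0.2, i.e. 200 um).
#' @param group study group: WT, P80 or P120.
#' @param snr baseline signal-to-noise ratio s0/sigma; \code{Inf} for
#'   noiseless data.
#' @param seed master RNG seed; per-stage child seeds are derived from it
#'   (see \code{\link{seed_child}}).
#' @param geometry \code{"brain_slab"} or \code{"spinal_cord"}.
#' @return A list of class \code{"phantom_config"}.
#' @export
phantom_config <- function(dim = c(48, 48, 48), voxel_mm = 0.2,
                           group = c("WT", "P80", "P120"), snr = 30,
                           seed = 1L,
                           geometry = c("brain_slab", "spinal_cord")) {
  group <- match.arg(group)
  geometry <- match.arg(geometry)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 16L))
    stop("grid dimensions must be three values, each >= 16")
  if (!(snr > 0)) stop("snr must be positive (Inf for noiseless)")
  structure(list(dim = dim, voxel_mm = voxel_mm, group = group, snr = snr,
                 seed = as.integer(seed), geometry = geometry),
            class = "phantom_config")
}

#' Derive a per-stage child seed from a master seed
#'
#' Splitting rule: \code{((master mod 1000003) * 1009 + stage * 7919) mod
#' 2147483629}.  Distinct stages of one run (geometry, orientations, noise)
#' use distinct small stage indices, so a single master seed reproduces the
#' whole dataset.
#'
#' @param master master seed (integer).
#' @param stage small non-negative stage index.
#' @return An integer seed.
#' @export
seed_child <- function(master, stage) {
  as.integer((as.numeric(master) %% 1000003) * 1009 + stage * 7919) %%
    2147483629L
}

#' Build a labeled phantom geometry
#'
#' Stylized neuraxial geometries (the acceptance surface is shape-metric
#' recovery, not anatomy).  \code{brain_slab}: a cortical shell (CCX), two
#' hippocampal blobs (Hipp), a left-right corpus callosum strip (CC) and two
#' rostro-caudal corticospinal columns (CST), pairwise disjoint inside an
#' ellipsoidal brain.  \code{spinal_cord}: an inner gray-matter cylinder
#' (SC_gm, with an anterior-horn sector GM_ah) surrounded by a white-matter
#' annulus partitioned into anterior/lateral/posterior funiculi (Af, Lf,
#' Pf).  Background is 0.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return An integer 3D array of label codes (see
#'   \code{\link{label_scheme}}) with attributes \code{geometry} and
#'   \code{voxel_mm}.
#' @export
build_label_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim
  ax <- (seq_len(d[1]) - 0.5) / d[1]
  ay <- (seq_len(d[2]) - 0.5) / d[2]
  az <- (seq_len(d[3]) - 0.5) / d[3]
  ux <- array(rep(ax, times = d[2] * d[3]), dim = d)
  uy <- array(rep(rep(ay, each = d[1]), times = d[3]), dim = d)
  uz <- array(rep(az, each = d[1] * d[2]), dim = d)
  lab <- array(0L, dim = d)

  if (config$geometry == "brain_slab") {
    rho <- sqrt(((ux - 0.5) / 0.42)^2 + ((uy - 0.5) / 0.42)^2 +
                  ((uz - 0.5) / 0.42)^2)
    lab[rho >= 0.80 & rho <= 1 & uz > 0.5] <- LABEL_SCHEME[["CCX"]]
    hip <- (pmin((ux - 0.35)^2, (ux - 0.65)^2) + (uy - 0.60)^2 +
              (uz - 0.45)^2) <= 0.07^2
    lab[hip] <- LABEL_SCHEME[["Hipp"]]
    cc <- ux >= 0.25 & ux <= 0.75 & abs(uy - 0.45) <= 0.06 &
      abs(uz - 0.62) <= 0.05
    lab[cc] <- LABEL_SCHEME[["CC"]]
    cst <- (pmin((ux - 0.42)^2, (ux - 0.58)^2) + (uy - 0.32)^2) <= 0.05^2 &
      uz >= 0.2 & uz <= 0.7
    lab[cst] <- LABEL_SCHEME[["CST"]]
  } else {
    r <- sqrt((ux - 0.5)^2 + (uy - 0.5)^2)
    theta <- atan2(uy - 0.5, ux - 0.5)  # anterior = -y, i.e. theta ~ -pi/2
    gm <- r <= 0.13
    wm <- r > 0.13 & r <= 0.30
    lab[gm] <- LABEL_SCHEME[["SC_gm"]]
    lab[gm & theta > -3 * pi / 4 & theta < -pi / 4] <-
      LABEL_SCHEME[["GM_ah"]]
    lab[wm] <- LABEL_SCHEME[["Lf"]]
    lab[wm & theta > -5 * pi / 6 & theta < -pi / 6] <- LABEL_SCHEME[["Af"]]
    lab[wm & theta > pi / 6 & theta < 5 * pi / 6] <- LABEL_SCHEME[["Pf"]]
  }

  expected <- label_scheme(config$geometry)
  expected <- unlist(expected[setdiff(names(expected), "SC_wm")])
  counts <- vapply(expected, function(code) sum(lab == code), numeric(1))
  if (any(counts < 50))
    stop("grid too small: region(s) under 50 voxels: ",
         paste(names(expected)[counts < 50], collapse = ", "))
  attr(lab, "geometry") <- config$geometry
  attr(lab, "voxel_mm") <- config$voxel_mm
  lab
}
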