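# --- orientation sampling -------------------------------------------------

# n uniform unit vectors
runif_sphere <- function(n) {
  z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
  m <- cbind(x, y, z)
  m / sqrt(rowSums(m^2))
}

# n draws from a von Mises-Fisher distribution on S^2 with mean direction
# mu (unit vector) and concentration kappa (kappa = Inf -> mu exactly).
rvmf <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(matrix(rep(mu, each = n), n, 3))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - w^2, 0))
  # tangent basis at mu
  h <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- h - sum(h * mu) * mu; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(mu[2] * t1[3] - mu[3] * t1[2],
          mu[3] * t1[1] - mu[1] * t1[3],
          mu[1] * t1[2] - mu[2] * t1[1])
  outer(w, mu) + outer(s * cos(phi), t1) + outer(s * sin(phi), t2)
}

# Vectorized tensor assembly: e1 (n x 3), eigenvalues lam (length 3),
# random spin of the (e2, e3) pair about e1. Returns n x 6 matrix
# (dxx, dyy, dzz, dxy, dxz, dyz).
tensors_from_axes <- function(e1, lam, spin = NULL) {
  n <- nrow(e1)
  # helper vector least aligned with e1, per row
  h <- matrix(0, n, 3)
  amax <- max.col(abs(e1), ties.method = "first")
  h[cbind(seq_len(n), ifelse(amax == 1L, 2L, 1L))] <- 1
  dot <- rowSums(h * e1)
  e2 <- h - dot * e1
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (is.null(spin)) spin <- stats::runif(n, 0, 2 * pi)
  c2 <- cos(spin); s2 <- sin(spin)
  e2r <- c2 * e2 + s2 * e3
  e3r <- -s2 * e2 + c2 * e3
  dxx <- lam[1] * e1[, 1]^2 + lam[2] * e2r[, 1]^2 + lam[3] * e3r[, 1]^2
  dyy <- lam[1] * e1[, 2]^2 + lam[2] * e2r[, 2]^2 + lam[3] * e3r[, 2]^2
  dzz <- lam[1] * e1[, 3]^2 + lam[2] * e2r[, 3]^2 + lam[3] * e3r[, 3]^2
  dxy <- lam[1] * e1[, 1] * e1[, 2] + lam[2] * e2r[, 1] * e2r[, 2] +
    lam[3] * e3r[, 1] * e3r[, 2]
  dxz <- lam[1] * e1[, 1] * e1[, 3] + lam[2] * e2r[, 1] * e2r[, 3] +
    lam[3] * e3r[, 1] * e3r[, 3]
  dyz <- lam[1] * e1[, 2] * e1[, 3] + lam[2] * e2r[, 2] * e2r[, 3] +
    lam[3] * e3r[, 2] * e3r[, 3]
  cbind(dxx = dxx, dyy = dyy, dzz = dzz, dxy = dxy, dxz = dxz, dyz = dyz)
}

# fixed tract axes for coherent/dispersed orientation modes
TRACT_AXES <- list(CC = c(1, 0, 0),   # left-right
                   CST = c(0, 0, 1),  # rostro-caudal
                   Af = c(0, 0, 1), Lf = c(0, 0, 1), Pf = c(0, 0, 1))

#' Paint ground-truth tensors into a label volume
#'
#' For every labeled voxel, builds a tensor whose eigenvalues are the
#' inverse-map image of the structure's target shape triple
#' (\code{\link{shape_to_eigenvalues}}) and whose principal axis follows the
#' structure's orientation model: \code{coherent} (the tract axis),
#' \code{dispersed} (von Mises-Fisher scatter about the axis with
#' concentration \code{dispersion_kappa}) or \code{random} (uniform on the
#' sphere).  Deterministic for a fixed seed.
#'
#' @param labels integer label volume from \code{\link{build_label_volume}}.
#' @param specs a \code{\link{tissue_specs}} data.frame covering every label
#'   present.
#' @param seed RNG seed.
#' @return A list with \code{tensors} (n_voxels x 6, NA rows for
#'   background), \code{e1} (n_voxels x 3 principal directions), and
#'   \code{labels}.
#' @export
paint_tensor_field <- function(labels, specs, seed = 1L) {
  labs <- as.integer(labels)
  present <- setdiff(sort(unique(labs)), 0L)
  missing <- setdiff(present, specs$label)
  if (length(missing))
    stop("no tissue spec for label(s): ", paste(missing, collapse = ", "))
  n <- length(labs)
  tens <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL,
                                 c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")))
  e1m <- matrix(NA_real_, n, 3)
  set.seed(seed)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    idx <- which(labs == sp$label)
    if (!length(idx)) next
    lam <- shape_to_eigenvalues(sp$cl, sp$cp, sp$cs, sp$trace)
    axis <- TRACT_AXES[[sp$name]]
    if (is.null(axis)) axis <- c(0, 0, 1)
    e1 <- switch(as.character(sp$orientation_mode),
                 coherent = matrix(rep(axis, each = length(idx)),
                                   length(idx), 3),
                 dispersed = rvmf(length(idx), axis, sp$dispersion_kappa),
                 random = runif_sphere(length(idx)),
                 stop("unknown orientation_mode: ", sp$orientation_mode))
    tens[idx, ] <- tensors_from_axes(e1, lam)
    e1m[idx, ] <- e1
  }
  list(tensors = tens, e1 = e1m, labels = labels)
}

# --- signal simulation ----------------------------------------------------

# quadratic forms g' D g for tensor rows (n x 6) against directions (N x 3)
quad_forms <- function(tensors, g) {
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  tensors %*% t(Q)
}

#' Simulate noiseless DWI signals from a tensor
#'
#' Mono-exponential model \code{S_i = s0 exp(-b_i g_i' D g_i)}; the b = 0
#' signal equals s0 exactly.
#'
#' @param tensor a \code{\link{diffusion_tensor}}, a length-6 vector, or an
#'   n x 6 matrix of tensor components (dxx, dyy, dzz, dxy, dxz, dyz).
#' @param protocol an \code{\link{acquisition_protocol}}.
#' @param s0 baseline amplitude; defaults to the tensor's own s0 (single
#'   tensor) or the protocol's.
#' @return A signal vector of length N (single tensor) or an n x N matrix.
#' @export
simulate_signal <- function(tensor, protocol, s0 = NULL) {
  single <- FALSE
  if (inherits(tensor, "diffusion_tensor")) {
    if (is.null(s0)) s0 <- tensor$s0
    tensor <- matrix(c(tensor$dxx, tensor$dyy, tensor$dzz,
                       tensor$dxy, tensor$dxz, tensor$dyz), 1)
    single <- TRUE
  } else if (is.null(dim(tensor))) {
    tensor <- matrix(tensor, 1)
    single <- TRUE
  }
  if (is.null(s0)) s0 <- protocol$s0
  sch <- protocol$scheme
  S <- s0 * exp(-sweep(quad_forms(tensor, sch$bvecs), 2, sch$bvals, `*`))
  if (single) drop(S) else S
}

#' Two-compartment crossing-fiber signal
#'
#' Signal from a voxel holding two fiber populations with volume fraction
#' \code{f} for the second: \code{S_i = s0 [(1-f) exp(-b g' D_a g) +
#' f exp(-b g' D_b g)]}.  A single-tensor fit of such a signal is biased
#' toward planar/spherical shape as f grows.
#'
#' @param tensor_a,tensor_b the two compartment tensors
#'   (\code{\link{diffusion_tensor}} or length-6 vectors).
#' @param f fraction of the second compartment, in [0, 1].
#' @param protocol an \code{\link{acquisition_protocol}}.
#' @param s0 baseline amplitude (default: protocol's).
#' @return A signal vector of length N.
#' @export
crossing_signal <- function(tensor_a, tensor_b, f, protocol, s0 = NULL) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("crossing fraction f must be a single value in [0, 1]")
  if (is.null(s0))
    s0 <- if (inherits(tensor_a, "diffusion_tensor")) tensor_a$s0 else
      protocol$s0
  sa <- simulate_signal(tensor_a, protocol, s0 = 1)
  sb <- simulate_signal(tensor_b, protocol, s0 = 1)
  s0 * ((1 - f) * sa + f * sb)
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI noise: \code{S_noisy = sqrt((S + n1)^2 + n2^2)} with
#' \code{n1, n2 ~ Normal(0, sigma)}, \code{sigma = s0/snr}, independent per
#' sample.  \code{snr = Inf} returns the input unchanged.  A Gaussian
#' alternative (\code{S + n1}) is available for debugging.
#'
#' @param signals numeric vector/matrix/array of signals.
#' @param snr signal-to-noise ratio s0/sigma (> 0).
#' @param s0 reference amplitude defining sigma.
#' @param seed optional RNG seed (bitwise-reproducible output).
#' @param model \code{"rician"} (default) or \code{"gaussian"}.
#' @return Noisy signals, same shape as the input.
#' @export
add_rician_noise <- function(signals, snr, s0 = 1000, seed = NULL,
                             model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (!(snr > 0)) stop("snr must be positive")
  if (!is.finite(snr)) return(signals)
  if (!is.null(seed)) set.seed(seed)
  sigma <- s0 / snr
  n <- length(signals)
  n1 <- stats::rnorm(n, 0, sigma)
  out <- if (model == "rician")
    sqrt((signals + n1)^2 + stats::rnorm(n, 0, sigma)^2)
  else signals + n1
  attributes(out) <- attributes(signals)
  out
}

#' Generate a complete synthetic DWI phantom
#'
#' End-to-end composition: build the labeled geometry, paint ground-truth
#' tensors, simulate the acquisition and add Rician noise.  Background
#' voxels get an air-like constant baseline (\code{s0_background}) so that
#' masking is exercised.
#'
#' @param config a \code{\link{phantom_config}}.
#' @param specs tissue specs (default: \code{\link{tissue_specs}} for the
#'   config's group and geometry).
#' @param protocol acquisition (default: \code{\link{acquisition_protocol}}).
#' @param s0_background baseline amplitude of unlabeled voxels.
#' @return A list of class \code{"dwi_phantom"}: \code{data} (4D array
#'   x,y,z,N), \code{labels}, \code{scheme}, \code{specs}, \code{config},
#'   \code{truth} (per-structure ground-truth table with renormalized
#'   triples and implied FA), \code{affine}.
#' @export
generate_phantom <- function(config,
                             specs = tissue_specs(config$group,
                                                  config$geometry),
                             protocol = acquisition_protocol(),
                             s0_background = 50) {
  stopifnot(inherits(config, "phantom_config"))
  labels <- build_label_volume(config)
  paint <- paint_tensor_field(labels, specs, seed_child(config$seed, 1L))
  n <- length(labels)
  N <- length(protocol$scheme$bvals)
  signals <- matrix(s0_background, n, N)
  fg <- which(!is.na(paint$tensors[, 1]))
  labs <- as.integer(labels)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    idx <- which(labs == sp$label)
    if (!length(idx)) next
    if (sp$crossing_fraction > 0) {
      lam <- shape_to_eigenvalues(sp$cl, sp$cp, sp$cs, sp$trace)
      # second population: principal axis rotated by crossing_angle
      # within a plane through the primary axis
      e1 <- paint$e1[idx, , drop = FALSE]
      ang <- sp$crossing_angle * pi / 180
      h <- matrix(0, length(idx), 3)
      amax <- max.col(abs(e1), ties.method = "first")
      h[cbind(seq_along(idx), ifelse(amax == 1L, 2L, 1L))] <- 1
      perp <- h - rowSums(h * e1) * e1
      perp <- perp / sqrt(rowSums(perp^2))
      e1b <- cos(ang) * e1 + sin(ang) * perp
      tens_b <- tensors_from_axes(e1b, lam, spin = rep(0, length(idx)))
      sa <- simulate_signal(paint$tensors[idx, , drop = FALSE], protocol,
                            s0 = 1)
      sb <- simulate_signal(tens_b, protocol, s0 = 1)
      signals[idx, ] <- protocol$s0 *
        ((1 - sp$crossing_fraction) * sa + sp$crossing_fraction * sb)
    } else {
      signals[idx, ] <- simulate_signal(paint$tensors[idx, , drop = FALSE],
                                        protocol, s0 = protocol$s0)
    }
  }
  signals <- add_rician_noise(signals, snr = config$snr, s0 = protocol$s0,
                              seed = seed_child(config$seed, 2L))
  truth <- specs[, c("label", "name", "group", "cl", "cp", "cs", "trace")]
  s <- truth$cl + truth$cp + truth$cs
  truth$cl <- truth$cl / s; truth$cp <- truth$cp / s; truth$cs <- truth$cs / s
  truth$fa <- vapply(seq_len(nrow(truth)), function(i) {
    lam <- shape_to_eigenvalues(truth$cl[i], truth$cp[i], truth$cs[i],
                                truth$trace[i])
    fractional_anisotropy(lam[1], lam[2], lam[3])
  }, numeric(1))
  vox <- config$voxel_mm
  affine <- diag(c(vox, vox, vox, 1))
  structure(list(data = array(signals, dim = c(config$dim, N)),
                 labels = labels, scheme = protocol$scheme, specs = specs,
                 config = config, truth = truth, affine = affine),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat("Synthetic DWI phantom:", x$config$geometry, "| group",
      x$config$group, "| snr", x$config$snr, "\n")
  cat("  grid:", paste(x$config$dim, collapse = " x "), "voxels at",
      x$config$voxel_mm, "mm;", dim(x$data)[4], "volumes\n")
  cat("  structures:", paste(x$specs$name, collapse = ", "), "\n")
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Writes the DWI volume and labels as compressed NIfTI, the gradient table
#' in FSL dialect, a CSV ground-truth table and a JSON manifest recording
#' the resolved configuration and seed.
#'
#' @param phantom a \code{\link{generate_phantom}} result, or a
#'   \code{\link{phantom_config}} (the phantom is then generated here).
#' @param out_dir output directory (created if needed).
#' @param ... passed to \code{\link{generate_phantom}} when \code{phantom}
#'   is a config.
#' @return Invisibly, a named character vector of the files written.
#' @export
generate_dataset <- function(phantom, out_dir, ...) {
  if (inherits(phantom, "phantom_config"))
    phantom <- generate_phantom(phantom, ...)
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- c(dwi = p("dwi.nii.gz"), labels = p("labels.nii.gz"),
             bval = p("dwi.bval"), bvec = p("dwi.bvec"),
             truth = p("truth.csv"), manifest = p("manifest.json"))
  write_dwi(phantom$data, phantom$scheme, phantom$affine,
            files["dwi"], files["bval"], files["bvec"])
  write_labels(phantom$labels, phantom$affine, files["labels"])
  utils::write.csv(phantom$truth, files["truth"], row.names = FALSE)
  manifest <- list(
    tool = "dtishape", version = as.character(utils::packageVersion("dtishape")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(phantom$config),
    protocol = list(bvals = phantom$scheme$bvals),
    specs = phantom$specs,
    files = as.list(files[1:5]))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), files["manifest"])
  invisible(files)
}
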