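#' Gradient scheme (b-values and diffusion directions)
#'
#' Bundles the diffusion weightings of an acquisition: one b-value per volume
#' (s/mm^2) and one unit direction vector per volume.  Directions for b = 0
#' volumes may be zero vectors; directions for diffusion-weighted volumes must
#' have unit Euclidean norm.
#'
#' @param bvals numeric vector of b-values in s/mm^2, length N.
#' @param bvecs N x 3 numeric matrix of gradient directions (image frame).
#' @param normalize logical; if TRUE, directions for b > 0 volumes whose norm
#'   deviates from 1 by more than 1e-6 are rescaled to unit length (with a
#'   warning when the deviation exceeds 1e-3).
#' @return An object of class \code{"gradient_scheme"}: a list with elements
#'   \code{bvals} and \code{bvecs}.
#' @examples
#' sch <- acquisition_protocol()$scheme
#' nrow(sch$bvecs)  # 21 = one b=0 plus 20 weighted directions
#' @export
gradient_scheme <- function(bvals, bvecs, normalize = TRUE) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns (x, y, z); got ", ncol(bvecs))
  if (nrow(bvecs) != length(bvals))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") lengths differ")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-finite entries in gradient table")
  if (any(bvals < 0)) stop("negative b-values")
  dw <- bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(nrm == 0))
      stop("zero direction vector with nonzero b-value")
    if (normalize && any(abs(nrm - 1) > 1e-6)) {
      if (any(abs(nrm - 1) > 1e-3))
        warning("bvec norms deviate from 1 by up to ",
                signif(max(abs(nrm - 1)), 3), "; renormalizing")
      bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm
    }
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- table(round(x$bvals))
  cat("Gradient scheme:", length(x$bvals), "volumes\n")
  for (b in names(shells))
    cat("  b =", b, "s/mm^2:", shells[[b]], "volume(s)\n")
  invisible(x)
}

# Fixed 20-point electrostatic-repulsion direction set (antipodally
# symmetric energy, optimized once and frozen so that all simulated
# datasets are reproducible). Rows are unit vectors.
DIRECTIONS20 <- local({
  m <- rbind(
    c(0.125948654845710, -0.145656110731200, 0.981285500631298),
    c(-0.346247254330905, 0.082277825497278, 0.934528329318993),
    c(0.151981543078140, 0.493170266232343, 0.856553967399549),
    c(0.583740409259719, 0.186536924323535, 0.790222190564914),
    c(0.104436591404906, -0.629020652677083, 0.770341493677591),
    c(-0.339426309013415, 0.630047286317682, 0.698448421684274),
    c(-0.672320001154571, -0.256449367347757, 0.694420289186925),
    c(0.667321080102349, -0.328499127202887, 0.668409230545162),
    c(-0.391784476821997, -0.693331910368828, 0.604810537098707),
    c(-0.769972769071635, 0.360381038914102, 0.526561906787181),
    c(0.610592827538997, 0.652564668349728, 0.448704527032593),
    c(0.059300458975148, 0.917126591810740, 0.394160208746333),
    c(0.530067758230465, -0.759482114390082, 0.377114159911954),
    c(0.931880084134055, 0.139021658703188, 0.335070868930322),
    c(-0.972487007747400, -0.039798111926301, 0.229532416119403),
    c(0.061439887804788, -0.972463406776964, 0.224811171133192),
    c(-0.517818366445992, 0.833676023373535, 0.191959442131127),
    c(-0.825503888769343, -0.547356295126185, 0.137638714802299),
    c(0.898428762215590, -0.430093436983944, 0.088574232636249),
    c(-0.435460098888226, -0.899104086386960, 0.044568420642044))
  m / sqrt(rowSums(m^2))
})

#' Shipped 20-direction set
#'
#' Returns the fixed 20-point electrostatic-repulsion direction set used by
#' the default acquisition protocol (unit vectors, antipodally optimized).
#'
#' @return A 20 x 3 numeric matrix of unit vectors.
#' @export
dti_directions20 <- function() DIRECTIONS20

#' Default single-shell acquisition protocol
#'
#' One b = 0 volume followed by 20 directions at b = 1000 s/mm^2, matching
#' a typical fixed-tissue ex vivo mouse protocol at 200 um isotropic
#' resolution, with baseline signal amplitude \code{s0}.
#'
#' @param bval b-value of the diffusion-weighted shell, s/mm^2.
#' @param directions matrix of unit direction vectors (one per row).
#' @param s0 baseline (non-diffusion-weighted) signal amplitude,
#'   arbitrary units.
#' @return A list of class \code{"acquisition_protocol"} with elements
#'   \code{scheme} (a \code{\link{gradient_scheme}}) and \code{s0}.
#' @export
acquisition_protocol <- function(bval = 1000, directions = dti_directions20(),
                                 s0 = 1000) {
  stopifnot(bval > 0, s0 > 0)
  scheme <- gradient_scheme(c(0, rep(bval, nrow(directions))),
                            rbind(c(0, 0, 0), directions))
  structure(list(scheme = scheme, s0 = s0), class = "acquisition_protocol")
}

#' Read an FSL-dialect gradient table
#'
#' \code{.bval}: one whitespace-separated row of N b-values. \code{.bvec}:
#' three whitespace-separated rows (x, y, z) of N components each, in the
#' image coordinate frame.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return A \code{\link{gradient_scheme}}.
#' @export
read_gradients <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("gradient table not found: ", p)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(strsplit(trimws(readLines(bvec_path, warn = FALSE)), "\\s+"),
                 function(r) as.numeric(r[nzchar(r)]))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3L)
    stop("bvec dialect error: expected 3 rows (x, y, z), got ", length(rows))
  n <- unique(vapply(rows, length, 1L))
  if (length(n) != 1L)
    stop("bvec rows have unequal lengths: ",
         paste(vapply(rows, length, 1L), collapse = ", "))
  if (n != length(bvals))
    stop("count mismatch: ", length(bvals), " b-values vs ", n, " directions")
  gradient_scheme(bvals, cbind(rows[[1]], rows[[2]], rows[[3]]))
}

#' Write an FSL-dialect gradient table
#'
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradients <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Design matrix for log-linear tensor estimation
#'
#' Row i is \code{[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz,
#' -2b gy gz]}, so that \code{log(S) = row \%*\% c(log(s0), dxx, dyy, dzz,
#' dxy, dxz, dyz)} under the mono-exponential tensor model.
#'
#' @param scheme a \code{\link{gradient_scheme}} (or list with \code{bvals},
#'   \code{bvecs}).
#' @return An N x 7 matrix with columns \code{log_s0, dxx, dyy, dzz, dxy,
#'   dxz, dyz}.
#' @export
build_design_matrix <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  X <- cbind(1,
             -b * g[, 1]^2,
             -b * g[, 2]^2,
             -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  colnames(X) <- c("log_s0", "dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  qrX <- qr(X)
  if (qrX$rank < 7L) {
    deficient <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("gradient scheme is not well posed: design matrix rank ", qrX$rank,
         " < 7; unresolved columns: ", paste(deficient, collapse = ", "))
  }
  X
}
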