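#' Diffusion tensor object
#'
#' A symmetric 3x3 apparent diffusion tensor plus the baseline signal
#' amplitude it was estimated with.
#'
#' @param dxx,dyy,dzz,dxy,dxz,dyz tensor components, mm^2/s.
#' @param s0 non-diffusion-weighted signal amplitude (> 0, arbitrary units).
#' @return An object of class \code{"diffusion_tensor"}.
#' @export
diffusion_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0,
                             s0 = 1) {
  vals <- c(dxx = dxx, dyy = dyy, dzz = dzz, dxy = dxy, dxz = dxz, dyz = dyz)
  if (any(!is.finite(vals))) stop("non-finite tensor components")
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  structure(c(as.list(vals), list(s0 = s0)), class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("Diffusion tensor (mm^2/s), s0 =", format(x$s0), "\n")
  print(tensor_matrix(x))
  invisible(x)
}

#' 3x3 matrix form of a diffusion tensor
#'
#' @param tensor a \code{\link{diffusion_tensor}} or a numeric vector with
#'   named components dxx, dyy, dzz, dxy, dxz, dyz.
#' @return A symmetric 3x3 matrix.
#' @export
tensor_matrix <- function(tensor) {
  matrix(c(tensor$dxx, tensor$dxy, tensor$dxz,
           tensor$dxy, tensor$dyy, tensor$dyz,
           tensor$dxz, tensor$dyz, tensor$dzz), 3, 3)
}

#' Eigendecomposition of a diffusion tensor
#'
#' Diagonalizes the tensor, sorts eigenvalues in descending order
#' (lambda1 >= lambda2 >= lambda3) and fixes each eigenvector's sign so its
#' largest-magnitude component is positive (for reproducible stored maps).
#' Negative eigenvalues (which arise under noise) are clamped to zero when
#' \code{clamp = TRUE}, with the clamp recorded.
#'
#' @param tensor a \code{\link{diffusion_tensor}} or symmetric 3x3 matrix.
#' @param clamp clamp negative eigenvalues to zero (default TRUE).
#' @return A list of class \code{"eigen_system"} with \code{lambda} (length-3,
#'   descending), \code{vectors} (3x3, columns e1, e2, e3), and
#'   \code{clamped} (logical).
#' @export
eigendecompose <- function(tensor, clamp = TRUE) {
  M <- if (is.matrix(tensor)) tensor else tensor_matrix(tensor)
  if (any(!is.finite(M))) stop("non-finite tensor input")
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)  # descending by default
  V <- es$vectors
  for (j in 1:3) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  lam <- es$values
  clamped <- FALSE
  if (clamp && any(lam < 0)) {
    lam <- pmax(lam, 0)
    clamped <- TRUE
  }
  structure(list(lambda = lam, vectors = V, clamped = clamped),
            class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat("Eigenvalues (mm^2/s):", paste(signif(x$lambda, 5), collapse = ", "),
      if (x$clamped) "[clamped]" else "", "\n")
  invisible(x)
}

# Vectorized analytical eigenvalues of many symmetric 3x3 tensors.
# `tens` is an n x 6 matrix with columns dxx, dyy, dzz, dxy, dxz, dyz.
# Returns an n x 3 matrix of eigenvalues sorted descending. Uses the
# trigonometric closed form for symmetric 3x3 matrices; the isotropic
# branch (p == 0) is handled explicitly.
eigenvalues3 <- function(tens) {
  tens <- matrix(as.numeric(tens), ncol = 6)
  dxx <- tens[, 1]; dyy <- tens[, 2]; dzz <- tens[, 3]
  dxy <- tens[, 4]; dxz <- tens[, 5]; dyz <- tens[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  axx <- dxx - q; ayy <- dyy - q; azz <- dzz - q
  detB <- axx * (ayy * azz - dyz^2) -
    dxy * (dxy * azz - dyz * dxz) +
    dxz * (dxy * dyz - ayy * dxz)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  iso <- !(p > 0)
  if (any(iso, na.rm = TRUE)) {
    l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  }
  cbind(lambda1 = l1, lambda2 = l2, lambda3 = l3)
}
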