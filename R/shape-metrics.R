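#' Fractional anisotropy
#'
#' \deqn{FA = \sqrt{\tfrac12 \,
#'   \frac{(\lambda_1-\lambda_2)^2 + (\lambda_1-\lambda_3)^2 +
#'         (\lambda_2-\lambda_3)^2}
#'        {\lambda_1^2 + \lambda_2^2 + \lambda_3^2}}}
#'
#' FA is 0 for an isotropic tensor and 1 in the stick limit
#' (lambda2 = lambda3 = 0).  The all-zero triple is degenerate; it returns
#' FA = 0 with attribute \code{degenerate = TRUE} (scalar input) or NaN-free
#' 0 entries (vector input).
#'
#' @param lambda1,lambda2,lambda3 eigenvalues (vectors of equal length), or a
#'   single \code{eigen_system} passed as \code{lambda1}.
#' @return Numeric vector of FA values in [0, 1].
#' @examples
#' fractional_anisotropy(1, 1, 1)  # 0
#' fractional_anisotropy(1, 0, 0)  # 1
#' @export
fractional_anisotropy <- function(lambda1, lambda2 = NULL, lambda3 = NULL) {
  if (inherits(lambda1, "eigen_system")) {
    lam <- lambda1$lambda
    lambda1 <- lam[1]; lambda2 <- lam[2]; lambda3 <- lam[3]
  }
  num <- (lambda1 - lambda2)^2 + (lambda1 - lambda3)^2 +
    (lambda2 - lambda3)^2
  den <- lambda1^2 + lambda2^2 + lambda3^2
  degenerate <- den <= 0
  fa <- ifelse(degenerate, 0, sqrt(0.5 * num / pmax(den, .Machine$double.xmin)))
  fa <- pmin(pmax(fa, 0), 1)
  if (length(fa) == 1L && degenerate[1]) attr(fa, "degenerate") <- TRUE
  fa
}

#' Westin shape metrics (linear, planar, spherical anisotropy)
#'
#' Decomposes tensor shape into barycentric coordinates
#' \deqn{C_L = (\lambda_1 - \lambda_2)/\mathrm{trace}, \quad
#'       C_P = 2(\lambda_2 - \lambda_3)/\mathrm{trace}, \quad
#'       C_S = 3\lambda_3/\mathrm{trace}}
#' with trace = lambda1 + lambda2 + lambda3, so that CL + CP + CS = 1 for
#' any ordered non-negative triple with positive trace.  Voxels with
#' non-positive trace are degenerate: all metrics are returned as NaN
#' (the sentinel excluded from ROI means).
#'
#' @inheritParams fractional_anisotropy
#' @return A data.frame with columns \code{cl}, \code{cp}, \code{cs},
#'   \code{fa}, \code{trace}, \code{md}.
#' @examples
#' westin_metrics(0.5, 0.3, 0.2)  # cl = 0.2, cp = 0.2, cs = 0.6
#' @export
westin_metrics <- function(lambda1, lambda2 = NULL, lambda3 = NULL) {
  if (inherits(lambda1, "eigen_system")) {
    lam <- lambda1$lambda
    lambda1 <- lam[1]; lambda2 <- lam[2]; lambda3 <- lam[3]
  }
  tr <- lambda1 + lambda2 + lambda3
  ok <- is.finite(tr) & tr > 0
  trs <- ifelse(ok, tr, NA_real_)
  cl <- (lambda1 - lambda2) / trs
  cp <- 2 * (lambda2 - lambda3) / trs
  cs <- 3 * lambda3 / trs
  cl[!ok] <- NaN; cp[!ok] <- NaN; cs[!ok] <- NaN
  fa <- fractional_anisotropy(lambda1, lambda2, lambda3)
  fa[!ok & !(lambda1 == 0 & lambda2 == 0 & lambda3 == 0)] <- NaN
  data.frame(cl = as.numeric(cl), cp = as.numeric(cp), cs = as.numeric(cs),
             fa = as.numeric(fa), trace = as.numeric(tr),
             md = as.numeric(tr) / 3)
}

#' Eigenvalues from a Westin shape triple (inverse map)
#'
#' Inverts the Westin decomposition: given (CL, CP, CS) and a trace, returns
#' the unique ordered eigenvalue triple with those shape metrics.  Triples
#' whose sum deviates from 1 by at most \code{tol} (printed tables are
#' rounded) are renormalized by dividing by their sum; larger deviations
#' are an error.
#'
#' @param cl,cp,cs shape triple, each >= 0.
#' @param trace eigenvalue sum, mm^2/s (> 0).
#' @param tol admissible deviation of cl+cp+cs from 1 before renormalizing.
#' @return Numeric length-3 vector \code{c(lambda1, lambda2, lambda3)}.
#' @examples
#' shape_to_eigenvalues(0.41, 0.15, 0.44, trace = 1)
#' @export
shape_to_eigenvalues <- function(cl, cp, cs, trace = 1.5e-3, tol = 0.02) {
  if (any(c(cl, cp, cs) < 0)) stop("shape metrics must be non-negative")
  if (trace <= 0) stop("trace must be positive")
  s <- cl + cp + cs
  if (abs(s - 1) > tol)
    stop("inconsistent shape triple: cl+cp+cs = ", format(s),
         " deviates from 1 by more than ", tol)
  cl <- cl / s; cp <- cp / s; cs <- cs / s
  l3 <- cs * trace / 3
  l2 <- l3 + cp * trace / 2
  l1 <- cl * trace + l2
  c(lambda1 = l1, lambda2 = l2, lambda3 = l3)
}

# Corner convention for the shape triangle: linear bottom-left (0,0),
# planar bottom-right (1,0), spherical apex (1/2, sqrt(3)/2).
TRIANGLE_CORNERS <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2,
                           byrow = TRUE,
                           dimnames = list(c("linear", "planar", "spherical"),
                                           c("x", "y")))

#' Barycentric shape-triangle coordinates
#'
#' Embeds a (CL, CP, CS) triple in the 2-simplex used for tensor shape-space
#' plots: the linear corner at bottom-left (0, 0), planar at bottom-right
#' (1, 0), spherical at the apex (1/2, sqrt(3)/2).  The map is affine and
#' invertible on the simplex (see \code{\link{triangle_to_shape}}).
#'
#' @param cl,cp,cs shape metrics (vectors of equal length).  A data.frame
#'   with columns \code{cl}, \code{cp}, \code{cs} may be passed as \code{cl}.
#' @return A data.frame with columns \code{x}, \code{y}.
#' @export
shape_triangle_coords <- function(cl, cp = NULL, cs = NULL) {
  if (is.data.frame(cl)) { cp <- cl$cp; cs <- cl$cs; cl <- cl$cl }
  x <- cl * TRIANGLE_CORNERS[1, 1] + cp * TRIANGLE_CORNERS[2, 1] +
    cs * TRIANGLE_CORNERS[3, 1]
  y <- cl * TRIANGLE_CORNERS[1, 2] + cp * TRIANGLE_CORNERS[2, 2] +
    cs * TRIANGLE_CORNERS[3, 2]
  data.frame(x = x, y = y)
}

#' Invert shape-triangle coordinates
#'
#' @param x,y plot coordinates from \code{\link{shape_triangle_coords}}.
#' @return A data.frame with columns \code{cl}, \code{cp}, \code{cs}.
#' @export
triangle_to_shape <- function(x, y) {
  cs <- y / TRIANGLE_CORNERS[3, 2]
  cp <- x - cs * TRIANGLE_CORNERS[3, 1]
  cl <- 1 - cp - cs
  data.frame(cl = cl, cp = cp, cs = cs)
}
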