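#' Fit diffusion tensors by log-linear least squares
#'
#' The central model fit: per voxel, the mono-exponential signal model
#' \deqn{S_i = S_0 \exp(-b_i\, g_i^T D\, g_i)}
#' is linearized by taking logs and solved by ordinary least squares against
#' the 7-column design of \code{\link{build_design_matrix}} (weighted least
#' squares, with squared-signal weights, is available via
#' \code{method = "wls"}).  Non-positive signals are clamped to
#' \code{floor_frac * s0} before the log; the number of clamped samples is
#' recorded per voxel.  Voxels whose signals are all non-positive are masked
#' out (all-NA coefficients, flagged in \code{masked}).
#'
#' @param dwi diffusion-weighted data: a voxels x N numeric matrix, a 4D
#'   array (x, y, z, N), or a \code{\link{read_dwi}} dataset (in which case
#'   \code{scheme} is taken from it).
#' @param scheme a \code{\link{gradient_scheme}}; ignored when \code{dwi}
#'   carries its own.
#' @param mask optional logical vector/array selecting voxels to fit.
#' @param method \code{"ols"} (default) or \code{"wls"}.
#' @param floor_frac positive-signal floor as a fraction of the per-voxel
#'   b = 0 estimate.
#' @param keep_data keep the input signals on the object (needed by
#'   \code{residuals}).
#' @return An object of class \code{"dti_fit"} with elements
#'   \code{coefficients} (voxels x 7: log_s0 and the six tensor components),
#'   \code{tensors} (voxels x 6), \code{s0}, \code{n_clamped} (clamped
#'   samples per voxel), \code{masked}, \code{scheme}, \code{dim} (spatial
#'   grid, or NULL for matrix input), and \code{affine} (if known).
#' @examples
#' prot <- acquisition_protocol()
#' D <- diffusion_tensor(1.7e-3, 3e-4, 3e-4, s0 = 1000)
#' sig <- simulate_signal(D, prot)
#' fit <- dti_fit(matrix(sig, nrow = 1), prot$scheme)
#' coef(fit)
#' @export
dti_fit <- function(dwi, scheme = NULL, mask = NULL,
                    method = c("ols", "wls"), floor_frac = 1e-6,
                    keep_data = TRUE) {
  method <- match.arg(method)
  affine <- NULL
  if (inherits(dwi, "dwi_dataset")) {
    scheme <- dwi$scheme
    affine <- dwi$affine
    if (is.null(mask)) mask <- dwi$mask
    dwi <- dwi$data
  }
  if (is.null(scheme)) stop("a gradient scheme is required")
  spatial_dim <- NULL
  if (is.array(dwi) && length(dim(dwi)) == 4L) {
    spatial_dim <- dim(dwi)[1:3]
    dwi <- matrix(dwi, nrow = prod(spatial_dim))
  } else {
    dwi <- as.matrix(dwi)
  }
  N <- length(scheme$bvals)
  if (ncol(dwi) != N)
    stop("signal count (", ncol(dwi), ") does not match gradient table (",
         N, ")")
  if (N < 7L) stop("underdetermined: ", N, " measurements < 7 unknowns")
  X <- build_design_matrix(scheme)
  n <- nrow(dwi)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != n) stop("mask length does not match voxel count")
  } else {
    mask <- rep(TRUE, n)
  }

  # per-voxel s0 estimate from b=0 volumes (fallback: max signal)
  b0 <- scheme$bvals == 0
  s0_est <- if (any(b0)) rowMeans(dwi[, b0, drop = FALSE]) else
    apply(dwi, 1, max)
  s0_est[!(s0_est > 0)] <- apply(dwi[!(s0_est > 0), , drop = FALSE], 1, max)

  dead <- !(s0_est > 0)                       # every signal non-positive
  fit_idx <- which(mask & !dead)
  coefs <- matrix(NA_real_, n, 7,
                  dimnames = list(NULL, colnames(X)))
  n_clamped <- rep(NA_integer_, n)

  if (length(fit_idx)) {
    S <- dwi[fit_idx, , drop = FALSE]
    floorv <- floor_frac * s0_est[fit_idx]
    Fm <- matrix(floorv, nrow = length(fit_idx), ncol = N)
    n_clamped[fit_idx] <- as.integer(rowSums(S < Fm))
    Y <- log(pmax(S, Fm))
    if (method == "ols") {
      XtXi <- solve(crossprod(X))
      coefs[fit_idx, ] <- Y %*% X %*% XtXi
    } else {
      W <- pmax(S, Fm)^2                      # squared-signal weights
      for (k in seq_along(fit_idx)) {
        w <- W[k, ]
        Xw <- X * w
        coefs[fit_idx[k], ] <- solve(crossprod(X, Xw), crossprod(Xw, Y[k, ]))
      }
    }
  }

  structure(list(
    coefficients = coefs,
    tensors = coefs[, 2:7, drop = FALSE],
    s0 = as.vector(exp(coefs[, 1])),
    n_clamped = n_clamped,
    masked = !mask | dead,
    scheme = scheme,
    method = method,
    dim = spatial_dim,
    affine = affine,
    data = if (keep_data) dwi else NULL
  ), class = "dti_fit")
}

#' Fit a single voxel's diffusion tensor
#'
#' Convenience wrapper around \code{\link{dti_fit}} for one signal vector.
#'
#' @param signals numeric vector of length N.
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param ... passed to \code{\link{dti_fit}}.
#' @return A \code{\link{diffusion_tensor}} with attribute \code{n_clamped},
#'   or a \code{"masked_voxel"} sentinel if every signal is non-positive.
#' @export
fit_tensor <- function(signals, scheme, ...) {
  fit <- dti_fit(matrix(signals, nrow = 1), scheme, keep_data = FALSE, ...)
  if (fit$masked[1])
    return(structure(list(reason = "all signals non-positive"),
                     class = "masked_voxel"))
  tv <- fit$tensors[1, ]
  out <- diffusion_tensor(tv["dxx"], tv["dyy"], tv["dzz"],
                          tv["dxy"], tv["dxz"], tv["dyz"], s0 = fit$s0[1])
  attr(out, "n_clamped") <- fit$n_clamped[1]
  out
}

#' Test for the masked-voxel sentinel
#' @param x object returned by \code{\link{fit_tensor}}.
#' @return TRUE for a masked voxel.
#' @export
is_masked_voxel <- function(x) inherits(x, "masked_voxel")

#' @export
coef.dti_fit <- function(object, ...) object$coefficients

#' @export
print.dti_fit <- function(x, ...) {
  nfit <- sum(!x$masked)
  cat("Log-linear diffusion tensor fit (", x$method, ")\n", sep = "")
  if (!is.null(x$dim))
    cat("  grid: ", paste(x$dim, collapse = " x "), "\n", sep = "")
  cat("  voxels fit: ", nfit, " of ", length(x$masked),
      " (", sum(x$masked), " masked)\n", sep = "")
  cat("  measurements per voxel: ", length(x$scheme$bvals), "\n", sep = "")
  ncl <- sum(x$n_clamped, na.rm = TRUE)
  if (is.finite(ncl) && ncl > 0)
    cat("  clamped log-signals: ", ncl, "\n", sep = "")
  invisible(x)
}

#' Per-voxel shape metrics of a tensor fit
#'
#' Computes eigenvalues of every fitted tensor (analytical symmetric 3x3
#' closed form), clamps negative eigenvalues to zero, and evaluates FA and
#' the Westin metrics.
#'
#' @param fit a \code{\link{dti_fit}}.
#' @param clamp clamp negative eigenvalues before computing metrics.
#' @return A data.frame with one row per voxel: \code{fa}, \code{cl},
#'   \code{cp}, \code{cs}, \code{trace}, \code{md}, \code{lambda1..3},
#'   \code{eig_clamped} (logical), masked voxels as NaN rows.
#' @export
shape_metrics <- function(fit, clamp = TRUE) {
  stopifnot(inherits(fit, "dti_fit"))
  lam <- eigenvalues3(fit$tensors)
  eig_clamped <- rowSums(lam < 0) > 0
  if (clamp) lam <- pmax(lam, 0)
  m <- westin_metrics(lam[, 1], lam[, 2], lam[, 3])
  m$lambda1 <- lam[, 1]; m$lambda2 <- lam[, 2]; m$lambda3 <- lam[, 3]
  m$eig_clamped <- eig_clamped
  m[fit$masked, ] <- NaN
  m$eig_clamped <- as.logical(m$eig_clamped)
  m[, c("fa", "cl", "cp", "cs", "trace", "md",
        "lambda1", "lambda2", "lambda3", "eig_clamped")]
}

#' Metric maps on the acquisition grid
#'
#' Reshapes per-voxel metrics back onto the 3D grid (only for fits made from
#' 4D input).
#'
#' @param fit a \code{\link{dti_fit}} with a spatial grid.
#' @param metrics which metrics to return.
#' @return A named list of 3D arrays, invalid voxels as NaN.
#' @export
metric_maps <- function(fit, metrics = c("fa", "cl", "cp", "cs", "md")) {
  if (is.null(fit$dim)) stop("fit has no spatial grid (matrix input)")
  sm <- shape_metrics(fit)
  out <- lapply(metrics, function(m) array(sm[[m]], dim = fit$dim))
  names(out) <- metrics
  out
}

#' @export
summary.dti_fit <- function(object, ...) {
  sm <- shape_metrics(object)
  ok <- !object$masked & is.finite(sm$fa)
  stats <- vapply(c("fa", "cl", "cp", "cs", "md"), function(m)
    c(mean = mean(sm[[m]][ok]), sd = stats::sd(sm[[m]][ok])), numeric(2))
  out <- list(n_voxels = length(object$masked), n_fit = sum(!object$masked),
              n_degenerate = sum(!ok & !object$masked),
              n_eig_clamped = sum(sm$eig_clamped, na.rm = TRUE),
              n_clamped_signals = sum(object$n_clamped, na.rm = TRUE),
              metric_stats = t(stats), method = object$method)
  class(out) <- "summary.dti_fit"
  out
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat("Diffusion tensor fit summary (", x$method, ")\n", sep = "")
  cat("  voxels fit:", x$n_fit, "of", x$n_voxels,
      "| degenerate:", x$n_degenerate,
      "| eigenvalue-clamped:", x$n_eig_clamped,
      "| clamped log-signals:", x$n_clamped_signals, "\n")
  print(round(x$metric_stats, 4))
  invisible(x)
}

#' @export
fitted.dti_fit <- function(object, ...) {
  X <- build_design_matrix(object$scheme)
  exp(object$coefficients %*% t(X))
}

#' Predicted signals from a tensor fit
#'
#' @param object a \code{\link{dti_fit}}.
#' @param scheme optionally, a different \code{\link{gradient_scheme}} to
#'   predict signals for.
#' @param ... unused.
#' @return voxels x N matrix of model signals.
#' @export
predict.dti_fit <- function(object, scheme = NULL, ...) {
  if (is.null(scheme)) return(fitted(object))
  X <- build_design_matrix(scheme)
  exp(object$coefficients %*% t(X))
}

#' @export
residuals.dti_fit <- function(object, type = c("signal", "log"), ...) {
  if (is.null(object$data))
    stop("fit was made with keep_data = FALSE; no residuals available")
  type <- match.arg(type)
  pred <- fitted(object)
  if (type == "signal") object$data - pred else
    log(pmax(object$data, .Machine$double.xmin)) - log(pred)
}

#' Simulate signals from a fitted tensor field
#'
#' Draws Rician-noise replicates of the model-predicted signals, one matrix
#' per simulation.
#'
#' @param object a \code{\link{dti_fit}}.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param snr signal-to-noise ratio s0/sigma; \code{Inf} for noiseless.
#' @param ... unused.
#' @return A list of voxels x N signal matrices.
#' @export
simulate.dti_fit <- function(object, nsim = 1, seed = NULL, snr = Inf, ...) {
  pred <- fitted(object)
  s0_ref <- stats::median(object$s0, na.rm = TRUE)
  lapply(seq_len(nsim), function(i) {
    add_rician_noise(pred, snr = snr, s0 = s0_ref,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
}

#' Shape-triangle plot of a tensor fit
#'
#' Scatters per-voxel (CL, CP, CS) triples in the barycentric shape triangle
#' (linear bottom-left, planar bottom-right, spherical apex).
#'
#' @param x a \code{\link{dti_fit}}.
#' @param max_points subsample cap for dense maps.
#' @param ... passed to \code{points()}.
#' @return Invisibly, the plotted coordinates.
#' @export
plot.dti_fit <- function(x, max_points = 2000, ...) {
  sm <- shape_metrics(x)
  ok <- which(is.finite(sm$cl))
  if (length(ok) > max_points) ok <- sample(ok, max_points)
  co <- shape_triangle_coords(sm[ok, ])
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 0.95),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = "Tensor shape space")
  tri <- rbind(TRIANGLE_CORNERS, TRIANGLE_CORNERS[1, ])
  graphics::lines(tri[, 1], tri[, 2])
  graphics::text(TRIANGLE_CORNERS[, 1], TRIANGLE_CORNERS[, 2],
                 labels = c("CL", "CP", "CS"),
                 pos = c(1, 1, 3), offset = 0.4)
  graphics::points(co$x, co$y, ...)
  invisible(co)
}
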