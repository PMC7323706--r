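# shared fixtures for the test suite

`%||%` <- function(a, b) if (is.null(a)) b else a

default_protocol <- function(s0 = 1000) acquisition_protocol(s0 = s0)

# random positive-definite diffusion tensor (mm^2/s scale typical of
# fixed tissue), as a length-6 component vector
random_pd_tensor <- function() {
  lam <- sort(stats::runif(3, 1e-4, 2e-3), decreasing = TRUE)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  M <- Q %*% diag(lam) %*% t(Q)
  c(dxx = M[1, 1], dyy = M[2, 2], dzz = M[3, 3],
    dxy = M[1, 2], dxz = M[1, 3], dyz = M[2, 3])
}

# independent oracle for the log-linear fit: Moore-Penrose pseudoinverse
# applied to log signals (no shared code with dti_fit's solve path)
pinv_fit <- function(signals, scheme) {
  X <- build_design_matrix(scheme)
  sv <- svd(X)
  pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  drop(pinv %*% log(signals))
}

# uniform random rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_tensor6 <- function(tens6, R) {
  M <- matrix(c(tens6[1], tens6[4], tens6[5],
                tens6[4], tens6[2], tens6[6],
                tens6[5], tens6[6], tens6[3]), 3, 3)
  M2 <- R %*% M %*% t(R)
  c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
}

# generate -> fit -> per-voxel metrics for one phantom, returning per-ROI
# means of fa/cl/cp/cs
phantom_roi_metrics <- function(config, protocol = acquisition_protocol()) {
  ph <- generate_phantom(config, protocol = protocol)
  b0 <- ph$data[, , , 1]
  mask <- as.vector(b0 > 0.1 * stats::quantile(b0, 0.99, names = FALSE))
  fit <- dti_fit(ph$data, ph$scheme, mask = mask, keep_data = FALSE)
  sm <- shape_metrics(fit)
  sch <- label_scheme(config$geometry)
  rows <- lapply(names(sch), function(nm) {
    v <- vapply(c("fa", "cl", "cp", "cs"), function(m)
      roi_means(sm[[m]], ph$labels, sch[[nm]])$mean, numeric(1))
    data.frame(structure = nm, fa = v[1], cl = v[2], cp = v[3], cs = v[4])
  })
  list(roi = do.call(rbind, rows), truth = ph$truth, phantom = ph)
}
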