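test_that("FA limit cases and the hand-evaluated reference triple", {
  expect_identical(fractional_anisotropy(1, 1, 1), 0)
  expect_identical(fractional_anisotropy(1, 0, 0), 1)
  expect_identical(fractional_anisotropy(2.5, 2.5, 2.5), 0)
  # independent hand evaluation of the FA formula for the eigenvalue triple
  # implied by a (0.41, 0.15, 0.44) shape with unit trace:
  lam <- c(0.63167, 0.22167, 0.14667)
  hand <- sqrt(0.5 * ((lam[1] - lam[2])^2 + (lam[1] - lam[3])^2 +
                        (lam[2] - lam[3])^2) / sum(lam^2))
  expect_equal(fractional_anisotropy(lam[1], lam[2], lam[3]), hand,
               tolerance = 1e-12)
  expect_equal(hand, 0.660, tolerance = 1e-3)
  # degenerate all-zero triple: FA defined as 0 with a flag
  fa0 <- fractional_anisotropy(0, 0, 0)
  expect_equal(as.numeric(fa0), 0)
  expect_true(isTRUE(attr(fa0, "degenerate")))
})

test_that("Westin metrics match direct arithmetic and flag degenerate voxels", {
  expect_equal(unlist(westin_metrics(1, 0, 0)[1, c("cl", "cp", "cs")]),
               c(cl = 1, cp = 0, cs = 0))
  expect_equal(unlist(westin_metrics(1, 1, 1)[1, c("cl", "cp", "cs")]),
               c(cl = 0, cp = 0, cs = 1))
  m <- westin_metrics(0.5, 0.3, 0.2)
  expect_equal(c(m$cl, m$cp, m$cs), c(0.2, 0.2, 0.6), tolerance = 1e-15)
  expect_equal(m$trace, 1)
  expect_equal(m$md, 1 / 3)
  # non-positive trace -> NaN sentinels
  bad <- westin_metrics(0, 0, 0)
  expect_true(all(is.nan(c(bad$cl, bad$cp, bad$cs))))
})

test_that("cl + cp + cs = 1 on random non-negative triples", {
  set.seed(12)
  lam <- matrix(stats::runif(3e4, 0, 2e-3), ncol = 3)
  lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  m <- westin_metrics(lam[, 1], lam[, 2], lam[, 3])
  expect_lt(max(abs(m$cl + m$cp + m$cs - 1)), 1e-12)
  expect_true(all(m$cl >= 0 & m$cl <= 1 & m$cp >= 0 & m$cp <= 1 &
                    m$cs >= 0 & m$cs <= 1))
  expect_true(all(m$fa >= 0 & m$fa <= 1))
})

test_that("shape_to_eigenvalues inverts the Westin map (both directions)", {
  expect_equal(unname(shape_to_eigenvalues(0, 0, 1, trace = 3)), c(1, 1, 1))
  expect_equal(unname(shape_to_eigenvalues(1, 0, 0, trace = 1)), c(1, 0, 0))
  lam <- shape_to_eigenvalues(0.41, 0.15, 0.44, trace = 1)
  expect_equal(unname(lam), c(0.63167, 0.22167, 0.14667), tolerance = 1e-5)
  set.seed(33)
  for (i in 1:50) {
    tri <- stats::runif(3); tri <- tri / sum(tri)
    tr <- stats::runif(1, 0.5e-3, 3e-3)
    lam <- shape_to_eigenvalues(tri[1], tri[2], tri[3], tr)
    expect_equal(sum(lam), tr, tolerance = 1e-12 * tr)
    m <- westin_metrics(lam[1], lam[2], lam[3])
    expect_equal(c(m$cl, m$cp, m$cs), tri, tolerance = 1e-12)
    # and the other direction: eigenvalues -> shape -> eigenvalues
    lam2 <- shape_to_eigenvalues(m$cl, m$cp, m$cs, tr)
    expect_equal(lam2, lam, tolerance = 1e-12)
  }
})

test_that("rounded printed triples are renormalized; bad triples rejected", {
  lam <- shape_to_eigenvalues(0.08, 0.14, 0.79, trace = 1)  # sums to 1.01
  expect_equal(sum(lam), 1, tolerance = 1e-12)
  m <- westin_metrics(lam[1], lam[2], lam[3])
  expect_equal(m$cl, 0.08 / 1.01, tolerance = 1e-12)
  expect_error(shape_to_eigenvalues(0.5, 0.5, 0.1, trace = 1),
               "inconsistent")
  expect_error(shape_to_eigenvalues(-0.1, 0.5, 0.6, trace = 1),
               "non-negative")
  expect_error(shape_to_eigenvalues(0.2, 0.2, 0.6, trace = 0), "trace")
})

test_that("fa and Westin metrics are rotation and scale invariant", {
  set.seed(21)
  for (i in 1:25) {
    tens <- random_pd_tensor()
    lam <- drop(dtishape:::eigenvalues3(matrix(tens, 1)))
    m0 <- westin_metrics(lam[1], lam[2], lam[3])
    rot <- rotate_tensor6(tens, random_rotation())
    lam_r <- drop(dtishape:::eigenvalues3(matrix(rot, 1)))
    m1 <- westin_metrics(lam_r[1], lam_r[2], lam_r[3])
    expect_equal(unlist(m1[c("cl", "cp", "cs", "fa")]),
                 unlist(m0[c("cl", "cp", "cs", "fa")]), tolerance = 1e-10)
    c_scale <- stats::runif(1, 0.1, 10)
    m2 <- westin_metrics(c_scale * lam[1], c_scale * lam[2],
                         c_scale * lam[3])
    expect_equal(unlist(m2[c("cl", "cp", "cs", "fa")]),
                 unlist(m0[c("cl", "cp", "cs", "fa")]), tolerance = 1e-10)
  }
})

test_that("FA increases monotonically in lambda1 with lambda2 = lambda3", {
  l1 <- seq(1, 5, by = 0.1)
  fa <- fractional_anisotropy(l1, rep(1, length(l1)), rep(1, length(l1)))
  expect_true(all(diff(fa) > 0))
})

test_that("eigendecompose sorts, reconstructs, and is rotation-consistent", {
  es <- eigendecompose(diag(c(3, 2, 1)))
  expect_equal(es$lambda, c(3, 2, 1))
  es_iso <- eigendecompose(diag(3) * 0.7)
  expect_equal(es_iso$lambda, rep(0.7, 3))
  expect_equal(crossprod(es_iso$vectors), diag(3), tolerance = 1e-8)
  # rotating diag(1.7, 0.3, 0.3)e-3 by 45 deg about z leaves eigenvalues
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  D0 <- diag(c(1.7e-3, 3e-4, 3e-4))
  es_r <- eigendecompose(R %*% D0 %*% t(R))
  expect_equal(es_r$lambda, c(1.7e-3, 3e-4, 3e-4), tolerance = 1e-12)
  # reconstruction and eigenvector sign convention
  set.seed(8)
  for (i in 1:20) {
    tens <- random_pd_tensor()
    M <- matrix(c(tens[1], tens[4], tens[5], tens[4], tens[2], tens[6],
                  tens[5], tens[6], tens[3]), 3, 3)
    es <- eigendecompose(M)
    expect_equal(es$vectors %*% diag(es$lambda) %*% t(es$vectors), M,
                 tolerance = 1e-10 * max(abs(M)))
    expect_true(all(diff(es$lambda) <= 1e-15))
    signs <- vapply(1:3, function(j)
      es$vectors[which.max(abs(es$vectors[, j])), j] > 0, logical(1))
    expect_true(all(signs))
  }
  # negative eigenvalues clamp with a flag
  es_neg <- eigendecompose(diag(c(1, 0.5, -0.1)))
  expect_true(es_neg$clamped)
  expect_equal(es_neg$lambda, c(1, 0.5, 0))
  expect_error(eigendecompose(diag(c(NaN, 1, 1))), "non-finite")
})

test_that("vectorized analytical eigenvalues match eigen()", {
  set.seed(99)
  tens <- t(replicate(300, random_pd_tensor()))
  # include some indefinite and degenerate tensors
  tens <- rbind(tens, c(1, 1, 1, 0, 0, 0), c(1, 0.5, -0.2, 0.1, 0, 0.05),
                c(0, 0, 0, 0, 0, 0))
  lam <- dtishape:::eigenvalues3(tens)
  for (i in seq_len(nrow(tens))) {
    M <- matrix(c(tens[i, 1], tens[i, 4], tens[i, 5],
                  tens[i, 4], tens[i, 2], tens[i, 6],
                  tens[i, 5], tens[i, 6], tens[i, 3]), 3, 3)
    expect_equal(unname(lam[i, ]), eigen(M, symmetric = TRUE,
                                         only.values = TRUE)$values,
                 tolerance = 1e-9)
  }
})

test_that("shape-triangle embedding hits the corners and inverts", {
  co <- shape_triangle_coords(c(1, 0, 1 / 3), c(0, 0, 1 / 3),
                              c(0, 1, 1 / 3))
  expect_equal(unlist(co[1, ]), c(x = 0, y = 0))                 # linear
  expect_equal(unlist(co[3, ]), c(x = 0.5, y = sqrt(3) / 6),
               tolerance = 1e-12)                                 # centroid
  pure_s <- shape_triangle_coords(0, 0, 1)
  expect_equal(unlist(pure_s), c(x = 0.5, y = sqrt(3) / 2))      # spherical
  set.seed(5)
  tri <- matrix(stats::runif(60), ncol = 3)
  tri <- tri / rowSums(tri)
  co <- shape_triangle_coords(tri[, 1], tri[, 2], tri[, 3])
  back <- triangle_to_shape(co$x, co$y)
  expect_equal(as.matrix(back), tri, tolerance = 1e-12,
               ignore_attr = TRUE)
})
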