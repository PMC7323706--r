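test_that("brain-slab geometry places all four regions, disjoint and sized", {
  cfg <- phantom_config(dim = c(32, 32, 32), geometry = "brain_slab")
  lab <- build_label_volume(cfg)
  sch <- label_scheme("brain_slab")
  counts <- vapply(sch, function(code) sum(lab == code), numeric(1))
  expect_true(all(counts >= 50))
  expect_setequal(setdiff(unique(as.integer(lab)), 0L), unlist(sch))
})

test_that("spinal-cord funiculi partition the WM annulus", {
  cfg <- phantom_config(dim = c(24, 24, 24), geometry = "spinal_cord")
  lab <- build_label_volume(cfg)
  sch <- label_scheme("spinal_cord")
  counts <- vapply(sch[c("SC_gm", "Af", "Lf", "Pf", "GM_ah")],
                   function(code) sum(lab == code), numeric(1))
  expect_true(all(counts >= 50))
  wm_total <- sum(as.integer(lab) %in% sch$SC_wm)
  expect_equal(counts[["Af"]] + counts[["Lf"]] + counts[["Pf"]], wm_total)
})

test_that("too-small grids raise a geometry error", {
  expect_error(phantom_config(dim = c(4, 4, 4)), ">= 16")
})

test_that("painted tensors reproduce spec triples and orientations", {
  cfg <- phantom_config(dim = c(32, 32, 32), geometry = "brain_slab",
                        group = "WT")
  lab <- build_label_volume(cfg)
  specs <- tissue_specs("WT", "brain_slab")
  paint <- paint_tensor_field(lab, specs, seed = 77)
  # coherent CC: principal axis is left-right
  cc_idx <- which(as.integer(lab) == label_scheme("all")$CC)
  expect_true(all(abs(paint$e1[cc_idx, 1]) > 1 - 1e-10))
  # every painted voxel's tensor has the spec's (renormalized) triple
  for (i in seq_len(nrow(specs))) {
    idx <- which(as.integer(lab) == specs$label[i])[1:5]
    lam <- dtishape:::eigenvalues3(paint$tensors[idx, , drop = FALSE])
    m <- westin_metrics(lam[, 1], lam[, 2], lam[, 3])
    s <- specs$cl[i] + specs$cp[i] + specs$cs[i]
    expect_equal(m$cl, rep(specs$cl[i] / s, 5), tolerance = 1e-10)
    expect_equal(m$cp, rep(specs$cp[i] / s, 5), tolerance = 1e-10)
    expect_equal(m$cs, rep(specs$cs[i] / s, 5), tolerance = 1e-10)
  }
  # determinism: same seed -> identical field; different seed -> different
  paint2 <- paint_tensor_field(lab, specs, seed = 77)
  expect_identical(paint$tensors, paint2$tensors)
  specs_d <- specs
  specs_d$orientation_mode <- "dispersed"
  specs_d$dispersion_kappa <- 20
  pa <- paint_tensor_field(lab, specs_d, seed = 1)
  pb <- paint_tensor_field(lab, specs_d, seed = 2)
  expect_false(identical(pa$e1, pb$e1))
  expect_error(paint_tensor_field(lab, specs[specs$name != "CC", ], 1),
               "no tissue spec")
})

test_that("dispersed orientations concentrate around the tract axis", {
  cfg <- phantom_config(dim = c(24, 24, 24), geometry = "spinal_cord")
  lab <- build_label_volume(cfg)
  specs <- tissue_specs("WT", "spinal_cord")
  specs$orientation_mode[specs$name == "Lf"] <- "dispersed"
  specs$dispersion_kappa[specs$name == "Lf"] <- 50
  paint <- paint_tensor_field(lab, specs, seed = 3)
  idx <- which(as.integer(lab) == label_scheme("all")$Lf)
  cosines <- abs(paint$e1[idx, 3])
  expect_gt(mean(cosines), 0.95)   # kappa = 50 -> tight scatter about z
  expect_lt(min(cosines), 1)       # but not exactly coherent
})

test_that("simulated signals follow the mono-exponential model", {
  prot <- default_protocol()
  D <- diffusion_tensor(1e-3, 0, 0, s0 = 1)
  sig <- simulate_signal(D, prot)
  expect_equal(sig[1], 1)  # b = 0 -> s0 exactly
  # direction (1,0,0) would give exp(-1); check against closed form per dir
  g <- prot$scheme$bvecs
  expect_equal(sig[-1], exp(-1000 * 1e-3 * g[-1, 1]^2), tolerance = 1e-12)
  one_dir <- acquisition_protocol(directions = rbind(c(1, 0, 0)), s0 = 1)
  expect_equal(simulate_signal(D, one_dir)[2], exp(-1), tolerance = 1e-12)
  # isotropic tensor -> identical signal in all 20 directions
  iso <- simulate_signal(diffusion_tensor(5e-4, 5e-4, 5e-4, s0 = 100), prot)
  expect_equal(max(iso[-1]) - min(iso[-1]), 0, tolerance = 1e-12)
})

test_that("crossing signal degenerates correctly and biases the fit", {
  prot <- default_protocol()
  lam <- shape_to_eigenvalues(0.41, 0.15, 0.44, 1.5e-3)
  Da <- c(lam[1], lam[2], lam[3], 0, 0, 0)
  M <- diag(c(lam[2], lam[1], lam[3]))  # same shape, rotated 90 deg
  Db <- c(M[1, 1], M[2, 2], M[3, 3], 0, 0, 0)
  expect_equal(crossing_signal(Da, Db, 0, prot),
               simulate_signal(Da, prot, s0 = prot$s0), tolerance = 1e-12)
  expect_equal(crossing_signal(Da, Da, 0.5, prot),
               simulate_signal(Da, prot, s0 = prot$s0), tolerance = 1e-12)
  expect_error(crossing_signal(Da, Db, 1.2, prot), "\\[0, 1\\]")
  # fit of the mixed signal: higher cs, lower cl than the pure fiber
  fit0 <- fit_tensor(crossing_signal(Da, Db, 0, prot), prot$scheme)
  fit5 <- fit_tensor(crossing_signal(Da, Db, 0.5, prot), prot$scheme)
  m0 <- westin_metrics(eigendecompose(fit0))
  m5 <- westin_metrics(eigendecompose(fit5))
  expect_gt(m5$cs, m0$cs)
  expect_lt(m5$cl, m0$cl)
})

test_that("Rician noise has the Rayleigh mean at zero signal and is seeded", {
  x <- matrix(runif(40, 100, 1000), 4)
  expect_identical(add_rician_noise(x, snr = Inf, s0 = 1000), x)
  n1 <- add_rician_noise(x, snr = 30, s0 = 1000, seed = 123)
  n2 <- add_rician_noise(x, snr = 30, s0 = 1000, seed = 123)
  expect_identical(n1, n2)
  expect_equal(dim(n1), dim(x))
  # zero signal: mean is sigma * sqrt(pi/2) (Rayleigh), Monte Carlo 1e5
  sigma <- 50
  draws <- add_rician_noise(rep(0, 1e5), snr = 1000 / sigma, s0 = 1000,
                            seed = 7)
  expect_equal(mean(draws), sigma * sqrt(pi / 2),
               tolerance = 3 * sigma / sqrt(1e5) / (sigma * sqrt(pi / 2)))
  expect_error(add_rician_noise(x, snr = -1), "positive")
})

test_that("noiseless phantom round-trips every spec triple through the fit", {
  for (geom in c("brain_slab", "spinal_cord")) {
    dims <- if (geom == "brain_slab") c(32, 32, 32) else c(24, 24, 24)
    cfg <- phantom_config(dim = dims, group = "WT", snr = Inf,
                          geometry = geom, seed = 2)
    out <- phantom_roi_metrics(cfg)
    truth <- out$truth
    for (i in seq_len(nrow(truth))) {
      got <- out$roi[out$roi$structure == truth$name[i], ]
      expect_equal(got$cl, truth$cl[i], tolerance = 1e-6)
      expect_equal(got$cp, truth$cp[i], tolerance = 1e-6)
      expect_equal(got$cs, truth$cs[i], tolerance = 1e-6)
      expect_equal(got$fa, truth$fa[i], tolerance = 1e-6)
    }
  }
})

test_that("phantom generation is deterministic and group-specific", {
  cfg <- phantom_config(dim = c(24, 24, 24), group = "P120", snr = 30,
                        geometry = "spinal_cord", seed = 9)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$data, ph2$data)
  # ground-truth table carries the symptomatic-group triples (renormalized)
  tg <- reference_shape_targets("SC_gm", "P120")
  s <- tg$cl + tg$cp + tg$cs
  row <- ph1$truth[ph1$truth$name == "SC_gm", ]
  expect_equal(row$cl, tg$cl / s, tolerance = 1e-12)
  expect_equal(row$cs, tg$cs / s, tolerance = 1e-12)
  cfg2 <- phantom_config(dim = c(24, 24, 24), group = "P120", snr = 30,
                         geometry = "spinal_cord", seed = 10)
  expect_false(identical(generate_phantom(cfg2)$data, ph1$data))
})

test_that("written datasets round-trip and rewrite identically", {
  tmp <- withr::local_tempdir()
  cfg <- phantom_config(dim = c(20, 20, 20), group = "WT", snr = 30,
                        geometry = "spinal_cord", seed = 4)
  d1 <- file.path(tmp, "a"); d2 <- file.path(tmp, "b")
  f1 <- generate_dataset(cfg, d1)
  f2 <- generate_dataset(cfg, d2)
  expect_true(all(file.exists(f1)))
  ds1 <- read_dwi(f1["dwi"], f1["bval"], f1["bvec"])
  ds2 <- read_dwi(f2["dwi"], f2["bval"], f2["bvec"])
  expect_equal(ds1$data, ds2$data)
  expect_identical(readLines(f1["truth"]), readLines(f2["truth"]))
  expect_identical(readLines(f1["bvec"]), readLines(f2["bvec"]))
  man <- jsonlite::fromJSON(f1["manifest"])
  expect_equal(man$config$seed, 4)
  expect_equal(man$config$group, "WT")
})
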