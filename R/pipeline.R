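# Pipeline-level wrappers: one function per subcommand of the command-line
# tool (inst/cli/dtishape.R). Each emits deterministic outputs for a fixed
# seed and writes a manifest of its resolved configuration.

#' Generate a phantom dataset directory
#'
#' @param out_dir output directory.
#' @param geometry,group,snr,seed,dim,voxel_mm see
#'   \code{\link{phantom_config}}.
#' @return Invisibly, the file set written (see
#'   \code{\link{generate_dataset}}).
#' @export
run_phantom <- function(out_dir, geometry = "brain_slab", group = "WT",
                        snr = 30, seed = 1L, dim = c(48, 48, 48),
                        voxel_mm = 0.2) {
  cfg <- phantom_config(dim = dim, voxel_mm = voxel_mm, group = group,
                        snr = snr, seed = seed, geometry = geometry)
  generate_dataset(cfg, out_dir)
}

# robust automask: voxels whose b0 signal clears 10% of the robust
# (99th-percentile) b0 maximum
auto_mask <- function(data, scheme, frac = 0.1) {
  b0 <- which(scheme$bvals == 0)
  vol <- if (length(b0)) {
    apply(array(data[, , , b0], dim = c(dim(data)[1:3], length(b0))),
          1:3, mean)
  } else array(apply(data, 1:3, max), dim = dim(data)[1:3])
  as.vector(vol >= frac * stats::quantile(vol, 0.99, names = FALSE))
}

#' Fit tensors and write metric maps
#'
#' Reads a DWI triplet, fits the tensor field, and writes fa/cl/cp/cs/md
#' NIfTI maps plus a per-voxel clamped-eigenvalue count map.  Without an
#' explicit mask, background is auto-masked by a b = 0 threshold (10% of
#' the robust b0 maximum).
#'
#' @param nifti_path,bval_path,bvec_path the DWI triplet.
#' @param out_prefix output path prefix for the metric maps.
#' @param mask_path optional mask NIfTI; overrides the automask.
#' @param method \code{"ols"} or \code{"wls"}.
#' @return Invisibly, the \code{\link{dti_fit}} object.
#' @export
run_fit <- function(nifti_path, bval_path, bvec_path, out_prefix,
                    mask_path = NULL, method = "ols") {
  ds <- read_dwi(nifti_path, bval_path, bvec_path, mask_path)
  if (is.null(ds$mask)) ds$mask <- auto_mask(ds$data, ds$scheme)
  fit <- dti_fit(ds, method = method, keep_data = FALSE)
  maps <- metric_maps(fit)
  maps$eigclamp <- array(as.numeric(shape_metrics(fit)$eig_clamped),
                         dim = fit$dim)
  files <- write_metric_maps(maps, fit$affine, out_prefix)
  manifest <- list(tool = "dtishape fit", method = method,
                   input = nifti_path,
                   n_voxels_fit = sum(!fit$masked),
                   n_clamped_signals = sum(fit$n_clamped, na.rm = TRUE),
                   files = as.list(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paste0(out_prefix, "_manifest.json"))
  invisible(fit)
}

#' Build the ROI summary table across subjects
#'
#' @param subjects data.frame with one row per subject: columns
#'   \code{subject}, \code{group}, \code{prefix} (metric-map prefix written
#'   by \code{\link{run_fit}}), \code{labels_path}.
#' @param out_csv output CSV path.
#' @param reference reference group.
#' @return Invisibly, the summary data.frame (also written as CSV).
#' @export
run_roi_table <- function(subjects, out_csv, reference = "WT") {
  per_subject <- lapply(seq_len(nrow(subjects)), function(i) {
    maps <- read_metric_maps(subjects$prefix[i])
    labels <- read_labels(subjects$labels_path[i])
    sm <- subject_roi_means(maps, labels)
    sm$subject <- subjects$subject[i]
    sm$group <- subjects$group[i]
    sm
  })
  tab <- build_summary_table(do.call(rbind, per_subject),
                             reference = reference)
  utils::write.csv(format(tab, digits = 10, trim = TRUE), out_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Group comparison report
#'
#' @inheritParams run_roi_table
#' @return Invisibly, the \code{\link{compare_groups}} data.frame (also
#'   written as CSV).
#' @export
run_compare <- function(subjects, out_csv, reference = "WT") {
  per_subject <- lapply(seq_len(nrow(subjects)), function(i) {
    maps <- read_metric_maps(subjects$prefix[i])
    labels <- read_labels(subjects$labels_path[i])
    sm <- subject_roi_means(maps, labels)
    sm$subject <- subjects$subject[i]
    sm$group <- subjects$group[i]
    sm
  })
  cmp <- compare_groups(do.call(rbind, per_subject), reference = reference)
  utils::write.csv(format(cmp, digits = 10, trim = TRUE), out_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(cmp)
}

#' Crossing-fiber sweep
#'
#' Simulates a voxel holding two equal-shape fiber populations crossing at
#' the given angle(s), sweeps the crossing fraction, fits a single tensor to
#' each mixed signal and reports its shape metrics.  This exercises the
#' mechanism by which crossing fibers push a single-tensor fit toward
#' planar/spherical shape (lower CL, higher CS).
#'
#' @param fractions crossing fractions to sweep (in [0, 0.5] by
#'   convention).
#' @param angles crossing angle(s), degrees.
#' @param cl,cp,cs,trace shape and trace of both populations (default: a
#'   strongly linear white-matter-like tensor).
#' @param protocol acquisition protocol.
#' @param out_csv optional CSV output path.
#' @return A data.frame with one row per (angle, fraction): fitted
#'   \code{fa}, \code{cl}, \code{cp}, \code{cs}.
#' @export
run_crossing_sweep <- function(fractions = seq(0, 0.5, by = 0.1),
                               angles = 90,
                               cl = 0.41, cp = 0.15, cs = 0.44,
                               trace = 1.5e-3,
                               protocol = acquisition_protocol(),
                               out_csv = NULL) {
  lam <- shape_to_eigenvalues(cl, cp, cs, trace)
  Da <- c(dxx = lam[[1]], dyy = lam[[2]], dzz = lam[[3]],
          dxy = 0, dxz = 0, dyz = 0)
  out <- list()
  for (ang in angles) {
    th <- ang * pi / 180
    # rotate population A's principal (x) axis toward y by th
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    M <- R %*% diag(c(lam[[1]], lam[[2]], lam[[3]])) %*% t(R)
    Db <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    for (f in fractions) {
      sig <- crossing_signal(Da, Db, f, protocol)
      tens <- fit_tensor(sig, protocol$scheme)
      es <- eigendecompose(tens)
      wm <- westin_metrics(es)
      out[[length(out) + 1L]] <- data.frame(
        angle = ang, fraction = f, fa = wm$fa, cl = wm$cl, cp = wm$cp,
        cs = wm$cs)
    }
  }
  out <- do.call(rbind, out)
  if (!is.null(out_csv))
    utils::write.csv(format(out, digits = 10, trim = TRUE), out_csv,
                     row.names = FALSE, quote = FALSE)
  out
}

#' Load a YAML run configuration
#'
#' Reads a nested key/value configuration file and overlays explicit
#' overrides (command-line flags take precedence over file values).
#'
#' @param path YAML file, or NULL.
#' @param overrides named list of values that win over the file.
#' @return A named list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  cfg
}
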