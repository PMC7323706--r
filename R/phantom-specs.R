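# Published per-structure, per-group shape targets (group means +/- SEM,
# n = 4 animals per group) for the G93A-SOD1 study groups: wild-type (WT),
# presymptomatic day 80 (P80), symptomatic day 120 (P120).  Six core
# structures (three GM, three WM) plus the lumbar spinal-cord subregions
# (anterior funiculus Af and gray-matter anterior horn GM_ah).  The lateral
# and posterior funiculi (Lf, Pf) have no published triples; the phantom
# reuses the spinal-cord WM triples for them, and Af/GM_ah P80 values (also
# unpublished) are the WT/P120 midpoint -- both synthetic defaults.
SHAPE_TARGETS <- local({
  g <- function(structure, tissue, group, fa, fa_sem, cl, cl_sem,
                cp, cp_sem, cs, cs_sem)
    data.frame(structure = structure, tissue = tissue, group = group,
               fa = fa, fa_sem = fa_sem, cl = cl, cl_sem = cl_sem,
               cp = cp, cp_sem = cp_sem, cs = cs, cs_sem = cs_sem)
  rbind(
    g("CCX",   "GM", "WT",   0.160, 0.004, 0.050, 0.003, 0.090, 0.004, 0.860, 0.001),
    g("CCX",   "GM", "P80",  0.140, 0.002, 0.050, 0.001, 0.070, 0.002, 0.870, 0.003),
    g("CCX",   "GM", "P120", 0.120, 0.006, 0.050, 0.002, 0.070, 0.001, 0.880, 0.003),
    g("Hipp",  "GM", "WT",   0.180, 0.009, 0.060, 0.003, 0.100, 0.005, 0.830, 0.008),
    g("Hipp",  "GM", "P80",  0.150, 0.010, 0.060, 0.005, 0.080, 0.002, 0.860, 0.011),
    g("Hipp",  "GM", "P120", 0.130, 0.007, 0.050, 0.006, 0.070, 0.005, 0.880, 0.002),
    g("SC_gm", "GM", "WT",   0.220, 0.009, 0.080, 0.002, 0.140, 0.007, 0.790, 0.008),
    g("SC_gm", "GM", "P80",  0.200, 0.004, 0.070, 0.003, 0.120, 0.002, 0.810, 0.004),
    g("SC_gm", "GM", "P120", 0.180, 0.007, 0.060, 0.005, 0.110, 0.006, 0.830, 0.008),
    g("CC",    "WM", "WT",   0.420, 0.013, 0.200, 0.004, 0.160, 0.003, 0.650, 0.004),
    g("CC",    "WM", "P80",  0.330, 0.017, 0.140, 0.009, 0.140, 0.006, 0.720, 0.014),
    g("CC",    "WM", "P120", 0.300, 0.017, 0.120, 0.006, 0.130, 0.005, 0.740, 0.010),
    g("CST",   "WM", "WT",   0.460, 0.006, 0.230, 0.011, 0.150, 0.007, 0.620, 0.018),
    g("CST",   "WM", "P80",  0.410, 0.010, 0.200, 0.008, 0.130, 0.004, 0.680, 0.005),
    g("CST",   "WM", "P120", 0.370, 0.012, 0.180, 0.013, 0.110, 0.007, 0.710, 0.015),
    g("SC_wm", "WM", "WT",   0.640, 0.011, 0.410, 0.006, 0.150, 0.003, 0.440, 0.004),
    g("SC_wm", "WM", "P80",  0.560, 0.060, 0.350, 0.010, 0.150, 0.008, 0.490, 0.004),
    g("SC_wm", "WM", "P120", 0.510, 0.025, 0.290, 0.019, 0.140, 0.006, 0.560, 0.024),
    g("Af",    "WM", "WT",   NA,    NA,    0.390, 0.009, 0.152, 0.009, 0.477, 0.013),
    g("Af",    "WM", "P120", NA,    NA,    0.296, 0.020, 0.135, 0.005, 0.567, 0.023),
    g("GM_ah", "GM", "WT",   NA,    NA,    0.075, 0.002, 0.132, 0.006, 0.792, 0.008),
    g("GM_ah", "GM", "P120", NA,    NA,    0.067, 0.004, 0.115, 0.002, 0.822, 0.007))
})

#' Reference per-structure shape targets
#'
#' Published group-mean shape metrics (with SEM) for the study structures and
#' groups.  These are the ground-truth targets the phantom paints.
#'
#' @param structure optionally filter by structure name.
#' @param group optionally filter by group (WT, P80, P120).
#' @return A data.frame with columns structure, tissue, group, fa, fa_sem,
#'   cl, cl_sem, cp, cp_sem, cs, cs_sem.
#' @export
reference_shape_targets <- function(structure = NULL, group = NULL) {
  out <- SHAPE_TARGETS
  if (!is.null(structure)) out <- out[out$structure %in% structure, ]
  if (!is.null(group)) out <- out[out$group %in% group, ]
  rownames(out) <- NULL
  out
}

# integer label codes shared by both geometries
LABEL_SCHEME <- c(CCX = 1L, Hipp = 2L, CC = 3L, CST = 4L,
                  SC_gm = 5L, Af = 7L, Lf = 8L, Pf = 9L, GM_ah = 10L)

#' Label codes and ROI composition
#'
#' Integer codes used in phantom label volumes.  \code{SC_wm} is a composite
#' region: the union of the three funiculi (Af, Lf, Pf).
#'
#' @param geometry \code{"brain_slab"}, \code{"spinal_cord"} or
#'   \code{"all"}.
#' @return A named list mapping ROI names to integer label vectors.
#' @export
label_scheme <- function(geometry = c("all", "brain_slab", "spinal_cord")) {
  geometry <- match.arg(geometry)
  brain <- list(CCX = 1L, Hipp = 2L, CC = 3L, CST = 4L)
  cord <- list(SC_gm = 5L, Af = 7L, Lf = 8L, Pf = 9L, GM_ah = 10L,
               SC_wm = c(7L, 8L, 9L))
  switch(geometry, brain_slab = brain, spinal_cord = cord,
         all = c(brain, cord))
}

#' Tissue specifications for a phantom group
#'
#' One row per structure in the chosen geometry: label code, target shape
#' triple, trace, orientation model and crossing parameters.  Targets come
#' from the published group means (\code{\link{reference_shape_targets}});
#' the unpublished Lf/Pf triples default to the SC_wm triples and the
#' unpublished Af/GM_ah P80 triples to the WT/P120 midpoint (synthetic
#' defaults).  Crossing fractions default to 0: the published triples are
#' the measured single-tensor shapes, so any crossing admixture would bias
#' the painted ground truth away from them.
#'
#' @param group \code{"WT"}, \code{"P80"} or \code{"P120"}.
#' @param geometry \code{"brain_slab"} or \code{"spinal_cord"}.
#' @param trace ground-truth eigenvalue sum, mm^2/s (default 1.5e-3,
#'   i.e. MD 0.5e-3, plausible for fixed ex vivo tissue).
#' @return A data.frame of class \code{"tissue_specs"}: columns
#'   \code{label}, \code{name}, \code{group}, \code{cl}, \code{cp},
#'   \code{cs}, \code{trace}, \code{orientation_mode},
#'   \code{dispersion_kappa}, \code{crossing_fraction},
#'   \code{crossing_angle}.
#' @export
tissue_specs <- function(group = c("WT", "P80", "P120"),
                         geometry = c("brain_slab", "spinal_cord"),
                         trace = 1.5e-3) {
  group <- match.arg(group)
  geometry <- match.arg(geometry)
  stopifnot(trace > 0)
  pick <- function(structure, grp = group) {
    r <- SHAPE_TARGETS[SHAPE_TARGETS$structure == structure &
                         SHAPE_TARGETS$group == grp, ]
    if (nrow(r) == 1) return(c(r$cl, r$cp, r$cs))
    # unpublished P80 subregion triple: WT/P120 midpoint
    wt <- pick(structure, "WT"); p120 <- pick(structure, "P120")
    (wt + p120) / 2
  }
  row <- function(name, source, mode, kappa = Inf) {
    tri <- pick(source)
    data.frame(label = unname(LABEL_SCHEME[name]), name = name,
               group = group, cl = tri[1], cp = tri[2], cs = tri[3],
               trace = trace, orientation_mode = mode,
               dispersion_kappa = kappa, crossing_fraction = 0,
               crossing_angle = 90)
  }
  specs <- if (geometry == "brain_slab") rbind(
    row("CCX", "CCX", "random"),
    row("Hipp", "Hipp", "random"),
    row("CC", "CC", "coherent"),
    row("CST", "CST", "coherent")
  ) else rbind(
    row("SC_gm", "SC_gm", "random"),
    row("Af", "Af", "coherent"),
    row("Lf", "SC_wm", "coherent"),
    row("Pf", "SC_wm", "coherent"),
    row("GM_ah", "GM_ah", "random")
  )
  s <- specs$cl + specs$cp + specs$cs
  if (any(abs(s - 1) > 0.02))
    stop("inconsistent shape triple in specs for ",
         paste(specs$name[abs(s - 1) > 0.02], collapse = ", "))
  rownames(specs) <- NULL
  class(specs) <- c("tissue_specs", "data.frame")
  specs
}
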