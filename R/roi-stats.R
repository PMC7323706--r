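#' Round half away from zero
#'
#' Integer rounding in the convention of printed percent-change tables:
#' 0.5 rounds to 1, -0.5 to -1.
#'
#' @param x numeric vector.
#' @return Integer vector.
#' @export
round_half_away <- function(x) {
  x <- round(x, 9)  # absorb float error so exact halves round as halves
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' ROI mean of a metric map
#'
#' Mean over the voxels carrying the given label code(s), excluding sentinel
#' (NaN/NA) voxels.
#'
#' @param map numeric 3D array (or vector) of per-voxel metric values.
#' @param labels integer array of matching length.
#' @param label one or more integer label codes forming the ROI.
#' @return A list with \code{mean}, \code{n_voxels} (valid voxels averaged)
#'   and \code{n_excluded} (sentinel voxels in the ROI).
#' @export
roi_means <- function(map, labels, label) {
  if (length(map) != length(labels))
    stop("metric map and label volume have different lengths")
  sel <- as.integer(labels) %in% as.integer(label)
  if (!any(sel))
    stop("label(s) ", paste(label, collapse = ","), " absent from volume")
  v <- map[sel]
  ok <- is.finite(v)
  if (!any(ok))
    stop("empty ROI: all ", sum(sel), " voxels with label ",
         paste(label, collapse = ","), " are sentinel")
  list(mean = mean(v[ok]), n_voxels = sum(ok), n_excluded = sum(!ok))
}

#' Signed integer percent change
#'
#' \code{100 (group_mean - reference_mean) / reference_mean}, rounded half
#' away from zero to the nearest integer percent (the convention of the
#' printed group tables).
#'
#' @param reference_mean reference (e.g. wild-type) mean; must be nonzero.
#' @param group_mean comparison group mean.
#' @return Signed integer percent.
#' @examples
#' percent_change(0.200, 0.120)  # -40
#' percent_change(0.44, 0.56)    # +27
#' @export
percent_change <- function(reference_mean, group_mean) {
  if (any(reference_mean == 0)) stop("undefined percent change: reference is 0")
  round_half_away(100 * (group_mean - reference_mean) / reference_mean)
}

# one-way ANOVA by explicit sums of squares; returns F and p
anova_oneway <- function(value, group) {
  group <- factor(group)
  k <- nlevels(group); n <- length(value)
  grand <- mean(value)
  ng <- tapply(value, group, length)
  mg <- tapply(value, group, mean)
  ss_between <- sum(ng * (mg - grand)^2)
  ss_within <- sum((value - mg[group])^2)
  df1 <- k - 1; df2 <- n - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / ms_w
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), ms_between = ms_b, ms_within = ms_w)
}

#' Compare groups of per-subject ROI means
#'
#' For each structure x metric: a one-way ANOVA across groups with Tukey HSD
#' post hoc pairwise p-values, plus pairwise Mann-Whitney (Wilcoxon rank
#' sum) tests, and the signed integer percent change of each contrast.
#' Contrasts with fewer than 2 subjects per group get NA p-values
#' (rows are still emitted, flagged in \code{computable}).
#'
#' @param data data.frame with columns \code{structure}, \code{metric},
#'   \code{group}, \code{value} (one row per subject), and optionally
#'   \code{subject}.
#' @param reference reference group name for ordering (default "WT").
#' @return A data.frame with one row per structure x metric x contrast:
#'   \code{structure}, \code{metric}, \code{contrast}, \code{percent_change},
#'   \code{f_anova}, \code{p_anova}, \code{p_tukey}, \code{p_mannwhitney},
#'   \code{computable}.
#' @export
compare_groups <- function(data, reference = "WT") {
  need <- c("structure", "metric", "group", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  lev <- unique(c(intersect(c(reference, "P80", "P120"), data$group),
                  setdiff(unique(data$group), c(reference, "P80", "P120"))))
  if (length(lev) < 2) stop("need at least 2 groups")
  out <- list()
  for (st in unique(data$structure)) {
    for (me in unique(data$metric[data$structure == st])) {
      d <- data[data$structure == st & data$metric == me, ]
      d$group <- factor(d$group, levels = lev)
      ng <- table(d$group)
      parametric_ok <- all(ng >= 2) && length(ng) >= 2
      aov_res <- if (parametric_ok) anova_oneway(d$value, d$group) else NULL
      tukey <- if (parametric_ok && is.finite(aov_res$F)) {
        tk <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
        stats::setNames(tk[, "p adj"], rownames(tk))
      } else NULL
      pairs <- utils::combn(lev, 2, simplify = FALSE)
      for (pr in pairs) {
        a <- d$value[d$group == pr[1]]; b <- d$value[d$group == pr[2]]
        if (!length(a) || !length(b)) next
        contrast <- paste(pr[1], "vs", pr[2])
        pc <- if (mean(a) != 0) percent_change(mean(a), mean(b)) else
          NA_integer_
        p_tk <- NA_real_
        if (!is.null(tukey)) {
          key <- paste0(pr[2], "-", pr[1])
          key2 <- paste0(pr[1], "-", pr[2])
          p_tk <- if (key %in% names(tukey)) tukey[[key]] else
            if (key2 %in% names(tukey)) tukey[[key2]] else NA_real_
        }
        p_mw <- if (length(a) >= 2 && length(b) >= 2)
          suppressWarnings(stats::wilcox.test(a, b)$p.value) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          structure = st, metric = me, contrast = contrast,
          percent_change = pc,
          f_anova = if (parametric_ok) aov_res$F else NA_real_,
          p_anova = if (parametric_ok) aov_res$p else NA_real_,
          p_tukey = p_tk, p_mannwhitney = p_mw,
          computable = parametric_ok)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-subject ROI means of metric maps
#'
#' @param maps named list of metric arrays (fa, cl, cp, cs, md, ...), e.g.
#'   from \code{\link{metric_maps}}.
#' @param labels integer label volume on the same grid.
#' @param scheme named list mapping ROI names to label codes (default:
#'   \code{\link{label_scheme}} restricted to labels present).
#' @return A data.frame with columns \code{structure}, \code{metric},
#'   \code{value}, \code{n_voxels}.
#' @export
subject_roi_means <- function(maps, labels, scheme = NULL) {
  if (is.null(scheme)) {
    scheme <- label_scheme("all")
    scheme <- scheme[vapply(scheme, function(code)
      any(as.integer(labels) %in% code), logical(1))]
  }
  out <- list()
  for (roi in names(scheme)) {
    for (m in names(maps)) {
      rm <- roi_means(maps[[m]], labels, scheme[[roi]])
      out[[length(out) + 1L]] <- data.frame(
        structure = roi, metric = toupper(m), value = rm$mean,
        n_voxels = rm$n_voxels)
    }
  }
  do.call(rbind, out)
}

#' Group summary table (mean +/- SEM, percent change, significance)
#'
#' Aggregates per-subject ROI means into a per-structure x metric x group
#' report in the style of a published group table: group mean, SEM across
#' subjects, signed integer percent change versus the reference group, and
#' Tukey / Mann-Whitney p-values with significance marks ("*" p < .05,
#' "**" p < .01, from the Tukey test).  ROI means are computed per subject
#' first; group statistics are across subjects.
#'
#' @param subjects data.frame with columns \code{subject}, \code{group},
#'   \code{structure}, \code{metric}, \code{value} (one row per subject x
#'   structure x metric), e.g. stacked \code{\link{subject_roi_means}}.
#' @param reference reference group (default "WT").
#' @return A data.frame with columns \code{structure}, \code{metric},
#'   \code{group}, \code{mean}, \code{sem}, \code{n_subjects},
#'   \code{pct_change_vs_ref}, \code{p_tukey}, \code{p_mannwhitney},
#'   \code{significance_mark}, \code{complete} (FALSE flags structures
#'   missing for some subject), in deterministic row order.
#' @export
build_summary_table <- function(subjects, reference = "WT") {
  need <- c("subject", "group", "structure", "metric", "value")
  if (!all(need %in% names(subjects)))
    stop("subjects must have columns ", paste(need, collapse = ", "))
  lev <- unique(c(intersect(c(reference, "P80", "P120"), subjects$group),
                  setdiff(unique(subjects$group),
                          c(reference, "P80", "P120"))))
  cmp <- compare_groups(subjects, reference = reference)
  n_subj_total <- tapply(subjects$subject, subjects$group,
                         function(s) length(unique(s)))
  rows <- list()
  structures <- unique(subjects$structure)
  metrics <- unique(subjects$metric)
  for (st in structures) for (me in metrics) for (g in lev) {
    d <- subjects[subjects$structure == st & subjects$metric == me &
                    subjects$group == g, ]
    if (!nrow(d)) next
    m <- mean(d$value)
    sem <- if (nrow(d) > 1) stats::sd(d$value) / sqrt(nrow(d)) else NA_real_
    pc <- NA_integer_; p_tk <- NA_real_; p_mw <- NA_real_
    if (g != reference) {
      ref <- subjects[subjects$structure == st & subjects$metric == me &
                        subjects$group == reference, ]
      if (nrow(ref) && mean(ref$value) != 0)
        pc <- percent_change(mean(ref$value), m)
      cr <- cmp[cmp$structure == st & cmp$metric == me &
                  cmp$contrast == paste(reference, "vs", g), ]
      if (nrow(cr)) { p_tk <- cr$p_tukey; p_mw <- cr$p_mannwhitney }
    }
    mark <- if (is.na(p_tk)) "" else if (p_tk < 0.01) "**" else
      if (p_tk < 0.05) "*" else ""
    rows[[length(rows) + 1L]] <- data.frame(
      structure = st, metric = me, group = g, mean = m, sem = sem,
      n_subjects = nrow(d), pct_change_vs_ref = pc, p_tukey = p_tk,
      p_mannwhitney = p_mw, significance_mark = mark,
      complete = nrow(d) == n_subj_total[[g]])
  }
  do.call(rbind, rows)
}
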