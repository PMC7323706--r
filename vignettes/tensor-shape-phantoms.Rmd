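---
title: "Tensor shape metrics, synthetic neuraxial phantoms, and what they can show"
author: "dtishape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor shape metrics, synthetic neuraxial phantoms, and what they can show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtishape)
```

## The model

Diffusion-weighted MRI measures, per voxel, signals

$$S_i = S_0 \exp\!\left(-b_i\, g_i^{\mathsf T} D\, g_i\right),$$

where $b_i$ (s/mm²) is the diffusion weighting, $g_i$ a unit gradient
direction, and $D$ a symmetric positive-semidefinite 3×3 apparent diffusion
tensor (mm²/s). Taking logs makes the model linear in the seven unknowns
$(\log S_0, d_{xx}, d_{yy}, d_{zz}, d_{xy}, d_{xz}, d_{yz})$;
`dti_fit()` solves the resulting least-squares problem voxelwise (ordinary
least squares by default; weighted least squares with squared-signal
weights behind `method = "wls"`, since the toolkits used in practice differ
on this point and the two coincide on noiseless data).

Diagonalizing $D$ gives ordered eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$. Shape is summarized by fractional
anisotropy

$$\mathrm{FA} = \sqrt{\tfrac12\,
  \frac{(\lambda_1-\lambda_2)^2 + (\lambda_1-\lambda_3)^2 +
        (\lambda_2-\lambda_3)^2}{\lambda_1^2+\lambda_2^2+\lambda_3^2}}$$

and by the Westin barycentric decomposition

$$C_L = \frac{\lambda_1-\lambda_2}{\mathrm{tr}}, \qquad
  C_P = \frac{2(\lambda_2-\lambda_3)}{\mathrm{tr}}, \qquad
  C_S = \frac{3\lambda_3}{\mathrm{tr}}, \qquad
  \mathrm{tr} = \lambda_1+\lambda_2+\lambda_3,$$

so that $C_L + C_P + C_S = 1$ exactly for any ordered non-negative triple
with positive trace. $C_L$, $C_P$, $C_S$ locate each voxel in a 2-simplex
between the stick, pancake and sphere limits;
`shape_triangle_coords()` embeds them with the linear corner bottom-left,
planar bottom-right and spherical at the apex (the corner convention is a
plotting choice; the mapping is affine and invertible on the simplex).

The decomposition inverts in closed form — given $(C_L, C_P, C_S)$ and a
trace, $\lambda_3 = C_S\,\mathrm{tr}/3$,
$\lambda_2 = \lambda_3 + C_P\,\mathrm{tr}/2$,
$\lambda_1 = C_L\,\mathrm{tr} + \lambda_2$ — which is what lets published
group-mean shape triples serve as simulator ground truth
(`shape_to_eigenvalues()`). Printed triples are rounded and may sum to
0.99–1.01; sums within ±0.02 of 1 are renormalized by division, larger
deviations are rejected.

## What the phantom emulates

The phantom stands in for an ex vivo mouse study of early-stage ALS
(G93A-SOD1 mice): three groups — wild-type (WT), presymptomatic day 80
(P80), symptomatic day 120 (P120), n = 4 animals each — scanned at 200 µm
isotropic resolution with one b = 0 volume plus 20 directions at
b = 1000 s/mm². `reference_shape_targets()` carries the published
per-structure group means (with SEM) that the phantom paints as ground
truth: prefrontal cortex (CCX), hippocampus (Hipp) and spinal-cord gray
matter (SC_gm) for GM; corpus callosum (CC), corticospinal tract (CST) and
spinal-cord white matter for WM, the latter subdivided into anterior,
lateral and posterior funiculi (Af, Lf, Pf) plus the gray-matter anterior
horn (GM_ah).

Two stylized geometries (`build_label_volume()`): a brain slab (cortical
shell, two hippocampal blobs, a left–right CC strip, two rostro-caudal CST
columns inside an ellipsoidal brain) and a spinal cord (inner GM cylinder
with an anterior-horn sector, WM annulus partitioned into the three
funiculi). Geometry is deliberately schematic — cylinders, slabs, sectors —
because the quantity under test is shape-metric recovery, not anatomy.

Per-structure orientation models: `coherent` aligns the principal axis
with the tract axis (CC left–right, CST and funiculi rostro-caudal),
`dispersed` scatters it with a von Mises–Fisher distribution of
concentration `dispersion_kappa`, `random` draws it uniformly (used for
GM, whose published triples are nearly spherical so orientation is
immaterial). The remaining eigenvector pair gets a uniform random spin
about the principal axis.

Crossing fibers are modeled as a two-compartment mixture
(`crossing_signal()`):
$S_i = S_0[(1-f)e^{-b g^{\mathsf T} D_a g} + f\,e^{-b g^{\mathsf T} D_b g}]$.
The default `crossing_fraction` is 0 for every tissue spec: the published
triples are the *measured single-tensor shapes* of each structure, so they
already absorb whatever crossing the tissue contains; painting extra
crossing on top would bias the simulated ground truth away from the
targets it is supposed to reproduce. The mechanism itself is exercised
separately by `run_crossing_sweep()`, which shows the single-tensor fit of
two equal-shape populations at 90° drifting monotonically toward lower
$C_L$ and higher $C_S$ as $f$ grows from 0 to 0.5 — the standard
explanation for why tracts with more crossing populations sit closer to
the spherical corner.

Noise is Rician (magnitude MRI):
$S_{\text{noisy}} = \sqrt{(S+n_1)^2 + n_2^2}$ with
$n_1, n_2 \sim N(0, \sigma)$, $\sigma = S_0/\mathrm{snr}$; a Gaussian
variant exists for debugging. One master seed expands into per-stage child
seeds (orientation painting, noise) through the documented splitting rule
in `seed_child()`, so a dataset is reproduced bit-for-bit from its
manifest.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| b-value | 1000 | s/mm² | the emulated acquisition's shell |
| directions | 20 (fixed set) | — | electrostatic-repulsion set, shipped as a frozen constant so outputs are reproducible; the original direction table was never published |
| voxel size | 0.2 | mm | the emulated 200 µm isotropic resolution |
| grid | 48³ | voxels | smallest grid giving every ROI ≥ 50 voxels with comfortable margins |
| trace | 1.5e-3 | mm²/s | MD 0.5e-3, plausible for fixed ex vivo tissue at room temperature; no diffusivities were published, and all shape targets are trace-invariant |
| s0 | 1000 (background 50) | a.u. | arbitrary amplitude; the air-like background exercises masking |
| snr | 30 | — | b0-amplitude SNR typical of long ex vivo acquisitions |
| dispersion_kappa | Inf (coherent) | — | per-structure orientation scatter |
| crossing_fraction | 0 | — | see above |

## Statistics

ROI means are computed per subject over non-sentinel voxels, then group
statistics across subjects (matching the n = 4 per group and SEM
convention of the emulated study): one-way ANOVA with Tukey HSD post hoc
pairwise tests, replicated by pairwise Mann–Whitney tests, significance at
p < .05. Metrics are averaged voxelwise (mean of per-voxel FA/CL/CP/CS),
not derived from a mean tensor — which is why a group's mean FA is not
algebraically implied by its mean shape triple. Percent changes are
rounded half away from zero to integer percent, the convention of printed
group tables. No multiple-testing correction is applied across structures
or metrics beyond Tukey within each ANOVA. With n = 4 per group the
smallest achievable two-sided Mann–Whitney p is 2/70 ≈ 0.029, so that test
can only reach significance under complete separation.

## Numerical choices

* Non-positive signals are floored at `1e-6 * s0` before the log; the
  per-voxel count of floored samples is recorded. Voxels whose signals are
  all non-positive become masked sentinels.
* Negative eigenvalues (noise) are clamped to zero before metrics, with a
  per-voxel flag, keeping all metrics inside [0, 1].
* Eigenvalues are sorted descending; each eigenvector's sign is fixed by
  making its largest-magnitude component positive, so stored maps are
  reproducible.
* Voxels with non-positive trace yield NaN sentinel metrics, excluded from
  ROI means (NaN is also the on-disk sentinel in metric maps).
* Without an explicit mask, the fit stage excludes voxels whose b0 signal
  is below 10% of the robust (99th-percentile) b0 maximum.
* Map-scale eigendecomposition uses the closed-form trigonometric solution
  for symmetric 3×3 matrices, vectorized across voxels and checked against
  `eigen()` in the tests.
* Unit-trace round-trip checks use the µm²/ms convention (trace 1 µm²/ms =
  1e-3 mm²/s) so that $b\lambda$ stays of order one; shape metrics are
  scale-invariant, so recovered $C_L$/$C_P$/$C_S$ are unaffected.

## Design choices that were genuinely open

* The lateral and posterior funiculi have no published triples; they
  default to the spinal-cord WM triples. The anterior funiculus and
  anterior horn have published WT and P120 values only; their P80 triples
  default to the WT/P120 midpoint. Both are synthetic defaults,
  overridable via `tissue_specs()`.
* Several printed percent-change cells are not arithmetically consistent
  with their own printed means (rounding in the source tables); the
  reproduction tests restrict themselves to the consistent cells rather
  than reconcile the rest by guesswork.
* The estimator behind the emulated study's toolkit is unstated; OLS on
  log signals is the default here, WLS a flag.

## What passing tests do and do not show

Noiseless end-to-end recovery (generate → fit → metrics → ROI means
reproduces every painted triple to 1e-6) validates the algebra and the
plumbing. The noisy study (n = 4 per group, snr 30, 48³ grids — sizes
chosen so the whole study re-runs in a few minutes) reproduces the
qualitative staging: WM FA/$C_L$/$C_P$ fall and $C_S$ rises from WT to
P120, GM FA/$C_P$ fall, and the WT→P120 WM $C_L$/$C_S$ contrasts are
significant by both tests.

Quantitatively, per-voxel shape metrics are noise-biased: sorting
eigenvalues repels them apart, so nearly isotropic voxels acquire spurious
$C_L$/$C_P$ and lose $C_S$, and averaging over an ROI does not remove this
systematic bias. At snr 30 with 20 directions the group ROI means recover
the painted triples within ±0.02 in WM; in the most spherical GM
structures (true $C_S \approx 0.88$) the $C_S$ bias reaches about −0.03,
the edge of what per-voxel averaging can deliver at these settings. A
Monte Carlo with an independent implementation reproduces the same bias,
confirming it is a property of the estimator at these acquisition
settings, not of this code. Real-data differences between groups are
therefore best interpreted via contrasts (which share the bias) rather
than absolute shape values.

The phantom does not emulate: partial-volume mixtures beyond the
two-tensor crossing model, spatially varying $S_0$ or $T_2$, eddy-current
or susceptibility distortion, anatomically realistic geometry, or
non-Gaussian (kurtosis / multi-exponential) diffusion — the single-tensor
model is the object of study, and its inadequacy in complex GM is part of
what the shape metrics quantify.
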