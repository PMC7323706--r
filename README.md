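# dtishape

Diffusion tensor *shape* analysis for neuraxial MRI: who needs it and what
it does. In diffusion tensor imaging (DTI), each voxel's water diffusion is
modeled by a symmetric 3×3 tensor **D**; its ordered eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ summarize local microstructure. Beyond the familiar
fractional anisotropy

FA = √(½ [(λ₁−λ₂)² + (λ₁−λ₃)² + (λ₂−λ₃)²] / (λ₁² + λ₂² + λ₃²)),

the Westin decomposition splits tensor shape into linear, planar and
spherical anisotropy

C_L = (λ₁−λ₂)/tr, C_P = 2(λ₂−λ₃)/tr, C_S = 3λ₃/tr, tr = λ₁+λ₂+λ₃,

a barycentric triple (C_L + C_P + C_S = 1) that distinguishes stick-like,
pancake-like and sphere-like diffusion — information FA alone collapses.
These shape ratios have been used to stage white- and gray-matter changes
in neurodegeneration, e.g. in the spinal cord and brain of the G93A-SOD1
ALS mouse, where white-matter FA, C_L and C_P fall and C_S rises as
disease progresses.

The package is aimed at researchers who want to work with these metrics
quantitatively: it provides

* `dti_fit()` — voxelwise log-linear least-squares tensor estimation (OLS,
  optional WLS) returning a classed model object with `print`, `summary`,
  `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot` (shape
  triangle) methods;
* `fractional_anisotropy()`, `westin_metrics()`, and the closed-form
  inverse `shape_to_eigenvalues()` that turns a published (C_L, C_P, C_S)
  triple back into eigenvalues;
* a synthetic neuraxial phantom (`generate_phantom()`, `run_phantom()`)
  that paints published per-structure, per-group shape targets into
  stylized brain-slab and spinal-cord geometries, simulates a single-shell
  acquisition (one b = 0 plus 20 directions at b = 1000 s/mm², 200 µm
  isotropic) and adds Rician noise — for validating pipelines by parameter
  recovery;
* two-compartment crossing-fiber simulation (`crossing_signal()`,
  `run_crossing_sweep()`);
* ROI group statistics (`build_summary_table()`, `compare_groups()`):
  per-subject ROI means, mean ± SEM, integer percent changes, one-way
  ANOVA with Tukey post hoc and Mann–Whitney tests;
* NIfTI / FSL bval-bvec / CSV / JSON readers and writers (`read_dwi()`,
  `write_metric_maps()`, …) and a command-line front end
  (`inst/cli/dtishape.R`, subcommands `phantom`, `fit`, `roi-table`,
  `compare`, `crossing-sweep`).

See the vignette `vignettes/tensor-shape-phantoms.Rmd` for the model,
phantom design, parameter defaults and known limitations.

## Worked example

Simulate a symptomatic-stage (P120) spinal-cord phantom at SNR 30, fit the
tensor field, and summarize two regions:

```r
library(dtishape)

cfg <- phantom_config(group = "P120", snr = 30,
                      geometry = "spinal_cord", seed = 42)
ph  <- generate_phantom(cfg)
b0  <- ph$data[, , , 1]
fit <- dti_fit(ph$data, ph$scheme,
               mask = as.vector(b0 > 0.1 * quantile(b0, .99)))
summary(fit)
#> Diffusion tensor fit summary (ols)
#>   voxels fit: 36785 of 110592 | degenerate: 0 | eigenvalue-clamped: 397 | clamped log-signals: 0
#>      mean     sd
#> fa 0.4841 0.1443
#> cl 0.2512 0.1029
#> cp 0.1843 0.1277
#> cs 0.5645 0.1569
#> md 0.0005 0.0001

sm <- shape_metrics(fit)
roi_means(sm$cl, ph$labels, label_scheme()$SC_wm)$mean
#> [1] 0.2946
```

The fitted spinal-cord WM mean C_L ≈ 0.295 recovers the painted
symptomatic-group target (0.290 renormalized ≈ 0.293) to well within the
noise floor, versus 0.410 for wild type — a 29% decrease:

```r
percent_change(0.410, 0.290)
#> [1] -29
```

The crossing-fiber mechanism — why a single-tensor fit of two crossing
populations looks more spherical and less linear:

```r
run_crossing_sweep(fractions = seq(0, 0.5, 0.25))
#>   angle fraction    fa      cl    cp    cs
#> 1    90     0.00 0.660 0.41000 0.150 0.440
#> 2    90     0.25 0.511 0.20535 0.338 0.457
#> 3    90     0.50 0.435 0.00114 0.536 0.462
```

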