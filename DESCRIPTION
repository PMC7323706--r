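Package: dtishape
Title: Diffusion Tensor Shape Metrics, Synthetic DWI Phantoms, and ROI
    Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates diffusion tensors from diffusion-weighted MRI by
    log-linear least squares and computes tensor shape metrics: fractional
    anisotropy and the Westin linear, planar and spherical anisotropy
    ratios (CL, CP, CS).  Includes a synthetic neuraxial phantom generator
    that paints per-structure ground-truth tensors (brain slab and spinal
    cord geometries, coherent/dispersed/random fiber orientation, two-tensor
    crossing voxels) and simulates a single-shell acquisition with Rician
    noise; region-of-interest summaries with percent changes, one-way
    ANOVA with Tukey post hoc tests and Mann-Whitney comparisons; and
    NIfTI/bval/bvec readers and writers for the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
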