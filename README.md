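# gliofuse

Non-invasive glioma grading from fused MRI contrasts. `gliofuse` is an R
package for studies that combine an apparent-diffusion-coefficient (ADC) map
and a susceptibility-weighted image (SWI) of the same brain slice into one
fused image, score how much source information the fusion retains, and then
classify tumour grade from the fused image's tumour-to-white-matter contrast.
It is aimed at medical-imaging researchers who want the whole chain —
cohort simulation, preprocessing, fusion, quality metrics, and the clinical
ROC analysis — reproducible from one seed.

## What it computes

**Fusion.** Four classical algorithms, implemented from first principles on
float intensities with a single quantization at output:

* `fuse_pca()` — weights from the leading eigenvector of the 2×2 covariance
  of the two pixel vectors, `w_i = v_i / (v_1 + v_2)`;
* `fuse_dchwt()` — orthonormal 2-D DCT partitioned into dyadic harmonic
  sub-bands; absolute-maximum selection of detail coefficients, averaged
  approximation; exactly invertible;
* `fuse_structure_aware()` — guided-filter two-scale split with per-pixel
  weight maps from smoothed gradient-magnitude saliency, normalized to sum
  to 1;
* `lrd_fuse()` — Laplacian re-decomposition: gradient-domain enhancement
  (Poisson reintegration of amplified gradients), Laplacian pyramid,
  decision split of each sub-band into overlapping / non-overlapping
  domains by local energy, energy-weighted vs winner-take-all fusion rules,
  local-energy-maximum base fusion, inverse pyramid.

**Quality metrics** (`img_entropy`, `img_std`, `img_psnr`, `ssim_pair`):
Shannon entropy of the L-bin histogram (0–8 bits for 8-bit images),
population standard deviation, `PSNR = 10 log10(L² / RMSE²)`, and the
structural similarity index computed from global image moments,
`SSIM(A,B,F) = (SSIM(A,F) + SSIM(B,F)) / 2`.

**Grading** (`rsc`, `compare_groups`, `roc_analysis`, `grading_table`): the
relative signal contrast

```
RSC = (mu_ROI - mu_WM) / mu_WM
```

with two-stage averaging over three tumour and three white-matter circular
ROIs; equal-variance two-tailed t-test between low-grade (LGG) and
high-grade (HGG) groups with a Kolmogorov–Smirnov normality check; empirical
ROC whose AUC equals the normalized Mann–Whitney statistic, with the cutoff
at the maximum Youden index `J = sensitivity + specificity − 1`. Lower RSC
predicts HGG (HGG tumours are darker than LGG on both contrasts).

**Synthetic cohorts** (`phantom_config`, `generate_cohort`): seeded paired
ADC/SWI slice phantoms — brain ellipse, white-matter annulus, one disk
tumour with grade-dependent mean contrast, per-subject severity variation,
Rician noise, optional SWI misalignment with known landmarks. The default
cohort is 96 subjects, 59.3 % HGG.

## Worked example

```r
library(gliofuse)

cfg <- pipeline_config(seed = 7, out_dir = "run1")
res <- run_pipeline(cfg)     # 96 subjects at 128 px, 4 fusion methods
print(res$grading_report)
```

Output from that exact run:

```
ROC grading table (methods with significant LGG/HGG RSC difference):
          method  cutoff    auc sensitivity specificity youden   p_value  direction
             PCA -0.2190 0.9240      0.8421      0.8974 0.7395 5.974e-16 lgg_higher
           DCHWT -0.2047 0.9253      0.8596      0.8974 0.7571 3.902e-16 lgg_higher
 STRUCTURE_AWARE -0.2983 0.9226      0.7895      0.9487 0.7382 6.342e-16 lgg_higher
             LRD -0.3471 0.9096      0.7895      0.8974 0.6869 1.546e-15 lgg_higher
Highest AUC: DCHWT
Note: p-values are per method; no multiple-testing correction applied.
```

Reading it: every fusion method preserved a significant RSC gap between the
grades (LGG contrast higher, as designed into the cohort), and classifying
"HGG when RSC ≤ cutoff" at the Youden-optimal cutoff reaches an AUC of about
0.91–0.93 on this synthetic cohort — the scale set by the generator's
between-subject severity spread, not a clinical claim. `run1/` also gets
`quality.csv` / `quality_summary.csv` (per-method entropy, STD, PSNR, SSIM
averages; the LRD row carries the highest entropy and STD, i.e. the most
retained contrast), `rsc.csv`, `grading.csv`, `demographics.csv`, a full
parameter dump in `config.yaml`, and `run.log`.

A shell entry point with the same functionality lives at
`inst/cli/gliofuse` (`gliofuse all --config cfg.yaml`, `gliofuse phantom
--out dir/`).

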