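# petmoco

MR-driven cardiorespiratory motion compensation for simultaneous
[18F]NaF PET/MR coronary plaque imaging — implemented end to end at desk
scale, with the simulators needed to validate every stage against a known
ground truth.

## The problem

Focal [18F]NaF uptake in coronary plaques is only a few millimetres wide.
Respiration and the heartbeat smear it, and they also misalign the
attenuation-correction (AC) map with the emission data; at the
lung–soft-tissue boundary, where attenuation changes four-fold, that
misalignment produces the crescent-shaped "banana" artefact right where the
coronaries run. In simultaneous PET/MR, the MR data acquired alongside the
PET can be retrospectively sorted into motion states, non-rigid motion
models estimated from the motion-resolved images, and both the emission
data and the AC map corrected *inside* the PET reconstruction
(motion-corrected image reconstruction, MCIR).

## What the package does

* **Dynamic thorax phantom** (`build_phantom`, `deform`,
  `generate_surrogates`): a 2D coronal slice with lungs, diaphragm, heart,
  chest fat, a 3-mm coronary plaque and an optional stented region;
  analytic, invertible respiratory + cardiac deformations with exact
  ground-truth displacement fields; respiratory belt, MR self-navigator
  and ECG R-peak surrogates.
* **Multi-echo Dixon radial MR simulation** (`simulate_acquisition`):
  golden-angle radial k-space of the moving phantom; echo `e` samples
  `W + F exp(i 2 pi df TE_e)`.
* **Motion-resolved water/fat reconstruction** (`bin_kspace`,
  `reconstruct_waterfat`): 6 equal-count respiratory amplitude bins /
  12 cardiac phase bins; CGLS with chemical-shift mixing, density
  compensation, and optional warps inside the encoding.
* **Motion models** (`register_pair`, `build_model`,
  `concatenate_models`): B-spline registration minimising the
  dual-channel cost

  `C(m) = w S(|W| o m, |W|_ref) + (1-w) S(|F| o m, |F|_ref) + r R(m)`

  with S = normalised mutual information, R = bending energy, w = 0.5;
  respiratory and cardiac models concatenate into a cardiorespiratory
  model; the belt is time-aligned to the self-navigator
  (`align_belt`) and extends the binning over the whole PET scan
  (`extend_mapper`).
* **MR-based attenuation correction** (`segment_tissues`,
  `inpaint_stent`, `assign_mu`, `warp_mu`): k-means 4-tissue
  segmentation of the motion-corrected water/fat image
  (air/lung/fat/soft), morphological inpainting of stent signal voids,
  511-keV coefficients, per-state warping.
* **PET simulation and reconstruction** (`simulate_pet`, `osem_avg`,
  `osem_mcir`): per-motion-bin Poisson sinograms; OSEM (21 subsets,
  3 iterations, 4-mm Gaussian post-filter) either motion-averaged (AVG)
  or motion-corrected (cr-MCIR) with warped image estimate *and* warped
  AC map.
* **Plaque quantification** (`plaque_signal`, `tbr_cbr`, `fit_profile`,
  `measure_plaque`, `summarize_study`, `wilcoxon_signed_rank`):
  target-to-background ratio TBR = s/b (plaque signal from a 5x5 patch
  with Otsu foreground selection; background from a left-ventricle
  blood-pool ROI), contrast-to-background ratio CBR = |s-b|/sd(b), and
  hotspot width D = 2 sqrt(2 ln 2) c from a constrained Gaussian+linear
  profile fit `l(x) = a exp(-(x-b)^2/(2 c^2)) + d x + e`; study tables
  summarised with means, sample SDs and exact Wilcoxon signed-rank tests.

`run_full()` chains all stages with per-stage caching, artifact output
(NIfTI/CSV/YAML) and a hash manifest; `inst/cli/petmoco.R` is a thin
command-line wrapper.

## Worked example

```r
library(petmoco)

tb <- plaque_study_table()   # built-in 10-plaque reference study table
summarize_study(tb)$mean
#>  TBR_stat  TBR_dual TBR_ratio  CBR_stat  CBR_dual CBR_ratio FWHM_stat
#>      1.67      1.78      6.70      5.51      6.46     25.70     14.91
#> FWHM_dual FWHM_ratio
#>     11.02    -22.60
round(summarize_study(tb, method = "normal")$p, 2)
#>  TBR  CBR FWHM
#> 0.02 0.04 0.01
```

Motion-averaged TBR across the table is 1.67; motion correction raises it
to 1.78 (+6.7% mean), raises CBR from 5.51 to 6.46, and narrows the fitted
hotspot width from 14.9 mm to 11.0 mm (−22.6% mean); all three paired
differences are significant at p < 0.05.

The same quantities on the synthetic study (default moving phantom,
several minutes of compute):

```r
res <- run_full(run_config(seed = 0L))   # several minutes
res$study_row
#>  TBR_stat TBR_dual TBR_ratio CBR_stat CBR_dual CBR_ratio FWHM_stat FWHM_dual
#> 0.3958646 0.474745        20 5.082679 9.346833        84  10.88498  7.192968
#> FWHM_ratio
#>        -34
```

Motion correction raises the synthetic plaque's TBR by 20% and CBR by
84%, and narrows the fitted hotspot width from 10.9 mm to 7.2 mm (-34%) —
the direction of the published study. The absolute TBR sits below 1
because the reconstructed peak of a 3-mm plaque at three times blood
activity stays below the adjacent blood pool after the 4-mm filter; the
change ratios, not the absolute level, are the quantity of interest, and
a single synthetic realisation can fall anywhere in the published
per-plaque spread (which itself includes negative TBR changes).

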