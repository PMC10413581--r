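# wmhseg

3D segmentation of white-matter hyperintensities (WMH) on FLAIR-like MRI,
lesion volumetry, and the cohort statistics that relate WMH burden to
cognition — in one R package, runnable end-to-end on synthetic data.

WMH are the bright white-matter lesions seen on T2-FLAIR in cerebral small
vessel disease; their total volume tracks cognitive decline across
dementia, mild cognitive impairment (MCI), and no cognitive impairment
(NCI). The package is aimed at researchers who want (a) an inspectable,
dependency-light implementation of an attention-gated residual 3D
encoder–decoder for WMH segmentation, (b) the volumetric agreement score
used to compare segmentation methods case by case, and (c) the standard
covariate-adjusted statistics (partial correlation, one-way ANOVA with
Fisher's LSD) applied to WMH volume and neuropsychological scores.

## What is inside

**Segmentation network.** An L-level 3D encoder–decoder (default L = 4,
8 base channels, ~430k parameters). The encoder adds *cross-level residual
shortcuts*: the input of level *l* is
`down(y[l-1]) + alpha_l * P(y[l-1]) + gamma_l * P(y[l-2])`, with `P` a
strided 1³ projection and `alpha`, `gamma` learnable scalars. The decoder
gates each upsampled feature map with a spatial attention map
`I_s = sigmoid(conv7([mean_c; max_c]))` in (0,1), fuses the encoder skip
residually (`Z = ReLU(I_s ⊙ u + proj(skip))`), and trains per-level deep
supervision heads under a soft-Dice + cross-entropy loss with weights
`0.5^d`. Everything runs on a small reverse-mode autodiff tape (R + C++
convolutions); every gradient is finite-difference checked in the tests.

**Volumetry.** `lesion_volume()` converts masks to mm³ via the NIfTI voxel
spacing (2×2×2 mm = 8 mm³ by default). `signed_ratio()` scores volume
agreement: `s/o` when the segmentation under-estimates, `1 - s/o` when it
over-estimates — 1 is perfect, negative flags over-segmentation.
`block_means()` reproduces the reference tables' per-block (5-case)
summaries. The printed reference tables (60 cases, three methods) ship as
CSV in `inst/extdata`.

**Cohort statistics.** `partial_correlation()` (residualize WMH volume and
score on sex/age/education, Pearson on residuals),
`lsd_pairwise()` (pooled-MSE unadjusted pairwise t tests), and
`group_summary()`, bundled by `analyze_cohort()`.

**Synthetic generator.** `make_phantom()` builds FLAIR-like volumes with
ellipsoidal hyperintense lesions and exact masks; `make_cohort()` simulates
dementia/MCI/NCI cohorts with ordered lesion burden and scores linearly
coupled to volume (negative coefficients for MMSE/MoCA), so every analysis
has a testable stand-in for patient data.

## Worked example

```r
library(wmhseg)

# a reproducible FLAIR-like phantom with ground-truth WMH mask
ph <- make_phantom(phantom_spec(seed = 7))
lesion_volume(ph$mask)
#> [1] 3288

# train the network on it (CPU, deterministic), predict, binarize
model <- train_segmenter(list(ph), seg_train_config(steps = 500, seed = 7))
prob  <- sliding_window_predict(model, ph$image)
mask  <- binarize(prob)

soft_dice(prob, ph$mask)
#> [1] 0.985613
lesion_volume(mask)
#> [1] 3288
signed_ratio(lesion_volume(mask), lesion_volume(ph$mask))
#> [1] 1
```

The network recovers the phantom's 3288 mm³ lesion load exactly (signed
ratio 1); the soft-Dice of 0.986 says the probability map, not just the
thresholded mask, matches the ground truth.

On the reference volume tables:

```r
signed_ratio(29474, 29836)   # dementia case 1, proposed method
#> [1] 0.9879
signed_ratio(17592, 12898)   # an over-segmented case
#> [1] -0.3639
block_means(wmh_reference_volumes_long(), block = 5)  # per-block summaries
```

And a synthetic cohort through the statistics:

```r
rec <- make_cohort(cohort_spec(seed = 1))   # n = 8 + 82 + 44
report <- analyze_cohort(rec)
dplyr::filter(report$correlations, score %in% c("mmse", "moca"))
#> # A tibble: 2 x 6
#>   score     n      r    df statistic  p_value
#>   <chr> <int>  <dbl> <dbl>     <dbl>    <dbl>
#> 1 mmse    134 -0.879   129     -21.0 2.38e-43
#> 2 moca    134 -0.872   129     -20.2 8.04e-42
```

Larger WMH volume, lower MMSE/MoCA — the negative correlations are strong
and far below p = 0.001, as the generator builds in.

A thin command-line interface over the same functions lives at
`inst/cli/wmhseg.R` (`synth`, `train`, `predict`, `quantify`, `stats`,
`pipeline` subcommands); `run_wmh_pipeline()` chains all stages and writes
config, checkpoint, masks, and CSV reports to an output directory.

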