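# retseg

Quantitative evaluation of HE-stained retinal histology sections in R.

Early retinal neurodegeneration — the phenotype of the monosodium-glutamate
(MSG) mouse model of metabolic syndrome — appears in sections as subtle
thinning of the inner plexiform (IPL), inner nuclear (INL) and nerve fiber
(RNFL) layers and loss of ganglion cells. retseg replaces eyeball scoring
with a measurable pipeline:

1. **Segmentation** — a fully convolutional U-Net (VGG-style encoder at 5
   scales, 2× max-pool downsampling, transposed-convolution upsampling,
   U-shaped skip connections) augmented with Spatial Group-wise Enhance
   (SGE) attention after every encoder stage, classifying each pixel into
   Background / CELL / INL / IPL / OPL / RNFL. The network, backpropagation
   and Adam optimizer are implemented in base R on BLAS (no deep-learning
   framework is required); gradients are finite-difference verified.
2. **Morphometry** — thresholding, binarization, erosion/dilation,
   8-connected domains and small-object filtering reduce a label map to ten
   parameters: areas `S_R, S_IPL, S_INL, S_OPL`, ganglion-cell count `A` and
   total area `S_A` (adherent clumps split by the bounding-box aspect ratio
   `max(w,h)/min(w,h)`), and mean thicknesses `H_R, H_IPL, H_INL, H_OPL`
   (mean per-column vertical extent).
3. **Evaluation** — pixel accuracy `PA = (TP+TN)/(TP+FP+FN+TN)`, per-class
   recall and its mean MPA, `IOU = TP/(TP+FP+FN)` and MIOU.
4. **Statistics** — percent-of-control scaling (control mean = 100%) and
   one-way ANOVA with significance tiers `* p<0.05, ** p<0.01, *** p<0.001`.
5. **Synthetic ground truth** — a seeded generator of layered HE-like
   phantoms with exact label maps and known morphometry, including an
   `msg_like` condition (IPL/INL ×0.6, RNFL ×0.7, cells ×0.6), so every
   stage is testable without real data.

## Worked example

```r
library(retseg)

sec <- generate_section(phantom_spec(seed = 7))   # 256 x 192 control phantom
profile_section(sec$labels, morpho_config())
#> Morphometric profile:
#>         S_R       S_IPL       S_INL       S_OPL         S_A           A
#> 4257.000000 7203.000000 5632.000000 2519.000000  764.000000   10.000000
#>         H_R       H_IPL       H_INL       H_OPL
#>   16.628906   28.136719   22.000000    9.839844
```

Areas are pixel counts, thicknesses mean per-column pixel extents (supply
`pixel_size_um` for µm). `A = 10` recovers the planted cell count exactly,
clumps included. A two-group cohort with the MSG-like phenotype:

```r
cohort   <- generate_cohort(8, phantom_spec(seed = 7), seed = 42)
profiles <- profile_cohort(cohort, source = "labels")
cmp      <- compare_profiles(profiles)
subset(cmp, group == "model" & parameter %in% c("A", "H_IPL", "H_INL", "H_OPL"))
#>  parameter percent_of_control F_vs_control p_vs_control tier
#>          A           60.49383    65.163636 1.232916e-06  ***
#>      H_IPL           63.45240    98.580533 1.020548e-07  ***
#>      H_INL           60.22997   244.152196 2.961119e-10  ***
#>      H_OPL          107.52700     2.562221 1.317614e-01   ns
```

The planted thinning (IPL/INL ≈ 60% of control, untouched OPL
non-significant) is recovered and starred as in a percent-of-control panel.

Training and end-to-end runs:

```r
cfg <- pipeline_config(seed = 1, out_dir = "out",
                       training = list(epochs = 4L))
run_pipeline(cfg)   # synth -> train -> evaluate -> quantify -> compare
```

or from the shell via the installed CLI script (`exec/retseg` in the source
tree; under `<library>/retseg/exec/retseg` after installation):

```sh
Rscript exec/retseg run-all --seed 1 --out out
Rscript exec/retseg quantify --config inst/extdata/demo-config.yaml --out out
```

Artifacts: section PNGs + single-channel label PNGs and a manifest CSV, a
model checkpoint and history CSV (the learning rate during epoch *e* is
`0.001 * 0.92^e`), a metrics CSV/JSON, a profiles CSV with the ten
parameters per section, and a comparison CSV/JSON with percent-of-control,
F, p and tiers. Every file embeds the run's configuration hash.

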