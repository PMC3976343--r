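# mscmorph

Label-free, image-based prediction of human bone marrow-derived mesenchymal
stromal cell (hBMSC) potency. Cultured hBMSCs lose their osteogenic,
adipogenic and chondrogenic differentiation potentials and their
proliferative capacity across passages, but the conventional readouts
(histochemical staining after weeks of differentiation; population doubling
time over repeated passages) are destructive and slow. `mscmorph`
implements a pipeline that predicts those four potency values from
phase-contrast images taken during the first four days of expansion
culture, and benchmarks that prediction against gene-expression-based and
mean-baseline alternatives.

The package is aimed at computational biologists working on image-based
cell quality control: it contains a fully seeded synthetic-data generator
that emulates the complete study design, so every stage is testable
end-to-end without any external data.

## The method

For each sample (one lot at one passage), all segmented cell objects from
~20 images per time point are pooled into per-feature population
distributions. Nine morphological features are measured per object --
breadth, elliptical form factor, fiber breadth, fiber length, hole area,
inner radius, relative hole area, shape factor (4&pi;A/P&sup2;), total
area -- plus the object count as a tenth feature. Distributions are
summarised by AVE, quantiles Q10/Q25/Q50/Q75/Q90, MED, INT (interquartile
range), robust skewness (Q75+Q25-2&middot;Q50)/INT and robust kurtosis
(Q90-Q10)/INT, and converted into six fixed-length "M-pattern" feature
vectors (lengths 40/184/138/148/46/46) that differ in quantile detail and
in whether statistics are "linked" across time points as ratios.

Teacher signals are the Alizarin-red pixel count (osteogenic), the Oil-red
stained droplet area (adipogenic), the Alcian-blue stained fraction of the
pellet (chondrogenic), and PDT = T&middot;ln2 / ln(n_harvest/n_seed)
(hours). Prediction models are L1-penalised (sparsity-inducing) linear
regressions minimising (1/2n)&middot;RSS + &lambda;&middot;||&beta;||&#8321;,
with &lambda; selected by leave-one-out cross-validation over a 100-point
log grid from &lambda;_max down to 10&#8315;&#8308;&middot;&lambda;_max;
reported per-sample predictions are nested-LOOCV out-of-fold values. The
benchmark evaluates 9 input configurations (NULL mean-predictor; 69 genes;
genes + M-pattern 1; M-patterns 1-6) &times; 4 potentials = 36 models on
two criteria: the scaled error rate (median over samples of
|ŷ&minus;y|/y) and the pooled Pearson correlation.

## Worked example

```r
library(mscmorph)

# a reduced design: 2 lots x 8 passages (P2-P9), 2 fields per sample
cfg <- synthetic_config(n_lots = 2, passages = 2:9, n_wells = 1,
                        n_fields = 2, seed = 19)
gs <- generate_image_set(cfg)          # renders 128 images in memory
m  <- measure_image(gs$images[[1]], threshold = gs$truth$threshold,
                    min_area = 50)
m$object_count
#> [1] 14
round(m$objects[1, c("total_area", "elliptical_form_factor",
                     "shape_factor")], 3)
#>   total_area elliptical_form_factor shape_factor
#> 1       1245                  4.095        0.518

bundle <- simulate_feature_bundle(cfg) # features + genes + teachers
bm <- run_benchmark(bundle, models = c(1, 4), potential_types = "adipo")
bm$results[, c("label", "scaled_error_rate", "correlation", "fold_vs_null")]
#>                   label scaled_error_rate correlation fold_vs_null
#> 1 NULL (mean predictor)        0.29563843          NA       1.0000
#> 2           M-pattern 1        0.02414026   0.9885449      12.2467
```

The 14 segmented objects in the first field match the generator's ground
truth for that image; the first one is a spindle-shaped cell (1245 px² of
area, axis ratio 4.1, shape factor 0.52 -- elongated, far from a disk's
1.0). In the benchmark rows, the morphology-only model (M-pattern 1)
predicts the adipogenic teacher with a 2.4% median relative error versus
~30% for the mean-predictor NULL -- a 12-fold improvement -- and its
out-of-fold predictions correlate at r = 0.99 with the ground-truth
teacher values across the 16 samples.

A command-line front end over the same functions is installed at
`inst/scripts/mscmorph-cli.R` (subcommands `simulate`, `segment`,
`features`, `benchmark`).

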