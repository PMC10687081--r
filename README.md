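# trilodisp

Landmark-based geometric morphometrics and disparity analysis for
trilobite cephala and pygidia.

## What this is for

Quantifying *morphological* diversity of trilobites through deep time —
the complement to the taxonomic richness curves that occurrence databases
provide. The package implements a complete 2D landmark workflow for the
two digitised exoskeletal structures:

1. **Shape IO & validation** — read/write the two shape-file dialects
   (tpsDig `*.tps` and StereoMorph-style `*.txt`, one file per specimen
   per structure, named `<ID>_C` / `<ID>_P`), specimen metadata (YAML)
   and a references table (CSV); validate every configuration against the
   built-in templates: **cephalon** = 16 landmarks + 4 semilandmark
   curves (glabella LM2–LM7, facial suture LM10–LM12, anterior margin
   LM13–LM15, posterior margin LM4–LM15), **pygidium** = 7 landmarks +
   3 curves (axis LM1–LM2, border furrow LM3–LM6, margin LM4–LM5).
2. **Resampling & assembly** — equal arc-length resampling of each curve
   to a user-chosen number of semilandmarks, then assembly into the
   standard `p × 2 × n` array. Curve endpoints coincide with bound
   landmarks and are deduplicated, so cephala resampled to
   `c(12, 20, 20, 20)` give `16 + 10 + 3·18 = 80` points.
3. **Superimposition** — generalised Procrustes analysis (GPA) from first
   principles: for configurations `X_i`, centre, scale to unit centroid
   size `CS(X) = √Σ‖x_j − x̄‖²`, and iteratively rotate onto the
   consensus using the SVD solution of the two-shape problem, with proper
   rotations only (det R = +1). Tangent-space distances between aligned
   pre-shapes feed all downstream statistics.
4. **Morphospace** — covariance PCA of aligned coordinates (eigenvalues
   λ₁ ≥ λ₂ ≥ …, Σλ = total variance), with virtual-shape reconstruction
   `x(s) = x̄ + Σ sⱼ vⱼ` and per-stage occupancy tables.
5. **Disparity through time** — SoV (Σ per-axis variances), SoR (Σ
   ranges), NND (mean nearest-neighbour distance) per geological stage,
   with seeded percentile bootstrap; range-through richness
   standardisation from occurrence tables; a Devonian stage table with
   ICS ages is built in.
6. **Measurement error** — the data-quality protocol: within-observer,
   among-observer and among-genus pairwise Procrustes distance
   distributions, Kruskal-Wallis rank test, PERMDISP-style homogeneity of
   multivariate dispersions (ANOVA F on distances to group centroids,
   permutation p), and Tukey HSD contrasts.
7. **Synthetic data** — a fully seeded generator (multi-genus datasets
   with nuisance similarity transforms and defect injection; replicate
   digitisation experiments, including the misplaced-LM15 scenario) so
   every stage above is testable without downloads.

## Worked example

Simulate a six-genus Devonian cephalon dataset, run the full pipeline,
and validate measurement error:

```r
library(trilodisp)

sim  <- simulate_dataset(tempfile(), n_genera = 6, n_per_genus = 3, seed = 42)
cfgs <- read_shape_dir(file.path(dirname(sim$metadata_path), "cephala"),
                       "cephalon")
arr  <- fix_shapes(cfgs, k_per_curve = c(12, 20, 20, 20))  # 80 x 2 x 18
fit  <- gpa(arr)
space <- shape_pca(fit)
bins <- assign_bins(read_metadata(sim$metadata_path))
disparity_through_time(space, bins, n_boot = 200, seed = 42)
#>         bin  n    SoV SoV_lo SoV_hi    SoR    NND
#>  Lochkovian  0     NA     NA     NA     NA     NA
#>     Pragian  6 0.0319 0.0003 0.0326 0.7671 0.0267
#>      Emsian  9 0.0292 0.0156 0.0311 0.9018 0.0241
#>    Eifelian  9 0.0302 0.0159 0.0313 0.9106 0.0217
#>    Givetian 12 0.0316 0.0173 0.0342 1.1340 0.0237
#>    Frasnian 15 0.0405 0.0263 0.0473 1.3477 0.0243
#>   Famennian  9 0.0317 0.0142 0.0336 0.9593 0.0250
```

Each row is one stage: `n` specimens whose age range overlaps it, the
three disparity metrics on their PC scores, and 95% bootstrap bounds.
Empty or singleton bins report `NA`, not zero.

```r
ee <- simulate_error_experiment(seed = 42)   # defaults: sigma 0.01/0.02/0.2
error_report(ee$within, ee$among, ee$reference, n_perm = 999, seed = 42)
#> Measurement-error report
#>   mean within-group pairwise distances:
#>  among_genus    among_obs within_obs_1 within_obs_2
#>       0.5557       0.0689       0.0264       0.0273
#>   ratio to among-genus variation:
#>  among_genus    among_obs within_obs_1 within_obs_2
#>        1.000        0.124        0.048        0.049
#>   Kruskal-Wallis: chi-sq = 227.12, df = 3, p = 5.79e-49
#>   dispersion test: F = 224.109, permutation p = 0.001
```

Observer noise (within 0.026–0.027, among 0.069) sits an order of
magnitude below inter-generic variation (0.556) — the regime in which
multi-contributor landmark data are usable for disparity analyses.

## Command line

```sh
Rscript -e 'trilodisp::main()' simulate --out data/ --seed 42 --n-genera 6
Rscript -e 'trilodisp::main()' validate --dir data/cephala --structure cephalon
Rscript -e 'trilodisp::main()' gpa --dir data/cephala --curves 12,20,20,20 --out gpa/
Rscript -e 'trilodisp::main()' disparity --dir data/cephala \
    --metadata data/metadata.yml --seed 1 --out disp/
```

Every stochastic subcommand requires `--seed`; each run writes a
`manifest.txt` sufficient to reproduce it. Exit codes: 0 success, 1
validation failures, 2 usage/runtime errors.

## Documentation

The methods vignette (`vignettes/trilobite-morphometrics.Rmd`) documents
the model and its assumptions, every tunable parameter with its default
and rationale, the numerical conventions, what the synthetic generator
does and does not emulate, and known limitations.
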