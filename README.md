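# safconn

Histology-guided evaluation of short-range prefrontal tractography.

The prefrontal cortex (PFC) is interconnected by short association fibers
(U-fibers) linking adjacent gyri and neighbouring cytoarchitectonic areas.
Primate tract-tracing gives a near-ground-truth picture of which area pairs
are connected, while human diffusion tractography — the only in-vivo
window on these fibers — is prone to false positives. `safconn` implements
the evaluation machinery for confronting the two: it classifies
population-level tractography reconstructions of the 91 connections among
14 prefrontal areas (grouped into the dorsolateral, ventrolateral,
frontal-pole, orbitofrontal and cingulate partitions) against a packaged
histology reference, and quantifies test-retest and between-subject bundle
reproducibility. It is aimed at tractography researchers who have bundles
(MRtrix `.tck`) and want the classification, statistics and reliability
layer — tracking itself is out of scope.

## The model at the core

Per subject, a connection is *present* when its cleaned bundle keeps at
least 5 streamlines. Per population, with *f* the fraction of subjects
where it is present and plausibility a strict majority vote:

| histology | tractography | label |
|---|---|---|
| present | f > 0.5, plausible | **TP** (robust **RTP** when f > 0.8) |
| present | f > 0.5, implausible | **FP** (trajectory false positive) |
| present | f ≤ 0.5 | **FN** |
| absent | f > 0.5 | **FP** |
| absent | f ≤ 0.5 | **TN** |

From the label counts: accuracy = 100·(TP+TN)/n, sensitivity =
100·TP/(TP+FN), specificity = 100·TN/(TN+FP), precision = 100·TP/(TP+FP).

Bundle reproducibility is measured on streamline density maps (exact
segment-traversal voxelization, one count per streamline per voxel) with
the density-weighted Dice coefficient

wDice(A, B) = ½ · ( Σ_{v∈A∩B} w_A(v) + Σ_{v∈A∩B} w_B(v) ),  w_X(v) = c_X(v)/Σ c_X

and bundle adjacency, the mean nearest-neighbour distance (mm) between the
non-overlapping portions of two supports. A synthetic U-fiber phantom
(quadratic Bézier arc bundles between patch ROIs on a hemispheric shell,
with subject-, session- and streamline-level jitter and a spurious mode)
makes every stage testable without diffusion data.

## Worked example

Replicate the packaged benchmark — the 1,003-subject histology-guided
study of all 91 prefrontal connections:

```r
library(safconn)
histology_benchmark()
#> Histology concordance of the packaged 91-connection benchmark
#>
#>        scope n_connections tp rtp tn fp fn accuracy_rounded sensitivity_rounded
#>      overall            91 49  41 17 13 12               73                  80
#>        dlPFC            46 26  20  8  6  6               74                  81
#>        vlPFC            36 20  16  7  6  3               75                  87
#>  FrontalPole            13 12   9  1  0  0              100                 100
#>          OFC            36 12  11 10  6  8               61                  60
#>          ACC            36 13  11  8  8  7               58                  65
#>  ...
```

Reading the first row: of 91 candidate connections, 49 were reconstructed
and histologically supported (41 of them in over 80% of subjects), 17 were
correctly absent, 13 were false positives and 12 false negatives — 73%
accuracy, 80% sensitivity, 57% specificity, 79% precision. The frontal
pole is perfect (13/13); the cingulate is the weakest partition (58%).

Run the full pipeline on a phantom population with known ground truth:

```r
prof <- phantom_connection_profile()[1:5, ]
prof$presence_probability <- c(0.95, 0.65, 0.30, 0.95, 0.05)
prof$plausible_mode      <- c("u_arc", "u_arc", "u_arc", "spurious", "u_arc")
prof$histology_status    <- c("present", "present", "present", "present", "absent")
cfg <- phantom_config(n_subjects = 20, seed = 7, connections = prof,
                      n_streamlines = 20)
run <- run_pipeline(cfg)
run$outcomes[, c("area_a", "area_b", "population_fraction", "outcome_label")]
#>   area_a area_b population_fraction outcome_label
#> 1      8      9                1.00           RTP
#> 2      8     46                0.65            TP
#> 3      8   9/46                0.40            FN
#> 4      8     44                0.95            FP
#> 5      8     45                0.15            TN
```

The classifier recovers each connection's generative truth: the
95%-present plausible bundle is a robust true positive, the 30% one a
false negative, the consistently-present-but-implausible one a trajectory
false positive, and so on. `glance(run)`, `tidy()` and `autoplot()` give
summary, long-format and graphical views of every result type.

Individual stages are available as plain functions on tibbles and small S3
records: `read_tck()` / `write_tck()`, `filter_by_length()`,
`reject_outliers()`, `compute_density_map()` / `write_density_nifti()`,
`dice()` / `weighted_dice()` / `bundle_adjacency()`,
`classify_connections()`, `reliability_within()` / `reliability_between()`.

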