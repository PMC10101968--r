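# cytotomo

Simulation and analysis toolkit for **tomographic phase imaging flow
cytometry (TPI-FC)** — label-free identification of tumor cells against
a monocyte background from 3D refractive-index (RI) tomograms of single
rolling cells.

In TPI-FC, cells tumble while flowing through a microfluidic channel in
front of an off-axis holographic microscope. Each hologram yields a
quantitative phase map (QPM), the line integral of the RI contrast
along the optical axis:

    phi(x, y) = (2 pi / lambda) * integral of (n(x,y,z) - n0) dz

with `lambda = 0.532 um` and medium RI `n0 = 1.334`. Collecting QPMs
over a full rotation and applying filtered back projection (FBP)
slice-by-slice recovers the volumetric RI map `n(x,y,z)` on a 201^3
grid. From every tomogram the package measures a 44-feature descriptor
— 11 RI statistics (including dry mass), 9 3D morphology values
(volume, convex volume, sphericity, extent, solidity, principal-axis
lengths, centroid offset) and 24 Haralick statistics of the 3D
gray-level co-occurrence matrix averaged over 13 directions at probing
distances of 0.5 and 1 um — and feeds it to a **hierarchical
classifier**: a shallow ReLU network separates monocyte-like cells (MC)
from tumor cells, a second network types the tumor as neuroblastoma
(NB) or ovarian cancer (OC). Stage-A errors propagate into the final
three-class report. A 2D baseline (logistic regression + linear
discriminant on the same 44-style features of the 0-degree QPM alone)
quantifies what the third dimension buys.

Everything is generated in-package: a seeded, class-conditional phantom
generator emulates the three populations (tumor cells less spherical
than monocytes, OC cells with higher average RI than NB, distinct
texture statistics), and the measured data augmentation — intensity
scaling `U(0.9, 1.1)`, intensity shifting bounded by half the minimum
support contrast, morphological resizing by `U(-20, 20)` voxels per
axis, at 9x/3x/3x per MC/NB/OC training cell — expands the 700-cell
training split to 2000/1000/1000. A minimal digital-holography layer
(angular-spectrum propagation, Tamura-coefficient autofocusing,
off-axis synthesis/demodulation) makes the upstream optical
computations testable.

## Worked example

A miniature end-to-end experiment (a few seconds):

```r
library(cytotomo)

cfg <- experiment_config(
  grid_dim = 75, voxel_pitch = 0.3,
  counts = list(train = c(MC = 8, NB = 8, OC = 8),
                test  = c(MC = 4, NB = 4, OC = 4)),
  multiplicity = c(MC = 1, NB = 1, OC = 1),
  seed = 4)
ex <- run_experiment(cfg)
ex
#> <tpifc_experiment> grid 75^3 @ 0.3 um, mode ideal, seed 4
#>   3D: stage A acc 100.0%, stage B acc 87.5%, hierarchical acc 91.7%
#>   2D: stage A acc 91.7%, stage B acc 50.0%, hierarchical acc 58.3%
#>   3D - 2D hierarchical accuracy gap: 33.3 points

ex$reports$`3D`$hierarchical$confusion
#> <confusion_matrix> (rows = true, cols = predicted)
#>     predicted
#> true MC NB OC
#>   MC  4  0  0
#>   NB  0  3  1
#>   OC  0  0  4
```

With only eight training cells per class the 3D route already separates
monocytes perfectly and drops one NB cell at stage B, while the 2D
baseline struggles — the package's central comparison in miniature. On
the full benchmark both improve and the gap narrows but persists.
The full benchmark (train 200/250/250 with 9x/3x/3x augmentation, test
47/122/60) at the documented desk-scale geometry is one call:
`run_experiment(desk_config(seed = 1))` (several minutes; prints the
same report for 4229 cells).

Single-cell building blocks compose freely:

```r
params <- sample_class_params("NB", rng_seed = 7)
ph  <- generate_phantom(params, dim = c(81, 81, 81), voxel_pitch = 0.28)
qs  <- project_sequence(ph$tomogram, angles = (0:129) * 3)  # rolling cell
trk <- estimate_angles(qs)                                  # period: 120 frames
rec <- reconstruct_fbp(qs[1:120], trk)
f   <- features_3d(rec)          # named 44-vector
aug <- augment(ph$tomogram, 11)  # one augmentation draw
```

Metric-layer utilities reproduce a full confusion-table panel from
counts, with percentages rounded half-up to one decimal:

```r
cm <- cm_from_recalls(c(95.7, 97.8), c(47, 182), c("MC", "tumor"))
binary_metrics(cm)
#> <metric_report> accuracy 97.4%
#>                      MC tumor
#> recall (TPR)       95.7  97.8
#> specificity (TNR)  97.8  95.7
#> precision (PPV)    91.8  98.9
#> NPV                98.9  91.8
#> balanced accuracy  96.8  96.8
#> F1                 93.8  98.3
#> MCC                92.1  92.1
#> Fowlkes-Mallows    93.8  98.3
```

A thin CLI over the same functions lives at `inst/cli/cytotomo.R`
(subcommands `generate`, `augment`, `project`, `reconstruct`,
`features`, `run-all`).

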