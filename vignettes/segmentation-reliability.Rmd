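---
title: "Quantifying inter- and intra-operator segmentation reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter- and intra-operator segmentation reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Manual segmentation of metastatic bone lesions on CT — delineating, voxel by
voxel, which parts of a femur are tumour — is a prerequisite both for
patient-specific finite-element models of fracture risk and for radiotherapy
planning. It is also notoriously subjective: lesion boundaries are often
diffuse, osteoblastic lesions blend into dense cortical bone, and two trained
operators may not even agree on *how many* lesions a femur contains. Before a
segmentation protocol can feed quantitative models, its reliability has to be
measured.

`segrel` implements the standard reliability design for this problem: two
operators each segment every femur twice (sessions separated by weeks), and
agreement is quantified per femur across four comparison sets:

* **inter_1** — operator I vs operator II, first session;
* **inter_2** — operator I vs operator II, second session;
* **intra_I** — operator I, session 1 vs session 2;
* **intra_II** — operator II, session 1 vs session 2.

## Agreement metrics

For two binary segmentations $A$ and $B$ on a shared voxel grid the package
computes the volumetric Sørensen–Dice coefficient

$$\mathrm{DC} = \frac{2\,|A \cap B|}{|A| + |B|}$$

and the non-overlapping segmentation volume (the symmetric difference, in
cm³)

$$V_{\mathrm{non}} = |A| + |B| - 2\,|A \cap B|.$$

The Dice coefficient is computed on voxel *counts*, so the (anisotropic)
voxel volume cancels exactly; volumes are reported in cm³ because multicentre
CT data mix voxel sizes (in-plane 0.86–1.27 mm, slice 2.5–3 mm) and voxel
counts are not comparable across scans. The two metrics are linked by the
identity $V_{\mathrm{non}} = (|A| + |B|)(1 - \mathrm{DC})$, which the test
suite checks exhaustively on all mask pairs over a small grid.

Three conventions matter and are used consistently:

* **Per-femur union.** All lesions an operator segmented in a femur are
  merged (`merge_lesions_per_femur()`) before comparison, because operators
  do not always agree on the lesion count; Dice on unions is robust to
  split/merge disagreement.
* **Both-empty pairs are an error, not DC = 1.** A pair with no segmentation
  on either side carries no agreement information; silently scoring it 1
  would inflate reliability. One-empty pairs score 0, as the formula gives.
* **Strict thresholds.** "Good" reliability is DC strictly above 0.7, and
  the size strata are strictly above / below 60 cm³ with the boundary
  resolved to the lower stratum.

## The analysis pipeline

`assemble_study_table()` turns a validated cohort (from `load_cohort()` or
the generator) into one row per femur × comparison set. On top of that,
`compile_report()` produces:

* per-type mean ± SD of Dice and of mean segmentation volume
  (`summarize_by_type()`), where SD is the sample SD ($n-1$) — the standard
  choice for cohort summaries;
* per-set overall summaries (`summarize_overall()`); because lesion types
  partition the femurs, each overall mean equals the $n$-weighted mean of
  the per-type means exactly (`pool_group_means()` exposes that identity);
* size strata at 60 cm³ with good-DC fractions (`split_by_size()`), where a
  row's size is the mean segmentation volume $(|A|+|B|)/2$ of its own pair —
  the two operators within a session for inter rows, one operator's two
  sessions for intra rows;
* Kruskal–Wallis comparisons of per-femur Dice across the three lesion types
  (`test_dc_by_type()`), one per comparison set, with the two inter-operator
  sessions flagged as the primary tests. The rank test is used because
  per-femur Dice values are far from normal; with ~17–19 femurs per group
  the chi-square approximation (with tie correction) is adequate. The one
  degenerate case — all values identical, where the tie correction divides
  by zero — is defined as $H = 0$, $p = 1$ with a warning.

`run_analysis()` wires these together behind a validated configuration
(thresholds 0.7 / 60 cm³ / α = 0.05 by default) and writes CSV tables plus a
JSON report containing full-precision numbers and a 2-decimal presentation
copy; rounding happens only at report time.

## The synthetic cohort generator

Reliability studies of clinical CT rarely deposit their masks, so the
package ships a generator that emulates the full study design and makes every
analysis stage testable end to end. Its defaults encode the study conditions
the analysis is aimed at:

* 54 femurs — 19 osteolytic, 17 osteoblastic, 18 mixed — × 2 operators × 2
  sessions;
* grid 96 × 96 × 160 voxels at 0.98 × 0.98 × 3 mm spacing (mid-range of the
  multicentre voxel sizes);
* per-type lesion volumes from log-normal distributions moment-matched to
  published cohort summaries (osteolytic 14.48 ± 13.83 cm³, osteoblastic
  33.35 ± 32.42 cm³, mixed 41.2 ± 27.47 cm³). Log-normal rather than normal
  because the SDs are of the order of the means, so a normal model would
  generate negative volumes;
* a global inter-operator Dice target of 0.52 (the mean of the two published
  inter-session means) with per-femur dispersion 0.15, intra-operator boosts
  of +0.04 (operator I) and +0.19 (operator II) reproducing the qualitative
  ordering intra II > intra I ≈ inter, and a size–agreement slope of +0.07
  Dice per doubling of volume around a 20 cm³ pivot;
* a 10% chance per femur that one randomly chosen mask renders the lesion as
  two components (count disagreement), and ~12% log-normal jitter on each
  observed mask's volume.

### How a femur is generated

Each femur gets a hidden **reference lesion**: a connected, roughly
ellipsoidal implicit surface (random axis ratios in [0.5, 2], random
orientation) roughened by smooth noise, levelled so its volume matches the
sampled target within 5%. There is no ground truth in the real problem — it
is impossible to know which operator's segmentation is closest to the true
lesion — so the reference is a testing device recorded in the truth table
and never consumed by the analysis pipeline.

The four observed masks are *volume-preserving level sets* of a perturbed
field

$$M_{o,s} = \text{top-}n_{o,s}\ \text{voxels of}\ \;
F + \alpha\,O_o + \beta_o\,S_{o,s},$$

where $F$ is the reference field, $O_o$ an operator-systematic smooth noise
field (persistent across that operator's sessions), $S_{o,s}$ a
session-specific field, and $n_{o,s}$ the jittered voxel budget. All noise
is spatially correlated (Gaussian-smoothed, 4 mm correlation length) because
real operator disagreement displaces whole stretches of boundary — it is not
salt-and-pepper voxel noise. Fixing the voxel budget means the noise
amplitude controls *where* the mask sits, not how big it is, which keeps
volumes matched to the type distributions and lets Dice be driven close
to 0.

The amplitudes are calibrated per femur by bisection **on the measured
Dice**: each $\beta_o$ on that operator's intra-session Dice, and $\alpha$
on the mean of the two inter-session Dice values, to within ±0.03 (±0.06
for targets below 0.3, where Dice responds very steeply to amplitude). The
tolerance is a compromise between runtime and tightness. A secant
refinement follows the bisection because tolerance-stopped bisection lands
below the target slightly more often than above. Model feasibility imposes
two constraints the generator enforces: intra targets must exceed the inter
target (inter disagreement contains the session noise), and high-agreement
femurs get proportionally smaller volume jitter (Dice bounds the volume
ratio). When an inter target is still unattainable, the session amplitudes
are relaxed stepwise — intra agreement then settles above its target,
preserving the intra > inter ordering.

Count disagreement is a thin planar gap carved through the lesion (breaking
26-connectivity while removing < 10% of voxels); it participates in the
calibration, so splits do not bias the achieved Dice.

The whole cohort is a pure function of the configuration, including its
seed; equal seeds give byte-identical manifests and truth tables.

### What the generator does and does not emulate

It reproduces the study's *structure*: cohort composition, volume
distributions, controllable agreement with an intra/inter gap and a
size–agreement trend, occasional count disagreement, and anisotropic voxel
geometry. It does not model CT intensities, osteoblastic density appearance,
anatomy-driven disagreement (e.g. cortical-rim ambiguity), or systematic
per-operator volume bias. Passing tests therefore demonstrate that the
*pipeline* measures agreement correctly under realistic cohort structure —
not that any particular clinical cohort will show these numbers.

## Numerical choices and degenerate inputs

* Grids must match exactly (shapes equal, spacing within 1e-6 mm); no
  resampling is provided, since paired segmentations annotate the same scan.
* Binarisation maps any nonzero stored label to in-set; it is idempotent.
* Connected components use 26-connectivity, the standard for 3-D blob
  counting; Dice never depends on it because lesions are merged per femur.
* Incomplete femurs (fewer than 4 records) are excluded with a warning, not
  imputed — every paired statistic needs all four segmentations.
* Empty summary cells (a lesion type or size stratum with no femurs) are
  reported as absent, never as zero.
* Reference-lesion generation pushes detached satellite specks just below
  the implicit surface instead of rejecting the draw; rejection made large
  lesions near grid capacity unrealisable.

## Problem sizes in the test suite

The unit tests run on small grids (16³–80³) and tiny cohorts built in code.
The cohort-level checks run the full default design: 20 seeds × 54 femurs
for global target recovery (the recovered overall inter-operator Dice must
sit within 3 standard errors of the configured 0.55), 4 pooled seeds for the
size-stratum ordering, and 2000 null replicates at group sizes 19/17/18 for
the type-I error of the Kruskal–Wallis test, which must lie in
[0.035, 0.065] at α = 0.05.

## A complete run

```{r example}
library(segrel)

# simulate a full 54-femur study and analyse it
cfg <- synthetic_config(seed = 42)
sim <- simulate_study(cfg)
report <- compile_report(sim$study)
report

# or, on disk: write NIfTI masks + manifest, then analyse the manifest
dir <- tempfile("cohort_")
generate_cohort(cfg, dir = dir)
report2 <- run_analysis(file.path(dir, "manifest.csv"),
                        out_dir = file.path(dir, "report"))

autoplot(sim$study)           # Dice vs mean segmentation volume
plot_dice_by_type(sim$study)  # per-type distributions
tidy(kruskal_wallis(sim$study$dice[sim$study$set == "inter_1"],
                    sim$study$lesion_type[sim$study$set == "inter_1"]))
```

## Known limitations

* Boundary-distance metrics (Hausdorff, average surface distance) are out of
  scope by design: with operators disagreeing on lesion *count*, volume
  overlap is the meaningful outcome.
* The analysis offers no post-hoc pairwise tests, ICC or kappa.
* The generator's size–agreement slope is calibrated qualitatively (the
  published evidence is scatter plots, not tabulated per-femur data).
* Masks for one femur must share a voxel grid; cross-scan registration is
  not provided.
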