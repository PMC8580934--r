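# segrel

Reliability analysis of repeated manual 3-D segmentations — built for
inter- and intra-operator studies of metastatic bone lesions on CT, and for
anyone who needs per-case volumetric agreement statistics over a cohort of
paired binary masks.

## What it computes

Manual delineation of femoral bone metastases is hard: boundaries are
diffuse, operators disagree on lesion counts, and downstream users
(biomechanical fracture-risk models, radiotherapy planning) need to know how
reproducible the masks are. `segrel` implements the standard two-operator,
two-session design. For each femur it compares the four pairs —
operator I vs II within each session (*inter*), and each operator's two
sessions (*intra*) — using the volumetric Sørensen–Dice coefficient

```
DC = 2 |A ∩ B| / (|A| + |B|)
```

and the non-overlapping segmentation volume `|A| + |B| − 2|A ∩ B|` in cm³.
All lesions within a femur are merged before comparison, so the metrics are
robust to split/merge disagreement. On top of the per-femur table the
package produces per-lesion-type summaries (osteolytic / osteoblastic /
mixed), overall per-set means, size-stratified agreement at a 60 cm³
threshold with good-DC (> 0.7) fractions, and Kruskal–Wallis comparisons of
Dice across lesion types.

Because studies of this kind rarely deposit their masks, the package also
ships a calibrated synthetic-cohort generator (`synthetic_config()`,
`generate_cohort()`, `simulate_study()`): 54 femurs (19/17/18 per type),
log-normal lesion volumes matched to published cohort summaries, paired
masks whose Dice agreement is bisected per femur to controllable targets,
an intra > inter agreement gap, a size–agreement trend, and occasional
lesion-count disagreement. See the methods vignette
(`vignettes/segmentation-reliability.Rmd`) for the model.

## Worked example

```r
library(segrel)

cfg <- synthetic_config(seed = 42)   # the default 54-femur study design
sim <- simulate_study(cfg)           # generate + compare, in memory
report <- compile_report(sim$study)
report
```

```
<segrel_report> 54 femurs, 216 comparisons

Overall Dice per comparison set:
# A tibble: 4 × 8
  set          n dice_mean dice_sd non_overlap_mean non_overlap_sd volume_mean
  <chr>    <int>     <dbl>   <dbl>            <dbl>          <dbl>       <dbl>
1 inter_1     54     0.523   0.196             23.2           18.5        29.7
2 inter_2     54     0.539   0.178             23.0           19.2        29.9
3 intra_I     54     0.616   0.187             18.0           15.5        29.8
4 intra_II    54     0.753   0.144             11.8           11.2        29.8

Size strata (threshold 60 cm^3, good DC > 0.7):
# A tibble: 4 × 6
  kind  size_stratum     n dice_mean dice_sd good_dc_fraction
  <chr> <chr>        <int>     <dbl>   <dbl>            <dbl>
1 inter large           11     0.737   0.162            0.727
2 inter small           97     0.507   0.175            0.155
3 intra large           11     0.847   0.159            0.818
4 intra small           97     0.666   0.173            0.474

Lesion-type Kruskal-Wallis tests:
# A tibble: 4 × 6
  set      primary statistic    df p.value significant
  <chr>    <lgl>       <dbl> <int>   <dbl> <lgl>      
1 inter_1  TRUE         4.65     2  0.0979 FALSE      
2 inter_2  TRUE         3.07     2  0.215  FALSE      
3 intra_I  FALSE        4.90     2  0.0861 FALSE      
4 intra_II FALSE        1.02     2  0.602  FALSE
```

Reading the output: inter-operator agreement averages DC ≈ 0.52–0.54 with
intra-operator agreement higher (operator II ≈ 0.75 — the only set above the
good-reliability line of 0.7); femurs with mean segmentation volume above
60 cm³ are mostly segmented with good agreement (73–82% of them above
DC 0.7) while small lesions are not; and Dice does not differ significantly
between osteolytic, osteoblastic and mixed lesions (p > 0.05 in the primary
inter-operator tests).

To work from files instead: `generate_cohort(cfg, dir = "cohort/")` writes
NIfTI masks, `manifest.csv` and a generation truth table, and

```r
run_analysis("cohort/manifest.csv", out_dir = "report/")
```

loads, validates, analyses and writes `per_femur.csv`, `per_type.csv`,
`overall.csv`, `per_size.csv`, `tests.csv` and `report.json`. The same
pipeline runs on any cohort of 3-D binary NIfTI masks with a five-column
manifest (`femur_id, operator, session, lesion_type, mask_path`). A thin
command-line wrapper lives at `exec/segrel`
(`segrel analyze|simulate|selftest`). Plot helpers: `autoplot(study)` (Dice
vs mean volume) and `plot_dice_by_type(study)`.

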