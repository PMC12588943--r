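# segagree

Inter-observer agreement analysis for tumour segmentations on 2-D
intraoperative ultrasound (iUS) stills.

When several clinicians outline "what they believe is tumour" on the same
B-mode image, how much do they agree — and how does that agreement depend on
tumour type, operative stage, and rater experience? `segagree` answers this
with:

- **Pairwise Dice similarity matrices.** For masks `A`, `B` on a common
  pixel grid, the Dice similarity coefficient is

  `DSC(A, B) = 2 |A ∩ B| / (|A| + |B|)`

  over foreground pixel sets: 1 for perfect overlap, 0 for disjoint
  segmentations. Every observer is compared against every other, giving
  `n(n−1)/2` values per image (153 for 18 observers) which are flattened
  into factor-tagged records (1,377 for a 9-image, 18-observer study).
- **Group summaries** (mean ± sample SD of DSC) by tumour type
  (metastasis / high-grade glioma / low-grade glioma), operative stage
  (before / during / near completion of resection), their crossing, and
  high-vs-low experience pairings.
- **Pixel agreement heatmaps.** Each pixel gets an aggregate score 0..n =
  how many observers included it; scores are banded green (> 80 %
  agreement), red (20–79 %) or white (< 20 %; for n = 18: green 15–18,
  red 4–14, white 0–3) and rendered as a transparent overlay on the
  original image.
- **Statistics**: tie-corrected Kruskal–Wallis with Dunn's post hoc
  (Bonferroni or Holm adjustment) across stages and tumour types, Spearman
  rank correlation of per-image mean DSC against mean difficulty rating
  (exact permutation p-value at n ≤ 9), and two-way ANOVA (Type II sums of
  squares) with Tukey HSD for the unbalanced experience contrast.
- **A deterministic synthetic study generator**: star-convex phantom
  tumours on a speckled background (with an optional posterior-enhancement
  band), a rater model with smooth boundary jitter, omission and spurious
  false-positive regions, and Likert difficulty ratings (1–10) linked to
  expected disagreement — so the whole pipeline is testable without
  clinical data.

Masks are read/written as 8-bit grayscale PNG or 2-D NRRD label maps (the
3D Slicer export dialect: any positive label is foreground); an all-zero
mask ("no tumour") is valid.

## Worked example

Simulate the canonical study (9 images = 3 tumour types × 3 stages,
18 observers) and summarise agreement:

```r
library(segagree)

ds   <- simulate_study(canonical_scenario(master_seed = 42))
mats <- lapply(ds$design$images$image_id, function(i)
  pairwise_dsc_matrix(lapply(ds$design$observers$observer_id,
                             function(o) get_mask(ds, i, o))))
rec  <- flatten_records(mats, ds$design)
nrow(rec)
#> [1] 1377

group_summary(rec, "stage")
#>       level  mean_dsc     sd_dsc   n
#>      before 0.9285027 0.02602257 459
#>      during 0.8320804 0.17001926 459
#>  completion 0.4943397 0.32808074 459

kruskal_wallis(rec$dsc, rec$stage)
#> Kruskal-Wallis rank sum test: statistic = 956.6, p = 1.904e-208

img_dsc  <- tapply(rec$dsc, rec$image_id, mean)
img_diff <- tapply(ds$difficulty$rating, ds$difficulty$image_id, mean)
spearman_cor(img_dsc[names(img_diff)], img_diff)
#> Spearman rank correlation: statistic = -0.958, p = 0.0002205
```

Agreement is near-perfect before resection, degrades during resection, and
breaks down near completion (mean DSC 0.93 → 0.83 → 0.49 here), and
images rated harder show lower agreement (negative rank correlation) —
the qualitative signature the simulator is built to emulate.

The one-command pipeline writes the full report bundle (per-image DSC
matrix CSVs, long-form records, group summaries, the statistics table,
banded overlay PNGs, and a manifest recording every convention used):

```r
run_pipeline(run_config(scenario = "canonical", out_dir = "report", seed = 42))
```

or, from a shell, via the installed script
`$(Rscript -e 'cat(find.package("segagree"))')/exec/segagree`:

```sh
segagree simulate --out study_dir --seed 42          # write a synthetic study
segagree run --config run.json                       # full pipeline
segagree report --records report/records.csv         # stats from records
```

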