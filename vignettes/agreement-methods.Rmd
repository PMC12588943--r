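---
title: "Measuring inter-observer segmentation agreement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-observer segmentation agreement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segagree)
```

## The problem

Intraoperative B-mode ultrasound is increasingly used to guide brain
tumour resection, but interpreting it is observer-dependent: the margin
between residual tumour, resection cavity and artifact (notably posterior
acoustic enhancement beneath fluid-filled cavities) is genuinely
ambiguous, and most ambiguous exactly when the surgeon needs it most —
near the end of resection. `segagree` quantifies this: given one binary
segmentation per observer per image, it measures pairwise overlap, maps
where on the image observers agree, and tests how agreement varies with
tumour type, operative stage, rated difficulty and observer experience.

## Agreement model

**Dice similarity.** For foreground pixel sets $A$ and $B$ on a common
grid,

$$\mathrm{DSC}(A,B) = \frac{2\,|A \cap B|}{|A| + |B|} \in [0, 1].$$

All $\binom{n}{2}$ observer pairs are scored per image. The statistic is
region-agnostic: observers may draw any number of regions (including
none) and each mask is the union of its regions, because a single
per-pair, per-image coefficient is wanted.

**The both-empty convention.** $\mathrm{DSC}$ is undefined when
$|A|+|B|=0$. Two observers who both report "no tumour" have, arguably,
agreed perfectly — and near-completion images make empty masks likely —
so the default policy scores both-empty pairs as 1 (`empty_policy =
"agree"`). `"zero"` and `"exclude"` are provided because the choice is a
convention, not a fact; every output flags convention cases
(`empty_pair`) and the run manifest records the policy used. A pair with
exactly one empty mask is always 0: that is a real disagreement, not a
convention.

**Pixel agreement maps.** Summing the $n$ binary masks gives each pixel
an aggregate score $0..n$ (how many observers called it tumour). Scores
are banded by the percentage rule — green above 80 % agreement, red
20–79 %, white below 20 % — realised for general $n$ as white
$[0, \lceil 0.2n \rceil - 1]$, red up to $\lfloor 0.8n \rfloor$, green
above. For $n = 18$: white 0–3, red 4–14, green 15–18. A count of 4/18
(≈ 22 %) therefore classifies as red; the ceil/floor realisation of the
20 % boundary is this package's documented choice, and `band_spec()`
accepts explicit ranges (rejecting gaps or overlaps at construction).
Overlays blend band colours onto the base image at `alpha = 0.5` by
default ("transparent" is otherwise unquantified); white-band pixels show
the base image unchanged.

## Statistics

Stage and tumour-type comparisons use the **tie-corrected
Kruskal–Wallis** statistic on the pairwise DSC records,

$$H = \frac{\frac{12}{N(N+1)}\sum_g R_g^2/n_g - 3(N+1)}
         {1 - \sum_t (t^3 - t)/(N^3 - N)},$$

with $p$ from $\chi^2_{k-1}$, followed by **Dunn's post hoc** z tests on
the pooled ranks with tie-corrected variance
$V = N(N+1)/12 - \sum_t(t^3-t)/(12(N-1))$. Dunn's adjustment is
Bonferroni by default (Dunn's original proposal; Holm available), and the
adjustment label travels with every result. These are authored from the
formulas and cross-checked in the test suite against base R's
`kruskal.test` and an independent rank-arithmetic oracle; for two groups
$z^2 = H$ is verified numerically.

Records entering these tests are the pairwise DSCs (1,377 in the
canonical design), treated as exchangeable observations. Pairs sharing an
observer are not independent; this caveat is deliberate and documented
rather than "fixed" — mixed-effects or permutation corrections for pair
dependence are out of scope. An option to aggregate per image before
testing is available through ordinary data manipulation of the records.

**Difficulty correlation.** Per-image mean DSC against per-image mean
Likert difficulty uses Spearman's $\rho$ (Pearson correlation of average
ranks, mean ranks for ties). With only 9 images the t approximation is
poor, so for $n \le 9$ the p-value is an exhaustive permutation
probability over all $n!$ label permutations (counting
$|\rho_\text{perm}| \ge |\rho_\text{obs}|$; the identity permutation
guarantees $p > 0$). Beyond that, the usual
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation is used.

**Experience.** A pairwise statistic has no single-observer attribution,
so the experience contrast uses within-band pairs only: both observers
high-experience (> 50 iUS cases) or both low (< 10); mixed and
middle-band pairs are excluded. This is the conservative reading, and the
more permissive "any pair touching a band" reading can be formed from the
records directly. With 5 high and 6 low observers the design is
unbalanced, so the two-way ANOVA (experience pairing × stage) reports
**Type II sums of squares** (`car::Anova`), followed by Tukey HSD on the
studentized range. SDs everywhere are sample SDs ($n-1$).

## The synthetic study generator

No clinical images ship with the package, so the generator produces
complete studies that exercise every pipeline stage:

- **Phantom** (`make_phantom`): a star-convex truth blob with radius
  $r(\theta) = r_0(1 + 0.12\,f(\theta))$, $f$ a smooth low-order harmonic
  field, $r_0$ set so the truth area is `area_frac` (default 0.10) of a
  128 × 128 grid. The base image is gamma-speckled background with the
  truth region brightened and an optional bright band beneath it,
  mimicking posterior acoustic enhancement.
- **Rater model** (`simulate_rater`): with probability `omission_prob`
  the rater segments nothing; otherwise the truth radius is perturbed by
  `boundary_jitter` (px) times a smooth harmonic field — disagreement at
  real margins is spatially coherent, not pixelwise noise, which is why a
  radial field was chosen over i.i.d. pixel flips — and with probability
  `spurious_prob` a disconnected false-positive disc of `spurious_size`
  px is added away from the blob.
- **Stage and type enter only through rater parameters** (there is no
  quantitative image model to copy): jitter 1.5 / 3 / 6 px and omission
  0 / 0.02 / 0.15 and spurious probability 0.02 / 0.05 / 0.15 for
  before / during / completion, jitter multipliers 0.8 / 1.0 / 1.3 for
  metastasis / HGG / LGG (progressively less distinct margins). These
  values were fixed once to reproduce the qualitative orderings of a
  real multi-rater iUS study — agreement decaying across stages,
  metastases easiest, gliomas harder — at desk scale.
- **Difficulty ratings**: integer Likert 1–10, drawn around
  `intercept + slope ×` (an analytic expected-disagreement proxy of the
  image's rater model), defaults `1 + 8·d` with unit Gaussian noise,
  rounded and clipped. Harder images therefore get lower agreement, giving
  the negative DSC–difficulty correlation by construction.
- **Determinism**: per-(image, observer) child seeds come from a counter
  scheme (`(master mod 2^15)·2^16 + image·256 + observer`; ratings use an
  offset image slot), so identical specs reproduce bit-identical studies
  and adding an observer never shifts another observer's draws. The
  jitter field is drawn before the omission branch, so the same seed
  yields the same field across jitter scales — which makes mean DSC
  exactly monotone in `boundary_jitter` under common random numbers.

**What the simulator does not emulate**: speckle physics, attenuation,
probe-angle variability, multi-focal tumours, registration error, or the
actual DSC magnitudes of any clinical dataset. Passing tests show the
pipeline measures what it claims on data with known structure; they do
not certify clinical effect sizes.

## Numerical and design choices

- Binarization thresholds at > 0; multi-label NRRD ingests as the union
  of labels; RGB masks are rejected rather than silently flattened.
- All observers are assumed to annotate the identical pixel grid of the
  distributed still (no registration); grids are validated per image at
  load, and a missing (image, observer) mask is a hard error naming the
  cell.
- Coordinates are 0-based row-major with origin top-left, matching
  common raster formats; mask round-trips are bit-exact for PNG and NRRD
  (raw, gzip and ascii encodings).
- Grid size is free: the source stills' dimensions are unknown, so
  nothing assumes a particular resolution.
- Degenerate inputs: constant values give $H = 0$, $p = 1$; constant
  vectors make $\rho$ undefined (error, not NaN); an empty ANOVA cell
  with interaction requested errors naming the cell; a factor level with
  no records is reported with $n = 0$.
- Exported CSVs use fixed column order and 6-decimal DSC formatting so
  deterministic reruns are byte-identical; the manifest records
  `empty_policy`, band boundaries, the Dunn adjustment, the ANOVA SS
  type and the SD definition.

## Problem sizes in the test suite

The suite validates against brute-force oracles on randomized instances
(masks ≤ 32 × 32, group sizes ≤ 30; 1,000 cases), calibrates the
Kruskal–Wallis type-I rate on 5,000 three-group null simulations of 20
draws each, checks monotone agreement decay over the jitter grid
{0, 1, 2, 4, 8} px with 18 simulated raters on a 128 × 128 phantom, and
runs the full canonical scenario (9 images × 18 observers, 1,377
records) end to end, all under fixed seeds. These sizes were chosen as
the smallest at which each property is sharply testable.

## Known limitations

- Pairwise DSC records are not independent across pairs sharing an
  observer; omnibus p-values are anti-conservative to an unquantified
  degree.
- DSC is the only overlap metric; boundary-sensitive metrics (Hausdorff,
  surface Dice) and consensus-truth estimation (STAPLE) are extension
  points, not features.
- 2-D only: volumetric segmentations and DICOM are out of scope.
- The exact-permutation Spearman p enumerates $n!$ permutations and is
  capped at $n \le 9$ by default.
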