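---
title: "Predicting HER2-low status from H&E slides with attention MIL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HER2-low status from H&E slides with attention MIL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemil)
```

## The problem

HER2-low breast cancer — IHC 1+ or IHC 2+ without ISH amplification — has
become a therapeutically relevant category, but calling it requires an IHC
assay and, for equivocal 2+ cases, a confirmatory in-situ hybridization
test. `hemil` implements a weakly-supervised pipeline that predicts the
HER2 group (negative / low / high) directly from hematoxylin-and-eosin
whole-slide images: a slide is represented as a *bag* of tile embeddings,
labeled only at slide level, and classified by a gated-attention multiple
instance learning (MIL) model whose attention weights afterwards explain
which tiles drove the call.

## Pipeline stages

1. **Tiling** (`enumerate_tiles`, `read_tile`): 256 px tiles at a working
   resolution of 0.5 µm/px, with a 128 px stride so adjacent tiles overlap
   by 50% in both axes. Slides scanned at 0.25 µm/px are read through a
   2× window with area-averaged downscaling. Coordinates are 0-based,
   half-open, at level 0; edge strips narrower than a tile are discarded
   rather than padded, avoiding partial-tissue artifacts.
2. **Tissue filtering** (`train_patch_classifier`, `apply_filter`,
   `exclude_sparse_slides`): a three-class tumor / non-tumor / background
   patch classifier feeds two filtering strategies — `NOBG` (drop
   background only) and `TUMO` (keep tumor tiles only) — plus an `ALL`
   pass-through. Slides with fewer than 1000 tumor tiles (strict
   inequality) are excluded regardless of strategy. The bundled classifier
   is a multinomial logistic model on color/optical-density summaries,
   trained on synthetic fixtures; the interface is pluggable so any
   three-class patch model (e.g. a CNN) can stand in for real cohorts.
3. **Stain normalization** (`estimate_stain_profile`, `normalize_tile`):
   Macenko-style — optical density `OD = -log10((I+1)/256)`, background
   pixels below a max-channel OD of 0.15 removed, the top-2 singular plane
   of the tissue OD cloud fitted, and the 1st/99th percentile projection
   angles taken as the hematoxylin and eosin directions. Concentrations
   are solved by exact two-variable non-negative least squares, rescaled
   by the ratio of reference to source 99th-percentile maxima, and
   re-rendered with the reference stain matrix. The bundled reference is
   a synthetic H&E-like tile (`synthetic_reference_tile`); any real
   reference image can be substituted. Profiles are intended to be
   estimated once per slide from a sample of tumor tiles, which
   stabilizes the percentile estimates.
4. **Feature bags** (`encode_tiles`, `bag_store`): each kept tile becomes
   one row of a per-slide embedding matrix (default width 1024) through a
   pluggable encoder; the default desk-scale encoder is a seeded random
   projection of a 3×16-bin color histogram. Bags are materialized once
   into a directory-backed store (float32 features, int32 coordinates,
   CSV manifest) and training reads from the store — the two-stage regime
   that keeps MIL training cheap. Features are snapped to float32 at
   construction so store round-trips are bitwise lossless.
5. **Label partitions and splits** (`build_partition`, `make_splits`):
   the five assay cells {0, 1+, 2+/ISH−, 2+/ISH+, 3+} map to HER2 groups
   (0 → neg; 1+, 2+/ISH− → low; 2+/ISH+, 3+ → high). Six training
   scenarios restrict and regroup these cells (see below). Cases are
   stratified by (class label, cohort); 15% are held out; each of 10
   folds independently splits the remainder 85/15 into training and
   validation within strata. Assignment is at patient level, so no
   patient appears in two roles.
6. **The MIL model** (`mil_config`, `mil_forward`, `train_fold`): a
   shared linear projection with ReLU, a gated attention backbone
   (`tanh(Vh) ⊙ sigmoid(Uh)`, shared) with one scoring head per class,
   per-class linear bag classifiers on the attention-weighted slide
   vectors, softmax combination, and per-class 2-way instance
   classifiers trained with a smooth SVM loss on attention-selected
   tiles (top-k of the true class as positives, bottom-k as negatives,
   top-k of other classes suppressed). Total loss =
   0.7 · bag cross-entropy + 0.3 · mean instance loss. ADAM, learning
   rate 1e-4, weight decay 1e-4, one bag per step, up to 200 epochs with
   early stopping on validation loss. The forward pass, analytic
   gradients and the optimizer are implemented directly in R matrix
   code; gradients are verified against finite differences in the test
   suite.
7. **Explainability** (`select_actionable`, `attention_heatmap`,
   `project_and_bin`, `color_bins`): *actionable tiles* are tiles with a
   per-class instance probability strictly above 0.5, ranked by
   attention, capped at 15 per slide and class, collected regardless of
   the slide-level call. Pooled actionable embeddings are projected onto
   their first two principal components and binned on a 30×30 equal-width
   grid; bins are colored by majority class, by fold consistency (≥ 50%
   of folds, inclusive), or by cross-scenario agreement (≥ 2, ≥ 3, ≥ 4
   scenarios).

## The six training scenarios

| Scenario | Cells used | Classes |
|---|---|---|
| M1 | 2+/ISH−, 2+/ISH+, 3+ | low vs high |
| M2 | 0, 2+/ISH+, 3+ | neg vs high |
| M3 | 1+, 2+/ISH−, 2+/ISH+, 3+ | low vs high |
| M4 | 0, 1+, 2+/ISH−, 3+ | neg / low / high |
| M5 | 0, 1+, 2+/ISH− | neg vs low |
| M6 | all five | neg / low / high |

The M4 row of the published partitioning table is not uniquely decodable;
we default to the 3-class reading {0} / {1+, 2+/ISH−} / {3+} because the
scenario is reported as non-binary in the method-comparison table, the
narrative describes it as including HER2 0 while subtracting part of
HER2-high, and four cells are marked. The composition is exposed as a
config override (`partition_spec("M4", m4_cells = ...)`) so either
reading can be run.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tile_px` / stride | 256 / 128 px | tile footprint and 50% overlap |
| `min_tumor_tiles` | 1000 | strict slide-exclusion threshold |
| `od_threshold` | 0.15 OD | background cut in stain estimation |
| `angle_percentiles` | 1%, 99% | robust stain-direction extremes |
| `d_in`, `d_proj`, `d_attn` | 1024, 1024, 512 | model widths; 2,109,964 parameters at 3 classes |
| `k_sample` | 8 | instances per branch for the instance loss |
| `bag_weight` | 0.7 | bag-CE weight in the total loss |
| learning rate / weight decay | 1e-4 / 1e-4 | ADAM settings |
| `holdout_fraction`, `n_folds`, `val_fraction` | 0.15, 10, 0.15 | split plan |

The printed width pair (1024, 512) is the unique common configuration
reproducing the 2.1M parameter count; both are config keys. Patience 20
and 50 minimum epochs are conventional for this model family; only the
criterion (validation loss) and the 200-epoch cap are fixed by the
training regime.

## The synthetic cohort

`generate_cohort()` emulates exactly the structure the method assumes:
tiles are draws from 10 shared background Gaussian clusters; HER2-low and
HER2-high slides additionally carry a class-specific *witness* cluster
whose mean is shifted by δ = 6σ, at a per-slide prevalence drawn from a
Beta distribution (mean 0.10 for low, 0.20 for high, concentration 20 —
mimicking tumor-fraction heterogeneity). Observed assay results follow a
simple model (high → 3+ w.p. 0.7 else 2+/ISH+; low → 1+ w.p. 0.6 else
2+/ISH−; neg → 0), after which IHC 0 and 1+ calls swap with probability
ε — the specific interobserver disagreement documented for those two
scores; 2+ and 3+ calls stay clean. Desk-scale defaults are 60 slides
(two synthetic sites, so cohort stratification is exercised), 50–200
tiles per slide, and 32-dimensional embeddings; paper-scale dimensions
are plain config values. The generator does **not** model spatial
autocorrelation of tiles, realistic H&E texture, scanner variation, or
batch effects — so passing tests demonstrate the correctness of the
machinery and the qualitative label-noise mechanism, not real-data
performance.

Two properties make the benchmark fair: with ε = 0 and δ ≥ 5σ a linear
probe on mean bag embeddings separates the latent classes perfectly (the
task is solvable), and with ε > 0 only the neg/low boundary degrades —
which is why the neg-vs-low scenario (M5) collapses under noise while
neg-vs-high (M2) is untouched, reproducing the central qualitative
finding that scenario performance tracks the reliability of the
underlying assay labels.

## Numerical choices and degenerate inputs

- Softmax and log-sum-exp use max-subtraction throughout.
- The smooth SVM loss `τ·log Σ exp((s_j + Δ·1[j≠y] − s_y)/τ)` equals
  cross-entropy at Δ = 0, τ = 1 and approaches the multiclass hinge as
  τ → 0; both identities are tested.
- Attention heads are initialized near zero so initial attention is
  close to uniform: early training is then driven by bag-level evidence
  rather than arbitrary peaked attention, which the instance loss would
  otherwise self-reinforce. This materially improves how often attention
  converges onto the witness tiles.
- Non-negative least squares for two stains is solved exactly
  (unconstrained 2×2 solve plus active-set fix-up), vectorized over
  pixels.
- Min-max normalization of a single attention value is defined as 1.
- Bin-coloring majority ties break by the fixed class order
  neg < low < high; points on a bin range's max edge join the last bin.
- Degenerate inputs error early and descriptively: empty bags, IHC 2+
  without ISH, background-only tiles in stain estimation, all-identical
  embeddings in PCA, single-class training sets, corrupt bag containers.
- Split counts are rounded half-up per stratum; strata with fewer than
  two patients merge into the largest stratum with the same label, with
  a warning.

## Known limitations

- **Mirror attention solutions.** In a binary scenario only logit
  *differences* matter, so a model that concentrates the *negative*
  branch's attention on witness tiles and scores their absence is
  exactly as good, in training loss, as the intended solution — we have
  observed folds converging to it (it can even reach a slightly lower
  validation loss). In those folds the class attribution of attention is
  inverted and the high-class actionable tiles are uninformative; in our
  runs roughly 8 of 10 folds converge to the intended solution, and the
  actionable-tile analysis pools across folds, which is robust to the
  minority. This degeneracy is a property of the per-class-branch
  objective itself, not of the data.
- Desk-scale runs use reduced widths (`d_proj = 64`, `d_attn = 32` on
  32-dimensional synthetic embeddings, preserving the 2:1
  projection-to-gate ratio) and schedules of 60–150 epochs; the full
  configuration is instantiated and its parameter count verified, but
  not trained in the tests.
- The default encoder is a color-histogram projection: sufficient for
  the synthetic benchmark, not a substitute for a pathology foundation
  model on real slides.
- Real-cohort AUROC values cannot be reproduced without the original
  restricted/external cohorts and are out of scope; the tests reproduce
  structural targets and qualitative orderings only.
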