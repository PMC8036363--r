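---
title: "Quantifying desmoplastic reaction at the invasive front: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying desmoplastic reaction at the invasive front: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drquant)
```

## The problem

Desmoplastic reaction (DR) is the fibrous stromal response at a tumour's
invasive edge. In colorectal cancer, the presence of large areas of *myxoid
stroma* — amorphous, mucin-rich pale stroma — just beyond the muscularis
propria defines the *immature* DR type, which carries markedly worse
disease-specific survival than other stroma types. Manual grading compares
the largest myxoid area against one 40x microscope field (a circle of
diameter 0.5 mm, area `pi * 0.25^2 = 0.196` mm^2) and is known to suffer
from inter-observer variability.

`drquant` implements a quantitative version of this assessment. Given an
invasive-front annotation and a myxoid-stroma segmentation of a slide
image, it:

1. builds outward **margin bands** of 500 and 1000 um around the front
   (Margin 1 and Margin 2);
2. measures object-level **area features** of myxoid stroma inside each
   band: total area, average (mean per-object) area and largest single
   area, all in mm^2;
3. **classifies** DR as immature vs other by comparing a feature against a
   cut-off, either a data-derived automatic cut-off point (ACP) or the
   manual 0.196 mm^2 field area (MCP);
4. evaluates **prognostic significance**: optimal cut-point discovery by
   the maximally selected rank statistic, Kaplan–Meier curves with log-rank
   tests, univariate and forward-stepwise Cox proportional-hazards models,
   and Benjamini–Hochberg correction across features.

Every stage runs on synthetic material produced by the package's own
generators, so the full pipeline is exercisable and testable without any
external data.

## Margin-band geometry

The band of width $w$ around a front polyline $F$ is defined per pixel: a
pixel belongs to the band iff its **centre** lies within Euclidean distance
$w$ of $F$ (true point-to-segment distance, so open polylines get rounded
end-caps) *and* outside the tumour polygon. Pixel $(r, c)$ (1-based) has
its centre at $((c-\tfrac12)\,\rho, (r-\tfrac12)\,\rho)$ for resolution
$\rho$ um/px.

Two choices here were genuinely open:

* **Orientation.** Nothing in a bare polyline says which side is
  extramural. We require a tumour polygon and define *outward* as "not
  inside it". Pixel centres falling exactly on the polygon boundary count
  as tumour (excluded) — a deterministic tie-break.
* **Exact distances rather than a distance transform.** We evaluate the
  point-to-segment distance at every pixel centre (compiled code) instead
  of a distance transform of a rasterised front. A transform of a
  rasterised polyline is off by up to half a pixel near diagonal segments;
  the exact evaluation makes the band's semantics self-describing and
  directly checkable against a brute-force per-pixel scan, which the test
  suite does pixel for pixel.

Consequences worth knowing: bands of increasing width are nested by
construction, and band area is `count * rho^2 / 1e6` mm^2. An optional
tissue mask can be intersected with the band; by default no tissue clipping
is applied, since margin quantification on a well-annotated front rarely
crosses glass.

## Segmentation interface and the reference pixel classifier

The segmentation stage is deliberately pluggable: any model that maps an
RGB image to a per-pixel myxoid probability map satisfies the contract.
Downstream of the probability map the operating point is fixed:

* **threshold 0.80**, boundary-inclusive (`p >= 0.8` is foreground);
* **minimum object size 0.1 mm^2** applied to 8-connected components of
  the whole mask (before margin clipping), boundary-inclusive — an object
  of exactly 0.1 mm^2 survives;
* working resolution **1 um/px**.

The shipped reference implementation is a logistic-regression pixel
classifier on seven features: R, G, B, HSV saturation and value, and the
local mean and standard deviation of intensity in a 7 px window (the
texture cue separating smooth myxoid pools from fibrillar collagen).
Training samples pixels from annotated images and from colour-augmented
copies: one uniform per-image jitter in HSV space (hue rotation,
saturation and brightness scaling) per copy, emulating stain variation so
the classifier does not overfit one staining profile. The handle
serialises to a small JSON artefact.

This classifier is intentionally desk-scale. It preserves every downstream
computation while remaining fast and fully reproducible; a convolutional
segmenter can be substituted through the same interface without touching
any other stage.

## Morphometry

Objects are maximal 8-connected components (8-connectivity is used
consistently everywhere components appear). For margin features each
object's **clipped** (in-margin) area is measured — "area detected within
the margin" — and objects with empty intersection are excluded; the
unclipped areas are reported alongside for transparency. The *average*
feature is the mean of per-object in-margin areas, parallel to the
object-level *largest* feature, not total area divided by band area.
These conventions make the conservation identity
`sum(in-margin object areas) == area(mask & band)` exact, and the test
suite asserts it.

Segmentation accuracy is scored by the Dice coefficient on areas,
$\mathrm{Dice} = 2\,TP / (2\,TP + FP + FN)$. Two conventions: when both
masks are empty the score is 1 (an all-negative slide predicted empty is a
perfect result — without this, slides with no myxoid stroma would be
unscorable), and multi-image evaluation pools TP/FP/FN areas before
applying the formula (per-image mean is available as an alternative).

## DR classification

A patient is *immature* when the chosen feature **strictly exceeds** the
cut-off; ties go to *other* ("greater than" taken literally, and
configurable). The shipped cut-off table contains the eight reference
thresholds (mm^2):

| feature | margin | regime | threshold |
|---|---|---|---|
| total | Margin 1 | ACP | 0.27392 |
| average | Margin 1 | ACP | 0.00622 |
| largest | Margin 1 | ACP | 1.04863 |
| largest | Margin 1 | MCP | 0.19600 |
| total | Margin 2 | ACP | 0.31949 |
| average | Margin 2 | ACP | 0.15859 |
| largest | Margin 2 | ACP | 0.17410 |
| largest | Margin 2 | MCP | 0.19600 |

ACPs are cohort-derived values, shipped as defaults but not universal
constants: on new data `maxstat_cutpoint()` recomputes them. The
three-tier scheme (mature / intermediate / immature) is not implemented:
discriminating intermediate DR requires keloid-like collagen assessment
for which no quantitative size guideline exists; the call structure leaves
room for an additional class.

## Survival statistics

**Stratified splitting** assigns `round_half_up(n_stratum * frac)` of each
stratum to training. Half-up rounding (not banker's) is what reproduces
the canonical 528-patient arithmetic: 125 immature x 0.75 = 93.75 -> 94,
403 x 0.75 = 302.25 -> 302, totalling 396 train / 132 test.

**Maximally selected rank statistics.** Each subject receives its log-rank
score $a_i = \delta_i - \hat\Lambda(t_i)$ (Nelson–Aalen cumulative hazard
at the observed time). For a candidate cut-point $c$ the two-group
log-rank statistic is the linear rank statistic
$S_c = \sum_{x_i \le c} a_i$, standardised by its permutation mean and
variance; candidates are midpoints between consecutive distinct marker
values whose left-group proportion lies in $[\text{minprop},
1-\text{minprop}]$ (default minprop 0.1, the convention of the widely
used implementations). The selected cut-point maximises the absolute
standardised statistic. Because the maximum over many correlated
candidates inflates type-I error, the p-value is computed by permutation
(default 10,000 seeded permutations of the score-to-marker assignment,
recomputing the maximal statistic each time); this is assumption-light
and directly checkable against brute-force enumeration, which the tests
do on every fixture up to 50 records.

**Cox models** use maximum partial likelihood via the `survival` package
with **Breslow** tie handling by default (parity with the clinical
statistics software commonly used for such analyses; Efron is available),
Wald 95% CIs $\exp(\beta \pm 1.96\,SE)$ and Wald p-values. Monotone
likelihood (complete separation) is flagged on the returned object rather
than silently reported. Ordinal stage covariates (pN 0/1/2, pT 3/4) are
entered as single ordinal scores, matching the one-HR-per-factor
reporting convention.

**Forward stepwise selection** adds, at each step, the candidate with the
smallest single-term p-value below `p_enter = 0.05`, then removes any term
whose removal p-value exceeds `p_remove = 0.10`, until a fixpoint. Both
entry and removal use the likelihood-ratio test: for single-parameter
terms it is asymptotically equivalent to the score test used by some
packages, and it falls directly out of the partial likelihoods already
computed. Thresholds mirror common forward-stepwise defaults and are
configurable.

**Kaplan–Meier** estimation and the log-rank test delegate to
`survival::survfit()` / `survdiff()`; survival rates are read off at an
explicit horizon (default 60 months) *and* at the last event time, each
labelled, since a bare "survival rate" without a horizon is ambiguous.
Benjamini–Hochberg correction (`stats::p.adjust`) is applied to the
log-rank p-values of all features analysed in one run — one family per
run.

## Synthetic data: what it emulates, and what it does not

**Slides.** A generated slide contains a tumour region bounded by a wavy
vertical invasive front, fibrillar eosin-pink collagenous stroma outside
it, and `n_blobs` myxoid blobs — Fourier-perturbed ellipses with a pale
blue-grey, smooth-textured signature — placed 150–900 um outward of the
front. Defaults: 1500 x 1500 px at 1 um/px, 3 blobs, log-normal blob area
with meanlog `log(0.25)` mm^2 and sdlog 0.4, which keeps essentially all
blobs above the 0.1 mm^2 filter, as in annotated immature-DR material;
randomly drawn areas are capped at the largest size that fits the canvas
(explicitly requested areas are never capped — they error if unfittable).
The ground-truth mask equals the rendered blob pixels exactly.

These slides are a *rendering convention*, not histology: real H&E has
nuclei, glands, gradual stroma transitions, scanner noise and stain
variation far richer than one HSV jitter. Passing the segmentation
benchmark on them shows the pipeline's plumbing — features, thresholding,
filtering, scoring — is correct and that the reference classifier learns
colour/texture signatures; it does not certify performance on clinical
slides, which is the job of whatever segmenter a user plugs in.

**Cohorts.** Patients are immature with probability 0.237; event times are
exponential with baseline hazard 0.0018/month multiplied by a planted
hazard ratio (default 3.5) for immature patients; censoring is
administrative at 134 months (~11.2 years of follow-up) plus uniform
dropout on (0, 360) months. With these settings the other-DR group sits
near 79% survival at the cap and the immature group near 43%, inside the
range clinical DR studies report, and roughly a third of patients
experience events. Feature values are drawn log-normally above (immature)
or below (other) the corresponding cut-offs; a `manual_DR` column agrees
with the true class with probability 0.9, emulating imperfect manual
grading. The planted effect is recoverable: a downstream Cox fit on 396
patients recovers log(3.5) to within ±0.15 on average, which the test
suite verifies.

## Numerical choices and degenerate inputs

* All tie-breaks are documented and boundary-inclusive where a boundary
  exists: threshold `>=`, minimum object size `>=`, pixel-on-tumour-edge
  -> excluded from the band; DR classification is the one strict
  inequality (`>`), because the criterion is "greater than the cut-off".
* Zero-width bands are empty; empty masks yield zero features and the
  call *other* under every regime; both-empty Dice is 1.
* `maxstat_cutpoint()` rejects constant markers and event-free cohorts;
  `logrank_test()` returns p = 1 when no events exist in either group.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; no function mutates global state or its inputs.
* Problem sizes in the shipped tests were chosen to keep the whole suite
  desk-scale: segmentation tests run on 400 x 400 px slides, the
  segmentation benchmark on 30 full-default slides (20 train / 10 test),
  statistical recovery suites on 200–400 patients with tens to hundreds
  of replicates.

## Known limitations

* The reference segmenter is a linear pixel classifier; it will not cope
  with appearance variation beyond what colour and local texture separate.
  It is the interface's reference implementation, not a claim about
  state-of-the-art segmentation.
* Margin geometry is purely Euclidean; no tissue-constrained or geodesic
  distance, no multi-resolution tiling. The front region must fit in one
  raster.
* Survival machinery covers right-censored, single-event data only — no
  competing risks, no time-varying covariates.
* The default cut-offs and the planted cohort parameters describe one
  published clinical setting; both are configuration, not ground truth.
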