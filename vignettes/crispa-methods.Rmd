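---
title: "Methods: colony-array pigment screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array pigment screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `crispa`, the
assumptions they make, the parameters that matter, and the design decisions
taken where the underlying screen protocol leaves the analysis
under-specified.

# The measurement model

A pigment screen photographs 1536-format colony arrays and asks, per gene,
whether deleting it raises or lowers pigment yield. Two per-colony
measurements carry all downstream analysis:

* **Size**: the number of pixels assigned to the colony, a proxy for strain
  fitness.
* **Yellowness**: the geometric mean of HSV Saturation and Value,
  $y = \sqrt{S\,V}$ with $S, V \in [0,1]$, averaged over the colony's
  retained pixels. This rests on the *fixed-hue assumption*: on the media
  used, a colony color is always some variant of yellow, so Saturation and
  brightness jointly encode pigment concentration and hue carries no
  information. The score is hue-invariant by construction and lies in
  $[0,1]$ ($1$ = fully saturated bright color, $0$ = any gray). $S$ is
  defined $0$ when $V = 0$.

## Segmentation and pixel filtering

Foreground is separated from the agar background by a single global
threshold on grayscale intensity (channel mean), chosen by Otsu's criterion
(`EBImage::otsu`); a fixed threshold is available as a fallback for unusual
lighting. Because the array grid is regular, each foreground pixel is
assigned to the grid cell with the nearest center, capped at one cell pitch,
which prevents an overgrown colony from annexing a neighbouring cell. Masks
of distinct colonies are disjoint by construction, so per-colony sizes sum
exactly to the plate's foreground pixel count.

The colony protocol this package follows states that colony pixels are
filtered before averaging but not how. `crispa` retains the mask pixels
whose grayscale intensity lies at or above the mask's median
(`filterQuantile = 0.5`, configurable), which discards the dim rim where
background bleeds into the mask. Size is deliberately the *unfiltered* mask
pixel count: the filter exists to stabilize the color average, while size
should reflect the whole colony footprint. This is an interpretive choice;
the quantile is exposed so users can disable it (`filterQuantile = 0`).

# Positional correction and normalization

High-density arrays show systematic positional effects: outer-frame colonies
receive more nutrients and grow larger and brighter. Two mechanisms address
this:

* **Randomization by design.** When a 384-format library is pinned in
  quadruplicate into the 1536 format, each of the four replicate arrays goes
  to a *different* screen plate, so plate and neighbour effects are
  randomized across replicates. Row/column positions are not altered by this
  scheme, so edge effects remain systematic.
* **Edge correction.** Per plate, each outer frame ring (ring 0 = outermost;
  ring = minimum grid distance to the border) is rescaled multiplicatively
  so its median matches the median of the plate center. Multiplicative
  rather than additive matching preserves the non-negativity of sizes and
  scores, and makes the operation exactly idempotent. The number of
  corrected rings defaults to `nFrames = 2` — the two pinned rows/columns
  classically affected in high-density arrays — and a pooled-outer-zone mode
  is available behind a flag, since ring-wise versus pooled matching is an
  open choice. Both yellowness and size are corrected by default (both are
  positionally biased); a per-metric switch exists.

After edge correction each screen is z-normalized over *all* its plates
pooled: $z = (x - \bar{x}) / s$ with the sample standard deviation. The
state machine `raw → edge_corrected → normalized` enforces the order;
z-scoring an already-normalized screen is the identity.

# Replicate filtering and gene scores

Within each gene's replicate set (4 per screen; up to 16 when four screens
are pooled), outliers — contaminated colonies, pinning failures — are
removed with the two-sided single-outlier Grubbs test,
$G = \max_i |x_i - \bar{x}| / s$, with the critical value from the
t-quantile formula
$\frac{n-1}{\sqrt{n}} \sqrt{t^2_{\alpha/(2n),\,n-2} \big/ (n - 2 + t^2)}$.
The test is applied *iteratively* (remove, retest) with a floor of $n = 3$,
because pooled replicate sets reach $n = 16$ and can harbour more than one
outlier; $\alpha$ defaults to 0.05. Both choices are configurable since the
protocol fixes neither. Filtering runs on the yellowness z-scores — the
screen's primary readout — and colonies removed there are excluded from both
the yellowness and the size mean, keeping each gene's two scores on the same
replicate set.

Genes with fewer than three surviving colonies are dropped; the replicate
mean is the final per-gene score. For multi-screen pooling, each screen is
edge-corrected and normalized independently *before* its records enter the
pool, so screens contribute on a common z-scale.

# Hit groups and inferential statistics

* **Yellow / white groups**: gene yellowness z-score above $+1.2$ / below
  $-1.2$ screen standard deviations.
* **Cyan group**: highly yellow strains with little or no fitness penalty.
  The protocol gives this group no numeric definition, so `crispa` uses a
  configurable rule (`mean_yellow > 1.2` and `mean_size > 0`) and always
  reports cyan as a logical *sub-label* of the yellow group, never as a
  replacement.
* **Hit-list overlap**: with $M$ genes scored in both trials and hit lists
  of size $n = N$, the overlap $k$ is tested against the upper-tail
  hypergeometric $P(X \ge k)$. Ranking ties at the list boundary are broken
  lexicographically by gene identifier — deterministic and logged, since the
  protocol is silent on ties.
* **Reproducibility**: Pearson correlation of gene scores over the common
  gene set.
* **Strain comparisons**: one-sided Student (pooled variance) or Welch
  (Satterthwaite df) tests, with the direction supplied by the caller
  (greater for raised-pigment hits, less for lowered).

# Enrichment and the term graph

Term over-representation uses the one-sided hypergeometric tail (equivalent
to one-sided Fisher) per term, over all terms with at least one population
gene, followed by Benjamini–Hochberg adjustment; terms with $q < 0.05$ count
as enriched. The population defaults to the genes the screen successfully
scored — enrichment of a screen subgroup should be judged against what the
screen could have found — not the whole genome; callers can pass any
population.

Annotations are used exactly as given: genes are *not* propagated to
ancestor terms. The is-a hierarchy (from a parent TSV or a minimal OBO
reader handling only `id`/`name`/`is_a` stanzas) is consulted solely for
node coloring. This is a stated divergence from ontology tools that
propagate annotations before testing.

The graph of enriched terms connects every pair sharing at least one
annotated gene. Node size is $s_{\min} + s_{\mathrm{scale}}\,(-\log_{10} q)$
with defaults 10 and 5 display units — a linear stand-in for the
qualitative "size reflects significance" rule; edge opacity is the
shared-gene count divided by the maximum observed count, hence in $(0,1]$;
node color is the first keyword found in the term's own description, then
breadth-first through ancestor descriptions, else `"other"`.

# The synthetic-screen generator

The generator exists so every stage above can be tested against ground
truth. It emulates, with defaults chosen to mirror the screen conditions the
analysis assumes:

* **Layouts**: gene assignment left-to-right, top-to-bottom over 384-format
  plates; quadruplicate 1536 assembly at interleave offsets
  $(dr, dc) \in \{0,1\}^2$ via $(2r + dr,\, 2c + dc)$. Under the
  `randomized` scheme the four offsets a library plate takes across its four
  screen plates follow a seeded 4×4 Latin square — the protocol states that
  replicates go to different plates but not how offsets rotate, and a Latin
  square guarantees every plate carries each offset exactly once. The
  `block` scheme (2×2 blocks on one plate) is kept as the unrandomized
  control.
* **Effects**: per-gene pigment effects from a three-part mixture — 90%
  bulk $N(0, 0.3)$, 5% yellow tail $N(+3, 0.5)$, 5% white tail
  $N(-3, 0.5)$, all on the z scale — or explicit planted hit lists. The
  yellow tail receives a fitness penalty
  $-0.6\,|\text{pigment}| + N(0, 0.3)$, reproducing the anti-correlation
  between strong pigment gain and growth observed in such screens. The
  mixture is a modelling choice: the screen literature reports the empirical
  shape (a dense bulk with two tails), not a generative law.
* **Nuisance structure**: per-plate multiplicative bias
  $\exp N(0, 0.05)$; edge bias 1.25× on the two outer rings (applied to
  colony area); 1% missing colonies; 1% contaminated colonies whose white
  fraction is $\mathrm{Beta}(1, 9)$ — consistent with reports that roughly
  2% of strains show >1% contamination in at least one trial. Per-colony
  measurement noise is $N(0, 0.3)$ on both effect scales, i.e. equal to the
  bulk effect sd.
* **Rendering**: colonies are filled discs; radius is monotone in
  baseline + fitness + bias + noise (area scales as
  $\exp(0.15\,\text{fitness})$ times the biases); color has fixed hue 1/6,
  Value 0.9, and Saturation $=\operatorname{logistic}(0.9\,\text{pigment})$;
  background is uniform dark gray (0.15). Discs that would exceed the cell
  pitch are clipped and flagged. `plantedYellowness()` gives the closed form
  of the color model *including 8-bit quantization*, which is the oracle the
  scorer round-trip tests use; quantization bounds the scorer's recovery
  error well below $10^{-3}$ over the operating range of the logistic map.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: colony texture and lighting gradients, camera
noise, agar surface artifacts beyond one multiplicative plate factor,
non-disc colony morphology, plate-to-plate focus differences, and
biological replicate structure beyond independent per-colony noise. The
generator validates the *pipeline's contracts* (bias removal, outlier
rejection, recovery of planted effects), not the imaging physics.

With four pooled screens and the 1%/1% missingness/contamination defaults,
nearly every gene keeps 15–16 of its 16 replicates; real screens lose more
colonies (failed pinnings, border blanks), which the generator does not
attempt to reproduce.

# Determinism and numerics

* Every stochastic step takes an explicit integer seed; the pipeline derives
  per-stage seeds from one global seed by stable hashing so stages are
  independently reproducible. Identical seeds give byte-identical layouts,
  images, and TSV outputs (floats written at 6 significant digits).
* Edge correction leaves a ring uncorrected (with a warning) when the ring
  or center median is undefined (all colonies missing) or zero, rather than
  dividing by zero or inventing a factor.
* A constant screen (zero standard deviation) is an error in normalization,
  as is a Pearson correlation on constant input; degenerate Grubbs inputs
  ($n < 3$ or zero sd) pass through untested.
* BH adjustment and hypergeometric tails are delegated to `stats::p.adjust`
  and `stats::phyper`; the test suite checks both against brute-force
  step-up and enumeration oracles at $10^{-12}$.

# Problem sizes in the test suite

The end-to-end study the tests and the acceptance script run uses a 384-gene
library, 4 screens × 4 replicates (16 plates of 1536 positions at 10 px cell
pitch), 20 planted yellow and 20 planted white genes at ±3 sd. This size
exercises every pipeline path — randomization, rendering, scoring,
correction, pooling, hit calling, overlap, enrichment — while a full run
completes in well under a minute; the statistical margins at this size
(planted effects at ±3 sd against a replicate standard error of ~0.1 sd) are
wide enough that recovery checks are not borderline.

# Known limitations

* Only the frame-median edge rule is implemented; spline or rank-based
  spatial normalizations used by some array toolkits are out of scope.
* No FDR control across genes for hit calling — groups are defined by sd
  thresholds, matching the screen's convention.
* Free-form (non-gridded) colony detection and fluorescence channels are
  not supported.
* The OBO reader handles `id`/`name`/`is_a` only; obsolete terms and other
  relationship types are ignored.
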