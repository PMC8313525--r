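---
title: "Movement predictability across spatio-temporal scales: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement predictability across spatio-temporal scales: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movepredict)
```

This vignette is the package's own account of the models and procedures it
implements: what is computed, under which assumptions, which defaults were
chosen and why, and what the synthetic test bed does and does not show
about real data.

## From points to symbols

A *trajectory* is a time-ordered set of positioned points $(x, y, t)$ in a
planar metric frame (metres). The pipeline symbolises it in three stages.

**Stay-point detection.** The scan accumulates consecutive points while
each lies within $\delta$ metres of the *first* point of the current
candidate; on the first violation the run becomes a stay-point if its
elapsed time strictly exceeds $\tau$, and is discarded otherwise, and the
scan restarts at the violating point. Defaults are $\delta = 300$ m and
$\tau = 10$ min — on the order of GNSS urban positioning error and of the
shortest dwell one would call a visit. Two conventions required a choice:

* the distance test is taken against the first candidate point, not the
  running centroid — the cheaper and more literal reading of the classic
  scan, kept so that results are reproducible from the description alone;
* the trailing candidate at end-of-data is subjected to the same $\tau$
  test and emitted if it passes, so overnight dwells at the end of an
  observation window are not silently lost.

A consequence worth knowing: departure and arrival samples that still lie
within $\delta$ of the dwell anchor are accumulated with it, so centroids
of noiseless dwells may sit a few metres off the true anchor. This is a
property of the scan, not noise.

**Stay-region aggregation.** Two families are implemented with one
parameter each:

* `grid_aggregate()` — a regular axis-aligned grid of spacing $G$,
  anchored at the minimum corner of the stay-point bounding box, with
  half-open cells $[x_0 + kG, x_0 + (k+1)G)$. Anchoring to the data makes
  assignments translation-invariant and reproducible without an external
  reference frame; the half-open rule resolves boundary ties
  deterministically. The grid can split a tight cluster of stay-points
  across an edge — the classic aggregation pathology that motivates the
  comparison with clustering.
* `dbscan_aggregate()` — density clustering with minimum cluster size one,
  which is mathematically the connected components of the graph joining
  stay-points at distance $< \varepsilon$ (strict, matching "smaller
  than"). With no minimum-size constraint there is no noise label, and the
  implementation (graph components) is oracle-checkable against a
  union-find over all pairwise distances, which the test suite does.

Region *area* is reported as the convex hull of member stay-points
(degenerate hulls get zero). The alternative readings — cell area $G^2$, or
a buffered radius — were rejected because they are either trivially the
parameter itself or require an arbitrary buffer; the hull is determined by
the data alone. The spatial sweep grid is 30 values log-spaced from
$10^1$ to $10^{4.8}$ m, covering building scale up to roughly half a
metropolitan extent.

**Sequences.** Two representations are built from the region-labelled
visit history:

* *Next time-bin*: one symbol per interval $\Delta t$ — the region with
  the largest within-bin dwell; ties break first by the region's visit
  count over the whole history ("more often visited"), then by smallest
  region id for determinism; bins with no visited time are null. Bins are
  anchored at the first visit's start floored to a multiple of $\Delta t$
  from the preceding midnight UTC, so hour bins align with the hour-based
  definition of record completeness $q$ (fraction of null bins). The
  $\Delta t$ sweep is 5, 10, 15, 30, 45, 60 min and 6, 12, 24, 48, 72,
  144 h.
* *Next place*: visit-ordered region ids with consecutive repeats
  collapsed — transitions only, no nulls, no temporal parameter. A history
  over a single region collapses to length one.

For self-transition counting in time-bin sequences, nulls break adjacency:
a gap gives no evidence that the user stayed put.

## Entropy and the Fano bound

For a sequence over $L$ distinct regions with visit frequencies $p_k$:
random entropy $S^{rand} = \log_2 L$; uncorrelated entropy
$S^{unc} = -\sum_k p_k \log_2 p_k$; and the Lempel-Ziv estimate of the
actual entropy rate
$$S^{est} = \left(\tfrac{1}{n}\sum_j \Lambda_j\right)^{-1} \log_2 n,$$
where $\Lambda_j$ is the length of the shortest substring starting at $j$
that does not occur as a contiguous substring of positions $1..j-1$; when
no such substring exists within the sequence, $\Lambda_j = n - j + 2$. The
first position, with an empty prefix, gets $\Lambda_1 = 1$ — the standard
convention, isolated in one function so it can be revisited. Nulls are
dropped (the sequence concatenated) before estimation: treating a null as
a symbol would inject spurious regularity, and bias induced by missingness
is the concern of the dedicated estimators below, not of the raw
estimator. The kernel is an online suffix automaton (Rcpp), exact and
near-linear; the test suite proves it equal to a brute-force substring
search on every binary sequence of length 2–12.

Each entropy $E$ (always in bits — the logarithm base must match on both
sides) is mapped to a predictability bound by solving Fano's inequality
$$E = -\Pi\log_2\Pi - (1-\Pi)\log_2(1-\Pi) + (1-\Pi)\log_2(L-1)$$
for the unique $\Pi \in [1/L, 1]$. The right-hand side is strictly
decreasing, so unconditionally convergent bisection is used rather than a
derivative method; iteration is on interval width (to $10^{-14}$) rather
than on the entropy mismatch because the curve is flat at its maximum
$\Pi = 1/L$, where an $f$-value stop would leave $\Pi$ imprecise. The
analytic corner $E = \log_2 L \Rightarrow \Pi = 1/L$ is resolved exactly.
Estimator noise on short sequences can push $E$ above $\log_2 L$; such
values clamp to $1/L$ with a `clamped` attribute rather than erroring, so
population sweeps keep every user. Sequences with fewer than two non-null
symbols are completely predictable by definition ($\Pi_{max} = 1$,
flagged `degenerate`) and are never dropped silently. On short sequences
$\Pi_{unc} > \Pi_{max}$ can occur — the Lempel-Ziv estimator converges
only as $n \to \infty$ — so that ordering is not asserted below
$n \approx 10^4$.

## Actual entropy from incomplete sequences

Three estimators are implemented for sequences with null bins, all driven
by *nested* degradation: removal order is a fixed seeded permutation of the
non-null bins, so the bins removed at a lower target $q$ are a subset of
those removed at any higher target, and degraded versions of one sequence
form a chain.

* $\hat H_{shuff}$: over the grid $q' = q, q+0.05, \ldots, 0.90$, the
  order parameter $\sigma(q') = \log_2(S^{est}(q')/S^{unc}(q'))$ is
  computed with $S^{unc}(q')$ the Lempel-Ziv entropy of the *shuffled*
  degraded sequence (one seeded shuffle per level); $\sigma$ is fitted
  against $q'$ and extrapolated to $q' = 0$, and the result rescaled:
  $\hat H = 2^{\sigma_{est}} S^{unc}(q)$.
* $\hat H_{unc}$: identical, except the scaling feature is the analytic
  uncorrelated entropy of the degraded frequencies.
* $\hat H_{\Delta e}$: an average relative-error curve
  $\Delta e(q') = (\hat H(q') - \hat H(q))/\hat H(q)$ is built from
  reference sequences with $q < 0.15$ (taken to carry the true entropy),
  pooled across references and fitted; an incomplete sequence is then
  corrected as $\hat H_{\Delta e} = S^{est}/(1 + \Delta e(q))$. Reference
  and evaluation sets must be disjoint, otherwise the estimation error is
  artificially deflated; the evaluation driver enforces this by taking the
  curve as a separately built argument.

Fitting choices: $\sigma(q')$ is fitted with both a straight line and an
offset exponential $a e^{bq} + c$ (Levenberg-Marquardt), and the form with
the higher $R^2$ wins — the observed shape genuinely varies between the
two. A flat response is treated as a perfect constant fit, which makes all
three estimators return the raw $S^{est}$ exactly when the relationships
carry no signal, a property the tests assert. The $\Delta e$ curve is
fitted with the zero-anchored form $a(e^{bq'} - 1)$ — an offset
exponential constrained to $\Delta e(0) = 0$, which holds by construction.
One shuffle per level is used (no averaging) since repeat-averaging is an
optional refinement, not part of the base procedure.

The evaluation protocol (`evaluate_estimators()`) takes complete sequences,
uses each sequence's intact $S^{est}$ as its reference $H$, degrades to
each level of the plan ($q = 0.15, 0.20, \ldots, 0.60$ by default), runs
all three estimators and pools relative absolute errors
$|\hat H - H|/H \cdot 100$, reported as mean with a
$1.96\,\mathrm{sd}/\sqrt{N}$ interval. The error metric is the absolute
relative deviation — an estimator-comparison table headed by a ratio is
ambiguous between ratio and deviation, and the deviation is the quantity a
user of the correction cares about.

## The synthetic test bed

Real high-resolution mobility data are personal and rarely shareable, so
every stage is validated against a seeded simulator with known ground
truth. An individual has a small set of anchor locations (home, work, and
so on) placed in a planar frame; a Markov visit schedule over the anchors
draws dwell times from a shifted exponential (mean per anchor, floor
`min(900 s, mean/2)` so visits are detectable dwells while keeping the
configured mean exact); travel between anchors is a straight line at
constant speed — deliberately minimal, since travel points exist only to
be discarded by stay-point detection. Positions are sampled at a fixed
interval (default 240 s, matching the point density of high-resolution
smartphone GNSS collections); dwell positions get isotropic Gaussian noise
(default 10 m). Missingness empties whole hour-long windows, because
record completeness is defined on hour intervals; the number of emptied
hours is rounded to hit the target fraction as exactly as the hour count
allows. The default population is 50 users, 28 days, 5–8 anchors in a
20 km extent with at least 2 km separation, per-user missing fractions
Beta-distributed with median near 0.04 — a synthetic stand-in for a
filtered high-completeness smartphone panel (the filtering rule itself,
$q \le 0.15$ and span $\ge 28$ days, is implemented in
`filter_users()`).

What the simulator does *not* emulate: circadian and weekly rhythm,
exploration of new places, bursty revisit statistics, road networks, and
spatially correlated missingness. Passing tests therefore demonstrate that
the pipeline measures what it claims on sequences of known structure — not
that any particular predictability value transfers to human data.

Problem sizes used in the checks are deliberate choices: estimator
consistency uses sequences of $10^5$ symbols (relative error of the
Lempel-Ziv estimate against known Markov rates within 5 % there);
the estimator-comparison benchmark uses 20 chains of $2 \times 10^4$
symbols with entropy rates spanning 0.3–1.5 bits; population-level
orderings use the 50-user default population.

## Known limitations

* The averaged $\Delta e$ correction assumes the degradation behaviour of
  the reference users transfers to the corrected ones. Relative entropy
  inflation under record removal is strongly structure-dependent (for
  sticky, low-entropy chains a $q = 0.6$ removal can nearly double the
  raw estimate; for fast chains it adds under 20 %), so on a population
  with deliberately heterogeneous entropy rates the pooled curve
  over-corrects some users and under-corrects others, and the
  per-sequence extrapolation of $\hat H_{unc}$ can come out ahead. On a
  homogeneous population — users sharing a common routine structure, the
  situation the correction was designed for — the averaged curve is the
  better estimator. The package exposes both so the comparison can be run
  on the data at hand.
* The Lempel-Ziv estimator is biased on short sequences; next place
  sequences at coarse spatial scales can collapse to a handful of symbols,
  where $\Pi_{max}$ values are indicative only (and clamping at the
  random floor can occur).
* Grid aggregation results depend on the (data-anchored) grid origin by
  construction; two datasets differing by a sub-cell translation of a
  shared reference frame will tessellate identically only relative to
  their own bounding boxes.
* The simulator's schedule realism is a free modelling choice, and is
  parameterised (transition matrix, dwell means, anchor geometry) rather
  than fixed, precisely because no canonical generative model of the
  emulated data exists.

## Reproducibility

Every stochastic step — simulation, degradation, shuffling — takes an
explicit seed, and population drivers derive per-user seeds
deterministically from a global seed and the user index, so results are
independent of execution order and two runs are identical.
`scripts/acceptance.R --seed <s> --out <path>` recomputes the headline
quantity (the two-location Fano bound, as a percentage) against the
installed package and writes bare-number JSON.
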