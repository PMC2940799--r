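---
title: "Kernel-convolution detection of recurrent copy-number aberrations: models and design"
author: "kernelCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-convolution detection of recurrent copy-number aberrations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelCNA)
```

# The problem

Array-CGH measures tumor-versus-normal DNA copy number as a log2
ratio at each arrayed probe, summarized here by the probe's genomic
midposition. Within a cohort of tumors sharing a genetic lesion (for
example BRCA1 loss on a p53-null background), the copy-number
aberrations (CNAs) that recur across tumors mark loci under selection.
`kernelCNA` addresses four connected questions:

1. Which genomic regions are *recurrently* gained or lost within one
   tumor group, beyond what noise could produce anywhere in the
   genome?
2. Which regions are aberrated significantly *more often in one group
   than in another* — separating lesion-specific aberrations from the
   background program shared by both groups?
3. How *unstable* is each tumor genome, and do groups differ in that
   instability?
4. Which significant regions are *syntenic between two species*, so
   that mouse-model findings can filter the human tumor genome?

# Group-level recurrence: the smoothed estimate and its null

## The kernel-smoothed estimate

At each probe $p$ (midposition $x_p$) the group's log2 ratios are
aggregated into a kernel height $H(p)$: the sum over samples of the
positive parts for the *gains* curve, of the negative parts for the
*losses* curve, or of the raw values for the *combined* curve. The
smoothed estimate at genome position $x$ is the truncated-Gaussian
convolution

$$\mathrm{KSE}(x) \;=\; \sum_{p:\ |x-x_p|\le R} \exp\!\big(-(x-x_p)^2/2\sigma^2\big)\, H(p),$$

with kernels never crossing chromosome boundaries. By construction
the combined curve equals gains + losses at every position, and the
group curve is additive over samples; both identities are enforced by
tests.

Separating gains from losses before smoothing matters: a locus gained
in half the tumors and lost in the other half would average to zero
in a combined curve, yet both recurrences are real.

## Parameter conventions

* **Kernel width** (`kernelWidth`, default 20 Mb): the user-facing
  smoothing scale. 20 Mb suits BAC arrays of a few thousand probes
  per genome, where probe spacing is ~1 Mb: it averages away
  single-probe noise while keeping focal amplicons and arm-level
  events distinguishable, for both mouse and human layouts.
* **Gaussian sigma** (`sigma`, default `kernelWidth/4`): chosen so
  that ±2σ spans the stated width. Published kernel conventions vary
  (FWHM, 2σ, support width); σ is therefore an explicit parameter, and
  any alternative convention can be matched exactly.
* **Truncation radius** (`truncationRadius`, default one kernel
  width, i.e. 4σ): beyond it the Gaussian has decayed to
  $e^{-8}\approx 3\times10^{-4}$ of its height; truncation there
  bounds the support of every kernel at a negligible bias.
* **Evaluation grid** (`gridStep`, default `kernelWidth/200` =
  100 kb): a regular per-chromosome grid *plus all probe
  midpositions*, so the curve is always evaluated where the data sit.
  Whether a published analysis evaluated only at probe positions is
  unknowable from the text; the grid is configurable, and region
  bounds are interpolated (below) so the grid step only limits bound
  resolution, not detection.

## The permutation threshold

Significance cutoffs for gains and losses are computed separately
from randomized data. The randomization unit is the per-probe
aggregate $H(p)$: the aggregates are shuffled uniformly across all
probe positions genome-wide, which preserves their marginal
distribution while destroying spatial clustering. For each of
`nPerm` shuffles the full curve is recomputed and its genome-wide
maximum absolute value recorded; the threshold is the empirical
$(1-\alpha)$ quantile of these maxima, taken conservatively as the
$k$-th largest with $k = \lfloor \alpha\,n_\mathrm{perm}\rfloor + 1$.
Because the null statistic is a genome-wide *maximum*, exceeding the
threshold anywhere controls the familywise error at $\alpha$ per
curve (gains and losses are each calibrated at their own $\alpha$).
A per-sample permutation variant (`unit = "sample"`), which shuffles
each tumor's profile independently before aggregating, is available
for sensitivity analysis. The default permutation count is 1000; a
published count exists only for the comparative analysis (6000), so
the group-level default is the package's own choice balancing
threshold stability (±few percent) against runtime.

Degenerate inputs are explicit: all-zero aggregates give threshold 0
with a warning, and `scaleCurve()` refuses to rescale by a zero
threshold.

## Regions, peaks and scaling

Significant regions are maximal grid runs at or beyond the threshold;
their bounds are placed at the *linear-interpolated crossing* between
the bounding grid points, so bounds are fractional base pairs (for
this reason regions are plain data frames rather than integer-range
objects; BED export rounds outward). Each region carries its extreme
value as peak. `findPeaks()` reports every interior grid point
strictly exceeding both neighbors (gains; strictly below for losses);
plateaus of tied values report their leftmost point, and chromosome
endpoints are never peaks. Local peaks inside one broad gain are
deliberately kept — they are part of the curve and often sit on the
genes driving the wider event. `scaleCurve()` divides a curve by its
threshold so the significance level sits at ±1, putting cohorts of
different sizes on one display scale; scaling commutes with region
calling.

# Comparative analysis: per-sample curves, SNR and permutation FDR

## Per-sample curves and their scale

Each tumor is smoothed individually with the same kernel, without
separating gains and losses. By default each position is divided by
the local sum of kernel weights, making the per-sample curve a
kernel-weighted *local average* of the tumor's log2 ratios. This
normalization is what keeps per-sample curves on the log2 scale: a
plain kernel sum is larger by the local summed weight (roughly 10× at
BAC density), which would make thresholds like 0.15 — the natural
scale for counting a single tumor's aberrations — meaningless and
density-dependent. The group-level KSE above deliberately stays a
plain sum (its permutation threshold is scale-free, so nothing is
gained by normalizing there), and `normalize = FALSE` restores the
plain sum for per-sample curves, where each row then equals the sum
of that sample's gains and losses curves.

The per-position SNR below is mathematically invariant to this
choice: normalization rescales every sample identically at a given
position, and the SNR is scale-free position by position.

## The SNR and its cutoffs

At each grid position the two groups' per-sample values are compared
with

$$\mathrm{SNR}(x) = \frac{\bar K_A(x) - \bar K_B(x)}{s_A(x) + s_B(x)},$$

using $(n-1)$ sample standard deviations and the convention
$0/0 = 0$. This form — group separation over the *sum* of spreads, the
classic signal-to-noise statistic of genomics group comparison — is
isolated in one function so a pooled-variance or $t$-like alternative
can be swapped in. It is antisymmetric under swapping the groups, and
a locus aberrated equally in both groups scores near zero regardless
of its amplitude: shared aberrations are suppressed by construction,
which is the point of the comparative method.

Cutoffs are set by class-label permutation at a target FDR $q$
(default 0.05, default 6000 permutations). All distinct label
assignments are enumerated when there are no more of them than
`nPerm` (e.g. 3-vs-3 gives $\binom{6}{3}=20$); otherwise `nPerm`
random assignments are drawn. The positive-tail FDR estimate at
candidate cutoff $c$ pools permuted SNR values across positions:

$$\widehat{\mathrm{FDR}}^+(c) = \frac{\mathrm{mean}_\pi\,\#\{x: \mathrm{SNR}_\pi(x)\ge c\}}{\max(1, \#\{x: \mathrm{SNR}_\mathrm{obs}(x)\ge c\})},$$

and the positive cutoff is the smallest *observed* SNR value with
estimate at or below $q$ (the FDR curve is a step function changing
only at observed values, so no continuous search is needed); the
negative tail is handled symmetrically, and `Inf` means no
significant positions in that direction. Per-tail control and pooled
(rather than position-wise) permutation values are the package's
choices where the estimator was otherwise unspecified; both are
documented here so alternates can be compared. Tail counting applies
a $10^{-9}$ relative tolerance so mathematically tied values (the
identity assignment reproduces the observed curve) count identically
in the vectorized permutation path and the observed path — this makes
the implementation agree *exactly* with naive enumeration on toys.

Differential regions are maximal runs beyond the cutoffs, with
interpolated bounds as for group-level regions, labelled "A>B" or
"B>A".

# Instability metrics

* `aberrantFraction()`: the fraction of a tumor's probes with log2
  ratio strictly above the cutoff (gains) or strictly below its
  negative (losses); missing probes leave both numerator and
  denominator. Conventional cutoffs are 0.3 for mouse BAC profiles
  and 0.2 for the dimmer human profiles — configuration, not code.
* `welchTest()`: two-tailed unequal-variance $t$ test
  (Welch–Satterthwaite), wrapping `stats::t.test` with explicit
  degenerate handling (both groups constant: $t=0, p=1$ if means
  agree, $p=0$ with a warning otherwise).
* `cnaCountSweep()`: for each tumor's combined per-sample curve and
  each threshold $t$ in a sweep (default 0.02–0.8 in 0.02 steps,
  covering the range over which BAC cohorts separate), the number of
  maximal runs above $+t$ plus runs below $-t$ (strict inequality,
  never crossing chromosomes). Group means are contrasted per
  threshold with the Welch test and contiguous significant threshold
  intervals reported. Counting *runs* matches counting the
  plotted excursions beyond a threshold; a peak-counting mode
  (`mode = "peaks"`) is provided because prose descriptions of such
  sweeps sometimes say "peaks", and the two modes differ when one
  excursion carries several local peaks.
* `classifyTumorType()`: epithelial/mesenchymal typing from E-cadherin
  and Vimentin log-expression; Mesenchymal when Vimentin exceeds
  E-cadherin by more than the margin (default 0.5 log units),
  Epithelial in the mirror case, Ambiguous otherwise — including a
  difference of exactly the margin, which published rules leave
  undefined.

# Cross-species synteny mapping

Genes are assigned to regions by the any-overlap rule (≥1 bp of the
gene's `[start, end)` interval inside the region): "maps to" is read
inclusively, so a gene straddling a region boundary is assigned. An
ortholog pair is *conserved* when its two genes fall in significant
regions of the same direction in the two species (gain–gain or
loss–loss; for comparative regions, the same contrast direction).
Conserved pairs are grouped by their (species-A region, species-B
region) combination — the simplest partition that yields one row per
region pair; a region of one species spanning several synteny blocks
of the other therefore splits into one overlap per counterpart
region. Each overlap reports bounds from the start of its first gene
to the end of its last gene per species, distinct gene counts, the
distinct ortholog-pair count, and a strand-inversion flag: `NA` when
either species contributes a single gene, otherwise the sign of the
Spearman correlation of gene-start orders (+1 on exact ties, with a
warning) — the rank-correlation sign generalizes the obvious
two-gene rule to any gene count. Overlaps supported by one pair are
flagged as singletons so abbreviated reports can drop them while full
output keeps every pair exactly once. Many-to-many homologies are
handled by counting distinct pairs, without weighting.

# The synthetic cohort generator

The generator emulates two-species BAC-array studies: ~3,080 probes
for a mouse-like genome (19 autosomes + X; the human-like default is
~3,500 over 22 + X, a free choice since published human BAC counts
vary), 30–60 samples per group, Gaussian log2 measurement noise
(typical sd 0.2), and planted CNAs given as chromosome, interval,
direction, carrier frequency, amplitude mean/sd, and an optional
whole-chromosome flag (implemented as the full `[0, length)`
interval, with identical frequency semantics). Probe midpositions are
uniform-random within chromosomes, allotted proportionally to length
(at least one per chromosome) — deliberately irregular, to exercise
the density sensitivity of a plain-sum KSE. A carrier's amplitude is
one draw applied to *all* probes of the event (segment-level biology;
no within-event gradient), and the simulator logs exactly which
sample carries which event at which amplitude, so every downstream
claim can be checked against ground truth. Ortholog tables are built
from synteny blocks (equally spaced genes; inverted blocks reverse
species-B gene order and flip strands).

A whole scenario — genome, probe count, and per-group sample counts,
noise levels, tumor-type mixes and planted events — can be described
in one YAML file and materialized (with its ground-truth log written
alongside the aCGH tables) by `simulateScenario()`, so simulation
studies are reproducible from a single small text file and a seed.

Random draws are consumed in a fixed, documented order so seeds are
portable across reimplementations of the same algorithm: carrier
indicators (one uniform per sample per event, events in listed
order), then carrier amplitudes (one normal per carrier), then the
noise matrix (probes × samples, filled column by column), then
tumor-type draws (one per sample).

What the generator does **not** emulate: dye-swap/duplicate-spot
structure and error-model weighting of real two-color arrays, GC/wave
artifacts, allele-specific copy number, within-event amplitude
gradients, or correlated noise along the genome. Passing tests
therefore demonstrate correctness of the statistical machinery under
idealized independent noise — not robustness to array artifacts,
which upstream normalization is assumed to have handled.

# Numerical and testing choices

* Coordinates are 0-based half-open everywhere internally and in BED
  output; ortholog and aCGH readers validate on ingest. Chromosome
  order is fixed by the `Genome` object (1..n, then X).
* Missing log2 values are excluded from kernel sums and from
  aberrant-fraction denominators — never imputed.
* aCGH text round trips are exact at six decimals; loaders never drop
  rows silently (duplicates and unparseable cells are errors or
  counted messages).
* The convolution engine is checked against a brute-force
  $O(\text{samples}\times\text{probes}\times\text{grid})$ double sum
  (50 random small datasets, agreement within $10^{-9}$), the FDR
  machinery against exhaustive enumeration on 3-vs-3 toys, the Welch
  wrapper against the textbook formulas, and region/count scanners
  against naive run scanners.
* Calibration and power suites use reduced sizes chosen once:
  familywise error on 200 null cohorts (1,000 probes, 30 samples,
  noise 0.2, 200 permutations, 2 Mb grid) expected in [0.01, 0.11]
  around the nominal 0.05; recovery of a planted 30 Mb gain
  (frequency 0.6, amplitude 0.8, 30 samples, 3,080 probes, 100 runs,
  each run redrawing the full dataset including the probe layout)
  requiring an overlapping called region with a local peak within
  half a kernel width of the event centre; comparative sensitivity/
  specificity on 30-vs-30 cohorts (1,000 probes, 500 permutations)
  where a group-specific gain must be called and an equal-frequency
  shared gain must not; Welch type-I error over 2,000 null draws.
  With a plain-sum KSE the *global* maximum of a broad event's
  plateau tracks random probe-density fluctuations, which is why
  recovery is scored by the nearest local peak within the called
  region rather than by the global maximum alone.

# Known limitations

* No per-sample segmentation (CBS/HMM): the method is
  smoothing-based by design and complements, not replaces,
  segment callers.
* Pairwise group contrasts only; no covariate adjustment.
* The uniform-probe synthetic layout understates the clustering of
  real BAC maps; density-sensitive conclusions should be re-checked
  with the probe map of the actual platform.
* The comparative FDR is estimated per tail from pooled permuted
  values; position-wise or joint two-tailed variants would need the
  alternate estimator slot.
* Raw-intensity processing (GPR/CEL), error-model weighting and
  annotation lookups are out of scope; inputs are normalized log2
  tables and ortholog tables in the documented TSV layouts.
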