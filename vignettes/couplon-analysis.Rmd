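---
title: "Regulon and couplon analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulon and couplon analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplonscan)
```

## The scientific setting

In bacteria, the composition of the RNA polymerase holoenzyme (which sigma
factor it carries) and the spectrum of abundant nucleoid-associated proteins
(NAPs) both change over the growth cycle, and their joint action organises
genomic transcription in space (along the OriC–Ter axis of the circular
chromosome) and in time (from inoculation through exponential growth to
stationary phase). A *couplon* is the set of genes that belongs to both the
regulon of a NAP or global transcription factor and the regulon of a sigma
factor — genes under the pair's joint control. couplonscan quantifies three
aspects of couplon biology on user-supplied or simulated data: spatial
clustering on the chromosome, growth-phase expression dynamics, and the
GC content of promoter regions (a proxy for the thermodynamic stability of
the DNA that transcription must open).

## Couplon construction

Regulons come from a regulator→target table with effect signs. Couplon
membership is the plain intersection of target-gene sets, *ignoring* signs.
This was a genuinely open choice: one could intersect only same-sign edges
(e.g. activation-only couplons). We default to unsigned membership because
the couplon concept is about joint *control*, not joint *direction*, and a
gene activated by a NAP but repressed by a sigma factor is still jointly
controlled; sign-restricted membership remains available through the
`effects` filter of `regulon_members()`. Genes listed under the same
regulator with conflicting signs collapse to effect `"dual"`. Alternative
sigma factors are handled as separate regulons (RpoS, RpoN, RpoH, RpoE),
never pooled into a single aggregate, because their regulons have distinct
sizes, locations and dynamics; a pooled analysis can always be run by
passing the union of their member sets.

All coordinates are 0-based, half-open and circular. GFF3 input (1-based) is
converted at the boundary: the TSS of a `+` gene is `start − 1`, of a `-`
gene `end − 1`.

## Spatial enrichment model

A gene set of size $n$ (of $N$ annotated genes) is counted per window on a
sliding grid and standardised against the null that the set is a uniform
draw of $n$ genes without replacement:

$$Z_w = \frac{O_w - \mu_w}{\sigma_w}.$$

Two interchangeable nulls are provided. The resampling mode estimates
$\mu_w, \sigma_w$ from 10,000 uniform draws (the reference procedure; the
draw count and seed are recorded in every profile). The analytic mode uses
the hypergeometric closed form
$\mu_w = n k_w/N$, $\sigma_w^2 = n \frac{k_w}{N}(1-\frac{k_w}{N})\frac{N-n}{N-1}$,
with $k_w$ the number of annotated genes in window $w$. The two agree as the
number of draws grows; the test suite enforces agreement against complete
enumeration of all $\binom{20}{4} = 4845$ subsets on a tiny genome.

Parameter choices, with units and defaults:

* `window_size = 100000` bp — the analysis window.
* `step = 10000` bp — window spacing. Only the window size is canonical; the
  step is our choice. A 10 kb slide gives smooth profiles; tiling
  (`step = window_size`) is available and changes no conclusion that
  overlapping windows support, only the profile's resolution.
* `n_samples = 10000`, `threshold = 2` — enrichment is called at $Z > 2$,
  depletion at $Z < -2$, with no multiple-testing correction across windows
  (the fixed-|Z| rule is the reference convention; windows are strongly
  dependent under a sliding grid, so per-window error control would be
  misleading anyway).

Genes enter windows as TSS points, not intervals: counting by gene extent
would weight long genes more, and "a gene is in a window" is otherwise
ambiguous for genes straddling window edges. Null sets are drawn from
annotated genes, not from random chromosomal positions, so the null carries
the same gene-density landscape as the observed set. Windows with
$\sigma_w = 0$ (possible when $n = N$ or a window is empty of genes) are
called `undefined` rather than producing infinite scores, and are excluded
pairwise from profile correlations.

Spatial organisation of two sets is compared by the Pearson correlation of
their Z-profiles over the full circular grid. Splitting by replichore is a
display option, not part of the statistic.

## Temporal profile model

The averaging order is fixed and matters: (1) each member gene is min–max
normalised to $[0,1]$ individually, (2) normalised patterns are averaged per
timepoint with equal gene weights, (3) the averaged curve is rescaled to
$[0,1]$. The extremes of the averaged curve *before* step 3 are reported
with every profile: an averaged minimum near 0 and maximum near 1 mean the
member genes rise and fall together; extremes near 0.5 mean the set is
heterogeneous and its "profile" is mostly an artifact of rescaling. Equal
gene weights (rather than expression-level weights) were chosen so that one
highly expressed gene cannot impersonate a regulon; this is also why step 1
precedes step 2.

Constant genes carry no temporal shape and are excluded from set averages
(with a logged count) instead of being mapped to an arbitrary level that
would flatten profiles. Timepoints are carried in minutes after inoculation
(default design 60, 120, 180, 300, 420) and never interpolated. With five
timepoints a profile correlation has $n = 5$; the value is reported with its
$n$ and without a p-value.

**Remapping envelope.** The reference reading of "10% random remapping" that
we implement as the default replaces `round(0.10 · |set|)` members with genes
drawn uniformly from outside the set, recomputes the profile, and reports
the per-timepoint SD over 100 replicates. The alternative reading — permuting
the expression-pattern-to-gene assignment for 10% of *all* genes while
keeping the membership fixed — is implemented as `mode = "permute"`. We
default to replacement because it models the actual uncertainty in regulon
catalogues (membership error), whereas genome-wide permutation models
measurement mix-ups, which are not set-specific. The replicate count (100)
is our choice; it is configurable, the seed is recorded, and the envelope is
reproducible from the stored replicate profiles.

## Promoter GC profiles

Contexts span −300 to +200 bp around the TSS on the coding strand
(minus-strand genes are reverse-complemented so +1 is always downstream of
the transcription start), extracted circularly across the origin. Both span
and the 21 bp moving-average smoothing width are declared defaults, not
values inferred from any particular dataset; both are configurable. The
per-position statistic is the fraction of G|C across sequences with N bases
excluded from numerator and denominator; ambiguity codes other than N are
rejected at load. The uniform centred smoother reproduces constants and
linear trends exactly on the interior of the span; near the edges it falls
back to the partial window that fits.

## What the synthetic-data generator emulates

The generator plants exactly the structure the analyses are designed to
detect, with defaults chosen once to resemble an E. coli-scale study:

* **Genome**: 4,000 genes uniform on a 4.6 Mb circle; promoter GC falling
  linearly with circular distance from OriC (position 0), 0.56 at OriC to
  0.48 at Ter, symmetric on both replichores — the simplest gradient shape
  consistent with the qualitative observation that GC-rich sequence
  concentrates near the origin and AT-rich sequence near the terminus. Bases
  are i.i.d. at the local GC probability.
* **TRN**: a roster of four NAPs, two global TFs and five sigma factors with
  regulon sizes between 100 and 800 genes; each regulon draws a configured
  fraction of members from within ±100 kb of its chromosomal centre; each
  NAP/global-TF regulon shares a configured fraction of its members with
  each sigma regulon. In the default "exact overlap" mode shared members are
  drawn from genes in exactly one sigma regulon and the remaining members
  from genes outside all sigma regulons, so couplon sizes equal
  `round(fraction × size)` exactly and counting oracles are sharp.
* **Expression**: one dominant temporal program per gene — early
  (1.00, 0.85, 0.50, 0.20, 0.10 across the five timepoints), mid
  (0.20, 0.70, 1.00, 0.50, 0.25), late (0.10, 0.20, 0.60, 1.00, 0.30) or
  flat — with genes in a sigma regulon following the sigma parent's program
  (this plants the observed sigma-side asymmetry of couplon expression;
  switchable), regulator-encoding genes following their own regulon, and
  `value = baseline · program + N(0, noise_sd · baseline · range)` clipped
  at zero, `noise_sd = 0.2` of the program range by default. The late
  program's decline after its 300-minute peak is the planted analogue of
  stationary-phase repression of the RpoS axis by FIS; the `fis_mutant`
  condition replaces it with a derepressed variant
  (0.10, 0.20, 0.60, 0.95, 1.00) that keeps rising. The wild-type and
  derepressed late programs correlate at r ≈ 0.67, a deliberately pronounced
  planted contrast. Flat (unregulated) genes get noise scaled by their mean
  program level so they fluctuate realistically instead of being constant.

One dominant program per gene (no additive mixing) keeps recovery tests
interpretable — the estimand is unambiguous. Real expression data violate
most of these simplifications: library-size and batch effects (inputs here
are assumed pre-normalised), genes under multiple regulators with
interacting effects, regulon catalogues with sign and condition dependence,
non-uniform gene density, and GC structure far richer than one linear
gradient. Passing tests on the generator therefore demonstrates that the
*computations* are correct and that planted signal of realistic size is
recovered — not that any particular biological claim holds in a given real
dataset.

## Numerical and degenerate-input conventions

* Monte-Carlo nulls use a single recorded seed; all generator and envelope
  randomness is seed-controlled, and identical seeds give byte-identical
  pipeline outputs.
* `n = N` null sets, empty gene sets, constant genes, constant averaged
  curves, sub-3-window correlations and zero-variance profiles each have an
  explicit behaviour (flag, warning or error) documented on the respective
  function; nothing silently returns ±Inf or NaN.
* Min–max normalisation is affine-invariant per gene, so profiles are
  insensitive to per-gene scale and offset by construction; the test suite
  asserts this on 1,000 random cases.

## Problem sizes used by the test suite

Unit tests run on genomes of 10–500 kb with tens to hundreds of genes, where
every oracle (exhaustive enumeration, brute-force set intersection, manual
reverse complement, closed-form moments) is computable exactly. The
full-scale property checks use the default study geometry — 4,000 genes on
4.6 Mb, 100 kb/10 kb grids, 10,000-draw nulls, 10 replicate seeds — which we
consider the smallest size at which the spatial statistics behave as they
do in practice.

## Known limitations

* The Pearson correlation between Z-profiles is a noisy statistic when one
  set's profile is dominated by a single cluster: with 100 kb windows on a
  4.6 Mb chromosome the correlation between a clustered set and a genuinely
  unrelated uniform set has a sampling SD of roughly 0.15 (about 46
  effectively independent windows, with high leverage on the cluster's
  windows). Correlations of this magnitude should not be over-interpreted in
  either direction; the package reports the number of windows used with
  every correlation for this reason.
* With five timepoints, profile correlations are based on n = 5 and are
  reported without significance claims.
* The GC profile equates promoter "stability" with GC content; no
  nearest-neighbour thermodynamic model is attempted, and no motif analysis
  is performed.
* The TRN is an input. No network inference, hierarchy or motif analysis is
  done, and genes absent from the annotation are dropped (with counts), not
  rescued.
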