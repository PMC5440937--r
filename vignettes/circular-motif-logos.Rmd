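---
title: "Measuring and drawing intra-motif dependencies"
author: "motifRing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and drawing intra-motif dependencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifRing)
```

## The model

A motif is summarized from `N` aligned, equal-length (`L`), gap-free
nucleotide sequences. Two layers are computed:

**Composition (nodes).** Each position `i` gets nucleotide frequencies
from pseudocounted counts and an information content
`R_i = log2(4) − (H_i + e_n)` bits, where `H_i` is the Shannon entropy of
those frequencies and `e_n = 3/(2·ln 2·N)` is the small-sample correction
for a four-letter alphabet. `R_i` is clamped to `[0, 2]`. This is the
standard sequence-logo stack height; the correction compensates the
downward bias of plug-in entropy at small `N` and vanishes as `N` grows.
It is on by default and can be disabled (`correction = FALSE`), since
deposited motif files differ in whether their stored `bit` values include
it.

**Dependency (links).** For every unordered position pair `(i < j)` a
4×4 dinucleotide contingency table is built from *raw* counts — never
pseudocounted, so the statistics keep their sampling calibration. Two
metrics are offered:

* `Q = Σ_k (O_k − E_k)²/E_k` over the 16 cells, with expected counts
  `E_k = N·p_i(a)·p_j(b)` from the pair's own marginals. Cells with zero
  expectation contribute zero; this is routine at conserved positions and
  is a convention, not an approximation (those cells also have `O_k = 0`).
  Significance is the upper chi-square tail with `m − 1 = 15` degrees of
  freedom. The classical count for a test with estimated marginals is
  `(4−1)(4−1) = 9`; we default to 15 — the convention under which the Q
  score was specified — and expose `df = "marginal"` for the classical
  choice. With 15 df the p-values are conservative (larger) relative to
  the 9-df calibration, which only makes link filtering stricter.
* Mutual information `I(X;Y) = Σ p(x,y) log2[p(x,y)/(p(x)p(y))]`, in bits
  (base 2, so node heights and link strengths share units); `0·log 0`
  terms are zero. Significance uses Chebyshev's inequality against a
  permutation null: column `j` is independently permuted `B` times
  (preserving both marginal compositions exactly while destroying the
  association), and if the observed MI lies `K` null standard deviations
  above the null mean, `P ≤ 1/K²`. The bound is distribution-free, hence
  honest for the skewed null of MI, at the price of being loose. The null
  is computed per pair; pooling the null over all pairs would assume
  exchangeable marginals across positions, which conserved positions
  violate, so per-pair is the default and only mode.

The two metrics deliberately disagree about what "dependent" means: χ²
measures co-occurrence and is most powerful between conserved positions,
while MI measures reduction of uncertainty and vanishes as either position
becomes invariant. For a pair of near-invariant positions MI tends to 0
even though the dominant dinucleotide always co-occurs; for two uniform,
strongly coupled positions MI approaches 2 bits. Both behaviours are
asserted in the test suite.

Degenerate inputs are handled by convention rather than error: a fully
conserved pair gives `Q = 0, p = 1`; a degenerate permutation null
(`stdev = 0`) gives `p = 0` when the observation exceeds the null mean and
`p = 1` otherwise; `K ≤ 0` gives `p = 1`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pseudocounts` | 0.25/nt | added to every position's counts; avoids zero frequencies in small samples. 0.25 is a weak prior (one total phantom observation). |
| `background` | 0.25/nt | genomic background frequencies; carried in the JSON format and used for display ordering. Heights use the uniform-maximum convention, not relative entropy. |
| `B` | 1000 | permutations per pair for the MI null. The null mean and sd stabilize by a few hundred; 1000 keeps the `K` estimate's own noise well below the Chebyshev slack. `B = 0` skips significance when only the ranking is needed. |
| `correction` | on | the `e_n` entropy correction above. |
| `df` | 15 | chi-square degrees of freedom (`m − 1`); `"marginal"` gives 9. |
| `alpha`, `percentile` | off | link filters; `percentile = 0.33` drops the weakest third by value, the convention used for structured-RNA figures. |
| ≥ 25 sequences | warning | below ~25 sequences both metrics are dominated by sampling noise; the package warns but proceeds. |

No multiple-testing correction is applied by default across the
`L(L−1)/2` pairs; an optional Bonferroni flag is provided. The default
matches the tool's intended exploratory use — filtering is a display
decision, and the Chebyshev bound is already conservative.

## The synthetic generator

`simulateAlignment()` draws independent positions from a per-position
frequency profile (uniform by default) and injects dependency by
copy-with-error: position `j` copies position `i`'s letter with
probability `1 − ε`, else redraws from the profile. This is the simplest
mechanism with a tunable MI: at `ε = 0` a uniform pair approaches 2 bits,
at `ε = 1` it is independent. The generator is seeded and restores the
caller's RNG state.

It emulates what the statistics need — controlled marginals and a known
coupled pair — and nothing else. Real binding sites have positional
conservation gradients, flanking background with neighbour correlations,
alignment errors and composition bias; none of these are modeled. Passing
the recovery tests therefore demonstrates that the estimators and their
ranking behave correctly under known truth, not that every biological
dependency of a given strength will be detected in real data.

`concatSpliceFragment()` (16 + 21 + 16 → 53 bases: donor site,
branch-point window, acceptor site) and `extendSite()` (e.g. 20 + 25 + 20
→ 65 nt: flanks around a binding site for estimating the background
dependency level) are the fragment-assembly conventions for composite
motifs, enforced as pure functions.

## File format and numerics

The JSON-Graph document uses the keywords `id`, `background`,
`pseudocounts`, `nodes` (`index`, `label`, `bit`, `base`, `freq`) and
`links` (`source`, `target`, `value`), with `background`/`pseudocounts`
in A,T,C,G order on disk and each node's `base`/`freq` co-sorted ascending
by frequency (alphabetical tie-break). One object per node and per link is
used, the natural JSON-Graph nesting. Internally everything is A,C,G,T;
the on-disk order is honored only at the serialization boundary, and U is
unified with T for counting while the RNA alphabet is remembered for
display. Missing `background`/`pseudocounts` default to 0.25 per
nucleotide. Floats are written with 6 significant digits; the reader
accepts frequency sums within 1e-5 of 1 (four rounded values can drift by
about 2e-6) and renormalizes, so a write/read round-trip agrees within
1e-6 per value and in-memory objects always satisfy the exact sum
invariant. Labels default to the decimal position string.

Links are serialized with the schema's three keywords only; the in-memory
statistic/p-value/metric annotations are working state, and a re-read
graph recovers `statistic = value` with unknown significance. Converted
count matrices (JASPAR counts; MEME probabilities × `nsites`, defaulting
to 20; TRANSFAC numbered rows) always yield an empty link list — matrix
formats carry no dependency information. `nSequences` for a converted
matrix is taken as the largest raw column sum, rounded; it only enters
through the `e_n` correction.

## Rendering choices

Sectors of equal angle are laid anticlockwise from `startAngle` (90°,
i.e. twelve o'clock, by default) with a small gap; node 1 starts at
`startAngle`. Within a stack, letters are drawn in ascending frequency
order from `radiusOuter` outward, so the most frequent letter sits
outermost; each letter's radial extent is its frequency share of
`bit × bitScale`. Ribbons are quadratic Bézier chords between sector
midpoints at `radiusInner` with the control point at the circle center;
stroke width is affine in the link value over `ribbonWidthRange`
(equal-valued links collapse to the midpoint width — any monotone map
would do; linear width was chosen over area scaling for legibility of
weak links). All coordinates are printed with fixed 4-decimal formatting,
making repeated renders byte-identical. Interactive exploration (sliders,
click-to-isolate) is deliberately replaced by the pure filter operations
`filterPvalue()`, `filterPercentile()` and `linksOfNode()`.

## Problem sizes used by the tests

The oracle-equivalence tests enumerate every two-letter alignment of up
to six sequences (4^6 = 4096 alignments) and compare Q and MI against
direct formula evaluation at 1e-9. The recovery test uses 100 simulated
alignments of 200 sequences × 20 positions with one injected pair at
ε = 0.1 and requires the pair to top the MI ranking in ≥ 95 of 100 runs;
with these sizes the injected MI (≈1.4 bits) is two orders of magnitude
above the `15/(2N ln 2)` noise floor of independent pairs, so the margin
is wide. Permutation-null tests use `B` of 50–1000. These sizes were
chosen to exercise the asymptotics cleanly while keeping the default
suite quick on a single core.

## Limitations

* Both metrics are pairwise; higher-order dependencies are projected onto
  pairs. Model-based approaches (mixture or Markov models) are out of
  scope.
* The Chebyshev bound is loose by construction; treat its p-values as
  screening thresholds, not calibrated tail probabilities.
* χ² with df = 15 is a convention (see above); users wanting classical
  calibration should set `df = "marginal"`.
* Inputs must be pre-aligned and gap-free; sequences with gaps or
  ambiguity codes are excluded (with a logged count), not realigned.
* The percentile filter is not idempotent under re-application: its
  cutoff is the quantile of the links it receives, so filtering survivors
  again removes more. Apply it once to the full link set.
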