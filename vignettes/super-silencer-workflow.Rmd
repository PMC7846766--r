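---
title: "Calling and characterizing H3K27me3-rich regions (super-silencers)"
author: "silencerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing H3K27me3-rich regions (super-silencers)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencerscape)
```

## The problem

Super-enhancers — broad clusters of H3K27ac peaks with exceptionally high
signal — have a repressive mirror image: broad clusters of H3K27me3 peaks
deposited by Polycomb (PRC2/EZH2). We call these H3K27me3-rich regions
(MRRs); they are candidate *super-silencers* that can repress genes both
proximally and through long-range chromatin loops. This package implements
the computational workflow for finding MRRs from ChIP-seq data and
characterizing how they engage the 3D genome:

1. **MRR calling** — peak stitching, signal ranking, slope-1 cutoff;
2. **anchor chromatin states** — A/R/B/Q labels for loop anchors and
   observed/expected state-pair enrichment under a marginal homogeneous
   model;
3. **gene–MRR looping** — proximal / distal / internal classification via
   interaction anchors, and a filtered random control gene set;
4. **permutation overlap tests** — same-chromosome shuffling against an
   external element list;
5. **expression specificity** — entropy-based specificity across tissue
   facets;
6. **differential 4C** — gained / lost / unchanged loop classification
   between conditions with bait-distance summaries;
7. **signal integration** — total ChIP signal areas at 4C regions, tertile
   labels, TF-binding Z-score matrices.

Every stage can be exercised end-to-end on synthetic data with planted
ground truth (the `make_*` generators and `simulate_full()`), so the whole
pipeline is testable offline; the numbered scripts under `analysis/` narrate
one such run.

## MRR calling

Peaks on the same chromosome are merged when the gap between consecutive
peaks is strictly below the stitching window; abutting or overlapping peaks
always merge. The defaults are the marks' conventional windows: **4 kb** for
H3K27me3 (MRRs) and **12.5 kb** for H3K27ac (super-enhancers). Each stitched
region is scored as treatment minus control signal mass (value × bp) over
the stitched interval, floored at zero — the total-signal convention of
ROSE-style super-enhancer callers. Because broad-domain callers are
sometimes described as ranking by *average* signal, a density mode
(`score_mode = "density"`, score divided by interval length) is provided and
the mode used is recorded on the result; total signal is the default.

The rank cutoff scales both axes of the ascending score curve to [0, 1] and
takes the point minimizing scaled score minus scaled rank — the tangent
point where the hockey-stick's slope reaches 1. Ties break toward the
largest index (fewer, more conservative rich calls), and membership uses a
strict inequality, so the tangent point itself stays "typical". Curves with
fewer than 3 points or constant scores are degenerate: everything is labeled
typical with a warning rather than guessing a cutoff.

```{r mrr-demo}
genome <- make_genome(1, 1e7)
pk <- make_peaks_and_signal(genome, seed = 42)
called <- call_regions(pk$peaks, pk$treatment, pk$control, mark = "H3K27me3")
table(S4Vectors::mcols(called)$label)
```

A property worth stating: a slope-1 rank cutoff on noisy scores always
labels some top tail "rich" — it finds the elbow of whatever curve it is
given. Absence of planted structure therefore shows up as *failure to
recover planted truth*, not as zero rich calls; the negative-control tests
are phrased accordingly.

## Anchor states and pair enrichment

Anchors are A (overlap only H3K27ac peaks), R (only H3K27me3), B (both), Q
(neither); in repressive mode, MRR takes precedence over typical H3K27me3
(T), and anchors overlapping neither are dropped from that analysis (the
count is reported). State-pair proportions are compared with the
expectation from anchor-slot marginals under independent pairing:
`p_s^2` on the diagonal and `2 p_s p_t` off it, with
`log2(observed/expected)` as the enrichment. Marginals are counted over
anchor *slots* (each loop contributes two), matching the homogeneous-pairing
null; counting unique loci instead is available via `marginals = "loci"`.
Unobserved pairs are reported as `NA` rather than `-Inf`; an optional
`epsilon` smooths both proportions when a finite value is needed.

## Gene–MRR looping

For each gene–MRR pair, *proximal* evidence is promoter–MRR overlap or
anchor co-occupancy; *loop* evidence is an interaction joining the MRR to
the promoter; *internal* requires proximal evidence plus a supporting loop
whose both anchors fall in the same MRR; *distal* requires the
promoter-side anchor to be clear of the MRR. Precedence is internal >
proximal > distal. The promoter is a symmetric TSS ± 2 kb window by default
(configurable); both proximal evidences are accepted (logical OR) and
flagged separately in the output, since anchor co-occupancy and plain
overlap are not distinguished in the source material. The control gene set
filters out genes overlapping blacklist or H3K9me3 regions (constitutive
heterochromatin), keeps genes touched by any interaction anchor, and
samples `floor(mean(category sizes))` genes — e.g. category sizes
(50, 41, 49) give 46 — uniformly without replacement under a required seed.

## Permutation overlap testing

`shuffle_same_chromosome()` relocates each region uniformly on its own
chromosome, preserving length; shuffled regions may overlap each other and
their original position (no exclusion is assumed). The test reports both
the one-sided one-sample t-test of the shuffled overlap percentages against
the observed one (alternative: expected < actual) and the empirical
permutation p-value `(1 + #{expected >= actual}) / (n + 1)`; the empirical
p is the safer headline, the t-test mirrors the conventional presentation.
The default is 1000 shuffles. The implementation draws all shuffles in one
batch and resolves them with a single overlap query, which keeps the
1000-shuffle default and the calibration studies fast.

## Expression specificity

With facet profile `p_i = x_i / sum(x)`,
`specificity(X) = 1 - entropy(X) / log2(N)` in bits with the `0 log 0 = 0`
convention: 0 for a uniform profile, 1 for a point mass, NA for an all-zero
vector. Samples are first averaged per facet; a cell line of interest joins
the 69 reference facets as its own facet, giving N = 70. Binning uses Q1
and Q3 of the defined scores (linear interpolation): low iff `<= Q1` and
`< Q3`, high iff `>= Q3` and `> Q1`, else mid — so a degenerate spread
(Q1 = Q3) puts every defined score in mid. Gene chromatin states for
state-change tables use the union of gene body and promoter, with
precedence SE > MRR > H3K27ac > H3K27me3 (rich regions subsume their
constituent marks); fold changes use a pseudocount of 1 on the expression
unit.

## Differential 4C

Fragments are significant at p < 0.05 (the conventional cutoff of
restriction-fragment interaction callers); a condition's set is the union
over its replicates, keyed by exact fragment coordinates — both conditions
derive from the same restriction map, so coordinates are comparable (a
tolerance merge is not needed for the synthetic data and is out of scope).
Gained/lost/unchanged is exact set algebra on those keys. Distance is
|fragment midpoint − bait midpoint| (midpoint chosen; start or nearest-edge
differ by at most a fragment length); trans fragments are flagged and kept
in the status classification but excluded from all distance analytics.
Distance tertiles are computed per comparison on the union set's cis
distances as balanced rank tertiles — sorted distances split into three
contiguous groups whose sizes differ by at most one. This coincides with
the interpolated-quantile split whenever n is divisible by 3, and unlike a
raw quantile threshold it keeps the middle category populated at any n.
Fixed genomic breakpoints would also be defensible, but per-comparison
tertiles adapt to each bait's reach.
Categories with fewer than 3 fragments are excluded from the
proportion-unchanged summary.

## Signal integration

`signal_area()` tiles a region left-to-right in bins (final bin truncated
to its true width), takes the mean track value per bin (absent coverage
is 0), and reports `sum(Sig * BS)`. At `bin_size = 1` this reduces exactly
to the per-bp signal mass, which the tests exploit as an oracle. The bin
size is not dictated by the method; 50 bp is the default and is recorded
per run. Tertile labels check `<=` the lower boundary first, so an
all-equal cohort degenerates to "low" with a warning. TF Z-scores
standardize per-factor overlap counts across regions, with Z = 0 when a
factor's counts are constant; downstream clustering of that matrix is
presentation plumbing and left to standard tools.

## The synthetic data and what it does (not) show

The generators emulate the *structure* the pipeline consumes, not the full
texture of real data:

- `make_peaks_and_signal()` plants rich clusters (8 peaks, intra-cluster
  gaps 0.5–3 kb, 10× Poisson signal over a flat background of mean 1 per
  10 bp bin) and isolated peaks at one third of the cluster enrichment,
  all separated by more than the stitching window. Real H3K27me3 domains
  have autocorrelated backgrounds, copy-number waves and mappability
  artifacts that this does not model.
- `make_interactions()` allocates pair counts by largest remainder of
  n × preference (remainder multinomial), then draws anchors uniformly
  within state — the realized pair distribution matches the planted matrix
  to rounding, so recovery tolerances test the estimator, not the sampler.
  Real Hi-C has distance decay and domain structure that are explicitly out
  of scope.
- `make_expression()` draws symmetric Dirichlet profiles (log-uniform
  concentrations in [0.01, 100]) scaled by lognormal totals; planted
  specificity is the formula applied to the drawn values, hence exact.
- `make_fourc_pair()` uses ~300 cis fragments over 6 Mb, control
  significance falling logistically from 0.9 to 0.35 with bait distance and
  a status-flip probability rising from 0.08 to 0.65, so changed loops are
  planted to be farther than unchanged ones; replicate 2 reports each
  significant fragment with probability 0.7 while replicate 1 reports all,
  so pooled-union recovery is exact by construction.

Passing the planted-recovery and calibration suites therefore demonstrates
correctness of the estimators under the stated generative conditions; it
does not certify performance on real ChIP-seq/Hi-C/4C data with their
unmodeled artifacts.

## Numerical choices and scale

Problem sizes in the tests and the acceptance script are chosen to make the
statistical checks sharp while keeping a laptop-scale run: a 10 Mb
single-chromosome genome with 20 planted clusters and 500 isolated peaks
for recovery; 20,000 loops for planted-enrichment recovery (±0.05 on
log2 ratios) and 50,000 for the homogeneous null (±0.1); 200 replicates ×
100 shuffles for p-value calibration (KS against uniform, discreteness of
the empirical p acknowledged); 100 simulated 4C libraries for the
distance-effect frequencies. Quantiles everywhere are type-7 (linear
interpolation). All generator randomness fans out from one seed through
fixed per-generator substreams, so adding a generator never perturbs the
draws of another, and identical (parameters, seed) reproduce byte-identical
files.

## Known limitations

- Coordinates are handled internally as GRanges (1-based closed); BED-style
  inputs are converted at parse time and back on write. Mixed "chr1" vs
  "1" naming is not aliased — unmatched chromosome names produce a warning.
- The caller does not model copy-number or input-coverage biases beyond the
  supplied control track; tracks are assumed depth-normalized.
- Hi-C loop calling, contact matrices, TADs/compartments, read-level
  processing and differential-expression testing are upstream or out of
  scope.
- The t-test on shuffled percentages treats shuffles as a sample; when all
  shuffles give the same percentage the t-test is undefined and only the
  empirical p is reported (with a warning).
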