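---
title: "Neutral dispersal and shared-segment selection in gut plasmidomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral dispersal and shared-segment selection in gut plasmidomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidrift)
```

# The scientific problem

Plasmids move between bacterial hosts and between people. Two opposing
forces can explain their distribution across a human cohort: neutral
(stochastic) dispersal, in which each person's plasmid community is a
random draw from a shared regional pool, and selection, in which
disease-associated gut environments favour particular plasmids or plasmid
fragments. plasmidrift packages the quantitative machinery needed to
separate the two: presence filtering for plasmid abundance tables,
circular-aware extraction of shared plasmid segments (the recombining
units), Sloan's neutral community model (NCM) with a deviation-based
selection rule, and a degree-preserving permutation null for sample-sample
segment-sharing networks, together with the surrounding enrichment and
lifestyle statistics.

# The neutral community model

For an entity (plasmid or segment cluster) with mean relative abundance
$p$ across samples, the Sloan model — in the beta approximation suitable
for very large prokaryotic populations — predicts its occurrence frequency
as

$$f(p) = 1 - I_d\big(N m\, p,\; N m (1 - p)\big),$$

where $I$ is the regularized incomplete beta function, $d$ the detection
limit (the smallest relative abundance at which an entity is observed),
and $Nm$ the metacommunity size times the immigration rate. `fit_ncm()`
estimates $Nm$ by bounded one-dimensional least squares on
$\log_{10} Nm \in [-2, 12]$, which is safe because the sum of squared
errors is unimodal in $\log Nm$ (the test suite checks the optimizer
against a dense grid search). Goodness of fit is the ordinary
$R^2 = 1 - SS_{res}/SS_{tot}$ about the mean frequency; a higher $R^2$
means dispersal closer to neutral.

Choices worth knowing about:

* **Detection limit.** The model's $d$ is not estimated; by default we use
  the smallest positive per-sample relative abundance in the data, the
  standard occupancy convention. It can be overridden wherever it enters.
* **Frequency scale.** Least squares is computed on untransformed
  frequencies, not logits, following the cited NCM tradition.
* **Confidence band.** The 95% band around the fitted curve uses Wilson
  score intervals for a binomial proportion at the cohort size. (The
  binomial variance is the natural scale for an occurrence frequency
  estimated from $n$ samples.)
* **Occurrence versus abundance inputs.** Occurrence frequencies come from
  the depth-masked presence matrix; mean abundances are sample-normalized
  and not depth-masked, so a presence decision never zeroes the abundance
  information it was based on.

## Selection rule

Entities under positive selection occur more often than their abundance
predicts. Two rules are implemented in `select_deviant()` because both
appear in the tradition this package follows: the default `"quantile"`
rule intersects the top 5% of occurrence frequencies with the top 5% of
deviations above the fit (deviation measured on the frequency axis); the
alternative `"ci"` rule requires prevalence above 95% and frequency above
the upper confidence band. On exchangeable neutral data the quantile rule
selects at most about 5% of entities (the intersection of two 5% tails,
usually far fewer); the planted-recovery experiments in the test suite
show it recovers essentially all strongly disease-enriched segments when
applied within the disease stratum, which is where selection acts.

## Unequal group sizes

$R^2$ comparisons between entity groups of very different sizes (e.g.
mobilizable versus non-mobilizable plasmids) are corrected by
`subsample_compare()`: the larger group is repeatedly subsampled to the
smaller group's size and refit, and the empirical p-value is the fraction
of subsample $R^2$ values at least as large as the small group's, with the
usual $(1+b)/(1+n)$ correction so p is never zero.

# Shared-segment extraction

A *segment* is a stretch of at least 1000 bp shared by two distinct
plasmids at a minimum 80% identity (matches over alignment columns) and
carried in at least two samples. Because plasmids are circular and
assembly linearizes them at an arbitrary origin, every sequence is doubled
(`seq + seq`) before searching, so any block straddling the origin stays
contiguous; hit coordinates are reduced modulo the plasmid length and the
duplicate hits the doubling creates are collapsed.

The default engine seeds candidate regions with exact 16-mers, chains
colinear seeds by diagonal, and verifies each candidate window with a
local (Smith-Waterman) alignment, iteratively widening any window the
optimal alignment touches the edge of — this is what rescues blocks whose
seed chain is split by the doubling boundary. A full dynamic-programming
mode over whole doubled sequences exists for validation on small inputs;
the tests require the two engines to agree.

Alignment scoring is match +2, mismatch −4, gap open 8, gap extend 4.
The penalties are deliberately strong: with them, alignments of unrelated
random DNA have sharply negative score drift even with gaps, so a local
alignment never creeps past true homology (with laxer penalties the score
of a random continuation is nearly neutral and the reported segment can
silently absorb flanking noise). An 80%-identity block still scores +0.8
per column, so threshold-level homology is always extendable.

Extracted segment instances are clustered greedily longest-first, CD-HIT
style: an instance joins the first cluster whose representative aligns at
≥80% identity covering ≥90% of *both* lengths, else founds a new cluster.
Sample × cluster incidence then follows member-plasmid presence, dropping
clusters carried by fewer than two samples.

Overlapping hits on the same plasmid pair (reciprocal overlap above 50%
on both plasmids) are merged keeping the longer hit and then the higher
identity; preferring length first means a truncated duplicate of a block
can never shadow its full-length alignment.

# Filtering rules

Presence requires read coverage over at least 70% of the plasmid length
(boundary inclusive) and positive abundance. Deduplication removes the
smaller plasmid of any pair with identity strictly above 95% covering at
least 95% of the larger plasmid — the asymmetric boundaries mirror the
wording of the protocol this package operationalizes — processing
candidate merges in decreasing larger-member length with lexicographic tie
breaks, which makes the survivor set independent of input order. The
depth cutoff equals 1% of the smallest present abundance in the sample
with the lowest read depth; cells below it are set absent (abundances are
retained). "Lowest abundance" deliberately means the lowest *nonzero,
present* abundance: including absent cells would make the cutoff zero
always.

# The sharing network and its null

Samples are connected when they share at least one segment cluster; the
edge weight is the number of shared clusters (the dot product of the two
incidence rows). Significance is always assessed against an ensemble of
incidence matrices randomized by checkerboard swaps
($[[1,0],[0,1]] \leftrightarrow [[0,1],[1,0]]$), which conserve every
sample degree and segment prevalence exactly — so any signal must come
from *which* samples share *which* segments, not from how many segments
anyone carries.

Implementation notes:

* Each ensemble member is a fresh chain from the observed matrix with
  $10\times$ (number of 1-cells) proposals, the standard
  switch-randomization practice; chains are seeded independently.
* A proposal draws two 1-cells uniformly *with* possible collision; a
  collision is a rejected proposal. This makes the chain lazy, hence
  aperiodic — on a $2\times2$ identity matrix the output is the original
  or the swapped state with probability exactly one half each.
* The group statistic is the total edge weight among qualifying pairs
  (same disease, optionally within a continent or across a continent
  pair), computed per segment from carrier counts
  ($\sum_s \binom{k_s}{2}$ or $\sum_s k_{s,1} k_{s,2}$), which the tests
  cross-check against brute-force pairwise dot products.
* Empirical p-values use $(1+b)/(1+n_{perm})$ and Benjamini-Hochberg
  correction. The p floor $1/(n_{perm}+1)$ interacts with FDR correction:
  when many hypotheses are tested (every edge, every segment), the
  ensemble must be large enough that the floor survives correction. The
  planted-recovery experiment uses 2000 permutations for 1000 segments at
  FDR 0.1 for exactly this reason; 10,000 is the full-study setting.
* Obesity samples are excluded from geography-resolved statistics by
  default (configurable), since their limited geographic origin would
  otherwise bias continent comparisons.
* Strength ratios (within-disease over between-disease connection
  strength) default to per-capita normalization: each strength is divided
  by the number of potential partners of its kind before the ratio is
  formed, so unequal group sizes do not masquerade as preferential
  sharing. The raw-sum mode is available for comparability.

# The synthetic-data generator

The generator is the package's study stand-in and is first-class, tested
code. What it emulates, and what it does not:

* **Regional pool:** log-normal abundances ($\mu = 0$, $\sigma = 2$),
  renormalized — heavy-tailed like real plasmidome pools. The generative
  pool shape is a package choice; nothing in the underlying protocol
  specifies one.
* **Local communities:** per sample, entity abundances are drawn
  $\mathrm{Beta}(Nm\,p_i, Nm(1-p_i))$ and renormalized, then observed
  through multinomial read sampling at a per-sample depth drawn uniformly
  from the configured range (default $2\times10^4$ to $8.6\times10^5$,
  a desk-scale rendering of depths between 2 and 86 million reads);
  detection applies the limit $d$. The simulator is exactly the
  generative counterpart of the fitted model, which is what makes
  parameter-recovery experiments meaningful.
* **Cohort structure:** disease labels default to the proportions
  1548 healthy : 339 IBD : 1035 GRD : 545 obese; continents to
  0.4/0.3/0.2/0.1 across Europe, North America, Asia and South America
  (continent proportions are a package choice). The mobilizable fraction
  defaults to 1027/11086, and AMR carriage probabilities (0.4 versus
  0.098 by lifestyle) give a mobilizable-versus-non odds ratio near 6.
* **Sequences:** bimodal lengths from a two-component log-normal mixture
  with modes near 3 kb and 30 kb at weights 0.8/0.2; shared blocks are
  copied between plasmids with i.i.d. substitutions splitting the target
  divergence across copies (substitutions only by default, so "identity"
  has a single unambiguous meaning); some blocks deliberately straddle
  the linearization origin; planted blocks never overlap on a host.
* **Selection:** `plant_selection()` multiplies a segment's carriage
  probability inside a target disease group by a boost factor (capped at
  one), implemented as upgrading absent cells so that a boost of one is
  exactly the identity. A fitness-based or frequency-floor mechanism
  would be equally defensible; the boost is exposed as configuration, not
  asserted as the only model of selection.

What the generator does *not* emulate: read-level noise and assembly
artifacts, chimeric plasmids, taxa-linked plasmid co-occurrence, indel
divergence (available but off by default), or realistic annotation
sparsity. Passing tests therefore demonstrate that the machinery is
correct and calibrated under the stated model, not that real gut data are
neutral.

# Problem sizes and numerical choices

The test and validation suite runs at desk scale, chosen so the full
suite completes in minutes while keeping every estimate well-determined:
parameter recovery uses 20 cohorts of 200 samples × 1000 entities;
permutation-null calibration uses 100 replicates of a 300 × 500 incidence
at 500 permutations; planted-selection recovery uses 10 planted among
1000 neutral segments at 2000 permutations; sequence-level runs use tens
of plasmids of 3-30 kb. Degenerate inputs are handled explicitly: beta
shapes below $10^{-8}$ are rejected with an actionable error, abundances
outside $(0,1)$ are clipped to $[10^{-12}, 1-10^{-12}]$ with a warning,
all-equal frequencies yield an undefined $R^2$ rather than a misleading
one, and an all-ones incidence (no checkerboard exists) is returned
unchanged with a flag.

# Known limitations

* The quantile selection rule is relative: it always defines a top-5%
  set when applied to a stratum, so it should be read together with the
  fit it deviates from (the `"ci"` rule is absolute and stricter).
* The full-DP alignment engine is quadratic and guarded to inputs whose
  doubled product stays below $2^{31}$ cells; it exists for validation,
  not production.
* Fisher-exact and hypergeometric computations use exact arithmetic via
  R's distribution functions; gene ratios count entities, not ORF
  instances, per term.
* The permutation null conditions on both margins; signals that live
  entirely in the margins (e.g. globally elevated carriage in a group)
  are invisible to it by design.
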