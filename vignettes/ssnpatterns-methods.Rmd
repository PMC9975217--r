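---
title: "Clustering and spatio-temporal analysis of unassigned metabarcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and spatio-temporal analysis of unassigned metabarcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnpatterns)
```

## Motivation

A large share of marine protist diversity observed by 18S rDNA V4
metabarcoding cannot be assigned to any reference taxon at the genus
level. These *unassigned* metabarcodes are invisible to analyses that key
on taxonomy, yet they often dominate communities — the parasitic
alveolate order Syndiniales being the canonical example. `ssnpatterns`
provides a tested pipeline for studying such lineages across
heterogeneous datasets: it homogenizes and merges per-dataset inputs,
clusters metabarcodes into exact-identity connected components (CCs) of a
sequence similarity network — a pragmatic genus-level proxy that needs no
reference database — and quantifies where (sea regions, depth layers) and
when (multi-year time series) those components occur.

## The model and its assumptions

### Taxonomy semantics

Taxonomy uses the eight PR2 ranks (kingdom … species). A rank labelled
`"Unknown"` is **unassigned** only when no more specific rank carries a
name; if a lower rank is assigned, the `"Unknown"` rank is a **gap** in
the reference hierarchy, not evidence that the organism is unknown
(`rank_status()`). This distinction matters because gaps are common in
curated hierarchies and must not inflate unassigned counts.

### Homogenization

Each dataset passes the same three screens before merging
(`harmonize()`): a taxon blocklist (metazoans, Streptophyta, macroalgal
classes — multicellular signal), a reference-identity screen (records
with best database identity strictly below 80% are dropped; the identity
is an input column, since database searches are out of scope here), and a
length screen (kept iff strictly longer than 200 bp). A record failing
several screens is attributed to the first in that order for reporting;
the retained set is order-invariant because the three predicates are
independent. Merged samples are then normalized to relative abundance
(each sample divided by its total), which is the "scaled from 0 to 1"
reading adopted here: totals-normalized columns already lie in [0, 1] and
a further min–max pass would destroy comparability across samples.

### The sequence similarity network

Two metabarcodes are linked when they share a gap-free exact segment
covering at least 80% of *both* sequences; a zero-mismatch local
alignment reduces exactly to the longest common substring, which is what
`build_ssn()` computes (in C++, with a shared-21-mer prefilter that can
only skip pairs provably unable to reach the required segment length).
One dataset made of short (230 bp) amplicons would almost never reach 80%
coverage of a ~430 bp partner, so when exactly one member of a pair is
flagged `short_amplicon`, coverage is tested on the short member only.
Coverage is inclusive (`>= 0.8`), taking "a minimum of 80% coverage" as
the operative definition. Reverse-complement matching is off: amplicons
are orientation-normalized upstream.

Connected components of this graph with at least 6 members are the
analysis units (`extract_ccs()`); the cutoff of 6 keeps components large
enough to be representable across all integrated datasets. If exactly one
assigned genus occurs among the members of a component, its name is
extrapolated to the whole component; none gives `"unknown"`, and two or
more give `"ambiguous"` — the multi-genus case is not specified by the
method this package follows, and a visible flag was preferred over any
majority rule. Components are labelled `CC_<genus>_<k>` with `k` ranking
total abundance.

### Spatial patterns

A component occurs in a region (or a depth layer within a region) when it
has positive normalized abundance in at least one sample there
(`occurrence_profiles()`). Region-combination counting is exact-set
(`combination_counts()`): a component found in the Mediterranean and the
Tropical/Subtropical Ocean counts once, for that pair only. Depth-layer
sharing between two regions is reported as non-exclusive percentages over
the components exclusively shared by the pair, so a component occupying
several layers contributes to several cells and columns may sum past
100%.

Region-level community comparison uses Bray–Curtis dissimilarity
`B = Σ|x−y| / Σ(x+y)` on per-region composite vectors and the transform
`J = 2B/(1+B)`. Composites are the *mean* of normalized sample vectors
per region: sample counts per region are wildly unequal (a campaign with
122 stations vs a single coastal station), and means neutralize that
imbalance where sums would not.

Redundancy analysis (`rda_fit()`) regresses the component-abundance
matrix on standardized environmental variables and ordinates the fitted
values by SVD; significance uses unrestricted row permutation of the
response (`rda_anova()`, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`). Axis
tests are sequential: each axis is tested on the residual of the response
after removing the preceding canonical axes, with the first canonical
eigenvalue as the permuted statistic — the axis-testing scheme is not
pinned down by the source method, and this marginal-on-previous-axes
choice is the package's own. The response is used untransformed by
default (no Hellinger step is part of the method), with a `hellinger`
flag available.

### Temporal patterns

Per-sample diversity is species richness, Shannon `H` (natural log) and
Pielou evenness `J = H / ln S` (`diversity_summary()`); the method
description mentions a "reverse" Pielou index without defining it, so the
standard evenness is computed and `one_minus_pielou = TRUE` emits its
complement.

Community indicators are selected with Escoufier's equivalent vectors
(`escoufier_select()`): greedy forward selection of component columns
maximizing the RV coefficient
`RV = tr(XXᵀYYᵀ) / sqrt(tr((XXᵀ)²) tr((YYᵀ)²))` between the selected
sub-matrix and the full community matrix, stopping at the shortest prefix
whose cumulative RV reaches 75% (100% would select everything).
Components observed on fewer than 5 dates are excluded first. Ties are
broken by larger total abundance, then lexicographic id, for determinism.
Raw normalized abundances, column-centred, are used — no variance
standardization, so abundant components can dominate, which is precisely
the "indicator of community variation" semantics.

Rhythmicity uses the classical Lomb–Scargle periodogram
(`lomb_scargle()`), suited to unevenly sampled series. The frequency grid
runs from `1/span` to the pseudo-Nyquist `n/(2·span)` with oversampling
factor 4. A component is rhythmic when the peak normalized power exceeds
10 (strictly), and `rhythmic_indicators()` intersects the Escoufier
selection with the rhythmic set. Seasonal prevalence counts the distinct
meteorological seasons (DJF/MAM/JJA/SON — all sites are in the Northern
Hemisphere) of a year with at least one positive observation, and annual
abundance is the mean over observed months of within-month means, with no
imputation of unobserved months.

## Numerical choices

* **False-alarm probability.** `p = 1 − (1 − e^(−PNmax))^M`. The number
  of independent frequencies `M` defaults to `n`, the number of
  observations: on the fortnightly 8-year design the common
  grid-size/`ofac` heuristic (≈ `n/2`) makes the white-noise rate of
  `p < 0.01` land near 0.02, while `M = n` yields ≈ 0.007–0.010 (measured
  by simulation). `M` is an explicit argument; the `PNmax > 10` decision
  rule is independent of it.
* **Boundaries.** Identity (< 80%) and length (> 200 bp) screens are
  strict, coverage (≥ 0.8) and the component-size cutoff (≥ 6) inclusive,
  `PNmax > 10` strict.
* **Degenerate inputs.** All-zero samples fail normalization by error
  (inside `harmonize()` they are dropped with a warning, since a dataset
  may legitimately lose all records to the screens); constant series have
  no periodogram; zero-variance matrices have no RV; rank-deficient
  explanatory matrices name their collinear columns.
* **Determinism.** Component ids order by descending total abundance then
  smallest member id; Escoufier ties as above; permutation tests consume
  the R RNG, so `set.seed()` makes them reproducible.

## The synthetic-data generator

`generate_synthetic()` emulates the statistical structure of the
integrated study at desk scale, with full ground truth: 40 planted groups
of 6–10 members (plus 5 decoy groups below the size cutoff and a few
blocklist/identity/length contaminants), six datasets — three fortnightly
8-year time series (one of them a 230 bp short-amplicon site), two
multi-layer campaigns, one coastal survey — across six sea regions, with
pair-sharing dominated by the Mediterranean Sea and the
Tropical/Subtropical Ocean, mirroring the sharing profile of the real
corpus (~23% endemic, ~58% two-region, tail up to ubiquity).

Guarantees are constructive, not probabilistic. Group members are nested
prefixes of a master sequence with length ≥ 0.8× the master (plus exact
230 bp prefixes in the short-amplicon dataset), so every in-group pair
satisfies the edge rule by containment. Master sequences are redrawn
until every cross-group pair has a longest common substring of at most
183 bp (< 0.8 × 230, the loosest coverage bound any pair can face), so no
cross-group edge can exist. Partition-recovery tests are therefore exact,
not statistical.

Rhythmic structure: per time-series site one planted group is
*dominant* — amplitude 6× the noise-group baseline, sinusoid of period
182, 365 or 548 days at signal-to-noise ratio 2 — and is the planted
community indicator for that site; additional minor rhythmic groups
(amplitude 1×) are periodic but deliberately not indicator truth. This
split is forced by the mathematics of the 75% cumulative-RV cut: over k
comparable dominant columns the greedy trace grows like `sqrt(j/k)`, so
the 75% prefix stops near `0.56·k` and "all rhythmic groups become
indicators" is not achievable — one overwhelming indicator per site is,
and is what the generator plants. Abundances are truncated at zero and
the pipeline's own normalization is applied downstream, so indicator
recovery is tested under the compositional distortion a real analysis
faces.

What the generator does *not* emulate: PCR/chimera error, phylogenetic
sequence evolution, read-level sampling noise, or taxonomically
structured abundance correlations. Passing tests demonstrate that the
algorithms recover planted structure through the full pipeline under
realistic sampling designs — not that any particular biological claim
holds on real data.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path while staying quick on one CPU: network-oracle
instances of 8–120 sequences of 40–80 bp, the 40-group corpus above
(~330 records × 624 samples), 1000 white-noise periodograms of length
192, 90 period-recovery runs, 50–100 random Escoufier matrices with up to
8 columns, and 200 null replicates of the RDA permutation test with 199
permutations each.

## Known limitations

* All-pairs scanning is quadratic in the number of sequences; the k-mer
  prefilter makes the constant small, but corpora far beyond ~10^4
  sequences would want an inverted k-mer index.
* The exact-segment model of "100% identity" does not allow terminal or
  internal indels; a BLAST HSP with gaps at 100% identity has no
  equivalent here.
* Forward selection and axis tests use unrestricted permutation; under
  strong autocorrelation (dense time series) restricted schemes would be
  more faithful.
* The RV-based selection inherits scale sensitivity from using raw
  normalized abundances; rare-but-faithful indicator taxa will not be
  selected.
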