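---
title: "Allele-dosage fingerprinting of polyploid collections: models and methods"
author: "polyfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-dosage fingerprinting of polyploid collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfp)
```

# Scope

`polyfp` implements the analysis chain of a SNP-fingerprinting study of a
polyploid germplasm collection: calling allele dosages 0–4 from two-channel
endpoint fluorescence of allele-specific PCR assays, scoring marker quality,
assessing robustness of the calls against the grouping of samples into
analysis units, verifying duplicates and identical profiles over dosage
matrices, and quantifying the extra discrimination that amplicon-sequencing
haplotypes provide. A synthetic-data generator reproduces the statistical
structure of such a study so that every stage is testable in code.

# The dosage caller

## Why calling is relative

An endpoint-fluorescence assay gives no absolute dosage signal. A sample's
allele-B signal fraction $r = b/(a+b)$ only becomes interpretable relative
to the other samples fitted in the same run: the caller models all samples
of one marker within one *analysis unit* jointly. This is also why the
package treats the analysis-unit scheme ("plate layout") as a first-class
quantity: the same well can be called differently depending on which other
samples it is modelled with, and measuring that sensitivity is part of the
method.

## The mixture model

Within one marker × unit the transformed ratios are modelled as a
$K$-component Gaussian mixture ($K = \text{ploidy} + 1$, default 5),

$$ p(r) = \sum_{d=0}^{K-1} w_d\, \mathcal{N}(r;\, \mu_d, \sigma_d^2),
   \qquad \mu_0 < \mu_1 < \dots < \mu_{K-1}, $$

fitted by EM. Component $d$ represents dosage $d$; the order constraint is
enforced by relabeling (sorting components by location) after each M-step.
A sample receives dosage $\arg\max_d\, P(d \mid r)$ when that posterior
reaches the threshold (default 0.95), and a missing call otherwise. Wells
with zero total signal are unprocessable and propagate to missing calls
rather than errors; negative controls are excluded from fitting and from
call-rate denominators.

## Numerical choices

* **Initialisation and anchoring.** Locations start at the canonical
  evenly spaced anchors $a_d = (2d+1)/2K$ (0.1, 0.3, 0.5, 0.7, 0.9 for
  tetraploids), weights uniform, and all scales at the pooled MAD of the
  ratios. The M-step adds a weak conjugate prior that pulls each location
  toward its anchor with the weight of `anchorStrength` pseudo-observations
  (default 2). With tens of samples in a class the data term dominates
  completely — location recovery on well-separated synthetic clusters is
  within ±0.01 — but a dosage class that is *empty* in the unit keeps its
  component parked at the anchor with its weight floored. We adopted this
  after observing that purely empirical initialisation (quantiles of the
  observed ratios) is not robust on small analysis units: when a dosage
  class is unoccupied, two components land in one cluster, every dosage
  label above the gap shifts by one, and a whole cluster of samples is
  miscalled. Anchoring also resolves the degenerate single-cluster case
  (a marker monomorphic within a unit): the component at the nearest
  anchor absorbs essentially all weight and samples are called with high
  posteriors instead of being split across coincident components.
* **Floors.** Scales are floored at $10^{-4}$ and weights at $10^{-6}$
  (renormalized), so sparse classes cannot collapse the likelihood.
* **Convergence.** EM stops when the log-likelihood changes by less than
  `convergenceTol` (default $10^{-8}$, relative) or after `maxIterations`
  (default 500). The fit is fully deterministic: no random restarts, so
  identical inputs give bit-identical calls.
* **`dipFilter`.** Accepted in `CallerConfig` for interface compatibility
  with the calling contract the package reimplements, but inert: the
  pipeline runs without a unimodality pre-filter.
* **Off-grid clusters.** Material of a different ploidy (e.g. triploids
  among tetraploids) produces clusters between the anchor positions. No
  special handling is implemented: such samples simply fail the posterior
  threshold or are absorbed with low confidence, which matches how a
  tetraploid-only caller treats them.

# Marker quality

For each marker the package reports the call rate, the dosage-class
proportions $p_i$ over called samples, and the Shannon–Wiener evenness

$$ H_S = -\sum_{i=1}^{S} p_i \ln p_i, \qquad I = H_S / \ln S, $$

with $0\ln 0 := 0$. **$S$ is the number of dosage classes** (5 for
tetraploids), not the ploidy: normalizing by $\ln 5$ is what makes $I = 1$
for uniform occupancy of the five classes and reproduces the published
worked values (e.g. proportions (0.03, 0.13, 0.16, 0.09, 0.59) give
$I = 0.740$) — normalizing by $\ln 4$ would not. Reports round proportions
to 2 decimals and evenness to 3, the conventional display precision; note
that recomputing evenness from *rounded* proportions can differ in the
third decimal from a value computed on raw frequencies, so only rows that
survive this round trip are useful as numeric anchors.

The chip-style selection filter evaluates three criteria on a
samples × classes posterior table: every class must hold ≥ 10 % of samples
(by each sample's maximum-posterior class — cluster occupancy before
threshold calling, not after), ≥ 90 % of samples must be assigned with
posterior ≥ 0.99, and the mean maximum posterior must be ≥ 0.99. The
criteria are monotone in the posteriors: raising any sample's maximum
posterior can never turn a passing marker into a failing one. Chromosome
coverage requires at least two panel markers on each of the seven
chromosomes.

# Layout robustness

Calls are produced under two analysis-unit schemes — the whole pooled
analysis plate ("original", 190–380 genotypes per fit) and the 95-genotype
source-plate groups ("single") — then compared and combined:

* **Comparison** counts, per marker, disagreements among cells called in
  both layouts, broken down by absolute dosage difference 1–4. The
  denominator uses only mutually called cells; a marker with no shared
  call has an undefined (NA) disagreement.
* **Combination** takes the unique call where only one layout called, the
  shared call where both agree, and the **higher-posterior** call where
  they conflict, recording the cell in a conflict set. The paper-style
  datasets this emulates do not state how conflicts were resolved; we
  chose the higher-posterior rule because it is deterministic, uses
  information already computed, and preserves the monotone property that
  the combined call rate is ≥ each input's rate for every marker (a
  conflicted cell counts as called). The later "identical in both
  layouts" filter is unaffected by which side wins.
* **Filtering** excludes markers whose disagreement fraction strictly
  exceeds 10 %; exactly 10 % is retained.
* **Robust subset**: accessions with no missing call in either layout and
  identical calls in both, over the whole panel — the set on which
  identical-profile clustering is well defined.

# Identity analysis

Distances between dosage profiles use the Chebyshev (maximum) metric over
mutually scored markers. Pairs with no shared scored marker are flagged NA
rather than given an arbitrary 0 or ∞, since silently extreme values would
corrupt clustering. Assumed duplicate pairs are classified with the
missing-exclusion rule first: a marker missing in *either* member counts
against the pair, and more than four missing markers (of an 18-marker
panel) make the pair inconclusive regardless of differences. Otherwise
0 differences → `identical`, 1–3 → `diff_1_3`, > 3 → `diff_gt3`;
differences are counted over the intersection of scored markers.

The combinatorics helpers compute $5^m$ panel capacity exactly (as
integer-valued doubles, exact far beyond $5^{18}$) and the minimum $m$
with $5^m \ge n$; six markers suffice in theory for 4,187 genotypes.
`countDistinguishableProfiles` gives the *realized* discriminatory power
of a marker subset on a complete score matrix.

# Amplicon haplotypes

Read tables (genotype × haplotype counts with gap-aligned sequences) are
filtered by two strict thresholds: genotypes with < 100 total reads are
removed and, per genotype, haplotypes with < 10 % of the genotype's reads
are zeroed (a 50-read variant is available by setting `minReads = 50`).
The two rules are iterated to a fixpoint so that filtering is idempotent —
zeroing can push a genotype's total below the read threshold, and a
deterministic, stable output is worth the marginal extra strictness.

Haplotype dosages distribute the ploidy over a genotype's retained
haplotypes by largest-remainder rounding of ploidy × read fraction, with
every retained haplotype guaranteed ≥ 1 copy and remainders computed
relative to the current allocation (so a haplotype already forced up to
the minimum does not compete with its pre-floor remainder). Ties break
toward the higher-count haplotype, then by haplotype id. A genotype
retaining more haplotypes than the ploidy cannot be dosed and is excluded
and reported, mirroring how markers with excess haplotypes per genotype
are dropped in practice. A per-genotype mixture fit is deliberately not
attempted here: one genotype's read fractions cannot support one.

Polymorphic sites are counted per alignment column, with the gap symbol
"-" counting as a state; a 2-bp indel therefore contributes two
polymorphic columns. Marker-combination tables count distinct joint
haplotype-dosage multiset pairs over genotypes retained in both markers;
off-diagonal entries are bounded below by each diagonal and above by
min(shared genotypes, product of diagonals). Concordance against a
reference dosage matrix reports identical/differing/unscored counts per
marker and an overall agreement over mutually scored cells.

# The synthetic generator

`generateTruthPanel` draws per-marker dosage-class frequencies from a
symmetric Dirichlet (default concentration 3, giving the broad spread of
evenness values — roughly 0.7 to 1.0 — seen across real marker panels)
and accession dosages from those frequencies. `simulateFluorescence`
arranges accessions into 95-genotype source plates with one
negative-control well each, pools four source plates per analysis plate
(380 genotypes + 4 controls in 384 wells), and emits signals whose
transformed ratio is $\mathcal{N}(\mu_d, \sigma)$ with defaults
$\mu_d = 0.1 + 0.2d$ and $\sigma = 0.02$ — a well-separated assay; the
"hard" preset ($\sigma = 0.07$) produces overlapping clusters and
threshold-driven missingness, bracketing the call-rate range a real
marker panel spans. Dropout (default 2 %) zeroes both channels, which the
pipeline turns into missing calls. Duplicates copy a profile under a new
id; mislabels swap the material behind one duplicate-pair member and the
most dissimilar outside accession, so an "assumed duplicate" pair stops
matching hard. All randomness flows from one master seed through named
substreams, so each operation is independently reproducible.

What the generator does **not** emulate: run-to-run fluorescence drift
(real plate runs differ in signal properties, which is why the emulated
study never pools fluorescence across runs), asymmetric or
chemistry-skewed cluster positions, triploid off-grid clusters,
contamination, or sequencing error and chimeras in amplicon reads (the
multinomial model is ideal). Passing tests therefore demonstrate the
correctness of the algorithms under the stated statistical model, not
robustness to every artefact of real instruments.

# Problem sizes and verification

The test-suite and acceptance runs use panels chosen to exercise the
plate structure at modest cost: 190–475 accessions × 3–18 markers for
pipeline properties (two to five source plates per analysis plate), 2,500
samples × 20 seeds for caller recovery, ≤ 30-sample fixtures for the
posterior Bayes oracle (agreement to $10^{-9}$), and ≤ 20-genotype
fixtures for brute-force joint-profile enumeration. Published worked
values that are exactly reproducible from printed inputs (the evenness
rows, the $5^m$ combinatorics) are asserted at their printed precision.
Quantities that depend on the original 4,187-accession collection (its
exact call rates, duplicate counts and cluster counts) are out of reach
of a synthetic panel and are replaced by the property checks above.

# Limitations

* All samples in a unit are modelled as tetraploid; mixed-ploidy material
  is tolerated only in the sense that off-grid samples fail the threshold.
* The anchor prior assumes clusters near evenly spaced ratio positions;
  assays with strongly skewed chemistry would need the transform behind
  `transformSignal` (kept deliberately replaceable) or the anchors
  adjusted.
* Combined call rates count conflicted cells as called; a stricter
  reading (conflict → missing) would lower combined rates below the
  monotone bound and is not what the emulated study's combined rates show.
* The identity analysis treats dosage profiles as exact fingerprints;
  sport mutations or small structural variants invisible to an 18-SNP
  panel cannot be distinguished.
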