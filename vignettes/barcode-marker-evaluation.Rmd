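---
title: "Evaluating DNA barcode markers: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A DNA barcode is a short, standardized locus used to assign individuals
to species. Whether a candidate locus works for a given group is an
empirical question with a standard battery of checks: does the locus
vary enough between species and little enough within them; do the two
distance distributions separate (the *barcoding gap*); and do species
come out monophyletic on a tree built from the locus? `barcodegap`
implements that battery for species-annotated multiple alignments, one
marker at a time, plus marker concatenation and a simulator that
generates data with known truth.

This vignette records the models and the design decisions behind each
stage — including the places where the conventions in the literature are
ambiguous and the package had to pick a reading.

## Sequence characteristics

`classify_sites()` labels each alignment column as `conserved`,
`variable`, `gap_containing` or `all_missing`. Ambiguity codes are
treated as missing everywhere in the package: a column containing any
gap or ambiguity code is excluded from the conserved/variable
classification, and a variable column is parsimony-informative when at
least two states each occur in at least two sequences. The *aberration
rate* is variable sites as a percentage of total alignment length (the
gap-containing columns stay in the denominator). This is the only
convention under which the published per-marker tables this analysis
style follows are internally consistent: conserved + variable equals the
number of gap-free columns, while the rate is still quoted against full
alignment length.

GC content is computed per ungapped sequence as 100·(G+C)/(A+C+G+T) and
reported as a min–max range across samples; pairwise similarity averages
the percentage of identical comparable columns over sample pairs
(pairwise deletion, consistent with the distance stage).

## K2P distances

The Kimura two-parameter model corrects observed differences for
multiple hits while distinguishing transitions from transversions:

$$d = -\tfrac{1}{2}\ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\,\right]$$

with $P$ and $Q$ the transition and transversion proportions over the
pair's comparable columns. Two policies are available for gap/ambiguous
columns: `pairwise` deletion (default — each pair keeps every column
where both have unambiguous bases) and `complete` deletion (columns with
any gap/ambiguity are removed for all pairs). Pairwise deletion is the
default because it preserves per-pair information that the gap analysis
needs; the switch exists because distance software differs in its
default and the choice is not always reported.

When $1-2P-Q \le 0$ or $1-2Q \le 0$ the correction is undefined
(saturation). Such pairs are returned as `NA` with a `saturated` flag
and *excluded* from downstream summaries with a logged count — clamping
them to an arbitrary large value would manufacture divergence.

## Divergence statistics

Six statistics summarize a marker (three interspecific, three
intraspecific): mean interspecific distance; θ′, the average over
species of the species' mean distance to heterospecific individuals;
minimum interspecific distance, averaged per species; mean intraspecific
distance; θ, the average over species (with ≥ 2 individuals) of the
species' mean conspecific distance; and coalescent depth, the average of
per-species maximum conspecific distance. θ′ here is
per-species-then-averaged; an alternative per-species-pair reading
exists in the literature and is one switch away
(`theta_prime = "per_species_pair"`). Because published tables rarely
state whether their ± is an SD or an SE, `divergence_summary()` reports
both.

Markers are compared with a Wilcoxon signed-rank test, implemented in
the package rather than wrapped, so that its exact small-sample branch
is under test: zero differences are dropped, tied absolute differences
get midranks, and for n ≤ 25 the null distribution of W is computed
exactly by convolution over doubled midranks (identical to enumerating
all 2ⁿ sign assignments); beyond that a normal approximation with tie
and continuity corrections takes over. Pairing across markers uses the
intersection of unordered sample-pair keys — the only construction that
yields a valid signed-rank pairing from two per-marker distance tables —
with unmatched pairs dropped and counted. No multiple-testing correction
is applied across marker pairs; raw p-values are reported and labelled
as such.

## The barcoding gap

`gap_profile()` uses the distribution-extrema rule: a gap is present iff
the smallest interspecific distance exceeds the largest intraspecific
distance, and the gap interval is reported in percent (100·d). A tie
counts as overlap. The overlap fraction — the share of interspecific
distances ≤ the intraspecific maximum — quantifies *how* overlapping a
gapless marker is, and drives the ranking in `gap_report()` (gapped
first, then least-overlapping; gapped markers tie-break on interval
width). Histograms with a configurable percent-scale bin width (default
0.2%) are attached for plotting; extrema, not bins, decide the verdict,
since binned "gaps" can be artifacts of bin placement.

Relative, lineage-specific gap formulations (nearest-neighbour versions)
are out of scope; the extrema rule matches the visual criterion used
when such distributions are plotted.

## Trees, bootstrap, monophyly

`nj_tree()` is the standard Saitou–Nei agglomeration. Two details are
pinned down that reference implementations leave to input order: Q-matrix
ties are broken by the lexicographically smallest pair of cluster labels
(a cluster is labelled by its smallest leaf), and negative branch
lengths are clamped to zero with the deficit moved to the sibling, with
a count kept. This makes tree, bootstrap supports and Newick output
invariant to the order samples appear in the file.

`bootstrap_support()` resamples alignment columns with replacement,
recomputes K2P + NJ per replicate, and attaches to each internal edge of
the original tree the percentage of replicates containing the same
bipartition (Felsenstein-style support on the original topology, not a
consensus). Replicates with undefined distances are dropped and counted;
more than 10% drops abort the run. Support denominators use retained
replicates. A species is monophyletic iff some edge bipartition isolates
exactly its leaves; singletons are trivially monophyletic and flagged.

## The simulator

`simulate_dataset()` generates species-labelled multi-marker alignments
with known truth. The root sequence is drawn with stationary composition
matching the marker's GC target; it evolves down a user-supplied species
tree under a two-rate Markov process (transitions weighted by κ,
normalized so branch lengths are expected substitutions/site), scaled
per marker by a rate multiplier. Within species, individuals radiate
independently from the species tip (a star), each along
`intraspecific_scale` × the terminal branch. Indels are whole-column gap
assignments hitting a random proper subset of sequences at a per-column
rate — enough to exercise the gap-column rules without modelling indel
evolution. The truth table carries expected inter/intraspecific
divergences from branch-length sums, the generating topology, and a gap
expectation (smallest expected interspecific divergence > 3× the largest
expected intraspecific one).

What the simulator does **not** emulate: coalescent within-species
genealogies (the star makes gap sharpness optimistic), composition drift
(the process is composition-neutral; GC is set at the root and only
approximately preserved at larger distances), rate variation across
sites, and realistic indel length structure. Passing tests therefore
show the pipeline recovers what this process plants, not that real data
are this clean.

### Default study shape

`rehmannia_simulation_config()` emulates a small plant genus surveyed
with the five classic candidate barcodes: six species, one densely
sampled focal species (20 individuals) and five sparse relatives, and
marker profiles (`rehmannia_markers()`) with alignment lengths 225
(ITS2), 610 (ITS), 497 (psbA-trnH), 1560 (matK) and 1287 (rbcL) columns,
GC targets from ~27% (psbA-trnH) to ~65% (ITS2), κ = 4 for the nuclear
spacers and 2 for the plastid loci, indel rates only for the spacer-rich
plastid regions, and rate multipliers {1, 0.55, 0.28, 0.10, 0.03} that
put mean interspecific divergence at roughly 3% for ITS2 down to ~0.1%
for rbcL — the magnitudes congeneric surveys report.

### Power and the planted-ranking design

A finding worth recording: at those realistic magnitudes the full
five-marker ranking by mean interspecific distance is *not* reliably
recoverable from a single dataset of this size. The limiting noise is
per-column substitution randomness — the standard deviation of a
marker's mean interspecific distance is on the order of
$\sqrt{f\,\bar d / L}$ with $f$ the (large) fraction of pair paths
shared across branches — and at L = 225–1560 it overlaps the
matK-vs-rbcL and ITS2-vs-ITS separations, so design-stage simulations
showed recovery well below the near-certainty a planted-truth
validation needs. The
planted-order validation therefore uses its own design,
`ranking_experiment_config()`: the same five marker profiles, balanced
sampling (4 individuals × 6 species) and rate multipliers
{3.6, 1.65, 0.75, 0.27, 0.09}, spaced so every adjacent pair of markers
is separated by roughly three standard errors of its mean-distance
estimator. That spacing was fixed from this power analysis before the
validation suite was written, and is not adjusted thereafter.

## Numerical choices and degenerate inputs

* Distances are substitutions/site everywhere internally; percent
  appears only at reporting boundaries (gap intervals, histograms).
* Exact signed-rank p-values switch to the normal approximation above
  n = 25; at the boundary the two agree to well under 0.01.
* NJ requires a fully defined matrix and refuses `NA` entries with an
  instruction to exclude or impute upstream — silent exclusion inside
  the tree stage would desynchronize the tree from the metadata.
* Concatenation drops (never pads) samples missing one marker: padding
  would fabricate sequence for exactly the comparisons concatenation is
  meant to sharpen.
* Validation suite sizes (e.g. 1000 random 5×50 alignments for the
  classification oracle, 100 random additive trees for NJ, 20 seeds for
  the planted-recovery experiments) were chosen as the smallest sizes at
  which the checked property is decisively separated from its failure
  modes.

## Known limitations

* Only the K2P model is implemented; for markers where transition bias
  or composition effects are extreme, model misspecification is not
  detectable inside the package.
* The extrema gap rule is brittle to single outlier distances by
  construction (one misidentified sample destroys a gap); the overlap
  fraction is the more robust companion number.
* Monophyly is read from unrooted bipartitions; paraphyly versus
  polyphyly is not distinguished.
* The simulator's star-shaped within-species structure understates
  intraspecific distance variance relative to a coalescent.
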