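---
title: "Methods: barcode diversity and bathymetric profiling of deep-sea octocorals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode diversity and bathymetric profiling of deep-sea octocorals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coraldive)
```

`coraldive` implements the quantitative backbone of a multi-marker
(mitochondrial *mtMutS* and *cox1*, nuclear 18S) barcoding and biogeography
workflow for calcaxonian octocorals: how informative each marker alignment
is, how many distinct haplotypes it resolves and where they occur, how far
apart taxa are in uncorrected genetic distance, and how species richness is
distributed across collection depth once museum and trawl records have been
curated. This vignette documents the models and procedures, the parameters
that matter, the numerical conventions, and what the synthetic-data
generators do and do not emulate.

## Data model

An alignment is a rectangular block of upper-case IUPAC symbols
(`A C G T`, the eleven ambiguity codes, and the gap `-`) with one row per
sequence. Taxonomy (genus, species, family), ocean basin (Atlantic, Indian,
Pacific, Antarctic) and collection depth ride in a sidecar metadata table
keyed by sequence id rather than being packed into FASTA deflines — the
fields are too structured for defline parsing. At ingest everything is
upper-cased and `U` is mapped to `T`, so downstream code sees a single
canonical alphabet. Depths are positive meters below the surface.

Occurrence records carry a station depth interval
(`depth_min_m`, `depth_max_m`); a point station supplies one depth, copied
into both bounds. Parsing is total: every input row either becomes a typed
record or is rejected with a reason, and accepted plus rejected rows always
equal the input count.

## Alignment information content

A site's **state set** is the set of distinct unambiguous bases (A, C, G, T)
observed in its column; gaps and ambiguity codes contribute no state. A site
is **variable** when it has at least two states, and
**parsimony-informative** when at least two states are each carried by at
least two sequences — so informative sites are a subset of variable sites by
construction. A switch (`gaps_as_state = TRUE`) admits the gap as a fifth
state for users who count indels as characters; the default excludes it,
which is the convention under which published per-marker percentages are
arithmetically self-consistent.

Percentages in `summarize_alignment()` are site counts divided by total
alignment length, rounded to the nearest integer. We verified that this
rounding convention reproduces every percentage cell of the published
marker-comparison table from its printed (count, length) pairs; the
acceptance checks exercise all twelve rows. One caveat worth recording: for
the 5' *mtMutS* fragment the published running text calls 31% of sites
"variable" while the table prints 46% variable and 31%
parsimony-informative; the text appears to use "variable" loosely, and this
package follows the table's definitions.

## Haplotype collapsing

A haplotype is an identity class of aligned sequences. The default `strict`
policy compares full symbol strings literally, so a sequence differing only
by an ambiguity code (or gap) founds a new haplotype. That is deliberately
the default: when richness at a marker exceeds what unambiguous variation
supports, the excess is attributable to ambiguous base calls, and literal
comparison is the policy under which that diagnosis is visible (the nuclear
18S marker in the motivating dataset behaves exactly this way).

The `mask_ambiguity` policy compares two sequences only on columns where
both carry an unambiguous symbol. That pairwise relation is not transitive
(`A` matches `R`, `R` matches `G`, but `A` does not match `G`), so no
canonical partition exists; the implementation assigns each sequence
greedily to the first existing class whose *representative* it matches, in
input order. This is deterministic, idempotent on representatives, and
coincides with exact equality on ambiguity-free data. Strict counts are
always greater than or equal to masked counts.

Richness tables report, per taxonomic group, the total number of haplotypes,
the number with at least one member in each basin (a haplotype sampled in
two basins counts in both, so basin columns need not sum to the total), the
specimen count, and the depth span of genotyped specimens. Sequences without
a basin label contribute to totals only; an unrecognized basin label is a
hard error rather than a silent category.

Ragged sequence ends must be encoded as gap characters at ingest (the
alignment invariant requires equal padded length); no implicit trimming to a
shared window is performed. Users wanting the "first *n* bp" behaviour of a
fragment analysis should subset columns before collapsing.

## Uncorrected p-distances and the delimitation rule

The uncorrected p-distance between two rows is the proportion of differing
sites among compared sites, with **pairwise deletion**: a column is compared
only when both symbols are unambiguous bases. Pairwise (not complete)
deletion is the standard convention for reported p-distances and is robust
to ragged ends; each pair's compared-site count is kept alongside the
proportion so that precision is never hidden. A pair with no comparable
sites yields `NA` with a warning rather than aborting the matrix. Internal
values are proportions; only display rounds to percent.

Transitions are `A<->G` and `C<->T`; the pooled tally over all pairs gives
the transition/transversion ratio, flagged undefined (rather than infinite)
when no transversions are observed.

The family-delimitation rule compares the distances from a candidate taxon
to a family's members against two data-derived constants from a calcaxonian
reference dataset: the maximum observed within-family p-distance (4.9%) and
the minimum observed between-family distance (3.8%). All distances at or
below 3.8% place the candidate within the family; all at or above 4.9% make
it a distinct family. Because the two thresholds overlap, an ambiguous zone
exists by construction, and the implementation returns an explicit third
verdict for it instead of forcing a call. The thresholds came from a
reference dataset that this package does not ship, so they are overridable
constants (`delimitation_thresholds()`), not recomputed quantities.

## Occurrence-record curation and depth profiling

About a third of deep-sea occurrence records come from dredging or trawling
and report a depth interval rather than a point. The curation rule takes the
record's **point depth** as the interval midpoint and excludes any record
whose interval width exceeds half of that midpoint (strict inequality), on
the grounds that so wide an interval makes the average meaningless. Point
records trivially pass. A manual exclusion list (shipped default: two
historical museum records whose extreme shallow depths are almost certainly
recording errors) is applied on top, and the manual flag takes precedence in
the report when both rules would fire. The curation report is an accounting
identity: input = retained + range-excluded + manually excluded, with
retained colony counts carried through.

Per-genus depth distributions are summarized as Tukey five-number summaries
(`stats::fivenum()` hinges, i.e. conventional box-plot quartiles) with
outliers flagged beyond 1.5 times the inter-hinge spread from the hinges —
the standard box-and-whisker construction.

Species depth ranges are the minimum and maximum of curated *point* depths
per species, not of raw trawl extremes; using curated midpoints keeps a
single depth convention across all downstream statistics. The
species-diversity profile counts, in each 100-m half-open bin from 0 to
4500 m, the species whose closed depth range `[lo, hi]` overlaps the bin
(**range-through** counting). We chose interval overlap over point sampling
at 100-m levels because a species whose entire range lies strictly between
two levels would otherwise vanish from the profile; the point-sampling
variant remains available as `method = "level"` since "species found every
100 m" admits either reading. Ranges extending below the deepest bin edge
are counted in the terminal bin and noted. Counting shallow species uses a
strict boundary (`depth_lo < threshold`).

## Synthetic data: what it emulates and what it does not

The simulators exist so that every pipeline stage is testable with known
ground truth, without shipping third-party sequence or museum data.

**Sequences.** A pure-birth tree (`ape::rphylo`) carries a root sequence
drawn uniformly over A/C/G/T. Along each branch, per-site substitution
events are Poisson with mean `rate x branch length`, and each event is a
transition with probability `kappa / (kappa + 2)` — a symmetric
two-parameter process. This is deliberately simpler than GTR: downstream
statistics distinguish only identity, transition and transversion, so two
parameters exercise every consumer while keeping realized event tallies
(recorded in the returned truth object) interpretable — the expected
realized transition:transversion event ratio is `kappa / 2`. Ambiguity
injection replaces a true base with a compatible IUPAC code at a per-symbol
rate, mimicking the ambiguous base calls that inflate strict haplotype
counts; gaps are injected the same way. What this does **not** emulate:
indel evolution, among-site rate heterogeneity, base-composition bias, and
saturation at deep divergences — so passing recovery tests says the pipeline
arithmetic is right, not that real markers are unsaturated.

**Fixed-count fixtures.** `construct_alignment_with_counts()` builds an
alignment whose summary returns exactly a requested (length, variable,
informative) triple: informative columns carry two states on two rows each,
variable-only columns a singleton state. This is how the published
percentage arithmetic is re-derived from printed counts without the
underlying GenBank data.

**Occurrence records.** Per-genus depths follow truncated log-normal laws —
positive, right-skewed, and shaped like observed deep-sea depth
distributions without claiming their parameters. Defaults emulate the
structure of the motivating database: ten genera totaling 985 records with
genus sample sizes and depth spans like the observed ones, a 35% trawl
fraction, exactly 24 forced depth-range violations and 2 forced manual
exclusions (so curation retains 959 by construction — the bookkeeping, not
the biology, is the reproducible quantity). Trawl intervals for rule-passing
records are drawn strictly inside the rule boundary and violations strictly
outside, with an exact recheck after rounding, so forced counts are exact at
any seed. Not emulated: spatial autocorrelation, sampling-effort bias across
depth, and duplicate museum records — the published database itself is
available only on request, so database-wide results (e.g. the observed
diversity peak) are covered by property tests on synthetic ranges, not
reproduced numerically.

All generators are fully deterministic under their seed.

## Numerical conventions and degenerate inputs

* Percentages: nearest-integer for alignment summaries, two decimals for
  displayed p-distances; internal values are never rounded.
* A 1-row alignment yields a 1x1 zero distance matrix; a 2-row alignment has
  zero parsimony-informative sites by definition.
* Groups with a single member contribute no intra-group distance; group
  pairs with no comparable sequence pair are omitted from the inter table.
* Genera with no retained records are omitted from depth summaries with a
  notice; empty record sets produce header-only output tables.
* Haplotype indices and representatives follow first appearance in input
  order — no arbitrary sort, so output is stable across platforms.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
generated data: alignments up to ~30 taxa x 4000 columns for
transition/transversion recovery, 100-seed batches of small record sets for
curation-flag equivalence, and the full 985-record default database for the
curation bookkeeping. These sizes give stable statistics for every check
while keeping a complete run in the order of seconds to a few minutes on a
single CPU.

## Known limitations

* The delimitation thresholds are fixed constants from an external
  calibration; the package applies the rule but cannot re-derive the
  calibration.
* The masking haplotype policy is order-dependent by necessity (see above);
  analyses requiring order-independence should use the strict policy.
* Depth curation assumes interval midpoints are meaningful point estimates;
  for gear towed across steep bathymetry this remains an approximation.
* No phylogenetic inference is performed here: tree building, model
  selection and support estimation are upstream concerns outside this
  package's scope.
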