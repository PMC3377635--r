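# coraldive

Barcode diversity and bathymetric profiling for deep-sea octocorals.

Deep-sea octocoral families (Calcaxonia: chrysogorgiids, primnoids, bamboo
corals and relatives) are routinely surveyed with a small set of markers —
the mitochondrial *mtMutS* and *cox1* genes and nuclear 18S — and with
occurrence records assembled from museums, the taxonomic literature and
research cruises. `coraldive` implements the quantitative steps such a study
needs, as tested, reusable functions:

* **Alignment information content** — variable sites (columns with ≥ 2
  unambiguous bases), parsimony-informative sites (≥ 2 states each carried by
  ≥ 2 sequences), de-gapped length ranges, and integer-rounded percentages of
  alignment length (`summarize_alignment()`).
* **Haplotypes** — collapsing aligned sequences into identity classes under a
  strict (literal) or ambiguity-masking comparison policy, with richness,
  sharing and frequency tabulated by ocean basin
  (`collapse_haplotypes()`, `richness_by_group()`, `shared_haplotypes()`).
* **Distances** — uncorrected p-distances
  *p* = (differing sites) / (compared sites) under pairwise deletion of gaps
  and ambiguities, with per-pair compared-site counts;
  transition/transversion tallies; within/between-group extrema; and a
  two-threshold family-delimitation rule (candidate distances all ≤ 3.8% →
  within the family, all ≥ 4.9% → distinct family, otherwise ambiguous)
  (`distance_matrix()`, `assess_rank_delimitation()`).
* **Biogeography** — curation of occurrence records mixing point depths and
  trawl intervals (a record is excluded when its depth range exceeds half its
  mean depth), Tukey box-plot depth summaries with 1.5×IQR outliers, species
  depth ranges, and range-through species-diversity profiles in 100-m bins
  (`curate_records()`, `genus_depth_summary()`, `diversity_profile()`).
* **Simulation** — seeded generators for birth trees, alignments evolving
  under a two-parameter transition/transversion-biased substitution process
  with ambiguity/gap injection, fixed-count alignment fixtures, and
  occurrence records with known curation flags (`simulate_alignment()`,
  `simulate_records()`, `construct_alignment_with_counts()`).
* **Pipeline** — `run_all()` reads a FASTA + metadata + records bundle and
  writes every output table with an MD5 manifest; identical inputs give
  byte-identical outputs.

## Worked example

```r
library(coraldive)

aln <- coral_alignment(
  c(ch1 = "ACGTACGTACGTACGTACGT", ch2 = "ACGTACGTACGTACGTACGT",
    ch3 = "ACGTACGAACGTACGTACGT", me1 = "GCGTACGTACTTACGTACGT"),
  meta = data.frame(
    seq_id = c("ch1", "ch2", "ch3", "me1"),
    genus  = c("Chrysogorgia", "Chrysogorgia", "Chrysogorgia", "Metallogorgia"),
    basin  = c("Atlantic", "Pacific", "Pacific", "Atlantic"),
    depth_m = c(1100, 950, 2300, 1420)),
  marker = "mtMutS")

summarize_alignment(aln)
#>   marker n_taxa n_columns degapped_min degapped_max n_variable pct_variable
#> 1 mtMutS      4        20           20           20          3           15
#>   n_parsinf pct_parsinf
#> 1         0           0

asg <- collapse_haplotypes(aln)
richness_by_group(asg, aln, "genus")
#>           group n_haplotypes Atlantic Indian Pacific Antarctic n_specimens
#> 1  Chrysogorgia            2        1      0       2         0           3
#> 2 Metallogorgia            1        1      0       0         0           1
#>   depth_min_m depth_max_m
#> 1         950        2300
#> 2        1420        1420

dm <- distance_matrix(aln)
round(dm$p, 3)
#>      ch1  ch2  ch3  me1
#> ch1 0.00 0.00 0.05 0.10
#> ch2 0.00 0.00 0.05 0.10
#> ch3 0.05 0.05 0.00 0.15
#> me1 0.10 0.10 0.15 0.00

assess_rank_delimitation(dm$p["me1", c("ch1", "ch2", "ch3")])
#> [1] "distinct_family"
```

Three of the twenty sites are variable but none is parsimony-informative
(each variant base occurs once). `ch1` and `ch2` are identical, so the three
*Chrysogorgia* specimens carry two haplotypes, one of which was sampled in
both the Atlantic and the Pacific — which is why the basin columns (1 + 2)
exceed the total of 2. All distances from `me1` to the *Chrysogorgia*
sequences are ≥ 10%, above the 4.9% maximum within-family distance, so the
delimitation rule calls it a distinct family.

## Scope

The package deliberately stops short of phylogenetic inference: alignment
construction, substitution-model selection, tree building and support
estimation, and map rendering are upstream/downstream concerns for the
established tools that do them well (MAFFT, jModelTest, PhyML/MrBayes, GIS).
See the methods vignette (`vignettes/coraldive-methods.Rmd`) for models,
conventions and limitations.
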