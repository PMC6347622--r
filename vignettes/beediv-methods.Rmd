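---
title: "Methods: diversity analysis of a simple gut metagenome at three taxonomic levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity analysis of a simple gut metagenome at three taxonomic levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`beediv` analyses shotgun-metagenomic diversity of low-complexity,
host-associated bacterial communities — the honey bee hindgut microbiota is
the motivating system — at three nested taxonomic levels:

* **phylotypes** (roughly, 16S rRNA clusters at ~97% identity),
* **SDPs** (sequence-discrete populations): divergent sub-lineages within a
  phylotype separated from each other by a genetic discontinuity, and
* **strains**: any residual genomic variation within an SDP, observed through
  single-nucleotide variants (SNVs) and accessory gene content.

This vignette documents the models and procedures, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations. It states no empirical claim
that the package's tests do not themselves compute.

## 1. SDP delineation and metagenomic validation

**Model.** Within a phylotype, genomes are clustered on pairwise average
nucleotide identity (ANI). `core_gene_ani()` computes a core-gene surrogate
of ANI: the mean pairwise percent identity over all shared single-copy core
gene families. At the granularity that matters here (within-SDP identities in
the mid-90s vs cross-SDP identities in the mid-80s), this surrogate is
interchangeable with whole-genome sliding-window estimators; a precomputed
square matrix (e.g. from FastANI) can be supplied and is used verbatim.

`candidate_sdps()` builds the graph with an edge wherever ANI ≥ `ani_within`
(default **89%**, the empirical lower edge of within-SDP identity in this
community) and takes connected components as candidate SDPs. Each component
is then checked for *complete linkage* (minimum internal pairwise ANI ≥
threshold). Chained components that fail the check are **flagged, not
split**: such conflicts are rare, informative, and in practice resolved by
inspecting the phylogeny, so silently auto-splitting would hide a real
ambiguity. If a Newick tree is supplied, each candidate SDP is additionally
checked for monophyly; tree inference itself is out of scope.

Core families in which any cross-SDP gene pair exceeds **95%** aligned
identity are removed by `filter_core_families()` before any SDP-level
analysis: conserved or recently recombined families recruit reads across SDP
boundaries and blur every downstream signal.

**Validation against metagenomes.** Database clusters can be artifacts of
isolate sampling. `recruit_orfs()` assigns metagenome-assembled ORFs (≥ 300
bp) to core families (retention thresholds: e-value < 1e-5, identity ≥ 80%,
query coverage > 0.5 — when a precomputed tabular hit file is given its
e-values are used as-is; the internal search scores exact global alignments
and approximates e-values with a Karlin–Altschul-style formula at a fixed
effective database size). `score_orf()` then records, per ORF, the maximum
identity to each SDP's members; the two largest maxima form the best /
second-best pair. For true SDPs the two distributions separate — the
"gap-zone".

The verdict in `gap_report()` is a stated convention, since the underlying
phenomenon is usually judged visually from density plots: SDPs are *discrete*
when the overlap coefficient of 1-percentage-point histogram estimates of the
two distributions is **< 0.05** and the medians differ by **≥ 5** points.
Both thresholds are exposed as arguments. Fewer than `min_orfs = 50` records
yield no verdict rather than a weak one.

## 2. Abundance and replication (PTR)

**Model.** In a replicating bacterial population, bidirectional replication
from a single origin makes read depth decline linearly (on average) with
circular distance from the origin, reaching its trough at the terminus. Depth
at the terminus measures the non-replicating population size and serves as
the taxon's raw abundance; the origin:terminus depth ratio (peak-to-trough
ratio, PTR) is a proxy for the average replication rate.

`build_profile()` sums, per retained core family, the depths of the taxon's
member genes and places the sum at the family's gene midpoint on a designated
reference genome. The summation is restricted to the taxon's own genomes
(`genomes` argument): at SDP level, summing over the whole phylotype would
conflate the SDPs' abundances.

`fit_segmented()` fits two ordinary-least-squares segments with a grid search
over candidate breakpoints (every observed position except the outermost 5%
of points). Fitting is on linear (untransformed) depth — terminus coverage is
the quantity of interest — with `log2_depth = TRUE` available. The candidate
minimising total RSS wins; because the prefix-sum RSS used for the coarse
scan loses precision at genomic position scales, the optimum is refined by
exact residual computation in a ±5-candidate window, with ties resolved
toward the profile centre (this makes a constant profile yield a central
breakpoint and PTR 1 rather than an arbitrary edge fit). `cov_ter` is the
mean of the two segment values at the breakpoint; `cov_ori` the larger fitted
value at the two profile ends.

**Validity and fallbacks.** A fit is valid iff `cov_ori >= cov_ter`,
`cov_ter > 0`, and the breakpoint lies in the central **80%** of positions.
The central-window rule is our concrete reading of "terminus inferred far
from the estimated breakpoint", which is qualitative as usually stated; edge
breakpoints mean the V-shape was not actually observed. Invalid fits report
**PTR = 1** and fall back to the **median family coverage** as abundance.
Profiles with fewer than 20 positive points return a reasoned invalid fit,
not an error. Draft-genome taxa without positional order are quantified by
median family coverage with PTR reported missing.

**Presence.** A taxon is present in a sample when ≥ **80%** of its
quantification families have mean depth > 1× (equivalently: absent when >
20% fall below 1×). Absent taxa get abundance 0 and no PTR.

## 3. Strain-level SNV analysis

Candidate SNVs (VCF-like rows: taxon, gene, 1-based position within gene,
ref, alt, per-sample alt fraction) are consumed, not called; they are assumed
to come from mapping with ≥ 50 bp alignment length and edit distance < 5 —
that is the provenance contract of the coverage inputs. `filter_snvs()`
applies, in order:

1. samples with taxon terminus coverage < **10×** are wholly missing;
2. sites in genes with mean coverage < **10×** in a sample are missing there;
3. intra-sample alt fractions < **10%** are set to 0 (the detection limit at
   10× coverage).

A site is retained only if it remains polymorphic: scored somewhere, ≥ 10%
in ≥ 1 sample, and not fixed (not 1 in every scored sample, not 0 in every
scored sample). Multi-allelic candidates arrive decomposed into biallelic
rows. The cascade's per-rule drop counts are returned as a ledger, and the
whole cascade is tested cell-for-cell against an independently coded
brute-force filter.

**Fractions and curves.** The overall polymorphic fraction divides retained
sites by the total scored core length; per-sample fractions divide
within-sample intermediate sites (fraction strictly between 0 and 1) by the
bp scored in that sample — missing genes are excluded from the denominator,
a choice we document because the per-sample denominator is not universally
standardised. Cumulative curves (`cumulative_curves()`, default **10**
random orders) count a site as variable within a sample subset when the
subset shows an intermediate fraction or both fixed states; this definition
is monotone under sample addition and makes every order terminate at the
overall fraction. `sampling_subset_test()` compares the fractions of the
real samplings (bees collected together) against **27** random 6-bee subsets
with Welch's t test; samplings need ≥ 5 eligible bees, taxa need ≥ 6 usable
samplings.

**Shared-SNV distances.** A SNV is shared between two samples when ≥ 10% in
both; the Jaccard distance is the number of sites present in exactly one of
the two divided by the sites scored in both, with pairs lacking co-scored
sites left missing. A classical-scaling (PCoA) embedding on the
complete-case submatrix accompanies the matrix, keeping only
positive-eigenvalue axes.

## 4. Variome and genomic islands

Gene-family coverages (sum over member genes) are rescaled per sample so the
phylotype's terminus coverage corresponds to **10×**
(`normalized = raw * 10 / terminus`); samples below 10× terminus are
excluded. A family is in the **variome** when its normalized coverage falls
below **1×** — below 10% of the phylotype abundance — in at least one
included sample. Both the presence boundary (1×) and the island-occurrence
fraction (80%) are inclusive (`>=`), matching "at least" semantics.

`correlate_with_sdps()` labels a variome family with an SDP when its log10
raw coverage correlates with exactly one SDP's log10 terminus coverage at
Pearson r > **0.8** across samples; zeros are replaced by half the smallest
positive value of the matrix before the log (an explicit choice — the
convention is not standardised). Zero or two qualifying SDPs give no label.

`build_islands()` chains variome genes within a genome when intergenic gaps
are < **5 kb** (a gap of exactly 5 kb splits); islands spanning ≥ **10 kb**
with ≥ **5 genes** are "big". Island span runs from first gene start to last
gene end, excluding flanking intergenic DNA. Among big islands, any whose
family set is a subset of another's is removed as redundant (identical
islands recur across database genomes); ties keep the longer island, then
the lexicographically smaller id. An island is present in a sample when ≥
80% of its families are present (normalized ≥ 1×). Variome-sharing Jaccard
distances use the same presence rule.

## 5. Community-level statistics

`cluster_sequences()` performs greedy centroid clustering at **95%**
identity: sequences in decreasing length (ties lexicographic by id) join the
first centroid within threshold or found a new cluster — first-founded
centroid wins, making results deterministic. `beta_dispersion()` computes,
per universal gene family table, Jaccard distances on presence/absence, a
PCoA restricted to positive-eigenvalue axes, and each sample's Euclidean
distance to its group mean centroid in that space; distances pooled across
families feed a one-way ANOVA. Using only positive-eigenvalue axes is a
simplification of the imaginary-part correction applied by the reference
ecology implementation (`vegan::betadisper`); the test suite checks the two
agree in ordering and closely in magnitude. The group *mean* (not spatial
median) is the centroid.

`permanova()` partitions the total sum of squared distances
(`SS_total = sum d^2 / n`; within-group analogue per group) into between-
and within-group parts, forms the pseudo-F, and permutes sample labels
(rows/columns jointly, default **999** permutations) for
`p = (1 + #{F* >= F}) / (1 + n_perm)`. The observed statistic and R² match
`vegan::adonis2` to 1e-8 in the tests; calibration under a simulated null
holds the 5% type-I error within [0.02, 0.09] over 500 datasets. ANOVA and
Welch's t go through `stats::aov` / `stats::t.test`.

## 6. The synthetic-data generator

`sim_config()` / `gen_reference()` / `gen_samples()` produce every input the
pipeline consumes, with planted ground truth. The defaults mirror the
motivating study design: **5 phylotypes** with **4/2/2/3/1 SDPs**, **3**
database genomes per SDP, within-SDP divergence **4%** (~96% ANI), between-
SDP divergence **14%** (~86% ANI, inside the commonly observed 83–95% ANI
discontinuity), **2 colonies** sampled over **9 samplings** (3 age groups,
one colony in two consecutive years) with **6 bees** each, **8 strains** per
SDP of which each bee draws **2** with Dirichlet weights (priority-effect
segregation; colonies share the full pool by default because no colony
signal is expected — a "structured" mode plants disjoint pools for power
testing), PTR uniform on **[1, 3]**, terminus coverage uniform on
**[20, 80]**, and Poisson counting noise (negative binomial optional).

Desk-scale choices we made once and kept: core families default to **60** of
**900 bp** (real phylotypes carry 867–1,737 core families; profiles of a few
hundred points carry the same information at a fraction of the cost, and the
PTR-recovery tests use 300-point profiles), and the strain-segregating site
rate defaults to **3%** of core positions (within the 4–33% range real SDPs
span, kept low to bound table sizes). Test fixtures shrink these further;
the properties under test do not depend on the sizes.

Mechanics worth knowing:

* **Mutation model** is substitution-only (no indels), keeping identity
  arithmetic exact. SDP-ancestor mutations occupy *disjoint* position sets,
  so planted ancestor divergence is exact; the divergence of non-conserved
  families is raised slightly to compensate for the dilution of mean ANI by
  the deliberately conserved families, keeping the emitted mean cross-SDP
  ANI within ±1 point of the configured value.
* **Coverage** follows the symmetric bidirectional-replication model:
  expected depth `ter * (1 + (PTR-1) * (1 - 2 d / L))` with `d` the circular
  distance from the origin (position 0) to the gene midpoint. Accessory
  islands are interleaved among core genes so core positions span the full
  replichore.
* **Accessory islands** are strain-private, live on each SDP's
  representative genome, and receive depth proportional to the carrying
  strains' mixture weights — low-weight carriers can fall below the 1×
  detection limit, which is the realistic behaviour.
* **ORF modes**: "strain" samples ORFs from strain gene sequences (gapped
  case); "chimeric" emits 50/50 position-mixtures of two SDP
  representatives, emulating a recombinant lineage continuum in which
  candidate SDPs fail metagenomic validation.
* **Determinism**: everything derives from one integer seed; outputs are
  byte-identical across reruns.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing error and read-level artifacts (no
FASTQ), indels and rearrangements, homologous recombination within SDPs
(except the deliberately conserved families), GC- or origin-skew biases in
coverage, assembly fragmentation and chimeric contigs, and database
incompleteness (every strain's core genome is represented). Conclusions
about robustness to those phenomena require real data.

## 7. Numerical choices and degenerate inputs

* Percent identity is computed over aligned columns excluding terminal
  gaps; internal gaps count as mismatches. Equal-length sequences are
  compared column-wise (exact for the substitution-only synthetic data);
  unequal lengths go through `Biostrings::pairwiseAlignment` with free end
  gaps.
* Segmented-fit tie-breaks prefer central breakpoints; RSS comparisons use
  a 1e-9 relative tolerance.
* Jaccard distances between two empty presence sets are defined as the
  maximum (1) and the samples flagged.
* Zero denominators (no scored sites, empty groups, constant vectors for
  correlation) yield flagged missing values, never silent zeros.
* All percent thresholds ("at least") are inclusive.

## 8. Problem sizes used by the shipped tests

The test suite and worked examples run on synthetic data sized for a
desktop: profiles of 100–300 families, databases of 4–9 genomes, SNV tables
up to a few hundred sites × 54 samples, 200-table filter-oracle sweeps, 500
PERMANOVA null datasets at 199 permutations. These sizes were chosen as the
smallest at which each property is non-trivially exercised.

## 9. Known limitations

* The ANI surrogate uses only single-copy core genes; genomes sharing no
  scored family with a partner cannot be placed (an error names the pair).
* One interior breakpoint is fitted; genomes whose assembly does not start
  near the origin can violate the central-window validity rule even when
  replicating. An optional circular refit (rotating the profile to the
  fitted maximum) mitigates but does not remove this.
* The gap-zone verdict thresholds (0.05 overlap, 5-point median gap) are
  conventions; borderline phylotypes deserve a look at the distributions.
* PERMANOVA assumes exchangeability under the null; with strongly unequal
  group dispersions its p-values conflate location and dispersion effects,
  as in any implementation of this statistic.
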