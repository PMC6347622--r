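# beediv

Genomic diversity analysis of simple host-associated gut microbiotas from
shotgun metagenomes, at three nested taxonomic levels. The package was built
for communities like the honey bee hindgut microbiota — a handful of
bacterial phylotypes, each potentially split into **sequence-discrete
populations (SDPs)**, each of those harbouring many **strains** — and for
study designs that sample individual hosts from colonies across age groups.

It is aimed at microbial ecologists and bioinformaticians who have reference
genomes plus per-sample gene-coverage and candidate-SNV tables (from any
standard mapping stack) and want reproducible, tested implementations of the
analyses that connect them.

## What it computes

**SDP delineation and validation.** Pairwise core-gene ANI
(`core_gene_ani`), candidate SDPs as complete-linkage-checked connected
components at ANI ≥ 89% (`candidate_sdps`), removal of core families with
cross-SDP identity > 95% (`filter_core_families`), and metagenomic
validation: assembled ORFs are recruited to core families
(`recruit_orfs`) and scored against each SDP; discrete SDPs show a
"gap-zone" between the best- and second-best-SDP identity distributions
(`score_orfs`, `gap_report`).

**Abundance and replication.** Positional core-family coverage profiles
(`build_profile`), a two-segment linear fit locating the replication
terminus (`fit_segmented`), raw abundance as coverage at the terminus, and
the peak-to-trough ratio

```
PTR = cov(Ori) / cov(Ter)
```

as a replication proxy. Invalid fits (origin below terminus, edge
breakpoints) report PTR = 1 with a median-coverage fallback; a taxon is
present only when ≥ 80% of its families exceed 1× depth
(`detect_presence`, `quantify_all`).

**Strain-level SNVs.** The filter cascade (≥ 10× terminus coverage per
sample, ≥ 10× gene coverage, intra-sample allele fractions < 10% zeroed,
only sites staying polymorphic retained; `filter_snvs`), polymorphic-site
fractions per sample and study-wide (`polymorphic_fraction`), cumulative
diversity curves over random sampling orders (`cumulative_curves`),
real-vs-random sampling comparisons with Welch's t
(`sampling_subset_test`), and shared-SNV Jaccard distances with PCoA
(`shared_snv_distance`).

**Variome and genomic islands.** Gene-family coverage normalized to a 10×
phylotype scale (`normalize_families`), the variome (families < 1×
normalized in ≥ 1 sample, `assign_variome`), SDP-correlation labels at
Pearson r > 0.8 (`correlate_with_sdps`), genomic islands chained at < 5 kb
intergenic gaps with big islands at ≥ 10 kb / ≥ 5 genes (`build_islands`,
`island_occurrence`), and variome-sharing Jaccard distances
(`variome_distance`).

**Community statistics.** Greedy 95%-identity centroid clustering
(`cluster_sequences`), presence-absence beta-dispersion with
distance-to-centroid ANOVA (`beta_dispersion`), PERMANOVA (`permanova`),
and ANOVA / Welch utilities (`basic_tests`).

**Synthetic data.** `sim_config` / `gen_reference` / `gen_samples` generate
reference databases, coverage, SNV, ORF and metadata inputs with planted
ground truth (SDP partition, strain mixtures per bee, PTRs, segregating
sites, island carriers), so every stage is testable without sequencing
data.

## Worked example

A complete round trip on synthetic data — one phylotype with two planted
SDPs (≈ 96% ANI within, ≈ 86% between), four strains per SDP, two of which
each bee carries:

```r
library(beediv)

cfg <- sim_config(n_phylotypes = 1, n_sdps = 2, n_genomes_per_sdp = 3,
                  n_core_families = 30, mean_gene_length = 400,
                  n_strains = 4, strains_per_bee = 2,
                  islands_per_strain = 1, genes_per_island = 5,
                  snv_rate = 0.02, bees_per_sampling = 2, n_orfs = 60)
ref <- gen_reference(cfg, seed = 11)
smp <- gen_samples(cfg, ref$truth, ref$db, seed = 12)

## SDP delineation from core-gene ANI
part <- candidate_sdps(core_gene_ani(ref$db, "P1"))
part
#> SDPPartition: 2 SDP(s) over 6 genomes (ani_within = 89 )
#>   SDP-1: P1S1G1, P1S1G2, P1S1G3
#>   SDP-2: P1S2G1, P1S2G2, P1S2G3

kept <- filter_core_families(ref$db, part, "P1")
length(kept)   # 3 deliberately conserved families are excluded
#> [1] 27

## metagenomic validation: gap-zone between best and second-best SDP
hits <- recruit_orfs(smp$orfs, ref$db, phylotype = "P1")
gap_report(score_orfs(smp$orfs, hits, ref$db, part), "P1")
#> GapReport (P1) : n = 60  overlap = 0  discrete = TRUE

## abundance and replication per SDP
taxa <- lapply(setNames(nm = unique(ref$truth$partition)), function(s)
  list(reference_genome = ref$truth$representative[[s]], families = kept,
       genomes = names(ref$truth$partition)[ref$truth$partition == s]))
am <- quantify_all(smp$coverage, ref$db, taxa)
round(head(cbind(abundance = am$abundance[, 1], ptr = am$ptr[, 1]), 3), 2)
#>         abundance  ptr
#> S1_bee1     21.53 2.26
#> S1_bee2     45.57 1.85
#> S2_bee1     58.88 1.41

## strain-level SNVs for the first SDP
tr  <- smp$sample_truth
ter <- with(tr[tr$sdp == "P1S1", ], setNames(terminus, sample_id))
tab <- filter_snvs(smp$snv[smp$snv$taxon == "P1S1", ], smp$coverage,
                   ter, kept, ref$db)
tab
#> SNVTable: 222 polymorphic sites x 18 samples ( 18 eligible )
#>   filter ledger: non_core=16, low_terminus_samples=0, low_cov_gene=0,
#>                  low_freq_zeroed=252, fixed_or_absent=0

signif(polymorphic_fraction(tab), 3)                          # study-wide
#> [1] 0.0206
signif(median(polymorphic_fraction(tab, "per_sample")), 3)    # per bee
#> [1] 0.0112
```

The printed numbers tell the story the package is built around: the two
planted SDPs are recovered exactly and validate as discrete against the
metagenome (overlap 0); per-sample terminus coverages and PTRs are
recovered from the coverage gradients; and each bee carries clearly less
strain-level polymorphism (median 1.1% of core sites) than the colony-wide
pool (2.1%, matching the planted 2% segregating-site rate), the signature
of strains segregating into individual hosts.

## Layout

```
R/            refdb, sdpval, quantify, snv, variome, ecostats, synthdata
tests/        testthat suite (unit, property-style and end-to-end checks)
scripts/      acceptance.R
vignettes/    beediv-methods.Rmd — models, parameters, design choices
```
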