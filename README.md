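# campart

Phylogenetic-bin null models for microbial community assembly.

`campart` quantifies *which ecological processes drive the turnover of
microbial communities* — the question behind membrane-biofilm studies in
membrane bioreactors (MBRs), where the biomass retained on a fouling
membrane assembles from the suspended sludge (MLSS) and changes character
as the biofilm ages. Given a rarefied OTU/ASV count table, a rooted
phylogeny, and sample metadata, the package partitions every pairwise
community comparison into the relative contributions of five processes:

| code | process | signature |
|------|---------|-----------|
| HeS | heterogeneous selection | communities more phylogenetically dissimilar than the null |
| HoS | homogeneous selection | communities more phylogenetically similar than the null |
| HD | homogenizing dispersal | taxonomically more similar than stochastic assembly |
| DL | dispersal limitation (+drift) | taxonomically more dissimilar than stochastic assembly |
| DR | drift | neither null rejected |

## The statistic

Taxa are first cut into phylogenetic **bins**: maximal clades whose
within-clade cophenetic diameter does not exceed `ds_cut` (default 0.2, the
framework's convention on 16S branch-length scales), with undersized clades
merged into their phylogenetically nearest neighbour until each bin holds at
least `bin_size_min` taxa. For each sample pair and bin, two null models are
evaluated:

* **βNRI** (beta net relatedness index): the standardized effect size of the
  abundance-weighted between-sample mean pairwise phylogenetic distance
  (βMPD),

  βNRI = (βMPD_obs − mean βMPD_null) / sd βMPD_null,

  against a null that shuffles taxon identities among the bin's members
  while holding abundances fixed. |βNRI| > 1.96 indicates selection
  (positive → HeS, negative → HoS).

* **RC** (modified Raup–Crick on Bray–Curtis): the rank of the observed
  bin-restricted Bray–Curtis dissimilarity within a null ensemble that
  preserves each sample's bin richness (taxa drawn with probability
  proportional to occurrence frequency) and bin abundance (individuals
  drawn proportional to mean relative abundance), rescaled to [−1, 1].
  When selection is not indicated, RC > +0.95 → DL, RC < −0.95 → HD,
  otherwise DR.

Each pair-bin's label is weighted by the bin's relative abundance in the two
samples and summed to pair-level process fractions; group-level fractions
average the pairs within each metadata group (e.g. sampling day × nucleic
acid type).

Around this core the package provides the full desk-side workflow:
rarefaction (`rarefy_counts`), alpha diversity (`alpha_diversity`:
observed richness, Shannon, Gini–Simpson, bias-corrected Chao1),
Bray–Curtis and unweighted UniFrac distances, PCoA and NMDS ordination,
one-way PERMANOVA (`permanova`), a reproducible pipeline driver
(`run_all`), and a metacommunity simulator with known ground-truth
assembly regimes (`simulate_scenario`, `generate_study_like`) used to
validate every stage end to end.

## Worked example

Simulate ten communities assembled under strong homogeneous selection
(shared environmental optimum, phylogenetically conserved niches) and
recover the generating process:

```r
library(campart)

study <- simulate_scenario(scenario_config("HoS", seed = 3))
cfg   <- null_model_config(n_null = 200, bin_size_min = 6, seed = 3)
part  <- quantify_assembly(study$table, study$tree, config = cfg)
summary(part)
#> Phylogenetic-bin null-model assembly partition
#> null-model config: n_null=200, |bNRI|>1.96, |RC|>0.95, bins>=6 taxa, ds_cut=0.2, abundance-weighted bMPD
#> phylogenetic bins: 2 bins over 200 taxa (sizes 77-123 )
#> pairs scored: 45 ; pair-bin scores: 90 ; degenerate nulls: 0
#> community assembly partition (2 bins, 45 sample pairs)
#>  group n_pairs HeS HoS HD DL DR
#>    all      45   0   1  0  0  0

head(part$scores[, c("sample_1", "sample_2", "bin", "bnri", "rc", "process")], 4)
#>   sample_1 sample_2 bin      bnri    rc process
#> 1      S01      S02   1 -3.356733 -1.00     HoS
#> 2      S01      S03   1 -3.201141 -1.00     HoS
#> 3      S01      S04   1 -3.275342 -1.00     HoS
#> 4      S01      S05   1 -3.395381 -0.95     HoS
```

Every pair-bin shows βNRI well below −1.96 — turnover among these
communities is confined to phylogenetically close, ecologically equivalent
taxa, the fingerprint of consistent selective pressure — so the whole
partition is assigned to homogeneous selection. `plot(part)` draws the
stacked process-fraction bars per group.

For a study-shaped dataset (5 membrane types × flux/no-flux × days
1/10/20/30 × DNA/cDNA, plus MLSS samples, 44 samples per nucleic type),
`generate_study_like(seed)` produces a table/tree/metadata triple whose
assembly regime shifts from selection-dominated early biofilm to
drift/dispersal-limitation-dominated aged biofilm, and
`run_all(run_config(...))` executes the complete pipeline (rarefy → alpha →
Bray–Curtis + UniFrac → PCoA + NMDS → PERMANOVA per design factor →
assembly partitioning → top-taxa table) into a directory of TSV outputs
with a manifest, bit-reproducible under a fixed seed.

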