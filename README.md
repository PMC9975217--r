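# ssnpatterns

Clustering and spatio-temporal analysis of taxonomically unassigned
metabarcodes from heterogeneous 18S rDNA V4 datasets.

## The problem

Marine protist surveys based on the 18S V4 marker routinely find that
half or more of their metabarcodes — representative sequences of
ASV/OTU read clusters — have no reference match at the genus level.
Entire lineages, most prominently the parasitic alveolates
(Syndiniales), are therefore invisible to taxonomy-keyed analyses.
`ssnpatterns` is for researchers who want to study those unassigned
lineages anyway, across datasets that were produced by different
projects with different pipelines: time series, oceanographic campaigns
and coastal surveys.

## The method

1. **Homogenization** (`harmonize`). Each dataset is screened with the
   same three filters — a taxon blocklist (metazoans, Streptophyta,
   macroalgae), best reference identity ≥ 80 %, length > 200 bp — then
   merged; every sample is normalized to relative abundance.
2. **Sequence similarity network** (`build_ssn`, `extract_ccs`). Nodes
   are metabarcodes; an edge requires a gap-free exact shared segment
   (100 % identity) covering ≥ 80 % of *both* sequences. For pairs where
   exactly one sequence comes from a short-amplicon (230 bp) dataset,
   coverage is tested on the short sequence only. Connected components
   (CCs) with ≥ 6 members are the analysis units — a genus-level proxy
   that needs no reference database. A single assigned genus within a CC
   is extrapolated to all its members.
3. **Spatial patterns** (`occurrence_profiles`, `combination_counts`,
   `depth_sharing_matrix`, `region_dissimilarity`, `rda_fit`,
   `rda_anova`, `forward_select_env`). Exact region-combination counts,
   non-exclusive depth-layer sharing between region pairs, Bray–Curtis
   dissimilarity B = Σ|x−y| / Σ(x+y) with its Jaccard transform
   J = 2B/(1+B) on per-region composites, and redundancy analysis of CC
   abundances on environmental variables with permutation ANOVA.
4. **Temporal patterns** (`diversity_summary`, `escoufier_select`,
   `lomb_scargle`, `rhythmic_set`, `rhythmic_indicators`,
   `seasonal_prevalence`, `annual_mean_monthly_abundance`). Escoufier
   equivalent-vector selection of community-indicator CCs (greedy RV
   maximization up to a 75 % cumulative level, on CCs present on ≥ 5
   dates), Lomb–Scargle rhythmicity on unevenly sampled series (rhythmic
   iff peak normalized power PNmax > 10, i.e. p < 0.01), and their
   intersection: the rhythmic indicator CCs.
5. **Synthetic data** (`synthetic_spec`, `generate_synthetic`). A
   generator with constructive ground truth (planted CC partition,
   region sets, rhythmic periods, genus labels) emulating the
   multi-dataset structure, so every stage is testable end to end.

## Worked example

```r
library(ssnpatterns)

sim <- generate_synthetic(synthetic_spec(seed = 7))   # 6 datasets, truth known
h <- harmonize(sim$datasets)                          # screen + merge + normalize
edges <- build_ssn(h$records, min_cov = 0.8)
ccs <- extract_ccs(edges, h$records$id, min_size = 6)
lab <- label_ccs(ccs, h$taxonomy, h$abundance)
head(lab$summary, 3)
#>          cc_id size genus_label    order_label total_abundance
#> 1 CC_unknown_1    9     unknown   Dino-Group-I       157.97830
#> 2 CC_unknown_2   10     unknown  Dino-Group-II        80.34896
#> 3 CC_unknown_3    8     unknown Dino-Group-III        70.38624
```

The run yields 1122 edges and 40 connected components; the summary ranks
CCs by total abundance and shows that the most abundant clusters are
unassigned at genus level (`CC_unknown_…`), each attributed to one
Syndiniales order. Region sharing:

```r
head(combination_counts(occurrence_profiles(lab$members, h$abundance, sim$metadata)))
#>                            Mediterranean Sea
#>                                            6
#>                                    North Sea
#>                                            1
#>                   Tropical/Subtropical Ocean
#>                                            5
#>                        Black Sea + North Sea
#>                                            2
#>          English Channel + Mediterranean Sea
#>                                            1
#> English Channel + Tropical/Subtropical Ocean
#>                                            1
```

Each CC counts once, for its exact region set — here 6 CCs are endemic
to the Mediterranean, 2 are shared exclusively by the Black Sea and the
North Sea, and so on. Temporal analysis at one time-series site:

```r
ccm <- cc_abundance_matrix(lab$members, h$abundance)
md <- sim$metadata
cols <- md$sample_id[md$dataset == "BBMO"]
m <- t(ccm[, cols]); dates <- md$date[match(cols, md$sample_id)]

es <- escoufier_select(m, level = 0.75, min_occurrence = 5)
es
#> Escoufier selection: 1 indicator(s) of 12 component(s)
#>   cumulative RV at cut: 0.9792

keep <- colnames(m)[colSums(m > 0) >= 5]
pg <- periodogram_table(t(m[, keep, drop = FALSE]), dates)
ind <- rhythmic_indicators(es, rhythmic_set(pg, pn_threshold = 10))
pg[pg$cc_id %in% ind, ]
#>          cc_id pn_max period_days     p_value
#> 1 CC_unknown_2 54.215    553.5238 5.47046e-22
```

One CC both drives community variation (first Escoufier pick, cumulative
RV 0.98 ≥ 0.75) and is strongly rhythmic (PNmax = 54 ≫ 10) with a
recurrence period of ~1.5 years — and it is exactly the dominant
rhythmic group planted by the generator at that site
(`sim$truth$indicator_ids$BBMO`).

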