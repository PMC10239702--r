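# cascall

Cohesin, the ring-shaped complex that anchors chromatin loops and TADs, binds
the genome differently in cancer and normal cells. `cascall` identifies
**cancer-aberrant cohesin binding sites (CASs)** from cohorts of cohesin
ChIP-seq data and quantifies what those sites are associated with:
dysregulated genes, 3D-genome reorganization, cis-regulatory evidence, and
patient outcome. It is aimed at computational epigenomics groups who have
per-sample peak calls and read-intensity matrices in hand and want the
downstream cohort statistics, together with a seeded synthetic-cohort
generator that makes every stage testable without any external data.

## The model

For each consensus site (peaks merged across samples, kept when supported by
at least two datasets, chromosomes Y and M excluded), two differential
statistics are computed between the cancer and normal cohorts:

* **Peak occupancy.** `PO = N_observed / N_all` per condition and
  `POC = PO_cancer − PO_normal`, tested with a two-sided Fisher exact test
  on the 2×2 presence table, BH-adjusted across sites.
* **Read intensity.** `logFC = mean(log2 cancer) − mean(log2 normal)`,
  tested with a two-sided Welch t-test, BH-adjusted.

A site is a **CAS** when both filters pass (`|POC| > 0.5`, `q < 0.01`,
`|logFC| > 1`, `q < 0.01`) and the two changes agree in sign: *gained* when
positive, *lost* when negative. Downstream statistics include:

* **DRS (DEG ratio score)** — with `f(x)` the fraction of genes at distance
  `x` from the query sites that are differentially expressed and
  `S = ∫₀^200kb f(x) dx`,
  `DRS = (S_CAS − S_B) / max(S_CAS, S_B) ∈ [−1, 1]`, where `S_B` averages
  500 size-matched draws from all cohesin sites;
* a **loop model** comparing the DEG ratio among loop-connected genes with
  resampled backgrounds (exact rank/Wilcoxon p, rank-biserial effect size);
* **compartment switches** (`E_cancer × E_normal < 0` and
  `|E_cancer − E_normal| > 0.05` on 50-kb PC1 tracks), **insulation scores**
  and their cancer-minus-normal change (ISC), TAD boundaries, and
  **aggregate peak analysis** of loop pixels;
* TF-colocalization and chromatin-state Fisher tests, cohesin-depletion
  response ratios, per-locus Mann-Whitney methylation differentials with a
  resampled site-overlap envelope, and mutation-density comparisons;
* patient clustering scored by the **adjusted Rand index**, and gene-set
  survival stratification (median split of a mean z-score sample score,
  Kaplan-Meier + log-rank).

## Worked example

Simulate a cohort with planted gained/lost sites, call CASs, and score DEG
enrichment near the gained ones:

```r
library(cascall)

cohort <- generate_cohort_chip(cohort_config(
  seed = 42, n_sites = 2000, n_tissues = 2,
  genome = genome_layout(c(chr1 = 2e7, chr2 = 2e7))))
genedata <- generate_expression(cohort)

diff <- cas_differential(cohort$occupancy$tissue1,
                         cohort$intensity$tissue1,
                         cohort$manifest, sites = cohort$sites)
summary(diff)
#> CAS calls: 75 of 2000 sites (38 gained, 37 lost)
#> thresholds: |POC| > 0.5, q_occ < 0.01, |logFC| > 1, q_int < 0.01

cas <- call_cas(diff)
gained <- attr(cas, "sites")[cas$direction == "gained", ]
drs_score(gained, cohort$sites, genedata$genes, genedata$de$tissue1,
          n_draws = 500, seed = 42, direction_filter = "up")
#> DRS = 0.510  (S_CAS = 63878.3, mean S_B = 31299.7 over 500 draws)
```

The cohort plants 2% gained + 2% lost sites (40 + 40 here); the caller
recovers 75 of them with both filters at their defaults. The DRS of 0.51
says the integrated DEG-ratio curve within 200 kb of gained CASs is roughly
twice the resampled all-cohesin background — upregulated genes concentrate
near gained sites, as planted.

The full pipeline (simulation → CAS calling → DRS/loop model → 3D statistics
→ regulatory tests → clinical statistics) runs from one config and one seed:

```r
report <- run_cas_pipeline(pipeline_config(cohort = cohort_config(seed = 1)))
```

or from a shell via `inst/scripts/cas-pipeline.R`. Every output directory
carries a `manifest.json` (seed, thresholds, versions) that reproduces the
run bit for bit.

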