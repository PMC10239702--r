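---
title: "Methods: calling and characterizing cancer-aberrant cohesin sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterizing cancer-aberrant cohesin sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cascall` takes cohorts of cohesin ChIP-seq summaries — per-sample peak
interval sets and per-site log-intensity matrices, split into cancer and
normal groups — and asks which binding sites changed, and what those changes
travel with. This vignette documents the statistical model, the parameters
that matter, the synthetic cohort that the test suite runs on, and the
design decisions taken where the analysis admitted more than one reasonable
choice.

## The dual differential test

Consensus sites are built by merging peaks that overlap by at least 1 bp
across samples and keeping sites supported by **at least two** datasets
(`min_occupancy = 2`, inclusive; the alternative strictly-greater reading is
available through the same argument). Chromosomes Y and M are excluded by
default. Two independent per-site statistics follow.

**Occupancy.** Peak occupancy is binomial: `PO = N_observed / N_all` per
condition, and its change is `POC = PO_cancer − PO_normal`. The 2×2 table of
presence/absence by condition is tested with a two-sided Fisher exact test
(`stats::fisher.test`), BH-adjusted across all consensus sites of the
comparison — not per chromosome, since the null is exchangeable across the
genome.

**Intensity.** `logFC` is the difference of group means of log2 intensity,
tested per site with a Welch (unequal-variance) t-test. The Welch form was
chosen because 550 heterogeneous public datasets cannot be assumed
homoscedastic; the t statistic is computed vectorized over sites and is
checked against `stats::t.test` in the unit tests. A site with zero variance
in both groups and equal means returns p = 1 (no evidence) rather than an
error. When raw counts are supplied they are library-size scaled and
`log2(x + 1)` transformed; pre-normalized matrices pass through untouched.

A site is a CAS iff `|POC| > 0.5` with `q_occ < 0.01` **and** `|logFC| > 1`
with `q_int < 0.01` **and** `sign(POC) = sign(logFC)`. Sites passing both
tests with discordant signs are excluded: a site cannot coherently be
"gained" by occupancy and "lost" by intensity, and excluding them is the
conservative reading of an intersection of the two result lists. Direction
is `gained` when the shared sign is positive.

Tissue specificity is summarized with the Simpson overlap coefficient
`|X ∩ Y| / min(|X|, |Y|)` (≥1 bp site overlap), and CTCF colocalization
change with the 2×2 of overlap against normal and cancer CTCF peak sets.

## DEG enrichment: nearby and loop models

The distance profile `f(x)` is the **per-bin** fraction of genes whose
nearest queried site lies at distance `x` (TSS to site midpoint; 0 when the
TSS falls inside the site), over 10-kb bins in 0–200 kb. A cumulative
variant is available, but the per-bin form is the default since the quantity
of interest is the local DEG density at each distance. Each gene is assigned
to its nearest site only, so a gene never counts for several nearby sites.

`S` is the discrete integral `Σ f(x)·Δx`; empty bins contribute zero. The
DEG ratio score is

`DRS = (S_CAS − S_B) / max(S_CAS, S_B)`,

with `S_B` the **mean** of 500 size-matched draws without replacement from
the all-cohesin background (the full draw vector and its 2.5/50/97.5%
quantiles are retained as an envelope). Using the mean makes DRS a single
reproducible number while the envelope carries the permutation uncertainty;
with both integrals zero the score is defined as 0. Because the constant bin
width cancels in the ratio, DRS is insensitive to the bin size up to
discretization. Background draws are size-matched but not
chromosome-matched by default (a flag could tighten this; on the synthetic
genome chromosomes are exchangeable).

The loop model connects a gene to a site when the site overlaps one loop
anchor and the gene's TSS the other, both padded by 5 kb, with anchor
separation inside 200 kb–5 Mb. The query's DEG ratio among connected genes
is compared against size-matched random site sets. With a single query
ratio against `n` draws, the normal approximation of the rank-sum test is
powerless (its z cannot exceed about 1.7), so the package computes the
**exact** two-sided Mann-Whitney p for n₁ = 1,
`p = 2·min(u + 1, n − u + 1)/(n + 1)` with ties mid-ranked, plus a
rank-biserial effect size. The smallest attainable p is `2/(n + 1)`;
detecting enrichment at p < 0.01 therefore needs at least 500 draws, which
is the default. Queries with no connected genes return an explicit
`undefined` flag, never a silent zero.

CAS-DEGs are DEGs within 5 kb of a CAS; their `|log2FC|` is compared with
the remaining DEGs by a two-sided Mann-Whitney U test.

## 3D-genome statistics

**Compartment switches.** `E` per condition is the mean of replicate PC1
tracks at the site's midpoint 50-kb bin (sites spanning two bins take the
midpoint bin). A site switches iff `E_cancer × E_normal < 0` and
`|E_cancer − E_normal| > 0.05`; otherwise it is stable-A/stable-B by the
cancer-side sign, or undefined when either value is missing. Tracks are
assumed sign-oriented upstream (positive = A).

**Insulation.** `IS(i) = log2(diamond_mean(i) / global_diamond_mean)` with a
10-bin window at 50-kb resolution — the log-ratio of contacts crossing bin
`i` to the chromosome-wide expectation of the same geometry. The formula is
this package's own (the quantity is standard, implementations differ); it is
pinned by a brute-force double-loop oracle in the tests at 1e-9. TAD
boundaries are local IS minima deeper than `mean − 1·sd`, thinned greedily
(deepest first) to a 3-bin minimum separation. ISC is the per-site bin
difference `IS_cancer − IS_normal` (bin value, not a window mean), and the
boundary stratum for the within-TAD/boundary split is ±1 bin.

**APA.** Submatrices of `(2·10 + 1)²` pixels centered on loop pixels are
averaged; the score is the center over the mean of the 3×3 lower-left
corner. By default the matrix is first divided by its per-diagonal expected
value: on raw matrices the corner sits closer to the diagonal than the
center, so distance decay alone deflates the score several-fold, while on
the observed/expected scale a uniform matrix scores exactly 1 and the score
estimates the loop-pixel fold enrichment. Condition comparisons report
per-sample scores with the normal mean normalized to 1 and a one-sided
t-test. Loops too close to the matrix edge are skipped and counted.
A single-region vanilla-coverage square-root balancing helper is provided
for raw matrices.

## Regulatory and clinical statistics

TF enrichment uses a one-sided Fisher test per TF (enrichment is the
directional question being asked) on CAS vs non-CAS overlap counts.
Chromatin states assign each site its majority-bp label over 200-bp
segments; "active" defaults to states 1, 2, 6, 7 of a 15-state vocabulary
(active promoter/flanking and enhancer states) and is configurable.
Depletion response counts a gene as decreased when its log2FC is negative
**and** flagged significant. Methylation differentials are per-locus
two-sided Mann-Whitney tests on beta values; the fraction of query sites
overlapping loci with p < 1e-7 is compared against 500 size-matched random
cohesin draws, mirroring the DRS background convention, with hyper/hypo
direction splits. Conserved sites are those occupied in ≥90% of both
cancer and normal datasets.

Patient clustering standardizes each gene, then uses either correlation
distance (1 − Pearson) with average-linkage hierarchical clustering or
k-means with 50 restarts under a fixed seed; `k` defaults to the number of
true label classes. The adjusted Rand index is implemented directly from
its pair-counting contingency form and cross-checked against both an
independent pair-enumeration oracle and `mclust::adjustedRandIndex`. Note
that step-up BH adjustment is *not* idempotent (re-adjusting an adjusted
vector can change it: (0.01, 0.5, 0.9) → (0.03, 0.75, 0.9) → (0.09, 0.9,
0.9)), so no such property is claimed or relied on. Gene-set survival
stratification uses a deliberately simple, deterministic sample score — the
mean per-gene z-score over the set — with a median split (ties to the low
group), Kaplan-Meier curves and the two-group log-rank test via the
`survival` package. The scorer is a documented stand-in for rank-based
set-scoring algorithms; the stratification contract (two groups from one
set-level score) is what downstream code depends on, and the scorer is
pluggable.

## The synthetic cohort

The generator is the package's study design, not a tuning knob. One root
seed drives named substreams per modality (sites, per-tissue ChIP, genes,
expression, tracks, contacts, clinical), so modalities are independently
reproducible. The default cohort is 3 tissues × (20 cancer + 20 normal)
samples, 10,000 consensus sites of 600 bp on a 3 × 60 Mb genome, with 2%
gained + 2% lost sites per tissue, occupancy effect (POC target) 0.7,
intensity effect 1.5 (log2), intensity noise sd 0.5, and stable-site
presence probability 0.15.

Planted aberrant sites are modelled as **truly unbound on their depleted
side**: presence there is a spurious-peak rate of 0.01 (technical noise),
and the enriched side is `0.7 + 0.01`. This reflects what a gained site is —
bound in cancer, absent in normal — rather than treating the depleted side
as another polymorphically occupied locus; a design-time power analysis of
the Fisher/BH stack at 20 + 20 samples shows the distinction matters, and
the near-absent model is the one under which the stated effect sizes are
comfortably recoverable.

Expression plants a DEG probability that decays linearly with TSS distance
to the nearest aberrant site, from 0.6 at the site to a background rate of
0.2 at 200 kb and beyond (a typical DEG fraction for cancer-vs-normal
comparisons at |log2FC| > 1, FDR < 0.01); direction follows the site class
(gained → up) with 0.9 concordance. Reported non-DEG fold changes are
estimation noise around a true null, so only DEGs shift the expression
matrix — random non-DEG gene lists genuinely carry no condition signal.
PC1 tracks flip planted bins between compartments with sign-preserving
multiplicative replicate noise, so unplanted bins can never satisfy the
switch rule; a bin holding both a gained and a lost site is left
unperturbed and its sites recorded as non-switching. Contact matrices
combine power-law distance decay, multiplicative TAD blocks, lognormal
noise, and loop pixels at a configured fold over their local expectation
(ratio 2 between conditions at site-linked loops). Clinical data plant
exponential survival with hazard ratio 3, Beta-distributed methylation with
hypermethylation only at lost sites (the gained side is deliberately left
unperturbed to emulate the observed asymmetry), TF peak sets with a
configurable site-class preference, uniform mutations with optional
class-wise enrichment, and depletion tables with a planted decreased-gene
excess.

What the generator does **not** emulate: read-level noise and peak-calling
artifacts, copy-number structure, GC/mappability bias, correlated
batch effects across the 550 heterogeneous public datasets, realistic gene
clustering along the genome, or trans-chromosomal contacts. Passing tests
therefore demonstrate that the statistics recover the planted effects under
idealized independent noise, not that any particular real cohort would
yield the same rates.

## Problem sizes and numerical conventions

The test suite exercises the full 10,000-site default cohort in the
acceptance properties and an 800-site, 2-tissue, 2 × 8 Mb reduction (same
effect sizes and per-group sample counts) in the module tests; calibration
loops use 500 replicates for rejection rates, 2,000 for the log-rank
type-I check, and 50 seeds for null-DRS placements, with 200 draws where
only the envelope's center matters and 500 where tail quantiles are read.
Fisher p-values are pinned to a hypergeometric enumeration oracle at 1e-10,
insulation to its diamond oracle at 1e-9. Coordinates are 0-based
half-open everywhere (BED convention), which makes overlap semantics
unambiguous; distances use interval midpoints. The promoter window is
(−2000, +500) bp around the TSS, strand-aware, with precedence promoter >
exonic > intronic > intergenic. Missing track bins propagate as `NA`,
never as zero. Boundary thinning keeps the deeper of two minima within the
separation window; median-split ties go to the low-expression group.

## Known limitations

* The Fisher test on occupancy is conditional on margins and discrete; at
  20 + 20 samples its q < 0.01 hurdle, not the |POC| filter, is the
  binding constraint on sensitivity.
* DRS compares a query against draws from a background that *contains* the
  query sites; with small backgrounds this biases the envelope toward the
  query.
* The insulation and APA conventions are this package's own where the
  field delegates to external tools with unpublished parameter choices;
  absolute values are comparable within `cascall` runs only.
* The sample scorer for survival stratification is linear; genuinely
  rank-based set scores can order patients differently on skewed
  expression distributions.
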