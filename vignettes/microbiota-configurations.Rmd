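---
title: "Analysing gut microbiota configurations in inflammatory disease cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing gut microbiota configurations in inflammatory disease cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microconfig)
```

## The scientific problem

Hidradenitis suppurativa (HS) and Crohn's disease (CD) are co-morbid
inflammatory diseases, and a question of clinical interest is whether some HS
patients carry a faecal microbiota "configuration" resembling CD — a
community state with depleted fibre-fermenting commensals and enriched
pathogen-like genera — rather than the configuration typical of healthy
controls. `microconfig` implements a genus-level 16S workflow for that
question on three-group case–control cohorts (controls, CD, HS) with
accompanying diet, drug-exposure and inflammatory-marker data:

1. quality filtering (genera present in ≥ 10% of samples) and per-sample
   relative abundances;
2. Bray–Curtis β-diversity, principal coordinates analysis (PCoA),
   and PERMANOVA with confounder adjustment;
3. a **median-centroid distance** statistic: the coordinate-wise median of a
   reference group's samples on the first two principal coordinates is taken
   as that group's centroid, and every sample's Euclidean distance from it in
   the PCo1/PCo2 plane becomes a univariate, nonparametrically testable
   summary of how far each microbiota lies from the reference community
   state;
4. co-abundance groups (CAGs): Ward-D2 clustering of the genus-level
   Spearman correlation matrix, cut at k = 4;
5. within-group **stratification**: rank-normalised genus abundances, sample–
   sample Spearman correlation, Ward-D2, cut at k = 2, with the sub-cluster
   closer to the control centroid labelled *NM-like* (normal microbiota) and
   the other *CDM-like*;
6. random-forest classification between configurations, with out-of-bag
   (OOB) error and signed feature importances;
7. covariate screens: Fisher tests and one-exposure-at-a-time logistic
   regression with fixed clinical adjusters, prevalence (≥ 20%) and effect
   size (|Cohen's d| ≥ 0.5) pre-filters, likelihood-ratio p-values and
   Benjamini–Hochberg q-values;
8. a dietary arm using Kendall-tau (τ_b) distances between food-frequency
   profiles, re-using the same ordination/centroid/testing machinery;
9. genus–inflammatory-marker association by per-pair linear regression and a
   compositionality-corrected permutation–renormalisation correlation.

Throughout, group comparisons follow one convention: Kruskal–Wallis with
Dunn's post hoc test for three or more groups, Wilcoxon rank-sum for two,
and Benjamini–Hochberg FDR correction.

## Key formulas and conventions

**Rank normalisation.** Each genus is mapped to [0, 1] across samples by
`(rank(x) − min(rank(x))) / (max(rank(x)) − min(rank(x)))` with average
ranks for ties. A constant vector has no rank spread; it is mapped to zeros
with a warning rather than an error so that degenerate simulated genera do
not halt a pipeline.

**Bray–Curtis.** `d(i,j) = Σ_g |x_ig − x_jg| / Σ_g (x_ig + x_jg)`, computed
on per-sample proportions by default (a flag allows raw counts; the choice
matters and proportions are the field's norm).

**Kendall-tau diet distance.** Food-frequency questionnaire data are heavily
tied (many zero frequencies), so the tie-corrected τ_b is used and mapped to
a distance by `(1 − τ)/2`, giving 0 for identical rankings and 1 for exact
reversals.

**PCoA.** Gower double-centering `B = −½ J D² J` with `J = I − 11'/n`,
eigendecomposition, coordinates scaled by the square roots of positive
eigenvalues. Bray–Curtis is semi-metric, so negative eigenvalues occur; they
are reported and excluded from the explained-variance denominator, keeping
explained fractions in [0, 1].

**Dunn's test.** For groups i, j:
`z = (R̄_i − R̄_j) / sqrt((N(N+1)/12 − Σ(t³−t)/(12(N−1))) (1/n_i + 1/n_j))`,
two-sided normal p, BH across the family of pairs.

**PERMANOVA.** Sequential (Type-I) sum-of-squares partitioning with
confounders entered before the term of interest, pseudo-F, and
`p = (1 + #{F* ≥ F}) / (1 + n_perm)` under free permutation (the +1 avoids
zero p-values). The partitioning is delegated to `vegan::adonis2`, which is
the reference implementation of this estimator; the surrounding term
handling is this package's.

**Permutation–renormalisation association.** For a marker–genus pair the
observed measure is the Spearman correlation between the ranked marker and
the genus's relative abundance. The null permutes that genus's abundances
across samples and renormalises every composition to sum to one — preserving
the sum constraint that induces spurious correlation in compositional data —
then recomputes the correlation; the two-sided p comes from a z-score
against the null's mean and standard deviation. This is a deliberate
simplification of the full CCREPE/ReBoot procedure (which combines a
bootstrap and a permutation distribution); on independent pairs its
empirical type-I error is within the nominal band (see the test suite).

## Design choices where the method description is open

* **Confounders that nest the grouping.** "Controlling for the study effect
  and patient identifier" is under-specified when each patient belongs to
  exactly one group: a patient-identifier term entered before the group term
  absorbs the entire group effect (and a study that recruited a single group
  does the same in pairwise comparisons). `permanova()` therefore detects a
  factor confounder whose levels each sit inside one level of the term of
  interest and *drops it from the model with a warning*. The restricted
  alternative — treating the variable as a permutation block via
  `restrict_within` — is surfaced for designs where the term of interest
  varies within blocks; for a between-patient contrast, within-patient
  permutation cannot move the group labels at all, which is why dropping is
  the default rather than demotion to a block.
* **Sample relatedness for stratification** uses Spearman correlation
  between rank-normalised genus profiles, mirroring the prior-work recipe of
  rank correlation plus Ward2 clustering; k is fixed at 2 and a mean
  silhouette below 0.25 triggers a weak-structure warning. The threshold
  sits between the silhouettes observed on structureless simulated cohorts
  (≈ 0.14–0.23) and clearly two-configuration ones (≈ 0.5–0.74).
* **Cluster labelling** uses the mean control-centroid distance (median as a
  tie-break); at n ≈ 20–35 per cluster the mean is stable and strictly
  ordered in all planted benchmarks.
* **CAG dissimilarity** is `1 − ρ` on the genus Spearman matrix. Ward-D2 on
  this non-Euclidean dissimilarity mirrors common practice; a
  `sqrt_transform` option gives a metric dissimilarity for users who prefer
  Euclidean validity.
* **CAG–centroid correlations** are member-wise by default (one correlation
  per genus, grouped by CAG, suitable for distributional comparison), with a
  `summed` mode correlating each CAG's total abundance instead.
* **"Error rate"** of the random forest is reported as OOB error; held-out
  fractions use majority vote at threshold 0.5.
* **Quasi-separation** in logistic screens (huge estimates with huge
  standard errors, a pattern visible in real cohort tables of this kind) is
  flagged rather than reported as a stable estimate; a ridge-penalised refit
  is optional.
* **Wilcoxon p-values** use exact enumeration when `n₁ + n₂ ≤ 12` and the
  data are tie-free, otherwise the normal approximation with tie and
  continuity correction.
* **Alpha diversity** is computed without rarefaction by default (the
  Gini–Simpson form `1 − Σp²` is reported as "Simpson"); a fixed-seed
  rarefaction option exists.
* **Prevalence filtering** is pooled across the cohort with presence defined
  as count strictly greater than zero and an inclusive boundary ("10% or
  more"); a per-study option can be had by filtering subsets before
  alignment.
* **BH families.** Dunn p-values are corrected within the family of pairwise
  comparisons of one test; diet item tests across the full item × pair grid;
  logistic q-values across one model's terms; association q-values across
  the full edge grid.

## The synthetic cohort generator

Real accession data cannot ship with a package, so `generate_cohort()`
produces cohorts with the statistical structure every stage assumes, plus a
complete `truth` record. The generative model:

* **Community structure.** 120 genera in four co-abundance blocks (two
  health-associated, two pathogen-like; weights 0.33/0.29/0.21/0.17). Each
  block has a latent factor per sample; a genus's log-intensity is
  `base_g + study_offset + σ(√ρ z_block + √(1−ρ) ε) + config shift`, with
  within-block latent correlation ρ = 0.7 and σ = 0.8. Pathogen-block
  baselines are one log-unit lower — blooms grow from rare taxa, which also
  keeps enrichment visible after compositional renormalisation. Counts are
  multinomial at a log-normal depth (median 20 000 reads).
* **Configurations.** Every sample carries a configuration: controls
  control-like, CD patients CD-like, and each HS patient CD-like with
  probability 0.4. The CD-like configuration shifts the block latent means
  (health down, pathogen up, 2 SD) and shifts every genus in its block's
  direction with genus-specific magnitude (uniform 0.2–0.8 of the full
  2.0 log-fold effect; 20 "normal" and 15 "CD" marker genera carry the full
  effect). Dysbiosis in this model therefore reshapes most of the community,
  as differential-abundance analyses of real configuration contrasts find,
  and the two configurations are strongly separated — the regime the
  recovery benchmarks are defined in. Control-like communities get tighter
  latent dispersion (×0.7), reflecting the greater stability of normal
  microbiotas (the "Anna Karenina" effect); without it, occasional
  control-like samples with pathogen-leaning factor draws are genuinely
  ambiguous and no clustering method can place them.
* **Design.** 95/164 control patients/samples, 102/212 CD, 55/55 HS;
  longitudinal replicates share a patient-level random effect
  (ICC 0.5); controls come from both studies, CD from one, HS from the
  other, with per-study per-genus batch offsets (SD 0.3).
* **Diet.** 40 FFQ items as zero-inflated (20% never-consumers) gamma
  frequencies; 10 "western" items shifted up one latent SD in CD and HS, 10
  "fibre" items shifted up in controls; the carbonated-soft-drink item gets
  an extra shift in CD-like-configuration samples.
* **Covariates.** Antibiotics in the last year: baseline prevalence 0.33
  with a planted odds ratio of 4 for the CD-like configuration (antibiotics
  are first-line HS therapy, so a third of patients is clinically
  plausible); cardiovascular drugs with OR 0.25; control-like HS patients
  are 8 years older on average; everything else independent noise.
* **Markers.** Ten serum/faecal inflammatory markers for the HS samples;
  four planted couplings at latent correlation 0.6 (an IL-12-like marker
  negatively and a Gas6-like marker positively coupled to the normal genus
  set; calprotectin- and C5a-like markers positively to the CD set).

What the generator does **not** emulate: taxonomic assignment noise,
variable library-size bias within a study, phylogenetic structure,
zero-inflation beyond the multinomial, real FFQ item semantics, and
marker assay detection limits. Passing recovery benchmarks on these cohorts
shows the pipeline's statistics behave as designed under their own
assumptions — it does not certify performance on real data, where effect
sizes are smaller and confounding richer.

## A worked run

```{r, eval = FALSE}
co <- generate_cohort(cohort_spec(seed = 1))
res <- run_pipeline(pipeline_config(seed = 1), cohort = co)

permanova_term(res$permanova)   # group R2 and permutation p
res$stratification              # NM-like / CDM-like split of the HS group
res$rf                          # OOB error; fraction of HS predicted CD
```

Stages can equally be run standalone (`prevalence_filter()`,
`bray_curtis()`, `pcoa()`, `median_centroid()`, `detect_cags()`,
`stratify_group()`, …); `run_pipeline()` only orchestrates them, expands one
global seed into fixed per-stage seeds (offsets 0/101/202/303/404/505 for
simulation, PERMANOVA, pairwise PERMANOVA, forest, association,
diet), and writes every stage table plus a `manifest.yaml` of all
parameters when `out_dir` is set. Re-running one configuration reproduces
every numeric output exactly.

## Numerical choices and degenerate inputs

* Tolerances: relative-abundance rows must sum to 1 within 1e-9; PCoA
  eigenvalues below `max|λ|·1e-9` count as zero; distance reconstruction is
  validated to 1e-8.
* Tie-breaking in agglomeration follows `hclust`'s deterministic
  lowest-index merge; no stage involves uncontrolled randomness.
* Constant vectors: rank normalisation returns zeros (warning); Spearman
  correlations involving a constant vector are set to 0 (warning);
  constant genera are excluded from differential-abundance screens and
  constant covariates/items dropped from correlation grids.
* All-zero samples are errors at `to_relative()` and `bray_curtis()`;
  empty filter results and empty sample intersections are errors.
* Permutation p-values use the +1 correction; with `n_perm = 999` the
  smallest attainable p is 0.001.

## Problem sizes used in the validation suite

The test suite exercises the pipeline at sizes chosen to make its
statistical properties measurable with modest compute: oracle equivalence
on 50 random small instances per statistic; PERMANOVA calibration on 500
null cohorts of n = 60 with 999 permutations and power on 40 planted
cohorts; centroid-ordering behaviour over 100 seeds; CAG recovery at
n = 150 over 20 seeds; stratification recovery on 20 full-size cohorts and
20 external-style cohorts of n = 17; forest behaviour over 10 planted and
10 label-shuffled cohorts of n = 120; 500 null logistic fits and 50 power
fits at n = 55; 500 null association edges and 50 planted couplings at
n = 55 with 1000 permutations; and a byte-identical double run of the full
default pipeline.

## Known limitations

* The rank-based differential-abundance screen is **not** ANCOM-BC: it
  applies no compositional bias correction and no covariate adjustment, and
  labels its output accordingly; externally computed ANCOM-BC tables can be
  imported instead.
* The permutation–renormalisation association simplifies CCREPE's
  bootstrap-permutation combination to a permutation-only z-test.
* PERMANOVA adjustment for patient identity is structurally limited in
  designs where each patient has one group (see above); the package makes
  the limitation explicit instead of silently absorbing the effect.
* Stratification is fixed at two sub-clusters; cohorts with more than two
  configurations would need the silhouette diagnostic and a different k.
* With ~400 samples the Kendall distance matrix and the association
  permutations dominate runtime (minutes, single core); the implementation
  is plain R and unoptimised beyond that.
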