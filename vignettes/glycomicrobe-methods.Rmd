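---
title: "Methods: linking gut mucosal 16S profiles to the plasma N-glycome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gut mucosal 16S profiles to the plasma N-glycome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Setting

The pipeline connects two compositional data sets measured on the same
individuals: genus-level 16S rRNA gene counts from gut mucosal biopsies
taken at three locations (ileum, transverse colon, rectum), each amplified
with three primer pairs (V1V2, V3V4, V5V6) and sequenced over several runs;
and total plasma N-glycome profiles quantified by UPLC as 39 chromatogram
peaks. Both data types are compositions — only relative information is
meaningful — so every analysis runs in log-ratio coordinates (the Aitchison
geometry). All logarithms in the package are natural.

# Microbiome processing

## Zero imputation and CLR

Counts are converted to relative abundances; each zero cell of a taxon is
replaced by that taxon's minimal positive relative abundance over all
libraries, and rows are renormalized. This is a deliberately simple
detection-limit style rule; it keeps the table strictly positive for the
centered log-ratio transform CLR(x)_i = ln x_i − mean_j ln x_j, whose rows
sum to zero by construction (tested to 1e-12).

## Contaminant rules

Reagent contaminants distort taxa-abundance distributions in recognizable
ways. Four rules are evaluated per genus on the CLR scale:

* **R1 (depth dependence):** in a linear model of CLR abundance on age,
  sex, BMI, smoking status, collection date, location, amplicon,
  run × amplicon nested in location, and log10 coverage, the coverage term
  is negative with Benjamini–Hochberg adjusted p < 0.05. A genus present at
  a fixed absolute amount (a reagent background) dilutes with sequencing
  depth, producing exactly this signature. A flag switches R1 to a marginal
  Spearman correlation with coverage, since either reading of
  "correlation with depth" is defensible.
* **R2 (replicate inconsistency):** Spearman correlation of CLR values
  across biological replicate pairs, pooled over pairs, below 0.3. Pooling
  (rather than averaging per-pair statistics) was chosen for stability at
  the typical 20–80 pairs.
* **R3:** the same consistency statistic below 0.4 *and* absence from an
  allowlist of gut-resident genera.
* **R4 (run discordance):** the F-test of the run × amplicon-in-location
  term, BH-adjusted p < 0.05, *and* absence from the allowlist.

BH adjustment is applied within each rule across genera, not across rules.
A genus is a contaminant if any rule fires. Negative-control libraries are
excluded from all fits.

Two evaluability guards apply to R2/R3: at least three replicate pairs, and
a genus must be quantifiable in the replicate libraries (nonzero in ≥ 50%
of them and ≥ 10 reads on average). Below ~10 reads the CLR value of a
genus is dominated by counting noise, so replicate consistency carries no
information about contamination; without the guard the rule flags genuinely
rare resident genera. Non-evaluable genera are reported as such and never
counted as hits.

The allowlist shipped with the package
(`inst/extdata/gut_genera_allowlist.txt`) is a user-editable list of common
gut-resident genera; membership-based rules are reproducible in mechanism
but their exact membership depends on this list. On synthetic data the
generator's own allowlist (all clean genera) is used instead.

## Filtering

Order: contaminant removal, then the coverage filter (≥ 10,000 reads for
V1V2 and V5V6 libraries, ≥ 5,000 for V3V4 — V3V4 amplicons yield usable
profiles at lower depth), then removal of taxa with mean relative abundance
below 0.01% in at least one location × amplicon stratum. The "in at least
one stratum" reading is exposed as `mode = "any"` (default) versus
`mode = "all"`, since "below threshold in any combination" is ambiguous in
prose. Filtering is a fixed point: re-running it on its output changes
nothing.

## Batch correction and averaging

Per taxon, the linear mixed model

```
clr ~ location + amplicon + location:amplicon:run + (1 | collection_date)
```

is fitted by REML with lme4, and the corrected value is the model residual
plus the taxon's grand mean — i.e. observed minus fitted fixed batch terms
minus the predicted date intercept. When the date variance is estimated at
the boundary (singular fit) the taxon falls back to OLS with date as a
fixed effect; aliased terms (a run with one library) are dropped by the QR
decomposition automatically. Location and amplicon means are treated as
technical here (each location × amplicon stratum is measured by its own
libraries and the nine profiles are subsequently averaged), so after
correction the only systematic between-library structure left is the
individual. The up-to-nine profiles per individual are then averaged
arithmetically; missing libraries reduce the divisor.

Two numerical notes. First, batch offsets must differ *between taxa* to be
meaningful: a log-offset common to all taxa of a library is annihilated by
the CLR and is unidentifiable — the generator therefore plants per-taxon,
per-(run, location, amplicon) offsets, and the correction is evaluated on
the same footing. Second, collection dates are properties of individuals,
so with few individuals per date the date term unavoidably absorbs a
~1/(individuals-per-date) share of the between-individual variance; the
tests bound this attenuation explicitly rather than pretending it is zero.

# Glycome processing

Harmonization maps the 39 cohort-specific peaks onto 36 harmonized GPs by
summation (total area conserved exactly). After total-area normalization,
117 analysis-ready traits are computed: the 36 CLR-transformed GPs and 81
derived traits, each defined in a registry file by one of three
transformations:

* **MERGE_CLR** — replace the numerator GPs by their sum, keep all other
  GPs, CLR the merged composition, return the merged component. The merged
  composition is taken over the 36 harmonized GPs (not the 39 raw peaks),
  matching the panel on which all other traits are defined.
* **SUBCOMP_CLR** — restrict to a repertoire of GPs, renormalize, then as
  MERGE_CLR within the subcomposition (subcompositionally coherent:
  rescaling all repertoire GPs by a common factor changes nothing).
* **RATIO_ILR** — the two-part balance (1/√2) ln(Σnum/Σden); 1/√2 is the
  normalization of the standard isometric basis for a 1-vs-1 balance.

Glycome zeros are handled by the same minimal-fraction rule as microbiome
zeros; real peak areas are rarely zero, so this is a guard rather than a
modeling choice. The registry format (name, class, numerator, repertoire,
denominator) is definition-driven, so other panels — e.g. a 24-peak IgG
panel — load from an alternative file. The shipped map and registry are
*synthetic stand-ins*, structurally faithful (36 GPs, 81 definitions with
plausible structural-feature semantics) but constructed for this package;
file names carry the `_synthetic` suffix.

# Inference

Alpha diversity is the Shannon index in nats on imputed relative
abundances, computed per library and averaged per individual (consistent
with the averaging of abundance profiles). Beta diversity is Euclidean
distance on (batch-corrected) CLR values. PERMANOVA uses Anderson's
pseudo-F with p = (1 + #{F* ≥ F}) / (1 + B); the pipeline tests the
interindividual grouping, because after mixed-model correction the observed
location means have been subtracted and a location test would be
degenerate. Mantel (Pearson, co-permutation) and Procrustes (correlation
√(1 − m²), row permutation) compare the two omics, by default on the first
10 PCs of each (the number of retained axes is configurable; 10 matches the
PC count used elsewhere in the pipeline). All permutation engines take
explicit seeds and report p ≥ 1/(B + 1), never zero.

The univariate scan regresses each trait (response) on each genus
(predictor, rank-based inverse-normal transformed with the plotting
positions (r − a)/(n + 1 − 2a), a = 3/8 for n ≤ 10 else 1/2, average ranks
for ties) with covariates age, sex (0/1), BMI, smoking (0/1) and the first
four microbial PC scores. The trait-as-response direction is a convention;
with a single predictor of interest the t-statistic is symmetric in the
roles. PCA components fix their sign by making the largest-magnitude
loading positive, so results are platform-reproducible.

Multiplicity: the Galwey effective number of tests,
M_eff = ⌊(Σ√λ)² / Σλ⌋ over the eigenvalues of the block's correlation
matrix (negative eigenvalues clipped), is computed for the glycome block
(all 117 analysis-ready traits) and each taxonomic block, and scan-level
corrections use the product of block counts. The floor matches the integer
counts reported by the reference estimator. Sidak correction
1 − (1 − p)^M is computed via `log1p`/`expm1` so that p-values of order
1e-8 survive; it is bounded by Bonferroni everywhere (tested). The
PRS stage regresses the (inverse-normal transformed) genus abundance on the
polygenic score of a glycan trait plus covariates — the instrumental
variable reading of a trait → genus effect.

The binomial enrichment test for an excess of nominal hits is the exact
one-sided tail P(X ≥ k | N, α). Its construction is validated against a
cumulative-sum oracle only; reported enrichment p-values in the literature
depend on unstated choices of N (raw vs effective pair counts) that cannot
be reverse-engineered, so no external value is asserted.

# The synthetic-data generator

The generator emulates the study design at desk scale: 200 individuals ×
3 locations × 3 amplicons (defaults), 25 replicated (individual, location)
combinations, 9 sequencing runs, library coverage uniform on
5,000–50,000 reads, and 20 collection dates assigned per individual. Clean
genus compositions follow a deterministic rank-abundance baseline
(log-levels from 0 to −7) plus Gaussian log-abundance layers: individual
(SD 1.0), location (0.5), amplicon (0.5), per-(run, location, amplicon)
per-taxon batch offsets (0.5), collection date (0.3) and library noise
(0.3); counts are multinomial at the library coverage, so rows sum to the
coverage exactly. Runs are assigned uniformly at random within strata: a
design where each run is exactly one location × amplicon stratum would
alias the run term with the stratum means and make the batch formula
unidentifiable, so the generator uses the crossing the model requires.

Contaminants are planted disjointly by mechanism, five per mechanism by
default: depth-inverse genera contribute Poisson(80) absolute reads per
library; run-specific genera appear at relative abundance 0.003 only in a
random third of the runs; replicate-inconsistent genera are redrawn
independently per library (median relative abundance 0.002, log-SD 1.5).
Disjoint planting keeps per-rule recall and precision interpretable even
though real contaminants may mix behaviors.

The glycome is logistic-normal: 39 latent log-abundances around a fixed
chromatogram-like mean profile with diagonal SD 0.5 (a realistic
coefficient of variation for glycan peaks), softmax-closed to a
composition. A planted (taxon, trait, beta) shifts the trait peak's latent
log-abundance by beta × (36/35) × (standardized per-individual CLR
abundance of the taxon, computed from the generated counts exactly as the
pipeline computes it). The 36/35 factor makes beta *exactly* the effect on
the harmonized 36-GP CLR trait scale; because planting and estimation share
the same count matrix there is no errors-in-variables attenuation, and the
only residual bias is the rank-INT transform of a nearly normal predictor
(~0.6% at n = 200, a design calculation made before any testing).
Covariates match the cohort moments (age 55.66 ± 13.05, BMI 26.37 ± 4.64,
42.3% male, 23.2% smokers) and are generated without effects on either
omics, keeping null calibration clean. The PRS equals
r × standardized trait + √(1 − r²) × noise with r = 0.3 by default — a
realistic instrument strength (R² ≈ 0.09).

What the generator does *not* emulate: read-level errors, chimeras and
taxonomy misassignment; covariate–omics confounding; phylogenetic
correlation among genera; glycan-peak measurement batch effects;
contaminants with mixed behaviors. Passing recovery tests therefore shows
that the analysis machinery is correct under its own model assumptions, not
that those assumptions hold for any particular real cohort.

# Problem sizes in the test suite

The suites run at sizes chosen to exercise the estimators meaningfully on
one CPU: contaminant recall/precision and the null false-positive rate over
20 seeds of the default 200 × 150 design; CI coverage of the planted beta
over 100 seeds (generator + trait engine + association stage; the lmer
batch-correction step is exercised separately on one seed with planted
offsets of SD 1.0, where it removes > 99% of the run-cell variance —
batch offsets cancel in the coverage loop because planting and estimation
share the count matrix); null-scan calibration on ≥ 2,000 pairs; the
regression engine against a normal-equations oracle on 100 random designs;
and permutation-test calibration at B = 99–999.

# Known limitations

* The R2/R3 consistency thresholds (0.3/0.4) are taken as given; their
  operating characteristics depend on replicate counts and sequencing depth.
* The date term of the batch model is confounded with individuals; with few
  individuals per collection date the correction trades some biological
  variance for batch removal.
* The shipped harmonization map, derived-trait registry and gut allowlist
  are constructed stand-ins; analyses of real cohorts should substitute
  cohort-specific files.
* Effective-test counts are estimated on the analysis-ready transformed
  variables; estimating them on a subset (e.g. original GPs only) changes
  the correction strength.
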