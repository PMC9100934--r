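# glycomicrobe

Tools for linking the **gut mucosal microbiome** (genus-level 16S amplicon
counts) to the **total plasma N-glycome** (UPLC glycan peaks), implemented as
a tested, reusable R pipeline. The package is aimed at microbiome and
glycomics analysts who need the full chain — compositional QC of multi-site,
multi-amplicon 16S data; glycan-peak harmonization and derived-trait
calculation; diversity and univariate association analyses with
effective-number-of-tests correction; and a polygenic-score
instrumental-variable stage — together with a synthetic-data generator that
plants known contaminants, batch effects and genus–trait effects so every
stage can be validated against ground truth.

## What it computes

**Microbiome QC.** Counts are zero-imputed by each genus's minimal observed
fraction, transformed with the centered log-ratio
CLR(x)_i = ln x_i − (1/D) Σ_j ln x_j, and screened for contaminants with
four rules on the CLR scale: (R1) a significant negative coverage-depth
coefficient (BH-adjusted p < 0.05), (R2) replicate consistency Spearman
r < 0.3, (R3) r < 0.4 and absence from a gut-resident allowlist, (R4)
significant run discordance (BH-adjusted ANOVA p < 0.05) and absence from
the allowlist. Libraries below the amplicon-specific coverage threshold
(10,000x for V1V2/V5V6, 5,000x for V3V4) and taxa under 0.01% mean
abundance in any location–amplicon stratum are removed. Technical structure
is stripped per taxon with the linear mixed model

```
clr ~ location + amplicon + location:amplicon:run + (1 | collection_date)
```

fitted by REML (lme4), and the up-to-nine location × amplicon profiles of
each individual are averaged into one measurement.

**Glycome.** 39 chromatogram peaks are harmonized into 36 glycan peaks
(GPs) by summation, total-area normalized, and expanded into 117
analysis-ready traits: the 36 CLR-transformed GPs plus 81 derived traits
computed by three compositional transformations (merge-then-CLR,
subcomposition-then-CLR, and the two-part isometric log-ratio
(1/√2) ln(num/den)).

**Inference.** Alpha diversity (Shannon, nats), PERMANOVA / Mantel /
Procrustes concordance in the Aitchison geometry, and a covariate-adjusted
(age, sex, BMI, smoking, first four microbial PCs) ordinary-least-squares
scan of every genus × trait pair, with genera rank-inverse-normal
transformed. Multiplicity is handled with the Galwey effective number of
tests M_eff = ⌊(Σ√λ)²/Σλ⌋ (eigenvalues of the trait/taxon correlation
matrices) and the Sidak correction p' = 1 − (1 − p)^M. The
Mendelian-randomization stage regresses genus abundance on the polygenic
score of a glycan trait.

## Worked example

```r
library(glycomicrobe)

cfg <- synth_config(n_individuals = 80, n_taxa = 60,
                    n_contaminants_per_mechanism = 3,
                    n_replicated_pairs = 12, seed = 101)
run <- run_pipeline(cfg, B = 999)
print(run)
#> glycomicrobe run (seed 101)
#>   libraries: 756 -> 699; taxa: 60 -> 45
#>   contaminants flagged: 9
#>   M_eff glycome x genus: 31 x 35 = 1085
#>   pairs tested: 5265 (291 nominal hits)

head(run$scan[order(run$scan$p_nominal),
              c("taxon", "trait", "beta", "se", "p_nominal", "p_sidak")], 3)
#>          taxon trait    beta     se p_nominal  p_sidak
#> 243  Genus_003   GP9  0.7571 0.1032  3.01e-10 3.26e-07
#> 307  Genus_003 PGP73 -0.1498 0.0353  6.56e-05 6.87e-02
#> 1147 Genus_010 PGP94 -0.0802 0.0197  1.17e-04 1.19e-01
```

The configuration plants one genus→trait effect (Genus_003 on peak P10,
which maps onto GP9) of size beta = 1 on the CLR trait scale; the scan
recovers it as the only Sidak-significant pair. The attenuation of the
fitted beta (0.76 at n = 80) reflects sampling noise in the genus CLR
estimate at this reduced scale. All nine planted contaminants are flagged
by their characteristic rules:

```r
contaminant_metrics(run$report, simulate_microbiome(cfg)$truth)
#>                mechanism rule recall precision n_planted n_flagged
#> 1          depth_inverse   R1      1         1         3         3
#> 2 replicate_inconsistent   R2      1         1         3         6
#> 3           run_specific   R4      1         1         3         6
```

PERMANOVA confirms that interindividual variation dominates beta diversity
(F = 23.4, p = 0.001 at 999 permutations), while Mantel
(R = −0.13, p = 0.98) and Procrustes (r = 0.32, p = 0.15) find no global
microbiome–glycome concordance in this simulation — the planted signal is a
single genus–trait pair, not a global coupling.

Individual stages are exported (`detect_contaminants`, `batch_correct`,
`compute_traits`, `assoc_scan`, `effective_tests_galwey`, `mr_stage`, ...)
and a thin command-line wrapper lives in `inst/scripts/glycomicrobe.R`.

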