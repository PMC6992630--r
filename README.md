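# tcrep — TCR-β repertoire analysis across tissue compartments

`tcrep` characterizes bulk TCR-β CDR3 repertoires sampled from multiple
compartments of the same patients — peripheral blood, tumor, adjacent
uninvolved lung, and healthy/COPD lung controls — the setting of early-stage
non-small cell lung cancer studies where anti-tumor T cell responses are
intermingled with responses to airway pathogens and smoking-related
inflammation. It is aimed at immunogenomics analysts working with
immunoSEQ- or AIRR-style rearrangement tables.

The package implements the full analysis chain:

* **I/O** — immunoSEQ and AIRR rearrangement TSVs, cohort manifests,
  TRBV/TRBJ nomenclature normalization (`read_rearrangements()`,
  `normalize_gene_name()`).
* **Per-sample attributes** — T cell density (templates per
  nucleated-cell equivalent), clonality `1 − H′/ln R` (one minus Pielou's
  evenness, natural log), and richness rarefied/extrapolated to a common
  template depth (exact subsampling expectation below the observed depth;
  Good–Toulmin extrapolation stabilized by a rational-function approximant,
  ensembled with a Chao1-bounded saturating fit, above it).
* **Homology** — Jaccard index `|A∩B|/|A∪B|`, Morisita–Horn overlap
  `2Σxᵢyᵢ/((Σxᵢ²/X² + Σyᵢ²/Y²)XY)`, top-100 prevalent-clone sharing,
  public clones, and generic set-sharing fractions.
* **Differential clone abundance** — per-clone two-sided exact tests of
  paired samples (minimum combined count 5, amino-acid identity),
  Benjamini–Hochberg FDR within the pair at α = 0.1, and tissue-enriched
  sub-repertoires.
* **Motif specificity** — GLIPH-style grouping of trimmed CDR3s by
  enriched k-mers (fold ≥ 10, resampling p ≤ 0.001) and global similarity
  (Hamming ≤ 1), viral classification (≥ 3 tetramer-reference CDR3 matches
  plus V-gene enrichment, Fisher p < 0.05), and separately normalized
  viral/non-viral tumor-only/lung-only/shared proportions.
* **Cohort statistics** — Spearman/Mann–Whitney/Wilcoxon/Kruskal–Wallis
  batteries with Dunn's post hoc, and median-split survival analysis
  (log-rank, univariate and covariate-adjusted Cox).
* **Synthetic cohorts** — `simulate_cohort()` generates multi-compartment
  repertoires with known ground truth (heavy-tailed clone sizes,
  configurable between-compartment sharing, planted viral public clones
  carrying known motifs and V-gene bias, multinomial template sampling,
  survival tied to repertoire features) for validation end to end.

See the methods vignette (`vignettes/tcr-repertoire-methods.Rmd`) for the
statistical details and design decisions.

## Worked example

```r
library(tcrep)

cfg <- sim_config(n_patients = 6, seed = 42,
                  clones_per_compartment = c(PBMC = 150, ADJACENT_LUNG = 120,
                                             TUMOR = 140),
                  depth = c(PBMC = 4000, ADJACENT_LUNG = 3000, TUMOR = 3500),
                  viral_reference_size = 300)
cohort <- simulate_cohort(cfg)
cohort$samples[["P001_TUMOR"]]
#> <tcr_sample> P001_TUMOR  [TUMOR, patient P001]
#>   161 clones, 3512 templates (153 productive clones)
#>   usable input: 19,134 nucleated-cell equivalents

repertoire_metrics(cohort$samples)[1:3, c("sample_id", "density",
  "richness_observed", "richness_extrapolated", "clonality")]
#>            sample_id density richness_observed richness_extrapolated clonality
#> 1          P001_PBMC   0.359               147                   156     0.143
#> 2 P001_ADJACENT_LUNG   0.135               138                   141     0.188
#> 3         P001_TUMOR   0.183               153                   156     0.167
```

Density is the fraction of nucleated cells that are T cells; richness is
reported at the compartment's reference depth (400,000 templates for PBMC,
120,000 for tissue — near-saturated here because the simulated repertoires
are small); clonality near 0 means an even repertoire, near 1 clonal
dominance. Note clonality is highest in the adjacent lung, the hallmark the
generator plants.

```r
cohort_overlap(cohort$samples, c("TUMOR", "ADJACENT_LUNG"), n = 100)[1:3, ]
#>   patient_id jaccard morisita top_n detected_in_partner in_partner_top_n
#> 1       P001   0.260    0.705   100                  54               51
#> 2       P002   0.261    0.368   100                  50               48
#> 3       P003   0.252    0.323   100                  45               41
```

About a quarter of clone identities are shared between paired tumor and
adjacent lung, and roughly half of the tumor's 100 most prevalent clones are
detected in the adjacent lung — the repertoire-homology pattern that
motivates the tissue-enriched analyses.

```r
enr <- call_enriched(cohort$samples[["P001_ADJACENT_LUNG"]],
                     cohort$samples[["P001_TUMOR"]])
sum(enr$enriched_in == "A")   # clones significantly lung-enriched vs tumor
#> [1] 55
```

On a 100-patient two-compartment cohort simulated with hazard increasing in
lung clonality, the survival stage recovers the planted effect from the
lung-enriched clonality variable:

```r
big <- simulate_cohort(sim_config(
  n_patients = 100, seed = 7,
  compartments = c("ADJACENT_LUNG", "TUMOR"),
  clones_per_compartment = c(ADJACENT_LUNG = 120, TUMOR = 140),
  sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0.30),
  depth = c(ADJACENT_LUNG = 2500, TUMOR = 3000),
  n_viral_public_clones = 0,
  survival_model = list(baseline = 2e-4,
                        coefs = c(ADJACENT_LUNG_clonality = 0.5),
                        censor_range = c(365, 3650))))
ec <- enriched_clonality_table(big$samples, "ADJACENT_LUNG", "TUMOR")
d  <- merge(big$manifest, ec, by = "patient_id")
survival_analysis(d, "clonality")
#> Survival (median split) for 'clonality': n = 100, events = 28
#>   log-rank p = 0.003094
#>   HR (high vs low) = 3.270 [1.427, 7.494], univariate p = 0.005095, multivariate p = 0.006436
```

Patients with above-median lung-enriched clonality have roughly three-fold
higher hazard, significant before and after covariate adjustment.

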