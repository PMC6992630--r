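---
title: "Methods: multi-compartment TCR-beta repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-compartment TCR-beta repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrep)
```

## What the package models

Bulk TCR-beta CDR3 sequencing reports, for each tissue sample, the set of
unique rearrangements (clones) with a template count per clone — the number
of input TCR molecules observed. `tcrep` analyzes such repertoires across
paired compartments of the same patient (peripheral blood, tumor, adjacent
uninvolved lung, plus healthy and COPD lung controls), asking three kinds of
question:

1. **Per-sample attributes** — how infiltrated (density), how diverse
   (richness) and how clonally focused (clonality) is each repertoire?
2. **Cross-compartment homology** — how much of the repertoire is shared
   between compartments, overall and among the most prevalent or
   tissue-enriched clones? Which CDR3 motifs recur, and do they point at
   viral rather than tumor antigens?
3. **Cohort-level inference** — do repertoire attributes associate with
   clinical covariates and overall survival?

All paper-facing computations run on productive rearrangements only
(`productive_filter()`); non-productive rows are kept at parse time so that
total repertoires remain inspectable.

### Clone identity

Two conventions are supported everywhere through the `key` argument:
amino-acid CDR3 only (`"aa"`, collapsing convergent recombination) and amino
acid plus V/J gene (`"aa_vj"`). The default is `"aa"`: sharing of T cell
specificities across samples and patients is an amino-acid-level statement,
and the differential-abundance stage is defined at amino-acid identity.
Overlap and richness can be switched to `"aa_vj"` when nucleotide-level
clonotype resolution matters.

## Per-sample attributes

**Density** is total productive templates over the usable input (the
nucleated-cell equivalents inferred from housekeeping-gene amplification):
the fraction of nucleated cells that are T cells. It is clipped to [0, 1]
with a warning, and reported absent — never zero — when the denominator is
unknown.

**Clonality** is $1 - H'/\ln R$ (one minus Pielou's evenness), with $H'$ the
Shannon entropy of clone frequencies in natural log and $R$ the observed
richness: 0 for a perfectly even repertoire, approaching 1 under clonal
dominance. A monoclonal repertoire is assigned clonality 1 by convention; an
empty repertoire has no clonality (absent, never 0). Natural log is used
throughout, matching Pielou's definition.

**Richness** is compared across samples at a common template depth (defaults:
400,000 templates for PBMC, 120,000 for tissue, `richness_targets()`),
because observed richness grows with sequencing depth. For targets at or
below the observed depth, `richness_extrapolated()` returns the exact
expectation of unique clones under without-replacement subsampling,
$E[S_t] = \sum_i [1 - \binom{n-n_i}{t}/\binom{n}{t}]$. For larger targets the
number of not-yet-seen clones is extrapolated from the count-frequency
histogram $f_j$ (clones seen $j$ times):

* a **Good–Toulmin** series $\sum_j (-1)^{j+1} f_j y^j$ in the relative extra
  depth $y = t/n - 1$, summed through a rational-function (Padé $[L/L{+}1]$)
  approximant. The raw series diverges for $y > 1$; the approximant is finite
  as $y \to \infty$. Approximant orders with poles, negative values or
  non-monotone discovery curves on $(0, y]$ are rejected, and among the
  stable orders the smallest discovery curve is kept — high orders can chase
  histogram noise and inflate the asymptote, so the conservative stable curve
  is preferred;
* a **Chao1-bounded saturating fit**: unseen clones
  $\hat f_0 = f_1^2/(2 f_2)$ discovered at the singleton rate,
  $\hat f_0 (1 - (1 - f_1/(n \hat f_0 + f_1))^{t-n})$.

The default estimator averages the two curves. The rationale is empirical
and documented here deliberately: across simulated populations the Padé–GT
curve is nearly unbiased but occasionally unstable, the Chao fit is stable
but biased low under heavy-tailed clone sizes, and the ensemble tracks
Monte-Carlo truth at 10x depth within a few percent across both regimes. Both
pure estimators remain available via `method=`. When no stable approximant
exists the Chao fit is used alone and flagged in the `"method"` attribute.
Samples with fewer than `min_templates` (default 100) observed templates
report observed richness only, with the extrapolated value absent. The
estimator is continuous across the interpolation/extrapolation boundary and
monotone in the target depth.

## Homology between repertoires

`jaccard_index()` is presence-based sharing over unique clone keys;
`morisita_index()` is the abundance-weighted Morisita–Horn form
$2\sum x_i y_i / ((\sum x_i^2/X^2 + \sum y_i^2/Y^2) X Y)$, chosen over the
original Morisita index because it is bounded in [0, 1] and invariant to
depth rescaling of either sample. `top_n_sharing()` ranks clones by template
count with a deterministic tie-break (higher count, then lexicographic
CDR3) and reports how many of the source's top N (default 100) are detected
in the partner and how many sit in the partner's own top N.
`public_clones()` tabulates clone keys across patients;
`set_sharing()` is the generic three-way partition used for per-tissue
mutation identifier sets.

The "tissue-enriched homology" recipe (`tissue_enriched_sample()`) first
restricts each repertoire to clones called enriched versus the paired
comparator by the differential-abundance stage, then applies the same
indices; it is a composition of existing operations, not a new statistic.

## Differential clone abundance

For a paired sample comparison, every amino-acid clone with combined count
of at least `min_total = 5` is tested with a two-sided exact test on the
2x2 table of clone counts versus the two samples' productive template
totals; clones absent from one sample count 0 there. P-values are adjusted
by Benjamini–Hochberg *within the pair* (per-patient enrichment semantics),
and clones with $q \le \alpha = 0.1$ are labeled by direction. The test is
implemented as direct hypergeometric enumeration (the same two-sided rule as
`stats::fisher.test`, to which it is equality-tested) so that thousands of
clones screen quickly; `test_clone()` isolates it so an alternative model
(e.g. beta-binomial) would be a drop-in.

## Motif-based specificity groups

GLIPH-style grouping proceeds on trimmed CDR3s (3 N-terminal and 2
C-terminal residues removed; sequences shorter than 7 excluded): k-mers
(k = 2, 3, 4) present in at least two analysis CDR3s are scored against a
reference repertoire — fold enrichment of containment rates (reference rate
floored at $0.5/n_{ref}$ when the motif is absent) and a resampling p-value
over analysis-sized draws from the reference. Motifs with fold $\ge 10$ and
$p \le 0.001$ (the clustering algorithm's published defaults; the source
study states none) define the local rule; the global rule joins equal-length
trimmed sequences at Hamming distance $\le 1$. Specificity groups are
connected components of the combined relation; singletons are discarded.

A group is **viral** when at least 3 member CDR3s exactly match a
tetramer-defined viral reference CDR3 (sequence equality, not motif
containment — tetramer hits are sequences) *and* some V gene is enriched
among members versus cohort-wide usage (one-sided Fisher p < 0.05).
Per patient, groups observed in tumor and/or adjacent lung are categorized
TUMOR_ONLY / LUNG_ONLY / SHARED, and viral and non-viral groups are
normalized *separately* (public specificity databases are skewed towards
well-studied viral epitopes, so absolute counts are not comparable);
`fold_shared` is the ratio of the two SHARED proportions. Location
proportions are computed per patient (a pooled mode would mask
between-patient heterogeneity); patients lacking both compartments are
reported absent.

## Cohort-level statistics

`associate()` runs a declared plan of nonparametric tests (Spearman,
Mann–Whitney, Wilcoxon matched pairs, Kruskal–Wallis with Dunn's post hoc
only after a significant omnibus test) and reports unadjusted p-values as
primary — the exploratory-screen convention — alongside a clearly separated
BH column. Classical tests delegate to `stats`; Dunn's test is implemented
in-package (tie-corrected rank-sum z) because no post hoc package is a
dependency.

`survival_analysis()` dichotomizes a repertoire variable at the sample
median — high strictly above the median, at-median observations to the low
group (flippable via `at_median`) — and reports the log-rank test, the
univariate Cox hazard ratio with 95% CI, and the variable's p-value from a
multivariate Cox model adjusted for age, sex, histology, stage, smoking and
tumor size. Fits delegate to the `survival` package; the package's
contribution is the faithful orchestration. Results with fewer than
`min_events` (default 10) events are flagged underpowered with no hazard
ratio. Cause-specific survival uses an alternate event column.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* latent clone populations per compartment with lognormal (or power-law)
  weights; a configurable fraction of mass shifted onto the top clone
  (`clonality_shift`) creates clonal dominance, and per-patient ranges
  create between-patient clonality heterogeneity;
* clone abundances correlated across compartments (patient-level base
  weight times compartment noise at half the lognormal sigma), and clones
  shared between adjacent lung and tumor additionally expanded
  (`shared_expansion`, default 3x) — antigen-driven clones present on both
  sides of the tumor margin are expanded in both, which is what makes
  enriched-repertoire homology exceed whole-repertoire homology;
* pairwise clone sharing between compartments at configured fractions;
  planted viral public clones (identical across patients) embedding known
  4-mer motifs, each motif family carrying one dominant V gene drawn from a
  biased distribution — the V-gene restriction of same-specificity TCRs
  that motif clustering relies on;
* observed counts as multinomial draws of `depth` templates from latent
  frequencies (no sequencing-error model: inputs are already-denoised
  clonotype tables);
* CDR3s of uniform length 8–20 with C...F framing; a small fraction of
  non-productive clones exercises the productive filter;
* exponential survival times with hazard log-linear in standardized latent
  repertoire features and uniform censoring — the simplest model permitting
  Cox coefficient recovery;
* a synthetic tetramer-defined viral reference (planted clones plus
  motif-free decoys), clearly a stand-in for a public database.

Identical config and seed give byte-identical output files.

Default conditions (50 patients; 400/250/300 latent clones and
12,000/6,000/8,000 templates for PBMC/lung/tumor; lung–tumor sharing 0.30
versus 0.05 for blood–tissue; latent T cell fraction with mean 0.24; lung
clonality shift 0.05–0.30 exceeding tumor and blood) reproduce the
qualitative structure of a real early-stage NSCLC cohort at desk scale:
clonality highest in the adjacent lung, homology concentrated between lung
and tumor, and survival responsive to lung-enriched clonality. What the
generator does **not** emulate: V(D)J recombination biology and germline
motif structure (CDR3s are uniform random, so motif-enrichment nulls are
cleaner than in real repertoires), sequencing error, real public-clone
frequency hierarchies, and clinical covariates correlated with repertoire
features. Passing tests therefore validate the statistical machinery, not
performance on any real cohort.

## Validation choices and problem sizes

The test suite validates each stage against independent oracles: exhaustive
subsample enumeration for richness interpolation (every repertoire of up to
12 templates); Monte-Carlo truth for extrapolation (20 populations, 500–5,000
clones, lognormal sigma 0–1, depth 6x the clone count, extrapolated to 10x
depth, each within 10%); hand-derived entropy and overlap values;
`stats::fisher.test` as the dual route for the exact test; brute-force
transitive closure for grouping; and simulator ground truth for
differential-abundance calibration (500 null pairs at depth $10^4$; planted
10-fold clones), motif recovery (5 planted families; null cohorts), homology
ordering (100 patients) and survival recovery (hazard coefficient +0.5 on
standardized lung clonality, 100 replicate cohorts of 200 patients,
log-rank p < 0.05 with HR > 1 required in at least 80%). These sizes were
chosen to make Monte-Carlo error small relative to each criterion while
keeping the suite runnable on a laptop in minutes.

Numerical conventions worth knowing: clonality is clamped to [0, 1] against
floating-point drift; ranking ties anywhere in top-N analyses break
deterministically; `normalize_gene_name()` maps unresolvable names to an
explicit `"unresolved"` sentinel that is excluded from V-gene tests but
never silently dropped; and empty repertoires propagate as absent values
with warnings rather than zeros, so downstream medians are not biased.

## Known limitations

* Richness extrapolation beyond ~10-20x the observed depth is increasingly
  an extrapolation of the estimator, not the data; accuracy claims are
  validated at 10x.
* The exact test treats templates as independent draws; PCR correlation
  between templates of one clone would make it anticonservative. The cited
  upstream framework shares this assumption.
* Motif resampling p-values are Monte-Carlo estimates (default 1,000
  draws); p-values below 1/resamples are reported as 0.
* Survival simulation draws covariates independently of repertoire
  features, so multivariate adjustment is validated only for sign
  stability, not confounding correction.
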