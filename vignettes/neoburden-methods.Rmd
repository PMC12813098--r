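---
title: "Methods: burden biomarkers, signature refitting, and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden biomarkers, signature refitting, and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoburden)
```

## Scope and model

`neoburden` analyses two per-patient burden biomarkers in resected cancer
cohorts and their relation to overall survival:

* **TMB** (tumor mutational burden): quality-filtered somatic variants per
  megabase of the coding region;
* **TNB** (tumor neoantigen burden): screened neoantigens — mutant peptides
  predicted to bind a patient's HLA class I molecules and supported by tumor
  RNA expression — per megabase of the exonic region.

The package covers the analysis stages downstream of variant calling and
annotation: variant-level quality filtering, burden statistics and grouping,
96-trinucleotide-context mutation catalogs with non-negative signature
refitting, sliding-window neoantigen enumeration and screening, and survival
stratification (Kaplan–Meier, log-rank, restricted mean survival time, Cox
proportional hazards, maximally selected cutpoint search). Read alignment,
variant calling, HLA typing and affinity prediction itself are upstream
tools; their outputs are this package's inputs.

## Somatic filtering

Six predicates are applied per variant, in a fixed order used to attribute
each removal to its first failing criterion:

1. alt-supporting reads ≥ 4;
2. variant allele fraction ≥ 2% (inclusive — "at least 2%");
3. mapping quality > 30 (calls at ≤ 30 are excluded, so the bound is strict);
4. mutated-base quality > 25 (same reading);
5. distance from the mutated base to the nearer read end;
6. population allele frequency < 0.01, taking the maximum over ExAC and
   gnomAD with a missing value treated as 0 (a variant absent from both
   databases is rare, which is what the criterion is designed to retain).

The end-distance criterion deserves a note. Removing variants whose
supporting reads carry the mutation *within* one barcode length (8 bp) of a
read end is the standard artifact guard; a literal "must be less than 8 bp"
reading would keep only end-proximal calls. The default
(`end_distance_rule = "exclude_proximal"`) requires
`min_end_distance >= 8`; the opposite literal reading is available as
`"require_proximal"` so either convention can be reproduced exactly.

TMB divides the passing count by `coding_region_mb`. No consensus exome
size exists; the default is 34 Mb, configurable, chosen so that the
conventional cutoffs of 12 mut/Mb and 6 neoantigens/Mb correspond to integer
counts (408 and 204). TMB-High is the top 30% of the cohort:
`floor(0.30 * n)` patients (25 of 85) with boundary ties expanded into the
High group, which keeps the labelling deterministic and invariant to input
order.

Copy-number segments are classified from tumor/normal copy ratios with
strict bounds: gain above 2-fold, loss below 0.5-fold, boundaries neutral.

## Mutation catalogs and signature refitting

Single-nucleotide variants are tabulated over 96 bins — six pyrimidine
substitution subtypes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 5' and
3' flanking bases. Purine-reference calls are reverse-complemented together
with their flanks, so the catalog is strand-collapsed by construction; the
suite checks that flipping every SNV to the opposite strand leaves the
catalog unchanged. Bin order is the substitution-major lexicographic
convention with labels like `A[C>A]A`, enforced on file read.

Exposures to a user-supplied signature matrix (e.g. the 30 reference
signatures, provided as TSV; nothing is bundled or downloaded) are refit by
non-negative least squares on the normalized catalog. Weights below
`prune_below` (default 0.06, the conventional refitting cutoff) are zeroed
and the remainder renormalized; the residual norm is reported for the pruned
solution. This is a direct constrained least-squares refit; iterative
golden-section refinement used by some refitting tools is not replicated —
on mixture catalogs the two agree within the pruning tolerance, which the
suite verifies against a brute-force simplex grid at 0.01 resolution. No
exome/genome context-frequency correction is applied to the catalog before
refitting; supply pre-corrected signatures if that correction is needed.

## Neoantigen screening

For each protein-changing variant, every window of length 8–11 on the
mutant protein that overlaps the mutated residue is enumerated (truncated at
the termini; an interior missense yields 8+9+10+11 = 38 windows). Lengths
are configurable; 8–11-mers are the HLA class I convention. For
substitutions the paired wild-type peptide is the same window on the
wild-type sequence; windows identical to their wild-type pair carry no
mutant residue and are dropped.

Binding prediction sits behind a minimal contract — a deterministic function
`(peptide, allele) -> affinity nM` — so any external predictor can be
plugged in, either as a function, through the named registry
(`list(name = "mock", ...)`), or as a pre-computed table
(`table_predictor()`). Screening passes a candidate iff

1. affinity < 500 nM (the community convention for class I binders; the
   threshold is configurable because published pipelines vary), and
2. the source transcript is expressed (TPM ≥ 1) **and** the mutant allele
   is seen in RNA (≥ 1 mutant-supporting read). For candidates without a
   paired wild-type window (frameshift/novel sequence) the mutant-read
   requirement cannot be defined at the peptide level and criterion (2)
   falls back to transcript-level TPM alone.

Duplicate HLA alleles (homozygosity) are deduplicated before prediction.
TNB divides the call count by `coding_region_mb`; the counting unit defaults
to distinct mutant peptides (a peptide presented on two alleles counts
once), with distinct variants and peptide–allele pairs selectable, since
"number of neoantigens" is reported without a unit in much of the
literature and the three conventions genuinely differ.

## Survival stratification

Overall survival counts cancer-related deaths as events; patients dying of
other causes are censored at their last known time (`death_cause` column).
Kaplan–Meier estimation, the two-group log-rank test and Cox regression are
computed through the `survival` package (product-limit estimator; Efron
correction for tied event times; Newton iteration to a 1e-9 log-likelihood
tolerance); the suite cross-checks them against independent oracles — a
hand risk-set tabulation for the log-rank statistic and a grid search of a
directly-coded Efron partial likelihood for the Cox estimate.

RMST at horizon τ is the area under the Kaplan–Meier step function on
[0, τ], with the curve extended flat beyond the last observed time; the
default horizons are 24 and 36 months (2- and 3-year RMST). The TNB-High
threshold is data-driven: an exhaustive maximally selected log-rank scan
over the midpoints between consecutive distinct biomarker values, keeping
only splits that leave at least 10% of patients in each group, with ties
broken toward the smaller cutoff. A stepwise/gradient-style search over the
same candidate set would return the same maximizer at cohort scale, so the
exhaustive scan is used for determinism, and the full scan table is returned
because the selected p-value is not multiplicity-corrected — users who want
a corrected p can apply one to the table.

## Synthetic cohort generator

The generator emulates every input the pipeline consumes, with known ground
truth, so the whole analysis is testable without any data download:

* per-patient mutation rates are log-normal with median 8 mut/Mb
  (`tmb_lognormal_mu = log(8)`, σ = 0.6), which places the top-30% boundary
  near 12 mut/Mb over the default 34 Mb coding region — the regime of a
  moderately mutated gastrointestinal cohort;
* filter violations are injected as exact rounded per-criterion counts
  (`round(rate * n_variants)`), each corrupted variant violating exactly one
  criterion while every other field passes, so filtering with matching
  thresholds removes exactly the ledger's variants;
* proteins are synthetic random sequences of 100–1,000 aa rather than real
  genes, giving full control over windowing edge cases; each
  protein-changing variant is a single-residue substitution;
* a configurable fraction of protein-changing variants (default 0.1) is
  "immunogenic": guaranteed expression evidence (TPM ≥ 1, mutant reads ≥ 1).
  Ground-truth TNB counts their distinct mutant windows scoring < 500 nM
  under the deterministic mock predictor, evaluated at generation time, so
  pipeline recovery is exact by construction. Non-immunogenic variants get
  zero mutant RNA reads and can never pass screening;
* the mock predictor hashes (peptide, allele, seed) to a uniform deviate
  and maps it piecewise-linearly so that a configurable fraction (default
  0.05) of random peptides are strong binders; with 0.05, median TNB sits
  near half of median TMB — the "low neoantigen load" regime typical of
  resected gastric cohorts;
* survival times follow a proportional-hazards model with exponential
  baseline (the simplest PH-compatible choice; nothing in the analysis
  depends on the baseline shape), default log hazard ratios ln(4.50) for
  age > 65, ln(2.68) for female sex, ln(4.32) for N3 nodal stage and a
  configurable TNB-High effect, covariate prevalences matching a published
  resected-cohort frequency table, independent exponential censoring,
  staggered administrative follow-up up to 44.4 months, and a small rate of
  flagged non-cancer deaths to exercise the censoring rule.

What the generator does **not** emulate: real genome coordinates, gene- or
hotspot-specific mutation distributions, linkage between variants, sequence
properties that real binding predictors respond to, or dependent censoring.
Passing recovery tests therefore demonstrates the correctness of the
analysis machinery under a controlled data-generating process, not the
biological validity of any particular cutoff on real cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script use scaled simulation sizes chosen
as reasonable desk-scale designs: parameter-recovery runs use 50 replicates
of n = 300 patients with 25 variants each (burden scale is irrelevant to the
survival contrast, so it is kept small), and cutpoint-recovery runs use
n = 200 with a Poisson(4) count biomarker and a hazard doubling above 5 —
count-valued biomarkers are the natural setting for burden cutoffs, and the
"within one candidate step" recovery notion is only meaningful at count
resolution. Other conventions: events precede censorings at tied times;
`classify_by_top_fraction` expands boundary ties into the High group; the
cutpoint scan requires ≥ 10% of patients per group; Cox convergence is
declared at a 1e-9 log-likelihood change within 100 iterations, and monotone
likelihood (complete separation) is surfaced via the `converged` flag.

## Known limitations

* Variant I/O is MAF-like TSV; VCF ingestion is not provided.
* The signature refit reports exposures for one catalog at a time; no
  hierarchical or multi-sample pooling.
* The cutpoint p-value is not corrected for the maximal selection; treat it
  as descriptive and use the scan table for corrected inference.
* The mock predictor is a calibration device, not a surrogate for real
  binding biology: its scores are uniform by construction and carry no
  anchor-residue structure.
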