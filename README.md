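# neoburden

Tumor mutational burden (TMB) counts filtered somatic variants per megabase
of coding sequence; tumor neoantigen burden (TNB) counts, per megabase,
the mutant peptides that are predicted to bind a patient's HLA class I
molecules **and** are supported by tumor RNA expression. In resected
cohorts without immunotherapy, TNB can stratify overall survival where TMB
does not, because it measures presented immunogenicity rather than raw
mutation load. `neoburden` is an R package for running and stress-testing
that comparison end to end.

It is aimed at cancer-immunogenomics analysts who already have upstream
calls (variants with QC fields, HLA types, expression tables) and need the
downstream statistics to be explicit, configurable and tested:

* **Somatic filtering** — six quality criteria (read support ≥ 4, VAF ≥ 2%,
  mapping quality > 30, base quality > 25, read-end distance, population
  AF < 0.01 over ExAC/gnomAD) with a per-criterion removal tally, plus
  copy-ratio gain/loss classification (> 2 / < 0.5).
* **Burdens** — TMB = passing variants / Mb with top-30% grouping;
  TNB = screened neoantigens / Mb with a selectable counting unit
  (distinct peptides, variants, or peptide–HLA pairs).
* **Mutational signatures** — 96-trinucleotide-context catalogs
  (strand-collapsed to the pyrimidine convention) and non-negative
  least-squares refitting against a user-supplied signature matrix with
  prune-and-renormalize exposures.
* **Neoantigen screening** — 8–11-mer sliding windows over the mutated
  residue, a pluggable deterministic binding-predictor contract (mock hash
  predictor and external-table adapter included), affinity < 500 nM plus
  expression evidence (TPM ≥ 1, ≥ 1 mutant RNA read).
* **Survival** — Kaplan–Meier, log-rank, restricted mean survival time at
  24/36 months, multivariate Cox (Efron ties), and a maximally selected
  log-rank cutpoint search with the full scan table exposed.
* **Synthetic cohorts** — a generator with exact ground truth (injected
  filter violations, constructed immunogenic variants, proportional-hazards
  survival with exponential baseline) so every stage is verifiable without
  external data.

## Worked example

Simulate a 60-patient cohort with a true TNB-High hazard ratio of 3, then
run the full pipeline on its files:

```r
library(neoburden)

cfg <- cohort_config(n_patients = 60, seed = 42, tmb_lognormal_mu = log(3))
gt  <- generate_cohort(cfg, "cohort_dir")

pcfg <- pipeline_config(
  variants   = gt$paths$variants,
  expression = gt$paths$expression,
  hla        = gt$paths$hla,
  clinical   = gt$paths$clinical,
  proteins   = gt$paths$proteins,
  predictor  = list(name = "mock", seed = 42, strong_binder_fraction = 0.05))
res <- run_pipeline(pcfg)
#> read 6644 variants, 60 patients
#> filtering: 6644 in, 5840 pass, removed by criterion: read-support=134,
#>   allele-fraction=134, mapping-quality=134, base-quality=134,
#>   end-distance=134, population-af=134
#> TMB: median 2.40 mut/Mb, High cutoff 3.24 (19 High)
#> neoantigens: 553982 candidates, 2966 calls, median TNB 1.16 /Mb
#> survival: TNB cutoff 1.22, log-rank p (TNB) = 0.0173, p (TMB) = 0.859

print(res$survival$cox$tnb_group)
#> Cox proportional-hazards fit (Efron ties): n = 60, events = 39
#>   tnb_groupLow             HR 0.29 (0.14-0.61)  p = 0.000905
#>   age_group>65             HR 4.01 (1.90-8.46)  p = 0.000268
#>   ...
```

Reading the output: 804 of 6,644 simulated variants were injected filter
violations and the tally attributes each removal to exactly the criterion
that was corrupted. The data-driven TNB cutoff (1.22 neoantigens/Mb here)
separates survival (log-rank p = 0.017) while the top-30% TMB grouping does
not (p = 0.86) — the TNB-High effect is what the generator planted, and in
the adjusted Cox fit TNB-Low carries HR 0.29 (i.e. TNB-High ≈ 3.5, close to
the simulated hazard ratio of 3). Per-patient TMB/TNB recover the
generator's ground truth exactly (`res$biomarkers` vs `gt$patients`).

A thin CLI over the same functions lives at
`inst/scripts/neoburden-cli.R` (`simulate`, `filter`, `run-all`, `report`
subcommands).

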