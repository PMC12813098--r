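Package: neoburden
Title: Tumor Mutational and Neoantigen Burden Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of tumor mutational burden (TMB) and tumor
    neoantigen burden (TNB) as prognostic biomarkers in resected cancer
    cohorts. Implements somatic variant quality filtering with per-criterion
    accounting, burden statistics (mutations and screened neoantigens per
    megabase of coding sequence), 96-trinucleotide-context mutational
    catalogs with non-negative signature refitting, sliding-window neoantigen
    enumeration and screening behind a pluggable HLA-binding predictor
    contract, and survival stratification (Kaplan-Meier, log-rank, restricted
    mean survival time at fixed horizons, Cox proportional hazards, and a
    maximally selected log-rank cutpoint search). A synthetic cohort
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
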