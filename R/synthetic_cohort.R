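# Synthetic cohort generator with known ground truth: somatic variant
# tables with injected filter violations, synthetic proteins and mutant
# contexts, expression evidence, HLA allele lists, and clinical/survival
# outcomes drawn from a proportional-hazards model with exponential
# baseline hazard.

#' Cohort generator configuration
#'
#' All knobs of the synthetic cohort. Defaults emulate a resected
#' gastric-cancer cohort: per-patient mutation rate log-normal around
#' 8 mut/Mb over a 34 Mb coding region, covariate prevalences and hazard
#' ratios (age>65 HR 4.50, female HR 2.68, N3 HR 4.32) typical of published
#' multivariate fits in this setting, and a follow-up horizon of 44.4
#' months.
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param tmb_lognormal_mu,tmb_lognormal_sigma Log-scale mean / sd of the
#'   per-patient true mutation rate (mut/Mb).
#' @param variants_per_patient Optional fixed total variant count per
#'   patient, overriding the log-normal draw (useful for exact tests).
#' @param protein_changing_fraction Probability that a clean SNV changes
#'   the protein (gets a transcript and mutant peptide context).
#' @param immunogenic_fraction Probability that a protein-changing variant
#'   is given expression support (TPM >= 1, mutant RNA reads >= 1) and so
#'   can yield neoantigens.
#' @param filter_violation_rates Named per-criterion rates; for each
#'   criterion, `round(rate * n_variants)` variants are corrupted to
#'   violate exactly that criterion. Names: read-support, allele-fraction,
#'   mapping-quality, base-quality, end-distance, population-af.
#' @param hla_allele_pool HLA class I allele names sampled per patient.
#' @param hla_alleles_per_patient Alleles drawn per patient (with
#'   replacement, so homozygosity occurs).
#' @param baseline_hazard_rate Exponential baseline hazard (events/month).
#' @param log_hr_map Named log hazard ratios applied to the linear
#'   predictor; recognized names: `age_gt65`, `female`, `n3`, `tnb_high`.
#' @param covariate_prevalence Named Bernoulli prevalences for the binary
#'   clinical covariates (`age_gt65`, `female`, `n3`, `late_stage`,
#'   `poor_diff`, `chemo`).
#' @param tmb_high_fraction,tnb_high_fraction Top fractions used for the
#'   ground-truth High/Low labels.
#' @param censor_rate Independent censoring hazard (per month).
#' @param noncancer_death_rate Hazard of death from non-cancer causes (per
#'   month); such deaths are flagged in `death_cause`.
#' @param followup_horizon Administrative follow-up horizon in months.
#' @param coding_region_mb Coding-region size (Mb) used for all burdens.
#' @param strong_binder_fraction Fraction of random peptides the mock
#'   predictor scores as strong binders (< 500 nM).
#' @param peptide_lengths Window lengths for neoantigen enumeration.
#' @param protein_length_range Length range (aa) of the synthetic proteins.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 85,
                          seed = 1,
                          tmb_lognormal_mu = log(8),
                          tmb_lognormal_sigma = 0.6,
                          variants_per_patient = NULL,
                          protein_changing_fraction = 0.7,
                          immunogenic_fraction = 0.1,
                          filter_violation_rates = c(
                            "read-support" = 0.02, "allele-fraction" = 0.02,
                            "mapping-quality" = 0.02, "base-quality" = 0.02,
                            "end-distance" = 0.02, "population-af" = 0.02),
                          hla_allele_pool = c("HLA-A*02:01", "HLA-A*11:01",
                                              "HLA-B*07:02", "HLA-B*40:01",
                                              "HLA-C*07:02", "HLA-C*01:02"),
                          hla_alleles_per_patient = 6,
                          baseline_hazard_rate = 0.015,
                          log_hr_map = c(age_gt65 = log(4.50),
                                         female = log(2.68),
                                         n3 = log(4.32),
                                         tnb_high = log(3)),
                          covariate_prevalence = c(age_gt65 = 43 / 85,
                                                   female = 22 / 85,
                                                   n3 = 31 / 85,
                                                   late_stage = 47 / 85,
                                                   poor_diff = 66 / 85,
                                                   chemo = 76 / 85),
                          tmb_high_fraction = 0.30,
                          tnb_high_fraction = 0.30,
                          censor_rate = 0.01,
                          noncancer_death_rate = 0.002,
                          followup_horizon = 44.4,
                          coding_region_mb = 34,
                          strong_binder_fraction = 0.05,
                          peptide_lengths = 8:11,
                          protein_length_range = c(100, 1000)) {
  cfg <- as.list(environment())
  if (!is.numeric(n_patients) || n_patients < 0 ||
      n_patients != floor(n_patients)) {
    stop("n_patients must be a non-negative integer")
  }
  probs <- c(protein_changing_fraction, immunogenic_fraction,
             filter_violation_rates, covariate_prevalence,
             tmb_high_fraction, tnb_high_fraction, strong_binder_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (coding_region_mb <= 0) stop("coding_region_mb must be > 0")
  if (any(c(baseline_hazard_rate, censor_rate, noncancer_death_rate) < 0)) {
    stop("hazard rates must be >= 0")
  }
  unknown <- setdiff(names(filter_violation_rates), .filter_criteria)
  if (length(unknown) > 0) {
    stop("unknown filter criterion name(s): ", paste(unknown, collapse = ", "))
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Deterministic mock HLA-binding predictor
#'
#' Stands in for an external affinity predictor behind the binding-predictor
#' contract: a pure deterministic mapping from (peptide, allele) to a
#' predicted affinity in nM. A hash of the pair (plus the generator seed)
#' yields a uniform deviate `u`; peptides with `u < strong_binder_fraction`
#' map linearly into (10, 500) nM (strong binders), the rest into
#' (500, 50000) nM, so approximately `strong_binder_fraction` of random
#' peptides score below the conventional 500 nM threshold.
#'
#' @param seed Integer mixed into the hash, so different seeds give
#'   different (but individually reproducible) predictors.
#' @param strong_binder_fraction Target fraction of strong binders among
#'   random peptides, in [0, 1].
#' @return A vectorized function `(peptide, allele) -> affinity nM`.
#' @export
generate_mock_predictor <- function(seed, strong_binder_fraction = 0.05) {
  if (!is.numeric(strong_binder_fraction) || strong_binder_fraction < 0 ||
      strong_binder_fraction > 1) {
    stop("strong_binder_fraction must lie in [0, 1]")
  }
  f <- strong_binder_fraction
  force(seed)
  function(peptide, allele) {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide)
    if (any(bad)) {
      stop("peptide contains non-amino-acid characters: ", peptide[bad][1])
    }
    u <- .hash01(paste0(peptide, "|", allele, "|", seed))
    if (f <= 0) {
      500 + 49500 * u
    } else if (f >= 1) {
      10 + 490 * u
    } else {
      ifelse(u < f, 10 + 490 * u / f, 500 + 49500 * (u - f) / (1 - f))
    }
  }
}

.random_proteins <- function(k, length_range) {
  if (k == 0) return(character(0))
  lens <- sample(seq(length_range[1], length_range[2]), k, replace = TRUE)
  chars <- sample(.aa_alphabet, sum(lens), replace = TRUE)
  vapply(split(chars, rep(seq_len(k), lens)), paste, "", collapse = "")
}

.empty_cohort_files <- function(out_dir) {
  paths <- list(
    variants = file.path(out_dir, "variants.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    hla = file.path(out_dir, "hla.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    proteins = file.path(out_dir, "proteins.fasta"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  writeLines(paste(c(.required_variant_columns, "variant_id", "transcript_id",
                     "context_5p", "context_3p"), collapse = "\t"),
             paths$variants)
  writeLines("transcript_id\ttpm\tmutant_rna_reads", paths$expression)
  writeLines("sample_id\thla_allele", paths$hla)
  writeLines(paste(c("sample_id", "time_months", "event", "death_cause",
                     "age_group", "sex", "stage", "n_status",
                     "differentiation", "chemotherapy", "tmb_true_group",
                     "tnb_true_group"), collapse = "\t"), paths$clinical)
  writeLines(character(0), paths$proteins)
  paths
}

#' Generate a synthetic cohort with known ground truth
#'
#' Writes a complete input bundle (variant TSV, expression TSV, HLA TSV,
#' clinical TSV, protein FASTA, ground-truth JSON) to `out_dir` and returns
#' the ground truth. Per-criterion filter violations are injected as exact
#' rounded counts of the per-patient variant totals; each corrupted variant
#' violates exactly its assigned criterion. "Immunogenic" protein-changing
#' variants receive guaranteed expression evidence, and the ground-truth
#' neoantigen burden counts their distinct mutant windows scoring below
#' 500 nM under the configured mock predictor, so a pipeline run with
#' matching thresholds recovers the truth exactly. Survival times are drawn
#' from a proportional-hazards model with exponential baseline hazard,
#' independent exponential censoring and staggered administrative
#' follow-up; a small rate of non-cancer deaths is flagged via
#' `death_cause`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (the six files), `patients`
#'   (per-patient true TMB/TNB and group labels), `ledger` (variant_id ->
#'   violated criterion), and `log_hr_map` (the true covariate effects).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_patients
  paths <- .empty_cohort_files(out_dir)
  if (n == 0) {
    gt <- list(patients = data.frame(sample_id = character(0),
                                     true_tmb = numeric(0),
                                     true_tnb = numeric(0),
                                     tmb_true_group = character(0),
                                     tnb_true_group = character(0)),
               ledger = data.frame(variant_id = character(0),
                                   criterion = character(0)),
               log_hr_map = as.list(config$log_hr_map))
    .write_ground_truth(gt, paths$ground_truth)
    gt$paths <- paths
    return(invisible(gt))
  }
  ids <- sprintf("P%04d", seq_len(n))

  ## ---- clinical covariates -------------------------------------------
  prev <- config$covariate_prevalence
  draw <- function(nm) stats::runif(n) < prev[[nm]]
  cov <- data.frame(sample_id = ids,
                    age_gt65 = draw("age_gt65"), female = draw("female"),
                    n3 = draw("n3"), late_stage = draw("late_stage"),
                    poor_diff = draw("poor_diff"), chemo = draw("chemo"))

  ## ---- variants -------------------------------------------------------
  rate <- stats::rlnorm(n, config$tmb_lognormal_mu, config$tmb_lognormal_sigma)
  n_total <- if (!is.null(config$variants_per_patient)) {
    rep(as.integer(config$variants_per_patient), n)
  } else {
    stats::rpois(n, rate * config$coding_region_mb)
  }
  nv <- sum(n_total)
  pid <- rep(ids, n_total)
  vdf <- data.frame(
    sample_id = pid,
    chrom = paste0("chr", sample(1:22, nv, replace = TRUE)),
    pos = sample.int(5e7, nv, replace = TRUE),
    variant_class = sample(c("SNV", "insertion", "deletion"), nv,
                           replace = TRUE, prob = c(0.9, 0.05, 0.05)),
    gene = paste0("GENE", sample.int(500, nv, replace = TRUE)),
    protein_change = rep(NA_character_, nv),
    alt_read_count = 4 + stats::rpois(nv, 16),
    allele_fraction = round(stats::runif(nv, 0.05, 0.6), 4),
    mapping_quality = round(stats::runif(nv, 31, 60), 1),
    base_quality = round(stats::runif(nv, 26, 40), 1),
    min_end_distance = sample(8:60, nv, replace = TRUE),
    pop_af_exac = ifelse(stats::runif(nv) < 0.2, NA,
                         round(stats::runif(nv, 0, 0.009), 5)),
    pop_af_gnomad = ifelse(stats::runif(nv) < 0.2, NA,
                           round(stats::runif(nv, 0, 0.009), 5)),
    variant_id = sprintf("V%07d", seq_len(nv)),
    transcript_id = rep(NA_character_, nv),
    stringsAsFactors = FALSE)
  is_snv <- vdf$variant_class == "SNV"
  b <- .bases
  vdf$ref <- sample(b, nv, replace = TRUE)
  alt_shift <- sample(1:3, nv, replace = TRUE)
  vdf$alt <- b[(match(vdf$ref, b) - 1 + alt_shift) %% 4 + 1]
  ins <- vdf$variant_class == "insertion"
  del <- vdf$variant_class == "deletion"
  vdf$alt[ins] <- paste0(vdf$ref[ins], sample(b, sum(ins), replace = TRUE))
  vdf$ref[del] <- paste0(vdf$ref[del], sample(b, sum(del), replace = TRUE))
  vdf$alt[del] <- substr(vdf$ref[del], 1, 1)
  vdf$context_5p <- ifelse(is_snv, sample(b, nv, replace = TRUE),
                           NA_character_)
  vdf$context_3p <- ifelse(is_snv, sample(b, nv, replace = TRUE),
                           NA_character_)

  ## ---- inject filter violations (exact rounded counts per patient) ----
  rates <- config$filter_violation_rates
  viol_criterion <- rep(NA_character_, nv)
  offset <- c(0, cumsum(n_total))
  for (p in seq_len(n)) {
    rows <- if (n_total[p] > 0) (offset[p] + 1):(offset[p] + n_total[p])
            else integer(0)
    counts <- vapply(.filter_criteria, function(cr) {
      r <- if (cr %in% names(rates)) rates[[cr]] else 0
      as.integer(round(r * n_total[p]))
    }, integer(1))
    total_viol <- min(sum(counts), n_total[p])
    if (total_viol > 0) {
      pick <- sample(rows, total_viol)
      viol_criterion[pick] <- rep(.filter_criteria,
                                  counts)[seq_len(total_viol)]
    }
  }
  corrupt <- function(cr, field, values) {
    i <- which(viol_criterion == cr)
    if (length(i) > 0) vdf[[field]][i] <<- values(length(i))
  }
  corrupt("read-support", "alt_read_count", function(k) sample(0:3, k, TRUE))
  corrupt("allele-fraction", "allele_fraction",
          function(k) round(stats::runif(k, 0.001, 0.019), 4))
  corrupt("mapping-quality", "mapping_quality",
          function(k) round(stats::runif(k, 0, 29.9), 1))
  corrupt("base-quality", "base_quality",
          function(k) round(stats::runif(k, 0, 24.9), 1))
  corrupt("end-distance", "min_end_distance",
          function(k) sample(0:7, k, TRUE))
  i <- which(viol_criterion == "population-af")
  if (length(i) > 0) {
    vdf$pop_af_exac[i] <- round(stats::runif(length(i), 0.011, 0.3), 5)
    vdf$pop_af_gnomad[i] <- round(stats::runif(length(i), 0, 0.009), 5)
  }
  clean <- is.na(viol_criterion)

  ## ---- proteins and mutant contexts for protein-changing clean SNVs ---
  pc <- clean & is_snv & stats::runif(nv) < config$protein_changing_fraction
  k <- sum(pc)
  tx_ids <- sprintf("TX%06d", seq_len(max(k, 0)))
  vdf$transcript_id[pc] <- tx_ids
  wt_seqs <- .random_proteins(k, config$protein_length_range)
  pos_aa <- if (k > 0) {
    vapply(nchar(wt_seqs), function(L) sample.int(L, 1), integer(1))
  } else integer(0)
  wt_aa <- substr(wt_seqs, pos_aa, pos_aa)
  mut_aa <- vapply(wt_aa, function(a) sample(setdiff(.aa_alphabet, a), 1), "",
                   USE.NAMES = FALSE)
  mut_seqs <- wt_seqs
  substr(mut_seqs, pos_aa, pos_aa) <- mut_aa
  vdf$protein_change[pc] <- paste0("p.", wt_aa, pos_aa, mut_aa)
  contexts <- data.frame(variant_id = vdf$variant_id[pc],
                         sample_id = vdf$sample_id[pc],
                         transcript_id = tx_ids,
                         wildtype_seq = wt_seqs, mutant_seq = mut_seqs,
                         span_start = pos_aa, span_end = pos_aa,
                         stringsAsFactors = FALSE)

  ## ---- expression evidence -------------------------------------------
  immuno <- if (k > 0) stats::runif(k) < config$immunogenic_fraction
            else logical(0)
  tpm <- round(stats::rlnorm(k, 1.5, 1), 3)
  tpm[immuno] <- round(1 + stats::rlnorm(sum(immuno), 1.5, 1), 3)
  reads <- integer(k)
  reads[immuno] <- 1 + stats::rpois(sum(immuno), 5)
  expr <- data.frame(transcript_id = tx_ids, tpm = tpm,
                     mutant_rna_reads = reads, stringsAsFactors = FALSE)

  ## ---- HLA alleles ----------------------------------------------------
  hla <- data.frame(
    sample_id = rep(ids, each = config$hla_alleles_per_patient),
    hla_allele = sample(config$hla_allele_pool,
                        n * config$hla_alleles_per_patient, replace = TRUE),
    stringsAsFactors = FALSE)

  ## ---- ground-truth TNB: screen the immunogenic variants --------------
  predictor <- generate_mock_predictor(config$seed,
                                       config$strong_binder_fraction)
  hla_by_sample <- split(hla$hla_allele, hla$sample_id)
  true_tnb_count <- stats::setNames(numeric(n), ids)
  if (any(immuno)) {
    im_rows <- which(immuno)
    cand <- vector("list", length(im_rows))
    for (j in seq_along(im_rows)) {
      r <- im_rows[j]
      win <- enumerate_mutant_peptides(contexts$mutant_seq[r],
                                       c(contexts$span_start[r],
                                         contexts$span_end[r]),
                                       contexts$wildtype_seq[r],
                                       config$peptide_lengths)
      alleles <- unique(hla_by_sample[[contexts$sample_id[r]]])
      if (nrow(win) == 0 || length(alleles) == 0) next
      cand[[j]] <- data.frame(sample_id = contexts$sample_id[r],
                              peptide = rep(win$peptide, length(alleles)),
                              hla_allele = rep(alleles, each = nrow(win)),
                              stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand) > 0) {
      aff <- predictor(cand$peptide, cand$hla_allele)
      hit <- cand[aff < 500, , drop = FALSE]
      if (nrow(hit) > 0) {
        cnt <- tapply(hit$peptide, hit$sample_id,
                      function(x) length(unique(x)))
        true_tnb_count[names(cnt)] <- as.numeric(cnt)
      }
    }
  }

  ## ---- ground-truth burdens and group labels -------------------------
  n_clean <- as.numeric(tapply(clean, factor(pid, levels = ids), sum))
  n_clean[is.na(n_clean)] <- 0
  true_tmb <- n_clean / config$coding_region_mb
  true_tnb <- unname(true_tnb_count) / config$coding_region_mb
  tmb_group <- if (length(unique(true_tmb)) > 1) {
    classify_by_top_fraction(true_tmb, config$tmb_high_fraction)$labels
  } else rep("Low", n)
  tnb_group <- if (length(unique(true_tnb)) > 1) {
    classify_by_top_fraction(true_tnb, config$tnb_high_fraction)$labels
  } else rep("Low", n)

  ## ---- survival from the proportional-hazards model -------------------
  lhr <- config$log_hr_map
  lp <- numeric(n)
  for (nm in names(lhr)) {
    x <- switch(nm,
                age_gt65 = cov$age_gt65, female = cov$female, n3 = cov$n3,
                tnb_high = tnb_group == "High",
                tmb_high = tmb_group == "High",
                late_stage = cov$late_stage, poor_diff = cov$poor_diff,
                chemo = cov$chemo,
                stop("unknown log_hr_map covariate: ", nm))
    lp <- lp + lhr[[nm]] * as.numeric(x)
  }
  rexp_or_inf <- function(rate) {
    if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  }
  t_event <- stats::rexp(n, config$baseline_hazard_rate * exp(lp))
  t_cens <- rexp_or_inf(config$censor_rate)
  t_nc <- rexp_or_inf(config$noncancer_death_rate)
  t_admin <- stats::runif(n, min(6, config$followup_horizon),
                          config$followup_horizon)
  time <- pmax(round(pmin(t_event, t_cens, t_nc, t_admin), 2), 0.01)
  which_min <- max.col(-cbind(t_event, t_cens, t_nc, t_admin),
                       ties.method = "first")
  event <- as.integer(which_min %in% c(1, 3))
  death_cause <- c("cancer", NA, "noncancer", NA)[which_min]

  clin <- data.frame(
    sample_id = ids, time_months = time, event = event,
    death_cause = death_cause,
    age_group = ifelse(cov$age_gt65, ">65", "<=65"),
    sex = ifelse(cov$female, "Female", "Male"),
    stage = ifelse(cov$late_stage, "III-IV", "I-II"),
    n_status = ifelse(cov$n3, "N3", "N0-2"),
    differentiation = ifelse(cov$poor_diff, "Poor", "Well"),
    chemotherapy = ifelse(cov$chemo, "Yes", "No"),
    tmb_true_group = tmb_group, tnb_true_group = tnb_group,
    stringsAsFactors = FALSE)

  ## ---- write the bundle ----------------------------------------------
  vcols <- c(.required_variant_columns, "variant_id", "transcript_id",
             "context_5p", "context_3p")
  utils::write.table(vdf[, vcols], paths$variants, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hla, paths$hla, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(clin, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  write_protein_contexts(contexts, paths$proteins)

  ledger <- data.frame(variant_id = vdf$variant_id[!clean],
                       criterion = viol_criterion[!clean],
                       stringsAsFactors = FALSE)
  gt <- list(patients = data.frame(sample_id = ids, true_tmb = true_tmb,
                                   true_tnb = true_tnb,
                                   tmb_true_group = tmb_group,
                                   tnb_true_group = tnb_group,
                                   stringsAsFactors = FALSE),
             ledger = ledger,
             log_hr_map = as.list(config$log_hr_map))
  .write_ground_truth(gt, paths$ground_truth)
  gt$paths <- paths
  invisible(gt)
}

.write_ground_truth <- function(gt, path) {
  jsonlite::write_json(list(patients = gt$patients, ledger = gt$ledger,
                            log_hr_map = gt$log_hr_map),
                       path, digits = 10, auto_unbox = TRUE, na = "null")
  invisible(path)
}
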