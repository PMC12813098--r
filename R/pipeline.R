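# Pipeline orchestration: generate/read inputs, filter, burden statistics,
# mutation catalogs, neoantigen screening, survival stratification, and the
# cohort report.

#' Pipeline configuration
#'
#' Paths to the input bundle plus every tunable threshold of the stages.
#' Nothing is hard-coded: filter thresholds, the coding-region size, peptide
#' lengths, binding/expression cutoffs, the neoantigen counting unit, the
#' TMB top fraction, cutpoint settings and the RMST horizons are all
#' surfaced here.
#'
#' @param variants,expression,hla,clinical,proteins Paths to the five input
#'   files (formats as written by [generate_cohort()]).
#' @param out_dir Directory for stage outputs.
#' @param thresholds A [filter_thresholds()] object.
#' @param coding_region_mb Coding-region size in Mb.
#' @param signature_matrix Optional path to a signature matrix TSV; when
#'   given, per-sample exposures are refit.
#' @param peptide_lengths Neoantigen window lengths.
#' @param binding_threshold_nm,min_tpm,min_mutant_rna_reads Screening
#'   cutoffs (see [screen_neoantigens()]).
#' @param counting_unit Neoantigen counting unit (see [compute_tnb()]).
#' @param tmb_top_fraction Fraction defining the TMB-High group.
#' @param tnb_grouping `"cutpoint"` (data-driven maximally selected
#'   log-rank cutoff, the default) or `"top_fraction"`.
#' @param tnb_top_fraction Fraction used when `tnb_grouping =
#'   "top_fraction"`.
#' @param min_group_fraction Minimum group fraction for the cutpoint scan.
#' @param tau_horizons RMST horizons in months (default 24 and 36).
#' @param predictor Binding predictor specification: a function
#'   `(peptide, allele) -> nM`, or a named registry entry as a list, e.g.
#'   `list(name = "mock", seed = 1, strong_binder_fraction = 0.05)` or
#'   `list(name = "table", path = "predictions.tsv")`.
#' @param prune_below Exposure pruning cutoff (see
#'   [fit_signature_exposures()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(variants, expression, hla, clinical, proteins,
                            out_dir = tempfile("neoburden_run_"),
                            thresholds = filter_thresholds(),
                            coding_region_mb = 34,
                            signature_matrix = NULL,
                            peptide_lengths = 8:11,
                            binding_threshold_nm = 500,
                            min_tpm = 1.0,
                            min_mutant_rna_reads = 1,
                            counting_unit = "distinct_peptides",
                            tmb_top_fraction = 0.30,
                            tnb_grouping = c("cutpoint", "top_fraction"),
                            tnb_top_fraction = 0.30,
                            min_group_fraction = 0.10,
                            tau_horizons = c(24, 36),
                            predictor = list(name = "mock", seed = 1,
                                             strong_binder_fraction = 0.05),
                            prune_below = 0.06) {
  tnb_grouping <- match.arg(tnb_grouping)
  cfg <- as.list(environment())
  for (p in c(variants, expression, hla, clinical, proteins)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  stopifnot(inherits(thresholds, "filter_thresholds"),
            coding_region_mb > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

# Named predictor registry: resolve a specification to a predictor function.
.resolve_predictor <- function(spec) {
  if (is.function(spec)) return(spec)
  if (!is.list(spec) || is.null(spec$name)) {
    stop("predictor must be a function or a named registry entry")
  }
  switch(spec$name,
         mock = generate_mock_predictor(
           seed = if (is.null(spec$seed)) 1 else spec$seed,
           strong_binder_fraction =
             if (is.null(spec$strong_binder_fraction)) 0.05
             else spec$strong_binder_fraction),
         table = table_predictor(spec$path),
         stop("unknown predictor registry entry: ", spec$name))
}

#' Enumerate peptide-HLA candidates for screened variants
#'
#' Expands every protein context into its mutant peptide windows and
#' crosses them with the patient's (deduplicated) HLA class I alleles.
#'
#' @param contexts Protein contexts (see [read_protein_contexts()]) with a
#'   `sample_id` column.
#' @param hla HLA table (`sample_id`, `hla_allele`).
#' @param lengths Peptide lengths.
#' @return Candidate data frame for [screen_neoantigens()].
#' @export
build_candidates <- function(contexts, hla, lengths = 8:11) {
  hla <- unique(hla[, c("sample_id", "hla_allele")])
  hla_by_sample <- split(hla$hla_allele, hla$sample_id)
  out <- vector("list", nrow(contexts))
  for (i in seq_len(nrow(contexts))) {
    win <- enumerate_mutant_peptides(contexts$mutant_seq[i],
                                     c(contexts$span_start[i],
                                       contexts$span_end[i]),
                                     contexts$wildtype_seq[i], lengths)
    alleles <- hla_by_sample[[contexts$sample_id[i]]]
    if (nrow(win) == 0 || is.null(alleles)) next
    out[[i]] <- data.frame(sample_id = contexts$sample_id[i],
                           variant_id = contexts$variant_id[i],
                           transcript_id = contexts$transcript_id[i],
                           peptide = rep(win$peptide, length(alleles)),
                           wt_peptide = rep(win$wt_peptide, length(alleles)),
                           hla_allele = rep(alleles, each = nrow(win)),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(sample_id = character(0), variant_id = character(0),
                      transcript_id = character(0), peptide = character(0),
                      wt_peptide = character(0), hla_allele = character(0)))
  }
  do.call(rbind, out)
}

#' Run the full biomarker pipeline
#'
#' Stages: somatic filtering with per-criterion tally; per-patient TMB and
#' top-fraction TMB grouping; per-patient 96-context catalogs (and optional
#' signature exposure refits); neoantigen enumeration, screening and TNB;
#' TNB grouping (data-driven log-rank cutpoint by default); survival
#' stratification (Kaplan-Meier per group, log-rank tests, RMST differences
#' at the configured horizons, multivariate Cox fits adjusting for age, sex,
#' stage, N status, differentiation and chemotherapy); and the cohort
#' summary. All intermediate artifacts are written under `out_dir`; rerun
#' with identical config and inputs reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_result` with elements `biomarkers`
#'   (per-patient TMB/TNB and group labels), `filter_tally`, `catalogs`,
#'   `exposures`, `calls`, `survival` (log-rank, RMST, Cox, cutpoint), and
#'   `cohort_summary`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  ## stage: inputs
  st <- "read-inputs"
  inputs <- tryCatch({
    list(variants = read_variants(config$variants),
         expression = read_expression(config$expression),
         hla = read_hla_alleles(config$hla),
         clinical = read_clinical(config$clinical),
         contexts = read_protein_contexts(config$proteins))
  }, error = function(e) fail(st, e))
  clin <- inputs$clinical
  samples <- clin$sample_id
  say("read %d variants, %d patients", nrow(inputs$variants), length(samples))

  ## stage: somatic filtering
  st <- "somatic-filtering"
  filt <- tryCatch(apply_somatic_filters(inputs$variants, config$thresholds),
                   error = function(e) fail(st, e))
  say("filtering: %d in, %d pass, removed by criterion: %s",
      nrow(inputs$variants), nrow(filt$passing),
      paste(names(filt$tally), filt$tally, sep = "=", collapse = ", "))
  write_variants(filt$passing, file.path(config$out_dir,
                                         "variants_passing.tsv"))
  jsonlite::write_json(as.list(filt$tally),
                       file.path(config$out_dir, "filter_tally.json"),
                       auto_unbox = TRUE)

  ## stage: TMB
  st <- "tmb"
  tmb <- tryCatch({
    counts <- table(factor(filt$passing$sample_id, levels = samples))
    compute_tmb(as.numeric(counts), config$coding_region_mb)
  }, error = function(e) fail(st, e))
  tmb_cls <- tryCatch(classify_by_top_fraction(tmb, config$tmb_top_fraction),
                      error = function(e) fail(st, e))
  say("TMB: median %.2f mut/Mb, High cutoff %.2f (%d High)",
      stats::median(tmb), tmb_cls$cutoff, sum(tmb_cls$labels == "High"))

  ## stage: signatures
  st <- "signatures"
  sigres <- tryCatch({
    snvs <- filt$passing[filt$passing$variant_class == "SNV" &
                           !is.na(filt$passing$context_5p), , drop = FALSE]
    catalogs <- lapply(split(snvs, factor(snvs$sample_id, levels = samples)),
                       build_catalog)
    exposures <- NULL
    if (!is.null(config$signature_matrix)) {
      sigmat <- read_signature_matrix(config$signature_matrix)
      exposures <- lapply(catalogs, function(cat) {
        if (sum(cat) < 1) return(NULL)
        fit_signature_exposures(cat, sigmat, config$prune_below)
      })
    }
    list(catalogs = catalogs, exposures = exposures)
  }, error = function(e) fail(st, e))
  catmat <- do.call(cbind, lapply(sigres$catalogs, as.numeric))
  rownames(catmat) <- trinucleotide_contexts()
  write_signature_matrix(catmat,
                         file.path(config$out_dir, "catalogs.tsv"))

  ## stage: neoantigens
  st <- "neoantigen"
  neo <- tryCatch({
    keep <- inputs$contexts$variant_id %in% filt$passing$variant_id
    ctx <- inputs$contexts[keep, , drop = FALSE]
    ctx$sample_id <- filt$passing$sample_id[match(ctx$variant_id,
                                                  filt$passing$variant_id)]
    candidates <- build_candidates(ctx, inputs$hla, config$peptide_lengths)
    predictor <- .resolve_predictor(config$predictor)
    calls <- screen_neoantigens(candidates, predictor, inputs$expression,
                                config$binding_threshold_nm, config$min_tpm,
                                config$min_mutant_rna_reads)
    tnb_counts <- vapply(samples, function(s) {
      compute_tnb(calls[calls$sample_id == s, , drop = FALSE],
                  config$coding_region_mb, config$counting_unit)
    }, numeric(1))
    list(calls = calls, tnb = unname(tnb_counts),
         n_candidates = nrow(candidates))
  }, error = function(e) fail(st, e))
  say("neoantigens: %d candidates, %d calls, median TNB %.2f /Mb",
      neo$n_candidates, nrow(neo$calls), stats::median(neo$tnb))
  utils::write.table(neo$calls, file.path(config$out_dir,
                                          "neoantigen_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: survival + TNB grouping
  st <- "survival"
  surv_res <- tryCatch({
    records <- clin
    tnb_cut <- NULL
    if (config$tnb_grouping == "cutpoint") {
      tnb_cut <- search_survival_cutpoint(neo$tnb, records,
                                          config$min_group_fraction)
      tnb_labels <- ifelse(neo$tnb >= tnb_cut$cutoff, "High", "Low")
      tnb_cutoff <- tnb_cut$cutoff
    } else {
      cls <- classify_by_top_fraction(neo$tnb, config$tnb_top_fraction)
      tnb_labels <- cls$labels
      tnb_cutoff <- cls$cutoff
    }
    group_tests <- function(labels) {
      hi <- records[labels == "High", , drop = FALSE]
      lo <- records[labels == "Low", , drop = FALSE]
      if (nrow(hi) == 0 || nrow(lo) == 0) {
        # degenerate grouping (e.g. all tied at one value): no contrast
        return(list(logrank = list(chisq = NA_real_, p_value = NA_real_),
                    rmst = NULL, km_high = NULL, km_low = NULL))
      }
      lr <- logrank_test(hi, lo)
      rd <- lapply(config$tau_horizons, function(tau) {
        list(tau = tau, rmst_high = rmst(hi, tau), rmst_low = rmst(lo, tau),
             difference = rmst_difference(hi, lo, tau))
      })
      list(logrank = lr, rmst = rd,
           km_high = km_estimate(hi), km_low = km_estimate(lo))
    }
    adjusters <- c("age_group", "sex", "stage", "n_status",
                   "differentiation", "chemotherapy")
    adjusters <- adjusters[vapply(adjusters, function(a) {
      a %in% names(records) && length(unique(records[[a]])) > 1
    }, logical(1))]
    records$tmb_group <- tmb_cls$labels
    records$tnb_group <- tnb_labels
    cox <- list()
    for (bm in c("tmb_group", "tnb_group")) {
      if (length(unique(records[[bm]])) > 1) {
        cox[[bm]] <- cox_fit(records, c(bm, adjusters))
      }
    }
    list(tnb_labels = tnb_labels, tnb_cutoff = tnb_cutoff,
         tnb_cutpoint = tnb_cut,
         tmb = group_tests(tmb_cls$labels), tnb = group_tests(tnb_labels),
         cox = cox)
  }, error = function(e) fail(st, e))
  say("survival: TNB cutoff %.3g, log-rank p (TNB) = %.3g, p (TMB) = %.3g",
      surv_res$tnb_cutoff, surv_res$tnb$logrank$p_value,
      surv_res$tmb$logrank$p_value)
  if (!is.null(surv_res$tnb_cutpoint)) {
    utils::write.table(surv_res$tnb_cutpoint$scan,
                       file.path(config$out_dir, "tnb_cutpoint_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage: report
  st <- "report"
  biomarkers <- data.frame(sample_id = samples, tmb = tmb,
                           tmb_group = tmb_cls$labels, tnb = neo$tnb,
                           tnb_group = surv_res$tnb_labels,
                           stringsAsFactors = FALSE)
  utils::write.table(biomarkers, file.path(config$out_dir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_tab <- tryCatch(
    summarize_cohort(clin, c("age_group", "sex", "stage", "n_status",
                             "differentiation", "chemotherapy")),
    error = function(e) fail(st, e))
  utils::write.table(summary_tab, file.path(config$out_dir,
                                            "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    n_patients = length(samples),
    tmb_cutoff = tmb_cls$cutoff, tnb_cutoff = surv_res$tnb_cutoff,
    logrank = list(tmb = surv_res$tmb$logrank[c("chisq", "p_value")],
                   tnb = surv_res$tnb$logrank[c("chisq", "p_value")]),
    rmst = list(tmb = surv_res$tmb$rmst, tnb = surv_res$tnb$rmst),
    cox = lapply(surv_res$cox, function(f) f$table))
  jsonlite::write_json(report, file.path(config$out_dir,
                                         "survival_report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")

  structure(list(biomarkers = biomarkers, filter_tally = filt$tally,
                 catalogs = sigres$catalogs, exposures = sigres$exposures,
                 calls = neo$calls, survival = surv_res,
                 cohort_summary = summary_tab, report = report,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("neoburden pipeline: %d patients\n", nrow(x$biomarkers)))
  cat(sprintf("  TMB-High cutoff %.2f mut/Mb (%d High); TNB cutoff %.3g /Mb (%d High)\n",
              x$report$tmb_cutoff, sum(x$biomarkers$tmb_group == "High"),
              x$report$tnb_cutoff, sum(x$biomarkers$tnb_group == "High")))
  cat(sprintf("  log-rank p: TMB %.3g, TNB %.3g\n",
              x$report$logrank$tmb$p_value, x$report$logrank$tnb$p_value))
  invisible(x)
}

#' Cohort characteristics summary
#'
#' Frequency and percentage per level of each categorical variable, in the
#' layout of a clinical "Table 1". Percentages are 100 * count / n rounded
#' half-up to two decimals.
#'
#' @param clinical Clinical data frame.
#' @param variables Column names to summarize (default: every non-numeric
#'   column except identifiers).
#' @param level_order Optional named list giving the level order per
#'   variable; unlisted variables use first-appearance order.
#' @return Data frame with columns `variable`, `level`, `count`,
#'   `percent`.
#' @examples
#' clin <- data.frame(sex = rep(c("Male", "Female"), c(63, 22)))
#' summarize_cohort(clin, "sex")  # Male 74.12%, Female 25.88%
#' @export
summarize_cohort <- function(clinical, variables = NULL, level_order = NULL) {
  if (!is.data.frame(clinical) || nrow(clinical) == 0) {
    stop("clinical table must be non-empty")
  }
  if (is.null(variables)) {
    variables <- names(clinical)[!vapply(clinical, is.numeric, logical(1))]
    variables <- setdiff(variables, c("sample_id", "death_cause"))
  }
  n <- nrow(clinical)
  out <- lapply(variables, function(v) {
    if (!v %in% names(clinical)) stop("no such clinical variable: ", v)
    x <- as.character(clinical[[v]])
    levels <- if (!is.null(level_order) && v %in% names(level_order)) {
      level_order[[v]]
    } else unique(x[!is.na(x)])
    cnt <- vapply(levels, function(l) sum(x == l, na.rm = TRUE), integer(1))
    data.frame(variable = v, level = levels, count = cnt,
               percent = .round_half_up(100 * cnt / n, 2),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
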