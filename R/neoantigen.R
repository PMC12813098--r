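# Neoantigen enumeration, screening through a pluggable HLA-binding
# predictor, and tumor neoantigen burden (TNB).

#' Enumerate mutant peptide windows over a protein-changing variant
#'
#' Slides windows of each requested length along the mutant protein and
#' keeps every window overlapping the mutated residue span, truncating at
#' the protein termini. For substitutions (wild-type sequence of equal
#' length) the paired wild-type peptide is the same window on the wild-type
#' sequence; for frameshift/novel sequence (no length-matched wild type) the
#' wild-type peptide is `NA` and expression screening falls back to
#' transcript-level evidence.
#'
#' @param mutant_seq Mutant protein sequence (single string, 20-letter
#'   amino-acid alphabet).
#' @param span Integer vector `c(start, end)` of the mutated residue span on
#'   the mutant sequence, 1-based inclusive.
#' @param wildtype_seq Wild-type protein sequence, or `NA` when no paired
#'   wild type exists.
#' @param lengths Peptide lengths to enumerate (default 8-11, the HLA class
#'   I convention).
#' @return Data frame with columns `peptide`, `wt_peptide`, `start`,
#'   `length`. Windows identical to their wild-type counterpart (possible at
#'   span edges of multi-residue spans) are dropped.
#' @examples
#' # interior missense: L windows per length, 8+9+10+11 = 38 total
#' nrow(enumerate_mutant_peptides(strrep("A", 20), c(10, 10),
#'                                paste0(strrep("A", 9), "C", strrep("A", 10))))
#' @export
enumerate_mutant_peptides <- function(mutant_seq, span, wildtype_seq = NA,
                                      lengths = 8:11) {
  n <- nchar(mutant_seq)
  if (length(span) != 2 || span[1] < 1 || span[2] > n || span[1] > span[2]) {
    stop("mutated span must lie within the mutant sequence")
  }
  has_wt <- !is.na(wildtype_seq) && nchar(wildtype_seq) == n
  out <- list()
  for (L in sort(unique(lengths))) {
    if (L > n) next
    starts <- seq.int(max(1L, span[1] - L + 1L), min(span[2], n - L + 1L))
    if (length(starts) == 0 || starts[1] > min(span[2], n - L + 1L)) next
    pep <- substring(mutant_seq, starts, starts + L - 1L)
    wt <- if (has_wt) substring(wildtype_seq, starts, starts + L - 1L)
          else rep(NA_character_, length(starts))
    out[[length(out) + 1L]] <- data.frame(peptide = pep, wt_peptide = wt,
                                          start = starts, length = L,
                                          stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(peptide = character(0), wt_peptide = character(0),
               start = integer(0), length = integer(0))
  # a window equal to its wild-type pair carries no mutant residue
  keep <- is.na(res$wt_peptide) | res$peptide != res$wt_peptide
  res[keep, , drop = FALSE]
}

#' Screen neoantigen candidates
#'
#' Applies the two screening criteria to peptide-HLA candidates:
#' (1) binding — predicted affinity strictly below `binding_threshold_nm`;
#' (2) expression — the source transcript is expressed (`TPM >= min_tpm`)
#' and the mutant allele is seen in RNA
#' (`mutant_rna_reads >= min_mutant_rna_reads`). For candidates without a
#' paired wild-type peptide (frameshift/novel sequence) criterion (2) uses
#' transcript-level TPM only. Candidates whose transcript has no expression
#' row fail criterion (2). Binding is only evaluated for candidates passing
#' expression (a candidate failing expression can never become a call).
#'
#' @param candidates Data frame with columns `sample_id`, `variant_id`,
#'   `transcript_id`, `peptide`, `wt_peptide`, `hla_allele`.
#' @param predictor A binding predictor: function `(peptide, allele)`
#'   returning predicted affinity in nM (vectorized, deterministic). See
#'   [generate_mock_predictor()] and [table_predictor()].
#' @param expression Data frame with columns `transcript_id`, `tpm`,
#'   `mutant_rna_reads`.
#' @param binding_threshold_nm Affinity cutoff in nM (default 500, the
#'   conventional class I binder threshold).
#' @param min_tpm Minimum transcript expression (default 1 TPM).
#' @param min_mutant_rna_reads Minimum mutant-allele RNA read support
#'   (default 1).
#' @return Data frame of neoantigen calls (candidates passing both
#'   criteria) with `affinity_nm`, `binding_pass`, `expression_pass`
#'   columns; the attribute `n_evaluated` records the candidate count.
#' @export
screen_neoantigens <- function(candidates, predictor, expression,
                               binding_threshold_nm = 500,
                               min_tpm = 1.0, min_mutant_rna_reads = 1) {
  need <- c("sample_id", "variant_id", "transcript_id", "peptide",
            "wt_peptide", "hla_allele")
  if (!all(need %in% names(candidates))) {
    stop("candidates must carry columns: ", paste(need, collapse = ", "))
  }
  empty <- candidates[0, , drop = FALSE]
  empty$affinity_nm <- numeric(0)
  empty$binding_pass <- logical(0)
  empty$expression_pass <- logical(0)
  if (nrow(candidates) == 0) {
    attr(empty, "n_evaluated") <- 0L
    return(empty)
  }
  i <- match(candidates$transcript_id, expression$transcript_id)
  tpm <- expression$tpm[i]
  reads <- expression$mutant_rna_reads[i]
  has_wt <- !is.na(candidates$wt_peptide)
  expr_pass <- !is.na(tpm) & tpm >= min_tpm &
    (!has_wt | (!is.na(reads) & reads >= min_mutant_rna_reads))
  aff <- rep(NA_real_, nrow(candidates))
  n_failed <- 0L
  idx <- which(expr_pass)
  if (length(idx) > 0) {
    batch <- tryCatch(
      predictor(candidates$peptide[idx], candidates$hla_allele[idx]),
      error = function(e) NULL)
    if (is.null(batch)) {
      # retry one-by-one so a single bad candidate is excluded, not fatal
      batch <- vapply(idx, function(j) {
        tryCatch(predictor(candidates$peptide[j], candidates$hla_allele[j]),
                 error = function(e) NA_real_)
      }, numeric(1))
      n_failed <- sum(is.na(batch))
      if (n_failed > 0) {
        warning(sprintf("%d candidate(s) unevaluable by the predictor; excluded",
                        n_failed))
      }
    }
    aff[idx] <- batch
  }
  bind_pass <- !is.na(aff) & aff < binding_threshold_nm
  calls <- candidates[expr_pass & bind_pass, , drop = FALSE]
  if (nrow(calls) > 0) {
    calls$affinity_nm <- aff[expr_pass & bind_pass]
    calls$binding_pass <- TRUE
    calls$expression_pass <- TRUE
  } else {
    calls <- empty
  }
  attr(calls, "n_evaluated") <- nrow(candidates)
  attr(calls, "n_unevaluable") <- n_failed
  calls
}

#' Tumor neoantigen burden
#'
#' TNB is the number of screened neoantigens per megabase of the exonic
#' region. The counting unit is configurable: distinct mutant peptides
#' (default; identical peptides presented on several HLA alleles count
#' once), distinct source variants, or peptide-HLA pairs.
#'
#' @param calls Neoantigen calls from [screen_neoantigens()].
#' @param coding_region_mb Exonic region size in Mb.
#' @param counting_unit One of `"distinct_peptides"`, `"distinct_variants"`,
#'   `"peptide_hla_pairs"`.
#' @return TNB in neoantigens/Mb.
#' @export
compute_tnb <- function(calls, coding_region_mb,
                        counting_unit = c("distinct_peptides",
                                          "distinct_variants",
                                          "peptide_hla_pairs")) {
  counting_unit <- match.arg(counting_unit)
  if (!is.numeric(coding_region_mb) || coding_region_mb <= 0) {
    stop("coding_region_mb must be > 0")
  }
  n <- switch(counting_unit,
              distinct_peptides = length(unique(calls$peptide)),
              distinct_variants = length(unique(calls$variant_id)),
              peptide_hla_pairs = nrow(unique(calls[, c("peptide",
                                                        "hla_allele")])))
  n / coding_region_mb
}

#' Adapter for externally computed binding predictions
#'
#' Wraps a table of pre-computed predictions (e.g. exported from an external
#' affinity predictor) as a binding predictor function. Lookups are exact on
#' (peptide, allele); a missing pair is an error.
#'
#' @param predictions Data frame with columns `peptide`, `hla_allele`,
#'   `affinity_nm`, or a path to a TSV with those columns.
#' @return A vectorized predictor function `(peptide, allele) -> nM`.
#' @export
table_predictor <- function(predictions) {
  if (is.character(predictions)) {
    predictions <- utils::read.delim(predictions, sep = "\t",
                                     stringsAsFactors = FALSE)
  }
  need <- c("peptide", "hla_allele", "affinity_nm")
  if (!all(need %in% names(predictions))) {
    stop("prediction table must carry columns: ", paste(need, collapse = ", "))
  }
  key <- paste(predictions$peptide, predictions$hla_allele, sep = "\r")
  aff <- predictions$affinity_nm
  function(peptide, allele) {
    i <- match(paste(peptide, allele, sep = "\r"), key)
    if (any(is.na(i))) {
      stop("no prediction available for ", peptide[which(is.na(i))[1]],
           " / ", allele[which(is.na(i))[1]])
    }
    aff[i]
  }
}

#' Read / write protein context FASTA
#'
#' Paired wild-type and mutant protein sequences keyed by variant. Headers
#' follow `><variant_id>|<wt|mut>|<transcript_id>|<span_start>-<span_end>`
#' (the span is present on mutant entries only).
#'
#' @param path FASTA path.
#' @return `read_protein_contexts()` returns a data frame with columns
#'   `variant_id`, `transcript_id`, `wildtype_seq`, `mutant_seq`,
#'   `span_start`, `span_end`.
#' @export
read_protein_contexts <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !any(hdr)) {
    return(data.frame(variant_id = character(0), transcript_id = character(0),
                      wildtype_seq = character(0), mutant_seq = character(0),
                      span_start = integer(0), span_end = integer(0)))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  heads <- sub("^>", "", lines[hdr])
  parts <- strsplit(heads, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  kind <- vapply(parts, `[`, "", 2)
  tx <- vapply(parts, `[`, "", 3)
  span <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  mut <- kind == "mut"
  sp <- do.call(rbind, lapply(strsplit(span[mut], "-"), as.integer))
  out <- data.frame(variant_id = ids[mut], transcript_id = tx[mut],
                    mutant_seq = unname(seqs[mut]),
                    span_start = sp[, 1], span_end = sp[, 2],
                    stringsAsFactors = FALSE)
  wt_idx <- match(out$variant_id, ids[!mut])
  out$wildtype_seq <- unname(seqs[!mut][wt_idx])
  out[, c("variant_id", "transcript_id", "wildtype_seq", "mutant_seq",
          "span_start", "span_end")]
}

#' @rdname read_protein_contexts
#' @param contexts Data frame as returned by `read_protein_contexts()`.
#' @export
write_protein_contexts <- function(contexts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(contexts))) {
    if (!is.na(contexts$wildtype_seq[i])) {
      writeLines(c(sprintf(">%s|wt|%s", contexts$variant_id[i],
                           contexts$transcript_id[i]),
                   contexts$wildtype_seq[i]), con)
    }
    writeLines(c(sprintf(">%s|mut|%s|%d-%d", contexts$variant_id[i],
                         contexts$transcript_id[i], contexts$span_start[i],
                         contexts$span_end[i]),
                 contexts$mutant_seq[i]), con)
  }
  invisible(path)
}

#' Read per-sample HLA class I alleles
#'
#' TSV with columns `sample_id`, `hla_allele` (standard nomenclature, e.g.
#' `HLA-A*02:01`). Duplicate alleles within a sample (homozygosity) are
#' deduplicated.
#'
#' @param path File path.
#' @return Data frame `sample_id`, `hla_allele`, one row per distinct
#'   allele per sample.
#' @export
read_hla_alleles <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "hla_allele") %in% names(d))) {
    stop("HLA table must carry sample_id and hla_allele columns")
  }
  unique(d[, c("sample_id", "hla_allele")])
}

#' Read per-transcript expression evidence
#'
#' TSV with columns `transcript_id`, `tpm`, `mutant_rna_reads`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "tpm", "mutant_rna_reads")
  if (!all(need %in% names(d))) {
    stop("expression table must carry columns: ", paste(need, collapse = ", "))
  }
  if (any(d$tpm < 0) || any(d$mutant_rna_reads < 0)) {
    stop("tpm and mutant_rna_reads must be >= 0")
  }
  d
}
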