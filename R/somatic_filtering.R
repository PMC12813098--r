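# Somatic-variant quality filtering, tumor mutational burden (TMB), and
# copy-number segment classification.

#' Somatic filter thresholds
#'
#' Bundle of the five quality criteria applied to high-confidence somatic
#' calls before burden calculation. Defaults follow common panel/exome
#' practice: at least 4 supporting reads, variant allele fraction of at
#' least 2%, mapping quality strictly above 30, base quality strictly above
#' 25, mutated base at least 8 bp (one barcode length) from the nearer read
#' end, and population minor-allele frequency below 1% in ExAC/gnomAD.
#'
#' @param min_alt_reads Minimum alt-supporting read count (inclusive).
#' @param min_allele_fraction Minimum variant allele fraction (inclusive).
#' @param min_mapping_quality Exclusive lower bound on mapping quality:
#'   variants with MQ less than or equal to this value are removed.
#' @param min_base_quality Exclusive lower bound on the mutated base quality.
#' @param min_end_distance_bp Distance threshold (bp) between the mutated
#'   base and the nearer end of a supporting read.
#' @param max_population_af Exclusive upper bound on the population allele
#'   frequency (maximum over available databases; missing values count as 0).
#' @param end_distance_rule `"exclude_proximal"` (default) keeps variants
#'   with `min_end_distance >= min_end_distance_bp`, removing likely
#'   end-of-read artifacts; `"require_proximal"` applies the opposite,
#'   literal reading (keep only `min_end_distance < min_end_distance_bp`).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_alt_reads = 4,
                              min_allele_fraction = 0.02,
                              min_mapping_quality = 30,
                              min_base_quality = 25,
                              min_end_distance_bp = 8,
                              max_population_af = 0.01,
                              end_distance_rule = c("exclude_proximal",
                                                    "require_proximal")) {
  end_distance_rule <- match.arg(end_distance_rule)
  th <- list(min_alt_reads = min_alt_reads,
             min_allele_fraction = min_allele_fraction,
             min_mapping_quality = min_mapping_quality,
             min_base_quality = min_base_quality,
             min_end_distance_bp = min_end_distance_bp,
             max_population_af = max_population_af,
             end_distance_rule = end_distance_rule)
  nums <- th[1:6]
  if (any(!vapply(nums, is.numeric, logical(1))) ||
      any(unlist(nums) < 0) || th$min_allele_fraction > 1) {
    stop("filter thresholds must be non-negative (allele fraction in [0,1])")
  }
  class(th) <- "filter_thresholds"
  th
}

# Fixed criterion order used for first-failure attribution.
.filter_criteria <- c("read-support", "allele-fraction", "mapping-quality",
                      "base-quality", "end-distance", "population-af")

.required_variant_columns <- c("sample_id", "chrom", "pos", "ref", "alt",
                               "variant_class", "gene", "protein_change",
                               "alt_read_count", "allele_fraction",
                               "mapping_quality", "base_quality",
                               "min_end_distance", "pop_af_exac",
                               "pop_af_gnomad")

.check_variant_table <- function(variants) {
  missing_cols <- setdiff(setdiff(.required_variant_columns,
                                  c("protein_change", "gene")),
                          names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) {
      stop(sprintf("malformed variant record (row %d): %s", i[1], what))
    }
  }
  bad(!is.finite(variants$pos) | variants$pos < 1, "pos must be >= 1")
  bad(!is.finite(variants$allele_fraction) |
        variants$allele_fraction < 0 | variants$allele_fraction > 1,
      "allele_fraction must lie in [0, 1]")
  bad(!is.finite(variants$alt_read_count) | variants$alt_read_count < 0,
      "alt_read_count must be >= 0")
  bad(variants$ref == variants$alt, "ref and alt must differ")
  invisible(TRUE)
}

#' Apply the somatic-variant filter criteria
#'
#' Evaluates each variant against the five quality criteria in fixed order
#' (read support, allele fraction, mapping quality, base quality, read-end
#' distance, population allele frequency) and removes any variant failing at
#' least one. For removed variants the *first* failing criterion is tallied,
#' so the tally attributes each removal to exactly one rule.
#'
#' A variant passes iff `alt_read_count >= min_alt_reads`,
#' `allele_fraction >= min_allele_fraction`,
#' `mapping_quality > min_mapping_quality`,
#' `base_quality > min_base_quality`, the end-distance rule holds
#' (by default `min_end_distance >= min_end_distance_bp`), and
#' `max(pop_af_exac, pop_af_gnomad)` (missing treated as 0, i.e. rare)
#' `< max_population_af`.
#'
#' @param variants Data frame of somatic calls with the MAF-like columns
#'   described in [read_variants()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `passing` (the surviving rows, input order
#'   preserved), `tally` (named integer vector, one entry per criterion),
#'   and `removed` (removed rows with a `failed_criterion` column).
#' @export
apply_somatic_filters <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!is.data.frame(variants)) stop("variants must be a data frame")
  tally <- stats::setNames(integer(length(.filter_criteria)), .filter_criteria)
  if (nrow(variants) == 0) {
    return(list(passing = variants, tally = tally,
                removed = cbind(variants, failed_criterion = character(0))))
  }
  .check_variant_table(variants)

  pop_af <- pmax(ifelse(is.na(variants$pop_af_exac), 0, variants$pop_af_exac),
                 ifelse(is.na(variants$pop_af_gnomad), 0,
                        variants$pop_af_gnomad))
  end_ok <- if (thresholds$end_distance_rule == "exclude_proximal") {
    variants$min_end_distance >= thresholds$min_end_distance_bp
  } else {
    variants$min_end_distance < thresholds$min_end_distance_bp
  }
  ok <- cbind(`read-support` = variants$alt_read_count >= thresholds$min_alt_reads,
              `allele-fraction` = variants$allele_fraction >= thresholds$min_allele_fraction,
              `mapping-quality` = variants$mapping_quality > thresholds$min_mapping_quality,
              `base-quality` = variants$base_quality > thresholds$min_base_quality,
              `end-distance` = end_ok,
              `population-af` = pop_af < thresholds$max_population_af)
  pass <- rowSums(ok) == ncol(ok)
  first_fail <- apply(!ok[!pass, , drop = FALSE], 1,
                      function(r) .filter_criteria[which(r)[1]])
  if (length(first_fail) > 0) {
    tb <- table(factor(first_fail, levels = .filter_criteria))
    tally[] <- as.integer(tb)
  }
  removed <- variants[!pass, , drop = FALSE]
  if (nrow(removed) > 0) removed$failed_criterion <- unname(first_fail)
  else removed$failed_criterion <- character(0)
  list(passing = variants[pass, , drop = FALSE], tally = tally,
       removed = removed)
}

#' Tumor mutational burden
#'
#' TMB is the number of filtered somatic variants per megabase of the coding
#' region.
#'
#' @param passing_variant_count Number of variants surviving the filters.
#' @param coding_region_mb Size of the interrogated coding region in Mb.
#' @return TMB in mutations/Mb.
#' @examples
#' compute_tmb(408, 34)  # 12 mut/Mb
#' @export
compute_tmb <- function(passing_variant_count, coding_region_mb) {
  if (!is.numeric(coding_region_mb) || coding_region_mb <= 0) {
    stop("coding_region_mb must be > 0")
  }
  if (any(passing_variant_count < 0)) stop("variant count must be >= 0")
  passing_variant_count / coding_region_mb
}

#' Classify patients by the top fraction of a biomarker
#'
#' Labels the `floor(fraction * n)` largest values "High" and the rest
#' "Low". The realized cutoff is the smallest High value; values tied with
#' the cutoff are all labelled High, so the High group can exceed
#' `floor(fraction * n)` only through ties (the labelling is therefore
#' deterministic and invariant to input order).
#'
#' @param values Numeric vector of per-patient scores.
#' @param fraction Fraction (0, 1) defining the High group.
#' @return List with `labels` (character, "High"/"Low", same order as
#'   `values`) and `cutoff` (realized cutoff; `NA` if the High group is
#'   empty).
#' @examples
#' classify_by_top_fraction(seq_len(85), 0.30)$labels  # 25 High
#' @export
classify_by_top_fraction <- function(values, fraction) {
  if (length(values) == 0) stop("values must be non-empty")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  k <- floor(fraction * n)
  if (k == 0) {
    return(list(labels = rep("Low", n), cutoff = NA_real_))
  }
  cutoff <- sort(values, decreasing = TRUE)[k]
  labels <- ifelse(values >= cutoff, "High", "Low")
  list(labels = labels, cutoff = cutoff)
}

#' Classify a copy-number segment from its copy ratio
#'
#' Segments with tumor/normal copy ratio strictly greater than 2 are gains,
#' strictly less than 0.5 losses, and neutral otherwise (the boundaries are
#' neutral).
#'
#' @param copy_ratio Numeric vector of fold changes (>= 0).
#' @return Character vector: `"gain"`, `"loss"`, or `"neutral"`.
#' @export
classify_cnv_segment <- function(copy_ratio) {
  if (any(!is.finite(copy_ratio)) || any(copy_ratio < 0)) {
    stop("copy_ratio must be finite and >= 0")
  }
  ifelse(copy_ratio > 2, "gain", ifelse(copy_ratio < 0.5, "loss", "neutral"))
}

#' Read / write a MAF-like somatic variant table
#'
#' Tab-separated with a header row; positions are 1-based inclusive.
#' Required columns: sample_id, chrom, pos, ref, alt, variant_class, gene,
#' protein_change, alt_read_count, allele_fraction, mapping_quality,
#' base_quality, min_end_distance, pop_af_exac, pop_af_gnomad. Extra columns
#' (e.g. variant_id, transcript_id, flanking context bases) pass through.
#'
#' @param path File path.
#' @return `read_variants()` returns a data frame.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (nrow(v) > 0) .check_variant_table(v)
  v
}

#' @rdname read_variants
#' @param variants Data frame to write.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
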