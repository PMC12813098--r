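# Independent oracles and fixture builders shared across the suite. These
# deliberately use naive loops / brute force, not the package's code paths.

# Two-group log-rank by direct risk-set tabulation (O - E over distinct
# event times, hypergeometric variance).
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 2), c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# Efron-corrected Cox log partial likelihood for a single covariate,
# written directly from the definition.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    tied <- which(time == t & event == 1)
    d <- length(tied)
    risk <- which(time >= t)
    sum_risk <- sum(exp(beta * x[risk]))
    sum_tied <- sum(exp(beta * x[tied]))
    ll <- ll + beta * sum(x[tied])
    for (j in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (j / d) * sum_tied)
    }
  }
  ll
}

# Exhaustive window enumeration: all substrings of length L overlapping
# the span [s1, s2].
brute_windows <- function(mutant_seq, span, L) {
  n <- nchar(mutant_seq)
  out <- character(0)
  for (s in seq_len(max(n - L + 1, 0))) {
    e <- s + L - 1
    if (s <= span[2] && e >= span[1]) {
      out <- c(out, substr(mutant_seq, s, e))
    }
  }
  out
}

# Brute-force recheck of all filter predicates on one variant row.
filter_oracle_pass <- function(row, th) {
  pop <- max(c(row$pop_af_exac, row$pop_af_gnomad, 0), na.rm = TRUE)
  end_ok <- if (th$end_distance_rule == "exclude_proximal") {
    row$min_end_distance >= th$min_end_distance_bp
  } else {
    row$min_end_distance < th$min_end_distance_bp
  }
  row$alt_read_count >= th$min_alt_reads &&
    row$allele_fraction >= th$min_allele_fraction &&
    row$mapping_quality > th$min_mapping_quality &&
    row$base_quality > th$min_base_quality &&
    end_ok &&
    pop < th$max_population_af
}

# A clean variant row with every field comfortably passing the defaults.
clean_variant <- function(sample_id = "S1", id = "V1") {
  data.frame(sample_id = sample_id, chrom = "chr1", pos = 1000, ref = "C",
             alt = "T", variant_class = "SNV", gene = "G1",
             protein_change = NA_character_, alt_read_count = 20,
             allele_fraction = 0.3, mapping_quality = 55, base_quality = 35,
             min_end_distance = 25, pop_af_exac = 0.0001,
             pop_af_gnomad = NA_real_, variant_id = id,
             stringsAsFactors = FALSE)
}

# Seven-variant fixture: one clean plus six variants violating exactly one
# criterion each (all other fields passing).
fixture_seven_variants <- function() {
  v <- do.call(rbind, lapply(1:7, function(i) clean_variant(id = paste0("V", i))))
  v$alt_read_count[2] <- 3        # read support below 4
  v$allele_fraction[3] <- 0.01    # allele fraction below 2%
  v$mapping_quality[4] <- 30      # mapping quality <= 30
  v$base_quality[5] <- 25         # base quality <= 25
  v$min_end_distance[6] <- 7      # end-proximal
  v$pop_af_gnomad[7] <- 0.02      # common in gnomAD
  v
}

# Two well-separated synthetic signatures (96-vectors summing to 1).
test_signatures <- function(k = 2) {
  ctx <- neoburden::trinucleotide_contexts()
  sigs <- sapply(seq_len(k), function(j) {
    w <- rep(0.1, 96)
    peak <- seq((j - 1) * floor(96 / k) + 1, j * floor(96 / k))
    w[peak] <- 5
    w / sum(w)
  })
  rownames(sigs) <- ctx
  colnames(sigs) <- paste0("SigTest", seq_len(k))
  sigs
}

random_peptides <- function(n, len = 9) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
}

# Random SNV table with explicit flanking context columns.
random_snvs <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1), "",
                USE.NAMES = FALSE)
  data.frame(sample_id = "S1", chrom = "chr1", pos = seq_len(n), ref = ref,
             alt = alt, context_5p = sample(b, n, replace = TRUE),
             context_3p = sample(b, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, ""))
}
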