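test_that("each filter criterion removes exactly its violating variant", {
  v <- fixture_seven_variants()
  res <- apply_somatic_filters(v, filter_thresholds())
  expect_equal(nrow(res$passing), 1)
  expect_equal(res$passing$variant_id, "V1")
  expect_equal(unname(res$tally),
               rep(1L, 6))
  expect_setequal(res$removed$failed_criterion,
                  c("read-support", "allele-fraction", "mapping-quality",
                    "base-quality", "end-distance", "population-af"))
})

test_that("threshold boundaries follow the stated inclusivity", {
  th <- filter_thresholds()
  at <- function(field, value) {
    v <- clean_variant()
    v[[field]] <- value
    nrow(apply_somatic_filters(v, th)$passing) == 1
  }
  expect_true(at("allele_fraction", 0.02))    # "at least 2%" is inclusive
  expect_false(at("allele_fraction", 0.0199))
  expect_true(at("alt_read_count", 4))        # at least 4 supporting reads
  expect_false(at("alt_read_count", 3))
  expect_false(at("mapping_quality", 30))     # MQ <= 30 excluded
  expect_true(at("mapping_quality", 30.01))
  expect_false(at("base_quality", 25))        # BQ <= 25 excluded
  expect_true(at("base_quality", 25.01))
  expect_true(at("min_end_distance", 8))      # 8 bp from read end passes
  expect_false(at("min_end_distance", 7))
  expect_false(at("pop_af_exac", 0.01))       # must be < 0.01
  expect_true(at("pop_af_exac", 0.0099))
})

test_that("population AF uses the maximum of available databases", {
  th <- filter_thresholds()
  v <- clean_variant()
  v$pop_af_exac <- NA
  v$pop_af_gnomad <- NA    # both missing: treated as rare, passes
  expect_equal(nrow(apply_somatic_filters(v, th)$passing), 1)
  v$pop_af_gnomad <- 0.05  # one common database is enough to remove
  expect_equal(nrow(apply_somatic_filters(v, th)$passing), 0)
})

test_that("the require_proximal switch inverts the end-distance rule", {
  th <- filter_thresholds(end_distance_rule = "require_proximal")
  v <- clean_variant()
  v$min_end_distance <- 3
  expect_equal(nrow(apply_somatic_filters(v, th)$passing), 1)
  v$min_end_distance <- 8
  expect_equal(nrow(apply_somatic_filters(v, th)$passing), 0)
})

test_that("filtering matches a brute-force predicate recheck and is idempotent", {
  set.seed(42)
  th <- filter_thresholds()
  for (rep in 1:5) {
    n <- 60
    v <- do.call(rbind, lapply(seq_len(n), function(i) clean_variant(id = paste0("V", i))))
    # scatter values across both sides of every boundary
    v$alt_read_count <- sample(0:10, n, replace = TRUE)
    v$allele_fraction <- round(runif(n, 0, 0.08), 3)
    v$mapping_quality <- round(runif(n, 20, 45), 1)
    v$base_quality <- round(runif(n, 15, 35), 1)
    v$min_end_distance <- sample(0:20, n, replace = TRUE)
    v$pop_af_exac <- ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.03), 4))
    v$pop_af_gnomad <- ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.03), 4))
    res <- apply_somatic_filters(v, th)
    oracle <- vapply(seq_len(n), function(i) {
      filter_oracle_pass(v[i, , drop = FALSE], th)
    }, logical(1))
    expect_equal(res$passing$variant_id, v$variant_id[oracle])
    expect_equal(sum(res$tally), n - sum(oracle))
    # idempotence: refiltering the passing set removes nothing
    again <- apply_somatic_filters(res$passing, th)
    expect_equal(again$passing, res$passing)
    expect_equal(sum(again$tally), 0)
  }
})

test_that("tightening any single threshold never increases the passing count", {
  set.seed(7)
  n <- 80
  v <- do.call(rbind, lapply(seq_len(n), function(i) clean_variant(id = paste0("V", i))))
  v$alt_read_count <- sample(0:10, n, replace = TRUE)
  v$allele_fraction <- round(runif(n, 0, 0.08), 3)
  v$mapping_quality <- round(runif(n, 20, 45), 1)
  v$base_quality <- round(runif(n, 15, 35), 1)
  v$min_end_distance <- sample(0:20, n, replace = TRUE)
  base_n <- nrow(apply_somatic_filters(v, filter_thresholds())$passing)
  tighter <- list(filter_thresholds(min_alt_reads = 6),
                  filter_thresholds(min_allele_fraction = 0.04),
                  filter_thresholds(min_mapping_quality = 35),
                  filter_thresholds(min_base_quality = 28),
                  filter_thresholds(min_end_distance_bp = 12),
                  filter_thresholds(max_population_af = 0.001))
  for (th in tighter) {
    expect_lte(nrow(apply_somatic_filters(v, th)$passing), base_n)
  }
})

test_that("TMB is passing count per megabase", {
  expect_equal(compute_tmb(0, 34), 0)
  expect_equal(compute_tmb(170, 34), 5)
  expect_equal(compute_tmb(408, 34), 12)  # the TMB-High cutoff in mut/Mb
  expect_error(compute_tmb(10, 0), "coding_region_mb")
})

test_that("top-fraction classification sizes, ties, and order invariance", {
  set.seed(11)
  vals <- sample(seq_len(85))
  cls <- classify_by_top_fraction(vals, 0.30)
  expect_equal(sum(cls$labels == "High"), 25)  # floor(0.30 * 85)
  expect_equal(sum(cls$labels == "Low"), 60)
  expect_equal(cls$cutoff, sort(vals, decreasing = TRUE)[25])

  expect_equal(sum(classify_by_top_fraction(1:10, 0.30)$labels == "High"), 3)

  all_tied <- classify_by_top_fraction(rep(4.2, 12), 0.30)
  expect_true(all(all_tied$labels == "High"))

  # label of each element does not depend on input order
  perm <- sample(length(vals))
  cls_perm <- classify_by_top_fraction(vals[perm], 0.30)
  expect_equal(cls_perm$labels, cls$labels[perm])

  expect_error(classify_by_top_fraction(numeric(0), 0.3), "non-empty")
})

test_that("CNV calls use strict fold-change bounds", {
  expect_equal(classify_cnv_segment(c(2.5, 0.4, 2.0, 0.5, 1.0)),
               c("gain", "loss", "neutral", "neutral", "neutral"))
  expect_error(classify_cnv_segment(-1), "copy_ratio")
})

test_that("variant tables round-trip through TSV", {
  v <- fixture_seven_variants()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, path)
  v2 <- read_variants(path)
  expect_equal(v2$variant_id, v$variant_id)
  expect_equal(v2$allele_fraction, v$allele_fraction)
  expect_true(is.na(v2$pop_af_gnomad[1]))
})
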