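make_context <- function(len = 30, pos = 15) {
  wt <- paste(rep("A", len), collapse = "")
  mut <- wt
  substr(mut, pos, pos) <- "C"
  list(wt = wt, mut = mut, span = c(pos, pos))
}

test_that("window counts for a missense variant follow sliding-window combinatorics", {
  cx <- make_context(len = 40, pos = 20)  # interior: >= L from both termini
  expect_equal(nrow(enumerate_mutant_peptides(cx$mut, cx$span, cx$wt, 9)), 9)
  expect_equal(nrow(enumerate_mutant_peptides(cx$mut, cx$span, cx$wt, 8:11)),
               8 + 9 + 10 + 11)

  # N-terminal truncation: mutation at position 3 leaves 3 nine-mers
  cx3 <- make_context(len = 40, pos = 3)
  expect_equal(nrow(enumerate_mutant_peptides(cx3$mut, cx3$span, cx3$wt, 9)), 3)
})

test_that("enumeration equals brute-force window enumeration and spans overlap", {
  set.seed(99)
  for (rep in 1:10) {
    len <- sample(12:60, 1)
    pos <- sample(seq_len(len), 1)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    wt <- paste(sample(aa, len, replace = TRUE), collapse = "")
    mut <- wt
    old <- substr(wt, pos, pos)
    substr(mut, pos, pos) <- sample(setdiff(aa, old), 1)
    for (L in c(8, 11)) {
      got <- enumerate_mutant_peptides(mut, c(pos, pos), wt, L)
      expect_setequal(got$peptide, brute_windows(mut, c(pos, pos), L))
      # every returned window carries the mutated residue
      expect_true(all(got$start <= pos & got$start + got$length - 1 >= pos))
      expect_true(all(got$peptide != got$wt_peptide))
    }
  }
  expect_error(enumerate_mutant_peptides("ACDEF", c(9, 9), "ACDEF"), "span")
})

test_that("screening applies the binding and expression criteria independently", {
  expr <- data.frame(transcript_id = c("T1", "T2", "T3"),
                     tpm = c(10, 10, 0.2), mutant_rna_reads = c(5, 0, 5))
  cand <- data.frame(sample_id = "S1", variant_id = paste0("V", 1:4),
                     transcript_id = c("T1", "T1", "T2", "T3"),
                     peptide = c("ACDEFGHIK", "ACDEFGHIW", "CDEFGHIKL",
                                 "DEFGHIKLM"),
                     wt_peptide = "ACDEFGHIA", hla_allele = "HLA-A*02:01",
                     stringsAsFactors = FALSE)
  aff <- c("ACDEFGHIK" = 100, "ACDEFGHIW" = 5000, "CDEFGHIKL" = 100,
           "DEFGHIKLM" = 100)
  predictor <- function(p, a) unname(aff[p])
  calls <- screen_neoantigens(cand, predictor, expr)
  # V1 passes; V2 fails binding; V3 fails mutant RNA support; V4 fails TPM
  expect_equal(calls$variant_id, "V1")
  expect_equal(calls$affinity_nm, 100)
  expect_true(all(calls$binding_pass & calls$expression_pass))
  expect_equal(attr(calls, "n_evaluated"), 4L)
})

test_that("frameshift candidates without wild-type pairs use TPM-only evidence", {
  expr <- data.frame(transcript_id = "T1", tpm = 10, mutant_rna_reads = 0)
  cand <- data.frame(sample_id = "S1", variant_id = "V1",
                     transcript_id = "T1", peptide = "ACDEFGHIK",
                     wt_peptide = NA_character_, hla_allele = "A",
                     stringsAsFactors = FALSE)
  calls <- screen_neoantigens(cand, function(p, a) 100, expr)
  expect_equal(nrow(calls), 1)  # no mutant-read requirement without a wt pair
  # but a missing expression row still fails criterion (2)
  cand$transcript_id <- "T9"
  expect_equal(nrow(screen_neoantigens(cand, function(p, a) 100, expr)), 0)
})

test_that("relaxing screening thresholds never loses calls", {
  set.seed(55)
  expr <- data.frame(transcript_id = paste0("T", 1:30),
                     tpm = round(rlnorm(30, 0.5, 1), 2),
                     mutant_rna_reads = rpois(30, 2))
  cand <- data.frame(sample_id = "S1", variant_id = paste0("V", 1:120),
                     transcript_id = sample(paste0("T", 1:30), 120, TRUE),
                     peptide = random_peptides(120),
                     wt_peptide = random_peptides(120),
                     hla_allele = sample(c("A1", "A2"), 120, TRUE),
                     stringsAsFactors = FALSE)
  predictor <- generate_mock_predictor(1, 0.3)
  n_calls <- function(thr, tpm) {
    nrow(screen_neoantigens(cand, predictor, expr, binding_threshold_nm = thr,
                            min_tpm = tpm))
  }
  base <- n_calls(500, 1)
  expect_gte(n_calls(5000, 1), base)   # higher affinity cutoff
  expect_gte(n_calls(500, 0.1), base)  # lower expression cutoff
})

test_that("predictor failures exclude only the affected candidates", {
  expr <- data.frame(transcript_id = "T1", tpm = 10, mutant_rna_reads = 5)
  cand <- data.frame(sample_id = "S1", variant_id = c("V1", "V2"),
                     transcript_id = "T1",
                     peptide = c("ACDEFGHIK", "ACDEFGHIX"),
                     wt_peptide = c("ACDEFGHIA", "ACDEFGHIA"),
                     hla_allele = "A", stringsAsFactors = FALSE)
  predictor <- function(p, a) {
    if (any(grepl("X", p))) stop("invalid residue")
    rep(100, length(p))
  }
  expect_warning(calls <- screen_neoantigens(cand, predictor, expr),
                 "unevaluable")
  expect_equal(calls$variant_id, "V1")
  expect_equal(attr(calls, "n_unevaluable"), 1L)
})

test_that("TNB counting units are consistent and per-megabase", {
  calls <- data.frame(sample_id = "S1",
                      variant_id = c("V1", "V1", "V2"),
                      peptide = c("PEPTIDEA", "PEPTIDEA", "PEPTIDEB"),
                      hla_allele = c("A1", "A2", "A1"),
                      stringsAsFactors = FALSE)
  expect_equal(compute_tnb(calls, 34, "distinct_peptides"), 2 / 34)
  expect_equal(compute_tnb(calls, 34, "distinct_variants"), 2 / 34)
  expect_equal(compute_tnb(calls, 34, "peptide_hla_pairs"), 3 / 34)
  expect_equal(compute_tnb(calls[0, ], 34), 0)
  # 204 distinct passing peptides over 34 Mb sit exactly at 6 neoantigens/Mb
  many <- data.frame(sample_id = "S1", variant_id = paste0("V", 1:204),
                     peptide = replicate(204, paste0("P", seq_len(204)))[, 1],
                     hla_allele = "A1")
  expect_equal(compute_tnb(many, 34), 6)
  expect_error(compute_tnb(calls, 0), "coding_region_mb")
})

test_that("unit ordering distinct_variants <= distinct_peptides <= pairs holds", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 50
    calls <- data.frame(sample_id = "S1",
                        variant_id = sample(paste0("V", 1:10), n, TRUE),
                        peptide = sample(random_peptides(15), n, TRUE),
                        hla_allele = sample(c("A1", "A2", "B1"), n, TRUE))
    # tie peptides to variants so variant count <= peptide count
    calls$peptide <- paste0(calls$variant_id, "_", calls$peptide)
    a <- compute_tnb(calls, 1, "distinct_variants")
    b <- compute_tnb(calls, 1, "distinct_peptides")
    c <- compute_tnb(calls, 1, "peptide_hla_pairs")
    expect_lte(a, b)
    expect_lte(b, c)
  }
})

test_that("protein contexts round-trip through paired FASTA", {
  cx <- data.frame(variant_id = c("V1", "V2"), transcript_id = c("T1", "T2"),
                   wildtype_seq = c("ACDEFGHIKLMNP", NA),
                   mutant_seq = c("ACDEFWHIKLMNP", "MNPQRSTVWY"),
                   span_start = c(6L, 1L), span_end = c(6L, 10L),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_contexts(cx, path)
  back <- read_protein_contexts(path)
  expect_equal(back$variant_id, cx$variant_id)
  expect_equal(back$mutant_seq, cx$mutant_seq)
  expect_equal(back$wildtype_seq, cx$wildtype_seq)
  expect_equal(back$span_start, cx$span_start)
})
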