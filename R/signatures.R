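# 96-trinucleotide-context mutation catalogs and non-negative signature
# refitting.

.bases <- c("A", "C", "G", "T")
.substitutions <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context labels
#'
#' Fixed lexicographic order (COSMIC v2 convention): substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each over
#' A, C, G, T. Labels look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
trinucleotide_contexts <- function() {
  unlist(lapply(.substitutions, function(s) {
    as.vector(t(outer(.bases, .bases, function(f, t) {
      paste0(f, "[", s, "]", t)
    })))
  }))
}

.revcomp_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

#' Build a 96-context mutation catalog from SNVs
#'
#' Each single-nucleotide variant is assigned to one of 96 bins defined by
#' the substitution subtype and the flanking 5'/3' reference bases.
#' Substitutions from a purine reference (A or G) are reverse-complemented
#' (reference, alternate and both flanks) so that every bin is
#' pyrimidine-centered; the catalog is therefore strand-collapsed. SNVs
#' containing an ambiguous base (N) in the allele or context are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param snvs Data frame with single-base `ref` and `alt` columns and
#'   `chrom`, `pos` identifying each variant.
#' @param context_provider Function `(chrom, pos)` returning a data frame
#'   with columns `five_prime` and `three_prime` giving the flanking
#'   reference bases for each (vectorized) query. Alternatively, if `snvs`
#'   already carries `context_5p` / `context_3p` columns, pass `NULL`.
#' @return Named integer vector of length 96 (class `trinucleotide_catalog`)
#'   in the order of [trinucleotide_contexts()], with attribute `n_skipped`.
#' @export
build_catalog <- function(snvs, context_provider = NULL) {
  ctx <- trinucleotide_contexts()
  counts <- stats::setNames(integer(96), ctx)
  n_skipped <- 0L
  if (!is.null(snvs) && nrow(snvs) > 0) {
    if (any(nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1)) {
      stop("build_catalog expects SNVs only (single-base ref and alt)")
    }
    if (is.null(context_provider)) {
      if (!all(c("context_5p", "context_3p") %in% names(snvs))) {
        stop("no context_provider given and no context_5p/context_3p columns")
      }
      fl <- data.frame(five_prime = snvs$context_5p,
                       three_prime = snvs$context_3p)
    } else {
      fl <- context_provider(snvs$chrom, snvs$pos)
      if (!all(c("five_prime", "three_prime") %in% names(fl)) ||
          nrow(fl) != nrow(snvs)) {
        stop("context_provider must return five_prime/three_prime for every SNV")
      }
    }
    if (any(is.na(fl$five_prime) | is.na(fl$three_prime))) {
      stop("missing flanking context for one or more SNVs")
    }
    ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
    p5 <- toupper(fl$five_prime); p3 <- toupper(fl$three_prime)
    valid <- ref %in% .bases & alt %in% .bases & p5 %in% .bases & p3 %in% .bases
    n_skipped <- sum(!valid)
    if (n_skipped > 0) {
      warning(sprintf("%d SNV(s) with ambiguous bases skipped", n_skipped))
    }
    ref <- ref[valid]; alt <- alt[valid]; p5 <- p5[valid]; p3 <- p3[valid]
    # collapse purine-reference calls onto the pyrimidine strand
    flip <- ref %in% c("A", "G")
    r <- ifelse(flip, .revcomp_base(ref), ref)
    a <- ifelse(flip, .revcomp_base(alt), alt)
    f5 <- ifelse(flip, .revcomp_base(p3), p5)
    f3 <- ifelse(flip, .revcomp_base(p5), p3)
    lab <- paste0(f5, "[", r, ">", a, "]", f3)
    tb <- table(factor(lab, levels = ctx))
    counts[] <- as.integer(tb)
  }
  attr(counts, "n_skipped") <- n_skipped
  class(counts) <- "trinucleotide_catalog"
  counts
}

#' Read a signature matrix (or catalog) from TSV
#'
#' First column holds the 96 context labels (e.g. `"A[C>A]A"`), one column
#' per signature. Rows may appear in any order but must cover exactly the
#' 96 contexts; they are reordered into the canonical order on read.
#'
#' @param path File path.
#' @return Numeric matrix, 96 rows in canonical order, one column per
#'   signature.
#' @export
read_signature_matrix <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  ctx <- trinucleotide_contexts()
  labels <- d[[1]]
  if (length(labels) != 96 || !setequal(labels, ctx)) {
    stop("signature matrix must have exactly the 96 canonical context rows")
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- labels
  m[ctx, , drop = FALSE]
}

#' @rdname read_signature_matrix
#' @param x Matrix (96 x k) or `trinucleotide_catalog` to write.
#' @export
write_signature_matrix <- function(x, path) {
  if (inherits(x, "trinucleotide_catalog")) {
    x <- matrix(as.numeric(x), ncol = 1,
                dimnames = list(trinucleotide_contexts(), "count"))
  }
  d <- data.frame(context = rownames(x), x, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_signature_matrix <- function(signatures) {
  if (!is.matrix(signatures) || nrow(signatures) != 96) {
    stop("signatures must be a 96-row matrix")
  }
  if (!identical(rownames(signatures), trinucleotide_contexts())) {
    stop("signature matrix rows must be in the canonical 96-context order")
  }
  if (any(signatures < 0)) stop("signature entries must be >= 0")
  s <- colSums(signatures)
  if (any(abs(s - 1) > 1e-6)) {
    stop("each signature must sum to 1 (tolerance 1e-6)")
  }
  invisible(TRUE)
}

#' Refit signature exposures by non-negative least squares
#'
#' Normalizes the catalog to a probability vector and finds the non-negative
#' signature weights minimizing the Euclidean distance to the
#' signature-weighted mixture. Weights whose normalized value falls below
#' `prune_below` are set to zero and the remaining weights renormalized to
#' sum to one; the residual norm is reported for the pruned, renormalized
#' solution.
#'
#' @param catalog A [build_catalog()] result (or named 96-vector of counts).
#' @param signatures 96 x k signature probability matrix in canonical row
#'   order (see [read_signature_matrix()]).
#' @param prune_below Weights below this value are zeroed (default 0.06, the
#'   conventional refitting cutoff).
#' @return List of class `exposure_fit`: `weights` (named, sums to 1),
#'   `residual` (Euclidean norm on the pruned solution), `prune_below`.
#' @export
fit_signature_exposures <- function(catalog, signatures, prune_below = 0.06) {
  .check_signature_matrix(signatures)
  x <- as.numeric(catalog)
  if (length(x) != 96 || any(x < 0)) stop("catalog must be a 96-vector of counts")
  total <- sum(x)
  if (total < 1) stop("catalog is empty: at least one mutation required")
  b <- x / total
  fit <- pracma::lsqnonneg(signatures, b)
  w <- fit$x
  if (sum(w) <= 0) stop("degenerate fit: all weights zero")
  w <- w / sum(w)
  w[w < prune_below] <- 0
  if (sum(w) <= 0) stop("all weights pruned; lower prune_below")
  w <- w / sum(w)
  names(w) <- colnames(signatures)
  res <- sqrt(sum((b - as.vector(signatures %*% w))^2))
  structure(list(weights = w, residual = res, prune_below = prune_below),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposure refit (non-negative least squares)\n")
  nz <- x$weights[x$weights > 0]
  for (i in seq_along(nz)) {
    cat(sprintf("  %-12s %.4f\n", names(nz)[i], nz[i]))
  }
  cat(sprintf("  residual norm %.4g (weights < %.2f pruned)\n",
              x$residual, x$prune_below))
  invisible(x)
}
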