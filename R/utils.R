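# Small shared internals.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic hash of strings to [0, 1): polynomial accumulation modulo the
# Mersenne prime 2^31 - 1 followed by Lehmer scrambling rounds. All
# intermediate products stay below 2^53, so the arithmetic is exact in
# doubles. Vectorized over its input.
.hash01 <- function(x) {
  m <- 2147483647
  n <- length(x)
  if (n == 0) return(numeric(0))
  maxlen <- max(nchar(x), 1L)
  codes <- vapply(x, function(s) {
    v <- utf8ToInt(s)
    length(v) <- maxlen
    v
  }, numeric(maxlen), USE.NAMES = FALSE)
  codes <- matrix(codes, nrow = maxlen)
  codes[is.na(codes)] <- 0
  h <- rep(7, n)
  for (i in seq_len(maxlen)) {
    h <- (h * 131 + codes[i, ] + 11) %% m
  }
  for (r in 1:4) {
    h <- (h * 48271 + 12345) %% m
  }
  h / m
}

# round-half-up to `digits` decimals (printed-table convention)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
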