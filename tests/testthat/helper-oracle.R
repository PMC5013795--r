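# Independent naive Smith-Waterman affine oracle (pure R, score only).
# Written against the scoring definition alone -- a gap of length k costs
# gap_open + k * gap_extend -- and deliberately not against the package
# implementation, so it can arbitrate.
naive_sw_score <- function(a, b, scores, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(av)
  n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + scores[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# random protein string from the matrix background (current RNG state)
random_protein <- function(n) {
  bg <- blosum62()$background
  bg <- bg[bg > 0]
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fraction of identical aligned positions between two equal-length strings
identity_frac <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av == bv)
}
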