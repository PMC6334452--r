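# Independent brute-force Needleman-Wunsch with affine gaps, used as the
# oracle for alignment scores. A gap of length k costs open + k * ext.
# Straightforward Gotoh dynamic programming over the full score matrices;
# shares nothing with the alignment path used by the package.
nw_affine_score <- function(a, b, match = 2, mismatch = -4,
                            open = 10, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e12
  Hprev <- c(0, -(open + seq_len(m) * ext))  # row i-1 of best scores
  Fprev <- rep(NEG, m + 1L)                  # vertical-gap state, row i-1
  for (i in seq_len(n)) {
    sv <- ifelse(B == A[i] & A[i] != "N", match, mismatch)
    Fcur <- pmax(Fprev - ext, Hprev - open - ext)
    Hcur <- numeric(m + 1L)
    Hcur[1] <- -(open + i * ext)
    Fcur[1] <- NEG
    E <- NEG
    for (j in seq_len(m)) {
      E <- max(E - ext, Hcur[j] - open - ext)
      Hcur[j + 1L] <- max(Hprev[j] + sv[j], E, Fcur[j + 1L])
    }
    Hprev <- Hcur
    Fprev <- Fcur
  }
  Hprev[m + 1L]
}

# two-sided Fisher exact p-value by direct hypergeometric enumeration:
# sum of the probabilities of all tables at least as extreme as observed
fisher_exact_oracle <- function(x11, x12, x21, x22) {
  m <- x11 + x21   # column-1 total
  nn <- x12 + x22  # column-2 total
  k <- x11 + x12   # row-1 total
  support <- max(0L, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(x11, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
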