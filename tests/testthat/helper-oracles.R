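# Independent oracles used across the suite.

# Closed-form solution of the constant-coefficient two-compartment system
# via the matrix exponential: y(t) = expm(A * (t - t0)) %*% y0 with
# A = [[-r, 2*b*ps], [r, -ps]].
matexp_trajectory <- function(q0, a0, r, b, ps, times) {
  A <- matrix(c(-r, r, 2 * b * ps, -ps), nrow = 2)
  t0 <- times[1]
  out <- vapply(times, function(t) {
    as.numeric(Matrix::expm(A * (t - t0)) %*% c(q0, a0))
  }, numeric(2))
  data.frame(time_days = times, qNSC = out[1, ], aNSC = out[2, ])
}

# Regular-expression oracle for the TOP-mRNA rule: first base C, then a
# maximal pyrimidine run of length 4 to 14 (terminated by a non-pyrimidine
# or the end of the sequence). Independent of the scanning implementation.
top_regex_oracle <- function(sequences) {
  s <- gsub("U", "T", toupper(sequences), fixed = TRUE)
  grepl("^C[CT]{4,14}($|[^CT])", s, perl = TRUE)
}

# Brute-force per-cell gene-set score: explicit loops, no vectorisation.
score_bruteforce <- function(counts, gene_set, target_sum = 1e6) {
  scores <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    s <- 0
    for (g in gene_set) {
      if (g %in% rownames(counts) && tot > 0) {
        s <- s + log(1 + counts[g, j] / tot * target_sum)
      }
    }
    scores[j] <- s
  }
  stats::setNames(scores, colnames(counts))
}

# Fast optimiser control for simulation studies in tests (affects only the
# local-search effort, not the data, thresholds or seeds).
fast_control <- list(maxit = 200, factr = 1e10)
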