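# Scalar, symbol-by-symbol reference implementation of fuzzy rank level
# fusion: explicit loops over models and classes, no shared code with the
# package internals. Used to cross-check the vectorized implementation.
oracle_frlf <- function(S, k = 1L, rank_penalty = 0.33, conf_penalty = 0.05,
                        variance = 1.0) {
  N <- nrow(S); C <- ncol(S)
  R <- matrix(0, N, C)
  for (i in seq_len(N)) {
    for (cc in seq_len(C)) {
      R[i, cc] <- 1 - exp(-(S[i, cc] - 1)^2 / (2 * variance))
    }
  }
  K <- vector("list", N)
  for (i in seq_len(N)) K[[i]] <- order(R[i, ])[seq_len(k)]
  RS <- numeric(C); conf_sum <- numeric(C)
  for (cc in seq_len(C)) {
    for (i in seq_len(N)) {
      if (cc %in% K[[i]]) {
        RS[cc] <- RS[cc] + R[i, cc]
        conf_sum[cc] <- conf_sum[cc] + S[i, cc]
      } else {
        RS[cc] <- RS[cc] + rank_penalty
        conf_sum[cc] <- conf_sum[cc] + conf_penalty
      }
    }
  }
  CSS <- 1 - conf_sum / N
  FS <- RS * CSS
  list(rank_sums = RS, conf_complements = CSS, final_scores = FS,
       predicted_class = which.min(FS))
}

# Random normalized score matrix, N models x C classes.
random_scores <- function(N, C) {
  m <- matrix(runif(N * C), N, C)
  score_matrix(m / rowSums(m))
}

# Random labelled binary prediction pair for metrics cross-checks.
random_labels <- function(n, labels = c("PD", "nonPD")) {
  list(truth = sample(labels, n, replace = TRUE),
       pred = sample(labels, n, replace = TRUE))
}
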