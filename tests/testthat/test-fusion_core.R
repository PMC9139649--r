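test_that("row normalization preserves proportions and handles zero rows", {
  m <- normalize_scores(rbind(c(2, 2), c(0.6, 0.4), c(0, 0)))
  expect_equal(unclass(m)[1, ], c(C1 = 0.5, C2 = 0.5))
  expect_equal(unclass(m)[2, ], c(C1 = 0.6, C2 = 0.4))
  expect_equal(unclass(m)[3, ], c(C1 = 0.5, C2 = 0.5))
  expect_true(is_normalized(m))

  big <- matrix(runif(12), 3, 4)
  expect_true(is_normalized(normalize_scores(big)))
})

test_that("invalid score entries are rejected with location information", {
  expect_error(score_matrix(rbind(c(0.5, -0.1), c(0.3, 0.7))),
               "model 1, class 2", class = "frlf_data_error")
  expect_error(score_matrix(rbind(c(NA, 1), c(0, 1))),
               class = "frlf_data_error")
  expect_error(score_matrix(matrix(1, 1, 1)), class = "frlf_data_error")
})

test_that("fuzzy rank matches the Gaussian-complement closed form", {
  expect_equal(fuzzy_rank(1), 0)
  expect_equal(fuzzy_rank(0), 1 - exp(-0.5))
  expect_equal(fuzzy_rank(0.9), 0.0049875208073176802, tolerance = 1e-12)
  expect_error(fuzzy_rank(0.5, variance = 0), class = "frlf_usage_error")

  # strictly decreasing on [0, 1]
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(fuzzy_rank(grid)) < 0))
  # variance stretches the Gaussian: larger variance -> smaller rank
  expect_true(all(fuzzy_rank(grid[-101], 2) < fuzzy_rank(grid[-101], 1)))
})

test_that("fuzzy rank matrix is elementwise and order-reversing within rows", {
  m <- score_matrix(rbind(c(0.9, 0.1), c(1, 0), c(0.5, 0.5)))
  r <- fuzzy_rank_matrix(m)
  expect_equal(unname(r[1, ]), c(0.0049875208073176802, 0.3330231891415256),
               tolerance = 1e-12)
  expect_equal(unname(r[2, ]), c(0, 1 - exp(-0.5)))
  expect_equal(r[3, 1], r[3, 2])
  # higher score => lower-or-equal rank, and range bound for scores in [0,1]
  expect_true(all(r >= 0 & r <= 1 - exp(-0.5)))
})

test_that("top-K selection sorts by rank with lowest-index tie-breaks", {
  r <- rbind(c(0.0, 0.33), c(0.2, 0.2))
  expect_equal(top_k_classes(r, 1), list(1L, 1L))
  r3 <- rbind(c(0.3, 0.1, 0.2))
  expect_equal(top_k_classes(r3, 2)[[1]], c(2L, 3L))
  expect_error(top_k_classes(r3, 4), class = "frlf_usage_error")
  expect_error(top_k_classes(r3, 0), class = "frlf_usage_error")
})

test_that("worked two-model binary example reproduces the hand computation", {
  s <- score_matrix(rbind(c(0.9, 0.1), c(0.6, 0.4)))
  res <- frlf_fuse(s)
  expect_equal(unname(res$rank_sums),
               c(0.081871174420681925, 0.66), tolerance = 1e-12)
  expect_equal(unname(res$conf_complements), c(0.25, 0.95))
  expect_equal(unname(res$final_scores),
               c(0.020467793605170481, 0.627), tolerance = 1e-12)
  expect_equal(res$predicted_class, 1L)
  expect_equal(res$top_k_sets, list(1L, 1L))
})

test_that("degenerate and reduction cases behave as the decision rule demands", {
  # unanimous fully confident models: winner's final score is exactly zero
  s <- score_matrix(rbind(c(1, 0), c(1, 0), c(1, 0)))
  res <- frlf_fuse(s)
  expect_identical(res$final_scores[[1]], 0)
  expect_equal(res$predicted_class, 1L)

  # N = 1 with k = C (no penalty active): equals plain argmax
  for (C in 2:5) {
    row <- random_scores(1, C)
    res <- frlf_fuse(row, fusion_params(k = C))
    expect_equal(res$predicted_class, unname(which.max(row[1, ])))
  }

  # unnormalized input errors unless auto_normalize
  raw <- score_matrix(rbind(c(2, 1), c(1, 1)))
  expect_error(frlf_fuse(raw), class = "frlf_data_error")
  expect_equal(frlf_fuse(raw, auto_normalize = TRUE)$predicted_class, 1L)
})

test_that("vectorized fusion agrees with the scalar oracle on random input", {
  set.seed(4242)
  for (rep in 1:250) {
    N <- sample(1:5, 1); C <- sample(2:6, 1)
    k <- sample(seq_len(C), 1)
    s <- random_scores(N, C)
    got <- frlf_fuse(s, fusion_params(k = k))
    want <- oracle_frlf(unclass(s), k = k)
    expect_equal(unname(got$rank_sums), want$rank_sums, tolerance = 1e-12)
    expect_equal(unname(got$conf_complements), want$conf_complements,
                 tolerance = 1e-12)
    expect_equal(unname(got$final_scores), want$final_scores,
                 tolerance = 1e-12)
    expect_equal(got$predicted_class, want$predicted_class)
  }
})

test_that("permuting class labels permutes final scores and the prediction", {
  set.seed(99)
  for (rep in 1:25) {
    C <- sample(2:5, 1)
    s <- random_scores(sample(1:4, 1), C)
    perm <- sample(C)
    res <- frlf_fuse(s)
    res_p <- frlf_fuse(score_matrix(unclass(s)[, perm, drop = FALSE]))
    expect_equal(unname(res_p$final_scores), unname(res$final_scores[perm]),
                 tolerance = 1e-12)
    expect_equal(perm[res_p$predicted_class], res$predicted_class)
  }
})

test_that("binary unanimity: agreeing models always win the fusion", {
  # every model puts its larger confidence on class 1; sweep that confidence
  for (p in seq(0.501, 1, by = 0.01)) {
    for (N in c(1, 2, 4)) {
      s <- score_matrix(matrix(c(rep(p, N), rep(1 - p, N)), N, 2))
      expect_equal(frlf_fuse(s)$predicted_class, 1L)
    }
  }
})

test_that("batch fusion preserves order and matches per-sample fusion", {
  expect_identical(frlf_fuse_batch(list()), list())
  set.seed(7)
  samples <- replicate(20, random_scores(3, 2), simplify = FALSE)
  batch <- frlf_fuse_batch(samples)
  expect_length(batch, 20)
  one <- frlf_fuse(samples[[13]])
  expect_equal(batch[[13]]$final_scores, one$final_scores)
  # heterogeneous shapes rejected
  expect_error(frlf_fuse_batch(list(random_scores(2, 2), random_scores(2, 3))),
               class = "frlf_data_error")
})

test_that("fusion parameters are validated", {
  expect_error(fusion_params(k = 0), class = "frlf_usage_error")
  expect_error(fusion_params(rank_penalty = -1), class = "frlf_usage_error")
  expect_error(fusion_params(variance = -2), class = "frlf_usage_error")
  expect_error(frlf_fuse(score_matrix(rbind(c(0.5, 0.5))),
                         fusion_params(k = 3)),
               class = "frlf_usage_error")
})
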