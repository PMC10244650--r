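test_that("contingency tables carry the right counts and marginals", {
  ct <- contingency_table(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unname(ct$counts), matrix(1, 2, 2))
  expect_equal(ct$n, 4)
  expect_equal(unname(ct$row_sums), c(2, 2))
  # identical labelings give a diagonal table
  ct2 <- contingency_table(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(sum(ct2$counts) - sum(diag(ct2$counts)), 0)
  # constant second labeling collapses to one column
  ct3 <- contingency_table(c(1, 2, 3), c(9, 9, 9))
  expect_equal(ncol(ct3$counts), 1L)
  expect_equal(unname(ct3$col_sums), 3)
  expect_error(contingency_table(1:3, 1:4), "length")
})

test_that("pair counts always partition all N(N-1)/2 pairs", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    pc <- pair_counts(a, b)
    expect_equal(pc$tp + pc$fp + pc$fn + pc$tn, n * (n - 1) / 2)
    opc <- oracle_pair_counts(a, b)
    expect_equal(pc, opc)
  }
})

test_that("ARI and FMI reproduce the hand-derived cases", {
  expect_equal(ari(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ari(c(0, 0, 0, 1, 1), c(0, 0, 1, 1, 1)), 1 / 6)
  expect_equal(fmi(c("x", "y", "x"), c("x", "y", "x")), 1)
  expect_equal(fmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(fmi(c(0, 0, 0, 1, 1), c(0, 0, 1, 1, 1)), 0.5)
})

test_that("ARI and FMI agree with the brute-force pair oracle", {
  set.seed(50)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    a <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    b <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    expect_lt(abs(ari(a, b) - oracle_ari(a, b)), 1e-12)
    expect_lt(abs(fmi(a, b) - oracle_fmi(a, b)), 1e-12)
  }
})

test_that("both indices are symmetric and renaming-invariant", {
  set.seed(8)
  for (rep in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari(a, b), ari(b, a))
    expect_equal(fmi(a, b), fmi(b, a))
    ren <- c("delta", "alpha", "gamma", "beta")[a]
    expect_equal(ari(ren, b), ari(a, b))
    expect_equal(fmi(ren, b), fmi(a, b))
  }
})

test_that("ARI of permuted labels concentrates near zero", {
  set.seed(123)
  labels <- sample(1:4, 200, replace = TRUE)
  vals <- vapply(1:200, function(i) ari(labels, sample(labels)), numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ARI handles degenerate partitions by convention", {
  expect_equal(ari(1:5, 1:5), 1)                 # both all-singletons, equal
  expect_equal(ari(rep(1, 5), rep(2, 5)), 1)     # both one cluster
  expect_equal(ari(1:4, c(1, 1, 2, 3)), 0)       # singletons vs non-singletons
})

test_that("clustering recovers well-separated blobs with either method", {
  blobs <- make_blobs(n_per = 25, separation = 50)
  for (method in c("kmeans", "hierarchical")) {
    cl <- cluster_embedding(blobs$x, k = 2, method = method, seed = 3)
    expect_equal(ari(cl, blobs$labels), 1)
  }
  expect_equal(cluster_embedding(blobs$x, k = 1), rep(1L, 50))
  expect_error(cluster_embedding(blobs$x, k = 51), "exceeds")
  # duplicated points merge first under Ward linkage
  x <- rbind(c(0, 0), c(0, 0), c(10, 10), c(5, 5))
  cl <- cluster_embedding(x, k = 3, method = "hierarchical")
  expect_equal(cl[1], cl[2])
})

test_that("reconstruction_rho measures distance-geometry fidelity", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30)
  expect_equal(reconstruction_rho(x, x), 1)
  expect_equal(reconstruction_rho(x, 2 * x), 1)   # scale-invariant
  y <- matrix(rnorm(200 * 6), 200)
  noise <- matrix(rnorm(200 * 6), 200)
  expect_lt(abs(reconstruction_rho(y, noise, seed = 1)), 0.1)
  expect_error(reconstruction_rho(x, matrix(1, 30, 4)), "degenerate")
  expect_error(reconstruction_rho(x[1:2, ], x[1:2, ]), "at least 3")
  expect_error(reconstruction_rho(x, x[, 1:2]), "shapes differ")
})

test_that("reconstruction_rho subsamples deterministically", {
  set.seed(9)
  x <- matrix(rnorm(120 * 3), 120)
  y <- x + matrix(rnorm(120 * 3, sd = 0.2), 120)
  r1 <- reconstruction_rho(x, y, max_cells = 40, seed = 7)
  r2 <- reconstruction_rho(x, y, max_cells = 40, seed = 7)
  expect_identical(r1, r2)
})

test_that("ors averages per-modality correlations and ignores order", {
  set.seed(4)
  xs <- list(matrix(rnorm(60), 20), matrix(rnorm(40), 20))
  perfect <- ors(xs, xs)
  expect_equal(perfect$ors, 1)
  recs <- list(xs[[1]] + rnorm(60, sd = 0.3), xs[[2]] + rnorm(40, sd = 0.8))
  s12 <- ors(xs, recs)
  s21 <- ors(rev(xs), rev(recs))
  expect_equal(s12$ors, s21$ors)
  expect_equal(s12$ors, mean(s12$rho), tolerance = 1e-12)
  expect_equal(s12$rho, rev(s21$rho))
})

test_that("internal indices separate tight blobs and flag degenerate input", {
  blobs <- make_blobs(n_per = 20, separation = 50)
  idx <- internal_indices(blobs$x, blobs$labels)
  expect_gt(idx$silhouette, 0.9)
  expect_lt(idx$davies_bouldin, 0.2)
  # random labels on one blob: silhouette near zero
  set.seed(2)
  one <- matrix(rnorm(100 * 3), 100)
  rnd <- sample(1:2, 100, replace = TRUE)
  expect_lt(abs(internal_indices(one, rnd)$silhouette), 0.15)
  expect_error(internal_indices(one, rep(1, 100)), "single cluster")
  # coincident centroids blow up Davies-Bouldin
  dup <- rbind(one[1:10, ], one[1:10, ])
  expect_equal(internal_indices(dup, rep(1:2, each = 10))$davies_bouldin, Inf)
})

test_that("ari and fmi match an established implementation on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (rep in 1:10) {
    a <- sample(1:5, 50, replace = TRUE)
    b <- sample(1:4, 50, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
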