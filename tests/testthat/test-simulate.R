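test_that("simulated datasets have the requested structure", {
  cfg <- simulation_config(n_cells = 300, n_clusters = 3,
                           modality_dims = c(200, 15),
                           dropout_rate = c(0.5, 0), seed = 42)
  ds <- simulate_multiomics(cfg)
  expect_equal(dim(ds$data$modalities[[1]]), c(300L, 200L))
  expect_equal(dim(ds$data$modalities[[2]]), c(300L, 15L))
  expect_equal(length(ds$true_labels), 300)
  expect_equal(length(unique(ds$true_labels)), 3)
  expect_equal(dim(ds$true_latent), c(300L, 10L))
  expect_true(all(as_dense(ds$data$modalities[[1]]) >= 0))
  expect_true(all(as_dense(ds$data$modalities[[1]]) ==
                    round(as_dense(ds$data$modalities[[1]]))))
  # same seed, identical dataset
  ds2 <- simulate_multiomics(cfg)
  expect_identical(as_dense(ds$data$modalities[[1]]),
                   as_dense(ds2$data$modalities[[1]]))
  expect_identical(ds$true_labels, ds2$true_labels)
})

test_that("dropout calibration matches its binomial expectation", {
  # continuous noise-free modality: zeros can only come from the dropout mask
  cfg <- simulation_config(n_cells = 300, n_clusters = 3,
                           modality_dims = c(200, 15), noise_sd = 0,
                           dropout_rate = c(0.5, 0), count_like = FALSE,
                           seed = 11)
  ds <- simulate_multiomics(cfg)
  m1 <- as_dense(ds$data$modalities[[1]])
  n_entries <- length(m1)
  zero_frac <- mean(m1 == 0)
  sd_binom <- sqrt(0.5 * 0.5 / n_entries)
  expect_lt(abs(zero_frac - 0.5), 3 * sd_binom + 1e-12)
  expect_lt(abs(zero_frac - 0.5), 0.05)
  expect_equal(mean(as_dense(ds$data$modalities[[2]]) == 0), 0)
})

test_that("the latent space is separable by construction", {
  cfg <- simulation_config(n_cells = 240, n_clusters = 3,
                           modality_dims = c(50, 10), noise_sd = 0,
                           dropout_rate = 0, cluster_separation = 12, seed = 3)
  ds <- simulate_multiomics(cfg)
  cl <- cluster_embedding(ds$true_latent, k = 3, seed = 1)
  expect_equal(ari(cl, ds$true_labels), 1)
})

test_that("separation monotonically improves single-modality clustering", {
  mean_ari <- vapply(c(1, 4, 10), function(sep) {
    mean(vapply(1:5, function(s) {
      ds <- simulate_multiomics(simulation_config(
        n_cells = 150, n_clusters = 3, modality_dims = c(40, 10),
        cluster_separation = sep, dropout_rate = 0, count_like = FALSE,
        seed = 100 + s))
      cl <- cluster_embedding(as_dense(ds$data$modalities[[1]]), k = 3,
                              seed = s)
      ari(cl, ds$true_labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= 0))
})

test_that("batch shifts are detectable by a linear classifier", {
  cfg <- simulation_config(n_cells = 400, n_clusters = 2,
                           modality_dims = c(30, 10), n_batches = 2,
                           batch_shift_sd = 1, count_like = FALSE,
                           dropout_rate = 0, seed = 21)
  ds <- simulate_multiomics(cfg)
  x <- as_dense(ds$data$modalities[[1]])
  y <- as.integer(ds$batch_labels == "batch1")
  train <- seq_len(200)
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(glm(y ~ ., data = df[train, ], family = binomial()))
  pred <- suppressWarnings(predict(fit, df[-train, ]))
  # AUC via the rank statistic
  r <- rank(pred)
  n1 <- sum(y[-train] == 1)
  n0 <- sum(y[-train] == 0)
  auc <- (sum(r[y[-train] == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.6)
  # without a shift the batch labels exist but carry no signal
  ds0 <- simulate_multiomics(simulation_config(
    n_cells = 100, n_clusters = 2, modality_dims = c(10, 5), n_batches = 3,
    batch_shift_sd = 0, seed = 5))
  expect_equal(sort(unique(ds0$batch_labels)),
               paste0("batch", 1:3))
})

test_that("fixtures round-trip through write_fixture/read_fixture", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_cells = 40, n_clusters = 2,
                           modality_dims = c(25, 8),
                           count_like = c(TRUE, FALSE), n_batches = 2,
                           batch_shift_sd = 0.5, seed = 14)
  ds <- simulate_multiomics(cfg)
  write_fixture(ds, dir)
  expect_true(file.exists(file.path(dir, "RNA.mtx")))
  expect_true(file.exists(file.path(dir, "ADT.csv")))
  expect_match(readLines(file.path(dir, "RNA.mtx"), n = 1), "integer")
  expect_equal(length(readLines(file.path(dir, "labels.tsv"))), 40)
  back <- read_fixture(dir)
  for (i in 1:2)
    expect_equal(unname(as.matrix(as_dense(back$modalities[[i]]))),
                 unname(as_dense(ds$data$modalities[[i]])), tolerance = 1e-12)
  expect_equal(back$labels, ds$true_labels)
  expect_equal(back$batches, ds$batch_labels)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(dropout_rate = 1), "dropout_rate")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_cells = 0))
})
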