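test_that("build_umint allocates the documented shapes deterministically", {
  cfg <- umint_config(hidden_widths = c(8, 4), bottleneck_width = 3, seed = 42)
  model <- build_umint(c(100, 10), cfg)
  shapes <- lapply(model$modules[[1]], dim)
  expect_equal(shapes$W1, c(100, 8))
  expect_equal(shapes$W2, c(8, 3))
  expect_equal(shapes$W3, c(3, 8))
  expect_equal(shapes$W4, c(8, 100))
  expect_length(model$modules[[1]]$b1, 8)
  expect_length(model$b2, 3)
  # encoder weight entries: 100*8 + 10*4 + (8+4)*3 = 876
  wc <- model_weight_counts(model)
  expect_equal(unname(wc["first"] + wc["fuse"]), 876)

  # single-module degeneration
  m1 <- build_umint(5, umint_config(hidden_widths = 2, bottleneck_width = 1))
  expect_equal(dim(m1$modules[[1]]$W1), c(5, 2))
  expect_equal(dim(m1$modules[[1]]$W2), c(2, 1))
  expect_equal(dim(m1$modules[[1]]$W3), c(1, 2))
  expect_equal(dim(m1$modules[[1]]$W4), c(2, 5))

  # same seed twice: bitwise-identical initialization
  expect_identical(build_umint(c(100, 10), cfg), build_umint(c(100, 10), cfg))

  expect_error(build_umint(c(4, 4), umint_config(bottleneck_width = 8)),
               "smaller than the total input")
  expect_error(build_umint(c(4, 4), umint_config(hidden_widths = c(2, 2, 2),
                                                 bottleneck_width = 2)),
               "length")
})

test_that("encode follows the layer equations on hand cases", {
  cfg <- umint_config(hidden_widths = 2, bottleneck_width = 1)
  model <- build_umint(2, cfg)
  # identity first layer, summing fusion
  model$modules[[1]]$W1 <- diag(2)
  model$modules[[1]]$b1 <- c(0, 0)
  model$modules[[1]]$W2 <- matrix(1, 2, 1)
  model$b2 <- 0
  x <- matrix(c(1, -1), 1, 2)
  enc <- umint_encode(model, list(x), with_activations = TRUE)
  expect_equal(unname(enc$activations$h2[[1]]), matrix(c(1, 0), 1))
  expect_equal(unname(enc$embedding$values), matrix(1, 1, 1))

  # all-zero parameters give an all-zero embedding
  z <- model
  for (nm in c("W1", "W2")) z$modules[[1]][[nm]][] <- 0
  z$modules[[1]]$b1[] <- 0
  expect_true(all(umint_encode(z, list(x))$values == 0))

  # large negative biases clamp everything to zero
  neg <- model
  neg$modules[[1]]$b1 <- c(-100, -100)
  expect_true(all(umint_encode(neg, list(x))$values == 0))
})

test_that("decode applies one ReLU module then a linear readout", {
  cfg <- umint_config(hidden_widths = 2, bottleneck_width = 1)
  model <- build_umint(2, cfg)
  model$modules[[1]]$W3 <- matrix(c(1, -1), 1, 2)
  model$modules[[1]]$b3 <- c(0, 0)
  model$modules[[1]]$W4 <- matrix(1, 2, 2)
  model$modules[[1]]$b4 <- c(0, 0)
  rec <- umint_decode(model, matrix(2, 1, 1))
  # h4 = ReLU([2, -2]) = [2, 0]; xhat = [2, 2]
  expect_equal(unname(rec[[1]]), matrix(2, 1, 2))

  # zero embedding, zero biases -> exactly zero reconstructions
  rec0 <- umint_decode(model, matrix(0, 3, 1))
  expect_true(all(rec0[[1]] == 0))

  expect_error(umint_decode(model, matrix(0, 1, 2)), "width")

  # decode(encode(x)) restores input shapes
  m2 <- build_umint(c(6, 3), umint_config(hidden_widths = c(4, 2),
                                          bottleneck_width = 2, seed = 1))
  xs <- list(matrix(rnorm(12), 2), matrix(rnorm(6), 2))
  rec2 <- umint_decode(m2, umint_encode(m2, xs))
  expect_equal(lapply(rec2, dim), lapply(xs, dim))
})

test_that("embedding activations are non-negative for any parameters", {
  set.seed(31)
  for (rep in 1:20) {
    model <- build_umint(c(5, 4), umint_config(hidden_widths = c(3, 3),
                                               bottleneck_width = 2,
                                               seed = rep))
    model$b2 <- rnorm(2, sd = 3)
    xs <- list(matrix(rnorm(20, sd = 5), 4), matrix(rnorm(16, sd = 5), 4))
    enc <- umint_encode(model, xs, with_activations = TRUE)
    expect_true(all(enc$embedding$values >= 0))
    expect_true(all(vapply(enc$activations$h2, min, numeric(1)) >= 0))
    expect_true(all(vapply(enc$activations$h4, min, numeric(1)) >= 0))
  }
})

test_that("the loss matches hand-derived values", {
  # perfect reconstruction with no penalties is exactly zero
  cfg <- umint_config(hidden_widths = 2, bottleneck_width = 1, lambdas = 1,
                      alpha = 0, beta = 0)
  model <- build_umint(2, cfg)
  x <- matrix(c(1, 2), 1, 2)
  fw <- list(h2 = list(matrix(0, 1, 2)), h3 = matrix(0, 1, 1),
             h4 = list(matrix(0, 1, 2)), xhat = list(x))
  expect_equal(umint_loss(model, list(x), forward = fw)$total, 0)

  # n = 1, single modality, residual (2, 0), lambda 0.5 -> 0.5 * 4 = 2
  cfg2 <- umint_config(hidden_widths = 2, bottleneck_width = 1, lambdas = 0.5,
                       alpha = 0, beta = 0)
  model2 <- build_umint(2, cfg2)
  fw2 <- fw
  fw2$xhat <- list(x + matrix(c(2, 0), 1, 2))
  lb <- umint_loss(model2, list(x), forward = fw2)
  expect_equal(lb$reconstruction_terms, 2)
  expect_equal(lb$total, 2)

  # a single active bottleneck unit under alpha = 1e-4
  cfg3 <- umint_config(hidden_widths = 2, bottleneck_width = 1, lambdas = 1,
                       alpha = 1e-4, beta = 0)
  model3 <- build_umint(2, cfg3)
  fw3 <- fw
  fw3$h3 <- matrix(1, 1, 1)
  fw3$xhat <- list(x)
  expect_equal(umint_loss(model3, list(x), forward = fw3)$activity_penalty, 1e-4)
})

test_that("loss equals an entrywise scalar re-derivation on random tensors", {
  set.seed(17)
  for (rep in 1:5) {
    dims <- c(5, 3)
    cfg <- umint_config(hidden_widths = c(3, 2), bottleneck_width = 2,
                        lambdas = c(0.3, 1.7), alpha = 0.01, beta = 0.02,
                        seed = rep)
    model <- build_umint(dims, cfg)
    xs <- list(matrix(rnorm(20), 4), matrix(rnorm(12), 4))
    lb <- umint_loss(model, xs)
    fw <- umint:::umint_forward(model, xs)
    # independent scalar loop over entries
    recon <- 0
    for (i in 1:2) for (r in 1:4) for (cc in seq_len(dims[i]))
      recon <- recon + cfg$lambdas[i] / 4 * (xs[[i]][r, cc] - fw$xhat[[i]][r, cc])^2
    act <- 0
    for (h in c(fw$h2, list(fw$h3), fw$h4)) for (v in as.numeric(h))
      act <- act + 0.01 * abs(v) / 4
    wt <- 0
    for (i in 1:2) for (nm in c("W2", "W3", "W4"))
      for (v in as.numeric(model$modules[[i]][[nm]])) wt <- wt + 0.02 * v^2
    expect_equal(lb$total, recon + act + wt, tolerance = 1e-9)
  }
})

test_that("models round-trip through the JSON archive", {
  dir <- withr::local_tempdir()
  model <- build_umint(c(7, 3), umint_config(hidden_widths = c(4, 2),
                                             bottleneck_width = 2, seed = 5))
  p <- file.path(dir, "model.json")
  save_umint(model, p)
  back <- load_umint(p)
  expect_equal(back$modules, model$modules, tolerance = 1e-12)
  expect_equal(back$b2, model$b2)
  expect_equal(back$dims, model$dims)
  expect_equal(unclass(back$config), unclass(model$config))
  # reloaded model encodes identically
  xs <- list(matrix(rnorm(14), 2), matrix(rnorm(6), 2))
  expect_equal(umint_encode(back, xs)$values, umint_encode(model, xs)$values)
})
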