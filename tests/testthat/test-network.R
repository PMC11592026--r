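small_spec <- function(nk = 8) network_spec(n_kernels = nk)

test_that("the network maps K x 37 to K x 2 for any K", {
  net <- build_network(small_spec(), seed = 1)
  for (K in c(1, 7, 50)) {
    X <- matrix(rnorm(K * 37), K, 37)
    out <- replate:::net_forward(net, X)
    expect_equal(dim(out), c(K, 2))
  }
  # the full-width reference architecture builds and has 5 layers / 2 outputs
  full <- network_spec()
  expect_length(full$layers, 5)
  expect_equal(full$layers[[5]]$n_kernels, 2L)
  expect_equal(vapply(full$layers, `[[`, integer(1), "kernel_size"),
               c(11L, 9L, 5L, 3L, 1L))
})

test_that("convolution is translation-equivariant away from the borders", {
  net <- build_network(small_spec(16), seed = 3)
  set.seed(8)
  K <- 60; shift <- 7
  X <- matrix(rnorm(K * 37), K, 37)
  Xs <- rbind(matrix(0, shift, 37), X)
  out <- replate:::net_forward(net, X)
  outs <- replate:::net_forward(net, Xs)
  # receptive field of the stack is 25, so compare well inside the borders
  interior <- 20:(K - 20)
  expect_lt(max(abs(out[interior, ] - outs[interior + shift, ])), 1e-8)
})

test_that("angle recovery is quadrant-aware and scale-invariant", {
  expect_equal(angles_from_sincos(cbind(0, 1))$values, 0)
  expect_equal(angles_from_sincos(cbind(1, 0))$values, pi / 2)
  set.seed(4)
  theta <- runif(1000, -pi, pi - 1e-6)
  pairs <- cbind(sin(theta), cos(theta)) * 0.3
  expect_angles_equal(angles_from_sincos(pairs)$values, theta, tol = 1e-9)
  deg <- angles_from_sincos(rbind(c(0, 0), c(1, 0)))
  expect_false(deg$defined[1])
  expect_true(deg$defined[2])
})

test_that("training pairs carry unit-circle targets aligned to plates", {
  h <- make_ideal_helix(12)
  ds <- make_training_pairs(list(h))
  d <- ds[[1]]
  expect_false(d$mask[1])
  expect_true(all(d$mask[-1]))
  expect_lt(max(abs(rowSums(d$Y[d$mask, ]^2) - 1)), 1e-12)
  # near-constant targets along the helix
  expect_lt(stats::sd(atan2(d$Y[d$mask, 1], d$Y[d$mask, 2])), 1e-9)
  # a cis plate's target is the extracted cis lambda, not a trans default
  ch <- make_synthetic_chain(20, seed = 99, cis_fraction = 0.3)
  stopifnot(any(ch$lambda$isomers == "cis"))
  ds2 <- make_training_pairs(list(ch))
  ang <- atan2(ds2[[1]]$Y[, 1], ds2[[1]]$Y[, 2])
  expect_angles_equal(ang[-1], ch$lambda$values, tol = 1e-9)
})

test_that("training is deterministic and can overfit a small set", {
  chains <- lapply(1:5, function(i) make_synthetic_chain(40, seed = i))
  ds <- make_training_pairs(chains)
  cfg <- training_config(seed = 1, epochs = 12, patience = 0,
                         validation_fraction = 0)
  m1 <- train_network(build_network(small_spec(16), seed = 2), ds, cfg)
  m2 <- train_network(build_network(small_spec(16), seed = 2), ds, cfg)
  for (li in 1:5)
    expect_identical(m1$layers[[li]]$W, m2$layers[[li]]$W)

  net <- build_network(network_spec(n_kernels = 32), seed = 1)
  net <- train_network(net, ds, training_config(
    seed = 1, epochs = 300, lr = 2e-3, patience = 0,
    validation_fraction = 0))
  expect_lt(tail(net$history$train, 1), 0.01)
  errs <- vapply(chains, function(ch)
    lambda_error(ch$lambda, predict_lambda(net, ch$trace))$mean, numeric(1))
  expect_lt(mean(errs), 0.05)

  # save -> load -> predict reproduces the lambda series
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(net, f)
  net2 <- load_model(f)
  p1 <- predict_lambda(net, chains[[1]]$trace)
  p2 <- predict_lambda(net2, chains[[1]]$trace)
  expect_identical(p1$values, p2$values)
})

test_that("prediction output respects length, range and layout checks", {
  ch <- make_synthetic_chain(35, seed = 6)
  net <- build_network(small_spec(), seed = 1)
  pl <- predict_lambda(net, ch$trace)
  expect_length(pl$values, 34)
  expect_true(all(pl$values >= -pi & pl$values < pi, na.rm = TRUE))
  expect_error(predict_lambda(net, matrix(0, 10, 12)), "configuration error")
  expect_error(load_model(withr::local_tempfile()), "cannot read")
})
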