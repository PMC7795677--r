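test_that("spec enforces the latent factorization and default hyperparameter rules", {
  sp <- ae_spec(L = 100, C = 5)
  expect_equal(sp$latent_dim, 200)
  expect_equal(sp$kernel, 25)
  expect_equal(sp$n_filters, 2)
  expect_error(ae_spec(L = 100, C = 5, latent_dim = 150), "factor")
})

test_that("encoder output and reconstruction shapes honor the contracts", {
  sp <- ae_spec(L = 100, C = 5, max_epochs = 2, batch_size = 8, seed = 2)
  set.seed(1)
  X <- array(runif(12 * 100 * 5), dim = c(12, 100, 5))
  m <- ae_train(ae_build(sp), X)
  codes <- ae_encode(m, X)
  expect_equal(dim(codes), c(12, 200))  # exactly omega values per instance
  R <- ae_reconstruct(m, X)
  expect_equal(dim(R), dim(X))
  expect_true(all(R > 0 & R < 1))
  expect_equal(dim(ae_encode(m, X[0, , , drop = FALSE])), c(0, 200))
})

test_that("parameter count matches the layer-arithmetic closed form", {
  for (L in c(16, 64)) for (C in c(1, 3)) {
    sp <- ae_spec(L = L, C = C)
    m <- ae_build(sp)
    actual <- sum(vapply(m$weights, length, numeric(1)))
    expect_equal(actual, ae_param_count(sp))
    # two encoder weight tensors only: the shallow-structure contract
    enc <- m$weights[c("w1", "k2")]
    expect_length(enc, 2)
  }
})

test_that("binary cross-entropy matches the direct summation formula", {
  x <- array(0.5, dim = c(2, 3, 1))
  expect_equal(bce_loss(x, x), log(2), tolerance = 1e-12)
  eps <- 1e-7
  hard <- array(rep(c(eps, 1 - eps), 6), dim = c(3, 4, 1))
  expect_lt(bce_loss(round(hard), hard), 1e-5)
  set.seed(41)
  for (i in 1:100) {
    x <- matrix(runif(8), 2)
    eta <- matrix(runif(8, 0.05, 0.95), 2)
    direct <- -sum(x * log(eta) + (1 - x) * log(1 - eta)) / length(x)
    expect_equal(bce_loss(x, eta), direct, tolerance = 1e-9)
  }
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("analytic gradients match finite differences", {
  sp <- ae_spec(L = 8, C = 2, kernel = 3, seed = 3)
  m <- ae_build(sp)
  set.seed(4)
  X <- array(runif(5 * 8 * 2), dim = c(5, 8, 2))
  si <- emofuse:::ae_split_input(X, sp)
  lg <- emofuse:::ae_loss_grad(m, si$Xc, si$Xflat)
  h <- 1e-6
  for (nm in names(m$weights)) {
    for (idx in seq_len(min(3, length(m$weights[[nm]])))) {
      m2 <- m
      m2$weights[[nm]][idx] <- m2$weights[[nm]][idx] + h
      up <- emofuse:::ae_loss_grad(m2, si$Xc, si$Xflat)$loss
      m2$weights[[nm]][idx] <- m2$weights[[nm]][idx] - 2 * h
      dn <- emofuse:::ae_loss_grad(m2, si$Xc, si$Xflat)$loss
      expect_equal(lg$grad[[nm]][idx], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and beats the mean predictor on low-rank signals", {
  set.seed(42)
  # rank-1 temporal structure shared across channels plus light noise
  n <- 60; L <- 16; C <- 2
  basis <- sin(2 * pi * seq_len(L) / L)
  amp <- runif(n, 0.2, 1)
  X <- array(0, dim = c(n, L, C))
  for (c in 1:C) X[, , c] <- 0.5 + 0.35 * outer(amp, basis) + rnorm(n * L, sd = 0.02)
  X <- pmin(pmax(X, 0), 1)
  sp <- ae_spec(L = L, C = C, kernel = 4, max_epochs = 300, patience = 20,
                batch_size = 16, seed = 5)
  m <- ae_train(ae_build(sp), X)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  R <- ae_reconstruct(m, X)
  mse <- mean((R - X)^2)
  mean_pred <- array(rep(apply(X, c(2, 3), mean), each = n), dim = dim(X))
  expect_lt(mse, mean((mean_pred - X)^2))
})

test_that("constant 0.5 inputs converge toward the log 2 loss floor", {
  X <- array(0.5, dim = c(8, 8, 1))
  sp <- ae_spec(L = 8, C = 1, kernel = 3, max_epochs = 50, batch_size = 4, seed = 6)
  m <- ae_train(ae_build(sp), X)
  expect_equal(tail(m$history$val_loss, 1), log(2), tolerance = 1e-2)
})

test_that("encoding is deterministic, order-preserving and duplicates map identically", {
  sp <- ae_spec(L = 12, C = 2, kernel = 3, max_epochs = 3, batch_size = 8, seed = 7)
  set.seed(8)
  X <- array(runif(10 * 12 * 2), dim = c(10, 12, 2))
  X[2, , ] <- X[1, , ]  # duplicate instance
  m <- ae_train(ae_build(sp), X)
  codes <- ae_encode(m, X)
  expect_equal(codes[1, ], codes[2, ])
  perm <- c(3, 1, 2, 5, 4, 6:10)
  expect_equal(ae_encode(m, X[perm, , , drop = FALSE]), codes[perm, ])
  expect_error(ae_encode(ae_build(sp), X), "not trained")
})

test_that("training is reproducible under a fixed seed", {
  sp <- ae_spec(L = 8, C = 1, kernel = 3, max_epochs = 10, batch_size = 8, seed = 9)
  set.seed(10)
  X <- array(runif(20 * 8 * 1), dim = c(20, 8, 1))
  m1 <- ae_train(ae_build(sp), X)
  m2 <- ae_train(ae_build(sp), X)
  expect_identical(m1$weights, m2$weights)
  expect_identical(ae_encode(m1, X), ae_encode(m2, X))
})

test_that("the compiled batch step matches the reference R implementation", {
  sp <- ae_spec(L = 12, C = 3, kernel = 5, seed = 21)
  m <- ae_build(sp)
  set.seed(22)
  X <- array(runif(7 * 12 * 3), dim = c(7, 12, 3))
  si <- emofuse:::ae_split_input(X, sp)
  fused <- emofuse:::ae_loss_grad(m, si$Xc, si$Xflat)
  ref <- emofuse:::ae_loss_grad_ref(m, si$Xc, si$Xflat)
  expect_equal(fused$loss, ref$loss, tolerance = 1e-12)
  for (nm in names(ref$grad)) {
    expect_equal(fused$grad[[nm]], ref$grad[[nm]], tolerance = 1e-12)
  }
})
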