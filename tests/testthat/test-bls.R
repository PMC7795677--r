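test_that("z-score normalization round-trips and guards constant columns", {
  F <- cbind(c(1, 2, 3), c(10, 10, 10), rnorm(3))
  expect_warning(zs <- zscore_fit(F), "constant")
  expect_equal(zs$x[, 1], c(-1, 0, 1))  # sample standard deviation
  expect_equal(zs$x[, 2], c(0, 0, 0))
  back <- sweep(sweep(zs$x[, c(1, 3)], 2, zs$sigma[c(1, 3)], `*`), 2, zs$mu[c(1, 3)], `+`)
  expect_equal(back, F[, c(1, 3)], tolerance = 1e-12)
  # test data reuses the training parameters
  expect_equal(zscore_apply(F[1, , drop = FALSE], zs$mu, zs$sigma),
               zs$x[1, , drop = FALSE])
})

test_that("tansig is the hyperbolic tangent sigmoid with range (-1, 1)", {
  expect_equal(tansig(0), 0)
  expect_equal(tansig(1e3), 1)
  expect_equal(tansig(-1e3), -1)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(tansig(x), tanh(x), tolerance = 1e-12)
})

test_that("the lasso refinement approaches least squares as lambda -> 0 and zero as lambda -> Inf", {
  set.seed(31)
  Z <- diag(5) + matrix(rnorm(25, sd = 0.05), 5)
  B <- matrix(rnorm(25), 5)
  W0 <- suppressWarnings(sparse_autoencoder_refine(Z, B, lambda = 1e-12, iters = 3000, tol = 1e-10))
  expect_lt(max(abs(Z %*% W0 - B)), 1e-6)
  Winf <- sparse_autoencoder_refine(Z, B, lambda = 1e6, iters = 50)
  expect_equal(Winf, matrix(0, 5, 5))
})

test_that("the lasso refinement matches the glmnet objective on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(32)
  obj <- function(Z, B, W, lam) sum((Z %*% W - B)^2) + lam * sum(abs(W))
  for (i in 1:10) {
    Z <- matrix(rnorm(20 * 5), 20)
    B <- matrix(rnorm(20 * 5), 20)
    lam <- 10^runif(1, -4, -1)
    W <- suppressWarnings(sparse_autoencoder_refine(Z, B, lam, iters = 200))
    Wg <- sapply(seq_len(ncol(B)), function(j) {
      as.numeric(glmnet::coef.glmnet(
        glmnet::glmnet(Z, B[, j], alpha = 1, lambda = lam / (2 * nrow(Z)),
                       standardize = FALSE, intercept = FALSE, thresh = 1e-14))[-1])
    })
    expect_lt(abs(obj(Z, B, W, lam) - obj(Z, B, Wg, lam)), 1e-4)
  }
})

test_that("output weights equal the closed-form ridge solution", {
  set.seed(33)
  for (i in 1:100) {
    E <- matrix(rnorm(50 * 10), 50)
    y <- matrix(rnorm(50 * 3), 50)
    C <- 10^runif(1, -9, 1)
    W <- solve_output_weights(E, y, C)
    oracle <- solve(t(E) %*% E + C * diag(10)) %*% t(E) %*% y
    expect_lt(max(abs(W - oracle)), 1e-8)
  }
  # orthogonal E with C -> 0 gives W = E'y
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  y <- matrix(rnorm(8 * 2), 8)
  expect_equal(solve_output_weights(Q, y, 1e-14), t(Q) %*% y, tolerance = 1e-9)
  expect_error(solve_output_weights(matrix(c(1, NA), 1, 2), matrix(1)), "non-finite")
})

test_that("enhancement pre-activations scale exactly to the shrinkage parameter", {
  set.seed(34)
  F <- matrix(rnorm(80 * 6), 80)
  y <- factor(rep(c("a", "b"), 40))
  cfg <- bls_config(N1 = 4, N2 = 3, N3 = 20, seed = 2)
  model <- suppressWarnings(bls_fit(F, y, cfg))
  # rebuild the training pre-activation with the stored weights
  Fz <- zscore_apply(F, model$mu, model$sigma)
  F2 <- cbind(Fz, 1)
  A <- do.call(cbind, lapply(model$WA, function(w) F2 %*% w))
  pre <- cbind(A, 1) %*% model$W_enh * model$s_scale
  expect_equal(max(abs(pre)), cfg$S, tolerance = 1e-9)
  B <- tansig(pre)
  expect_true(all(abs(B) <= 1))  # saturates to +/-1 in floating point at |t| = S
})

test_that("the orthonormalized enhancement matrix has orthonormal columns when tall", {
  set.seed(35)
  cfg <- bls_config(N1 = 5, N2 = 4, N3 = 10, seed = 9)  # N3 < N1 N2 + 1: tall
  F <- matrix(rnorm(60 * 6), 60)
  y <- factor(rep(c("a", "b"), 30))
  model <- suppressWarnings(bls_fit(F, y, cfg))
  expect_equal(crossprod(model$W_enh), diag(cfg$N3), tolerance = 1e-9)
})

test_that("separable classes are classified nearly perfectly and prediction is deterministic", {
  set.seed(36)
  n <- 120
  F <- rbind(matrix(rnorm(n / 2 * 4, mean = 2), n / 2),
             matrix(rnorm(n / 2 * 4, mean = -2), n / 2))
  y <- factor(rep(c("pos", "neg"), each = n / 2))
  model <- suppressWarnings(bls_fit(F, y, bls_config(N3 = 50, seed = 4)))
  Fte <- rbind(matrix(rnorm(200 * 4, mean = 2), 200),
               matrix(rnorm(200 * 4, mean = -2), 200))
  yte <- factor(rep(c("pos", "neg"), each = 200))
  pred <- bls_predict(model, Fte)
  expect_gt(mean(pred$label$class == yte), 0.95)
  # bitwise determinism
  pred2 <- bls_predict(model, Fte)
  expect_identical(pred$label$scores, pred2$label$scores)
  model2 <- suppressWarnings(bls_fit(F, y, bls_config(N3 = 50, seed = 4)))
  expect_identical(model$W, model2$W)
  # permutation equivariance over rows
  perm <- sample(nrow(Fte))
  expect_equal(bls_predict(model, Fte[perm, ])$label$scores, pred$label$scores[perm, ],
               tolerance = 1e-12)
  expect_error(bls_predict(model, Fte[, 1:2]), "mismatch")
})

test_that("multi-task fitting shares nodes and yields one weight matrix per task", {
  set.seed(37)
  F <- matrix(rnorm(60 * 5), 60)
  ys <- list(valence = factor(sample(c("low", "high"), 60, TRUE)),
             arousal = factor(sample(c("low", "high"), 60, TRUE)))
  model <- suppressWarnings(bls_fit(F, ys, bls_config(N3 = 30, seed = 6)))
  expect_named(model$W, c("valence", "arousal"))
  pred <- bls_predict(model, F)
  expect_named(pred, c("valence", "arousal"))
  expect_equal(levels(pred$valence$class), c("high", "low"))
})
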