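#' Broad learning system configuration
#'
#' The flat-network classifier: `N2` groups of `N1` random feature nodes,
#' each group's uniform [-1, 1] random weights refined into sparse compact
#' nodes by a lasso autoencoder; `N3` tansig enhancement nodes driven by an
#' orthonormalized random matrix with shrinkage `S`; output weights solved
#' in closed form by ridge pseudo-inverse with regularizer `C`. No gradient
#' descent is used anywhere.
#'
#' Canonical values: shrinkage `S = 1200`, ridge `C = 2^-30`, lasso
#' `lambda = 1e-3`. Node counts `N1 = 10`, `N2 = 10`, `N3 = 500` follow
#' common broad-learning practice and are configurable.
#'
#' @param N1 nodes per feature-node group
#' @param N2 number of feature-node groups
#' @param N3 number of enhancement nodes
#' @param S shrinkage scale of the enhancement pre-activation
#' @param C ridge regularization of the output weights
#' @param lambda lasso penalty of the sparse-autoencoder refinement
#' @param admm_iters iteration budget of the ADMM lasso solver
#' @param seed integer seed for the random node weights
#' @return a `bls_config` list
#' @export
bls_config <- function(N1 = 10L, N2 = 10L, N3 = 500L, S = 1200, C = 2^-30,
                       lambda = 1e-3, admm_iters = 100L, seed = 1L) {
  stopifnot(N1 >= 1, N2 >= 1, N3 >= 1, S > 0, C > 0, lambda >= 0)
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2), N3 = as.integer(N3),
                 S = S, C = C, lambda = lambda, admm_iters = as.integer(admm_iters),
                 seed = as.integer(seed)),
            class = "bls_config")
}

#' Fit z-score parameters and transform
#'
#' Per-column `(x - mu) / sigma` with training mean and (sample) standard
#' deviation; constant columns pass through as zeros with a warning. Test
#' data must reuse the training parameters via [zscore_apply()].
#'
#' @param F numeric matrix with >= 2 rows
#' @return list: `x` (normalized matrix), `mu`, `sigma`
#' @export
zscore_fit <- function(F) {
  stopifnot(nrow(F) >= 2)
  mu <- colMeans(F)
  sigma <- apply(F, 2, stats::sd)
  if (any(sigma == 0)) {
    warn_emofuse("bls", "%d constant feature column(s) pass through as zeros",
                 sum(sigma == 0))
  }
  list(x = zscore_apply(F, mu, sigma), mu = mu, sigma = sigma)
}

#' Apply stored z-score parameters
#' @param F numeric matrix
#' @param mu,sigma training means and standard deviations
#' @return normalized matrix (constant columns map to zero)
#' @export
zscore_apply <- function(F, mu, sigma) {
  s <- ifelse(sigma == 0, 1, sigma)
  out <- sweep(sweep(F, 2, mu), 2, s, `/`)
  out[, sigma == 0] <- 0
  out
}

#' Sparse-autoencoder refinement of random feature weights
#'
#' Solves the multi-response lasso
#' `min_W || Z W - B ||_F^2 + lambda * ||W||_1` by ADMM (scaled form,
#' rho = 1) with a fixed iteration budget, where `Z = F'' W'` is the
#' random projection of the augmented features and `B = F''`. The solution
#' (transposed) replaces the raw random weights with sparse, compact
#' feature-node weights.
#'
#' @param Z n x N1 projected features
#' @param B n x d target (the augmented feature matrix)
#' @param lambda lasso penalty
#' @param iters iteration budget (default 100)
#' @param rho ADMM penalty parameter (default 1)
#' @param tol primal/dual residual tolerance for early exit
#' @return N1 x d weight matrix; if the budget is exhausted before the
#'   residuals drop below `tol`, the last iterate is returned with a
#'   warning
#' @export
sparse_autoencoder_refine <- function(Z, B, lambda, iters = 100L, rho = 1, tol = 1e-4) {
  p <- ncol(Z)
  ZtZ <- crossprod(Z)
  ZtB <- crossprod(Z, B)
  ch <- chol(2 * ZtZ + rho * diag(p))
  Wz <- matrix(0, p, ncol(B))
  U <- matrix(0, p, ncol(B))
  soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)
  converged <- FALSE
  for (it in seq_len(iters)) {
    Wx <- backsolve(ch, forwardsolve(t(ch), 2 * ZtB + rho * (Wz - U)))
    Wz_new <- soft(Wx + U, lambda / rho)
    U <- U + Wx - Wz_new
    r_primal <- sqrt(sum((Wx - Wz_new)^2))
    r_dual <- rho * sqrt(sum((Wz_new - Wz)^2))
    Wz <- Wz_new
    if (r_primal < tol && r_dual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn_emofuse("bls", "ADMM lasso did not converge within %d iterations; returning last iterate",
                 iters)
  }
  Wz
}

# orthonormalize: columns when tall, rows when wide (the enhancement matrix
# typically has more nodes than input dimensions)
orthonormalize <- function(M) {
  if (nrow(M) >= ncol(M)) qr.Q(qr(M)) else t(qr.Q(qr(t(M))))
}

#' Solve BLS output weights by ridge pseudo-inverse
#'
#' `W = (E'E + C I)^(-1) E' y` with the identity on the feature dimension;
#' multiclass targets enter as one-hot columns. Computed through the
#' eigendecomposition of the Gram matrix `E'E`, dropping directions in the
#' numerical null space of `E`: with the canonical `C = 2^-30` those
#' directions would be amplified by `1/C` yet carry only rounding noise.
#'
#' @param E n x p node matrix
#' @param y n x k one-hot (or numeric) target matrix
#' @param C ridge regularizer (default 2^-30)
#' @return p x k weight matrix
#' @export
solve_output_weights <- function(E, y, C = 2^-30) {
  if (!all(is.finite(E))) stop_emofuse("bls", "non-finite values in node matrix")
  y <- as.matrix(y)
  stopifnot(nrow(E) == nrow(y))
  G <- crossprod(E)
  e <- eigen(G, symmetric = TRUE)
  # directions numerically in the null space of E carry no signal; their
  # 1/C amplification would only inject rounding noise, so drop them
  keep <- e$values > max(e$values) * 1e-12
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (crossprod(V, crossprod(E, y)) / (e$values[keep] + C))
}

# build feature + enhancement nodes; training mode fits the refinement and
# the shrinkage scale, prediction mode reuses them
bls_nodes <- function(Fz, model, fit = FALSE) {
  cfg <- model$config
  F2 <- cbind(Fz, 1)
  A <- matrix(0, nrow(F2), cfg$N1 * cfg$N2)
  for (i in seq_len(cfg$N2)) {
    if (fit) {
      set.seed(derive_seed(cfg$seed, paste0("feature_group_", i)))
      Wp <- matrix(stats::runif(ncol(F2) * cfg$N1, -1, 1), ncol(F2), cfg$N1)
      Z <- F2 %*% Wp
      WA <- t(sparse_autoencoder_refine(Z, F2, cfg$lambda, cfg$admm_iters))
      model$WA[[i]] <- WA
    }
    A[, (i - 1) * cfg$N1 + seq_len(cfg$N1)] <- F2 %*% model$WA[[i]]
  }
  Ap <- cbind(A, 1)
  if (fit) {
    set.seed(derive_seed(cfg$seed, "enhancement"))
    W2 <- matrix(stats::runif(ncol(Ap) * cfg$N3, -1, 1), ncol(Ap), cfg$N3)
    model$W_enh <- orthonormalize(W2)
    pre <- Ap %*% model$W_enh
    mx <- max(abs(pre))
    if (mx == 0) stop_emofuse("bls", "enhancement pre-activation is identically zero")
    model$s_scale <- cfg$S / mx
  } else {
    pre <- Ap %*% model$W_enh
  }
  B <- tansig(pre * model$s_scale)
  list(model = model, E = cbind(A, B))
}

#' Fit a broad learning system classifier
#'
#' Z-score normalizes the features (training parameters stored), builds
#' sparse-refined random feature nodes and tansig enhancement nodes, and
#' solves the output weights by ridge pseudo-inverse; training is entirely
#' closed-form plus the ADMM lasso refinement. `y` may be a single factor
#' or a named list of factors (e.g. valence and arousal targets): the node
#' construction is shared and one output-weight matrix is solved per task.
#'
#' @param F n x d feature matrix
#' @param y factor of length n, or named list of such factors
#' @param config a [bls_config()]
#' @return an `emofuse_bls` model
#' @export
bls_fit <- function(F, y, config = bls_config()) {
  F <- as.matrix(F)
  tasks <- if (is.list(y)) y else list(label = y)
  tasks <- lapply(tasks, as.factor)
  stopifnot(all(vapply(tasks, length, 0L) == nrow(F)))
  zs <- zscore_fit(F)
  model <- structure(list(config = config, mu = zs$mu, sigma = zs$sigma,
                          WA = vector("list", config$N2)),
                     class = "emofuse_bls")
  nd <- bls_nodes(zs$x, model, fit = TRUE)
  model <- nd$model
  model$W <- lapply(tasks, function(yy) {
    onehot <- stats::model.matrix(~ yy - 1)
    colnames(onehot) <- levels(yy)
    solve_output_weights(nd$E, onehot, config$C)
  })
  model$classes <- lapply(tasks, levels)
  model
}

#' Predict with a fitted broad learning system
#'
#' Applies the stored z-score parameters, rebuilds the nodes with the
#' stored refined weights and shrinkage scale, and returns per-class
#' scores `E W` with argmax-decoded classes for each task.
#'
#' @param model an `emofuse_bls` model
#' @param F n x d feature matrix (same columns as at fit time)
#' @return named list per task: `scores` (n x n_classes) and `class`
#'   (factor)
#' @export
bls_predict <- function(model, F) {
  F <- as.matrix(F)
  if (ncol(F) != length(model$mu)) {
    stop_emofuse("bls", "feature dimension mismatch: got %d, model expects %d",
                 ncol(F), length(model$mu))
  }
  Fz <- zscore_apply(F, model$mu, model$sigma)
  E <- bls_nodes(Fz, model, fit = FALSE)$E
  lapply(stats::setNames(names(model$W), names(model$W)), function(task) {
    sc <- E %*% model$W[[task]]
    cls <- factor(model$classes[[task]][max.col(sc, ties.method = "first")],
                  levels = model$classes[[task]])
    list(scores = sc, class = cls)
  })
}
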