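#' Fit regularized CCA between two modalities' latent codes
#'
#' Whitened-SVD canonical correlation analysis with additive-identity
#' covariance regularization. Columns are mean-centered (training means are
#' stored and reused at transform time), covariances are
#' `S_jj = phi_j' phi_j / (m - 1) + reg * I` and the cross-covariance
#' `C_12 = phi_1' phi_2 / (m - 1)`. Whitening operators
#' `S_jj^{-1/2} = V_j D_j V_j'` are built from the `k` largest eigenpairs
#' (`D_j` diagonal of inverse square-root eigenvalues), the whitened
#' cross-covariance is decomposed by SVD, and the projections are
#' `H1 = S_11^{-1/2} U'`, `H2 = S_22^{-1/2} V'` from the first K singular
#' vector pairs. The identity regularizer shrinks the canonical
#' correlations, so even identical inputs give correlations slightly
#' below 1.
#'
#' Sign convention: each singular pair is flipped so the largest-magnitude
#' element of U's column is positive.
#'
#' @param phi1,phi2 m x omega latent matrices (same row index)
#' @param K number of canonical pairs to keep
#' @param reg identity regularization multiplier (default 1, as used for
#'   stability with few instances per stimulus)
#' @param k_whiten eigenpairs kept for whitening (default `K`; eigenvalues
#'   below 1e-10 are dropped)
#' @param center mean-center columns before covariances (default TRUE)
#' @return a `cca_projection`: `H1`, `H2` (omega x K), `cor` (K canonical
#'   correlations, non-increasing), centering means, `n_fit`
#' @export
fit_cca <- function(phi1, phi2, K, reg = 1, k_whiten = K, center = TRUE) {
  stopifnot(is.matrix(phi1), is.matrix(phi2), nrow(phi1) == nrow(phi2))
  m <- nrow(phi1)
  if (m < 2) stop_emofuse("cca", "need at least 2 instances to fit (got %d)", m)
  w1 <- ncol(phi1); w2 <- ncol(phi2)
  mu1 <- if (center) colMeans(phi1) else numeric(w1)
  mu2 <- if (center) colMeans(phi2) else numeric(w2)
  p1 <- sweep(phi1, 2, mu1)
  p2 <- sweep(phi2, 2, mu2)
  S11 <- crossprod(p1) / (m - 1) + reg * diag(w1)
  S22 <- crossprod(p2) / (m - 1) + reg * diag(w2)
  C12 <- crossprod(p1, p2) / (m - 1)

  inv_sqrt <- function(S, k) {
    e <- eigen(S, symmetric = TRUE)
    keep <- which(e$values > 1e-10)
    keep <- keep[seq_len(min(k, length(keep)))]
    e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep]))
  }
  W1 <- inv_sqrt(S11, k_whiten)
  W2 <- inv_sqrt(S22, k_whiten)
  sv <- svd(W1 %*% C12 %*% W2)
  K_eff <- min(K, sum(sv$d > 1e-12))
  if (K_eff < K) {
    warn_emofuse("cca", "only %d positive canonical pairs available; K reduced from %d",
                 K_eff, K)
  }
  U <- sv$u[, seq_len(K_eff), drop = FALSE]
  V <- sv$v[, seq_len(K_eff), drop = FALSE]
  for (i in seq_len(K_eff)) {
    if (U[which.max(abs(U[, i])), i] < 0) {
      U[, i] <- -U[, i]
      V[, i] <- -V[, i]
    }
  }
  structure(list(H1 = W1 %*% U, H2 = W2 %*% V,
                 cor = sv$d[seq_len(K_eff)], mu1 = mu1, mu2 = mu2,
                 K = K_eff, n_fit = m),
            class = "cca_projection")
}

#' Project latent codes through a fitted CCA
#'
#' Exactly linear (after centering with the stored training means):
#' `[phi1 H1, phi2 H2]`, an m x 2K block of correlation-based features.
#'
#' @param projection a [fit_cca()] result
#' @param phi1,phi2 m x omega latent matrices
#' @return m x 2K feature matrix
#' @export
cca_transform <- function(projection, phi1, phi2) {
  stopifnot(inherits(projection, "cca_projection"))
  if (ncol(phi1) != nrow(projection$H1) || ncol(phi2) != nrow(projection$H2)) {
    stop_emofuse("cca", "latent dimension mismatch: got %d/%d, projection expects %d/%d",
                 ncol(phi1), ncol(phi2), nrow(projection$H1), nrow(projection$H2))
  }
  if (nrow(phi1) == 0) return(matrix(0, 0, 2 * projection$K))
  cbind(sweep(phi1, 2, projection$mu1) %*% projection$H1,
        sweep(phi2, 2, projection$mu2) %*% projection$H2)
}

#' Per-stimulus CCA fit and transform
#'
#' Instances are grouped by video stimulus; for each stimulus the CCA is
#' fit on the training-split instances only and then used to transform all
#' (training and test) instances of that stimulus, assembling the fused
#' feature matrix F (n x 2K). Fitting on held-out subjects would leak the
#' test distribution into the projections, so `train_idx`/`test_idx` are
#' checked for disjointness and a test stimulus never seen in training is
#' a protocol error.
#'
#' @param phi1,phi2 n x omega latent matrices for the two modalities
#' @param stimulus length-n stimulus id per instance
#' @param K canonical pairs per stimulus
#' @param train_idx integer/logical index of training instances (default:
#'   all)
#' @param test_idx optional index of test instances, used for the
#'   leakage assertion
#' @param reg identity regularization multiplier
#' @return list: `features` (n x 2K matrix), `projections` (named list of
#'   `cca_projection` per stimulus)
#' @export
fit_transform_by_stimulus <- function(phi1, phi2, stimulus, K,
                                      train_idx = seq_len(nrow(phi1)),
                                      test_idx = NULL, reg = 1) {
  n <- nrow(phi1)
  stopifnot(nrow(phi2) == n, length(stimulus) == n)
  if (is.logical(train_idx)) train_idx <- which(train_idx)
  if (is.logical(test_idx)) test_idx <- which(test_idx)
  if (!is.null(test_idx) && length(intersect(train_idx, test_idx))) {
    stop_emofuse("cca", "leakage: train and test indices overlap (%d instances)",
                 length(intersect(train_idx, test_idx)))
  }
  is_train <- logical(n)
  is_train[train_idx] <- TRUE
  feats <- matrix(0, n, 2 * K)
  projections <- list()
  for (st in unique(as.character(stimulus))) {
    rows <- which(as.character(stimulus) == st)
    tr <- rows[is_train[rows]]
    if (!length(tr)) {
      stop_emofuse("cca", "stimulus '%s' has no training instances (protocol violation)", st)
    }
    proj <- fit_cca(phi1[tr, , drop = FALSE], phi2[tr, , drop = FALSE], K, reg = reg)
    block <- cca_transform(proj, phi1[rows, , drop = FALSE], phi2[rows, , drop = FALSE])
    if (ncol(block) < 2 * K) {
      # a stimulus with fewer positive pairs pads with zero columns
      kk <- ncol(block) / 2
      padded <- matrix(0, length(rows), 2 * K)
      padded[, seq_len(kk)] <- block[, seq_len(kk), drop = FALSE]
      padded[, K + seq_len(kk)] <- block[, kk + seq_len(kk), drop = FALSE]
      block <- padded
    }
    feats[rows, ] <- block
    projections[[st]] <- proj
  }
  list(features = feats, projections = projections)
}
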