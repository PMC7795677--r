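#' Specification of the two-layer convolutional autoencoder
#'
#' Encoder: a 1 x C channel-fusion convolution (linear) collapses the C
#' channels at every time step, then a temporal convolution with kernel
#' length `kernel` and `latent_dim / L` filters (ReLU, length-preserving
#' padding) whose output flattens to exactly `latent_dim` values. Decoder:
#' a temporal convolution over the reshaped code maps with C filters and a
#' sigmoid output, reconstructing the L x C instance in (0, 1). The
#' structure is deliberately shallow (two encoder layers) because a 2 s
#' instance carries little information and deeper encoders overfit.
#'
#' Defaults follow the standard hyperparameter rules: latent dimension
#' `2 * L`, kernel `L / 4`.
#'
#' @param L instance length in samples
#' @param C number of channels in the modality
#' @param latent_dim latent code dimension (default `2 * L`; must be a
#'   multiple of `L`, the filter-count factorization)
#' @param kernel temporal kernel length (default `max(1, round(L/4))`)
#' @param max_epochs training epoch cap (default 30; early stopping is
#'   the intended termination)
#' @param patience early-stopping patience on validation loss (default 5)
#' @param min_delta smallest validation-loss improvement that resets the
#'   patience counter (default 1e-4)
#' @param val_fraction validation fraction (default 0.1)
#' @param batch_size minibatch size; `NULL` (default) chooses
#'   `max(32, min(128, n_train / 64))`, giving small datasets enough
#'   updates per epoch and large ones efficient batches
#' @param seed integer seed for initialization and splits
#' @return an `ae_spec` list
#' @export
ae_spec <- function(L, C, latent_dim = 2L * L, kernel = max(1L, as.integer(round(L / 4))),
                    max_epochs = 30L, patience = 5L, min_delta = 2e-4,
                    val_fraction = 0.1, batch_size = NULL, seed = 1L) {
  stopifnot(L >= 2, C >= 1, latent_dim > 0, kernel >= 1)
  nf <- latent_dim / L
  if (abs(nf - round(nf)) > 1e-9) {
    stop_emofuse("autoencoder",
                 "latent_dim %d is not achievable: it must factor as n_filters * L (L = %d)",
                 latent_dim, L)
  }
  structure(list(L = as.integer(L), C = as.integer(C),
                 latent_dim = as.integer(latent_dim), kernel = as.integer(kernel),
                 n_filters = as.integer(round(nf)),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 min_delta = min_delta, val_fraction = val_fraction,
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ae_spec")
}

#' Closed-form parameter count of the autoencoder
#'
#' Channel fusion `C + 1`, temporal convolution `kernel * n_filters +
#' n_filters`, decoder `kernel * n_filters * C + C`.
#'
#' @param spec an [ae_spec()]
#' @return integer parameter count
#' @export
ae_param_count <- function(spec) {
  with(spec, (C + 1L) + (kernel * n_filters + n_filters) +
         (kernel * n_filters * C + C))
}


#' Build an untrained autoencoder
#'
#' Initializes weights (Glorot-uniform, seeded) for the channel-fusion
#' layer, the temporal convolution and the decoder.
#'
#' @param spec an [ae_spec()]
#' @return an `emofuse_ae` model (untrained)
#' @export
ae_build <- function(spec) {
  stopifnot(inherits(spec, "ae_spec"))
  set.seed(derive_seed(spec$seed, "ae_init"))
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  w <- list(
    w1 = glorot(spec$C, spec$C, 1),
    b1 = 0,
    k2 = matrix(glorot(spec$kernel * spec$n_filters, spec$kernel, spec$kernel),
                spec$kernel, spec$n_filters),
    b2 = rep(0.1, spec$n_filters),
    kd = array(glorot(spec$kernel * spec$n_filters * spec$C,
                      spec$kernel * spec$n_filters, spec$kernel),
               dim = c(spec$kernel, spec$n_filters, spec$C)),
    bd = numeric(spec$C))
  structure(list(spec = spec, weights = w, trained = FALSE, history = NULL,
                 pad = (spec$kernel - 1L) %/% 2L),
            class = "emofuse_ae")
}

# split an n x L x C array into per-channel matrices plus the flat target
ae_split_input <- function(X, spec) {
  stopifnot(length(dim(X)) == 3, dim(X)[2] == spec$L, dim(X)[3] == spec$C)
  Xc <- lapply(seq_len(spec$C), function(c) X[, , c, drop = TRUE])
  if (dim(X)[1] == 1) Xc <- lapply(Xc, function(v) matrix(v, 1))
  list(Xc = Xc, Xflat = do.call(cbind, Xc))
}

# forward pass; returns codes, reconstruction and intermediates for backprop
# (temporal convolutions run in compiled code, see src/conv.cpp)
ae_forward <- function(model, Xc) {
  sp <- model$spec
  w <- model$weights
  pad <- model$pad
  Y <- w$b1
  for (c in seq_len(sp$C)) Y <- Y + Xc[[c]] * w$w1[c]
  if (!is.matrix(Y)) Y <- matrix(Y, nrow(Xc[[1]]), sp$L)
  Zpre <- vector("list", sp$n_filters)
  Z <- vector("list", sp$n_filters)
  for (f in seq_len(sp$n_filters)) {
    Zpre[[f]] <- conv_band_apply(Y, w$k2[, f], pad, FALSE) + w$b2[f]
    Z[[f]] <- pmax(Zpre[[f]], 0)
  }
  Zcat <- do.call(cbind, Z)
  P <- matrix(0, nrow(Y), sp$L * sp$C)
  for (j in seq_len(sp$C)) {
    cols <- (j - 1) * sp$L + seq_len(sp$L)
    acc <- w$bd[j]
    for (f in seq_len(sp$n_filters)) {
      acc <- acc + conv_band_apply(Z[[f]], w$kd[, f, j], pad, FALSE)
    }
    P[, cols] <- acc
  }
  R <- sigmoid(P)
  list(Y = Y, Zpre = Zpre, Z = Z, Zcat = Zcat, R = R)
}

#' Binary cross-entropy reconstruction loss
#'
#' `-(1 / (n * L * C)) * sum[x log(eta) + (1 - x) log(1 - eta)]`, averaged
#' over instances, time samples and channels so the loss scale is invariant
#' to instance size. Reconstructions are clipped away from 0 and 1 by
#' `eps`.
#'
#' @param x target batch (values in [0, 1]); any numeric array
#' @param eta reconstruction batch, same shape
#' @param eps clipping epsilon (default 1e-7)
#' @return scalar loss
#' @export
bce_loss <- function(x, eta, eps = 1e-7) {
  if (!identical(dim(x), dim(eta)) || length(x) != length(eta)) {
    stop_emofuse("autoencoder", "shape mismatch between target and reconstruction")
  }
  eta <- pmin(pmax(eta, eps), 1 - eps)
  -mean(x * log(eta) + (1 - x) * log(1 - eta))
}

# loss and analytic gradients for one batch, fused in compiled code
ae_loss_grad <- function(model, Xc, Xflat) {
  sp <- model$spec
  w <- model$weights
  st <- ae_batch_step_cpp(Xflat, sp$L, sp$C, w$w1, w$b1, w$k2, w$b2,
                          as.numeric(w$kd), w$bd, model$pad)
  list(loss = st$loss,
       grad = list(w1 = st$w1, b1 = st$b1, k2 = st$k2, b2 = st$b2,
                   kd = st$kd, bd = st$bd))
}

# reference R implementation of the same step (kept for gradient checking)
ae_loss_grad_ref <- function(model, Xc, Xflat) {
  sp <- model$spec
  w <- model$weights
  pad <- model$pad
  fw <- ae_forward(model, Xc)
  loss <- bce_loss(Xflat, fw$R)
  # d loss / d pre-sigmoid = (R - X) / (n L C)
  dP <- (fw$R - Xflat) / length(Xflat)
  g <- list(w1 = numeric(sp$C), b1 = 0,
            k2 = matrix(0, sp$kernel, sp$n_filters), b2 = numeric(sp$n_filters),
            kd = array(0, dim = c(sp$kernel, sp$n_filters, sp$C)),
            bd = numeric(sp$C))
  dZ <- vector("list", sp$n_filters)
  for (f in seq_len(sp$n_filters)) dZ[[f]] <- 0
  for (j in seq_len(sp$C)) {
    cols <- (j - 1) * sp$L + seq_len(sp$L)
    dPj <- dP[, cols, drop = FALSE]
    g$bd[j] <- sum(dPj)
    for (f in seq_len(sp$n_filters)) {
      g$kd[, f, j] <- conv_kernel_grad_cpp(fw$Z[[f]], dPj, sp$kernel, pad)
      dZ[[f]] <- dZ[[f]] + conv_band_apply(dPj, w$kd[, f, j], pad, TRUE)
    }
  }
  dY <- 0
  for (f in seq_len(sp$n_filters)) {
    dZpre <- dZ[[f]] * (fw$Zpre[[f]] > 0)
    g$b2[f] <- sum(dZpre)
    g$k2[, f] <- conv_kernel_grad_cpp(fw$Y, dZpre, sp$kernel, pad)
    dY <- dY + conv_band_apply(dZpre, w$k2[, f], pad, TRUE)
  }
  for (c in seq_len(sp$C)) g$w1[c] <- sum(Xc[[c]] * dY)
  g$b1 <- sum(dY)
  list(loss = loss, grad = g)
}

#' Train the autoencoder
#'
#' Minibatch training with the adadelta update (rho 0.95, eps 1e-6; no
#' learning-rate tuning required) minimizing binary cross-entropy
#' reconstruction. Training stops at `max_epochs` or when validation loss
#' has not improved for `patience` epochs; the best-validation weights are
#' kept. The validation split is taken by subject where possible so
#' early stopping never sees instances of training subjects.
#'
#' @param model an untrained [ae_build()] model
#' @param X n x L x C instance array with values in [0, 1]
#' @param subjects optional per-instance subject ids for the split
#' @return the trained model, with a `history` data.frame (epoch,
#'   train_loss, val_loss)
#' @export
ae_train <- function(model, X, subjects = NULL) {
  sp <- model$spec
  n <- dim(X)[1]
  if (n < 2) stop_emofuse("autoencoder", "need at least 2 instances to train")
  set.seed(derive_seed(sp$seed, "ae_train"))
  # validation split, by subject where possible
  if (!is.null(subjects) && length(unique(subjects)) > 1) {
    subj <- sample(unique(subjects))
    cum <- cumsum(table(subjects)[subj])
    take <- subj[seq_len(max(1, which(cum >= sp$val_fraction * n)[1]))]
    if (length(take) == length(subj)) take <- subj[1]
    val_idx <- which(subjects %in% take)
  } else {
    val_idx <- sample(n, max(1, floor(sp$val_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop_emofuse("autoencoder", "validation split left no training data")
  tr <- ae_split_input(X[tr_idx, , , drop = FALSE], sp)
  va <- ae_split_input(X[val_idx, , , drop = FALSE], sp)

  rho <- 0.95; eps <- 1e-6
  Eg2 <- rapply(model$weights, function(x) x * 0, how = "replace")
  Edx <- Eg2
  best <- list(loss = Inf, weights = model$weights)
  hist <- list()
  wait <- 0L
  n_tr <- length(tr_idx)
  batch_size <- sp$batch_size %||% max(32L, min(128L, n_tr %/% 64L))
  for (epoch in seq_len(sp$max_epochs)) {
    ord <- sample(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (b in batches) {
      bXc <- lapply(tr$Xc, function(m) m[b, , drop = FALSE])
      lg <- ae_loss_grad(model, bXc, tr$Xflat[b, , drop = FALSE])
      if (!is.finite(lg$loss)) {
        stop_emofuse("autoencoder",
                     "non-finite training loss at epoch %d (batch of %d); aborting",
                     epoch, length(b))
      }
      ep_loss <- ep_loss + lg$loss * length(b)
      for (nm in names(model$weights)) {
        gg <- lg$grad[[nm]]
        Eg2[[nm]] <- rho * Eg2[[nm]] + (1 - rho) * gg^2
        dx <- -sqrt(Edx[[nm]] + eps) / sqrt(Eg2[[nm]] + eps) * gg
        Edx[[nm]] <- rho * Edx[[nm]] + (1 - rho) * dx^2
        model$weights[[nm]] <- model$weights[[nm]] + dx
      }
    }
    val_loss <- bce_loss(va$Xflat, ae_forward(model, va$Xc)$R)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n_tr,
                                val_loss = val_loss)
    improved <- val_loss < best$loss - sp$min_delta
    if (val_loss < best$loss) best <- list(loss = val_loss, weights = model$weights)
    if (improved) {
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= sp$patience) break
    }
  }
  model$weights <- best$weights
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Encode instances into latent codes
#'
#' Row-order-preserving map from an n x L x C instance array to the
#' n x latent_dim code matrix (the flattened activations of the temporal
#' convolution layer).
#'
#' @param model a trained autoencoder
#' @param X n x L x C instance array
#' @return n x latent_dim numeric matrix
#' @export
ae_encode <- function(model, X) {
  if (!isTRUE(model$trained)) stop_emofuse("autoencoder", "model is not trained")
  sp <- model$spec
  if (dim(X)[1] == 0) return(matrix(0, 0, sp$latent_dim))
  ae_forward(model, ae_split_input(X, sp)$Xc)$Zcat
}

#' Reconstruct instances through the autoencoder
#'
#' @param model a trained autoencoder
#' @param X n x L x C instance array
#' @return n x L x C array of reconstructions in (0, 1)
#' @export
ae_reconstruct <- function(model, X) {
  if (!isTRUE(model$trained)) stop_emofuse("autoencoder", "model is not trained")
  sp <- model$spec
  R <- ae_forward(model, ae_split_input(X, sp)$Xc)$R
  array(R, dim = c(nrow(R), sp$L, sp$C))
}
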