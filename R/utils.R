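#' Derive a component seed from a master seed
#'
#' A single pipeline seed fans out to per-component seeds (autoencoder
#' initialization, random node weights, CV splits, data generation) so that
#' each component is independently reproducible. The derivation is a small
#' deterministic integer hash of the master seed and a component label, kept
#' below 2^31 so it is always a valid R seed.
#'
#' @param seed master integer seed
#' @param label character label of the component
#' @return an integer seed
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483399 + 1)
}

#' Hyperbolic-tangent sigmoid
#'
#' `tansig(t) = 2/(1 + exp(-2t)) - 1`, the activation used for the
#' enhancement nodes of the broad learning system. Identical to `tanh` but
#' written in its conventional BLS form.
#'
#' @param t numeric vector or matrix
#' @return values in (-1, 1)
#' @export
tansig <- function(t) 2 / (1 + exp(-2 * t)) - 1

sigmoid <- function(t) 1 / (1 + exp(-t))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emofuse <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

warn_emofuse <- function(stage, ...) {
  warning(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}
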