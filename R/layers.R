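# User-facing single-instance layer operations. These wrap the compiled
# batched kernels with batch size one; the training path in model.R calls
# the kernels directly on (T, C, B) arrays.

as_cube <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  array(x, dim = c(nrow(x), ncol(x), 1L))
}

from_cube <- function(a) matrix(a, nrow = dim(a)[1], ncol = dim(a)[2])

#' Causal 1-D convolution
#'
#' `F(t) = sum_{i=0}^{k-1} f(i) x(t - i)` with implicit zeros for `t <= 0`:
#' each output depends only on current and past inputs.
#'
#' @param x Numeric input vector.
#' @param f Numeric kernel (tap 1 multiplies the current sample).
#' @return Vector of the same length as `x`.
#' @examples
#' causal_conv(c(1, 2, 3), c(0, 1))  # unit delay: 0 1 2
#' @export
causal_conv <- function(x, f) dilated_causal_conv(x, f, d = 1L)

#' Dilated causal 1-D convolution
#'
#' `F(s) = sum_{i=0}^{k-1} f(i) x(s - d i)`, zero-padded on the past side;
#' `d = 1` reduces to [causal_conv()]. Dilation spaces the taps so stacked
#' layers grow their receptive field exponentially.
#'
#' @inheritParams causal_conv
#' @param d Integer dilation factor (>= 1).
#' @return Vector of the same length as `x`.
#' @export
dilated_causal_conv <- function(x, f, d) {
  assert_that(length(f) >= 1, "kernel must have at least one tap")
  assert_that(d >= 1, "dilation must be at least 1")
  W <- array(f, dim = c(1L, 1L, length(f)))
  as.numeric(cpp_conv1d_fw(as_cube(x), W, 0, as.integer(d)))
}

#' Largest feasible attention head count
#'
#' Returns the largest `h' <= requested` that divides the feature
#' dimension, so each head gets an equal subspace; always at least 1.
#'
#' @param feature_dim Model feature dimension.
#' @param requested Requested number of heads.
#' @return Integer head count.
#' @examples
#' adjust_heads(128, 4)  # 4
#' adjust_heads(6, 4)    # 3
#' @export
adjust_heads <- function(feature_dim, requested) {
  assert_that(feature_dim >= 1 && requested >= 1,
              "`feature_dim` and `requested` must be positive")
  for (h in seq(min(requested, feature_dim), 1L)) {
    if (feature_dim %% h == 0) return(as.integer(h))
  }
  1L
}

#' Bidirectional LSTM layer
#'
#' Runs one LSTM pass left-to-right and an independent pass right-to-left
#' (zero initial states) and concatenates the hidden states per time step,
#' so each output row carries both past and future context.
#'
#' @param x Numeric `T x D` input matrix.
#' @param fwd,bwd Parameter lists with `W` (`D x 4H`), `U` (`H x 4H`) and
#'   `b` (`4H`); gate block order along the 4H axis is input, forget,
#'   candidate, output.
#' @return `T x 2H` matrix, forward states in the first H columns.
#' @export
bilstm <- function(x, fwd, bwd) {
  assert_that(is.matrix(x), "`x` must be a T x D matrix")
  f <- cpp_lstm_fw(as_cube(x), fwd$W, fwd$U, fwd$b)
  xr <- x[rev(seq_len(nrow(x))), , drop = FALSE]
  b <- cpp_lstm_fw(as_cube(xr), bwd$W, bwd$U, bwd$b)
  hb <- from_cube(b$H)
  cbind(from_cube(f$H), hb[rev(seq_len(nrow(hb))), , drop = FALSE])
}

#' Multi-head self-attention layer
#'
#' Scaled dot-product attention in `n_heads` equal subspaces:
#' `head_i = softmax(Q_i K_i' / sqrt(d_k)) V_i`, heads concatenated and
#' mapped back through the output projection. No positional encoding is
#' applied, so permuting the rows of `x` permutes the output rows.
#'
#' @param x Numeric `T x D` input matrix.
#' @param p Parameter list with square `D x D` matrices `Wq`, `Wk`, `Wv`,
#'   `Wo` and integer `n_heads` (must divide `D`).
#' @return `T x D` matrix.
#' @export
mhsa <- function(x, p) {
  D <- ncol(x)
  assert_that(D %% p$n_heads == 0,
              "`n_heads` must divide the feature dimension (see adjust_heads)")
  out <- cpp_mhsa_fw(as_cube(x), p$Wq, p$Wk, p$Wv, p$Wo, as.integer(p$n_heads))
  from_cube(out$Y)
}

#' Per-time-step affine projection into the fusion space
#'
#' `P = F W + b` applied to every row, mapping branch features into the
#' shared fusion dimension.
#'
#' @param f Numeric `T x D_in` feature matrix.
#' @param W `D_in x D_fusion` weight matrix.
#' @param b Length-`D_fusion` bias.
#' @return `T x D_fusion` matrix.
#' @export
project_modality <- function(f, W, b) {
  assert_that(ncol(f) == nrow(W), "feature/projection dimension mismatch")
  sweep(f %*% W, 2, b, "+")
}

#' Cross-modal attention fusion
#'
#' Builds the time-by-time similarity matrix
#' `S = softmax(P_bcg P_ppg' / sqrt(D))` (row-wise softmax) and mixes the
#' modalities as `F = S P_ppg + (J - S) P_bcg`, with `J` the all-ones
#' matrix. Rows of `S` are probability distributions over the other
#' modality's time steps.
#'
#' @param p_bcg,p_ppg Numeric `T x D` projected feature matrices.
#' @return List with `fused` (`T x D`) and the similarity matrix `S`
#'   (`T x T`).
#' @export
crossmodal_fuse <- function(p_bcg, p_ppg) {
  assert_that(all(dim(p_bcg) == dim(p_ppg)),
              "both modalities must share T and D")
  out <- cpp_fuse_fw(as_cube(p_bcg), as_cube(p_ppg))
  list(fused = from_cube(out$F), S = matrix(out$S, nrow = nrow(p_bcg)))
}

#' Residual TCN block (evaluation mode)
#'
#' Pre-activation residual block: twice (ReLU -> dilated causal conv ->
#' spatial dropout), added to a skip path and rectified,
#' `o = ReLU(skip(x) + F(x))`. The skip path is the identity when input
#' and output channel counts match, else a 1x1 convolution. Spatial
#' dropout masks whole channels and is active only during training; this
#' evaluation-mode entry point applies the identity.
#'
#' @param x Numeric `T x C_in` input matrix.
#' @param p Parameter list: `conv1`, `conv2` (each `W` of dim
#'   `(C_in, C_out, k)` resp. `(C_out, C_out, k)` and bias `b`), optional
#'   `skip` (1x1 conv parameters), and `dilation`.
#' @return `T x C_out` matrix.
#' @export
tcn_block <- function(x, p) {
  xc <- as_cube(x)
  d <- as.integer(p$dilation)
  r1 <- pmax(xc, 0)
  c1 <- cpp_conv1d_fw(r1, p$conv1$W, p$conv1$b, d)
  r2 <- pmax(c1, 0)
  c2 <- cpp_conv1d_fw(r2, p$conv2$W, p$conv2$b, d)
  skip <- if (!is.null(p$skip)) cpp_conv1d_fw(xc, p$skip$W, p$skip$b, 1L) else xc
  assert_that(all(dim(skip) == dim(c2)),
              "skip projection required when channel counts differ")
  from_cube(pmax(skip + c2, 0))
}

#' Huber loss
#'
#' Quadratic for errors within `delta`, linear beyond:
#' `0.5 e^2` if `|e| <= delta`, else `delta (|e| - 0.5 delta)`; the batch
#' reduction is the mean. Robust to occasional motion-corrupted windows.
#'
#' @param y,y_hat Numeric vectors on the same scale.
#' @param delta Transition point (> 0).
#' @return Mean loss (scalar).
#' @export
huber_loss <- function(y, y_hat, delta = 1) {
  assert_that(delta > 0, "`delta` must be positive")
  e <- abs(y_hat - y)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}
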