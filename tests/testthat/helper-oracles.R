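# Literal-equation reference implementations used as independent oracles.
# Each is a direct transcription of the defining formula (scalar loops,
# no shared code with the package kernels).

oracle_causal_conv <- function(x, f, d = 1) {
  T <- length(x)
  k <- length(f)
  out <- numeric(T)
  for (t in seq_len(T)) {
    acc <- 0
    for (i in 0:(k - 1)) {
      j <- t - d * i
      if (j >= 1) acc <- acc + f[i + 1] * x[j]
    }
    out[t] <- acc
  }
  out
}

sigm <- function(z) 1 / (1 + exp(-z))

# Scalar-loop LSTM recurrence; p holds W (D x 4H), U (H x 4H), b (4H) with
# gate blocks (input, forget, candidate, output).
oracle_lstm <- function(x, p) {
  H <- nrow(p$U)
  h <- rep(0, H)
  cc <- rep(0, H)
  out <- matrix(0, nrow(x), H)
  for (t in seq_len(nrow(x))) {
    a <- as.numeric(t(p$W) %*% x[t, ] + t(p$U) %*% h + p$b)
    gi <- sigm(a[1:H])
    gf <- sigm(a[(H + 1):(2 * H)])
    gg <- tanh(a[(2 * H + 1):(3 * H)])
    go <- sigm(a[(3 * H + 1):(4 * H)])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    out[t, ] <- h
  }
  out
}

oracle_bilstm <- function(x, fwd, bwd) {
  T <- nrow(x)
  cbind(oracle_lstm(x, fwd), oracle_lstm(x[T:1, , drop = FALSE], bwd)[T:1, , drop = FALSE])
}

oracle_row_softmax <- function(m) {
  z <- exp(m - apply(m, 1, max))
  z / rowSums(z)
}

oracle_mhsa <- function(x, p) {
  D <- ncol(x)
  h <- p$n_heads
  dk <- D / h
  Q <- x %*% p$Wq
  K <- x %*% p$Wk
  V <- x %*% p$Wv
  O <- matrix(0, nrow(x), D)
  for (j in seq_len(h)) {
    cls <- ((j - 1) * dk + 1):(j * dk)
    A <- oracle_row_softmax(Q[, cls, drop = FALSE] %*% t(K[, cls, drop = FALSE]) / sqrt(dk))
    O[, cls] <- A %*% V[, cls, drop = FALSE]
  }
  O %*% p$Wo
}

oracle_project <- function(f, W, b) {
  out <- matrix(0, nrow(f), ncol(W))
  for (t in seq_len(nrow(f))) {
    for (j in seq_len(ncol(W))) {
      out[t, j] <- sum(f[t, ] * W[, j]) + b[j]
    }
  }
  out
}

oracle_fuse <- function(pb, pp) {
  T <- nrow(pb)
  D <- ncol(pb)
  S <- oracle_row_softmax(pb %*% t(pp) / sqrt(D))
  S %*% pp + (matrix(1, T, T) - S) %*% pb
}

rand_mat <- function(r, c, scale = 0.5) matrix(rnorm(r * c) * scale, r, c)

rand_lstm_params <- function(D, H) {
  list(W = rand_mat(D, 4 * H), U = rand_mat(H, 4 * H), b = rnorm(4 * H) * 0.1)
}

rand_attn_params <- function(D, h) {
  list(Wq = rand_mat(D, D), Wk = rand_mat(D, D), Wv = rand_mat(D, D),
       Wo = rand_mat(D, D), n_heads = h)
}
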