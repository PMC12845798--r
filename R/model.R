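# Dual-branch temporal fusion network. The BCG branch processes 4-channel
# windows through parallel multi-scale causal convolutions {3,5,7}, max
# pooling and a four-stage TCN (dilations 1,2,4,8); the PPG branch uses
# kernels {3,5} and a three-stage TCN (dilations 1,2,4). Each branch then
# runs a BiLSTM and multi-head self-attention, is projected into a shared
# fusion space, and the branches are mixed by cross-modal attention. Global
# average pooling and a 128 -> 64 -> 1 head regress heart rate, with a
# bounded output mapping into the physiological BPM range.

#' Model configuration
#'
#' All architectural hyperparameters plus the ablation switches. The
#' regression head expects `D_fusion` inputs, so `head_dims[1]` must equal
#' `D_fusion`. Single-modality variants bypass fusion and therefore require
#' `use_dynamic_fusion = FALSE`.
#'
#' @param bcg_kernels,ppg_kernels Integer kernel sizes of the parallel
#'   multi-scale convolutions per branch.
#' @param filters_per_kernel Output channels of each multi-scale kernel.
#' @param pool_size Max-pooling factor applied once per branch.
#' @param bcg_tcn_dilations,ppg_tcn_dilations Dilation ladder of each TCN.
#' @param tcn_channels TCN channel width.
#' @param tcn_kernel TCN kernel size.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param attn_heads Requested attention head count (adjusted down to the
#'   largest divisor of the feature dimension, see [adjust_heads()]).
#' @param D_fusion Shared fusion-space dimension.
#' @param head_dims Regression head layer widths.
#' @param dropout_p Spatial dropout probability inside TCN blocks.
#' @param use_tcn,use_bilstm,use_mhsa,use_dynamic_fusion Ablation switches.
#' @param modality `"both"`, `"bcg_only"` or `"ppg_only"`.
#' @param hr_range Output BPM range of the bounded prediction mapping.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `hr_net_config`.
#' @export
model_config <- function(bcg_kernels = c(3, 5, 7), ppg_kernels = c(3, 5),
                         filters_per_kernel = 32, pool_size = 2,
                         bcg_tcn_dilations = c(1, 2, 4, 8),
                         ppg_tcn_dilations = c(1, 2, 4),
                         tcn_channels = 128, tcn_kernel = 3,
                         lstm_hidden = 128, attn_heads = 4, D_fusion = 128,
                         head_dims = c(128, 64, 1), dropout_p = 0.1,
                         use_tcn = TRUE, use_bilstm = TRUE, use_mhsa = TRUE,
                         use_dynamic_fusion = TRUE,
                         modality = c("both", "bcg_only", "ppg_only"),
                         hr_range = c(35, 120), seed = 1L) {
  modality <- match.arg(modality)
  assert_that(head_dims[1] == D_fusion,
              "`head_dims[1]` must equal `D_fusion` (the head reads the fused features)")
  if (modality != "both" && use_dynamic_fusion) {
    stop_domain("single-modality variants have nothing to fuse: ",
                "set `use_dynamic_fusion = FALSE` for modality \"", modality, "\"")
  }
  assert_that(dropout_p >= 0 && dropout_p < 1, "`dropout_p` must be in [0, 1)")
  structure(
    list(bcg_kernels = as.integer(bcg_kernels),
         ppg_kernels = as.integer(ppg_kernels),
         filters_per_kernel = as.integer(filters_per_kernel),
         pool_size = as.integer(pool_size),
         bcg_tcn_dilations = as.integer(bcg_tcn_dilations),
         ppg_tcn_dilations = as.integer(ppg_tcn_dilations),
         tcn_channels = as.integer(tcn_channels),
         tcn_kernel = as.integer(tcn_kernel),
         lstm_hidden = as.integer(lstm_hidden),
         attn_heads = as.integer(attn_heads),
         D_fusion = as.integer(D_fusion),
         head_dims = as.integer(head_dims),
         dropout_p = dropout_p,
         use_tcn = use_tcn, use_bilstm = use_bilstm, use_mhsa = use_mhsa,
         use_dynamic_fusion = use_dynamic_fusion, modality = modality,
         hr_range = hr_range, seed = as.integer(seed)),
    class = "hr_net_config"
  )
}

#' Named ablation variants
#'
#' Convenience constructors for the standard ablation ladder: `"baseline"`
#' (multi-scale convolutions + dynamic fusion + head), `"tcn"` (+ TCN),
#' `"tcn_bilstm"` (+ TCN + BiLSTM), `"full"` (+ MHSA), `"no_fusion"` (full
#' model with plain concatenation instead of cross-modal attention), and
#' the single-modality models `"bcg_only"` / `"ppg_only"`.
#'
#' @param name Variant name.
#' @param ... Passed to [model_config()] (widths, seed, ...).
#' @return An `hr_net_config`.
#' @export
variant_config <- function(name = c("full", "baseline", "tcn", "tcn_bilstm",
                                    "no_fusion", "bcg_only", "ppg_only"),
                           ...) {
  name <- match.arg(name)
  switch(name,
    full = model_config(...),
    baseline = model_config(use_tcn = FALSE, use_bilstm = FALSE,
                            use_mhsa = FALSE, ...),
    tcn = model_config(use_bilstm = FALSE, use_mhsa = FALSE, ...),
    tcn_bilstm = model_config(use_mhsa = FALSE, ...),
    no_fusion = model_config(use_dynamic_fusion = FALSE, ...),
    bcg_only = model_config(use_dynamic_fusion = FALSE,
                            modality = "bcg_only", ...),
    ppg_only = model_config(use_dynamic_fusion = FALSE,
                            modality = "ppg_only", ...)
  )
}

# Derived dimensions of each stage for a given config.
config_dims <- function(cfg) {
  branch <- function(kernels, in_ch) {
    ms_ch <- length(kernels) * cfg$filters_per_kernel
    d <- ms_ch
    if (cfg$use_tcn) d <- cfg$tcn_channels
    if (cfg$use_bilstm) d <- 2L * cfg$lstm_hidden
    heads <- adjust_heads(d, cfg$attn_heads)
    list(in_ch = in_ch, ms_ch = ms_ch, feat = d, heads = heads)
  }
  list(bcg = branch(cfg$bcg_kernels, 4L), ppg = branch(cfg$ppg_kernels, 1L))
}

# --- initialization (uniform fan-in) ---------------------------------------

unif_init <- function(dims, fan_in) {
  array(runif(prod(dims), -1 / sqrt(fan_in), 1 / sqrt(fan_in)), dim = dims)
}

init_conv <- function(c_in, c_out, k) {
  list(W = unif_init(c(c_in, c_out, k), c_in * k), b = numeric(c_out))
}

init_lstm_dir <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias 1 eases early gradient flow
  list(W = unif_init(c(d_in, 4 * h), d_in), U = unif_init(c(h, 4 * h), h),
       b = b)
}

init_branch <- function(cfg, kernels, dilations, in_ch, bd) {
  p <- list()
  p$ms <- lapply(kernels, function(k) init_conv(in_ch, cfg$filters_per_kernel, k))
  if (cfg$use_tcn) {
    ch_in <- bd$ms_ch
    p$tcn <- lapply(seq_along(dilations), function(j) {
      blk <- list(
        conv1 = init_conv(ch_in, cfg$tcn_channels, cfg$tcn_kernel),
        conv2 = init_conv(cfg$tcn_channels, cfg$tcn_channels, cfg$tcn_kernel),
        dilation = dilations[j]
      )
      if (ch_in != cfg$tcn_channels) {
        blk$skip <- init_conv(ch_in, cfg$tcn_channels, 1L)
      }
      ch_in <<- cfg$tcn_channels
      blk
    })
  }
  d_seq <- if (cfg$use_tcn) cfg$tcn_channels else bd$ms_ch
  if (cfg$use_bilstm) {
    p$lstm_f <- init_lstm_dir(d_seq, cfg$lstm_hidden)
    p$lstm_b <- init_lstm_dir(d_seq, cfg$lstm_hidden)
  }
  if (cfg$use_mhsa) {
    D <- bd$feat
    p$attn <- list(Wq = unif_init(c(D, D), D), Wk = unif_init(c(D, D), D),
                   Wv = unif_init(c(D, D), D), Wo = unif_init(c(D, D), D))
  }
  p$proj <- list(W = unif_init(c(bd$feat, cfg$D_fusion), bd$feat),
                 b = numeric(cfg$D_fusion))
  p
}

init_params <- function(cfg, dims) {
  with_seed(cfg$seed, {
    p <- list()
    if (cfg$modality != "ppg_only") {
      p$bcg <- init_branch(cfg, cfg$bcg_kernels, cfg$bcg_tcn_dilations, 4L,
                           dims$bcg)
    }
    if (cfg$modality != "bcg_only") {
      p$ppg <- init_branch(cfg, cfg$ppg_kernels, cfg$ppg_tcn_dilations, 1L,
                           dims$ppg)
    }
    if (cfg$modality == "both" && !cfg$use_dynamic_fusion) {
      p$reduce <- list(W = unif_init(c(2L * cfg$D_fusion, cfg$D_fusion),
                                     2L * cfg$D_fusion),
                       b = numeric(cfg$D_fusion))
    }
    h <- cfg$head_dims
    p$head <- list(
      fc1 = list(W = unif_init(c(h[1], h[2]), h[1]), b = numeric(h[2])),
      fc2 = list(W = unif_init(c(h[2], h[3]), h[2]), b = numeric(h[3]))
    )
    p
  })
}

#' Build the heart-rate fusion network
#'
#' Instantiates parameters for the configured architecture (deterministic
#' under `cfg$seed`) and reports the trainable parameter count.
#'
#' @param cfg An [model_config()].
#' @return An object of class `hr_net` with elements `cfg`, `dims`,
#'   `params` and `n_params`.
#' @export
build_hr_net <- function(cfg = model_config()) {
  dims <- config_dims(cfg)
  params <- init_params(cfg, dims)
  net <- structure(
    list(cfg = cfg, dims = dims, params = params, n_params = n_params(params)),
    class = "hr_net"
  )
  message(sprintf("hr_net (%s%s): %s trainable parameters",
                  cfg$modality,
                  if (cfg$use_dynamic_fusion) ", dynamic fusion" else "",
                  format(net$n_params, big.mark = ",")))
  net
}

#' @export
print.hr_net <- function(x, ...) {
  cfg <- x$cfg
  stages <- c("multi-scale conv", if (cfg$use_tcn) "TCN",
              if (cfg$use_bilstm) "BiLSTM", if (cfg$use_mhsa) "MHSA",
              if (cfg$modality == "both") {
                if (cfg$use_dynamic_fusion) "cross-modal fusion" else "concat fusion"
              }, "head")
  cat(sprintf("<hr_net> %s | %s | %s parameters\n", cfg$modality,
              paste(stages, collapse = " -> "),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# --- cube helpers ----------------------------------------------------------

cube_slice <- function(Z, s) array(Z[, , s], dim = dim(Z)[1:2])

cube_cat <- function(lst) {
  T <- dim(lst[[1]])[1]; B <- dim(lst[[1]])[3]
  cs <- vapply(lst, function(z) dim(z)[2], integer(1))
  out <- array(0, dim = c(T, sum(cs), B))
  off <- 0L
  for (z in lst) {
    out[, off + seq_len(dim(z)[2]), ] <- z
    off <- off + dim(z)[2]
  }
  out
}

cube_affine <- function(Z, W, b) {
  T <- dim(Z)[1]; B <- dim(Z)[3]
  out <- array(0, dim = c(T, ncol(W), B))
  for (s in seq_len(B)) {
    out[, , s] <- sweep(cube_slice(Z, s) %*% W, 2, b, "+")
  }
  out
}

cube_affine_bw <- function(Z, W, dY) {
  T <- dim(Z)[1]; B <- dim(Z)[3]
  dZ <- array(0, dim = dim(Z))
  dW <- array(0, dim = dim(W))
  db <- numeric(ncol(W))
  for (s in seq_len(B)) {
    Zs <- cube_slice(Z, s); dYs <- cube_slice(dY, s)
    dZ[, , s] <- dYs %*% t(W)
    dW <- dW + t(Zs) %*% dYs
    db <- db + colSums(dYs)
  }
  list(dZ = dZ, dW = dW, db = db)
}

rev_time <- function(Z) Z[rev(seq_len(dim(Z)[1])), , , drop = FALSE]

# multiply cube (T,C,B) by a per-(channel, sample) mask (C,B)
mask_mult <- function(Z, M) {
  T <- dim(Z)[1]
  Z * aperm(array(M, dim = c(dim(M), T)), c(3, 1, 2))
}

# --- forward / backward ----------------------------------------------------

branch_forward <- function(par, X, cfg, bd, training, p_drop) {
  cache <- list(X = X)
  ms_out <- lapply(par$ms, function(cp) cpp_conv1d_fw(X, cp$W, cp$b, 1L))
  A0 <- cube_cat(ms_out)
  A1 <- pmax(A0, 0)
  cache$A0 <- A0
  pool <- cpp_maxpool_fw(A1, cfg$pool_size)
  Z <- pool$Y
  cache$pool_idx <- pool$idx
  cache$T_in <- dim(A1)[1]
  if (cfg$use_tcn) {
    cache$tcn <- list()
    for (j in seq_along(par$tcn)) {
      blk <- par$tcn[[j]]
      d <- as.integer(blk$dilation)
      bc <- list(Zin = Z)
      r1 <- pmax(Z, 0)
      bc$r1 <- r1
      c1 <- cpp_conv1d_fw(r1, blk$conv1$W, blk$conv1$b, d)
      bc$c1 <- c1
      if (training && p_drop > 0) {
        bc$m1 <- matrix(rbinom(dim(c1)[2] * dim(c1)[3], 1, 1 - p_drop),
                        dim(c1)[2]) / (1 - p_drop)
        c1 <- mask_mult(c1, bc$m1)
      }
      r2 <- pmax(c1, 0)
      bc$s1 <- c1
      bc$r2 <- r2
      c2 <- cpp_conv1d_fw(r2, blk$conv2$W, blk$conv2$b, d)
      bc$c2 <- c2
      if (training && p_drop > 0) {
        bc$m2 <- matrix(rbinom(dim(c2)[2] * dim(c2)[3], 1, 1 - p_drop),
                        dim(c2)[2]) / (1 - p_drop)
        c2 <- mask_mult(c2, bc$m2)
      }
      skip <- if (!is.null(blk$skip)) {
        cpp_conv1d_fw(Z, blk$skip$W, blk$skip$b, 1L)
      } else Z
      pre <- skip + c2
      bc$pre <- pre
      Z <- pmax(pre, 0)
      cache$tcn[[j]] <- bc
    }
  }
  if (cfg$use_bilstm) {
    cache$lstm_in <- Z
    fw <- cpp_lstm_fw(Z, par$lstm_f$W, par$lstm_f$U, par$lstm_f$b)
    Zr <- rev_time(Z)
    bw <- cpp_lstm_fw(Zr, par$lstm_b$W, par$lstm_b$U, par$lstm_b$b)
    cache$lstm_f <- fw
    cache$lstm_b <- bw
    cache$lstm_in_rev <- Zr
    Z <- cube_cat(list(fw$H, rev_time(bw$H)))
  }
  if (cfg$use_mhsa) {
    cache$attn_in <- Z
    at <- cpp_mhsa_fw(Z, par$attn$Wq, par$attn$Wk, par$attn$Wv, par$attn$Wo,
                      bd$heads)
    cache$attn <- at
    Z <- at$Y
  }
  cache$proj_in <- Z
  P <- cube_affine(Z, par$proj$W, par$proj$b)
  cache$P <- P
  cache
}

branch_backward <- function(par, cache, cfg, bd, dP) {
  g <- list()
  pb <- cube_affine_bw(cache$proj_in, par$proj$W, dP)
  g$proj <- list(W = pb$dW, b = pb$db)
  dZ <- pb$dZ
  if (cfg$use_mhsa) {
    at <- cache$attn
    ab <- cpp_mhsa_bw(cache$attn_in, par$attn$Wq, par$attn$Wk, par$attn$Wv,
                      par$attn$Wo, bd$heads, at$Q, at$K, at$V, at$O, at$A, dZ)
    g$attn <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo)
    dZ <- ab$dX
  }
  if (cfg$use_bilstm) {
    H <- cfg$lstm_hidden
    dHf <- dZ[, seq_len(H), , drop = FALSE]
    dHb <- rev_time(dZ[, H + seq_len(H), , drop = FALSE])
    fb <- cpp_lstm_bw(cache$lstm_in, par$lstm_f$W, par$lstm_f$U,
                      cache$lstm_f$H, cache$lstm_f$G, cache$lstm_f$C, dHf)
    bb <- cpp_lstm_bw(cache$lstm_in_rev, par$lstm_b$W, par$lstm_b$U,
                      cache$lstm_b$H, cache$lstm_b$G, cache$lstm_b$C, dHb)
    g$lstm_f <- list(W = fb$dW, U = fb$dU, b = fb$db)
    g$lstm_b <- list(W = bb$dW, U = bb$dU, b = bb$db)
    dZ <- fb$dX + rev_time(bb$dX)
  }
  if (cfg$use_tcn) {
    g$tcn <- vector("list", length(par$tcn))
    for (j in rev(seq_along(par$tcn))) {
      blk <- par$tcn[[j]]
      bc <- cache$tcn[[j]]
      d <- as.integer(blk$dilation)
      dpre <- dZ * (bc$pre > 0)
      gb <- list(dilation = blk$dilation)
      if (!is.null(blk$skip)) {
        sb <- cpp_conv1d_bw(bc$Zin, blk$skip$W, dpre, 1L)
        gb$skip <- list(W = sb$dW, b = sb$db)
        dZin <- sb$dX
      } else {
        dZin <- dpre
      }
      dc2 <- if (!is.null(bc$m2)) mask_mult(dpre, bc$m2) else dpre
      c2b <- cpp_conv1d_bw(bc$r2, blk$conv2$W, dc2, d)
      gb$conv2 <- list(W = c2b$dW, b = c2b$db)
      ds1 <- c2b$dX * (bc$s1 > 0)
      dc1 <- if (!is.null(bc$m1)) mask_mult(ds1, bc$m1) else ds1
      c1b <- cpp_conv1d_bw(bc$r1, blk$conv1$W, dc1, d)
      gb$conv1 <- list(W = c1b$dW, b = c1b$db)
      dZin <- dZin + c1b$dX * (bc$Zin > 0)
      g$tcn[[j]] <- gb
      dZ <- dZin
    }
  }
  dA1 <- cpp_maxpool_bw(dZ, cache$pool_idx, cache$T_in)
  dA0 <- dA1 * (cache$A0 > 0)
  g$ms <- vector("list", length(par$ms))
  off <- 0L
  for (i in seq_along(par$ms)) {
    C <- dim(par$ms[[i]]$W)[2]
    dAi <- dA0[, off + seq_len(C), , drop = FALSE]
    mb <- cpp_conv1d_bw(cache$X, par$ms[[i]]$W, dAi, 1L)
    g$ms[[i]] <- list(W = mb$dW, b = mb$db)
    off <- off + C
  }
  g
}

# Forward pass over a batch. Xb: (L, 4, B); Xp: (L, 1, B).
net_forward <- function(net, Xb, Xp, training = FALSE) {
  cfg <- net$cfg
  par <- net$params
  cache <- list()
  Ps <- list()
  if (cfg$modality != "ppg_only") {
    cache$bcg <- branch_forward(par$bcg, Xb, cfg, net$dims$bcg, training,
                                cfg$dropout_p)
    Ps$bcg <- cache$bcg$P
  }
  if (cfg$modality != "bcg_only") {
    cache$ppg <- branch_forward(par$ppg, Xp, cfg, net$dims$ppg, training,
                                cfg$dropout_p)
    Ps$ppg <- cache$ppg$P
  }
  if (cfg$modality == "both") {
    stopifnot(dim(Ps$bcg)[1] == dim(Ps$ppg)[1])
    if (cfg$use_dynamic_fusion) {
      fu <- cpp_fuse_fw(Ps$bcg, Ps$ppg)
      cache$S <- fu$S
      Fz <- fu$F
    } else {
      cache$cat_in <- cube_cat(list(Ps$bcg, Ps$ppg))
      Fz <- cube_affine(cache$cat_in, par$reduce$W, par$reduce$b)
    }
  } else {
    Fz <- Ps[[1]]
  }
  cache$Fz <- Fz
  Tf <- dim(Fz)[1]
  B <- dim(Fz)[3]
  g <- vapply(seq_len(B), function(s) colMeans(cube_slice(Fz, s)),
              numeric(dim(Fz)[2]))
  g <- matrix(g, ncol = B)
  cache$gap <- g
  h1pre <- sweep(t(par$head$fc1$W) %*% g, 1, par$head$fc1$b, "+")
  h1 <- pmax(h1pre, 0)
  cache$h1pre <- h1pre
  cache$h1 <- h1
  u <- as.numeric(t(par$head$fc2$W) %*% h1 + par$head$fc2$b)
  cache$u <- u
  pred <- cfg$hr_range[1] + diff(cfg$hr_range) * sigmoid(u)
  list(pred = pred, u = u, cache = cache)
}

# Backward pass given du = dL/du (length B).
net_backward <- function(net, cache, du) {
  cfg <- net$cfg
  par <- net$params
  B <- length(du)
  du <- matrix(du, nrow = 1)
  g <- list()
  dh1 <- (par$head$fc2$W %*% du) * (cache$h1pre > 0)
  g$head <- list(
    fc2 = list(W = cache$h1 %*% t(du), b = sum(du)),
    fc1 = list(W = cache$gap %*% t(dh1), b = rowSums(dh1))
  )
  dg <- par$head$fc1$W %*% dh1
  Tf <- dim(cache$Fz)[1]
  dF <- array(0, dim = dim(cache$Fz))
  for (s in seq_len(B)) {
    dF[, , s] <- matrix(dg[, s], nrow = Tf, ncol = nrow(dg), byrow = TRUE) / Tf
  }
  if (cfg$modality == "both") {
    if (cfg$use_dynamic_fusion) {
      fb <- cpp_fuse_bw(cache$bcg$P, cache$ppg$P, cache$S, dF)
      dPb <- fb$dPb
      dPp <- fb$dPp
    } else {
      rb <- cube_affine_bw(cache$cat_in, par$reduce$W, dF)
      g$reduce <- list(W = rb$dW, b = rb$db)
      Df <- cfg$D_fusion
      dPb <- rb$dZ[, seq_len(Df), , drop = FALSE]
      dPp <- rb$dZ[, Df + seq_len(Df), , drop = FALSE]
    }
    g$bcg <- branch_backward(par$bcg, cache$bcg, cfg, net$dims$bcg, dPb)
    g$ppg <- branch_backward(par$ppg, cache$ppg, cfg, net$dims$ppg, dPp)
  } else if (cfg$modality == "bcg_only") {
    g$bcg <- branch_backward(par$bcg, cache$bcg, cfg, net$dims$bcg, dF)
  } else {
    g$ppg <- branch_backward(par$ppg, cache$ppg, cfg, net$dims$ppg, dF)
  }
  g[names(par)]
}

# Assemble window tibble rows into model input arrays.
windows_to_arrays <- function(windows) {
  B <- nrow(windows)
  assert_that(B >= 1, "no windows to assemble")
  L <- length(windows$ppg[[1]])
  Xb <- array(0, dim = c(L, 4L, B))
  Xp <- array(0, dim = c(L, 1L, B))
  for (s in seq_len(B)) {
    Xb[, , s] <- windows$bcg[[s]]
    Xp[, 1L, s] <- windows$ppg[[s]]
  }
  list(Xb = Xb, Xp = Xp)
}

#' Predict heart rate for preprocessed windows
#'
#' Runs the network in evaluation mode (dropout off) and appends the
#' predictions to the window table.
#'
#' @param object An `hr_net`.
#' @param windows Window tibble from [preprocess_cohort()].
#' @param batch_size Windows per forward pass.
#' @param ... Unused.
#' @return The window tibble with columns `hr_true` (the label) and
#'   `hr_pred` (BPM), without the signal list-columns.
#' @export
predict.hr_net <- function(object, windows, batch_size = 64, ...) {
  n <- nrow(windows)
  preds <- numeric(n)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    arr <- windows_to_arrays(windows[idx, ])
    preds[idx] <- net_forward(object, arr$Xb, arr$Xp, training = FALSE)$pred
  }
  out <- windows[, setdiff(names(windows), c("bcg", "ppg"))]
  out$hr_true <- windows$hr_bpm
  out$hr_pred <- preds
  tibble::as_tibble(out)
}
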