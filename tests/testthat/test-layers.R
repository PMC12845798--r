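test_that("causal and dilated convolutions match the literal summation", {
  expect_equal(causal_conv(c(1, 5, -2), 1), c(1, 5, -2))
  expect_equal(causal_conv(c(1, 2, 3), c(0, 1)), c(0, 1, 2))
  expect_equal(dilated_causal_conv(c(1, 2, 3, 4), c(1, 1), 2), c(1, 2, 4, 6))
  set.seed(101)
  for (i in 1:100) {
    T <- sample(5:40, 1)
    k <- sample(1:6, 1)
    d <- sample(1:4, 1)
    x <- rnorm(T)
    f <- rnorm(k)
    expect_equal(dilated_causal_conv(x, f, d), oracle_causal_conv(x, f, d),
                 tolerance = 1e-6)
    if (d == 1) expect_equal(causal_conv(x, f), dilated_causal_conv(x, f, 1))
  }
  expect_error(dilated_causal_conv(1:3, 1, 0), "dilation")
  expect_error(dilated_causal_conv(1:3, numeric(0), 1), "tap")
})

test_that("perturbations never propagate backwards through causal convolutions", {
  set.seed(7)
  x <- rnorm(64)
  f <- rnorm(3)
  for (t0 in c(10, 30, 50)) {
    x2 <- x
    x2[t0] <- x2[t0] + 1
    d <- dilated_causal_conv(x2, f, 4) - dilated_causal_conv(x, f, 4)
    expect_true(all(d[seq_len(t0 - 1)] == 0))
  }
})

test_that("the bidirectional LSTM matches the scalar gate recurrence", {
  set.seed(202)
  for (i in 1:100) {
    T <- sample(2:6, 1)
    D <- sample(1:4, 1)
    H <- sample(1:4, 1)
    fwd <- rand_lstm_params(D, H)
    bwd <- rand_lstm_params(D, H)
    x <- matrix(rnorm(T * D), T, D)
    out <- bilstm(x, fwd, bwd)
    expect_equal(dim(out), c(T, 2 * H))
    expect_equal(out, oracle_bilstm(x, fwd, bwd), tolerance = 1e-6)
  }
  # all-zero parameters force gates to 0.5 and a zero candidate: output 0
  z <- list(W = matrix(0, 3, 8), U = matrix(0, 2, 8), b = rep(0, 8))
  expect_equal(bilstm(matrix(rnorm(12), 4, 3), z, z), matrix(0, 4, 4))
})

test_that("multi-head self-attention matches the scaled dot-product formula", {
  set.seed(303)
  for (i in 1:100) {
    h <- sample(1:3, 1)
    dk <- sample(1:3, 1)
    D <- h * dk
    T <- sample(2:6, 1)
    p <- rand_attn_params(D, h)
    x <- matrix(rnorm(T * D), T, D)
    expect_equal(mhsa(x, p), oracle_mhsa(x, p), tolerance = 1e-6)
  }
  # T = 1 degenerates to x Wv Wo
  p <- rand_attn_params(4, 1)
  x <- matrix(rnorm(4), 1, 4)
  expect_equal(mhsa(x, p), x %*% p$Wv %*% p$Wo, tolerance = 1e-10)
  # no positional encoding: permuting rows permutes outputs identically
  p <- rand_attn_params(6, 2)
  x <- matrix(rnorm(30), 5, 6)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(mhsa(x[perm, ], p), mhsa(x, p)[perm, ], tolerance = 1e-10)
  expect_error(mhsa(matrix(rnorm(10), 2, 5), rand_attn_params(5, 5)[c(1:4)] |>
                      c(list(n_heads = 2))), "divide")
})

test_that("head-count adjustment returns the largest feasible divisor", {
  expect_equal(adjust_heads(128, 4), 4L)
  expect_equal(adjust_heads(6, 4), 3L)
  expect_equal(adjust_heads(7, 4), 1L)
  expect_equal(adjust_heads(12, 5), 4L)
  for (D in sample(1:200, 20)) {
    h <- adjust_heads(D, 4)
    expect_true(h >= 1 && h <= 4 && D %% h == 0)
  }
})

test_that("modality projection is the per-step affine map", {
  set.seed(404)
  for (i in 1:100) {
    T <- sample(1:6, 1)
    Din <- sample(1:5, 1)
    Dout <- sample(1:5, 1)
    f <- matrix(rnorm(T * Din), T, Din)
    W <- matrix(rnorm(Din * Dout), Din, Dout)
    b <- rnorm(Dout)
    expect_equal(project_modality(f, W, b), oracle_project(f, W, b),
                 tolerance = 1e-6)
  }
  f <- matrix(rnorm(12), 4, 3)
  expect_equal(project_modality(f, diag(3), rep(0, 3)), f)
  expect_equal(project_modality(f, matrix(0, 3, 2), c(5, -1)),
               matrix(rep(c(5, -1), each = 4), 4, 2))
})

test_that("cross-modal fusion matches the similarity-mixing equations", {
  set.seed(505)
  for (i in 1:100) {
    T <- sample(c(1:4), 1)
    D <- sample(1:4, 1)
    pb <- matrix(rnorm(T * D), T, D)
    pp <- matrix(rnorm(T * D), T, D)
    fu <- crossmodal_fuse(pb, pp)
    expect_equal(fu$fused, oracle_fuse(pb, pp), tolerance = 1e-6)
    expect_equal(rowSums(fu$S), rep(1, T), tolerance = 1e-6)
  }
  # T = 1: the softmax of a scalar is 1, so the fused output is exactly P_ppg
  pb <- matrix(rnorm(3), 1, 3)
  pp <- matrix(rnorm(3), 1, 3)
  expect_equal(crossmodal_fuse(pb, pp)$fused, pp)
  expect_error(crossmodal_fuse(matrix(0, 2, 3), matrix(0, 3, 3)), "share")
})

test_that("TCN residual blocks follow the pre-activation residual form", {
  set.seed(606)
  # zero residual branch with matching channels: o = ReLU(x)
  x <- matrix(rnorm(40), 10, 4)
  p <- list(conv1 = list(W = array(0, c(4, 4, 3)), b = rep(0, 4)),
            conv2 = list(W = array(0, c(4, 4, 3)), b = rep(0, 4)),
            dilation = 2)
  expect_equal(tcn_block(x, p), pmax(x, 0))
  # channel change requires the 1x1 skip
  p2 <- list(conv1 = list(W = array(rnorm(24) * 0.3, c(4, 2, 3)), b = rnorm(2)),
             conv2 = list(W = array(rnorm(12) * 0.3, c(2, 2, 3)), b = rnorm(2)),
             skip = list(W = array(rnorm(8) * 0.3, c(4, 2, 1)), b = rep(0, 2)),
             dilation = 1)
  out <- tcn_block(x, p2)
  expect_equal(dim(out), c(10, 2))
  expect_true(all(out >= 0))
})

test_that("a dilation-(1,2,4,8) kernel-3 TCN stack has a 61-sample receptive field", {
  set.seed(707)
  C <- 3
  # positive weights and inputs keep every ReLU active, so the probe measures
  # the full architectural receptive field
  blocks <- lapply(c(1, 2, 4, 8), function(d) {
    list(conv1 = list(W = array(abs(rnorm(C * C * 3)) * 0.2, c(C, C, 3)), b = rep(0.01, C)),
         conv2 = list(W = array(abs(rnorm(C * C * 3)) * 0.2, c(C, C, 3)), b = rep(0.01, C)),
         dilation = d)
  })
  stack_fw <- function(x) {
    for (b in blocks) x <- tcn_block(x, b)
    x
  }
  T <- 200
  x <- matrix(abs(rnorm(T * C)), T, C)
  base <- stack_fw(x)
  probe <- function(t0) {
    x2 <- x
    x2[t0, ] <- x2[t0, ] + 10
    which(rowSums(abs(stack_fw(x2) - base)) > 1e-12)
  }
  changed <- probe(80)
  expect_equal(min(changed), 80)               # causality: nothing before t0
  expect_equal(max(changed) - min(changed), 60) # 1 + 2*(k-1)*(1+2+4+8) = 61 samples
})

test_that("analytic network gradients agree with finite differences", {
  nf <- hrfusion:::net_forward
  nb <- hrfusion:::net_backward
  net <- suppressMessages(build_hr_net(tiny_model_cfg()))
  set.seed(9)
  B <- 2
  L <- 24
  Xb <- array(rnorm(L * 4 * B), c(L, 4, B))
  Xp <- array(rnorm(L * B), c(L, 1, B))
  y <- runif(B, 0.2, 0.8)
  lossfn <- function(params) {
    net$params <- params
    p <- 1 / (1 + exp(-nf(net, Xb, Xp, FALSE)$u))
    mean(0.5 * (p - y)^2)
  }
  fw <- nf(net, Xb, Xp, FALSE)
  p <- 1 / (1 + exp(-fw$u))
  du <- (p - y) * p * (1 - p) / B
  gr <- nb(net, fw$cache, du)
  flat_paths <- function(tree, pre = character()) {
    if (!is.list(tree)) return(list(pre))
    do.call(c, lapply(names(tree), function(nm) flat_paths(tree[[nm]], c(pre, nm))))
  }
  eps <- 1e-5
  for (pth in flat_paths(net$params)) {
    if (utils::tail(pth, 1) == "dilation") next
    k <- sample(length(net$params[[pth]]), 1)
    pp <- net$params
    pp[[pth]][k] <- pp[[pth]][k] + eps
    pm <- net$params
    pm[[pth]][k] <- pm[[pth]][k] - eps
    fd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
    expect_equal(gr[[pth]][k], fd, tolerance = 1e-4,
                 label = paste(pth, collapse = "/"))
  }
})
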