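test_that("configuration validation rejects inconsistent settings", {
  expect_error(model_config(modality = "ppg_only"), "use_dynamic_fusion")
  expect_error(model_config(head_dims = c(64, 32, 1)), "D_fusion")
  expect_error(model_config(dropout_p = 1), "dropout")
  cfg <- variant_config("ppg_only")
  expect_false(cfg$use_dynamic_fusion)
  expect_equal(cfg$modality, "ppg_only")
})

test_that("building under one seed is fully reproducible", {
  n1 <- suppressMessages(build_hr_net(tiny_model_cfg()))
  n2 <- suppressMessages(build_hr_net(tiny_model_cfg()))
  expect_identical(n1$params, n2$params)
  expect_gt(n1$n_params, 0)
  set.seed(1)
  B <- 3
  Xb <- array(rnorm(24 * 4 * B), c(24, 4, B))
  Xp <- array(rnorm(24 * B), c(24, 1, B))
  f1 <- hrfusion:::net_forward(n1, Xb, Xp, FALSE)
  f2 <- hrfusion:::net_forward(n2, Xb, Xp, FALSE)
  expect_identical(f1$pred, f2$pred)
  expect_message(build_hr_net(tiny_model_cfg()), "parameters")
})

test_that("the default architecture sits at the stated parameter scale", {
  net <- suppressMessages(build_hr_net(model_config()))
  expect_gt(net$n_params, 1.5e6)
  expect_lt(net$n_params, 2.5e6)
})

test_that("forward output is a bounded BPM scalar per window for every variant", {
  set.seed(2)
  B <- 3
  Xb <- array(rnorm(24 * 4 * B), c(24, 4, B))
  Xp <- array(rnorm(24 * B), c(24, 1, B))
  for (v in c("full", "baseline", "tcn", "tcn_bilstm", "no_fusion",
              "bcg_only", "ppg_only")) {
    cfg <- switch(v,
      full = tiny_model_cfg(),
      baseline = tiny_model_cfg(use_tcn = FALSE, use_bilstm = FALSE, use_mhsa = FALSE),
      tcn = tiny_model_cfg(use_bilstm = FALSE, use_mhsa = FALSE),
      tcn_bilstm = tiny_model_cfg(use_mhsa = FALSE),
      no_fusion = tiny_model_cfg(use_dynamic_fusion = FALSE),
      bcg_only = tiny_model_cfg(use_dynamic_fusion = FALSE, modality = "bcg_only"),
      ppg_only = tiny_model_cfg(use_dynamic_fusion = FALSE, modality = "ppg_only"))
    net <- suppressMessages(build_hr_net(cfg))
    fw <- hrfusion:::net_forward(net, Xb, Xp, FALSE)
    expect_length(fw$pred, B)
    expect_true(all(is.finite(fw$pred)))
    expect_true(all(fw$pred >= 35 & fw$pred <= 120))
  }
})

test_that("shape algebra holds over randomized configurations", {
  set.seed(5)
  for (i in 1:4) {
    cfg <- model_config(
      filters_per_kernel = sample(2:4, 1), pool_size = sample(c(2, 4), 1),
      tcn_channels = sample(3:6, 1), lstm_hidden = sample(2:5, 1),
      attn_heads = sample(1:4, 1), D_fusion = 6, head_dims = c(6, 3, 1),
      dropout_p = 0, seed = i)
    net <- suppressMessages(build_hr_net(cfg))
    B <- sample(1:4, 1)
    L <- 40
    Xb <- array(rnorm(L * 4 * B), c(L, 4, B))
    Xp <- array(rnorm(L * B), c(L, 1, B))
    fw <- hrfusion:::net_forward(net, Xb, Xp, FALSE)
    expect_length(fw$pred, B)
    expect_true(all(is.finite(fw$pred)))
  }
})

test_that("branch sequence lengths agree before fusion and pre-pool features are causal", {
  net <- suppressMessages(build_hr_net(tiny_model_cfg()))
  set.seed(8)
  L <- 40
  Xb <- array(rnorm(L * 4), c(L, 4, 1))
  Xp <- array(rnorm(L), c(L, 1, 1))
  fw <- hrfusion:::net_forward(net, Xb, Xp, FALSE)
  expect_equal(dim(fw$cache$bcg$P)[1], dim(fw$cache$ppg$P)[1])
  # pre-pooling multi-scale feature maps: no future-to-past flow
  t0 <- 25
  Xb2 <- Xb
  Xb2[t0, , 1] <- Xb2[t0, , 1] + 5
  fw2 <- hrfusion:::net_forward(net, Xb2, Xp, FALSE)
  d <- abs(fw2$cache$bcg$A0 - fw$cache$bcg$A0)
  expect_true(all(d[seq_len(t0 - 1), , 1] == 0))
  expect_gt(max(d), 0)
})

test_that("evaluation mode is deterministic and dropout only acts in training", {
  cfg <- tiny_model_cfg(dropout_p = 0.4)
  net <- suppressMessages(build_hr_net(cfg))
  set.seed(3)
  Xb <- array(rnorm(24 * 4 * 2), c(24, 4, 2))
  Xp <- array(rnorm(24 * 2), c(24, 1, 2))
  e1 <- hrfusion:::net_forward(net, Xb, Xp, FALSE)$pred
  e2 <- hrfusion:::net_forward(net, Xb, Xp, FALSE)$pred
  expect_identical(e1, e2)
  set.seed(10)
  t1 <- hrfusion:::net_forward(net, Xb, Xp, TRUE)$pred
  t2 <- hrfusion:::net_forward(net, Xb, Xp, TRUE)$pred
  expect_false(identical(t1, t2))
})

test_that("predict returns a tidy prediction table", {
  win <- small_window_set()
  net <- suppressMessages(build_hr_net(scaled_model_cfg()))
  pr <- predict(net, win[1:10, ])
  expect_s3_class(pr, "tbl_df")
  expect_named(pr, c("subject_id", "t_start", "hr_bpm", "hr_true", "hr_pred"))
  expect_true(all(pr$hr_pred >= 35 & pr$hr_pred <= 120))
})
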