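test_that("the Huber loss takes its textbook values and is smooth at delta", {
  expect_equal(huber_loss(0, 0, 1), 0)
  expect_equal(huber_loss(0, 0.5, 1), 0.125)
  expect_equal(huber_loss(0, 2, 1), 1.5)
  expect_error(huber_loss(0, 1, delta = 0), "positive")
  # gradient continuity at |e| = delta (finite differences either side)
  delta <- 1
  eps <- 1e-6
  g_in <- (huber_loss(0, delta, delta) - huber_loss(0, delta - eps, delta)) / eps
  g_out <- (huber_loss(0, delta + eps, delta) - huber_loss(0, delta, delta)) / eps
  expect_equal(g_in, g_out, tolerance = 1e-4)
  expect_equal(g_in, 1, tolerance = 1e-4)
})

test_that("the plateau rule halves the rate after exactly five flat epochs", {
  lr <- schedule_lr_history(rep(1, 6), lr0 = 1e-3)
  expect_equal(lr[5], 1e-3)
  expect_equal(lr[6], 5e-4)
  # an improvement resets the wait counter
  lr <- schedule_lr_history(c(1, 0.9, rep(0.9, 4), 0.89, rep(0.89, 5)), lr0 = 1e-3)
  expect_equal(lr[6], 1e-3)   # only 4 flat epochs since the epoch-2 best
  expect_equal(lr[12], 5e-4)
  # two consecutive plateaus cut twice
  lr <- schedule_lr_history(rep(1, 11), lr0 = 1e-3)
  expect_equal(lr[11], 2.5e-4)
})

test_that("early stopping fires after exactly fifteen flat validation epochs", {
  es <- early_stop_epoch(rep(2, 16), patience = 15)
  expect_equal(es$best_epoch, 1L)
  expect_equal(es$stop_epoch, 16L)
  es <- early_stop_epoch(c(3, 2.5, rep(2.5, 14)), patience = 15)
  expect_true(is.na(es$stop_epoch))  # only 14 flat epochs after the best
  es <- early_stop_epoch(seq(3, 1, length.out = 30), patience = 15)
  expect_true(is.na(es$stop_epoch))
  expect_equal(es$best_epoch, 30L)
})

test_that("fold assignment partitions data without subject leakage", {
  win <- fake_windows(10, 6)
  folds <- hrfusion:::assign_folds(win, 5, "subject", seed = 1)
  expect_length(folds, nrow(win))
  per_fold_subjects <- tapply(win$subject_id, folds, function(s) length(unique(s)))
  expect_true(all(per_fold_subjects == 2))
  for (s in unique(win$subject_id)) {
    expect_length(unique(folds[win$subject_id == s]), 1)
  }
  expect_identical(folds, hrfusion:::assign_folds(win, 5, "subject", seed = 1))
  expect_false(identical(folds, hrfusion:::assign_folds(win, 5, "subject", seed = 2)))
  # window mode: every window in exactly one fold, all folds used
  fw <- hrfusion:::assign_folds(win, 4, "window", seed = 3)
  expect_equal(sort(unique(fw)), 1:4)
  expect_equal(as.numeric(table(fw)), rep(15, 4))
  expect_error(hrfusion:::assign_folds(fake_windows(3, 2), 5, "subject", 1),
               "at least as many subjects")
})

test_that("training reduces validation error and records a faithful history", {
  win <- small_window_set()
  cfg <- tiny_model_cfg()
  net <- suppressMessages(build_hr_net(cfg))
  tc <- train_config(max_epochs = 8, batch_size = 16, seed = 2)
  fit <- fit_hr_net(net, win, tc)
  h <- tidy(fit)
  expect_s3_class(h, "tbl_df")
  expect_lte(nrow(h), 8)
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(is.finite(h$train_loss)))
  expect_lt(h$val_mae[fit$best_epoch], h$val_mae[1] + 1e-9)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  # determinism under seed
  fit2 <- fit_hr_net(suppressMessages(build_hr_net(cfg)), win, tc)
  expect_equal(fit$history$train_loss, fit2$history$train_loss)
  expect_error(fit_hr_net(net, win[1:10, ], tc), "two batches")
})

test_that("subject-mode cross-validation yields disjoint out-of-fold predictions", {
  win <- small_window_set()
  mc <- tiny_model_cfg()
  tc <- train_config(max_epochs = 2, batch_size = 16, cv_folds = 2,
                     cv_mode = "subject", seed = 4)
  cv <- suppressMessages(cross_validate(win, mc, tc))
  expect_length(cv$fold_reports, 2)
  expect_equal(nrow(cv$predictions), nrow(win))
  expect_equal(sort(unique(cv$predictions$fold)), 1:2)
  # each subject predicted by exactly one fold's model
  by_sub <- tapply(cv$predictions$fold, cv$predictions$subject_id,
                   function(f) length(unique(f)))
  expect_true(all(by_sub == 1))
  expect_s3_class(cv$pooled, "hr_eval")
  expect_equal(cv$pooled$n_windows, nrow(win))
})
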