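# Training protocol: Huber loss (delta = 1) on range-scaled labels, Nadam
# at 1e-3, learning-rate halving on a 5-epoch training-loss plateau, early
# stopping on validation MAE (patience 15), batch size 32, and a
# cross-validation driver with subject-disjoint or window-shuffled folds.

#' Training configuration
#'
#' @param delta Huber transition point on the scaled-label axis.
#' @param lr0 Initial learning rate.
#' @param lr_factor Multiplier applied on a training-loss plateau.
#' @param lr_patience Consecutive non-improving epochs before the cut.
#' @param early_patience Non-improving validation epochs before stopping.
#' @param max_epochs Epoch budget.
#' @param batch_size Windows per gradient step.
#' @param cv_folds Number of cross-validation folds.
#' @param cv_mode `"subject"` keeps every subject inside one fold
#'   (leakage-free given the 75% overlap of 1 s-stride windows);
#'   `"window"` shuffles windows irrespective of subject.
#' @param val_fraction Fraction of training windows held out for the early
#'   stopper when no explicit validation set is supplied.
#' @param seed Integer seed covering shuffling, dropout and splits.
#' @return An object of class `train_config`.
#' @export
train_config <- function(delta = 1.0, lr0 = 1e-3, lr_factor = 0.5,
                         lr_patience = 5, early_patience = 15,
                         max_epochs = 100, batch_size = 32, cv_folds = 5,
                         cv_mode = c("subject", "window"),
                         val_fraction = 0.15, seed = 1L) {
  cv_mode <- match.arg(cv_mode)
  assert_that(delta > 0, "`delta` must be positive")
  assert_that(lr_factor > 0 && lr_factor < 1, "`lr_factor` must lie in (0, 1)")
  assert_that(all(c(lr0, lr_patience, early_patience, max_epochs,
                    batch_size) > 0), "all training parameters must be positive")
  structure(
    list(delta = delta, lr0 = lr0, lr_factor = lr_factor,
         lr_patience = lr_patience, early_patience = early_patience,
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         cv_folds = as.integer(cv_folds), cv_mode = cv_mode,
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}

# --- plateau rules (pure functions of the loss history) --------------------

#' Learning-rate trajectory implied by a training-loss history
#'
#' Replays the plateau rule over a recorded loss sequence: the rate is cut
#' by `factor` once the loss has failed to improve by more than `eps` for
#' `patience` consecutive epochs (the wait counter resets after each cut).
#'
#' @param losses Per-epoch training losses.
#' @param lr0 Initial learning rate.
#' @param factor Cut multiplier.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param eps Minimum absolute improvement that resets the counter.
#' @return Numeric vector: the learning rate in effect *after* each epoch.
#' @export
schedule_lr_history <- function(losses, lr0 = 1e-3, factor = 0.5,
                                patience = 5, eps = 1e-4) {
  lr <- lr0
  best <- Inf
  wait <- 0L
  out <- numeric(length(losses))
  for (i in seq_along(losses)) {
    if (losses[i] < best - eps) {
      best <- losses[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0L
      }
    }
    out[i] <- lr
  }
  out
}

#' Early-stopping decision implied by a validation history
#'
#' @param val_metric Per-epoch validation metric (lower is better).
#' @param patience Non-improving epochs tolerated before stopping.
#' @param eps Minimum absolute improvement.
#' @return List with `best_epoch` and `stop_epoch` (`NA` when training runs
#'   to the end of the history).
#' @export
early_stop_epoch <- function(val_metric, patience = 15, eps = 1e-4) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  for (i in seq_along(val_metric)) {
    if (val_metric[i] < best - eps) {
      best <- val_metric[i]
      best_epoch <- i
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(best_epoch = best_epoch, stop_epoch = i))
      }
    }
  }
  list(best_epoch = best_epoch, stop_epoch = NA_integer_)
}

# --- Nadam -----------------------------------------------------------------

# One Nadam update over the parameter tree; leaves named "dilation" are
# structural, not trainable. Returns updated (params, m, v).
nadam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      if (nm == "dilation" || is.null(g[[nm]])) next
      res <- nadam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- res$p
      m[[nm]] <- res$m
      v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  ghat <- g / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  p <- p - lr * (b1 * mhat + (1 - b1) * ghat) / (sqrt(vhat) + eps)
  list(p = p, m = m, v = v)
}

huber_grad <- function(e, delta) ifelse(abs(e) <= delta, e, delta * sign(e))

#' Fit the network
#'
#' Mini-batch training with the full protocol: Huber loss on labels scaled
#' to the output range, Nadam, plateau learning-rate halving monitored on
#' the training loss, early stopping monitored on validation MAE with the
#' best-validation weights restored. Deterministic under `cfg$seed`.
#'
#' @param net An `hr_net` from [build_hr_net()].
#' @param windows Training window tibble.
#' @param cfg A [train_config()].
#' @param val_windows Optional validation window tibble; when omitted, a
#'   random `val_fraction` of `windows` is held out under the seed.
#' @param verbose Print one line per epoch.
#' @return An object of class `hr_fit`: list with the trained `net`, the
#'   per-epoch `history` tibble and `best_epoch`.
#' @export
fit_hr_net <- function(net, windows, cfg = train_config(),
                       val_windows = NULL, verbose = FALSE) {
  assert_that(nrow(windows) >= 2 * cfg$batch_size,
              "need at least two batches of training windows")
  with_seed(cfg$seed, {
    if (is.null(val_windows)) {
      n_val <- max(1L, round(cfg$val_fraction * nrow(windows)))
      vi <- sample.int(nrow(windows), n_val)
      val_windows <- windows[vi, ]
      windows <- windows[-vi, ]
    }
    lo <- net$cfg$hr_range[1]
    span <- diff(net$cfg$hr_range)
    y_scaled <- (windows$hr_bpm - lo) / span
    arr <- windows_to_arrays(windows)
    n <- nrow(windows)

    m <- tree_map(function(x) x * 0, net$params)
    v <- m
    lr <- cfg$lr0
    sched_best <- Inf
    sched_wait <- 0L
    es_best <- Inf
    es_wait <- 0L
    best_epoch <- 0L
    best_params <- net$params
    step <- 0L
    history <- vector("list", cfg$max_epochs)

    for (epoch in seq_len(cfg$max_epochs)) {
      t0 <- proc.time()[3]
      idx <- sample.int(n)
      losses <- c()
      for (i0 in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[i0:min(i0 + cfg$batch_size - 1, n)]
        if (length(bi) < 2) next
        fw <- net_forward(net,
                          arr$Xb[, , bi, drop = FALSE],
                          arr$Xp[, , bi, drop = FALSE], training = TRUE)
        p_sc <- sigmoid(fw$u)
        e <- p_sc - y_scaled[bi]
        loss <- huber_loss(y_scaled[bi], p_sc, cfg$delta)
        if (!is.finite(loss)) {
          stop_domain("training aborted: non-finite loss at epoch ", epoch,
                      " (learning rate ", lr, ")")
        }
        losses <- c(losses, loss)
        du <- huber_grad(e, cfg$delta) * p_sc * (1 - p_sc) / length(bi)
        grads <- net_backward(net, fw$cache, du)
        step <- step + 1L
        upd <- nadam_step(net$params, grads, m, v, lr, step)
        net$params <- upd$p
        m <- upd$m
        v <- upd$v
      }
      train_loss <- mean(losses)
      val_pred <- predict(net, val_windows)
      val_mae <- mean(abs(val_pred$hr_pred - val_pred$hr_true))

      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, val_mae = val_mae, lr = lr,
        seconds = proc.time()[3] - t0
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val MAE %.2f BPM  lr %.2g",
                        epoch, train_loss, val_mae, lr))
      }
      # plateau rule on the training loss
      if (train_loss < sched_best - 1e-4) {
        sched_best <- train_loss
        sched_wait <- 0L
      } else {
        sched_wait <- sched_wait + 1L
        if (sched_wait >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          sched_wait <- 0L
        }
      }
      # early stopping on validation MAE
      if (val_mae < es_best - 1e-4) {
        es_best <- val_mae
        es_wait <- 0L
        best_epoch <- epoch
        best_params <- net$params
      } else {
        es_wait <- es_wait + 1L
        if (es_wait >= cfg$early_patience) break
      }
    }
    net$params <- best_params
    structure(
      list(net = net, history = dplyr::bind_rows(history),
           best_epoch = best_epoch, train_cfg = cfg),
      class = "hr_fit"
    )
  })
}

#' @export
predict.hr_fit <- function(object, windows, ...) {
  predict(object$net, windows, ...)
}

#' @export
print.hr_fit <- function(x, ...) {
  cat(sprintf("<hr_fit> %d epoch(s), best epoch %d (val MAE %.2f BPM)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_mae[x$best_epoch]))
  invisible(x)
}

#' @rdname fit_hr_net
#' @param x An `hr_fit`.
#' @method tidy hr_fit
#' @export
tidy.hr_fit <- function(x, ...) x$history

#' @rdname fit_hr_net
#' @method glance hr_fit
#' @export
glance.hr_fit <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mae = x$history$val_mae[x$best_epoch],
    n_params = x$net$n_params
  )
}

# Assign subjects (or windows) to folds; deterministic under seed.
assign_folds <- function(windows, cv_folds, cv_mode, seed) {
  if (cv_mode == "subject") {
    subjects <- sort(unique(windows$subject_id))
    assert_that(length(subjects) >= cv_folds,
                "subject-mode cross-validation needs at least as many subjects as folds")
    perm <- with_seed(seed, sample(subjects))
    fold_of <- rep(seq_len(cv_folds), length.out = length(perm))
    names(fold_of) <- perm
    unname(fold_of[windows$subject_id])
  } else {
    with_seed(seed, {
      f <- rep(seq_len(cv_folds), length.out = nrow(windows))
      sample(f)
    })
  }
}

#' Cross-validated training and evaluation
#'
#' Splits the windows into `cv_folds` folds (whole subjects per fold in
#' `"subject"` mode; shuffled windows in `"window"` mode), trains one model
#' per fold on the remaining data and evaluates on the held-out fold.
#' Pooled metrics are computed over the concatenated out-of-fold
#' predictions.
#'
#' @param windows Preprocessed window tibble.
#' @param model_cfg An [model_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `fold_reports` (one [hr_eval] per fold), `pooled`
#'   (pooled [hr_eval]), `predictions` (out-of-fold prediction tibble with
#'   a `fold` column) and `folds` (the assignment vector).
#' @export
cross_validate <- function(windows, model_cfg = model_config(),
                           train_cfg = train_config(), verbose = FALSE) {
  assert_that(train_cfg$cv_folds >= 2, "`cv_folds` must be at least 2")
  folds <- assign_folds(windows, train_cfg$cv_folds, train_cfg$cv_mode,
                        train_cfg$seed)
  preds <- vector("list", train_cfg$cv_folds)
  reports <- vector("list", train_cfg$cv_folds)
  for (f in seq_len(train_cfg$cv_folds)) {
    test <- windows[folds == f, ]
    train <- windows[folds != f, ]
    if (train_cfg$cv_mode == "subject") {
      stopifnot(length(intersect(unique(test$subject_id),
                                 unique(train$subject_id))) == 0)
    }
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    net <- build_hr_net(cfg_f)
    tc <- train_cfg
    tc$seed <- train_cfg$seed + f
    fitted <- fit_hr_net(net, train, tc, verbose = verbose)
    pf <- predict(fitted, test)
    pf$fold <- f
    preds[[f]] <- pf
    reports[[f]] <- evaluate_predictions(pf)
  }
  all_preds <- dplyr::bind_rows(preds)
  list(fold_reports = reports, pooled = evaluate_predictions(all_preds),
       predictions = all_preds, folds = folds)
}
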