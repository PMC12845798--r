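# Shared fixtures. Everything is generated in code at test time; the tiny
# model configuration keeps layer and gradient tests fast.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_model_cfg <- function(dropout_p = 0, ...) {
  model_config(filters_per_kernel = 2, pool_size = 4, tcn_channels = 4,
               lstm_hidden = 3, attn_heads = 2, D_fusion = 5,
               head_dims = c(5, 4, 1), dropout_p = dropout_p, seed = 3, ...)
}

scaled_model_cfg <- function(variant = "full", seed = 1) {
  variant_config(variant, filters_per_kernel = 8, tcn_channels = 32,
                 lstm_hidden = 32, pool_size = 4, seed = seed)
}

# A small two-subject window set for training smoke tests (cached per session).
small_window_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(2, 80, c(60, 90), seed = 5)
      cache <<- suppressMessages(preprocess_cohort(coh))
    }
    cache
  }
})

# Eight-subject study cohort (120 s each, moderate noise), preprocessed once.
acceptance_cohort_windows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(8, 120, c(50, 100), seed = 11)
      cache <<- suppressMessages(preprocess_cohort(coh))
    }
    cache
  }
})

# Same cohort geometry with heavy PPG-specific motion artifacts.
corrupted_cohort_windows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(8, 120, c(50, 100), seed = 11,
                         ppg_noise = noise_spec(white_sd = 0.1,
                                                artifact_rate = 20,
                                                artifact_amp = 4))
      cache <<- suppressMessages(preprocess_cohort(coh))
    }
    cache
  }
})

# Synthetic window tibble with fake signals but controlled labels/subjects,
# for fold-assignment and bookkeeping tests.
fake_windows <- function(n_subjects, per_subject, len = 8) {
  rows <- expand.grid(w = seq_len(per_subject), subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    subject_id = rows$subject_id,
    t_start = as.numeric(rows$w - 1),
    hr_bpm = 60 + 10 * sin(seq_len(nrow(rows))),
    bcg = replicate(nrow(rows), matrix(rnorm(len * 4), len, 4), simplify = FALSE),
    ppg = replicate(nrow(rows), rnorm(len), simplify = FALSE)
  )
}
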