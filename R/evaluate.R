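# Agreement analysis of predicted vs reference heart rate: MAE,
# Bland-Altman bias with 95% limits of agreement, Pearson correlation,
# and per-subject breakdowns.

#' Mean absolute error
#'
#' @param y Reference values (BPM).
#' @param y_hat Predicted values (BPM), same length.
#' @return Mean of `|y_hat - y|`.
#' @export
mae <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat) && length(y) >= 1,
              "`y` and `y_hat` must be equal-length, non-empty vectors")
  mean(abs(y_hat - y))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are oriented predicted minus reference. The bias is their
#' mean; the limits are `bias +/- 1.96 * sd` with the sample (n-1)
#' standard deviation. For plotting, the abscissa convention is the
#' pairwise mean `(y + y_hat)/2`.
#'
#' @inheritParams mae
#' @return Named list with `bias`, `loa_low`, `loa_high` and `sd_diff`.
#' @export
bland_altman <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat) && length(y) >= 2,
              "Bland-Altman analysis needs at least two paired values")
  d <- y_hat - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s)
}

#' Pearson correlation with a zero-variance guard
#'
#' @inheritParams mae
#' @return The product-moment correlation, or `NA` (with a warning) when
#'   either input has zero variance.
#' @export
pearson <- function(y, y_hat) {
  assert_that(length(y) == length(y_hat) && length(y) >= 2,
              "correlation needs at least two paired values")
  if (sd(y) < 1e-12 || sd(y_hat) < 1e-12) {
    warning("zero variance: Pearson correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(y, y_hat)
}

#' Evaluation report for a prediction table
#'
#' Computes the pooled agreement surface (MAE, Bland-Altman bias and 95%
#' limits of agreement, Pearson correlation) plus a per-subject MAE
#' breakdown.
#'
#' @param predictions Tibble (or CSV path) with columns `subject_id`,
#'   `hr_true` and `hr_pred`.
#' @return An object of class `hr_eval`.
#' @export
evaluate_predictions <- function(predictions) {
  if (is.character(predictions)) predictions <- tibble::as_tibble(read.csv(predictions))
  assert_that(nrow(predictions) >= 1, "empty prediction table")
  assert_that(all(c("subject_id", "hr_true", "hr_pred") %in% names(predictions)),
              "predictions need columns subject_id, hr_true, hr_pred")
  y <- predictions$hr_true
  yh <- predictions$hr_pred
  ba <- if (length(y) >= 2) bland_altman(y, yh) else
    list(bias = 0, loa_low = 0, loa_high = 0, sd_diff = 0)
  r <- if (length(y) >= 2) suppressWarnings(pearson(y, yh)) else NA_real_
  per_subject <- predictions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mae = mae(.data$hr_true, .data$hr_pred),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(mae = mae(y, yh), bias = ba$bias, loa_low = ba$loa_low,
         loa_high = ba$loa_high, sd_diff = ba$sd_diff, pearson_r = r,
         n_windows = length(y), per_subject = per_subject,
         predictions = predictions),
    class = "hr_eval"
  )
}

#' @export
print.hr_eval <- function(x, ...) {
  cat(sprintf(paste0("<hr_eval> n = %d windows, %d subject(s)\n",
                     "  MAE        %.2f BPM\n",
                     "  bias       %.2f BPM (LoA %.2f to %.2f)\n",
                     "  Pearson r  %s\n"),
              x$n_windows, nrow(x$per_subject), x$mae, x$bias, x$loa_low,
              x$loa_high,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r)))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x An `hr_eval`.
#' @param ... Unused.
#' @method tidy hr_eval
#' @export
tidy.hr_eval <- function(x, ...) x$per_subject

#' @rdname evaluate_predictions
#' @method glance hr_eval
#' @export
glance.hr_eval <- function(x, ...) {
  tibble::tibble(mae = x$mae, bias = x$bias, loa_low = x$loa_low,
                 loa_high = x$loa_high, pearson_r = x$pearson_r,
                 n_windows = x$n_windows)
}

#' Serialize an evaluation report to JSON
#'
#' @param x An `hr_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(x, path) {
  jsonlite::write_json(
    list(mae = x$mae, bias = x$bias, loa_low = x$loa_low,
         loa_high = x$loa_high, pearson_r = x$pearson_r,
         n_windows = x$n_windows,
         per_subject = x$per_subject),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Bland-Altman plot of an evaluation report
#'
#' Scatter of prediction-reference differences against pairwise means,
#' with the bias and 95% limits of agreement drawn as horizontal lines.
#'
#' @param object An `hr_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_eval
#' @export
autoplot.hr_eval <- function(object, ...) {
  df <- tibble::tibble(
    avg = (object$predictions$hr_true + object$predictions$hr_pred) / 2,
    diff = object$predictions$hr_pred - object$predictions$hr_true
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$bias, colour = "black") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of reference and predicted HR (BPM)",
                  y = "Predicted - reference (BPM)",
                  title = sprintf("Bias %.2f BPM, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low,
                                  object$loa_high))
}

#' Identity-line scatter of predictions vs reference
#'
#' @param report An `hr_eval`.
#' @return A ggplot object.
#' @export
plot_agreement <- function(report) {
  df <- report$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr_true, y = .data$hr_pred)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "Reference HR (BPM)", y = "Predicted HR (BPM)",
                  title = if (is.na(report$pearson_r)) "Agreement" else
                    sprintf("Pearson r = %.3f", report$pearson_r))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
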