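# Flat-file containers. The signal dialect is one CSV per recording with
# columns t, bcg1..bcg4, ppg, ecg (time in seconds, monotone, constant step);
# a cohort directory adds manifest.csv (subject_id, file, fs, ptt_s,
# beats_file) and optional per-subject beat-time sidecars.

signal_columns <- c("t", "bcg1", "bcg2", "bcg3", "bcg4", "ppg", "ecg")

#' Write one recording as a flat signal CSV
#'
#' @param record A `signal_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  n <- length(record$ecg)
  df <- data.frame(
    t = (seq_len(n) - 1) / record$fs,
    bcg1 = record$bcg[, 1], bcg2 = record$bcg[, 2],
    bcg3 = record$bcg[, 3], bcg4 = record$bcg[, 4],
    ppg = record$ppg, ecg = record$ecg
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one flat signal CSV into a `signal_record`
#'
#' @param path CSV path in the documented dialect.
#' @param subject_id Identifier; defaults to the file stem.
#' @param ptt_s,beat_times Optional metadata to attach.
#' @return A `signal_record`.
#' @export
read_signal_csv <- function(path, subject_id = NULL, ptt_s = NA_real_,
                            beat_times = NULL) {
  df <- read.csv(path)
  missing_cols <- setdiff(signal_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_domain("signal CSV is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  dt <- diff(df$t)
  if (any(dt <= 0)) stop_domain("time column `t` must be strictly increasing")
  fs <- 1 / stats::median(dt)
  if (!is.finite(fs)) stop_domain("sampling rate inferred from `t` is not finite")
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path))
  structure(
    list(subject_id = subject_id, fs = fs,
         bcg = as.matrix(df[, c("bcg1", "bcg2", "bcg3", "bcg4")]),
         ppg = df$ppg, ecg = df$ecg,
         beat_times = beat_times, ptt_s = ptt_s),
    class = "signal_record"
  )
}

#' Write a cohort as a CSV directory with manifest
#'
#' @param cohort Cohort tibble from [make_cohort()] (or a list of
#'   `signal_record`s).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  records <- cohort_records(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    f <- paste0(r$subject_id, ".csv")
    write_signal_csv(r, file.path(dir, f))
    bf <- NA_character_
    if (!is.null(r$beat_times)) {
      bf <- paste0(r$subject_id, "_beats.csv")
      write.csv(data.frame(beat_time_s = r$beat_times),
                file.path(dir, bf), row.names = FALSE)
    }
    data.frame(subject_id = r$subject_id, file = f, fs = r$fs,
               ptt_s = r$ptt_s, beats_file = bf)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a signal container (single CSV or cohort directory)
#'
#' A path ending in `.csv` is read as one recording; a directory must hold
#' a `manifest.csv` in the documented dialect.
#'
#' @param path CSV file or cohort directory.
#' @return A cohort tibble (`subject_id`, `fs`, `ptt_s`, `record`).
#' @export
read_signal_container <- function(path) {
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.csv")
    if (!file.exists(mf)) stop_domain("cohort directory lacks manifest.csv: ", path)
    man <- read.csv(mf)
    records <- lapply(seq_len(nrow(man)), function(i) {
      bt <- NULL
      if (!is.na(man$beats_file[i]) && nzchar(man$beats_file[i])) {
        bt <- read.csv(file.path(path, man$beats_file[i]))$beat_time_s
      }
      read_signal_csv(file.path(path, man$file[i]),
                      subject_id = man$subject_id[i],
                      ptt_s = man$ptt_s[i], beat_times = bt)
    })
  } else if (file.exists(path)) {
    records <- list(read_signal_csv(path))
  } else {
    stop_domain("no such signal container: ", path)
  }
  tibble::tibble(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    fs = vapply(records, function(r) r$fs, numeric(1)),
    ptt_s = vapply(records, function(r) r$ptt_s %||% NA_real_, numeric(1)),
    record = records
  )
}

# Accept either the cohort tibble or a bare list of records.
cohort_records <- function(cohort) {
  if (tibble::is_tibble(cohort) || is.data.frame(cohort)) return(cohort$record)
  if (inherits(cohort, "signal_record")) return(list(cohort))
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-window predictions as CSV
#'
#' @param predictions Tibble with at least `subject_id`, `t_start`,
#'   `hr_true`, `hr_pred`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  keep <- intersect(c("subject_id", "t_start", "hr_true", "hr_pred"),
                    names(predictions))
  write.csv(as.data.frame(predictions[, keep]), path, row.names = FALSE)
  invisible(path)
}
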