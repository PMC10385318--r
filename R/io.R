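# Readers/writers for the plain-text interchange formats: EEG CSV + JSON
# sidecar (+ annotations CSV), HRV CSV, clinical JSON, predictions CSV,
# run-config JSON. All round trips are lossless to full double precision
# (values are printed with format("%.17g")).

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read an EEG recording from CSV + JSON sidecar
#'
#' The CSV holds the signal matrix (rows = time samples, columns = channels;
#' an optional single header row of channel names; no index column). The JSON
#' sidecar declares `fs` (Hz), `channels` and optionally `subject_id`.
#' Annotations, if present, are a CSV with columns `state,start_s,end_s`.
#'
#' @param csv_path path to the signal CSV.
#' @param sidecar_json_path path to the sidecar JSON.
#' @param annotations_csv_path optional path to the annotations CSV; defaults
#'   to `<csv_path minus .csv>_annotations.csv` when that file exists.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(csv_path, sidecar_json_path,
                     annotations_csv_path = NULL) {
  sidecar <- jsonlite::read_json(sidecar_json_path, simplifyVector = TRUE)
  if (is.null(sidecar$fs) || is.null(sidecar$channels)) {
    stop("sidecar must declare 'fs' and 'channels'")
  }
  channels <- as.character(sidecar$channels)
  first <- readLines(csv_path, n = 1L)
  has_header <- !all(grepl("^[-+0-9.eE ]*$",
                           strsplit(first, ",", fixed = TRUE)[[1L]]))
  raw <- utils::read.csv(csv_path, header = has_header,
                         colClasses = "character", check.names = FALSE)
  if (ncol(raw) != length(channels)) {
    stop("channel count mismatch: CSV has ", ncol(raw),
         " columns but sidecar declares ", length(channels), " channels")
  }
  mat <- vapply(raw, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("non-numeric cell in EEG CSV")
    v
  }, numeric(nrow(raw)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(raw))
  annotations <- NULL
  if (is.null(annotations_csv_path)) {
    cand <- paste0(sub("\\.csv$", "", csv_path), "_annotations.csv")
    if (file.exists(cand)) annotations_csv_path <- cand
  }
  if (!is.null(annotations_csv_path)) {
    annotations <- utils::read.csv(annotations_csv_path,
                                   stringsAsFactors = FALSE)
  }
  subject_id <- if (!is.null(sidecar$subject_id)) {
    as.character(sidecar$subject_id)
  } else {
    sub("\\.csv$", "", basename(csv_path))
  }
  eeg_recording(subject_id, mat, as.numeric(sidecar$fs), channels,
                annotations)
}

#' Write an EEG recording to CSV + JSON sidecar
#'
#' Inverse of [read_eeg()]; values are printed with 17 significant digits so
#' the round trip reproduces the matrix exactly.
#'
#' @param rec an [eeg_recording()].
#' @param csv_path output signal CSV path.
#' @param sidecar_json_path output sidecar JSON path.
#' @param annotations_csv_path optional annotations CSV path; defaults to
#'   `<csv_path minus .csv>_annotations.csv` when annotations exist.
#' @return invisibly, the paths written.
#' @export
write_eeg <- function(rec, csv_path, sidecar_json_path,
                      annotations_csv_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- as.data.frame(apply(rec$signal, 2L, fmt_num), optional = TRUE)
  colnames(out) <- rec$channel_names
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channel_names,
         subject_id = rec$subject_id),
    sidecar_json_path, auto_unbox = TRUE, digits = NA)
  paths <- c(csv_path, sidecar_json_path)
  if (nrow(rec$annotations) > 0L) {
    if (is.null(annotations_csv_path)) {
      annotations_csv_path <- paste0(sub("\\.csv$", "", csv_path),
                                     "_annotations.csv")
    }
    ann <- rec$annotations
    ann$start_s <- fmt_num(ann$start_s)
    ann$end_s <- fmt_num(ann$end_s)
    utils::write.csv(ann, annotations_csv_path, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, annotations_csv_path)
  }
  invisible(paths)
}

#' Read an HRV feature series from CSV
#'
#' Expected columns: `time_s,Lmax,SDNN,LF_HF,MeanHR,pNN50`.
#'
#' @param csv_path input path.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return An [hrv_series()].
#' @export
read_hrv <- function(csv_path, subject_id = NULL) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("HRV CSV must have a 'time_s' column")
  if (is.null(subject_id)) {
    subject_id <- sub("\\.csv$", "", basename(csv_path))
  }
  hrv_series(subject_id, df$time_s, df[setdiff(names(df), "time_s")])
}

#' Write an HRV feature series to CSV
#' @param series an [hrv_series()].
#' @param csv_path output path.
#' @return invisibly, `csv_path`.
#' @export
write_hrv <- function(series, csv_path) {
  stopifnot(inherits(series, "hrv_series"))
  df <- cbind(data.frame(time_s = fmt_num(series$times)),
              as.data.frame(lapply(series$features, fmt_num)))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read clinical records from JSON
#'
#' The JSON is either one record object or an array of records with fields
#' `subject_id, age, gender, genetic, metabolic, seizure_event_count`.
#'
#' @param json_path input path.
#' @return A list of [clinical_record()] objects.
#' @export
read_clinical <- function(json_path) {
  raw <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (!is.null(raw$subject_id)) raw <- list(raw)
  lapply(raw, function(r) {
    clinical_record(as.character(r$subject_id), r$age, r$gender,
                    isTRUE(r$genetic), isTRUE(r$metabolic),
                    r$seizure_event_count)
  })
}

#' Write clinical records to JSON
#' @param records a [clinical_record()] or list of them.
#' @param json_path output path.
#' @return invisibly, `json_path`.
#' @export
write_clinical <- function(records, json_path) {
  if (inherits(records, "clinical_record")) records <- list(records)
  jsonlite::write_json(lapply(records, unclass), json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Write per-window predictions to CSV
#'
#' @param records data.frame (or list coercible to one) with columns
#'   `subject_id, window_start_s, window_end_s, preictal_probability,
#'   predicted_state`. Probabilities must lie in \[0, 1\] and are printed with
#'   at least 6 significant digits.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(records, path) {
  cols <- c("subject_id", "window_start_s", "window_end_s",
            "preictal_probability", "predicted_state")
  if (is.null(records) || (is.data.frame(records) && nrow(records) == 0L) ||
      (is.list(records) && !is.data.frame(records) && length(records) == 0L)) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  df <- as.data.frame(records)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("predictions missing column(s): ", paste(missing, collapse = ", "))
  }
  p <- df$preictal_probability
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("preictal_probability outside [0, 1]")
  }
  df <- df[cols]
  df$preictal_probability <- formatC(p, format = "g", digits = 9)
  df$window_start_s <- fmt_num(df$window_start_s)
  df$window_end_s <- fmt_num(df$window_end_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions CSV written by [write_predictions()]
#' @param path input path.
#' @return data.frame.
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a run configuration to JSON
#' @param cfg a [run_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path input path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}
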