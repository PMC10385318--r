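# Multi-timescale segmentation, balanced training-sample generation, and
# ROC-based bi-timescale selection.

#' Sliding-window segmentation of a recording
#'
#' Extracts windows of `scale_s` seconds starting at `0, stride_s,
#' 2*stride_s, ...` while fully inside the recording (half-open intervals;
#' start samples are rounded to the sample grid). Each window is labelled
#' with the annotated state covering at least half of it, or `NA`.
#'
#' @param recording an [eeg_recording()].
#' @param scale_s window length in seconds; `scale_s * fs` must be integral.
#' @param stride_s positive step between window starts in seconds
#'   (default `scale_s`, i.e. no overlap).
#' @return object of class `segment_set`: list with `scale_s`, `stride_s`
#'   and `segments`, a list of entries `(window, label, subject_id,
#'   start_s)`. A recording shorter than `scale_s` yields an empty set.
#' @export
segment <- function(recording, scale_s, stride_s = scale_s) {
  stopifnot(inherits(recording, "eeg_recording"), stride_s > 0)
  fs <- recording$fs
  win <- scale_s * fs
  if (abs(win - round(win)) > 1e-9) {
    stop("scale_s * fs must be an integral number of samples")
  }
  win <- as.integer(round(win))
  n <- nrow(recording$signal)
  segments <- list()
  duration <- n / fs
  if (duration >= scale_s) {
    n_windows <- floor((duration - scale_s) / stride_s + 1e-9) + 1L
    for (k in seq_len(n_windows)) {
      start_s <- (k - 1L) * stride_s
      i0 <- as.integer(round(start_s * fs))
      if (i0 + win > n) next
      window <- recording$signal[(i0 + 1L):(i0 + win), , drop = FALSE]
      segments[[length(segments) + 1L]] <- list(
        window = window,
        label = window_label(recording$annotations, start_s,
                             start_s + scale_s),
        subject_id = recording$subject_id,
        start_s = start_s
      )
    }
  }
  structure(list(scale_s = scale_s, stride_s = stride_s, segments = segments),
            class = "segment_set")
}

# label = state of the annotation covering >= 50% of [start_s, end_s)
window_label <- function(annotations, start_s, end_s) {
  if (nrow(annotations) == 0L) return(NA_character_)
  cover <- pmin(annotations$end_s, end_s) - pmax(annotations$start_s, start_s)
  cover <- pmax(cover, 0)
  best <- which.max(cover)
  if (cover[best] >= (end_s - start_s) / 2) annotations$state[best]
  else NA_character_
}

#' @export
print.segment_set <- function(x, ...) {
  labs <- vapply(x$segments, `[[`, character(1), "label")
  cat(sprintf("<segment_set> scale %g s, stride %g s: %d segments (%s)\n",
              x$scale_s, x$stride_s, length(x$segments),
              paste(names(table(labs, useNA = "ifany")),
                    table(labs, useNA = "ifany"), sep = "=", collapse = ", ")))
  invisible(x)
}

segment_labels <- function(set) vapply(set$segments, `[[`, character(1),
                                       "label")

# total window count across annotated intervals for a given stride
count_windows <- function(durations, scale_s, stride_s) {
  sum(vapply(durations, function(d) {
    if (d < scale_s) 0 else floor((d - scale_s) / stride_s + 1e-9) + 1
  }, numeric(1)))
}

#' Balanced preictal/interictal training samples
#'
#' Segments annotated intervals of both classes at one timescale. The
#' majority class is segmented without overlap (stride = scale); the
#' minority class uses the largest stride whose window count reaches the
#' majority count (found to sample precision by bisection, per annotated
#' interval), then the minority windows are truncated to exact balance.
#'
#' @param recordings an [eeg_recording()] or list of them.
#' @param scale_s window length in seconds.
#' @param positive,negative class labels (defaults `preictal` /
#'   `interictal`).
#' @return a `segment_set` with equal counts of both classes and an extra
#'   `strides` field naming the per-class stride used.
#' @export
generate_training_samples <- function(recordings, scale_s,
                                      positive = "preictal",
                                      negative = "interictal") {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  # durations on the sample grid, matching the extraction below
  durations <- function(state) {
    unlist(lapply(recordings, function(rec) {
      a <- rec$annotations
      a <- a[a$state == state, , drop = FALSE]
      (round(a$end_s * rec$fs) - round(a$start_s * rec$fs)) / rec$fs
    }))
  }
  dur_pos <- durations(positive)
  dur_neg <- durations(negative)
  for (cls in list(c(positive, length(dur_pos)), c(negative, length(dur_neg)))) {
    if (as.integer(cls[2L]) == 0L) {
      stop("class '", cls[1L], "' absent from the annotations")
    }
  }
  n_pos_max <- count_windows(dur_pos, scale_s, scale_s)
  n_neg_max <- count_windows(dur_neg, scale_s, scale_s)
  fs_min <- min(vapply(recordings, `[[`, numeric(1), "fs"))
  if (n_pos_max >= n_neg_max) {
    majority <- positive; minority <- negative
    n_major <- n_pos_max; dur_min <- dur_neg
  } else {
    majority <- negative; minority <- positive
    n_major <- n_neg_max; dur_min <- dur_pos
  }
  if (count_windows(dur_min, scale_s, 1 / fs_min) < n_major) {
    stop("cannot balance: class '", minority,
         "' too short even at single-sample stride")
  }
  # largest stride reaching the majority count (count is non-increasing in
  # the stride, so bisect)
  lo <- 1 / fs_min
  hi <- scale_s
  if (count_windows(dur_min, scale_s, hi) >= n_major) {
    stride_min <- hi
  } else {
    for (iter in seq_len(60L)) {
      mid <- (lo + hi) / 2
      if (count_windows(dur_min, scale_s, mid) >= n_major) lo <- mid
      else hi <- mid
    }
    stride_min <- lo
  }
  collect <- function(state, stride) {
    segs <- list()
    for (rec in recordings) {
      a <- rec$annotations
      a <- a[a$state == state, , drop = FALSE]
      for (r in seq_len(nrow(a))) {
        i0 <- round(a$start_s[r] * rec$fs)
        i1 <- round(a$end_s[r] * rec$fs)
        sub <- eeg_recording(
          rec$subject_id,
          rec$signal[(i0 + 1L):i1, , drop = FALSE],
          rec$fs, rec$channel_names,
          data.frame(state = state, start_s = 0, end_s = (i1 - i0) / rec$fs))
        ss <- segment(sub, scale_s, stride)
        for (sgm in ss$segments) {
          sgm$start_s <- sgm$start_s + a$start_s[r]
          segs[[length(segs) + 1L]] <- sgm
        }
      }
    }
    segs
  }
  seg_major <- collect(majority, scale_s)
  seg_minor <- collect(minority, stride_min)
  if (length(seg_minor) < length(seg_major)) {
    stop("internal error: balancing produced too few minority windows")
  }
  seg_minor <- seg_minor[seq_len(length(seg_major))]
  strides <- stats::setNames(c(scale_s, stride_min), c(majority, minority))
  structure(list(scale_s = scale_s, stride_s = NA_real_,
                 segments = c(seg_major, seg_minor),
                 strides = strides),
            class = "segment_set")
}

#' Default probe evaluator for timescale selection
#'
#' Fits a logistic model on cheap per-segment features (per-channel means of
#' the spike fraction, mean spike-run duration, run rate, and log variance)
#' on a training split and returns validation preictal probabilities.
#' Deterministic given the split.
#'
#' @param train_segments,train_labels training windows (list of matrices) and
#'   0/1 labels.
#' @param valid_segments validation windows.
#' @param fs sampling rate of the windows (Hz).
#' @param spiking spiking-encoder settings used for the probe features.
#' @return numeric vector of validation scores.
#' @export
probe_evaluator <- function(train_segments, train_labels, valid_segments, fs,
                            spiking = run_config()$spiking) {
  featurize <- function(w) {
    rep_ <- spike_representation(w, kappa = spiking$kappa,
                                 mode = spiking$mode, beta_slope = NA)
    c(mean(rep_$spike_count) / nrow(w),
      mean(rep_$spike_duration) / fs,
      mean(rep_$n_runs) / (nrow(w) / fs),
      mean(log(apply(w, 2L, stats::var) + 1e-12)))
  }
  X <- t(vapply(train_segments, featurize, numeric(4)))
  Xv <- t(vapply(valid_segments, featurize, numeric(4)))
  df <- as.data.frame(X)
  df$y <- train_labels
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df))
  as.numeric(suppressWarnings(
    stats::predict(fit, newdata = as.data.frame(Xv), type = "response")))
}

#' Select the two best timescales by validation AUC
#'
#' For each candidate timescale, splits its balanced segment set into
#' training and validation parts (stratified, seeded), scores the validation
#' windows with the probe classifier and computes the ROC AUC. Returns the
#' two scales of highest AUC; ties prefer the shorter scale.
#'
#' @param sets_by_scale named list mapping scale (as character, e.g. `"2"`)
#'   to a balanced `segment_set` (from [generate_training_samples()]).
#' @param fs sampling rate of the windows.
#' @param validation_split fraction held out per class (default 0.25).
#' @param seed RNG seed for the stratified split.
#' @param evaluator probe, signature as [probe_evaluator()]. Replaceable for
#'   testing.
#' @param auc_override optional named numeric vector of AUCs keyed by scale;
#'   when given, skips evaluation entirely (stub injection for tests).
#' @return object of class `bi_timescale_choice`: `scales` (numeric pair,
#'   best first) and `auc_by_scale`.
#' @export
select_bi_timescale <- function(sets_by_scale, fs, validation_split = 0.25,
                                seed = 42L, evaluator = probe_evaluator,
                                auc_override = NULL) {
  if (is.null(auc_override)) {
    aucs <- vapply(names(sets_by_scale), function(sc) {
      set <- sets_by_scale[[sc]]
      labs <- segment_labels(set)
      y <- as.integer(labs == "preictal")
      if (length(unique(y)) < 2L) {
        stop("segment set at scale ", sc, " has a single class")
      }
      n <- length(y)
      set.seed(seed)
      valid_idx <- unlist(lapply(split(seq_len(n), y), function(idx) {
        k <- max(1L, round(length(idx) * validation_split))
        sample(idx, k)
      }))
      if (length(unique(y[valid_idx])) < 2L ||
          length(unique(y[-valid_idx])) < 2L) {
        stop("degenerate validation split at scale ", sc)
      }
      windows <- lapply(set$segments, `[[`, "window")
      scores <- evaluator(windows[-valid_idx], y[-valid_idx],
                          windows[valid_idx], fs)
      roc_auc(scores, y[valid_idx])$auc
    }, numeric(1))
  } else {
    aucs <- auc_override[names(sets_by_scale)]
  }
  scales_num <- as.numeric(names(sets_by_scale))
  ord <- order(-aucs, scales_num)
  structure(list(scales = scales_num[ord[1:2]],
                 auc_by_scale = stats::setNames(as.numeric(aucs),
                                                names(sets_by_scale))),
            class = "bi_timescale_choice")
}

#' @export
print.bi_timescale_choice <- function(x, ...) {
  cat("<bi_timescale_choice> scales:", paste(x$scales, collapse = ", "),
      "| AUC:", paste(names(x$auc_by_scale),
                      sprintf("%.3f", x$auc_by_scale),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}
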