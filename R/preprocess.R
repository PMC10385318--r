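# Preprocessing: per-window z-score normalization and correlative channel
# selection (design-of-experiments screening followed by a backward wrapper).

#' Per-window z-score normalization
#'
#' Splits each channel into consecutive non-overlapping blocks of
#' `window_s` seconds and z-scores each block independently (sample standard
#' deviation). EEG amplitudes drift and vary strongly across channels;
#' normalizing per second rather than over the whole recording keeps local
#' transient structure comparable across channels and time. Blocks with
#' standard deviation below `eps`, and any trailing partial block, are set to
#' zero.
#'
#' @param signal numeric matrix (`n_samples x n_channels`) or vector.
#' @param fs sampling rate in Hz.
#' @param window_s block length in seconds (default 1); `window_s * fs` must
#'   be at least 2 samples.
#' @param eps degenerate-block threshold on the standard deviation.
#' @return matrix (or vector) of the same shape.
#' @export
normalize_per_window <- function(signal, fs, window_s = 1.0, eps = 1e-12) {
  vec_in <- !is.matrix(signal)
  if (vec_in) signal <- matrix(signal, ncol = 1L)
  win <- as.integer(round(window_s * fs))
  if (win < 2L) stop("window_s * fs must be >= 2 samples")
  n <- nrow(signal)
  n_complete <- (n %/% win) * win
  out <- matrix(0, n, ncol(signal), dimnames = dimnames(signal))
  if (n_complete > 0L) {
    for (ch in seq_len(ncol(signal))) {
      blocks <- matrix(signal[seq_len(n_complete), ch], nrow = win)
      mu <- colMeans(blocks)
      sdv <- sqrt(colSums((blocks - rep(mu, each = win))^2) / (win - 1L))
      scale <- ifelse(sdv < eps, 0, 1 / pmax(sdv, eps))
      z <- (blocks - rep(mu, each = win)) * rep(scale, each = win)
      out[seq_len(n_complete), ch] <- as.numeric(z)
    }
  }
  if (vec_in) out[, 1L] else out
}

# 12-run Plackett-Burman design for up to 11 two-level factors,
# built by cyclic rotation of the standard generator row plus an all-minus row
pb12_design <- function(m) {
  stopifnot(m <= 11L)
  gen <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)
  rows <- t(vapply(0:10, function(s) gen[((seq_len(11L) - 1L + s) %% 11L) + 1L],
                   numeric(11L)))
  rbind(rows, rep(-1, 11L))[, seq_len(m), drop = FALSE]
}

# fallback two-level screening design for m > 11 factors: seeded balanced
# random columns plus their fold-over (guarantees each factor appears at
# both levels equally often and main effects are estimable)
foldover_design <- function(m, seed) {
  half <- 2L * ceiling((m + 2L) / 4L)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  block <- vapply(seq_len(m), function(j) sample(rep(c(1, -1), half / 2L)),
                  numeric(half))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rbind(block, -block)
}

#' Screening design for channel in/out experiments
#'
#' For `m <= 11` channels, the 12-run Plackett-Burman design; otherwise a
#' seeded fold-over balanced two-level design. `+1` means the channel is in
#' the evaluated subset.
#'
#' @param m number of channels.
#' @param seed seed for the fold-over fallback.
#' @return a `runs x m` matrix of +1/-1.
#' @export
screening_design <- function(m, seed = 42L) {
  if (m <= 11L) pb12_design(m) else foldover_design(m, seed)
}

#' Correlative channel selection
#'
#' Two-phase wrapper selection of a minimal channel subset. Phase 1
#' (screening): evaluate the channel subsets given by a two-level
#' [screening_design()] and rank channels by the main effect of their
#' presence on validation accuracy. Phase 2 (wrapper): backward elimination
#' in ascending main-effect order (ties removed highest-index first);
#' a channel is dropped iff accuracy does not decrease by more than
#' `tolerance`; elimination stops at the first channel whose removal hurts.
#' The selected set is never empty.
#'
#' @param m number of channels (or an [eeg_recording()] / list of them, from
#'   which the channel count is taken).
#' @param evaluator function(channel_indices) -> validation accuracy in
#'   \[0, 1\]; must be deterministic for reproducible traces.
#' @param tolerance maximal accepted accuracy drop per removal (default 0:
#'   only removals that do not decrease accuracy at all are kept).
#' @param seed seed forwarded to the screening design.
#' @return list of class `channel_selection` with `kept_channels` (integer
#'   indices), `main_effects`, and `accuracy_trace` (data.frame of evaluated
#'   subsets and accuracies).
#' @export
select_channels <- function(m, evaluator, tolerance = 0.0, seed = 42L) {
  if (inherits(m, "eeg_recording")) m <- n_channels(m)
  if (is.list(m)) m <- n_channels(m[[1L]])
  m <- as.integer(m)
  stopifnot(m >= 1L)
  trace_sets <- list()
  trace_acc <- numeric()
  eval_subset <- function(idx) {
    acc <- tryCatch(evaluator(idx), error = function(e) {
      stop("evaluator failed on channel set {",
           paste(idx, collapse = ","), "}: ", conditionMessage(e))
    })
    trace_sets[[length(trace_sets) + 1L]] <<- idx
    trace_acc[length(trace_acc) + 1L] <<- acc
    acc
  }
  if (m == 1L) {
    acc <- eval_subset(1L)
    return(structure(list(kept_channels = 1L, main_effects = numeric(1),
                          accuracy_trace = selection_trace(trace_sets, trace_acc)),
                     class = "channel_selection"))
  }
  design <- screening_design(m, seed)
  run_acc <- rep(NA_real_, nrow(design))
  for (r in seq_len(nrow(design))) {
    idx <- which(design[r, ] > 0)
    if (length(idx) == 0L) next
    run_acc[r] <- eval_subset(idx)
  }
  main_effects <- vapply(seq_len(m), function(j) {
    up <- run_acc[design[, j] > 0]
    dn <- run_acc[design[, j] < 0]
    mean(up, na.rm = TRUE) - mean(dn, na.rm = TRUE)
  }, numeric(1))
  main_effects[is.nan(main_effects)] <- 0
  # elimination candidates: least helpful first; ties drop the higher index
  order_idx <- order(main_effects, -seq_len(m))
  current <- seq_len(m)
  best_acc <- eval_subset(current)
  for (ch in order_idx) {
    if (length(current) == 1L) break
    cand <- setdiff(current, ch)
    acc <- eval_subset(cand)
    if (acc >= best_acc - tolerance) {
      current <- cand
      best_acc <- max(best_acc, acc)
    } else {
      break
    }
  }
  structure(list(kept_channels = sort(current), main_effects = main_effects,
                 accuracy_trace = selection_trace(trace_sets, trace_acc)),
            class = "channel_selection")
}

selection_trace <- function(sets, acc) {
  data.frame(
    channel_set = vapply(sets, function(s) paste(s, collapse = "+"),
                         character(1)),
    accuracy = acc,
    stringsAsFactors = FALSE
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection> kept:", paste(x$kept_channels, collapse = ", "),
      sprintf("(%d evaluations)\n", nrow(x$accuracy_trace)))
  invisible(x)
}

#' Full preprocessing of a recording
#'
#' Bandpass filtering followed by per-window normalization; optionally
#' restricted to a subset of channels.
#'
#' @param rec an [eeg_recording()].
#' @param config a [run_config()].
#' @param channels optional integer indices of channels to keep.
#' @return a preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, config = run_config(), channels = NULL) {
  sig <- rec$signal
  names <- rec$channel_names
  if (!is.null(channels)) {
    sig <- sig[, channels, drop = FALSE]
    names <- names[channels]
  }
  sig <- butterworth_bandpass(sig, rec$fs, config$filter$low_hz,
                              config$filter$high_hz, config$filter$order)
  sig <- normalize_per_window(sig, rec$fs, config$normalize$window_s,
                              config$normalize$eps)
  eeg_recording(rec$subject_id, sig, rec$fs, names, rec$annotations)
}
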