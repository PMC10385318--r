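# HRV transition-pattern matching (alpha/beta/gamma), risk staging, and
# preictal-onset / seizure-prediction-horizon localization.

# discretize a positive series into step codes:
#   "L" relative increase  > delta_large        ("much greater")
#   "M" relative increase in (delta_small, delta_large]  ("greater")
#   "S" |relative change| <= delta_small        ("approximately equal")
#   "D" relative decrease beyond delta_small
hrv_step_codes <- function(values, delta_small, delta_large) {
  rel <- diff(values) / values[-length(values)]
  ifelse(rel > delta_large, "L",
         ifelse(rel > delta_small, "M",
                ifelse(rel >= -delta_small, "S", "D")))
}

# match one numeric series; returns list(pattern, index) where index is the
# 1-based series position at which the pattern starts (NA when none)
match_pattern_single <- function(values, delta_small, delta_large) {
  if (length(values) < 5L) stop("need at least 5 points for pattern matching")
  codes <- hrv_step_codes(values, delta_small, delta_large)
  rel <- diff(values) / values[-length(values)]
  n <- length(codes)
  matches <- list()
  for (i in seq_len(n)) {
    # alpha: greater then much-greater, sustained afterwards
    if (i + 1L <= n && codes[i] == "M" && codes[i + 1L] == "L" &&
        (i + 2L > n || all(rel[(i + 2L):n] >= -delta_small))) {
      matches[[length(matches) + 1L]] <- list(pattern = "alpha", index = i)
    }
    # beta: approx-equal, greater, much-greater
    if (i + 2L <= n && codes[i] == "S" && codes[i + 1L] == "M" &&
        codes[i + 2L] == "L") {
      matches[[length(matches) + 1L]] <- list(pattern = "beta", index = i)
    }
    # gamma: approx-equal, approx-equal, greater, much-greater
    if (i + 3L <= n && codes[i] == "S" && codes[i + 1L] == "S" &&
        codes[i + 2L] == "M" && codes[i + 3L] == "L") {
      matches[[length(matches) + 1L]] <- list(pattern = "gamma", index = i)
    }
  }
  if (!length(matches)) return(list(pattern = "none", index = NA_integer_))
  idx <- vapply(matches, `[[`, numeric(1), "index")
  pats <- vapply(matches, `[[`, character(1), "pattern")
  at_min <- idx == min(idx)
  prio <- c(alpha = 1L, beta = 2L, gamma = 3L)
  pick <- which(at_min)[order(prio[pats[at_min]])][1L]
  list(pattern = pats[pick], index = as.integer(idx[pick]))
}

#' Classify the HRV transition pattern of a series
#'
#' Relative changes between consecutive points are discretized
#' (`delta_small` bounds "approximately equal", `delta_large` separates
#' "greater" from "much greater"). The high-risk pattern `alpha` is a
#' moderate rise followed by a jump (sustained thereafter); `beta` prepends
#' one flat step; `gamma` prepends two. Earliest match wins; on the same
#' start index `alpha` beats `beta` beats `gamma`. For a full
#' [hrv_series()], each of the five features is matched independently and
#' the majority pattern is returned (ties toward higher risk, i.e.
#' `alpha > beta > gamma > none`).
#'
#' @param series an [hrv_series()] or a positive numeric vector.
#' @param delta_small relative-change bound for "approximately equal"
#'   (default 0.05).
#' @param delta_large relative-change bound for "much greater"
#'   (default 0.25).
#' @return list with `pattern` (`"alpha"`, `"beta"`, `"gamma"` or
#'   `"none"`), `index` (1-based series position of the match start, NA if
#'   none) and, for an [hrv_series()], `per_feature` votes.
#' @export
classify_hrv_pattern <- function(series, delta_small = 0.05,
                                 delta_large = 0.25) {
  if (is.numeric(series)) {
    return(match_pattern_single(series, delta_small, delta_large))
  }
  stopifnot(inherits(series, "hrv_series"))
  if (length(series$times) < 5L) {
    stop("need at least 5 time points for pattern matching")
  }
  per <- lapply(series$features, function(v) {
    match_pattern_single(as.numeric(v), delta_small, delta_large)
  })
  pats <- vapply(per, `[[`, character(1), "pattern")
  counts <- table(factor(pats, levels = c("alpha", "beta", "gamma", "none")))
  winners <- names(counts)[counts == max(counts)]
  pattern <- winners[1L]  # factor levels are ordered by risk
  idx <- vapply(per[pats == pattern], `[[`, numeric(1), "index")
  list(pattern = pattern,
       index = if (pattern == "none") NA_integer_
               else as.integer(min(idx)),
       per_feature = pats)
}

#' Stage the preictal risk of a patient
#'
#' The matched HRV pattern dominates: `alpha -> Pk1` (high), `beta -> Pk2`
#' (medium), `gamma -> Pk3` (low). Without a pattern, the class falls back
#' to the ANFIS output tier.
#'
#' @param anfis_output continuous risk level from [anfis_predict()] (list
#'   with `output` and `risk_class`, or a bare risk class string).
#' @param hrv_pattern result of [classify_hrv_pattern()] (or a pattern
#'   string).
#' @param eeg_prob coarse-grained preictal probability (recorded in the
#'   assessment).
#' @param subject_id optional subject identifier.
#' @return object of class `risk_assessment`: `subject_id`, `risk_class`,
#'   `pattern`, `source` (`"hrv_pattern"` or `"anfis"`), `eeg_prob`,
#'   `anfis_class`; localization fields are NA until
#'   [localize_preictal_sph()] fills them.
#' @export
stage_risk <- function(anfis_output, hrv_pattern, eeg_prob = NA_real_,
                       subject_id = NA_character_) {
  pattern <- if (is.list(hrv_pattern)) hrv_pattern$pattern else hrv_pattern
  anfis_class <- if (is.list(anfis_output)) anfis_output$risk_class
                 else as.character(anfis_output)
  by_pattern <- c(alpha = "Pk1", beta = "Pk2", gamma = "Pk3")
  if (pattern %in% names(by_pattern)) {
    risk <- unname(by_pattern[pattern])
    source <- "hrv_pattern"
  } else {
    risk <- anfis_class
    source <- "anfis"
  }
  structure(
    list(subject_id = subject_id, risk_class = risk, pattern = pattern,
         source = source, eeg_prob = eeg_prob, anfis_class = anfis_class,
         preictal_start_s = NA_real_, alarm_onset_s = NA_real_,
         sph_s = NA_real_),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %s: %s (pattern %s, via %s), SPH %s\n",
              x$subject_id, x$risk_class, x$pattern, x$source,
              if (is.na(x$sph_s)) "undefined" else paste0(x$sph_s, " s")))
  invisible(x)
}

# localization on one numeric series: earliest k with two successive
# much-greater jumps; preictal start = time of the preceding point
localize_single <- function(times, values, delta_large) {
  rel <- diff(values) / values[-length(values)]
  n <- length(rel)
  for (k in seq_len(max(n - 1L, 0L))) {
    if (rel[k] > delta_large && rel[k + 1L] > delta_large) {
      start_idx <- max(k - 1L, 1L)
      return(list(k = k, preictal_start_s = times[start_idx]))
    }
  }
  NULL
}

#' Localize the preictal onset and the seizure prediction horizon
#'
#' Finds the earliest segment followed by two successive much-greater HRV
#' jumps (relative increase beyond `delta_large`); the preceding segment
#' marks the start of the preictal interval and the alarm onset. The
#' seizure prediction horizon (SPH) is the time from alarm onset to seizure
#' onset. Without a qualifying jump pair the SPH is undefined (explicit NA,
#' not 0). For an [hrv_series()] the earliest localization across the five
#' features is used.
#'
#' @param series an [hrv_series()] or positive numeric vector.
#' @param seizure_onset_s seizure onset time (seconds), at or after the
#'   series start.
#' @param delta_large relative-change bound for "much greater"
#'   (default 0.25).
#' @param times observation times, required when `series` is a bare vector.
#' @return list with `preictal_start_s`, `alarm_onset_s`, `sph_s` (all NA
#'   when no pattern qualifies) and `pattern` (`"jump_pair"` or `"none"`).
#' @export
localize_preictal_sph <- function(series, seizure_onset_s,
                                  delta_large = 0.25, times = NULL) {
  if (is.numeric(series)) {
    stopifnot(!is.null(times), length(times) == length(series))
    hits <- list(localize_single(times, series, delta_large))
  } else {
    stopifnot(inherits(series, "hrv_series"))
    times <- series$times
    hits <- lapply(series$features, function(v) {
      localize_single(times, as.numeric(v), delta_large)
    })
  }
  if (seizure_onset_s < times[1L]) {
    stop("seizure_onset_s precedes the series span")
  }
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) {
    return(list(preictal_start_s = NA_real_, alarm_onset_s = NA_real_,
                sph_s = NA_real_, pattern = "none"))
  }
  starts <- vapply(hits, `[[`, numeric(1), "preictal_start_s")
  start <- min(starts)
  list(preictal_start_s = start, alarm_onset_s = start,
       sph_s = seizure_onset_s - start, pattern = "jump_pair")
}
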