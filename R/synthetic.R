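# Seeded multi-hospital synthetic data: EEG with planted class-dependent
# transient structure, HRV series with planted transition patterns, and
# clinical records drawn from the reference class table. Everything any
# downstream stage needs is generated here, so the full pipeline is
# testable with no external data.

#' Specification of a synthetic multi-hospital dataset
#'
#' Defaults state the simulated world used throughout the test suite:
#' three hospitals of two subjects each, 8 channels at 128 Hz, 5 min
#' interictal + 2.5 min preictal per subject, preictal transients at 2/s
#' (duration 40-80 ms, 25 Hz carrier) against interictal transients at
#' 0.2/s (150-300 ms, 6 Hz carrier), transient amplitude 3x the background
#' standard deviation. Heterogeneous channel counts / sampling rates across
#' hospitals are supported via vector arguments.
#'
#' @param n_hospitals number of simulated hospitals.
#' @param n_subjects subjects per hospital (scalar or per-hospital vector).
#' @param n_channels channels (scalar or per-hospital vector).
#' @param fs sampling rate in Hz (scalar or per-hospital vector).
#' @param interictal_minutes,preictal_minutes annotated minutes per state
#'   and subject.
#' @param preictal_spike_rate,interictal_spike_rate transient rates
#'   (events/s); the preictal rate must exceed the interictal rate (planted
#'   separability).
#' @param spike_amplitude_factor transient amplitude as a multiple of the
#'   background standard deviation (0 disables the planted signal).
#' @param noise_sd background noise standard deviation (microvolts).
#' @param preictal_burst_ms,interictal_burst_ms transient duration ranges
#'   (ms); preictal transients are briefer.
#' @param preictal_carrier_hz,interictal_carrier_hz transient carrier
#'   frequencies; `fs` must be at least twice the highest carrier.
#' @param hrv_risk_classes risk classes cycled over subjects
#'   (`Pk1`/`Pk2`/`Pk3`).
#' @param seed integer master seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_hospitals = 3L, n_subjects = 2L,
                           n_channels = 8L, fs = 128,
                           interictal_minutes = 5, preictal_minutes = 2.5,
                           preictal_spike_rate = 2.0,
                           interictal_spike_rate = 0.2,
                           spike_amplitude_factor = 3,
                           noise_sd = 1,
                           preictal_burst_ms = c(40, 80),
                           interictal_burst_ms = c(150, 300),
                           preictal_carrier_hz = 25,
                           interictal_carrier_hz = 6,
                           hrv_risk_classes = c("Pk1", "Pk2", "Pk3"),
                           seed = 42L) {
  expand <- function(x) rep(x, length.out = n_hospitals)
  spec <- list(
    n_hospitals = as.integer(n_hospitals),
    n_subjects = expand(as.integer(n_subjects)),
    n_channels = expand(as.integer(n_channels)),
    fs = expand(fs),
    interictal_minutes = interictal_minutes,
    preictal_minutes = preictal_minutes,
    preictal_spike_rate = preictal_spike_rate,
    interictal_spike_rate = interictal_spike_rate,
    spike_amplitude_factor = spike_amplitude_factor,
    noise_sd = noise_sd,
    preictal_burst_ms = preictal_burst_ms,
    interictal_burst_ms = interictal_burst_ms,
    preictal_carrier_hz = preictal_carrier_hz,
    interictal_carrier_hz = interictal_carrier_hz,
    hrv_risk_classes = hrv_risk_classes,
    seed = as.integer(seed)
  )
  if (spec$preictal_spike_rate <= spec$interictal_spike_rate) {
    stop("preictal_spike_rate must exceed interictal_spike_rate")
  }
  if (any(spec$fs < 2 * max(spec$preictal_carrier_hz,
                            spec$interictal_carrier_hz))) {
    stop("fs must be at least twice the highest transient carrier frequency")
  }
  if (!all(spec$hrv_risk_classes %in% c("Pk1", "Pk2", "Pk3"))) {
    stop("hrv_risk_classes must be Pk1/Pk2/Pk3")
  }
  class(spec) <- "synthetic_spec"
  spec
}

# AR(1)-colored background noise, unit variance, scaled to noise_sd
colored_noise <- function(n, m, noise_sd, phi = 0.9) {
  w <- matrix(stats::rnorm(n * m), n, m)
  x <- apply(w, 2L, function(col) {
    as.numeric(stats::filter(col, phi, method = "recursive"))
  })
  x * noise_sd * sqrt(1 - phi^2)
}

# damped sinusoid burst, peak amplitude ~1; the decay constant equals the
# nominal duration so the oscillation carries energy across the whole
# burst (at t = duration the envelope is still exp(-1) ~ 0.37)
burst_shape <- function(duration_s, carrier_hz, fs) {
  n <- max(as.integer(round(duration_s * fs)), 2L)
  t <- (seq_len(n) - 1L) / fs
  exp(-t / duration_s) * sin(2 * pi * carrier_hz * t)
}

# overlay transients of one state into a (samples x channels) matrix;
# returns the clean transient component. `focal` is the subject's fixed
# focus: epileptiform activity concentrates in a stable seizure onset
# zone, and the cross-channel seizure-indicator rule relies on the
# resulting contrast between focal and non-focal channels.
plant_transients <- function(n, m, fs, rate, burst_ms, carrier_hz,
                             amplitude, focal) {
  out <- matrix(0, n, m)
  if (amplitude <= 0 || rate <= 0) return(out)
  duration_s <- n / fs
  n_events <- stats::rpois(1L, rate * duration_s)
  if (n_events == 0L) return(out)
  starts <- stats::runif(n_events, 0, duration_s)
  for (ev in seq_len(n_events)) {
    dur <- stats::runif(1L, burst_ms[1L], burst_ms[2L]) / 1000
    shape <- burst_shape(dur, carrier_hz, fs) *
      amplitude * stats::runif(1L, 0.8, 1.2)
    gains <- stats::runif(m, 0.5, 1) * focal
    i0 <- as.integer(round(starts[ev] * fs))
    if (i0 + 2L > n) next  # event starts at the very edge; nothing to plant
    idx <- (i0 + 1L):min(i0 + length(shape), n)
    out[idx, ] <- out[idx, ] + outer(shape[seq_along(idx)], gains)
  }
  out
}

generate_eeg_recording <- function(subject_id, n_channels, fs, spec, seed,
                                   return_components = FALSE) {
  set.seed(seed)
  ti <- spec$interictal_minutes * 60
  tp <- spec$preictal_minutes * 60
  n_i <- as.integer(round(ti * fs))
  n_p <- as.integer(round(tp * fs))
  n <- n_i + n_p
  background <- colored_noise(n, n_channels, spec$noise_sd)
  amp <- spec$spike_amplitude_factor * spec$noise_sd
  # stable per-subject seizure onset zone spanning about half the montage
  focal <- rep(FALSE, n_channels)
  focal[sample.int(n_channels, max(1L, n_channels %/% 2L))] <- TRUE
  trans <- rbind(
    plant_transients(n_i, n_channels, fs, spec$interictal_spike_rate,
                     spec$interictal_burst_ms, spec$interictal_carrier_hz,
                     amp, focal),
    plant_transients(n_p, n_channels, fs, spec$preictal_spike_rate,
                     spec$preictal_burst_ms, spec$preictal_carrier_hz, amp,
                     focal)
  )
  ann <- data.frame(state = c("interictal", "preictal"),
                    start_s = c(0, ti), end_s = c(ti, ti + tp))
  rec <- eeg_recording(subject_id, background + trans, fs,
                       paste0("ch", seq_len(n_channels)), ann)
  attr(rec, "focal") <- focal
  if (return_components) attr(rec, "transients") <- trans
  rec
}

#' Generate the synthetic multi-hospital EEG dataset
#'
#' One recording per subject: colored-noise background, an interictal
#' interval with sparse long low-frequency transients followed by a
#' preictal interval with frequent brief high-frequency transients, and
#' exact annotations of the planted states. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param return_components attach the clean transient component of each
#'   recording as attribute `"transients"` (for oracle checks).
#' @return list (one element per hospital) of lists of [eeg_recording()].
#' @export
generate_eeg_dataset <- function(spec, return_components = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lapply(seq_len(spec$n_hospitals), function(h) {
    lapply(seq_len(spec$n_subjects[h]), function(s) {
      generate_eeg_recording(
        sprintf("H%02dS%02d", h, s), spec$n_channels[h], spec$fs[h], spec,
        seed = spec$seed + 1000L * h + s, return_components)
    })
  })
}

#' Generate an HRV feature series with a planted transition pattern
#'
#' Base levels sit at each feature's class-range midpoint for the given
#' risk class. Exactly one transition pattern is planted at a random
#' position: `alpha` for Pk1 (moderate rise then jump), `beta` for Pk2
#' (flat, rise, jump), `gamma` for Pk3 (flat, flat, rise, jump). Elsewhere
#' fluctuations stay well below `delta_small` relative change; when the
#' pattern does not start at the first point, the step immediately before
#' it is a small guard drop (just beyond `delta_small`) so the planted
#' pattern start is unambiguous to the matcher.
#'
#' @param risk_class `"Pk1"`, `"Pk2"` or `"Pk3"`.
#' @param n_points number of observations (>= 5; >= 6 for a guard before a
#'   non-initial gamma).
#' @param delta_small,delta_large relative-change bounds (defaults 0.05 /
#'   0.25).
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @param dt_s spacing of observations in seconds (default 60).
#' @return an [hrv_series()] with attributes `planted_pattern` and
#'   `planted_index` (1-based series position of the pattern start).
#' @export
generate_hrv_series <- function(risk_class, n_points = 12L,
                                delta_small = 0.05, delta_large = 0.25,
                                seed = 42L, subject_id = "synthetic",
                                dt_s = 60) {
  if (n_points < 5L) stop("n_points must be at least 5")
  risk_class <- match.arg(risk_class, c("Pk1", "Pk2", "Pk3"))
  pattern <- c(Pk1 = "alpha", Pk2 = "beta", Pk3 = "gamma")[[risk_class]]
  n_steps_pat <- c(alpha = 2L, beta = 3L, gamma = 4L)[[pattern]]
  table_class <- c(Pk1 = "High", Pk2 = "Medium", Pk3 = "Low")[[risk_class]]
  set.seed(seed)
  n_steps <- n_points - 1L
  # pattern start step p (1-based); leave room for a guard when p > 1
  p_max <- n_steps - n_steps_pat + 1L
  if (p_max < 1L) stop("n_points too small for pattern '", pattern, "'")
  p <- sample.int(p_max, 1L)
  rel_steps <- stats::runif(n_steps, -0.4 * delta_small, 0.4 * delta_small)
  if (p > 1L) rel_steps[p - 1L] <- -1.5 * delta_small  # guard drop
  pat_rel <- c(
    if (pattern == "gamma") stats::runif(2L, -0.4, 0.4) * delta_small,
    if (pattern == "beta") stats::runif(1L, -0.4, 0.4) * delta_small,
    stats::runif(1L, 1.3 * delta_small, 0.9 * delta_large),   # "greater"
    stats::runif(1L, 1.2 * delta_large, 1.8 * delta_large)    # "much greater"
  )
  rel_steps[p:(p + n_steps_pat - 1L)] <- pat_rel
  ranges <- fuzzy_class_ranges()
  features <- lapply(HRV_FEATURES, function(f) {
    r <- ranges[[f]][table_class, ]
    base <- (r[["lo"]] + r[["hi"]]) / 2
    base * cumprod(c(1, 1 + rel_steps))
  })
  names(features) <- HRV_FEATURES
  out <- hrv_series(subject_id, (seq_len(n_points) - 1L) * dt_s,
                    as.data.frame(features))
  attr(out, "planted_pattern") <- pattern
  attr(out, "planted_index") <- p
  out
}

#' Generate a clinical record for a risk class
#'
#' Flags and seizure-event counts follow the reference class table: Low
#' (Pk3) has no genetic/metabolic etiology and 1-2 prior events; Medium
#' (Pk2) has both flags and 3-5 events; High (Pk1) has both flags and more
#' than 5 events.
#'
#' @param subject_id subject identifier.
#' @param risk_class `"Pk1"`, `"Pk2"` or `"Pk3"`.
#' @param seed integer seed.
#' @return a [clinical_record()].
#' @export
generate_clinical_record <- function(subject_id, risk_class, seed = 42L) {
  risk_class <- match.arg(risk_class, c("Pk1", "Pk2", "Pk3"))
  set.seed(seed)
  events <- switch(risk_class,
                   Pk3 = sample(1:2, 1L),
                   Pk2 = sample(3:5, 1L),
                   Pk1 = sample(6:12, 1L))
  flags <- risk_class %in% c("Pk1", "Pk2")
  clinical_record(subject_id, age = sample(5:60, 1L),
                  gender = sample(c("F", "M"), 1L),
                  genetic = flags, metabolic = flags,
                  seizure_event_count = events)
}

#' Generate the full multi-hospital dataset (EEG + HRV + clinical)
#'
#' @param spec a [synthetic_spec()].
#' @return list per hospital: `recordings`, `hrv` (one [hrv_series()] per
#'   subject), `clinical` (one [clinical_record()] per subject),
#'   `risk_classes`.
#' @export
generate_federation_dataset <- function(spec) {
  eeg <- generate_eeg_dataset(spec)
  lapply(seq_len(spec$n_hospitals), function(h) {
    n_sub <- spec$n_subjects[h]
    classes <- rep(spec$hrv_risk_classes, length.out = n_sub)
    list(
      recordings = eeg[[h]],
      hrv = lapply(seq_len(n_sub), function(s) {
        generate_hrv_series(classes[s], seed = spec$seed + 500L * h + s,
                            subject_id = eeg[[h]][[s]]$subject_id)
      }),
      clinical = lapply(seq_len(n_sub), function(s) {
        generate_clinical_record(eeg[[h]][[s]]$subject_id, classes[s],
                                 seed = spec$seed + 700L * h + s)
      }),
      risk_classes = classes
    )
  })
}
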