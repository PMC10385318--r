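# Shared fixtures, built in code and cached per test run.

# small single-hospital synthetic world (kept light: every user re-runs it)
tiny_spec <- function(seed = 7L) {
  synthetic_spec(n_hospitals = 1L, n_subjects = 1L,
                 interictal_minutes = 2, preictal_minutes = 1, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

# one preprocessed recording from the tiny world, cached
tiny_recording <- function(seed = 7L) {
  key <- paste0("rec", seed)
  if (is.null(.fixture_env[[key]])) {
    data <- generate_eeg_dataset(tiny_spec(seed))
    .fixture_env[[key]] <- preprocess_recording(data[[1]][[1]])
  }
  .fixture_env[[key]]
}

# small bi-timescale pair set + graph from the tiny world, cached
tiny_pairs <- function(seed = 7L, scales = c(1, 2)) {
  key <- paste0("pairs", seed, paste(scales, collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    rec <- tiny_recording(seed)
    .fixture_env[[key]] <- list(
      pairs = build_timescale_pairs(list(rec), scales),
      graph = build_graph(rec$signal, 0.3),
      fs = rec$fs
    )
  }
  .fixture_env[[key]]
}

# independent brute-force spike-run oracle (rle-based, per channel)
oracle_spike_stats <- function(encoded) {
  m <- ncol(encoded)
  count <- numeric(m); duration <- numeric(m); runs <- numeric(m)
  for (q in seq_len(m)) {
    r <- rle(as.integer(encoded[, q]))
    lens <- r$lengths[r$values == 1L]
    count[q] <- sum(lens)
    runs[q] <- length(lens)
    duration[q] <- if (length(lens)) mean(lens) else 0
  }
  list(spike_count = count, spike_duration = duration, n_runs = runs)
}

# independent regex-style HRV pattern matcher over the discretized step
# sequence (dual route for classify_hrv_pattern)
oracle_match_pattern <- function(values, delta_small, delta_large) {
  rel <- diff(values) / values[-length(values)]
  code <- ifelse(rel > delta_large, "L",
                 ifelse(rel > delta_small, "M",
                        ifelse(rel >= -delta_small, "S", "D")))
  s <- paste(code, collapse = "")
  hits <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1L]]
    if (m[1L] > 0) as.integer(m) else integer(0)
  }
  ia <- hits("ML")
  # alpha requires sustained rises afterwards (no drop beyond delta_small)
  ia <- ia[vapply(ia, function(i) {
    !any(rel[seq_along(rel) > i + 1L] < -delta_small)
  }, logical(1))]
  ia <- if (length(ia)) min(ia) else NA_integer_
  ib <- hits("SML"); ib <- if (length(ib)) min(ib) else NA_integer_
  ig <- hits("SSML"); ig <- if (length(ig)) min(ig) else NA_integer_
  cand <- c(alpha = ia, beta = ib, gamma = ig)
  if (all(is.na(cand))) return(list(pattern = "none", index = NA_integer_))
  best <- min(cand, na.rm = TRUE)
  at_best <- names(cand)[!is.na(cand) & cand == best]
  list(pattern = at_best[1L], index = best)  # names ordered by priority
}

# reduced PSO/ANFIS settings so training tests stay fast
fast_anfis_config <- function() {
  run_config(pso = list(swarm_size = 4L, iterations = 3L),
             anfis = list(premise_iterations = 3L))
}
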