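test_that("synthetic spec validates its invariants", {
  expect_error(synthetic_spec(preictal_spike_rate = 0.1,
                              interictal_spike_rate = 0.2),
               "must exceed")
  expect_error(synthetic_spec(fs = 32), "twice the highest")
  sp <- synthetic_spec(n_hospitals = 2, n_channels = c(8, 6), fs = c(128, 64))
  expect_equal(sp$n_channels, c(8L, 6L))
})

test_that("EEG generation is deterministic given the seed", {
  a <- generate_eeg_dataset(tiny_spec(3))
  b <- generate_eeg_dataset(tiny_spec(3))
  expect_identical(a[[1]][[1]]$signal, b[[1]][[1]]$signal)
  c <- generate_eeg_dataset(tiny_spec(4))
  expect_false(identical(a[[1]][[1]]$signal, c[[1]][[1]]$signal))
})

test_that("hospitals can differ in channel count and sampling rate", {
  sp <- synthetic_spec(n_hospitals = 3, n_subjects = 1, n_channels = c(8, 6, 10),
                       fs = c(128, 64, 256), interictal_minutes = 0.5,
                       preictal_minutes = 0.25, seed = 5)
  data <- generate_eeg_dataset(sp)
  expect_equal(vapply(data, function(h) ncol(h[[1]]$signal), numeric(1)),
               c(8, 6, 10))
  expect_equal(vapply(data, function(h) h[[1]]$fs, numeric(1)),
               c(128, 64, 256))
})

test_that("zero amplitude factor removes the planted class difference", {
  sp <- tiny_spec(21)
  sp$spike_amplitude_factor <- 0
  rec <- generate_eeg_dataset(sp)[[1]][[1]]
  set1 <- segment(rec, 1)
  labs <- vapply(set1$segments, `[[`, character(1), "label")
  v <- vapply(set1$segments, function(s) mean(apply(s$window, 2, stats::var)),
              numeric(1))
  pre <- v[labs == "preictal"][1:50]
  int <- v[labs == "interictal"][1:50]
  expect_gt(stats::t.test(pre, int)$p.value, 0.01)
})

test_that("planted transient rate separates classes on the clean component", {
  sp <- tiny_spec(22)  # rates 2.0 vs 0.2 by default
  rec <- generate_eeg_dataset(sp, return_components = TRUE)[[1]][[1]]
  trans <- attr(rec, "transients")
  thr <- 0.5 * sp$spike_amplitude_factor * sp$noise_sd
  per_second <- function(idx) {
    sec <- floor((idx - 1) / rec$fs)
    active <- rowSums(abs(trans[idx, , drop = FALSE]) > thr) > 0
    mean(tapply(active, sec[seq_along(active)] - sec[1], function(x) {
      sum(diff(c(FALSE, x)) == 1)
    }))
  }
  n_i <- sp$interictal_minutes * 60 * rec$fs
  rate_int <- per_second(1:n_i)
  rate_pre <- per_second((n_i + 1):nrow(trans))
  expect_gte(rate_pre, 3 * rate_int)
})

test_that("HRV generator plants the class pattern and the matcher recovers it", {
  h1 <- generate_hrv_series("Pk1", seed = 31)
  expect_identical(attr(h1, "planted_pattern"), "alpha")
  # the planted high-risk transition: one moderate rise then one jump
  v <- h1$features$SDNN
  rel <- diff(v) / v[-length(v)]
  i <- attr(h1, "planted_index")
  expect_true(rel[i] > 0.05 && rel[i] <= 0.25)
  expect_gt(rel[i + 1], 0.25)

  h3 <- generate_hrv_series("Pk3", seed = 32)
  expect_identical(classify_hrv_pattern(h3)$pattern, "gamma")

  same <- generate_hrv_series("Pk2", seed = 33)
  again <- generate_hrv_series("Pk2", seed = 33)
  expect_identical(same$features, again$features)
})

test_that("matcher recovers the planted class across seeds and classes", {
  classes <- c("Pk1", "Pk2", "Pk3")
  expected <- c(Pk1 = "alpha", Pk2 = "beta", Pk3 = "gamma")
  for (seed in 1:60) {
    cls <- classes[(seed %% 3) + 1]
    h <- generate_hrv_series(cls, n_points = 5L + (seed %% 8), seed = seed)
    expect_identical(classify_hrv_pattern(h)$pattern,
                     unname(expected[cls]))
  }
})

test_that("clinical records follow the class table", {
  high <- generate_clinical_record("s", "Pk1", seed = 41)
  expect_gte(high$seizure_event_count, 6L)
  expect_true(high$genetic && high$metabolic)
  low <- generate_clinical_record("s", "Pk3", seed = 42)
  expect_false(low$genetic || low$metabolic)
  expect_true(low$seizure_event_count > 0 && low$seizure_event_count < 3)
  med <- generate_clinical_record("s", "Pk2", seed = 43)
  expect_true(med$seizure_event_count >= 3 && med$seizure_event_count <= 5)
  expect_identical(unclass(generate_clinical_record("s", "Pk1", seed = 9)),
                   unclass(generate_clinical_record("s", "Pk1", seed = 9)))
})

test_that("stronger planted amplitude never hurts downstream separability", {
  # probe-level proxy for end-to-end performance (validation AUC, averaged
  # over a fixed seed grid), 3 amplitude levels
  aucs <- vapply(c(0, 1.5, 3), function(amp) {
    mean(vapply(17:19, function(sd) {
      sp <- tiny_spec(sd)
      sp$spike_amplitude_factor <- amp
      rec <- preprocess_recording(generate_eeg_dataset(sp)[[1]][[1]])
      set2 <- generate_training_samples(rec, 2)
      labs <- vapply(set2$segments, `[[`, character(1), "label")
      y <- as.integer(labs == "preictal")
      windows <- lapply(set2$segments, `[[`, "window")
      set.seed(1)
      valid <- sort(sample(length(y), 30))
      scores <- probe_evaluator(windows[-valid], y[-valid], windows[valid],
                                rec$fs)
      roc_auc(scores, y[valid])$auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})
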