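test_that("fuzzification follows the coarse-probability class ranges", {
  var <- fuzzy_variable("eeg", fuzzy_class_ranges()$eeg_probability)
  mu_low <- fuzzify(0.15, var)
  expect_equal(which.max(mu_low), 1L, ignore_attr = TRUE)
  expect_equal(unname(mu_low[["Low"]]), 1)  # 0.15 is the Low peak
  mu_high <- fuzzify(0.80, var)
  expect_equal(which.max(mu_high), 3L, ignore_attr = TRUE)
  mu_med <- fuzzify(0.455, var)
  expect_equal(unname(mu_med[["Medium"]]), 1)
  # any in-range value keeps a positive membership sum (gap at 0.3/0.31)
  expect_gt(sum(fuzzify(0.305, var)), 0)
})

test_that("composite aggregation maps the nine raw inputs to three", {
  ranges <- fuzzy_class_ranges()
  peak <- function(f, cls) mean(ranges[[f]][cls, ])
  hrv3 <- c(Lmax = peak("Lmax", "High"), SDNN = peak("SDNN", "High"),
            LF_HF = peak("LF_HF", "High"), MeanHR = peak("MeanHR", "High"),
            pNN50 = peak("pNN50", "High"))
  clin_high <- list(genetic = TRUE, metabolic = TRUE,
                    seizure_event_count = 8L)
  x <- aggregate_inputs(0.9, hrv3, clin_high)
  expect_equal(unname(x["hrv"]), 1.0)
  expect_equal(unname(x["eeg"]), 0.9)

  # classes {1,1,2,2,3} -> mean of {0,0,0.5,0.5,1} = 0.4
  hrv_mixed <- c(Lmax = peak("Lmax", "Low"), LF_HF = peak("LF_HF", "Low"),
                 SDNN = peak("SDNN", "Medium"),
                 MeanHR = peak("MeanHR", "Medium"),
                 pNN50 = peak("pNN50", "High"))
  xm <- aggregate_inputs(0.5, hrv_mixed, clin_high)
  expect_equal(unname(xm["hrv"]), 0.4)

  clin_low <- list(genetic = FALSE, metabolic = FALSE,
                   seizure_event_count = 1L)
  xl <- aggregate_inputs(0.1, hrv_mixed, clin_low)
  expect_equal(unname(xl["clinical"]), 0)

  expect_error(aggregate_inputs(0.5, hrv_mixed[-1], clin_low), "Lmax")
  expect_error(aggregate_inputs(0.5, hrv_mixed, list(genetic = TRUE)),
               "metabolic")
})

test_that("Sugeno prediction is a normalized convex rule combination", {
  model <- anfis_init(1)
  model$consequents[] <- 0
  model$consequents[, 1] <- 0.42
  for (x in list(c(0, 0, 0), c(0.5, 0.2, 0.9), c(1, 1, 1))) {
    expect_equal(anfis_predict(model, x)$output, 0.42, tolerance = 1e-12)
  }
  # inputs at the Low peaks fire the (Low,Low,Low) rule alone
  model2 <- anfis_init(2)
  x0 <- c(0.15, 0.15, 0.15)
  rule1 <- which(rowSums(model2$rules == 1L) == 3L)
  want <- model2$consequents[rule1, 1] +
    sum(model2$consequents[rule1, 2:4] * x0)
  expect_equal(anfis_predict(model2, x0)$output, want, tolerance = 1e-9)
})

test_that("the ANFIS surface is continuous in each input", {
  model <- anfis_init(3)
  grid <- seq(0, 1, by = 0.01)
  out <- vapply(grid, function(v) {
    anfis_predict(model, c(v, 0.4, 0.6))$output
  }, numeric(1))
  expect_true(all(abs(diff(out)) < 0.05))
})

test_that("rule firing strengths normalize to one whenever any rule fires", {
  model <- anfis_init(4)
  set.seed(4)
  for (i in 1:50) {
    w <- fedseizr:::firing_strengths(model, stats::runif(3))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("hybrid ANFIS training reduces the MAE on a monotone target", {
  cfg <- fast_anfis_config()
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(stats::runif(60), 20, 3)
    y <- 0.2 * X[, 1] + 0.5 * X[, 2] + 0.3 * X[, 3]
    model <- train_anfis_pso(anfis_init(seed), X, y, cfg, seed = seed)
    log <- model$training_log
    expect_lte(log[length(log)], log[1] + 1e-12)
  }
})

test_that("training is deterministic and degenerate PSO is plain hybrid", {
  set.seed(1)
  X <- matrix(stats::runif(45), 15, 3)
  y <- rowMeans(X)
  cfg <- fast_anfis_config()
  m1 <- train_anfis_pso(anfis_init(5), X, y, cfg, seed = 9)
  m2 <- train_anfis_pso(anfis_init(5), X, y, cfg, seed = 9)
  expect_identical(m1$premise, m2$premise)
  expect_identical(m1$consequents, m2$consequents)

  cfg1 <- run_config(pso = list(swarm_size = 1L, iterations = 0L),
                     anfis = list(premise_iterations = 3L))
  m3 <- train_anfis_pso(anfis_init(5), X, y, cfg1, seed = 9)
  plain <- fedseizr:::anfis_hybrid(anfis_init(5), X, y, 3L,
                                   cfg1$anfis$premise_step,
                                   cfg1$anfis$ridge_lambda)
  expect_equal(m3$premise, plain$premise)
  expect_equal(m3$consequents, plain$consequents)

  expect_warning(
    train_anfis_pso(anfis_init(1), X, rep(0.5, nrow(X)), cfg, seed = 1),
    "identical")
  expect_error(train_anfis_pso(anfis_init(1), X[1:5, ], y[1:5], cfg, 1),
               "at least 10")
})

test_that("HRV pattern matching follows the worked examples", {
  a <- classify_hrv_pattern(c(100, 110, 150, 160, 161))
  expect_identical(a$pattern, "alpha")
  expect_equal(a$index, 1L)

  expect_identical(classify_hrv_pattern(c(100, 101, 100.5, 101, 100.8))$pattern,
                   "none")
  b <- classify_hrv_pattern(c(100, 101, 112, 150, 151))
  expect_identical(b$pattern, "beta")
  g <- classify_hrv_pattern(c(100, 101, 100, 111, 145, 146))
  expect_identical(g$pattern, "gamma")
  expect_error(classify_hrv_pattern(c(1, 2, 3)), "5 points")
})

test_that("earliest match wins and longer patterns claim their start", {
  # beta at step 2 contains an alpha at step 3: beta starts earlier
  s <- c(100, 92, 92.5, 102, 135, 136)
  expect_identical(classify_hrv_pattern(s)$pattern, "beta")
  # two flat steps before the rise make it gamma, which starts earlier
  # than the contained beta and alpha
  s1 <- c(100, 100.5, 101, 112, 150, 152)
  expect_identical(classify_hrv_pattern(s1)$pattern, "gamma")
  # a drop resets the context; alpha stands alone afterwards
  s2 <- c(100, 92, 102, 140, 141)
  expect_identical(classify_hrv_pattern(s2)$pattern, "alpha")
})

test_that("pattern matching agrees with the independent oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    v <- 100 * cumprod(1 + stats::runif(n, -0.2, 0.35))
    got <- classify_hrv_pattern(v)
    want <- oracle_match_pattern(v, 0.05, 0.25)
    expect_identical(got$pattern, want$pattern)
    if (got$pattern != "none") expect_equal(got$index, want$index)
  }
})

test_that("majority vote across the five features breaks ties to higher risk", {
  h <- generate_hrv_series("Pk2", seed = 14)
  res <- classify_hrv_pattern(h)
  expect_identical(res$pattern, "beta")
  expect_length(res$per_feature, 5L)
  expect_true(all(res$per_feature == "beta"))
})

test_that("risk staging prioritizes the HRV pattern over the ANFIS tier", {
  expect_identical(stage_risk("Pk3", "alpha")$risk_class, "Pk1")
  expect_identical(stage_risk("Pk1", "gamma")$risk_class, "Pk3")
  expect_identical(stage_risk("Pk2", "beta")$risk_class, "Pk2")
  a <- stage_risk(list(output = 0.9, risk_class = "Pk1"), "none")
  expect_identical(a$risk_class, "Pk1")
  expect_identical(a$source, "anfis")
})

test_that("SPH localization matches the worked example", {
  loc <- localize_preictal_sph(c(100, 102, 140, 200, 210),
                               seizure_onset_s = 300, delta_large = 0.25,
                               times = c(0, 60, 120, 180, 240))
  expect_equal(loc$preictal_start_s, 0)
  expect_equal(loc$alarm_onset_s, 0)
  expect_equal(loc$sph_s, 300)

  flat <- localize_preictal_sph(c(100, 101, 102, 101, 100), 300,
                                times = c(0, 60, 120, 180, 240))
  expect_true(is.na(flat$sph_s))
  expect_identical(flat$pattern, "none")

  # the preceding segment is clamped to the series start
  loc2 <- localize_preictal_sph(c(100, 140, 200, 201, 202), 250,
                                times = c(0, 60, 120, 180, 240))
  expect_equal(loc2$preictal_start_s, 0)
  expect_error(localize_preictal_sph(c(100, 140, 200, 201, 202), -10,
                                     times = c(0, 60, 120, 180, 240)),
               "precedes")
})

test_that("SPH is nonnegative whenever defined (random onsets)", {
  set.seed(15)
  for (i in 1:30) {
    v <- 100 * cumprod(1 + stats::runif(8, -0.1, 0.4))
    times <- seq(0, by = 60, length.out = 8)
    onset <- stats::runif(1, max(times), max(times) + 600)
    loc <- localize_preictal_sph(v, onset, times = times)
    if (!is.na(loc$sph_s)) expect_gte(loc$sph_s, 0)
  }
})
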