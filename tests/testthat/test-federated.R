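random_params <- function(seed, cfg = run_config()) {
  set.seed(seed)
  fedseizr:::init_gcnn_params(cfg, 2L)
}

test_that("FedAvg is the sample-count weighted convex combination", {
  a <- random_params(1); b <- random_params(2)
  same <- fedavg_aggregate(list(a, a), c(5, 5))
  expect_equal(fedseizr:::param_tensors(same), fedseizr:::param_tensors(a))

  zero <- a; one <- a
  for (k in 1:2) {
    zero$branches[[k]]$W0[] <- 0; zero$branches[[k]]$W1[] <- 0
    one$branches[[k]]$W0[] <- 1; one$branches[[k]]$W1[] <- 1
  }
  zero$Wd[] <- 0; zero$bd[] <- 0; zero$offset <- 0
  one$Wd[] <- 1; one$bd[] <- 1; one$offset <- 1
  mid <- fedavg_aggregate(list(zero, one), c(1, 1))
  expect_true(all(abs(unlist(fedseizr:::param_tensors(mid)) - 0.5) < 1e-12))
  quarter <- fedavg_aggregate(list(zero, one), c(3, 1))
  expect_true(all(abs(unlist(fedseizr:::param_tensors(quarter)) - 0.25) < 1e-12))
})

test_that("aggregated parameters stay inside the clients' elementwise range", {
  ps <- lapply(1:4, random_params)
  agg <- fedavg_aggregate(ps, c(2, 1, 4, 3))
  at <- unlist(fedseizr:::param_tensors(agg))
  mat <- vapply(ps, function(p) unlist(fedseizr:::param_tensors(p)),
                numeric(length(at)))
  expect_true(all(at >= apply(mat, 1, min) - 1e-12))
  expect_true(all(at <= apply(mat, 1, max) + 1e-12))
})

test_that("architecture mismatches are rejected", {
  a <- random_params(1)
  b <- random_params(2, run_config(gcnn = list(hidden_units = c(8L, 8L))))
  expect_error(fedavg_aggregate(list(a, b), c(1, 1)), "mismatch")
})

test_that("the global loss is the summed NLL of the true class", {
  P <- matrix(c(1, 0), 1)
  expect_equal(global_loss(P, 1L), 0)
  expect_equal(global_loss(matrix(c(0.5, 0.5), 1), 1L), 0.6931, tolerance = 1e-4)
  # additive over subjects
  P1 <- matrix(c(0.8, 0.2), 1); P2 <- matrix(c(0.3, 0.7), 1)
  expect_equal(global_loss(list(P1, P2), list(1L, 2L)),
               global_loss(P1, 1L) + global_loss(P2, 2L))
  expect_error(global_loss(matrix(c(0, 1), 1), 1L), "zero probability")
  expect_equal(global_loss(matrix(c(0, 1), 1), 1L, eps = 1e-6),
               -log(1e-6))
})

test_that("Eq.-style normalization of the global probability branches", {
  expect_equal(normalize_global_probability(0.8, 10, 2), 0.8)
  expect_equal(normalize_global_probability(0.5, 2, 10), 0.6931,
               tolerance = 1e-4)
  expect_equal(normalize_global_probability(0.9, 2, 10), 0.1054,
               tolerance = 1e-3)
  # damped value is clamped into (0, 1]
  expect_equal(normalize_global_probability(0.05, 0, 5), 1)
  expect_error(normalize_global_probability(1, 1, 0), "inside")
})

test_that("Bregman divergence equals the Bernoulli KL and is nonnegative", {
  expect_equal(bregman_divergence(0.5, 0.5), 0)
  expect_equal(bregman_divergence(0.9, 0.5), 0.3681, tolerance = 1e-4)
  grid <- seq(0.01, 0.99, length.out = 99)
  kl <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  D <- outer(grid, grid, Vectorize(bregman_divergence))
  K <- outer(grid, grid, kl)
  expect_true(all(D >= 0))
  expect_true(all(D[abs(outer(grid, grid, `-`)) > 1e-12] > 0))
  expect_lt(max(abs(D - K)), 1e-12)
  # random-pair cross-check against the independent two-term KL
  set.seed(12)
  for (i in 1:1000) {
    p <- stats::runif(1, 0.001, 0.999); q <- stats::runif(1, 0.001, 0.999)
    expect_equal(bregman_divergence(p, q), kl(p, q), tolerance = 1e-12)
  }
  expect_equal(bregman_divergence(0, 0.3), -log(0.7), tolerance = 1e-12)
  expect_error(bregman_divergence(0.5, 1), "boundary")
})

test_that("the personalized loss is the stated weighted sum", {
  expect_equal(personalized_loss(0.7, 0.3, w1 = 2, w2 = 0), 1.4)
  expect_equal(personalized_loss(0.5, 0.25, 1, 1), 0.75)
  l1 <- personalized_loss(0.5, 0.2, 1, 0.5)
  l2 <- personalized_loss(0.5, 0.4, 1, 0.5)
  expect_gt(l2, l1)
  expect_error(personalized_loss(0.5, 0.2, -1, 0), "w1")
})

test_that("early stopping retains the best round", {
  es <- early_stopping_trace(c(1.0, 0.9, 0.9, 0.9), patience = 2)
  expect_equal(es$stop_round, 4L)
  expect_equal(es$best_round, 2L)
  es2 <- early_stopping_trace(c(1, 0.8, 0.6, 0.5), patience = 2)
  expect_equal(es2$stop_round, 4L)
  expect_equal(es2$best_round, 4L)
  es3 <- early_stopping_trace(c(1, 1.1, 1.2), patience = 2)
  expect_equal(es3$stop_round, 3L)
  expect_equal(es3$best_round, 1L)
})

test_that("a single client with w2 = 0 reproduces centralized training", {
  fx <- tiny_pairs(7, c(1, 2))
  cfg <- run_config(gcnn = list(epochs = 3L),
                    federated = list(w2 = 0, rounds_max = 1L))
  fed <- run_federation(list(list(pairs = fx$pairs, graph = fx$graph,
                                  fs = fx$fs)), cfg, seed = 21)
  labs <- vapply(fx$pairs, `[[`, character(1), "label")
  train_idx <- setdiff(seq_along(fx$pairs),
                       fedseizr:::stratified_split(
                         labs, cfg$federated$validation_split,
                         21 + 7919L))
  central <- train_local(fx$pairs[train_idx], fx$graph, fx$fs, cfg,
                         seed = 21)
  expect_identical(fedseizr:::param_tensors(fed$clients[[1]]),
                   fedseizr:::param_tensors(central))
  # the aggregate of one client is that client
  expect_identical(fedseizr:::param_tensors(fed$global),
                   fedseizr:::param_tensors(central))
})

test_that("federation rounds improve the personalized validation loss", {
  fx <- tiny_pairs(7, c(1, 2))
  half <- length(fx$pairs) %/% 2
  clients <- list(
    list(pairs = fx$pairs[seq_len(half)], graph = fx$graph, fs = fx$fs),
    list(pairs = fx$pairs[(half + 1):length(fx$pairs)], graph = fx$graph,
         fs = fx$fs))
  cfg <- run_config(gcnn = list(epochs = 3L),
                    federated = list(rounds_max = 3L))
  fed <- run_federation(clients, cfg, seed = 5)
  expect_s3_class(fed, "federation_state")
  expect_equal(nrow(fed$history), fed$stop_round)
  expect_lte(min(fed$history$validation_loss),
             fed$history$validation_loss[1] + 1e-9)
  expect_equal(length(fed$n_high), 2L)
  expect_equal(length(fed$clients), 2L)
})

test_that("federation does not lose to the best single-hospital model", {
  # three hospitals sharing the planted structure: the federated
  # personalized models, pooled over all hospitals' held-out windows, must
  # reach at least the best single-hospital model's pooled accuracy - 0.02
  # on each of 5 seeds (single models train on the same split the
  # federation clients use)
  for (seed in 1:5) {
    spec <- synthetic_spec(n_subjects = 1L, seed = 400 + seed)
    data <- generate_eeg_dataset(spec)
    cfg <- run_config(federated = list(rounds_max = 4L))
    clients <- list()
    tests <- list()
    for (h in 1:3) {
      rec <- preprocess_recording(data[[h]][[1]])
      pairs <- build_timescale_pairs(list(rec), c(2, 4))
      labs <- vapply(pairs, `[[`, character(1), "label")
      tidx <- fedseizr:::stratified_split(labs, 0.25, seed + 100L * h)
      clients[[h]] <- list(pairs = pairs[-tidx],
                           graph = build_graph(rec$signal, 0.3),
                           fs = rec$fs)
      tests[[h]] <- pairs[tidx]
    }
    fed <- run_federation(clients, cfg, seed = seed)
    pooled_acc <- function(model_for) {
      tot <- 0; n <- 0
      for (h in 1:3) {
        P <- gcnn_predict(model_for(h), tests[[h]], clients[[h]]$graph,
                          clients[[h]]$fs, cfg)
        y <- vapply(tests[[h]], `[[`, character(1), "label") == "preictal"
        tot <- tot + sum((P[, "preictal"] >= 0.5) == y)
        n <- n + length(y)
      }
      tot / n
    }
    fed_acc <- pooled_acc(function(h) fed$clients[[h]])
    singles <- vapply(1:3, function(h) {
      labs <- vapply(clients[[h]]$pairs, `[[`, character(1), "label")
      tr <- setdiff(seq_along(clients[[h]]$pairs),
                    fedseizr:::stratified_split(
                      labs, cfg$federated$validation_split,
                      seed + 7919L * h))
      m <- train_local(clients[[h]]$pairs[tr], clients[[h]]$graph,
                       clients[[h]]$fs, cfg, seed = seed)
      pooled_acc(function(hh) m)
    }, numeric(1))
    expect_gte(fed_acc, max(singles) - 0.02)
  }
})

test_that("round payloads carry parameters and scalars, no signal arrays", {
  fx <- tiny_pairs(7, c(1, 2))
  cfg <- run_config(gcnn = list(epochs = 2L),
                    federated = list(rounds_max = 1L))
  fed <- run_federation(list(list(pairs = fx$pairs, graph = fx$graph,
                                  fs = fx$fs)), cfg, seed = 2)
  tensors <- fedseizr:::param_tensors(fed$global)
  h <- run_config()$gcnn$hidden_units
  expect_setequal(names(tensors),
                  c("W0_1", "W1_1", "W0_2", "W1_2", "Wd", "bd", "offset"))
  # total exchanged payload is architecture-sized, far below any window
  n_window <- nrow(fx$pairs[[1]]$windows[[1]]) * length(fx$pairs)
  expect_lt(length(unlist(tensors)), n_window)
  expect_null(fed$global$pairs)
  expect_null(fed$global$signal)
})
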