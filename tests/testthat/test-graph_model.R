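# independent brute-force renormalization using explicit diagonal matrices
oracle_renorm <- function(A) {
  At <- A + diag(nrow(A))
  D <- diag(rowSums(At), nrow(A))
  Di <- diag(1 / sqrt(diag(D)), nrow(A))
  Di %*% At %*% Di
}

test_that("two identical channels give the hand-computed operator", {
  set.seed(2)
  x <- stats::rnorm(100)
  g <- build_graph(cbind(x, x), corr_threshold = 0.3)
  expect_equal(g$adjacency, matrix(c(0, 1, 1, 0), 2),
               ignore_attr = TRUE)
  expect_equal(g$operator, matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("independent channels at a high threshold give isolated nodes", {
  set.seed(3)
  g <- build_graph(matrix(stats::rnorm(400), 100, 4), corr_threshold = 0.9)
  expect_true(all(g$adjacency == 0))
  expect_equal(g$operator, diag(4), ignore_attr = TRUE)
})

test_that("constant channels get zero correlations, not NAs", {
  set.seed(4)
  sig <- cbind(stats::rnorm(50), rep(1, 50), stats::rnorm(50))
  g <- build_graph(sig, corr_threshold = 0.1)
  expect_true(all(is.finite(g$operator)))
  expect_true(all(g$adjacency[2, ] == 0))
})

test_that("renormalization matches the oracle on random weighted graphs", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    A <- matrix(stats::runif(n * n), n)
    A <- (A + t(A)) / 2
    A[A < 0.5] <- 0
    diag(A) <- 0
    got <- renormalize_adjacency(A)
    expect_equal(got, oracle_renorm(A), tolerance = 1e-12)
    ev <- eigen(got, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
  expect_error(renormalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("softmax outputs are proper probabilities", {
  set.seed(6)
  cfg <- run_config()
  params <- fedseizr:::init_gcnn_params(cfg, 2L)
  op <- diag(4)
  for (i in 1:100) {
    feats <- lapply(1:2, function(k) {
      list(M0 = matrix(stats::rnorm(16), 4, 4),
           RS = stats::runif(4))
    })
    out <- fedseizr:::gcnn_forward_cached(feats, op, params)
    expect_equal(sum(out$probs), 1, tolerance = 1e-9)
    expect_true(all(out$probs > 0))
  }
})

test_that("an all-zero node gate makes the output input-independent", {
  set.seed(7)
  cfg <- run_config()
  params <- fedseizr:::init_gcnn_params(cfg, 2L)
  op <- fedseizr:::renormalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  feats_a <- lapply(1:2, function(k) list(M0 = matrix(stats::rnorm(8), 2, 4),
                                          RS = c(0, 0)))
  feats_b <- lapply(1:2, function(k) list(M0 = matrix(stats::rnorm(8), 2, 4),
                                          RS = c(0, 0)))
  pa <- fedseizr:::gcnn_forward_cached(feats_a, op, params)$probs
  pb <- fedseizr:::gcnn_forward_cached(feats_b, op, params)$probs
  expect_equal(pa, pb, tolerance = 1e-12)
})

test_that("forward pass matches an independent reimplementation", {
  set.seed(8)
  cfg <- run_config()
  params <- fedseizr:::init_gcnn_params(cfg, 2L)
  m <- 5
  A <- matrix(stats::rbinom(m * m, 1, 0.4), m)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  op <- renormalize_adjacency(A)
  feats <- lapply(1:2, function(k) list(M0 = matrix(stats::rnorm(m * 4), m, 4),
                                        RS = stats::runif(m)))
  got <- fedseizr:::gcnn_forward_cached(feats, op, params)$probs
  gelu <- function(x) x * stats::pnorm(x)
  pooled <- unlist(lapply(1:2, function(k) {
    br <- params$branches[[k]]
    M0s <- (feats[[k]]$M0 - matrix(params$feat_mean, m, 4, byrow = TRUE)) /
      matrix(params$feat_sd, m, 4, byrow = TRUE)
    H1 <- gelu((op %*% (diag(feats[[k]]$RS) %*% M0s)) %*% br$W0)
    H2 <- tanh((op %*% (diag(feats[[k]]$RS) %*% H1)) %*% br$W1)
    colMeans(H2)
  }))
  h <- stats::plogis(as.numeric(pooled %*% params$Wd) + params$bd)
  want <- exp(h) / sum(exp(h))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("pooled outputs are equivariant to channel permutation", {
  set.seed(9)
  cfg <- run_config()
  params <- fedseizr:::init_gcnn_params(cfg, 2L)
  m <- 6
  A <- matrix(stats::runif(m * m), m); A <- (A + t(A)) / 2
  A[A < 0.4] <- 0; diag(A) <- 0
  op <- renormalize_adjacency(A)
  feats <- lapply(1:2, function(k) list(M0 = matrix(stats::rnorm(m * 4), m, 4),
                                        RS = stats::runif(m)))
  p1 <- fedseizr:::gcnn_forward_cached(feats, op, params)$probs
  perm <- sample(m)
  opp <- renormalize_adjacency(A[perm, perm])
  featsp <- lapply(feats, function(f) list(M0 = f$M0[perm, , drop = FALSE],
                                           RS = f$RS[perm]))
  p2 <- fedseizr:::gcnn_forward_cached(featsp, opp, params)$probs
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(10)
  cfg <- run_config()
  params <- fedseizr:::init_gcnn_params(cfg, 2L)
  m <- 4
  op <- renormalize_adjacency(matrix(c(0, 1, 0, 0,
                                       1, 0, 1, 0,
                                       0, 1, 0, 1,
                                       0, 0, 1, 0), m, m))
  feats <- lapply(1:2, function(k) list(M0 = matrix(stats::rnorm(m * 4), m, 4),
                                        RS = stats::runif(m)))
  loss_of <- function(p) {
    fwd <- fedseizr:::gcnn_forward_cached(feats, op, p)
    -log(fwd$probs[1])
  }
  fwd <- fedseizr:::gcnn_forward_cached(feats, op, params)
  bk <- fedseizr:::gcnn_backward(fwd$probs - c(1, 0), fwd, feats, op,
                                 params, NULL)
  gt <- fedseizr:::param_tensors(list(branches = bk$branches, Wd = bk$Wd,
                                      bd = bk$bd, offset = bk$offset,
                                      config = params$config))
  tens <- fedseizr:::param_tensors(params)
  h <- 1e-6
  for (nm in c("W0_1", "W1_1", "W0_2", "Wd", "bd")) {
    for (i in sample(length(tens[[nm]]), min(3, length(tens[[nm]])))) {
      tp <- tens; tp[[nm]][i] <- tp[[nm]][i] + h
      tm <- tens; tm[[nm]][i] <- tm[[nm]][i] - h
      num <- (loss_of(fedseizr:::tensors_to_params(tp, params)) -
                loss_of(fedseizr:::tensors_to_params(tm, params))) / (2 * h)
      expect_equal(gt[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("local training learns a separable synthetic set deterministically", {
  fx <- tiny_pairs(7, c(1, 2))
  cfg <- run_config(gcnn = list(epochs = 5L))
  p1 <- train_local(fx$pairs, fx$graph, fx$fs, cfg, seed = 3)
  p2 <- train_local(fx$pairs, fx$graph, fx$fs, cfg, seed = 3)
  expect_identical(fedseizr:::param_tensors(p1),
                   fedseizr:::param_tensors(p2))
  log <- attr(p1, "log")
  expect_lt(log$loss[nrow(log)], log$loss[1])
  expect_error(train_local(list(), fx$graph, fx$fs, cfg), "empty")
})

test_that("gcnn_forward on raw segments returns named class probabilities", {
  fx <- tiny_pairs(7, c(1, 2))
  cfg <- run_config(gcnn = list(epochs = 2L))
  params <- train_local(fx$pairs[1:20], fx$graph, fx$fs, cfg, seed = 1)
  out <- gcnn_forward(fx$pairs[[1]]$windows, fx$graph, params, fx$fs,
                      cfg$spiking)
  expect_named(out, c("preictal", "other"))
  expect_equal(sum(out), 1, tolerance = 1e-9)
})
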