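# The spiking graph-convolutional classifier.
#
# Per timescale branch, node features from the fine-tuned spike
# representation propagate through two graph-conv layers
#   M^{L+1} = act( Ahat %*% diag(RS) %*% M^L %*% W^L ),
# where Ahat is the renormalized channel graph and RS the per-node spike
# score (fraction of 1s in the fine-tuned spike matrix, in [0,1]).
# Node states are mean-pooled, the two branch vectors are concatenated, and
# a sigmoid dense head feeds a softmax over {preictal, other}.
# Training: Adam on the cross-entropy (optionally plus the Bregman
# personalization term), with a fast-sigmoid surrogate gradient through the
# encoder's threshold offset. Backpropagation is written out by hand; no
# autodiff engine is available in the target stack.

act_fun <- function(name) {
  switch(name,
    gelu = list(f = function(x) x * stats::pnorm(x),
                df = function(x) stats::pnorm(x) + x * stats::dnorm(x)),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    sigmoid = list(f = stats::plogis,
                   df = function(x) stats::plogis(x) * (1 - stats::plogis(x))),
    linear = list(f = identity, df = function(x) x * 0 + 1),
    stop("unknown activation: ", name)
  )
}

#' Node features of a segment for the graph model
#'
#' Per channel: spike fraction, mean spike-run duration (seconds),
#' spike-run rate (runs/s, scaled by 1/10), and the within-segment standard
#' deviation. The per-node gate `RS` is the spike fraction (a spike score
#' in \[0, 1\]): channels that never spike are silenced in the propagation
#' rule. The raw (not indicator-gated) statistics are used: the binary
#' seizure indicator is noisy at the single-segment level and hard-gating
#' the features with it measurably discards class information, while the
#' indicator's segment probability still feeds the federated
#' personalization counts.
#'
#' @param window numeric matrix (`timesteps x channels`).
#' @param fs sampling rate in Hz.
#' @param spiking spiking config (kappa, mode, offset, beta_slope), e.g.
#'   `run_config()$spiking`.
#' @return list: `M0` (`channels x 4`), `RS`, `dM0_doffset` (gradient of the
#'   spike-fraction column), `probability` (segment seizure probability).
#' @export
node_features <- function(window, fs, spiking = run_config()$spiking) {
  rep_ <- spike_representation(window, kappa = spiking$kappa,
                               mode = spiking$mode, offset = spiking$offset,
                               beta_slope = spiking$beta_slope)
  T_ <- rep_$timesteps
  mu <- colMeans(window)
  sds <- sqrt(pmax(colSums(window^2) - T_ * mu^2, 0) / (T_ - 1L))
  M0 <- cbind(
    frac = rep_$spike_count / T_,
    dur = rep_$spike_duration / fs,
    rate = rep_$n_runs / (T_ / fs) / 10,
    sd = sds
  )
  list(M0 = M0, RS = M0[, "frac"],
       dM0_doffset = rep_$dcount_doffset / T_,
       probability = rep_$probability)
}

init_gcnn_params <- function(cfg, n_branches = 2L) {
  h <- cfg$gcnn$hidden_units
  glorot <- function(n_in, n_out) {
    matrix(stats::runif(n_in * n_out, -1, 1) * sqrt(6 / (n_in + n_out)),
           n_in, n_out)
  }
  branches <- lapply(seq_len(n_branches), function(k) {
    list(W0 = glorot(4L, h[1L]), W1 = glorot(h[1L], h[2L]))
  })
  list(branches = branches,
       Wd = glorot(n_branches * h[2L], 2L),
       bd = numeric(2L),
       offset = cfg$spiking$offset,
       feat_mean = rep(0, 4L), feat_sd = rep(1, 4L),
       config = list(hidden_units = h, activations = cfg$gcnn$activations,
                     n_branches = n_branches))
}

# per-feature standardization statistics over a featurized training set
feature_stats <- function(feat_sets) {
  M <- do.call(rbind, unlist(lapply(feat_sets, function(fs) {
    lapply(fs, `[[`, "M0")
  }), recursive = FALSE))
  mu <- unname(colMeans(M))
  sd_ <- unname(apply(M, 2L, stats::sd))
  sd_[sd_ < 1e-8] <- 1
  list(mean = mu, sd = sd_)
}

# forward pass for one sample (list of per-branch feature lists);
# returns probs plus caches for backprop. dropout masks: NULL (inference,
# no dropout) or list per branch of list(m1, m2) inverted-dropout masks.
gcnn_forward_cached <- function(feats, operator, params, masks = NULL) {
  acts <- params$config$activations
  a1 <- act_fun(acts[1L]); a2 <- act_fun(acts[2L]); a3 <- act_fun(acts[3L])
  caches <- vector("list", length(feats))
  pooled <- NULL
  for (k in seq_along(feats)) {
    br <- params$branches[[k]]
    M0 <- sweep(sweep(feats[[k]]$M0, 2L, params$feat_mean), 2L,
                params$feat_sd, "/")
    RS <- feats[[k]]$RS
    m <- nrow(M0)
    X1 <- operator %*% (M0 * RS)
    Z1 <- X1 %*% br$W0
    H1 <- a1$f(Z1)
    if (!is.null(masks)) H1 <- H1 * masks[[k]]$m1
    X2 <- operator %*% (H1 * RS)
    Z2 <- X2 %*% br$W1
    H2 <- a2$f(Z2)
    if (!is.null(masks)) H2 <- H2 * masks[[k]]$m2
    p <- colMeans(H2)
    caches[[k]] <- list(M0 = M0, RS = RS, X1 = X1, Z1 = Z1, H1 = H1,
                        X2 = X2, Z2 = Z2, m = m)
    pooled <- c(pooled, p)
  }
  u <- as.numeric(pooled %*% params$Wd) + params$bd
  h <- a3$f(u)
  eh <- exp(h - max(h))
  probs <- eh / sum(eh)
  list(probs = probs, u = u, h = h, pooled = pooled, caches = caches)
}

#' Forward pass of the spiking-GCNN
#'
#' Computes class probabilities for one bi-timescale segment pair (or a
#' single segment when the model has one branch).
#'
#' @param segments list of per-branch windows (`timesteps x channels`
#'   matrices), one per timescale branch.
#' @param graph a [build_graph()] result.
#' @param params model parameters from [train_local()] /
#'   `init_gcnn_params`.
#' @param fs sampling rate in Hz.
#' @param spiking spiking config; the trainable offset in `params` takes
#'   precedence.
#' @return named numeric vector of probabilities `(preictal, other)`,
#'   summing to 1.
#' @export
gcnn_forward <- function(segments, graph, params, fs,
                         spiking = run_config()$spiking) {
  spiking$offset <- params$offset
  feats <- lapply(segments, node_features, fs = fs, spiking = spiking)
  out <- gcnn_forward_cached(feats, graph$operator, params)
  stats::setNames(out$probs, c("preictal", "other"))
}

# backward pass for one sample. dh = dL/dh (length 2).
# returns list(grads = same shape as trainable params, doffset contribution)
gcnn_backward <- function(dh, fwd, feats, operator, params, masks) {
  acts <- params$config$activations
  a1 <- act_fun(acts[1L]); a2 <- act_fun(acts[2L]); a3 <- act_fun(acts[3L])
  du <- dh * a3$df(fwd$u)
  gWd <- outer(fwd$pooled, du)
  gbd <- du
  dz <- as.numeric(params$Wd %*% du)
  h2w <- params$config$hidden_units[2L]
  gbr <- vector("list", length(feats))
  doffset <- 0
  for (k in seq_along(feats)) {
    cache <- fwd$caches[[k]]
    br <- params$branches[[k]]
    dp <- dz[((k - 1L) * h2w + 1L):(k * h2w)]
    dH2 <- matrix(dp / cache$m, cache$m, h2w, byrow = TRUE)
    if (!is.null(masks)) dH2 <- dH2 * masks[[k]]$m2
    dZ2 <- dH2 * a2$df(cache$Z2)
    gW1 <- t(cache$X2) %*% dZ2
    dX2 <- dZ2 %*% t(br$W1)
    dH1 <- (t(operator) %*% dX2) * cache$RS
    if (!is.null(masks)) dH1 <- dH1 * masks[[k]]$m1
    dZ1 <- dH1 * a1$df(cache$Z1)
    gW0 <- t(cache$X1) %*% dZ1
    dGM0 <- (t(operator) %*% (dZ1 %*% t(br$W0)))  # grad wrt RS*M0std
    # the offset reaches layer 1 through the standardized spike-fraction
    # column (scaled by 1/sd) and through the raw-fraction gate RS (which
    # also multiplies H1 in layer 2)
    dfrac <- feats[[k]]$dM0_doffset  # d(raw fraction)/d offset, per node
    direct <- dGM0[, 1L] * cache$RS / params$feat_sd[1L]
    rs_path_l1 <- rowSums(dGM0 * cache$M0)  # cache$M0 is standardized
    dRS_l2 <- rowSums((t(operator) %*% (dZ2 %*% t(br$W1))) * cache$H1)
    doffset <- doffset + sum((direct + rs_path_l1 + dRS_l2) * dfrac)
    gbr[[k]] <- list(W0 = gW0, W1 = gW1)
  }
  list(branches = gbr, Wd = gWd, bd = gbd, offset = doffset)
}

# elementwise helpers over the trainable-parameter structure
param_tensors <- function(p) {
  out <- list()
  for (k in seq_along(p$branches)) {
    out[[paste0("W0_", k)]] <- p$branches[[k]]$W0
    out[[paste0("W1_", k)]] <- p$branches[[k]]$W1
  }
  out$Wd <- p$Wd
  out$bd <- p$bd
  out$offset <- p$offset
  out
}

tensors_to_params <- function(tensors, template) {
  p <- template
  for (k in seq_along(p$branches)) {
    p$branches[[k]]$W0 <- tensors[[paste0("W0_", k)]]
    p$branches[[k]]$W1 <- tensors[[paste0("W1_", k)]]
  }
  p$Wd <- tensors$Wd
  p$bd <- tensors$bd
  p$offset <- as.numeric(tensors$offset)
  p
}

adam_init <- function(tensors) {
  list(m = lapply(tensors, function(x) x * 0),
       v = lapply(tensors, function(x) x * 0), t = 0L)
}

adam_step <- function(tensors, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(tensors)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- tensors[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    attributes(upd) <- attributes(tensors[[nm]])  # no name leakage from grads
    tensors[[nm]] <- upd
  }
  list(tensors = tensors, state = state)
}

featurize_pairs <- function(pairs, fs, spiking, offset) {
  spiking$offset <- offset
  lapply(pairs, function(pair) {
    lapply(pair$windows, node_features, fs = fs, spiking = spiking)
  })
}

#' Train the spiking-GCNN on one client's segment pairs
#'
#' Minimizes the (sparse categorical) cross-entropy with Adam; minibatches,
#' inverted dropout after each conv layer, the surrogate gradient through
#' the encoder threshold offset (updated once per epoch, when spike features
#' are re-encoded), and an optional Bregman-divergence personalization term
#' against reference probabilities (used by the federated loop).
#'
#' @param pairs list of training samples; each a list with `windows` (list
#'   of per-branch `timesteps x channels` matrices) and `label`
#'   (`"preictal"` or other).
#' @param graph a [build_graph()] result for this client.
#' @param fs sampling rate in Hz.
#' @param config a [run_config()].
#' @param seed integer seed; the full run (init, shuffling, dropout) is
#'   deterministic given it.
#' @param init optional starting parameters (e.g. global model weights). The
#'   RNG stream is identical whether or not `init` is supplied, so a
#'   single-client federation reproduces centralized training exactly.
#' @param ref_probs optional numeric vector, one reference (global-model,
#'   Eq.-normalized) preictal probability per sample, enabling the
#'   divergence term.
#' @param w1,w2 weights of the prediction and divergence losses.
#' @return list of class `gcnn_params` (the trained parameters) with an
#'   attached `log` data.frame of per-epoch mean training loss.
#' @export
train_local <- function(pairs, graph, fs, config = run_config(), seed = 42L,
                        init = NULL, ref_probs = NULL, w1 = 1.0, w2 = 0.0) {
  if (length(pairs) == 0L) stop("empty training set")
  gcfg <- config$gcnn
  set.seed(seed)
  n_branches <- length(pairs[[1L]]$windows)
  params <- init_gcnn_params(config, n_branches)
  if (!is.null(init)) {
    init$config <- params$config
    params <- init
  }
  # class index 1 = preictal, 2 = other (matches gcnn_predict columns)
  y_idx <- ifelse(vapply(pairs, `[[`, character(1), "label") == "preictal",
                  1L, 2L)
  n <- length(pairs)
  tensors <- param_tensors(params)
  state <- adam_init(tensors)
  log_loss <- numeric(gcfg$epochs)
  offset_trainable <- isTRUE(config$spiking$offset_trainable)
  for (epoch in seq_len(gcfg$epochs)) {
    params <- tensors_to_params(tensors, params)
    feats <- featurize_pairs(pairs, fs, config$spiking, params$offset)
    needs_stats <- all(params$feat_mean == 0) && all(params$feat_sd == 1)
    if (epoch == 1L && needs_stats) {
      st <- feature_stats(feats)
      params$feat_mean <- st$mean
      params$feat_sd <- st$sd
    }
    idx <- sample(n)
    batches <- split(idx, ceiling(seq_along(idx) / gcfg$batch_size))
    epoch_loss <- 0
    offset_grad <- 0
    for (batch in batches) {
      params <- tensors_to_params(tensors, params)
      grads <- NULL
      for (i in batch) {
        masks <- lapply(seq_len(n_branches), function(k) {
          m <- nrow(feats[[i]][[1L]]$M0)
          h <- gcfg$hidden_units
          keep <- 1 - gcfg$dropout
          list(
            m1 = matrix(stats::rbinom(m * h[1L], 1L, keep) / keep, m, h[1L]),
            m2 = matrix(stats::rbinom(m * h[2L], 1L, keep) / keep, m, h[2L])
          )
        })
        fwd <- gcnn_forward_cached(feats[[i]], graph$operator, params, masks)
        p_true <- max(fwd$probs[y_idx[i]], 1e-12)
        loss <- -w1 * log(p_true)
        onehot <- c(0, 0); onehot[y_idx[i]] <- 1
        dh <- w1 * (fwd$probs - onehot)
        if (!is.null(ref_probs) && w2 > 0) {
          pg <- ref_probs[i]
          pp <- min(max(fwd$probs[1L], 1e-7), 1 - 1e-7)
          loss <- loss + w2 * bregman_divergence(pg, pp)
          ddiv_dpp <- (pp - pg) / (pp * (1 - pp))
          # dP_preictal/dh_j = P1 (1[j=1] - P_j)
          dP1 <- fwd$probs[1L] * (c(1, 0) - fwd$probs)
          dh <- dh + w2 * ddiv_dpp * dP1
        }
        bk <- gcnn_backward(dh, fwd, feats[[i]], graph$operator, params,
                            masks)
        gt <- param_tensors(
          list(branches = bk$branches, Wd = bk$Wd, bd = bk$bd,
               offset = bk$offset, config = params$config))
        grads <- if (is.null(grads)) gt else Map(`+`, grads, gt)
        epoch_loss <- epoch_loss + loss
      }
      grads <- lapply(grads, function(g) g / length(batch))
      offset_grad <- offset_grad + grads$offset
      grads$offset <- 0  # offset updated once per epoch (features are
                         # re-encoded only at epoch boundaries)
      upd <- adam_step(tensors, grads, state, gcfg$learning_rate)
      tensors <- upd$tensors
      state <- upd$state
    }
    if (offset_trainable) {
      og <- offset_grad / length(batches)
      upd <- adam_step(tensors["offset"], list(offset = og),
                       list(m = state$m["offset"], v = state$v["offset"],
                            t = state$t - 1L), gcfg$learning_rate)
      # keep the comparison point within half a standard deviation of the
      # channel mean: the encoding stays meaningful and cannot drift into
      # an all-ones / all-zeros regime
      tensors$offset <- min(max(upd$tensors$offset, -0.5), 0.5)
      state$m$offset <- upd$state$m$offset
      state$v$offset <- upd$state$v$offset
    }
    log_loss[epoch] <- epoch_loss / n
  }
  params <- tensors_to_params(tensors, params)
  attr(params, "log") <- data.frame(epoch = seq_len(gcfg$epochs),
                                    loss = log_loss)
  class(params) <- "gcnn_params"
  params
}

#' Save a model checkpoint to a directory
#'
#' One CSV per weight tensor plus an `architecture.json`; the round trip
#' through [load_gcnn_params()] is exact (17-significant-digit printing).
#'
#' @param params `gcnn_params` from [train_local()].
#' @param dir checkpoint directory (created if missing).
#' @return invisibly, `dir`.
#' @export
save_gcnn_params <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tensors <- param_tensors(params)
  tensors$feat_mean <- params$feat_mean
  tensors$feat_sd <- params$feat_sd
  for (nm in names(tensors)) {
    x <- tensors[[nm]]
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
    utils::write.table(formatC(m, format = "g", digits = 17),
                       file.path(dir, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    c(params$config, list(tensor_names = names(tensors),
                          is_matrix = vapply(tensors, is.matrix, logical(1)))),
    file.path(dir, "architecture.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model checkpoint written by [save_gcnn_params()]
#'
#' @param dir checkpoint directory.
#' @return a `gcnn_params` object.
#' @export
load_gcnn_params <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  tensors <- lapply(seq_along(arch$tensor_names), function(i) {
    nm <- arch$tensor_names[i]
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                     sep = ",", header = FALSE))
    dimnames(m) <- NULL
    if (isTRUE(arch$is_matrix[i])) m else as.numeric(m)
  })
  names(tensors) <- arch$tensor_names
  template <- list(
    branches = lapply(seq_len(arch$n_branches), function(k) list()),
    config = list(hidden_units = arch$hidden_units,
                  activations = arch$activations,
                  n_branches = arch$n_branches))
  out <- tensors_to_params(tensors, template)
  out$feat_mean <- tensors$feat_mean
  out$feat_sd <- tensors$feat_sd
  class(out) <- "gcnn_params"
  out
}

#' Predict preictal probabilities for segment pairs
#'
#' @param params trained [train_local()] parameters.
#' @param pairs list of samples as in [train_local()].
#' @param graph a [build_graph()] result.
#' @param fs sampling rate in Hz.
#' @param config a [run_config()].
#' @return numeric matrix (`n x 2`), columns `preictal`, `other`.
#' @export
gcnn_predict <- function(params, pairs, graph, fs, config = run_config()) {
  feats <- featurize_pairs(pairs, fs, config$spiking, params$offset)
  out <- t(vapply(feats, function(f) {
    gcnn_forward_cached(f, graph$operator, params)$probs
  }, numeric(2)))
  colnames(out) <- c("preictal", "other")
  out
}
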