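# Simulated cross-hospital federation: FedAvg aggregation, the global
# negative log-likelihood, Eq.-style normalization of the global preictal
# probability, Bregman (Bernoulli KL) divergence, the personalized loss, and
# the round loop with early stopping. Only parameter containers and scalar
# counts cross the client boundary.

#' Federated averaging of client parameters
#'
#' Elementwise convex combination of client model parameters weighted by
#' their training sample counts: `global = sum_s (T_s / sum T) * params_s`.
#'
#' @param client_params list of `gcnn_params` (or any conforming nested
#'   numeric structure with identical shapes).
#' @param sample_counts positive numeric vector, one `T_s` per client.
#' @return aggregated parameters of the same structure.
#' @export
fedavg_aggregate <- function(client_params, sample_counts) {
  stopifnot(length(client_params) >= 1L,
            length(sample_counts) == length(client_params),
            all(sample_counts > 0))
  tensor_sets <- lapply(client_params, param_tensors)
  shapes <- lapply(tensor_sets, function(ts) lapply(ts, dim))
  for (s in shapes[-1L]) {
    if (!identical(s, shapes[[1L]])) stop("client architecture mismatch")
  }
  wts <- sample_counts / sum(sample_counts)
  agg <- tensor_sets[[1L]]
  for (nm in names(agg)) {
    agg[[nm]] <- agg[[nm]] * wts[1L]
    for (s in seq_along(tensor_sets)[-1L]) {
      agg[[nm]] <- agg[[nm]] + tensor_sets[[s]][[nm]] * wts[s]
    }
  }
  out <- tensors_to_params(agg, client_params[[1L]])
  # feature standardization statistics travel with the model and are
  # averaged like any other parameter
  for (fld in c("feat_mean", "feat_sd")) {
    vals <- lapply(client_params, `[[`, fld)
    out[[fld]] <- Reduce(`+`, Map(`*`, vals, wts))
  }
  class(out) <- "gcnn_params"
  out
}

#' Global prediction-model loss
#'
#' Summed negative log-likelihood of the true class over all subjects and
#' samples: the indicator selects the probability the model assigned to the
#' observed state.
#'
#' @param predictions list (one element per subject) of numeric matrices
#'   (`samples x classes`) of predicted probabilities, or a single matrix.
#' @param labels list (or vector) of 1-based true class indices, matching
#'   `predictions`.
#' @param eps optional clamp for zero probabilities; `NA` (default) makes a
#'   zero true-class probability an error.
#' @return scalar loss.
#' @export
global_loss <- function(predictions, labels, eps = NA) {
  if (is.matrix(predictions)) {
    predictions <- list(predictions)
    labels <- list(labels)
  }
  total <- 0
  for (s in seq_along(predictions)) {
    P <- predictions[[s]]
    y <- labels[[s]]
    stopifnot(nrow(P) == length(y))
    p_true <- P[cbind(seq_len(nrow(P)), y)]
    if (any(p_true <= 0)) {
      if (is.na(eps)) stop("zero probability assigned to a true class")
      p_true <- pmax(p_true, eps)
    }
    total <- total - sum(log(p_true))
  }
  total
}

#' Normalize the global preictal probability for a client
#'
#' When the client's spiking indicator flags more High than Low segments,
#' the global probability is used as-is; otherwise its influence is damped
#' to `clamp(-log(P_G), eps, 1)`, shrinking confident global preictal
#' probabilities on clients whose own data shows little seizure activity.
#'
#' @param p_global global preictal probability, in (0, 1).
#' @param n_high,n_low counts of High/Low seizure-indicator segments on the
#'   client's data.
#' @param eps lower clamp (default 1e-6).
#' @return normalized probability.
#' @export
normalize_global_probability <- function(p_global, n_high, n_low,
                                         eps = 1e-6) {
  if (any(p_global <= 0) || any(p_global >= 1)) {
    stop("p_global must lie strictly inside (0, 1)")
  }
  if (n_high > n_low) p_global
  else pmin(pmax(-log(p_global), eps), 1)
}

#' Bregman divergence between Bernoulli probabilities
#'
#' The Bregman divergence generated by the logistic (negative entropy) loss,
#' i.e. the KL divergence of `Bernoulli(p_global)` from `Bernoulli(p_local)`:
#' `p*log(p/q) + (1-p)*log((1-p)/(1-q))`. Nonnegative, zero iff equal;
#' boundary values of `p_global` use the `0*log 0 = 0` convention.
#'
#' @param p_global reference (normalized global) probability in \[0, 1\].
#' @param p_local client probability in (0, 1); boundary values with an
#'   interior `p_global` are an error.
#' @return scalar divergence.
#' @export
bregman_divergence <- function(p_global, p_local) {
  stopifnot(length(p_global) == 1L, length(p_local) == 1L)
  if (p_local <= 0 || p_local >= 1) {
    if (!isTRUE(all.equal(p_global, p_local))) {
      stop("p_local on the boundary with interior p_global: divergence infinite")
    }
    return(0)
  }
  term <- function(p, q) if (p == 0) 0 else p * log(p / q)
  term(p_global, p_local) + term(1 - p_global, 1 - p_local)
}

#' Personalized client loss
#'
#' Weighted combination of the prediction loss and the divergence loss:
#' `L_P = w1 * L_pred + w2 * L_div`.
#'
#' @param l_pred prediction (cross-entropy) loss.
#' @param l_div divergence loss.
#' @param w1,w2 nonnegative constant weights.
#' @return scalar loss.
#' @export
personalized_loss <- function(l_pred, l_div, w1 = 1.0, w2 = 0.1) {
  stopifnot(w1 >= 0, w2 >= 0, is.finite(l_pred), is.finite(l_div))
  w1 * l_pred + w2 * l_div
}

#' Early-stopping bookkeeping
#'
#' Given a sequence of per-round validation losses, returns the round at
#' which training stops (the first round after which the loss has failed to
#' improve for `patience` consecutive rounds, or the last round) and the
#' best (retained) round.
#'
#' @param losses numeric vector of validation losses by round.
#' @param patience consecutive non-improving rounds tolerated.
#' @return list with `stop_round` and `best_round`.
#' @export
early_stopping_trace <- function(losses, patience) {
  best <- Inf
  best_round <- 0L
  bad <- 0L
  for (r in seq_along(losses)) {
    if (losses[r] < best - 1e-12) {
      best <- losses[r]
      best_round <- r
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(stop_round = r, best_round = best_round))
      }
    }
  }
  list(stop_round = length(losses), best_round = best_round)
}

# stratified train/validation split of sample indices (seeded)
stratified_split <- function(labels, validation_split, seed) {
  set.seed(seed)
  valid <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    k <- max(1L, round(length(idx) * validation_split))
    sample(idx, k)
  }))
  sort(valid)
}

#' Run a simulated federation over hospital clients
#'
#' Per round, every client trains locally (starting from the current global
#' parameters) on the personalized loss `w1 * L_pred + w2 * L_div`, where
#' the divergence is taken against the global model's predictions on the
#' client's own samples, normalized per the client's High/Low
#' seizure-indicator counts. The server then aggregates with
#' [fedavg_aggregate()]. Pooled validation loss drives early stopping; the
#' best round's global parameters are retained. Only parameters and scalar
#' counts are exchanged.
#'
#' @param clients list; each client is a list with `pairs` (training samples
#'   as in [train_local()]), `graph`, `fs`, and optionally `client_id`.
#' @param config a [run_config()] (federated settings: `w1`, `w2`,
#'   `rounds_max`, `patience`, `validation_split`).
#' @param seed integer seed.
#' @return list of class `federation_state`: `global` (retained global
#'   params), `clients` (per-client personalized params), `history`
#'   (data.frame of round, pooled validation loss), `best_round`,
#'   `stop_round`, `n_high`, `n_low`.
#' @export
run_federation <- function(clients, config = run_config(), seed = 42L) {
  stopifnot(length(clients) >= 1L)
  fcfg <- config$federated
  n_branches <- length(clients[[1L]]$pairs[[1L]]$windows)
  set.seed(seed)
  global <- init_gcnn_params(config, n_branches)
  # per-client validation split and spiking-indicator counts (scalars only)
  prep <- lapply(seq_along(clients), function(ci) {
    cl <- clients[[ci]]
    labs <- vapply(cl$pairs, `[[`, character(1), "label")
    valid_idx <- stratified_split(labs, fcfg$validation_split,
                                  seed + 7919L * ci)
    probs_high <- vapply(cl$pairs, function(pair) {
      mean(vapply(pair$windows, function(w) {
        spike_representation(w, kappa = config$spiking$kappa,
                             mode = config$spiking$mode,
                             beta_slope = NA)$probability
      }, numeric(1)))
    }, numeric(1))
    n_high <- sum(probs_high >= 0.5)
    list(valid_idx = valid_idx, train_idx = setdiff(seq_along(cl$pairs),
                                                    valid_idx),
         labels = as.integer(labs == "preictal"),
         n_high = n_high, n_low = length(cl$pairs) - n_high)
  })
  history <- numeric(0)
  best_global <- global
  best_clients <- NULL
  round_clients <- NULL
  best <- Inf
  bad <- 0L
  stop_round <- fcfg$rounds_max
  for (round in seq_len(fcfg$rounds_max)) {
    round_params <- vector("list", length(clients))
    counts <- numeric(length(clients))
    for (ci in seq_along(clients)) {
      cl <- clients[[ci]]
      pp <- prep[[ci]]
      train_pairs <- cl$pairs[pp$train_idx]
      ref <- NULL
      if (fcfg$w2 > 0) {
        pg <- gcnn_predict(global, train_pairs, cl$graph, cl$fs,
                           config)[, "preictal"]
        pg <- pmin(pmax(pg, 1e-7), 1 - 1e-7)
        ref <- vapply(pg, normalize_global_probability, numeric(1),
                      n_high = pp$n_high, n_low = pp$n_low, eps = fcfg$eps)
      }
      round_params[[ci]] <- train_local(
        train_pairs, cl$graph, cl$fs, config,
        seed = seed + 1000L * (round - 1L) + ci - 1L,
        init = global, ref_probs = ref, w1 = fcfg$w1, w2 = fcfg$w2)
      counts[ci] <- length(train_pairs)
    }
    global <- fedavg_aggregate(round_params, counts)
    round_clients <- round_params
    # pooled validation loss of the personalized client models (each on its
    # own held-out split): the personalized models are what a hospital
    # deploys, so they drive retention and early stopping
    val_loss <- 0
    val_n <- 0L
    for (ci in seq_along(clients)) {
      cl <- clients[[ci]]
      pp <- prep[[ci]]
      if (length(pp$valid_idx) == 0L) next
      P <- gcnn_predict(round_params[[ci]], cl$pairs[pp$valid_idx],
                        cl$graph, cl$fs, config)
      # column 1 of P is preictal (label 1), column 2 the other class
      val_loss <- val_loss + global_loss(P, 2L - pp$labels[pp$valid_idx],
                                         eps = 1e-12)
      val_n <- val_n + length(pp$valid_idx)
    }
    val_loss <- val_loss / max(val_n, 1L)
    history <- c(history, val_loss)
    if (val_loss < best - 1e-12) {
      best <- val_loss
      best_global <- global
      best_clients <- round_params
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= fcfg$patience) {
        stop_round <- round
        break
      }
    }
  }
  es <- early_stopping_trace(history, fcfg$patience)
  structure(
    list(global = best_global,
         clients = if (is.null(best_clients)) round_clients else best_clients,
         history = data.frame(round = seq_along(history),
                              validation_loss = history),
         best_round = es$best_round, stop_round = length(history),
         n_high = vapply(prep, `[[`, numeric(1), "n_high"),
         n_low = vapply(prep, `[[`, numeric(1), "n_low")),
    class = "federation_state"
  )
}

#' @export
print.federation_state <- function(x, ...) {
  cat(sprintf("<federation_state> %d round(s), best round %d (val loss %.4f), %d client(s)\n",
              nrow(x$history), x$best_round,
              min(x$history$validation_loss), length(x$clients)))
  invisible(x)
}
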