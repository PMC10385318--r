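# Sugeno ANFIS over three composite inputs (EEG preictal probability, HRV
# composite, clinical composite), each with three triangular membership
# functions, 27 first-order rules. Hybrid training: rule consequents by
# (ridge-regularized) least squares given firing strengths, premise
# parameters by finite-difference gradient steps on the mean absolute
# error; particle swarm optimization searches premise initializations.

#' Reference class ranges of the fuzzy input variables
#'
#' Low/Medium/High value ranges per raw variable: coarse-grained EEG
#' probability, the five HRV features (Lmax beats, LF/HF ratio, SDNN ms,
#' MeanHR beats/min, pNN50 percent) and the clinical seizure-event count.
#' Ranges overlap across classes for several HRV features; that overlap is
#' kept (fuzzy by design).
#'
#' @return named list; each element a 3x2 matrix of class (lo, hi) bounds,
#'   rows Low/Medium/High.
#' @export
fuzzy_class_ranges <- function() {
  rng <- function(...) {
    m <- matrix(c(...), nrow = 3L, byrow = TRUE,
                dimnames = list(c("Low", "Medium", "High"), c("lo", "hi")))
    m
  }
  list(
    eeg_probability = rng(0, 0.3, 0.31, 0.6, 0.61, 1.0),
    Lmax = rng(198, 238, 239, 245, 245, 290),
    LF_HF = rng(1.3, 1.7, 1.1, 2.1, 1.3, 2.9),
    SDNN = rng(109, 141.6, 85.4, 165, 83.7, 159.1),
    MeanHR = rng(65.2, 76.2, 71.6, 81.4, 72.1, 92.5),
    pNN50 = rng(6.2, 17.6, 2.5, 8.1, 1.6, 9.6),
    seizure_event_count = rng(0, 3, 3, 5, 5, 12)
  )
}

#' Construct a fuzzy variable with three triangular membership functions
#'
#' Each class's triangle peaks at the class-range midpoint with feet at the
#' class bounds. For any in-range value the membership sum is kept positive:
#' if all three triangles evaluate to zero (possible in gaps between
#' non-overlapping class ranges) the value is attributed to the nearest
#' peak.
#'
#' @param name variable name.
#' @param ranges 3x2 matrix of class bounds (rows Low/Medium/High), as from
#'   [fuzzy_class_ranges()].
#' @return object of class `fuzzy_variable` with a 3x3 `mf` matrix (rows =
#'   classes, columns = left/peak/right).
#' @export
fuzzy_variable <- function(name, ranges) {
  mf <- cbind(left = ranges[, "lo"],
              peak = (ranges[, "lo"] + ranges[, "hi"]) / 2,
              right = ranges[, "hi"])
  rownames(mf) <- c("Low", "Medium", "High")
  structure(list(name = name, mf = mf), class = "fuzzy_variable")
}

tri_membership <- function(x, left, peak, right) {
  up <- if (peak > left) (x - left) / (peak - left) else as.numeric(x >= peak)
  dn <- if (right > peak) (right - x) / (right - peak) else as.numeric(x <= peak)
  pmax(pmin(up, dn, 1), 0)
}

#' Evaluate the membership triple of a value
#'
#' @param value numeric scalar (clipped to the variable support).
#' @param variable a [fuzzy_variable()].
#' @return named numeric vector (Low, Medium, High). The attribute
#'   `argmax_class` gives the maximal class index (1..3), ties resolved
#'   toward the higher-risk (higher) class, with a nearest-peak fallback
#'   when all memberships vanish.
#' @export
fuzzify <- function(value, variable) {
  mf <- variable$mf
  value <- min(max(value, min(mf[, "left"])), max(mf[, "right"]))
  mu <- vapply(1:3, function(k) {
    tri_membership(value, mf[k, "left"], mf[k, "peak"], mf[k, "right"])
  }, numeric(1))
  names(mu) <- rownames(mf)
  if (sum(mu) <= 0) {
    nearest <- which.min(abs(mf[, "peak"] - value))
    mu[nearest] <- .Machine$double.eps
  }
  cls <- max(which(mu == max(mu)))  # ties -> higher risk class
  attr(mu, "argmax_class") <- cls
  mu
}

#' Aggregate the nine raw inputs into the three ANFIS inputs
#'
#' The EEG preictal probability passes through. The HRV composite is the
#' mean, over the five HRV features, of the fuzzified class index mapped to
#' `{0, 0.5, 1}`; the clinical composite likewise over the three clinical
#' features (genetic and metabolic map No -> Low, Yes -> High, matching
#' their class table rows; the seizure-event count is fuzzified on its
#' ranges).
#'
#' @param eeg_prob coarse-grained preictal probability in \[0, 1\].
#' @param hrv_features named numeric vector (or single-row data.frame) with
#'   the five [HRV_FEATURES].
#' @param clinical a [clinical_record()] (or list with `genetic`,
#'   `metabolic`, `seizure_event_count`).
#' @return named numeric vector `(eeg, hrv, clinical)`, each in \[0, 1\].
#' @export
aggregate_inputs <- function(eeg_prob, hrv_features, clinical) {
  ranges <- fuzzy_class_ranges()
  hrv_features <- unlist(as.data.frame(as.list(hrv_features))[1, ,
                                                              drop = TRUE])
  missing <- setdiff(HRV_FEATURES, names(hrv_features))
  if (length(missing)) {
    stop("missing HRV feature: ", paste(missing, collapse = ", "))
  }
  class_score <- function(value, var_name) {
    mu <- fuzzify(value, fuzzy_variable(var_name, ranges[[var_name]]))
    (attr(mu, "argmax_class") - 1) / 2
  }
  hrv <- mean(vapply(HRV_FEATURES, function(f) {
    class_score(hrv_features[[f]], f)
  }, numeric(1)))
  for (fld in c("genetic", "metabolic", "seizure_event_count")) {
    if (is.null(clinical[[fld]])) stop("missing clinical feature: ", fld)
  }
  clin <- mean(c(
    if (isTRUE(clinical$genetic)) 1 else 0,
    if (isTRUE(clinical$metabolic)) 1 else 0,
    class_score(clinical$seizure_event_count, "seizure_event_count")
  ))
  c(eeg = as.numeric(eeg_prob), hrv = hrv, clinical = clin)
}

#' Initialize a Sugeno ANFIS model
#'
#' Three inputs on \[0, 1\], three triangular membership functions each
#' (premise parameters initialized from the coarse-grained probability
#' class ranges), and `3^3 = 27` first-order rules with consequent
#' coefficient vectors `(c0, c1, c2, c3)`.
#'
#' @param seed seed for the small random jitter of the initial consequents.
#' @return object of class `anfis_model`.
#' @export
anfis_init <- function(seed = 42L) {
  base <- fuzzy_variable("unit", fuzzy_class_ranges()$eeg_probability)
  premise <- rep(as.numeric(t(base$mf)), 3L)  # 3 vars x 3 MFs x (l,p,r)
  rules <- as.matrix(expand.grid(mf1 = 1:3, mf2 = 1:3, mf3 = 1:3))
  set.seed(seed)
  consequents <- matrix(stats::runif(nrow(rules) * 4L, -0.1, 0.1),
                        nrow(rules), 4L)
  structure(
    list(premise = premise, rules = rules, consequents = consequents,
         out_range = c(0, 1), training_log = NULL),
    class = "anfis_model"
  )
}

premise_mf <- function(premise, var, mf) {
  i <- ((var - 1L) * 3L + (mf - 1L)) * 3L
  sort(premise[(i + 1L):(i + 3L)])  # enforce left <= peak <= right
}

# normalized rule firing strengths for one input triple
firing_strengths <- function(model, x) {
  mu <- matrix(0, 3L, 3L)  # vars x mfs
  for (v in 1:3) {
    for (k in 1:3) {
      p <- premise_mf(model$premise, v, k)
      mu[v, k] <- tri_membership(min(max(x[v], 0), 1), p[1L], p[2L], p[3L])
    }
  }
  w <- mu[cbind(1L, model$rules[, 1L])] *
    mu[cbind(2L, model$rules[, 2L])] *
    mu[cbind(3L, model$rules[, 3L])]
  if (sum(w) <= 0) {
    # no rule fires (gap between supports): fall back to the nearest-peak
    # rule so the output stays defined
    peaks <- vapply(1:3, function(v) {
      vapply(1:3, function(k) premise_mf(model$premise, v, k)[2L], numeric(1))
    }, numeric(3))
    nearest <- vapply(1:3, function(v) which.min(abs(peaks[, v] - x[v])),
                      integer(1))
    hit <- which(model$rules[, 1L] == nearest[1L] &
                   model$rules[, 2L] == nearest[2L] &
                   model$rules[, 3L] == nearest[3L])
    w[hit] <- 1
  }
  w / sum(w)
}

#' Sugeno ANFIS prediction
#'
#' Output is the firing-strength-weighted sum of the first-order rule
#' consequents; the risk class is assigned by thirds of the calibrated
#' output range (`out_range`, set during training; `[0,1]` before).
#'
#' @param model an `anfis_model`.
#' @param x numeric vector of the 3 composite inputs (or a matrix with one
#'   row per case).
#' @return for a single input, a list with `output` (continuous risk level)
#'   and `risk_class` (`"Pk1"` high / `"Pk2"` medium / `"Pk3"` low); for a
#'   matrix, a data.frame.
#' @export
anfis_predict <- function(model, x) {
  if (is.matrix(x)) {
    out <- apply(x, 1L, function(row) anfis_predict(model, row)$output)
    return(data.frame(output = out,
                      risk_class = vapply(out, anfis_class, character(1),
                                          model$out_range)))
  }
  wbar <- firing_strengths(model, x)
  f <- model$consequents[, 1L] + model$consequents[, 2:4] %*% x
  output <- sum(wbar * f)
  list(output = output, risk_class = anfis_class(output, model$out_range))
}

# class by thirds of the scaled output range; top third = highest risk Pk1
anfis_class <- function(output, out_range) {
  span <- max(out_range[2L] - out_range[1L], 1e-12)
  z <- (output - out_range[1L]) / span
  if (z >= 2 / 3) "Pk1" else if (z >= 1 / 3) "Pk2" else "Pk3"
}

anfis_mae <- function(model, X, y) {
  pred <- apply(X, 1L, function(row) anfis_predict(model, row)$output)
  mean(abs(pred - y))
}

# least-squares consequent update given premises (ridge-regularized: the
# 27x4 = 108 coefficient system is typically underdetermined)
anfis_lse <- function(model, X, y, lambda = 1e-6) {
  n <- nrow(X)
  D <- matrix(0, n, nrow(model$rules) * 4L)
  for (i in seq_len(n)) {
    wbar <- firing_strengths(model, X[i, ])
    D[i, ] <- as.numeric(t(outer(wbar, c(1, X[i, ]))))
  }
  G <- crossprod(D) + lambda * diag(ncol(D))
  coef <- solve(G, crossprod(D, y))
  model$consequents <- matrix(coef, nrow(model$rules), 4L, byrow = TRUE)
  model
}

# one hybrid pass: LSE consequents + finite-difference gradient steps on
# the premise parameters against the MAE
anfis_hybrid <- function(model, X, y, iterations, step, lambda) {
  mae_log <- numeric(0)
  model <- anfis_lse(model, X, y, lambda)
  mae_log <- c(mae_log, anfis_mae(model, X, y))
  h <- 1e-4
  for (it in seq_len(iterations)) {
    grad <- numeric(length(model$premise))
    base_mae <- mae_log[length(mae_log)]
    for (j in seq_along(model$premise)) {
      mp <- model
      mp$premise[j] <- mp$premise[j] + h
      grad[j] <- (anfis_mae(mp, X, y) - base_mae) / h
    }
    gn <- sqrt(sum(grad^2))
    if (gn > 0) {
      cand <- model
      cand$premise <- pmin(pmax(model$premise - step * grad / gn, -0.2), 1.2)
      cand <- anfis_lse(cand, X, y, lambda)
      cand_mae <- anfis_mae(cand, X, y)
      if (cand_mae <= base_mae) {
        model <- cand
        mae_log <- c(mae_log, cand_mae)
      } else {
        mae_log <- c(mae_log, base_mae)
      }
    } else {
      mae_log <- c(mae_log, base_mae)
    }
  }
  model$training_log <- mae_log
  model
}

#' Train the ANFIS with PSO-searched premise initialization
#'
#' Hybrid estimation (least-squares consequents, finite-difference premise
#' steps on the MAE) wrapped in a global-best particle swarm over premise
#' initializations; the best learner by validation MAE (training MAE when
#' no split is possible) is refined with a final hybrid pass. A swarm of
#' one particle and zero PSO iterations reduces exactly to plain hybrid
#' training from the model's own initial premises.
#'
#' @param model an [anfis_init()] model.
#' @param X numeric matrix (`n x 3`) of composite inputs.
#' @param y numeric targets (risk level in \[0, 1\]); at least 10 pairs.
#' @param config a [run_config()] (PSO and ANFIS settings).
#' @param seed integer seed.
#' @return trained `anfis_model` with `training_log` (MAE per hybrid
#'   iteration) and calibrated `out_range`.
#' @export
train_anfis_pso <- function(model, X, y, config = run_config(), seed = 42L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 10L) stop("need at least 10 training pairs")
  if (stats::sd(y) == 0) {
    warning("all targets identical; returning constant model")
    model$consequents[] <- 0
    model$consequents[, 1L] <- y[1L]
    model$out_range <- c(y[1L] - 0.5, y[1L] + 0.5)
    model$training_log <- 0
    return(model)
  }
  pso <- config$pso
  acfg <- config$anfis
  set.seed(seed)
  dim_p <- length(model$premise)
  n_particles <- pso$swarm_size
  # particle 1 is the model's own premises (PSO-degenerate reduction)
  pos <- rbind(model$premise,
               matrix(stats::runif((n_particles - 1L) * dim_p, 0, 1),
                      n_particles - 1L, dim_p, byrow = TRUE))
  if (n_particles > 1L) {
    # random particles: jittered copies of the default premises
    jitter <- matrix(stats::runif((n_particles - 1L) * dim_p, -0.15, 0.15),
                     n_particles - 1L, dim_p)
    pos[-1L, ] <- pmin(pmax(rep(model$premise, each = n_particles - 1L) +
                              jitter, -0.2), 1.2)
  }
  vel <- matrix(0, n_particles, dim_p)
  fitness <- function(premise) {
    mdl <- model
    mdl$premise <- premise
    mdl <- anfis_lse(mdl, X, y, acfg$ridge_lambda)
    -anfis_mae(mdl, X, y)  # higher fitness = lower MAE
  }
  pbest <- pos
  pbest_fit <- apply(pos, 1L, fitness)
  gbest_idx <- which.max(pbest_fit)
  gbest <- pos[gbest_idx, ]
  gbest_fit <- pbest_fit[gbest_idx]
  for (it in seq_len(pso$iterations)) {
    r1 <- matrix(stats::runif(n_particles * dim_p), n_particles, dim_p)
    r2 <- matrix(stats::runif(n_particles * dim_p), n_particles, dim_p)
    vel <- pso$inertia * vel +
      pso$cognitive * r1 * (pbest - pos) +
      pso$social * r2 * (rep(gbest, each = n_particles) - pos)
    pos <- pmin(pmax(pos + vel, -0.2), 1.2)
    fit <- apply(pos, 1L, fitness)
    improved <- fit > pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    if (max(pbest_fit) > gbest_fit) {
      gbest_idx <- which.max(pbest_fit)
      gbest <- pbest[gbest_idx, ]
      gbest_fit <- pbest_fit[gbest_idx]
    }
  }
  model$premise <- as.numeric(gbest)
  model <- anfis_hybrid(model, X, y, acfg$premise_iterations,
                        acfg$premise_step, acfg$ridge_lambda)
  pred <- apply(X, 1L, function(row) anfis_predict(model, row)$output)
  model$out_range <- range(pred)
  if (diff(model$out_range) < 1e-9) model$out_range <- c(0, 1)
  model
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("<anfis_model> 3 inputs x 3 MFs, %d rules; training MAE %s\n",
              nrow(x$rules),
              if (is.null(x$training_log)) "(untrained)"
              else sprintf("%.4f", x$training_log[length(x$training_log)])))
  invisible(x)
}
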