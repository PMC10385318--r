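# End-to-end orchestration: synthetic multi-hospital data -> preprocessing
# -> bi-timescale selection -> paired training samples -> federated
# spiking-GCNN -> held-out coarse evaluation -> optional ANFIS risk staging.

#' Build bi-timescale training pairs for one hospital
#'
#' Generates balanced segment sets at the two chosen timescales and pairs
#' the i-th window of each class at one scale with the i-th at the other
#' (windows sorted by subject and start time; the pair count per class is
#' the smaller of the two per-scale counts).
#'
#' @param recordings list of (preprocessed) [eeg_recording()].
#' @param scales numeric pair of window lengths in seconds.
#' @return list of samples, each `list(windows = list(w1, w2), label,
#'   subject_id, start_s)`.
#' @export
build_timescale_pairs <- function(recordings, scales) {
  sets <- lapply(scales, function(sc) {
    generate_training_samples(recordings, sc)
  })
  pairs <- list()
  for (lab in c("preictal", "interictal")) {
    per_scale <- lapply(sets, function(set) {
      segs <- Filter(function(s) identical(s$label, lab), set$segments)
      ord <- order(vapply(segs, `[[`, character(1), "subject_id"),
                   vapply(segs, `[[`, numeric(1), "start_s"))
      segs[ord]
    })
    n <- min(vapply(per_scale, length, integer(1)))
    for (i in seq_len(n)) {
      pairs[[length(pairs) + 1L]] <- list(
        windows = lapply(per_scale, function(segs) segs[[i]]$window),
        label = lab,
        subject_id = per_scale[[1L]][[i]]$subject_id,
        start_s = per_scale[[1L]][[i]]$start_s
      )
    }
  }
  pairs
}

#' Reference training data for the ANFIS risk stager
#'
#' Draws composite-input/target pairs from the synthetic HRV and clinical
#' generators across the three risk classes (targets 1 / 0.5 / 0 for
#' Pk1 / Pk2 / Pk3); EEG probabilities are drawn from the matching
#' coarse-grained class range.
#'
#' @param n_per_class training rows per risk class.
#' @param seed integer seed.
#' @param config a [run_config()].
#' @return list with matrix `X` (columns eeg/hrv/clinical) and vector `y`.
#' @export
anfis_training_data <- function(n_per_class = 10L, seed = 42L,
                                config = run_config()) {
  classes <- c("Pk1", "Pk2", "Pk3")
  targets <- c(Pk1 = 1, Pk2 = 0.5, Pk3 = 0)
  eeg_ranges <- list(Pk1 = c(0.61, 1.0), Pk2 = c(0.31, 0.6),
                     Pk3 = c(0, 0.3))
  rows <- list()
  y <- numeric(0)
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (i in seq_len(n_per_class)) {
      s <- seed + 10000L * ci + i
      hrv <- generate_hrv_series(cls, n_points = 8L,
                                 delta_small = config$hrv$delta_small,
                                 delta_large = config$hrv$delta_large,
                                 seed = s)
      clin <- generate_clinical_record("ref", cls, seed = s)
      set.seed(s)
      eeg_p <- stats::runif(1L, eeg_ranges[[cls]][1L], eeg_ranges[[cls]][2L])
      feats <- vapply(hrv$features, stats::median, numeric(1))
      rows[[length(rows) + 1L]] <- aggregate_inputs(eeg_p, feats, clin)
      y <- c(y, targets[[cls]])
    }
  }
  list(X = do.call(rbind, rows), y = y)
}

#' Run the full seizure-prediction pipeline on synthetic hospitals
#'
#' Generates the multi-hospital dataset, preprocesses every recording
#' (bandpass + per-second normalization), selects the bi-timescale per
#' hospital with the probe classifier, builds balanced paired training
#' samples and the channel correlation graph, holds out a stratified test
#' fraction per hospital, trains the federated spiking-GCNN with
#' divergence-regularized personalization, and evaluates the personalized
#' client models on the held-out pairs. Optionally stages per-subject risk
#' with the ANFIS-PSO model over EEG probability, HRV and clinical
#' features.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [run_config()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @param test_split held-out fraction per hospital (default 0.2).
#' @param risk_staging also run fine-grained ANFIS risk staging
#'   (default FALSE; adds PSO training time).
#' @return list of class `pipeline_result`: `choices` (per-hospital
#'   bi-timescale choices), `federation`, `metrics` (pooled
#'   `metric_report`), `per_client` metrics, `predictions` (data.frame),
#'   `risk` (per-subject [stage_risk()] results when requested).
#' @export
run_pipeline <- function(spec = synthetic_spec(), config = run_config(),
                         seed = spec$seed, test_split = 0.2,
                         risk_staging = FALSE) {
  data <- generate_federation_dataset(spec)
  # per-hospital preprocessing and bi-timescale AUCs
  prep_recs <- list()
  choices <- list()
  for (h in seq_along(data)) {
    recs <- lapply(data[[h]]$recordings, preprocess_recording,
                   config = config)
    prep_recs[[h]] <- recs
    sets_by_scale <- stats::setNames(
      lapply(config$segmentation$scales_s, function(sc) {
        generate_training_samples(recs, sc)
      }),
      as.character(config$segmentation$scales_s))
    choices[[h]] <- select_bi_timescale(
      sets_by_scale, recs[[1L]]$fs,
      validation_split = config$segmentation$validation_split,
      seed = seed + h)
  }
  # consensus bi-timescale across hospitals: federated weight averaging is
  # only meaningful when every client's branches see the same timescales,
  # so the per-hospital validation AUCs are averaged per scale and the two
  # best scales are fixed globally (ties prefer the shorter scale)
  auc_mat <- do.call(rbind, lapply(choices, `[[`, "auc_by_scale"))
  mean_auc <- colMeans(auc_mat)
  scales_num <- as.numeric(names(mean_auc))
  consensus <- scales_num[order(-mean_auc, scales_num)][1:2]
  clients <- list()
  test_sets <- list()
  for (h in seq_along(data)) {
    recs <- prep_recs[[h]]
    fs <- recs[[1L]]$fs
    pairs <- build_timescale_pairs(recs, consensus)
    labs <- vapply(pairs, `[[`, character(1), "label")
    test_idx <- stratified_split(labs, test_split, seed + 31L * h)
    graph <- build_graph(do.call(rbind, lapply(recs, `[[`, "signal")),
                         config$graph$corr_threshold)
    clients[[h]] <- list(pairs = pairs[-test_idx], graph = graph, fs = fs,
                         client_id = sprintf("H%02d", h))
    test_sets[[h]] <- pairs[test_idx]
  }
  fed <- run_federation(clients, config, seed)
  pred_rows <- list()
  per_client <- list()
  for (h in seq_along(clients)) {
    P <- gcnn_predict(fed$clients[[h]], test_sets[[h]], clients[[h]]$graph,
                      clients[[h]]$fs, config)
    labs <- vapply(test_sets[[h]], `[[`, character(1), "label")
    predicted <- ifelse(P[, "preictal"] >= 0.5, "preictal", "interictal")
    per_client[[h]] <- confusion_metrics(confusion_counts(predicted, labs))
    pred_rows[[h]] <- data.frame(
      client = clients[[h]]$client_id,
      subject_id = vapply(test_sets[[h]], `[[`, character(1), "subject_id"),
      window_start_s = vapply(test_sets[[h]], `[[`, numeric(1), "start_s"),
      preictal_probability = P[, "preictal"],
      predicted_state = predicted,
      actual_state = labs
    )
  }
  predictions <- do.call(rbind, pred_rows)
  pooled <- confusion_metrics(confusion_counts(
    predictions$predicted_state, predictions$actual_state))
  risk <- NULL
  if (risk_staging) {
    train <- anfis_training_data(seed = seed, config = config)
    model <- train_anfis_pso(anfis_init(seed), train$X, train$y, config,
                             seed)
    risk <- list()
    for (h in seq_along(data)) {
      for (s in seq_along(data[[h]]$recordings)) {
        sid <- data[[h]]$recordings[[s]]$subject_id
        rows <- predictions[predictions$subject_id == sid &
                              predictions$actual_state == "preictal", ,
                            drop = FALSE]
        eeg_p <- if (nrow(rows)) mean(rows$preictal_probability) else 0.5
        hrv <- data[[h]]$hrv[[s]]
        feats <- vapply(hrv$features, stats::median, numeric(1))
        x <- aggregate_inputs(eeg_p, feats, data[[h]]$clinical[[s]])
        pattern <- classify_hrv_pattern(hrv, config$hrv$delta_small,
                                        config$hrv$delta_large)
        risk[[sid]] <- stage_risk(anfis_predict(model, x), pattern,
                                  eeg_prob = eeg_p, subject_id = sid)
      }
    }
  }
  structure(
    list(choices = choices, consensus_scales = consensus, federation = fed,
         metrics = pooled, per_client = per_client,
         predictions = predictions, risk = risk, seed = seed),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  consensus bi-timescale:",
      paste(x$consensus_scales, collapse = "+"), "s\n  pooled: ")
  print(x$metrics)
  invisible(x)
}
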