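#' Decode one trial into motor commands
#'
#' Replays a trial as the embedded 250 ms loop: each chunk is band-pass
#' filtered, reduced to its 14-channel band-power feature vector, classified
#' by the two-stage network, and mapped to a motor command record.
#'
#' @param trial an [eeg_trial].
#' @param model a fitted [two_stage_model].
#' @param cfg a [psd_config].
#' @param trial_id identifier used in chunk ids.
#' @return List with `predictions` (character vector, one label per chunk)
#'   and `trace` (the [command_trace()] data.frame).
#' @export
decode_trial <- function(trial, model, cfg = psd_config(), trial_id = "trial") {
  chunks <- stream_chunks(trial, trial_id = trial_id)
  feats <- t(vapply(chunks, extract_features, numeric(length(emotiv_channels)),
                    cfg = cfg))
  preds <- classify_all(model, feats)
  ids <- sprintf("%s_chunk%03d", trial_id,
                 vapply(chunks, `[[`, 1L, "index"))
  list(predictions = as.character(preds),
       trace = command_trace(ids, as.character(preds)))
}

#' End-to-end synthetic decoding experiment
#'
#' Runs the whole pipeline on generated data: a training dataset of
#' `n_train_trials_per_class` trials per class and a disjoint test dataset
#' (distinct per-trial seeds) are generated from `cfg`; band-power features
#' are extracted from every 250 ms chunk; the two-stage network is trained
#' on all training chunks; then `n_test_chunks_per_class` chunks per class
#' (31 by default, mirroring the embedded evaluation protocol) are sampled
#' from the test trials, classified, and scored.
#'
#' @param cfg a [synth_config] for the training data; its `seed` drives both
#'   data generation and the test-chunk sampling.
#' @param n_train_trials_per_class training trials per class (default 20).
#' @param n_test_trials_per_class test trials per class (default 2, i.e. 80
#'   candidate chunks per class).
#' @param n_test_chunks_per_class chunks per class actually scored
#'   (default 31).
#' @param ridge L2 penalty for [train_two_stage()].
#' @param test_cfg configuration for the test data; defaults to `cfg`.
#'   Supplying a different regime (e.g. the blink preset against a
#'   clean-trained network) reproduces the acquisition-regime comparison of
#'   a decoder fit once and deployed on subjects with different artifact
#'   levels: the test trials share the training trials' seed stream, so two
#'   test regimes differing only in blink parameters score the same
#'   underlying rhythms and noise.
#' @return List with `report` (an [evaluation_report()]), `model`,
#'   `mean_percent` (rounded macro accuracy) and `confusion`.
#' @export
pipeline_experiment <- function(cfg = synth_preset("category_II"),
                                n_train_trials_per_class = 20L,
                                n_test_trials_per_class = 2L,
                                n_test_chunks_per_class = 31L,
                                ridge = 1e-8,
                                test_cfg = cfg) {
  train_cfg <- cfg
  train_cfg$n_trials_per_class <- as.integer(n_train_trials_per_class)
  test_cfg$n_trials_per_class <- as.integer(n_test_trials_per_class)

  train <- generate_dataset(train_cfg, trial_seed_offset = 0L)
  test <- generate_dataset(test_cfg,
                           trial_seed_offset = 3L * train_cfg$n_trials_per_class)

  train_ft <- feature_table(train$trials)
  model <- train_two_stage(train_ft, train_ft$label, ridge = ridge)

  test_ft <- feature_table(test$trials)

  picked <- with_local_seed(cfg$seed + 7L, function() {
    unlist(lapply(movement_classes, function(cl) {
      idx <- which(test_ft$label == cl)
      if (length(idx) < n_test_chunks_per_class) {
        stop("not enough test chunks for class ", cl, call. = FALSE)
      }
      sample(idx, n_test_chunks_per_class)
    }))
  })
  preds <- classify_all(model, test_ft[picked, ])
  cm <- confusion(test_ft$label[picked], as.character(preds))
  report <- evaluation_report(cm)
  list(report = report, model = model,
       mean_percent = report$mean, confusion = cm)
}
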