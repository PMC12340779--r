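# End-to-end phantom study: generate a cohort, train cross-validation folds
# of the tiny preset, Beta-calibrate each fold on its validation split,
# ensemble the calibrated test predictions, and score patient-level AUROC
# plus zero-shot semantic inference on the held-out patients.

#' Tiny-preset model factory for phantom studies
#'
#' @param tokenizer The [toy_tokenizer] whose vocabulary sizes the text tower.
#' @param tuning Tuning mode (randomly initialized encoders default to full
#'   fine-tuning; adapter-only tuning presumes pretrained base weights).
#' @export
tiny_model_factory <- function(tokenizer, tuning = "full", ...) {
  # full fine-tuning of randomly initialized encoders carries no adapters;
  # rank-2 adapters are for adapter-mode tuning of pretrained weights
  lora <- if (tuning == "full") lora_config(rank = 0L) else lora_config()
  cfg <- encoder_config("tiny", vocab_size = length(tokenizer$vocab),
                        lora = lora, ...)
  function(seed) build_model(cfg, tuning = tuning, seed = seed)
}

#' Run the phantom-cohort training study
#'
#' Generates (or reuses) a phantom cohort, holds out 20% of patients, trains
#' the tiny preset on `n_folds_trained` cross-validation folds with the full
#' loss (contrastive + two class-weighted cross-entropies), fits a Beta
#' calibrator per fold on that fold's validation predictions, ensembles the
#' calibrated fold predictions on the held-out patients, and reports
#' patient-level AUROC.
#'
#' @param train_seed Master seed for splitting and training.
#' @param phantom_cfg Cohort configuration ([phantom_config]); generation is
#'   governed by its own seed, so several training seeds can share a cohort.
#' @param data Optional pre-built result of [phantom_dataset] for the same
#'   config (avoids re-rendering when sweeping training seeds).
#' @param n_folds_trained Number of folds to train and ensemble.
#' @param epochs,lr,batch_size,patience,sampler_temperature Training-loop
#'   settings passed to [train_config] (tiny-preset defaults; random
#'   initialization tolerates a larger learning rate than adapter
#'   fine-tuning of pretrained weights, and the softened sampler temperature
#'   suits a 400-case cohort where full inverse-frequency upsampling would
#'   concentrate training on a few rare-feature nodules).
#' @param vision Optional named-list override of the tiny preset's vision
#'   tower (e.g. `list(input = 112L, patch = 56L)`).
#' @return List with `test_auroc`, `test_scores` (data.frame), `folds`
#'   (per-fold results incl. calibrators), `plan`, `tokenizer`, `data`.
#' @export
phantom_benchmark <- function(train_seed = 1L,
                              phantom_cfg = phantom_config(n_cases = 400L,
                                                           vol_size = 32L,
                                                           seed = 7L),
                              data = NULL, n_folds_trained = 2L,
                              epochs = 24L, lr = 2e-3, batch_size = 16L,
                              patience = Inf, sampler_temperature = 0.5,
                              vision = NULL) {
  tokenizer <- toy_tokenizer()
  factory <- tiny_model_factory(tokenizer, vision = vision)
  input <- encoder_config("tiny", vision = vision)$vision$input
  if (is.null(data)) data <- phantom_dataset(phantom_cfg, input)
  ds <- data$data
  patients <- dataset_patients(ds)
  plan <- make_splits(patients, seed = train_seed, n_folds = 5L)
  cfg <- train_config(lr = lr, batch_size = batch_size, epochs = epochs,
                      patience = patience,
                      sampler_temperature = sampler_temperature,
                      min_select_epoch = ceiling(0.4 * epochs),
                      seed = train_seed)
  fold_ids <- seq_len(n_folds_trained)
  fits <- train_all_folds(ds, plan, factory, cfg, tokenizer,
                          folds = fold_ids)

  test_idx <- which(patients %in% plan$test_patients)
  test_ds <- subset_dataset(ds, test_idx)
  test_labels <- dataset_labels(test_ds)
  test_patients <- dataset_patients(test_ds)

  fold_cal_scores <- matrix(0, length(test_idx), length(fold_ids))
  for (j in seq_along(fold_ids)) {
    k <- fold_ids[j]
    fit <- fits[[j]]
    val_idx <- which(patients %in% plan$folds[[k]]$val)
    val_ds <- subset_dataset(ds, val_idx)
    val_probs <- predict_dataset(fit$model, val_ds)
    cal <- fit_beta_calibrator(val_probs, dataset_labels(val_ds))
    fits[[j]]$calibrator <- cal
    fold_cal_scores[, j] <- calibrate(cal, predict_dataset(fit$model, test_ds))
  }
  nodule_scores <- apply(fold_cal_scores, 1, ensemble,
                         n_models = length(fold_ids))
  # patient-level risk: max over each patient's nodules
  patient_score <- tapply(nodule_scores, test_patients, aggregate_patient)
  patient_label <- tapply(test_labels, test_patients, max)
  test_auroc <- auroc(as.numeric(patient_score),
                      as.numeric(patient_label[names(patient_score)]))
  list(
    test_auroc = test_auroc,
    test_scores = data.frame(patient_id = names(patient_score),
                             score = as.numeric(patient_score),
                             label = as.numeric(patient_label[names(patient_score)])),
    fold_cal_scores = fold_cal_scores,
    folds = fits, plan = plan, tokenizer = tokenizer, data = data,
    test_idx = test_idx
  )
}

#' Zero-shot consistency discrimination on the held-out phantoms
#'
#' Restricts the study's held-out patients to nodules whose observed
#' consistency is solid or pure ground glass, scores each with the zero-shot
#' probability of the "solid" prompt (averaged over the trained folds), and
#' returns the AUROC of solid vs pure ground glass.
#'
#' @param study Result of [phantom_benchmark].
#' @return List with `auroc`, `n_solid`, `n_ground_glass`.
#' @export
zero_shot_consistency_auroc <- function(study) {
  ds <- subset_dataset(study$data$data, study$test_idx)
  cons <- vapply(ds$entries, function(e) {
    v <- e$record$values$consistency
    if (length(v) == 1L && is.na(v)) NA_character_ else v
  }, character(1))
  keep <- which(cons %in% c("solid", "pure ground glass"))
  if (length(unique(cons[keep])) < 2L) {
    stop("held-out phantoms do not contain both consistency classes")
  }
  sub <- subset_dataset(ds, keep)
  bank <- build_prompts(default_schema())["consistency"]
  class(bank) <- "prompt_bank"
  p_solid <- rep(0, length(keep))
  for (fit in study$folds) {
    zs <- zero_shot_dataset(fit$model, sub, bank, study$tokenizer)
    p_solid <- p_solid +
      vapply(zs, function(z) z$consistency[["solid"]], numeric(1)) /
      length(study$folds)
  }
  list(auroc = auroc(p_solid, as.integer(cons[keep] == "solid")),
       n_solid = sum(cons[keep] == "solid"),
       n_ground_glass = sum(cons[keep] == "pure ground glass"))
}
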