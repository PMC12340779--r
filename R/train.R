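#' Training configuration
#'
#' Defaults follow the published recipe: AdamW with learning rate 1e-4 and
#' weight decay 0.1, batch size 16, learnable temperature initialized at
#' 0.03, and model selection on validation AUROC of the image branch. The
#' epoch budget and early-stopping patience are package choices. A batch
#' needs at least 2 samples so the contrastive loss has in-batch negatives.
#'
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Nodules per batch.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation AUROC
#'   improvement); `Inf` disables early stopping.
#' @param warmup_epochs Linear learning-rate warmup span (epochs; may be 0).
#' @param lr_schedule `"cosine"` (decay to `lr_min_frac * lr` after warmup)
#'   or `"constant"`.
#' @param lr_min_frac Final fraction of `lr` under the cosine schedule.
#' @param clip_norm Global gradient-norm clipping threshold (`Inf` disables).
#' @param view_augment Apply training-time augmentation to the precomputed
#'   views (exact volumetric flips via the view-set symmetry, Gaussian noise
#'   sd 0.02, log-gamma contrast).
#' @param sampler_temperature Temperature of the rarity-upsampling weights
#'   passed to [compute_sample_weights] by [train_all_folds].
#' @param restart_after,restart_val_floor,max_restarts Restart-on-stall rule:
#'   if after `restart_after` epochs an attempt's best validation AUROC is
#'   still below `restart_val_floor`, the attempt is abandoned and training
#'   restarts from a freshly seeded initialization (at most `max_restarts`
#'   times), within the same total epoch budget. Small randomly initialized
#'   towers occasionally start in a basin the optimizer does not leave;
#'   the rule is deterministic under the run seed. Set `max_restarts = 0`
#'   to disable.
#' @param min_select_epoch Earliest epoch (within an attempt) eligible for
#'   checkpoint selection; defaults to the first post-warmup epoch, so a
#'   noise spike during warmup cannot freeze an unconverged checkpoint.
#' @param select_smooth Width (epochs) of the trailing mean of validation
#'   AUROC used as the selection score. On validation sets of a few dozen
#'   patients the per-epoch AUROC is noisy; selecting on a short trailing
#'   mean favours stable plateaus over single-epoch spikes. 1 = raw AUROC.
#' @param ema_decay Per-step decay of an exponential moving average of the
#'   trainable parameters; validation is scored and checkpoints are stored
#'   on the averaged weights, which damps the step-to-step noise of small-
#'   batch training. 0 disables averaging.
#' @param text_policy A [text_aug_policy] for training text, or NULL.
#' @param seed Master seed for the run.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 0.1, batch_size = 16L,
                         epochs = 30L, patience = 10L, warmup_epochs = 2L,
                         lr_schedule = c("cosine", "constant"),
                         lr_min_frac = 0.1, clip_norm = 1,
                         view_augment = TRUE, sampler_temperature = 1,
                         restart_after = 8L, restart_val_floor = 0.58,
                         max_restarts = 2L, min_select_epoch = NULL,
                         select_smooth = 3L, ema_decay = 0.99,
                         text_policy = text_aug_policy(), seed = 1L) {
  stopifnot(lr > 0, batch_size >= 2L, epochs >= 1L, warmup_epochs >= 0,
            lr_min_frac > 0, lr_min_frac <= 1, clip_norm > 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 warmup_epochs = warmup_epochs,
                 lr_schedule = match.arg(lr_schedule),
                 lr_min_frac = lr_min_frac, clip_norm = clip_norm,
                 view_augment = isTRUE(view_augment),
                 sampler_temperature = sampler_temperature,
                 restart_after = restart_after,
                 restart_val_floor = restart_val_floor,
                 max_restarts = max_restarts,
                 min_select_epoch = min_select_epoch %||% (warmup_epochs + 1),
                 select_smooth = as.integer(select_smooth),
                 ema_decay = ema_decay,
                 text_policy = text_policy, seed = as.integer(seed)),
            class = "train_config")
}

epoch_lr <- function(cfg, epoch) {
  if (cfg$warmup_epochs > 0 && epoch <= cfg$warmup_epochs) {
    return(cfg$lr * epoch / cfg$warmup_epochs)
  }
  if (cfg$lr_schedule == "constant" || cfg$epochs <= cfg$warmup_epochs) {
    return(cfg$lr)
  }
  frac <- (epoch - cfg$warmup_epochs) / (cfg$epochs - cfg$warmup_epochs)
  lo <- cfg$lr * cfg$lr_min_frac
  lo + (cfg$lr - lo) * (1 + cos(pi * frac)) / 2
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, `*`, max_norm / total)
  grads
}

# planes (50x50x9) -> rows of raw [0,1] pixels at the model input resolution,
# following the standard path (bilinear to 224, then block-mean pooling).
planes_to_vmat <- function(planes, input, via = 224L) {
  f <- via %/% input
  stopifnot(f * input == via)
  g <- rep(seq_len(input), each = f)
  Vmat <- matrix(0, 9L, input * input)
  for (k in seq_len(9L)) {
    r <- resize_bilinear(planes[, , k], via, via)
    if (f > 1L) r <- t(rowsum(t(rowsum(r, g)), g)) / f^2
    Vmat[k, ] <- as.vector(r)
  }
  Vmat
}

#' Assemble a training dataset from cases
#'
#' Converts preprocessed nodule cases into the flat structure the training
#' loop consumes: per nodule the nine raw views at the model input
#' resolution, the rendered report, the semantic record, and the label.
#'
#' @param cases List of cases, each with `crop` (a `nodule_crop`), `record`
#'   (a `semantic_record`), `label`, `patient_id`, `nodule_id`.
#' @param input Model input resolution (`config$vision$input`).
#' @return Object of class `nodule_dataset`.
#' @export
prepare_nodule_data <- function(cases, input) {
  entries <- lapply(cases, function(cs) {
    planes <- extract_nine_views(cs$crop)$planes
    list(patient_id = cs$patient_id, nodule_id = cs$nodule_id,
         label = cs$label, views = planes_to_vmat(planes, input),
         record = cs$record, report = render_report(cs$record))
  })
  structure(list(entries = entries, input = input), class = "nodule_dataset")
}

dataset_labels <- function(data) {
  vapply(data$entries, `[[`, numeric(1), "label")
}

dataset_patients <- function(data) {
  vapply(data$entries, `[[`, character(1), "patient_id")
}

subset_dataset <- function(data, idx) {
  structure(list(entries = data$entries[idx], input = data$input),
            class = "nodule_dataset")
}

stack_views <- function(entries) {
  do.call(rbind, lapply(entries, `[[`, "views"))
}

make_text_batch <- function(entries, tokenizer, text_policy) {
  toks <- lapply(entries, function(e) {
    txt <- select_training_text(e$report)
    if (!is.null(text_policy)) txt <- augment_text(txt, text_policy)
    tokenize(tokenizer, txt)
  })
  list(mat = do.call(rbind, lapply(toks, as.integer)),
       eots = vapply(toks, function(t) attr(t, "eot"), numeric(1)))
}

predict_dataset <- function(model, data, chunk = 32L) {
  n <- length(data$entries)
  probs <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    Vmat <- stack_views(data$entries[idx])
    inf <- encode_images_infer(model, Vmat, length(idx))
    P <- softmax_rows(inf$logits)
    probs[idx] <- P[, 2L]
  }
  probs
}

#' Train one cross-validation fold
#'
#' Weighted sampling with replacement (rarity upsampling) over the fold's
#' training nodules, the symmetric contrastive loss plus the two
#' class-weighted cross-entropy branches with equal weighting, AdamW updates
#' on the trainable parameters, temperature clamped to \[1e-3, 1\] after each
#' step, and model selection at the epoch with the best validation AUROC of
#' the image branch. Fully seeded; aborts with a diagnostic if any loss
#' component becomes non-finite.
#'
#' @param train_data,val_data `nodule_dataset`s (patient-disjoint).
#' @param model A `nodule_model` (its tuning mode decides what trains).
#' @param cfg A [train_config].
#' @param tokenizer A [toy_tokenizer].
#' @param sample_weights Optional per-nodule sampling weights
#'   ([compute_sample_weights]); uniform when NULL.
#' @return List with `model` (parameters of the best epoch), `log`
#'   (per-epoch data.frame), `best_epoch`, `best_val_auroc`.
#' @export
train_fold <- function(train_data, val_data, model, cfg, tokenizer,
                       sample_weights = NULL, model_factory = NULL) {
  n <- length(train_data$entries)
  stopifnot(n >= cfg$batch_size)
  if (length(intersect(dataset_patients(train_data),
                       dataset_patients(val_data)))) {
    stop("patient leakage between train and validation data")
  }
  labels <- dataset_labels(train_data)
  cw <- class_weights_from_labels(labels)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  stopifnot(all(is.finite(sample_weights)), all(sample_weights > 0))
  steps <- ceiling(n / cfg$batch_size)
  val_labels <- dataset_labels(val_data)

  best <- list(auroc = -Inf, params = model$params, epoch = 0L, attempt = 1L)
  log <- NULL
  epochs_used <- 0L
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > 1L) {
      model <- model_factory(derive_seed(cfg$seed, "restart", attempt))
    }
    budget <- cfg$epochs - epochs_used
    att_cfg <- cfg
    att_cfg$epochs <- budget
    opt <- adamw_init(model_trainable_names(model))
    trainables <- model_trainable_names(model)
    ema <- if (cfg$ema_decay > 0) model$params[trainables] else NULL
    since_best <- 0L
    att_best <- -Inf
    att_vaucs <- numeric(0)
    restart <- FALSE
    for (epoch in seq_len(budget)) {
      ep <- with_seed(derive_seed(cfg$seed, "epoch", attempt, epoch), {
        comp <- c(clip = 0, ce_img = 0, ce_txt = 0, total = 0)
        for (st in seq_len(steps)) {
          idx <- sample.int(n, cfg$batch_size, replace = TRUE,
                            prob = sample_weights)
          entries <- train_data$entries[idx]
          Vmat <- stack_views(entries)
          if (cfg$view_augment) {
            Vmat <- augment_view_batch(Vmat, length(entries))
          }
          txt <- make_text_batch(entries, tokenizer, cfg$text_policy)
          res <- model_step(model, Vmat, txt$mat, txt$eots, labels[idx],
                            class_weights = cw, train = TRUE)
          grads <- clip_gradients(res$grads, cfg$clip_norm)
          up <- adamw_step(model$params, grads, opt,
                           lr = epoch_lr(att_cfg, epoch),
                           weight_decay = cfg$weight_decay)
          model$params <- up$params
          model$params$tau <- min(max(model$params$tau, 1e-3), 1)
          opt <- up$state
          if (!is.null(ema)) {
            d <- cfg$ema_decay
            for (nm in trainables) {
              ema[[nm]] <- d * ema[[nm]] + (1 - d) * model$params[[nm]]
            }
          }
          comp <- comp + unlist(res$losses[c("clip", "ce_img", "ce_txt",
                                             "total")]) / steps
        }
        comp
      })
      eval_model <- model
      if (!is.null(ema)) eval_model$params[trainables] <- ema
      val_probs <- predict_dataset(eval_model, val_data)
      vauc <- if (length(unique(val_labels)) == 2L) {
        auroc(val_probs, val_labels)
      } else NA_real_
      log <- rbind(log, data.frame(attempt = attempt, epoch = epoch,
                                   clip = ep[["clip"]],
                                   ce_img = ep[["ce_img"]],
                                   ce_txt = ep[["ce_txt"]],
                                   total = ep[["total"]], val_auroc = vauc))
      if (!is.na(vauc)) att_best <- max(att_best, vauc)
      att_vaucs <- c(att_vaucs, vauc)
      smooth <- mean(att_vaucs[seq(max(1, epoch - cfg$select_smooth + 1),
                                   epoch)], na.rm = TRUE)
      eligible <- epoch >= cfg$min_select_epoch
      if (eligible && is.finite(smooth) && smooth > best$auroc) {
        best <- list(auroc = smooth, params = eval_model$params,
                     epoch = epoch, attempt = attempt)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      epochs_used <- epochs_used + 1L
      if (epoch == cfg$restart_after && attempt <= cfg$max_restarts &&
          !is.null(model_factory) && att_best < cfg$restart_val_floor &&
          (cfg$epochs - epochs_used) > cfg$restart_after) {
        restart <- TRUE
        break
      }
      if (since_best >= cfg$patience && epoch >= cfg$min_select_epoch) break
    }
    if (!restart) break
  }
  model$params <- best$params
  list(model = model, log = log, best_epoch = best$epoch,
       best_attempt = best$attempt, best_val_auroc = best$auroc,
       attempts = attempt)
}

#' Train all cross-validation folds
#'
#' Runs [train_fold] for each fold of the plan with fold seeds derived from
#' the master seed, returning one trained model per fold.
#'
#' @param data A `nodule_dataset` covering all non-test patients.
#' @param plan A [make_splits] plan.
#' @param model_factory Function `(seed) -> nodule_model` building a fresh
#'   model per fold.
#' @param cfg A [train_config]; `cfg$seed` is the master seed.
#' @param tokenizer A [toy_tokenizer].
#' @param folds Which folds to train (default: all in the plan).
#' @return List of [train_fold] results, one per requested fold.
#' @export
train_all_folds <- function(data, plan, model_factory, cfg, tokenizer,
                            folds = seq_len(plan$n_folds)) {
  audit_splits(plan)
  patients <- dataset_patients(data)
  lapply(folds, function(k) {
    f <- plan$folds[[k]]
    tr <- subset_dataset(data, which(patients %in% f$train))
    va <- subset_dataset(data, which(patients %in% f$val))
    sw <- compute_sample_weights(lapply(tr$entries, `[[`, "record"),
                                 temperature = cfg$sampler_temperature)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, "fold", k)
    fold_model <- model_factory(derive_seed(cfg$seed, "init", k))
    train_fold(tr, va, fold_model, fold_cfg, tokenizer, sample_weights = sw,
               model_factory = model_factory)
  })
}
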