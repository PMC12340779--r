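#' Low-rank adapter configuration
#'
#' Rank-2 adapters with scale factor `alpha = 1` and dropout 0.25 are
#' injected into every query/key/value projection of both transformers. The
#' effective projection weight is `W0 + (alpha/rank) * B %*% A` with `B`
#' zero-initialized (identity at initialization) and `A` small-random.
#'
#' @param rank Adapter rank (>= 1; 0 disables adapters).
#' @param alpha Scale numerator; the adapter contribution is scaled by
#'   `alpha / rank`.
#' @param dropout Dropout rate applied to the adapter input during training.
#' @export
lora_config <- function(rank = 2L, alpha = 1, dropout = 0.25) {
  stopifnot(rank >= 0, dropout >= 0, dropout < 1)
  structure(list(rank = as.integer(rank), alpha = alpha, dropout = dropout),
            class = "lora_config")
}

#' Dual-encoder architecture configuration
#'
#' Two presets are provided. `"vitb32"` replicates the pretrained image-text
#' encoder pair at ViT-B/32 dimensions (vision: patch 32, width 768, depth
#' 12, heads 12, input 224; text: vocab 49408, width 512, depth 12, heads 8,
#' context 77; both projecting to a 512-d shared width). `"tiny"` is the
#' desk-scale configuration used for training without pretrained weights
#' (vision input 56 with patch 14, width 32, depth 2; matching tiny text
#' tower over the toy tokenizer vocabulary). Both attach the heads of the
#' full model: 256-d projection heads, the attention-MIL pooling head over
#' the nine views, two linear prediction heads, and a learnable temperature.
#'
#' @param preset `"tiny"` or `"vitb32"`.
#' @param vocab_size Text vocabulary size override (tiny preset: set this to
#'   the toy tokenizer's vocabulary size).
#' @param lora A [lora_config].
#' @param proj_dim Shared embedding dimension of the projection heads.
#' @param mil_hidden Attention-MIL hidden size.
#' @param tau_init Initial temperature.
#' @param ... Named overrides merged into the `vision`/`text` sublists.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(preset = c("tiny", "vitb32"), vocab_size = NULL,
                           lora = lora_config(), proj_dim = 256L,
                           mil_hidden = 128L, tau_init = 0.03, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "vitb32") {
    list(
      vision = list(input = 224L, patch = 32L, width = 768L, depth = 12L,
                    heads = 12L, mlp_ratio = 4L, embed = 512L),
      text = list(vocab = 49408L, context = 77L, width = 512L, depth = 12L,
                  heads = 8L, mlp_ratio = 4L, embed = 512L)
    )
  } else {
    list(
      vision = list(input = 56L, patch = 28L, width = 32L, depth = 2L,
                    heads = 4L, mlp_ratio = 4L, embed = 32L),
      text = list(vocab = 64L, context = 32L, width = 32L, depth = 2L,
                  heads = 4L, mlp_ratio = 4L, embed = 32L)
    )
  }
  dots <- list(...)
  for (side in c("vision", "text")) {
    if (!is.null(dots[[side]])) {
      cfg[[side]][names(dots[[side]])] <- dots[[side]]
    }
  }
  if (!is.null(vocab_size)) cfg$text$vocab <- as.integer(vocab_size)
  for (side in c("vision", "text")) {
    w <- cfg[[side]]$width
    if (w %% cfg[[side]]$heads != 0L) {
      stop(side, " width must be divisible by head count")
    }
  }
  if (cfg$vision$input %% cfg$vision$patch != 0L) {
    stop("vision input size must be a multiple of the patch size")
  }
  structure(
    c(cfg, list(preset = preset, lora = lora, proj_dim = as.integer(proj_dim),
                mil_hidden = as.integer(mil_hidden), tau_init = tau_init)),
    class = "encoder_config"
  )
}

tower_layer_params <- function(prefix, w, mlp_ratio, lora_rank, depth = 2L) {
  p <- list()
  add <- function(nm, shape, init, group) {
    p[[length(p) + 1]] <<- list(name = nm, shape = shape, init = init,
                                group = group)
  }
  # residual output projections get depth-scaled init (stabilizes training
  # of randomly initialized towers); recorded as a distinct init family

  for (nm in c("ln1", "ln2")) {
    add(paste0(prefix, "_", nm, "_g"), w, "ones", "base")
    add(paste0(prefix, "_", nm, "_b"), w, "zeros", "base")
  }
  for (qkv in c("q", "k", "v")) {
    add(paste0(prefix, "_W", qkv), c(w, w), "attn", "base")
    add(paste0(prefix, "_b", qkv), w, "zeros", "base")
    if (lora_rank > 0) {
      add(paste0(prefix, "_A", qkv), c(lora_rank, w), "lora_A", "adapter")
      add(paste0(prefix, "_B", qkv), c(w, lora_rank), "zeros", "adapter")
    }
  }
  resid <- sprintf("resid:%d", depth)
  add(paste0(prefix, "_Wo"), c(w, w), resid, "base")
  add(paste0(prefix, "_bo"), w, "zeros", "base")
  add(paste0(prefix, "_Wfc"), c(w, w * mlp_ratio), "fc", "base")
  add(paste0(prefix, "_bfc"), w * mlp_ratio, "zeros", "base")
  add(paste0(prefix, "_Wpr"), c(w * mlp_ratio, w), resid, "base")
  add(paste0(prefix, "_bpr"), w, "zeros", "base")
  p
}

#' Parameter manifest of the assembled model
#'
#' Enumerates every parameter tensor of the dual encoder plus heads: name,
#' shape, initialization family, and group (`base`, `adapter`, or `head`).
#' The manifest is the source of truth for parameter counting and for which
#' tensors train under each tuning mode, and can be built without allocating
#' the (possibly very large) tensors themselves.
#'
#' @param config An [encoder_config].
#' @return data.frame with columns name, group, init, n (element count) and a
#'   list column `shape`.
#' @export
param_manifest <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  v <- config$vision; tx <- config$text
  r <- config$lora$rank
  p <- list()
  add <- function(nm, shape, init, group) {
    p[[length(p) + 1]] <<- list(name = nm, shape = shape, init = init,
                                group = group)
  }
  n_patches <- (v$input %/% v$patch)^2
  add("v_patch_W", c(3L * v$patch^2, v$width), "patch", "base")
  add("v_cls", v$width, "small", "base")
  add("v_pos", c(n_patches + 1L, v$width), "small", "base")
  add("v_ln_pre_g", v$width, "ones", "base")
  add("v_ln_pre_b", v$width, "zeros", "base")
  for (l in seq_len(v$depth)) {
    p <- c(p, tower_layer_params(paste0("v_l", l), v$width, v$mlp_ratio, r,
                                 v$depth))
  }
  add("v_ln_post_g", v$width, "ones", "base")
  add("v_ln_post_b", v$width, "zeros", "base")
  add("v_proj", c(v$width, v$embed), "proj", "base")

  add("t_tok", c(tx$vocab, tx$width), "small", "base")
  add("t_pos", c(tx$context, tx$width), "small", "base")
  for (l in seq_len(tx$depth)) {
    p <- c(p, tower_layer_params(paste0("t_l", l), tx$width, tx$mlp_ratio, r,
                                 tx$depth))
  }
  add("t_ln_f_g", tx$width, "ones", "base")
  add("t_ln_f_b", tx$width, "zeros", "base")
  add("t_proj", c(tx$width, tx$embed), "proj", "base")

  add("img_proj_W", c(v$embed, config$proj_dim), "head", "head")
  add("img_proj_b", config$proj_dim, "zeros", "head")
  add("txt_proj_W", c(tx$embed, config$proj_dim), "head", "head")
  add("txt_proj_b", config$proj_dim, "zeros", "head")
  add("mil_V", c(config$mil_hidden, v$embed), "head", "head")
  add("mil_w", config$mil_hidden, "head", "head")
  add("img_head_W", c(config$proj_dim, 2L), "head", "head")
  add("img_head_b", 2L, "zeros", "head")
  add("txt_head_W", c(config$proj_dim, 2L), "head", "head")
  add("txt_head_b", 2L, "zeros", "head")
  add("tau", 1L, "tau", "head")

  data.frame(
    name = vapply(p, `[[`, character(1), "name"),
    group = vapply(p, `[[`, character(1), "group"),
    init = vapply(p, `[[`, character(1), "init"),
    n = vapply(p, function(x) prod(x$shape), numeric(1)),
    shape = I(lapply(p, `[[`, "shape")),
    stringsAsFactors = FALSE
  )
}

trainable_groups <- function(tuning) {
  switch(tuning,
    lora = c("adapter", "head"),
    probe = "head",
    full = c("base", "adapter", "head"),
    stop("unknown tuning mode: ", tuning)
  )
}

init_param <- function(shape, init) {
  n <- prod(shape)
  if (startsWith(init, "resid:")) {
    depth <- as.integer(sub("resid:", "", init))
    vals <- stats::rnorm(n, 0, 1 / sqrt(shape[1]) / sqrt(2 * depth))
  } else {
    vals <- switch(init,
      zeros = rep(0, n),
      ones = rep(1, n),
      small = stats::rnorm(n, 0, 0.02),
      patch = stats::rnorm(n, 0, 1 / sqrt(shape[1])),
      attn = stats::rnorm(n, 0, 1 / sqrt(shape[1])),
      fc = stats::rnorm(n, 0, 1 / sqrt(shape[1])),
      proj = stats::rnorm(n, 0, 1 / sqrt(shape[1])),
      head = stats::rnorm(n, 0, 1 / sqrt(shape[1])),
      lora_A = stats::rnorm(n, 0, 0.02),
      tau = NA_real_,  # overwritten with tau_init
      stop("unknown init: ", init)
    )
  }
  if (length(shape) == 2L) matrix(vals, shape[1], shape[2]) else vals
}

#' Assemble the dual-encoder model
#'
#' Materializes all parameters of [param_manifest] with a seeded random
#' initialization (pretrained weights, when available, can be loaded over the
#' base tensors afterwards). Adapter `B` matrices start at zero so the
#' adapted model's forward pass is exactly the base model's.
#'
#' @param config An [encoder_config].
#' @param tuning Tuning mode: `"full"` (all parameters trainable; the default
#'   for randomly initialized encoders), `"lora"` (base frozen, adapters and
#'   heads trainable), or `"probe"` (heads only).
#' @param seed Seed for the initialization draw.
#' @return Object of class `nodule_model`.
#' @export
build_model <- function(config, tuning = c("full", "lora", "probe"),
                        seed = 1L) {
  tuning <- match.arg(tuning)
  man <- param_manifest(config)
  params <- with_seed(seed, {
    ps <- lapply(seq_len(nrow(man)), function(i) {
      init_param(man$shape[[i]], man$init[i])
    })
    names(ps) <- man$name
    ps
  })
  params$tau <- config$tau_init
  structure(
    list(config = config, params = params, manifest = man, tuning = tuning),
    class = "nodule_model"
  )
}

#' @export
print.nodule_model <- function(x, ...) {
  ct <- count_trainable(x)
  cat(sprintf(
    "nodule_model (%s preset, %s tuning): %s parameters, %s trainable (%.3f%%)\n",
    x$config$preset, x$tuning, format(ct$n_total, big.mark = ","),
    format(ct$n_trainable, big.mark = ","), ct$percent))
  invisible(x)
}

#' Switch a model to adapter-based fine-tuning
#'
#' Re-initializes the low-rank adapters under `cfg` (zero `B`, small-random
#' `A`), freezes the base weights, and marks adapters, projection heads, MIL
#' head, prediction heads, and the temperature trainable. Immediately after
#' injection the forward pass is bit-identical to the unadapted model.
#'
#' @param model A `nodule_model` whose config carries adapter slots
#'   (`lora_config(rank >= 1)`).
#' @param cfg A [lora_config]; must match the rank the model was built with.
#' @param seed Seed for the adapter `A` initialization.
#' @export
inject_lora <- function(model, cfg = lora_config(), seed = 1L) {
  stopifnot(inherits(model, "nodule_model"))
  if (cfg$rank != model$config$lora$rank) {
    stop("adapter rank differs from the rank the model was assembled with; ",
         "rebuild with encoder_config(lora = ...)")
  }
  adapters <- model$manifest$name[model$manifest$group == "adapter"]
  if (cfg$rank > 0 && length(adapters) == 0L) {
    stop("no adapter slots found in this model")
  }
  model$config$lora <- cfg
  with_seed(seed, {
    for (nm in adapters) {
      i <- match(nm, model$manifest$name)
      model$params[[nm]] <- init_param(model$manifest$shape[[i]],
                                       model$manifest$init[i])
    }
  })
  model$tuning <- "lora"
  model
}

#' Count trainable and total parameters
#'
#' Exact integer counts by enumeration of the parameter manifest. Reports
#' both the full trainable set under the model's tuning mode and the
#' adapter-only breakdown.
#'
#' @param x A `nodule_model`, or an [encoder_config] (counted under `tuning`).
#' @param tuning Tuning mode used when `x` is a config.
#' @return List with `n_trainable`, `n_total`, `percent`, `n_adapter`,
#'   `percent_adapter`.
#' @export
count_trainable <- function(x, tuning = "lora") {
  man <- if (inherits(x, "nodule_model")) {
    tuning <- x$tuning
    x$manifest
  } else {
    param_manifest(x)
  }
  groups <- trainable_groups(tuning)
  n_total <- sum(man$n)
  n_trainable <- sum(man$n[man$group %in% groups])
  n_adapter <- sum(man$n[man$group == "adapter"])
  list(
    n_trainable = n_trainable,
    n_total = n_total,
    percent = 100 * n_trainable / n_total,
    n_adapter = n_adapter,
    percent_adapter = 100 * n_adapter / n_total
  )
}
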