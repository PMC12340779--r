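# AdamW with decoupled weight decay. Decay is applied to weight matrices
# only; biases, layer-norm gains, embeddings' positional tables and the
# temperature are not decayed.

adamw_init <- function(names) {
  list(m = stats::setNames(vector("list", length(names)), names),
       v = stats::setNames(vector("list", length(names)), names),
       t = 0L)
}

adamw_decay_param <- function(nm) {
  grepl("(_W|_A|_B|proj$|mil_V|patch_W|t_tok)", nm) &&
    !grepl("(_b$|_g$|tau|pos)", nm)
}

adamw_step <- function(params, grads, state, lr = 1e-4, weight_decay = 0.1,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && adamw_decay_param(nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
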