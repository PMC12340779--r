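# Batched forward/backward through the dual encoder.
#
# Image input to the batched path is a matrix of raw [0,1] view pixels
# (rows = views, bag-major: the nine views of nodule 1, then nodule 2, ...),
# at the model's input resolution. The three standardized channels of each
# view are affine copies of the same grayscale source, so they are expanded
# inside the patch-embedding step.

patch_pixel_index <- function(input, patch) {
  g <- input %/% patch
  idx <- matrix(0L, patch * patch, g * g)
  p <- 0L
  for (py in seq_len(g)) {
    for (px in seq_len(g)) {
      p <- p + 1L
      rows <- (py - 1L) * patch + seq_len(patch)
      cols <- (px - 1L) * patch + seq_len(patch)
      idx[, p] <- as.integer(outer(rows, (cols - 1L) * input, "+"))
    }
  }
  idx
}

# Raw (single-channel) patch matrix: one row per (view, patch).
patches_from_views <- function(Vmat, input, patch) {
  idx <- patch_pixel_index(input, patch)
  np <- ncol(idx)
  nv <- nrow(Vmat)
  P <- matrix(0, nv * np, patch * patch)
  for (p in seq_len(np)) {
    rows <- (seq_len(nv) - 1L) * np + p
    P[rows, ] <- Vmat[, idx[, p], drop = FALSE]
  }
  P
}

# The three standardized channels are affine copies of the same grayscale
# source, so the 3-channel patch embedding T W collapses to
# P Wc + b with Wc = sum_c W_c / sd_c and b = -sum_c mean_c/sd_c colSums(W_c).
fold_patch_weight <- function(W, patch) {
  stats <- clip_channel_stats()
  pp <- patch * patch
  Wc <- matrix(0, pp, ncol(W))
  b <- numeric(ncol(W))
  for (ch in seq_len(3L)) {
    blk <- W[(ch - 1L) * pp + seq_len(pp), , drop = FALSE]
    Wc <- Wc + blk / stats$sd[ch]
    b <- b - stats$mean[ch] / stats$sd[ch] * .colSums(blk, pp, ncol(W))
  }
  list(Wc = Wc, b = b)
}

# gradient wrt the full 3-channel patch weight from dWc-space quantities
unfold_patch_grad <- function(PtdE, col_dE, patch) {
  stats <- clip_channel_stats()
  pp <- patch * patch
  out <- matrix(0, 3L * pp, ncol(PtdE))
  ones <- rep(1, pp)
  for (ch in seq_len(3L)) {
    out[(ch - 1L) * pp + seq_len(pp), ] <-
      PtdE / stats$sd[ch] - (stats$mean[ch] / stats$sd[ch]) * outer(ones, col_dE)
  }
  out
}

encode_image_fwd <- function(model, Vmat, train = FALSE, grads_for = NULL) {
  cfg <- model$config$vision
  p <- model$params
  np <- (cfg$input %/% cfg$patch)^2
  Tn <- np + 1L
  nv <- nrow(Vmat)
  P <- patches_from_views(Vmat, cfg$input, cfg$patch)
  fw <- fold_patch_weight(p$v_patch_W, cfg$patch)
  E0 <- P %*% fw$Wc + rep(fw$b, each = nrow(P))
  X <- matrix(0, nv * Tn, cfg$width)
  cls_rows <- (seq_len(nv) - 1L) * Tn + 1L
  patch_rows <- rep((seq_len(nv) - 1L) * Tn + 1L, each = np) +
    rep(seq_len(np), nv)
  X[cls_rows, ] <- rep(p$v_cls, each = nv)
  X[patch_rows, ] <- E0
  pos_ix <- rep(seq_len(Tn), nv)
  X <- X + p$v_pos[pos_ix, ]
  lnp <- ln_fwd(X, p$v_ln_pre_g, p$v_ln_pre_b)
  X <- lnp$out
  blocks <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    bl <- block_fwd(X, p, paste0("v_l", l), cfg$heads, nv, Tn, FALSE,
                    model$config$lora, train, grads_for)
    blocks[[l]] <- bl$cache
    X <- bl$out
  }
  Xc <- X[cls_rows, , drop = FALSE]
  lnpost <- ln_fwd(Xc, p$v_ln_post_g, p$v_ln_post_b)
  E <- lnpost$out %*% p$v_proj
  list(out = E,
       cache = list(P = P, lnp = lnp, blocks = blocks, lnpost = lnpost,
                    cls_rows = cls_rows, patch_rows = patch_rows,
                    pos_ix = pos_ix, nv = nv, Tn = Tn, np = np))
}

encode_image_bwd <- function(model, dE, cache, grads_for, grads) {
  cfg <- model$config$vision
  p <- model$params
  want <- function(nm) nm %in% grads_for
  acc <- function(nm, val) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) val else grads[[nm]] + val
  }
  dLnPost <- dE %*% t(p$v_proj)
  if (want("v_proj")) acc("v_proj", crossprod(cache$lnpost$out, dE))
  lb <- ln_bwd(dLnPost, cache$lnpost, p$v_ln_post_g, want("v_ln_post_g"))
  if (want("v_ln_post_g")) {
    acc("v_ln_post_g", lb$dg); acc("v_ln_post_b", lb$db)
  }
  dX <- matrix(0, cache$nv * cache$Tn, cfg$width)
  dX[cache$cls_rows, ] <- lb$dX
  for (l in rev(seq_len(cfg$depth))) {
    bb <- block_bwd(dX, cache$blocks[[l]], p, paste0("v_l", l), cfg$heads,
                    cache$nv, cache$Tn, model$config$lora, grads_for, grads)
    dX <- bb$dX
    grads <- bb$grads
  }
  lpb <- ln_bwd(dX, cache$lnp, p$v_ln_pre_g, want("v_ln_pre_g"))
  if (want("v_ln_pre_g")) {
    acc("v_ln_pre_g", lpb$dg); acc("v_ln_pre_b", lpb$db)
  }
  dX <- lpb$dX
  if (want("v_pos")) {
    dp <- rowsum(dX, cache$pos_ix, reorder = TRUE)
    acc("v_pos", dp)
  }
  if (want("v_cls")) acc("v_cls", colSums(dX[cache$cls_rows, , drop = FALSE]))
  if (want("v_patch_W")) {
    dE0 <- dX[cache$patch_rows, , drop = FALSE]
    acc("v_patch_W",
        unfold_patch_grad(crossprod(cache$P, dE0),
                          .colSums(dE0, nrow(dE0), ncol(dE0)),
                          cfg$patch))
  }
  grads
}

encode_text_fwd <- function(model, tok_mat, eots, train = FALSE,
                            grads_for = NULL) {
  cfg <- model$config$text
  p <- model$params
  B <- nrow(tok_mat)
  Tn <- cfg$context
  stopifnot(ncol(tok_mat) == Tn)
  ids <- as.integer(t(tok_mat))
  pos_ix <- rep(seq_len(Tn), B)
  X <- p$t_tok[ids, , drop = FALSE] + p$t_pos[pos_ix, , drop = FALSE]
  blocks <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    bl <- block_fwd(X, p, paste0("t_l", l), cfg$heads, B, Tn, TRUE,
                    model$config$lora, train, grads_for)
    blocks[[l]] <- bl$cache
    X <- bl$out
  }
  eot_rows <- (seq_len(B) - 1L) * Tn + as.integer(eots)
  lnf <- ln_fwd(X[eot_rows, , drop = FALSE], p$t_ln_f_g, p$t_ln_f_b)
  E <- lnf$out %*% p$t_proj
  list(out = E,
       cache = list(blocks = blocks, lnf = lnf, eot_rows = eot_rows,
                    ids = ids, pos_ix = pos_ix, B = B, Tn = Tn))
}

encode_text_bwd <- function(model, dE, cache, grads_for, grads) {
  cfg <- model$config$text
  p <- model$params
  want <- function(nm) nm %in% grads_for
  acc <- function(nm, val) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) val else grads[[nm]] + val
  }
  dLnf <- dE %*% t(p$t_proj)
  if (want("t_proj")) acc("t_proj", crossprod(cache$lnf$out, dE))
  lb <- ln_bwd(dLnf, cache$lnf, p$t_ln_f_g, want("t_ln_f_g"))
  if (want("t_ln_f_g")) { acc("t_ln_f_g", lb$dg); acc("t_ln_f_b", lb$db) }
  dX <- matrix(0, cache$B * cache$Tn, cfg$width)
  dX[cache$eot_rows, ] <- lb$dX
  for (l in rev(seq_len(cfg$depth))) {
    bb <- block_bwd(dX, cache$blocks[[l]], p, paste0("t_l", l), cfg$heads,
                    cache$B, cache$Tn, model$config$lora, grads_for, grads)
    dX <- bb$dX
    grads <- bb$grads
  }
  if (want("t_pos")) acc("t_pos", rowsum(dX, cache$pos_ix, reorder = TRUE))
  if (want("t_tok")) {
    ds <- rowsum(dX, cache$ids, reorder = FALSE)
    dT <- matrix(0, cfg$vocab, cfg$width)
    dT[as.integer(rownames(ds)), ] <- ds
    acc("t_tok", dT)
  }
  grads
}

#' Attention-based multiple-instance pooling
#'
#' Computes attention weights `a_k = softmax_k(w' tanh(V h_k))` over the
#' instances of a bag and the aggregate `z = sum_k a_k h_k`. The non-gated
#' attention form is used.
#'
#' @param H Instance-feature matrix (n_instances x d), one bag.
#' @param head List with `V` (L x d) and `w` (length L).
#' @return List with `z` (length d) and `a` (attention, sums to 1).
#' @export
mil_aggregate <- function(H, head) {
  H <- as.matrix(H)
  if (any(!is.finite(H))) stop("non-finite instance features")
  A <- tanh(H %*% t(head$V))
  a <- softmax_vec(as.vector(A %*% head$w))
  list(z = as.vector(crossprod(H, a)), a = a)
}

mil_batch_fwd <- function(E, mil_V, mil_w, n_inst, B) {
  A <- tanh(E %*% t(mil_V))        # (B*n_inst) x L
  s <- as.vector(A %*% mil_w)
  Smat <- matrix(s, n_inst, B)     # instance-major within bag
  att <- apply(Smat, 2, softmax_vec)
  if (is.null(dim(att))) att <- matrix(att, n_inst, B)
  a_flat <- as.vector(att)
  bag <- rep(seq_len(B), each = n_inst)
  Z <- rowsum(E * a_flat, bag, reorder = TRUE)
  list(Z = Z, att = att, cache = list(A = A, a_flat = a_flat, bag = bag,
                                      n_inst = n_inst, B = B))
}

mil_batch_bwd <- function(dZ, E, mil_V, mil_w, cache) {
  a_flat <- cache$a_flat
  bag <- cache$bag
  dZ_exp <- dZ[bag, , drop = FALSE]
  dE <- dZ_exp * a_flat
  da <- rowSums(E * dZ_exp)
  damat <- matrix(da, cache$n_inst, cache$B)
  amat <- matrix(a_flat, cache$n_inst, cache$B)
  ds <- amat * (damat - rep(colSums(damat * amat), each = cache$n_inst))
  ds_flat <- as.vector(ds)
  A <- cache$A
  dA <- outer(ds_flat, mil_w)
  dpre <- dA * (1 - A * A)
  dE <- dE + dpre %*% mil_V
  list(dE = dE,
       dV = crossprod(dpre, E),
       dw = as.vector(crossprod(A, ds_flat)))
}

model_trainable_names <- function(model) {
  man <- model$manifest
  man$name[man$group %in% trainable_groups(model$tuning)]
}

# Full forward + loss (+ gradients) on one batch.
# Vmat: (B*9) x input^2 raw [0,1] views, bag-major. tok_mat: B x context.
model_step <- function(model, Vmat, tok_mat, eots, labels,
                       class_weights = c(1, 1), train = TRUE,
                       compute_grads = TRUE) {
  p <- model$params
  B <- nrow(tok_mat)
  n_inst <- nrow(Vmat) / B
  stopifnot(n_inst == round(n_inst))
  grads_for <- if (compute_grads) model_trainable_names(model) else character(0)

  img <- encode_image_fwd(model, Vmat, train, grads_for)
  txt <- encode_text_fwd(model, tok_mat, eots, train, grads_for)
  mil <- mil_batch_fwd(img$out, p$mil_V, p$mil_w, n_inst, B)
  img_emb <- mil$Z %*% p$img_proj_W + rep(p$img_proj_b, each = B)
  txt_emb <- txt$out %*% p$txt_proj_W + rep(p$txt_proj_b, each = B)
  In <- l2norm_rows_fwd(img_emb)
  Sn <- l2norm_rows_fwd(txt_emb)
  simmat <- tcrossprod(In$out, Sn$out)
  tau <- p$tau
  img_logits <- img_emb %*% p$img_head_W + rep(p$img_head_b, each = B)
  txt_logits <- txt_emb %*% p$txt_head_W + rep(p$txt_head_b, each = B)

  cl <- clip_loss_grad(simmat, tau)
  ce_i <- weighted_ce_grad(img_logits, labels, class_weights)
  ce_t <- weighted_ce_grad(txt_logits, labels, class_weights)
  losses <- list(clip = cl$loss, l_img = cl$l_img, l_sem = cl$l_sem,
                 ce_img = ce_i$loss, ce_txt = ce_t$loss,
                 total = cl$loss + ce_i$loss + ce_t$loss)
  out <- list(losses = losses, simmat = simmat, attention = mil$att,
              img_logits = img_logits, txt_logits = txt_logits,
              img_emb = img_emb, txt_emb = txt_emb)
  if (!compute_grads) return(out)

  for (nm in names(losses)) {
    if (!is.finite(losses[[nm]])) {
      stop("non-finite loss component '", nm, "' (", losses[[nm]],
           "); aborting this run")
    }
  }
  grads <- list()
  want <- function(nm) nm %in% grads_for
  acc <- function(nm, val) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) val else grads[[nm]] + val
  }
  if (want("tau")) acc("tau", cl$dtau)
  dIn <- cl$dS %*% Sn$out
  dSn <- crossprod(cl$dS, In$out)
  d_img_emb <- l2norm_rows_bwd(dIn, In)
  d_txt_emb <- l2norm_rows_bwd(dSn, Sn)
  d_img_emb <- d_img_emb + ce_i$dlogits %*% t(p$img_head_W)
  d_txt_emb <- d_txt_emb + ce_t$dlogits %*% t(p$txt_head_W)
  if (want("img_head_W")) {
    acc("img_head_W", crossprod(img_emb, ce_i$dlogits))
    acc("img_head_b", colSums(ce_i$dlogits))
    acc("txt_head_W", crossprod(txt_emb, ce_t$dlogits))
    acc("txt_head_b", colSums(ce_t$dlogits))
  }
  dZ <- d_img_emb %*% t(p$img_proj_W)
  dTxtE <- d_txt_emb %*% t(p$txt_proj_W)
  if (want("img_proj_W")) {
    acc("img_proj_W", crossprod(mil$Z, d_img_emb))
    acc("img_proj_b", colSums(d_img_emb))
    acc("txt_proj_W", crossprod(txt$out, d_txt_emb))
    acc("txt_proj_b", colSums(d_txt_emb))
  }
  mb <- mil_batch_bwd(dZ, img$out, p$mil_V, p$mil_w, mil$cache)
  if (want("mil_V")) { acc("mil_V", mb$dV); acc("mil_w", mb$dw) }
  grads <- encode_image_bwd(model, mb$dE, img$cache, grads_for, grads)
  grads <- encode_text_bwd(model, dTxtE, txt$cache, grads_for, grads)
  out$grads <- grads
  out
}

view_stack_to_vmat <- function(stack, input) {
  stopifnot(inherits(stack, "view_stack"))
  stats <- clip_channel_stats()
  size <- stack$size
  f <- size %/% input
  if (f * input != size) stop("model input size must divide the stack size")
  Vmat <- matrix(0, 9L, input * input)
  for (k in seq_len(9L)) {
    raw <- stack$views[, , 1L, k] * stats$sd[1] + stats$mean[1]
    if (f > 1L) {
      # block-mean pooling to the model input resolution
      raw <- rowsum(t(rowsum(raw, rep(seq_len(input), each = f))),
                    rep(seq_len(input), each = f)) / f^2
      raw <- t(raw)
    }
    Vmat[k, ] <- as.vector(raw)
  }
  pmin(pmax(Vmat, 0), 1)
}

#' Forward pass for one image/text pair
#'
#' Runs the nine views through the vision tower, pools them with the MIL
#' head, and projects to the shared 256-d space; runs the token sequence
#' through the text tower and its projection head. Both prediction branches
#' are evaluated. Deterministic in eval mode.
#'
#' @param model A `nodule_model`.
#' @param views A `view_stack`.
#' @param tokens Integer token vector from [tokenize] (or a list of them).
#' @return List with `img_emb`, `txt_emb` (256-d), `img_logits`,
#'   `txt_logits`, and the MIL `attention` over the nine views.
#' @export
forward_pair <- function(model, views, tokens) {
  p <- model$params
  Vmat <- view_stack_to_vmat(views, model$config$vision$input)
  img <- encode_image_fwd(model, Vmat, train = FALSE)
  mil <- mil_batch_fwd(img$out, p$mil_V, p$mil_w, 9L, 1L)
  img_emb <- mil$Z %*% p$img_proj_W + rep(p$img_proj_b, each = 1L)
  tok_mat <- matrix(tokens, nrow = 1)
  eot <- attr(tokens, "eot") %||% max(which(tokens != 1L))
  txt <- encode_text_fwd(model, tok_mat, eot, train = FALSE)
  txt_emb <- txt$out %*% p$txt_proj_W + rep(p$txt_proj_b, each = 1L)
  list(
    img_emb = as.vector(img_emb), txt_emb = as.vector(txt_emb),
    img_logits = as.vector(img_emb %*% p$img_head_W + p$img_head_b),
    txt_logits = as.vector(txt_emb %*% p$txt_head_W + p$txt_head_b),
    attention = as.vector(mil$att)
  )
}

# image-branch embeddings/logits for a batch of raw view matrices
encode_images_infer <- function(model, Vmat, B) {
  p <- model$params
  img <- encode_image_fwd(model, Vmat, train = FALSE)
  mil <- mil_batch_fwd(img$out, p$mil_V, p$mil_w, nrow(Vmat) / B, B)
  img_emb <- mil$Z %*% p$img_proj_W + rep(p$img_proj_b, each = B)
  list(emb = img_emb,
       logits = img_emb %*% p$img_head_W + rep(p$img_head_b, each = B),
       attention = mil$att)
}

encode_texts_infer <- function(model, tok_list) {
  p <- model$params
  tok_mat <- do.call(rbind, lapply(tok_list, as.integer))
  eots <- vapply(tok_list, function(t) attr(t, "eot"), numeric(1))
  txt <- encode_text_fwd(model, tok_mat, eots, train = FALSE)
  txt$out %*% p$txt_proj_W + rep(p$txt_proj_b, each = nrow(tok_mat))
}
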