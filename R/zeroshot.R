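# Zero-shot semantic-feature inference.
#
# Each feature's candidate prompts are embedded by the text tower; a nodule's
# image embedding is scored by cosine similarity against each prompt and the
# similarities are passed through a softmax over that feature's prompt set,
# at the learned temperature.

embed_prompt_bank <- function(model, bank, tokenizer) {
  lapply(unclass(bank), function(prompts) {
    toks <- lapply(prompts, function(s) tokenize(tokenizer, s))
    E <- encode_texts_infer(model, toks)
    En <- l2norm_rows_fwd(E)$out
    rownames(En) <- names(prompts)
    En
  })
}

zs_probs_from_embeddings <- function(img_emb, prompt_emb, tau) {
  u <- img_emb / sqrt(sum(img_emb^2))
  sims <- as.vector(prompt_emb %*% u)
  stats::setNames(softmax_vec(sims / tau), rownames(prompt_emb))
}

#' Zero-shot semantic-feature inference for one nodule
#'
#' @param model A trained `nodule_model`.
#' @param views A `view_stack`.
#' @param bank A [build_prompts] prompt bank.
#' @param tokenizer The [toy_tokenizer] used in training.
#' @return Named list: per categorical feature a class-probability vector
#'   (summing to 1); per binary feature the presence probability (softmax
#'   over the positive prompt and the shared negative).
#' @export
zero_shot_infer <- function(model, views, bank, tokenizer) {
  stopifnot(inherits(bank, "prompt_bank"), length(bank) >= 1L)
  Vmat <- view_stack_to_vmat(views, model$config$vision$input)
  inf <- encode_images_infer(model, Vmat, 1L)
  pe <- embed_prompt_bank(model, bank, tokenizer)
  zero_shot_from_image_emb(as.vector(inf$emb), pe, model$params$tau)
}

zero_shot_from_image_emb <- function(img_emb, prompt_embeddings, tau) {
  out <- lapply(names(prompt_embeddings), function(nm) {
    pr <- zs_probs_from_embeddings(img_emb, prompt_embeddings[[nm]], tau)
    if (identical(names(pr), c("present", "absent"))) unname(pr["present"])
    else pr
  })
  stats::setNames(out, names(prompt_embeddings))
}

# batch zero-shot over a nodule_dataset; prompt embeddings computed once
zero_shot_dataset <- function(model, data, bank, tokenizer, chunk = 32L) {
  pe <- embed_prompt_bank(model, bank, tokenizer)
  n <- length(data$entries)
  res <- vector("list", n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    Vmat <- stack_views(data$entries[idx])
    inf <- encode_images_infer(model, Vmat, length(idx))
    for (j in seq_along(idx)) {
      res[[idx[j]]] <- zero_shot_from_image_emb(inf$emb[j, ], pe,
                                                model$params$tau)
    }
  }
  res
}
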