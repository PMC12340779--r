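# Whitespace toy tokenizer.
#
# The pretrained encoder family uses a byte-pair-encoding tokenizer with a
# 49,408-word vocabulary and context length 77; loading those merges is only
# meaningful together with pretrained weights. For desk-scale training the
# package uses a deterministic whitespace tokenizer whose vocabulary is built
# from the schema, the report templates, and the augmentation lexicon, with
# <start>/<end>/<unk>/<pad> specials and truncation at the context length.

#' Build the toy tokenizer for a schema
#'
#' @param schema A `semantic_schema`.
#' @param context Context length (token positions per sequence).
#' @return Object of class `toy_tokenizer`.
#' @export
toy_tokenizer <- function(schema = default_schema(), context = 32L) {
  words <- c(
    "this", "the", "a", "an", "nodule", "is", "there", "no", "findings",
    "in", "shape", "with", "and", "of",
    unlist(lapply(schema$features, function(ft) c(ft$display, ft$classes))),
    names(default_lexicon()), unlist(default_lexicon())
  )
  toks <- sort(unique(unlist(lapply(words, split_words))))
  vocab <- c("<pad>", "<start>", "<end>", "<unk>", toks)
  structure(
    list(vocab = vocab, context = as.integer(context),
         id = stats::setNames(seq_along(vocab), vocab)),
    class = "toy_tokenizer"
  )
}

split_words <- function(s) {
  s <- gsub("[^a-z0-9 ]", " ", tolower(s))
  w <- strsplit(trimws(s), "[ ]+")[[1]]
  w[nzchar(w)]
}

#' Tokenize sentences into a padded id sequence
#'
#' Joins the sentences, lowercases, splits on non-alphanumeric characters,
#' and maps to vocabulary ids with `<start>`/`<end>` markers, `<unk>` for
#' out-of-vocabulary words, and `<pad>` to the context length. Sequences
#' longer than the context are truncated (the `<end>` marker is kept).
#'
#' @param tok A [toy_tokenizer].
#' @param sentences Character vector.
#' @return Integer vector of length `tok$context`; attribute `eot` holds the
#'   position of the `<end>` token.
#' @export
tokenize <- function(tok, sentences) {
  stopifnot(inherits(tok, "toy_tokenizer"))
  w <- split_words(paste(sentences, collapse = " "))
  ids <- unname(tok$id[w])
  ids[is.na(ids)] <- tok$id[["<unk>"]]
  keep <- min(length(ids), tok$context - 2L)
  seqn <- c(tok$id[["<start>"]], ids[seq_len(keep)], tok$id[["<end>"]])
  eot <- length(seqn)
  out <- c(seqn, rep(tok$id[["<pad>"]], tok$context - length(seqn)))
  attr(out, "eot") <- eot
  out
}
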