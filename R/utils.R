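#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state; restores the caller's state after.
# All stochastic paths in the package funnel through this so that a master
# seed makes full runs bit-reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# Deterministically derive a child seed from a master seed and a stream tag.
# Keeps results below 2^31 and decorrelates named substreams.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

row_maxs <- function(m) {
  # max.col is C-level; guard against -Inf columns (masked attention)
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

logsumexp_rows <- function(m) {
  mx <- row_maxs(m)
  mx + log(.rowSums(exp(m - mx), nrow(m), ncol(m)))
}

softmax_rows <- function(m) {
  e <- exp(m - row_maxs(m))
  e / .rowSums(e, nrow(m), ncol(m))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
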