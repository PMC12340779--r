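# Shared fixtures, built in code.

make_constant_volume <- function(dim = c(30, 30, 30), hu = 100,
                                 spacing = c(2, 2, 2)) {
  ct_volume(array(hu, dim = dim), spacing = spacing)
}

# sphere of given HU in a uniform background, 1 mm isotropic
make_sphere_volume <- function(n = 64, radius = 10, hu_in = 30,
                               hu_out = -850) {
  centre <- rep((n + 1) / 2, 3)
  ax <- seq_len(n)
  X <- rep(ax, times = n * n) - centre[1]
  Y <- rep(rep(ax, each = n), times = n) - centre[2]
  Z <- rep(ax, each = n * n) - centre[3]
  vox <- array(ifelse(sqrt(X^2 + Y^2 + Z^2) <= radius, hu_in, hu_out),
               dim = rep(n, 3))
  list(vol = ct_volume(vox, spacing = c(1, 1, 1)), centre_mm = centre - 1,
       radius = radius)
}

micro_encoder_config <- function(vocab = 24L, lora = lora_config()) {
  encoder_config(
    "tiny", vocab_size = vocab, lora = lora,
    vision = list(input = 14L, patch = 7L, width = 8L, depth = 2L,
                  heads = 2L, embed = 8L),
    text = list(vocab = vocab, context = 8L, width = 8L, depth = 2L,
                heads = 2L, embed = 8L),
    proj_dim = 6L, mil_hidden = 3L
  )
}

micro_batch <- function(B = 3L, cfg = micro_encoder_config(), seed = 11L) {
  withr::with_seed(seed, {
    npix <- cfg$vision$input^2
    list(
      Vmat = matrix(stats::runif(B * 9 * npix), B * 9, npix),
      tok = matrix(sample.int(cfg$text$vocab, B * cfg$text$context, TRUE),
                   B, cfg$text$context),
      eots = sample(2:cfg$text$context, B, TRUE),
      labels = c(0L, rep(1L, B - 1L))
    )
  })
}

# all-pairs AUROC oracle with half-credit for ties
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# cached phantom study shared by the expensive end-to-end tests
phantom_study_cache <- local({
  env <- new.env(parent = emptyenv())
  function(seeds = 1:5) {
    key <- paste0("study_", paste(seeds, collapse = "_"))
    if (is.null(env[[key]])) {
      cfg <- phantom_config(n_cases = 400L, vol_size = 32L, seed = 7L)
      shared <- phantom_dataset(cfg, encoder_config("tiny")$vision$input)
      env[[key]] <- lapply(seeds, function(s) {
        phantom_benchmark(train_seed = s, phantom_cfg = cfg, data = shared,
                          n_folds_trained = 2L)
      })
    }
    env[[key]]
  }
})
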