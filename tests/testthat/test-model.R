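test_that("parameter accounting: adapter arithmetic and tiny/full counts", {
  cfg <- micro_encoder_config()
  man <- param_manifest(cfg)
  # per adapted d x d projection with rank r: 2*d*r added parameters
  d <- cfg$vision$width
  r <- cfg$lora$rank
  aq <- man[man$name == "v_l1_Aq", ]
  bq <- man[man$name == "v_l1_Bq", ]
  expect_equal(aq$n + bq$n, 2 * d * r)
  # full tuning counts everything
  ct_full <- count_trainable(cfg, tuning = "full")
  expect_equal(ct_full$percent, 100)
  expect_equal(ct_full$n_trainable, ct_full$n_total)
  # one extra scalar moves the count by exactly 1 (tau is that scalar)
  no_heads <- sum(man$n[man$group != "head"])
  expect_equal(ct_full$n_total - no_heads, sum(man$n[man$group == "head"]))
  expect_true("tau" %in% man$name[man$group == "head"])
  expect_equal(man$n[man$name == "tau"], 1)
  # integer counts by enumeration
  expect_equal(ct_full$n_total,
               sum(vapply(man$shape, prod, numeric(1))))
})

test_that("LoRA injection is the identity at initialization and freezes the
           base", {
  tokv <- 24L
  cfg <- micro_encoder_config(vocab = tokv)
  base <- build_model(cfg, tuning = "full", seed = 2)
  adapted <- inject_lora(base, lora_config(), seed = 9)
  expect_identical(adapted$tuning, "lora")
  b <- micro_batch(cfg = cfg)
  ns <- asNamespace("noduleclip")
  out_base <- ns$model_step(base, b$Vmat, b$tok, b$eots, b$labels,
                            train = FALSE, compute_grads = FALSE)
  out_adapted <- ns$model_step(adapted, b$Vmat, b$tok, b$eots, b$labels,
                               train = FALSE, compute_grads = FALSE)
  expect_identical(out_base$losses$total, out_adapted$losses$total)
  expect_identical(out_base$img_logits, out_adapted$img_logits)
  # freeze audit: backward yields gradients only for adapters + heads
  res <- ns$model_step(adapted, b$Vmat, b$tok, b$eots, b$labels,
                       train = FALSE, compute_grads = TRUE)
  man <- adapted$manifest
  frozen <- man$name[man$group == "base"]
  expect_length(intersect(names(res$grads), frozen), 0)
  trainable <- ns$model_trainable_names(adapted)
  expect_true(all(c("v_l1_Aq", "t_l2_Bv", "mil_V", "img_proj_W", "tau")
                  %in% trainable))
  # adapter B gradients are non-trivial even at B = 0
  expect_gt(max(abs(res$grads$v_l1_Bq)), 0)
  expect_error(inject_lora(base, lora_config(rank = 3)), "rank")
})

test_that("MIL attention satisfies its contract and the two-instance hand
           value", {
  withr::with_seed(4, {
    d <- 5
    head <- list(V = matrix(stats::rnorm(3 * d), 3, d), w = stats::rnorm(3))
    H <- matrix(stats::rnorm(9 * d), 9, d)
  })
  res <- mil_aggregate(H, head)
  expect_equal(sum(res$a), 1)
  expect_true(all(res$a > 0))
  # identical instances -> uniform attention, aggregate equals the instance
  H1 <- matrix(rep(H[1, ], each = 9), 9, d)
  res1 <- mil_aggregate(H1, head)
  expect_equal(res1$a, rep(1 / 9, 9))
  expect_equal(res1$z, H[1, ])
  # permutation equivariance
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  resp <- mil_aggregate(H[perm, ], head)
  expect_equal(resp$a, res$a[perm])
  expect_equal(resp$z, res$z)
  # d = 1, L = 1 hand oracle
  r2 <- mil_aggregate(matrix(c(1, 2), 2, 1), list(V = matrix(1), w = 1))
  expect_equal(r2$a, c(0.4496, 0.5504), tolerance = 1e-4)
  expect_equal(r2$z, 1.5504, tolerance = 1e-4)
  expect_error(mil_aggregate(matrix(c(1, NaN), 2, 1),
                             list(V = matrix(1), w = 1)), "finite")
})

test_that("contrastive losses match closed forms and symmetries", {
  # uniform similarity matrices: loss = ln B in both directions
  for (B in c(2, 5, 17, 64)) {
    M <- matrix(0.42, B, B)
    expect_equal(info_nce(M, 0.07, "image"), log(B), tolerance = 1e-12)
    expect_equal(info_nce(M, 0.07, "semantic"), log(B), tolerance = 1e-12)
  }
  # identity at tau = 1
  expect_equal(clip_loss(diag(2), 1), log(1 + exp(-1)), tolerance = 1e-9)
  # semantic direction on M equals image direction on t(M)
  withr::with_seed(6, {
    M <- matrix(stats::runif(25, -1, 1), 5, 5)
  })
  expect_equal(info_nce(M, 0.3, "semantic"), info_nce(t(M), 0.3, "image"))
  # softmax shift invariance
  expect_equal(clip_loss(M + 0.37, 0.3), clip_loss(M, 0.3))
  # symmetric matrix: both directions agree
  S <- (M + t(M)) / 2
  expect_equal(info_nce(S, 0.2, "image"), info_nce(S, 0.2, "semantic"))
  expect_gte(info_nce(M, 0.3, "image"), 0)
  expect_error(info_nce(M, 0), "positive")
})

test_that("weighted cross-entropy matches hand evaluation", {
  logits <- rbind(c(2, -1), c(-0.5, 1.5))
  labels <- c(0, 1)
  # uniform weights = ordinary mean CE
  p <- exp(logits) / rowSums(exp(logits))
  mean_ce <- mean(-log(p[cbind(1:2, labels + 1)]))
  expect_equal(weighted_ce(logits, labels, c(1, 1)), mean_ce)
  # weights (1, 3): (l0 + 3 l1) / 4
  l0 <- -log(p[1, 1]); l1 <- -log(p[2, 2])
  expect_equal(weighted_ce(logits, labels, c(1, 3)), (l0 + 3 * l1) / 4)
  # probability one on the true class -> zero loss
  sure <- rbind(c(100, 0), c(0, 100))
  expect_equal(weighted_ce(sure, c(0, 1), c(1, 2)), 0)
  expect_error(weighted_ce(logits, c(0, 2), c(1, 1)), "binary")
  expect_error(weighted_ce(logits, labels, c(0, 1)), "positive")
})

test_that("analytic gradients of the losses match finite differences", {
  ns <- asNamespace("noduleclip")
  withr::with_seed(13, {
    B <- 4
    S <- matrix(stats::runif(B * B, -1, 1), B, B)
    tau <- 0.21
    g <- ns$clip_loss_grad(S, tau)
    eps <- 1e-6
    for (probe in 1:6) {
      i <- sample(B, 1); j <- sample(B, 1)
      Sp <- S; Sp[i, j] <- Sp[i, j] + eps
      Sm <- S; Sm[i, j] <- Sm[i, j] - eps
      fd <- (clip_loss(Sp, tau) - clip_loss(Sm, tau)) / (2 * eps)
      expect_equal(g$dS[i, j], fd, tolerance = 1e-4)
    }
    fd_tau <- (clip_loss(S, tau + eps) - clip_loss(S, tau - eps)) / (2 * eps)
    expect_equal(g$dtau, fd_tau, tolerance = 1e-4)

    logits <- matrix(stats::rnorm(8), 4, 2)
    labels <- c(0, 1, 1, 0)
    cw <- c(1, 2.5)
    gr <- ns$weighted_ce_grad(logits, labels, cw)
    for (probe in 1:6) {
      i <- sample(4, 1); j <- sample(2, 1)
      Lp <- logits; Lp[i, j] <- Lp[i, j] + eps
      Lm <- logits; Lm[i, j] <- Lm[i, j] - eps
      fd <- (weighted_ce(Lp, labels, cw) - weighted_ce(Lm, labels, cw)) /
        (2 * eps)
      expect_equal(gr$dlogits[i, j], fd, tolerance = 1e-4)
    }
  })
})

test_that("full-model analytic gradients match central differences", {
  ns <- asNamespace("noduleclip")
  cfg <- micro_encoder_config()
  model <- build_model(cfg, tuning = "full", seed = 3)
  b <- micro_batch(cfg = cfg)
  res <- ns$model_step(model, b$Vmat, b$tok, b$eots, b$labels,
                       class_weights = c(1, 2), train = FALSE)
  f <- function(m) {
    ns$model_step(m, b$Vmat, b$tok, b$eots, b$labels, class_weights = c(1, 2),
                  train = FALSE, compute_grads = FALSE)$losses$total
  }
  eps <- 1e-5
  withr::with_seed(77, {
    probe_names <- sample(names(res$grads), 12)
    for (nm in unique(c(probe_names, "tau", "v_patch_W", "t_tok", "mil_w"))) {
      g <- res$grads[[nm]]
      i <- sample.int(length(g), 1)
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      fd <- (f(m2) - f(m3)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-3,
                   label = paste("grad", nm, "elem", i))
    }
  })
})

test_that("forward_pair is deterministic with 256-d embeddings and unit
           attention mass", {
  tok <- toy_tokenizer()
  cfg <- encoder_config("tiny", vocab_size = length(tok$vocab))
  model <- build_model(cfg, tuning = "full", seed = 8)
  withr::with_seed(10, {
    planes <- array(stats::runif(50 * 50 * 9), dim = c(50, 50, 9))
  })
  stack <- to_view_stack(planes)
  ids <- tokenize(tok, "The nodule margin is smooth.")
  out1 <- forward_pair(model, stack, ids)
  out2 <- forward_pair(model, stack, ids)
  expect_identical(out1$img_emb, out2$img_emb)
  expect_length(out1$img_emb, 256)
  expect_length(out1$txt_emb, 256)
  expect_length(out1$img_logits, 2)
  expect_equal(sum(out1$attention), 1)
  expect_true(all(out1$attention > 0))
})

test_that("a small optimizer step on a fixed batch decreases the total
           loss", {
  ns <- asNamespace("noduleclip")
  cfg <- micro_encoder_config()
  model <- build_model(cfg, tuning = "full", seed = 21)
  b <- micro_batch(B = 4L, cfg = cfg)
  res <- ns$model_step(model, b$Vmat, b$tok, b$eots, b$labels, train = FALSE)
  opt <- ns$adamw_init(names(model$params))
  up <- ns$adamw_step(model$params, res$grads, opt, lr = 1e-3,
                      weight_decay = 0)
  model$params <- up$params
  res2 <- ns$model_step(model, b$Vmat, b$tok, b$eots, b$labels,
                        train = FALSE, compute_grads = FALSE)
  expect_lt(res2$losses$total, res$losses$total)
})

test_that("temperature stays clamped and the loss is continuous in tau", {
  M <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  taus <- seq(0.001, 1, length.out = 50)
  vals <- vapply(taus, function(t) clip_loss(M, t), numeric(1))
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(diff(vals))), 1)  # no jumps on a fine grid
})
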