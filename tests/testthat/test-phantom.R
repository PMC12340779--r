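test_that("semantic sampling matches the configured marginals and
           dependencies", {
  cfg <- phantom_config(n_cases = 1, seed = 7)
  recs <- lapply(1:10000, function(i) {
    sample_semantics(cfg, seed = i, mask_missing = FALSE)
  })
  cons <- vapply(recs, function(r) r$values$consistency, character(1))
  expect_lt(abs(mean(cons == "solid") - 0.73), 0.02)
  expect_lt(abs(mean(cons == "pure ground glass") - 0.09), 0.02)
  # dependencies: spiculated never smooth; pure GG never calcified
  for (r in recs[1:2000]) {
    m <- r$values$margin
    expect_false(all(c("spiculated", "smooth") %in% m))
    if (identical(r$values$consistency, "pure ground glass")) {
      expect_false(isTRUE(r$values$eccentric_calcification))
    }
  }
  # no missingness without the mask; determinism under equal seed
  expect_false(anyNA(unlist(recs[[1]]$values)))
  expect_identical(sample_semantics(cfg, seed = 5)$values,
                   sample_semantics(cfg, seed = 5)$values)
  # mask applied: airway cutoff mostly missing over many draws
  masked <- vapply(1:800, function(i) {
    v <- sample_semantics(cfg, seed = i)$values$airway_cutoff
    length(v) == 1 && is.na(v)
  }, logical(1))
  expect_gt(mean(masked), 0.6)
})

test_that("rendered morphology encodes consistency, calcification, and
           margin class", {
  cfg <- phantom_config(n_cases = 1, vol_size = 48, seed = 7)
  base <- list(margin = "smooth", shape = "round",
               margin_conspicuity = "well marginated")
  mk <- function(extra, seed = 33, radius = 8) {
    rec <- semantic_record(utils::modifyList(base, extra))
    render_volume(rec, cfg, seed = seed, radius_mm = radius)
  }
  interior_mean <- function(r) {
    d <- dim(r$vol$voxels)
    ax <- seq_len(d[1])
    ctr <- r$centroid_mm + 1
    X <- rep(ax, times = d[1]^2) - ctr[1]
    Y <- rep(rep(ax, each = d[1]), times = d[1]) - ctr[2]
    Z <- rep(ax, each = d[1]^2) - ctr[3]
    mask <- sqrt(X^2 + Y^2 + Z^2) < 0.6 * r$params$radius
    mean(r$vol$voxels[array(mask, dim = d)])
  }
  solid <- mk(list(consistency = "solid"))
  gg <- mk(list(consistency = "pure ground glass"))
  expect_gt(interior_mean(solid) - interior_mean(gg), 400)
  # calcification: bright focus above +300 HU; absent stays below +200
  calc <- mk(list(consistency = "solid", eccentric_calcification = TRUE))
  expect_gte(max(calc$vol$voxels), 300)
  expect_lt(max(solid$vol$voxels), 200)
  # spiculated margins roughen the projected silhouette
  rough <- function(r) {
    crop <- crop_and_normalize(r$vol, r$centroid_mm)
    planes <- extract_nine_views(crop)$planes
    thr <- (normalize_hu(30) + normalize_hu(-850)) / 2
    mean(vapply(1:9, function(k) {
      m <- planes[, , k] > thr
      per <- sum(abs(diff(m)) ) + sum(abs(t(diff(t(m)))))
      per^2 / max(sum(m), 1)
    }, numeric(1)))
  }
  spic <- mk(list(consistency = "solid",
                  margin = c("spiculated", "lobulated")))
  expect_gt(rough(spic), rough(solid))
  expect_error(
    render_volume(semantic_record(list(margin = c("spiculated", "smooth"))),
                  cfg, seed = 1),
    "inconsistent"
  )
})

test_that("label model matches its closed forms and empirical prevalence", {
  # all-zero covariates
  rec0 <- semantic_record(list(consistency = "solid"))
  expect_equal(assign_label(rec0, radius_mm = 6)$prob, stats::plogis(-2))
  # spiculated-only nodule of radius 6: -2 + 2 = 0 -> one half
  rec1 <- semantic_record(list(margin = "spiculated"))
  expect_equal(assign_label(rec1, radius_mm = 6)$prob, 0.5)
  # empirical prevalence over draws matches the analytic mixture
  cfg <- phantom_config(n_cases = 1, seed = 7)
  withr::with_seed(55, {
    draws <- lapply(1:4000, function(i) {
      rec <- sample_semantics(cfg, seed = i)
      r <- withr::with_seed(i + 1e6, stats::runif(1, cfg$radius_range[1],
                                                  cfg$radius_range[2]))
      assign_label(rec, radius_mm = r, seed = i + 5e5)
    })
    probs <- vapply(draws, `[[`, numeric(1), "prob")
    labs <- vapply(draws, `[[`, integer(1), "label")
  })
  expect_lt(abs(mean(labs) - mean(probs)), 0.03)
  # determinism
  expect_identical(assign_label(rec1, 8, seed = 3),
                   assign_label(rec1, 8, seed = 3))
})

test_that("logistic regression on 5000 phantom records recovers the label
           coefficients", {
  cfg <- phantom_config(n_cases = 1, seed = 7)
  n <- 5000
  X <- matrix(0, n, 5,
              dimnames = list(NULL, c("spiculated", "ill_defined", "smooth",
                                      "gg", "radius")))
  y <- integer(n)
  for (i in seq_len(n)) {
    rec <- sample_semantics(cfg, seed = i, mask_missing = FALSE)
    r <- withr::with_seed(i + 2e6,
                          stats::runif(1, cfg$radius_range[1],
                                       cfg$radius_range[2]))
    m <- rec$values$margin
    X[i, ] <- c("spiculated" %in% m, "ill-defined" %in% m, "smooth" %in% m,
                identical(rec$values$consistency, "pure ground glass"),
                (r - 6) / 3)
    y[i] <- assign_label(rec, r, seed = i + 5e5)$label
  }
  # withhold the two rare covariates; their absence perturbs estimates
  # far less than the recovery tolerance
  fit <- stats::glm(y ~ X, family = stats::binomial())
  beta <- phantom_beta()
  est <- stats::coef(fit)
  expect_lt(abs(est[["Xspiculated"]] - beta[["spiculated"]]), 0.3)
  expect_lt(abs(est[["Xill_defined"]] - beta[["ill-defined"]]), 0.3)
  expect_lt(abs(est[["Xsmooth"]] - beta[["smooth"]]), 0.3)
  expect_lt(abs(est[["Xgg"]] - beta[["pure ground glass"]]), 0.3)
  expect_lt(abs(est[["Xradius"]] - beta[["radius"]]), 0.3)
  expect_lt(abs(est[["(Intercept)"]] - beta[["intercept"]]), 0.3)
})

test_that("mean crop intensity separates solid from pure ground glass
           phantoms", {
  cfg <- phantom_config(n_cases = 1, vol_size = 32, seed = 7)
  vals <- list()
  for (i in 1:120) {
    rec <- sample_semantics(cfg, seed = i, mask_missing = FALSE)
    cons <- rec$values$consistency
    if (!cons %in% c("solid", "pure ground glass")) next
    rnd <- render_volume(rec, cfg, seed = i, radius_mm = 8)
    crop <- crop_and_normalize(rnd$vol, rnd$centroid_mm)
    ctr <- crop$cube[21:30, 21:30, 21:30]
    vals[[length(vals) + 1]] <- c(mean(ctr), cons == "solid")
  }
  m <- do.call(rbind, vals)
  expect_gte(auroc(m[, 1], m[, 2]), 0.95)
})

test_that("generate_dataset writes a round-trippable cohort", {
  out <- withr::local_tempdir()
  cfg <- phantom_config(n_cases = 6, vol_size = 32, seed = 7)
  man <- generate_dataset(cfg, file.path(out, "cohort"))
  expect_equal(nrow(man), 6)
  files <- list.files(file.path(out, "cohort"))
  expect_length(grep("nii.gz$", files), 6)
  expect_true(all(c("manifest.csv", "semantics.csv") %in% files))
  expect_error(generate_dataset(cfg, file.path(out, "cohort")),
               "already exists")
  # round trip through imaging + text preprocessing
  man2 <- utils::read.csv(file.path(out, "cohort", "manifest.csv"))
  recs <- read_semantics_csv(file.path(out, "cohort", "semantics.csv"))
  vol <- read_ct_nifti(man2$image_path[1])
  stack <- preprocess_nodule(vol, c(man2$x_mm[1], man2$y_mm[1], man2$z_mm[1]))
  expect_s3_class(stack, "view_stack")
  rep <- render_report(recs[[1]])
  expect_gt(length(rep$findings), 0)
  expect_true(all(man2$label %in% 0:1))
  # regeneration under an equal seed is identical
  out2 <- file.path(out, "cohort2")
  man3 <- generate_dataset(cfg, out2)
  expect_identical(man2$label, utils::read.csv(file.path(out2,
                                                         "manifest.csv"))$label)
  v1 <- read_ct_nifti(man2$image_path[1])
  v2 <- read_ct_nifti(file.path(out2, basename(man2$image_path[1])))
  expect_identical(v1$voxels, v2$voxels)
})
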