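# Seeded synthetic cohort generator.
#
# Each phantom case is a CT-like volume containing one nodule whose rendered
# morphology is a deterministic-plus-noise function of a sampled semantic
# record: consistency sets interior attenuation, margin classes add spikes /
# lobes / edge blur, shape perturbs the radial profile, and selected internal
# and external findings add calcification, cyst-like spaces, or a pleural
# plate. Outcome labels are drawn from a declared logistic model on the
# semantic covariates (never on the pixels directly), so image-based
# prediction must proceed through the rendered morphology.

#' Phantom cohort configuration
#'
#' @param n_cases Number of cases (one nodule per patient).
#' @param vol_size Cubic volume edge in voxels at 1 mm spacing. 64 is the
#'   full-size default; tests and the training benchmark use 32 for speed.
#' @param bg_mean,bg_sd Background (lung parenchyma) HU texture moments.
#' @param radius_range Nodule radius range (mm).
#' @param marginals Semantic marginals; see [phantom_marginals].
#' @param missingness Named per-feature missingness probabilities.
#' @param beta Label-model coefficients; see [phantom_beta].
#' @param seed Master seed.
#' @export
phantom_config <- function(n_cases = 400L, vol_size = 64L, bg_mean = -850,
                           bg_sd = 40, radius_range = c(3, 15),
                           marginals = phantom_marginals(),
                           missingness = phantom_missingness(),
                           beta = phantom_beta(), seed = 7L) {
  stopifnot(radius_range[1] > 0, radius_range[2] < vol_size / 2,
            n_cases >= 1L)
  structure(
    list(n_cases = as.integer(n_cases), vol_size = as.integer(vol_size),
         bg_mean = bg_mean, bg_sd = bg_sd, radius_range = radius_range,
         marginals = marginals, missingness = missingness, beta = beta,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Default semantic marginals of the phantom cohort
#'
#' Loosely shaped like the screening-cohort class percentages: solid nodules
#' dominate consistency, most margins are smooth, internal findings are rare.
#' Margin classes are drawn as (dependent) indicators: a spiculated nodule is
#' never also smooth, and a pure-ground-glass nodule never carries eccentric
#' calcification.
#'
#' @export
phantom_marginals <- function() {
  list(
    margin = c(smooth = 0.67, lobulated = 0.22, spiculated = 0.24,
               "ill-defined" = 0.19),
    consistency = c("peri-cystic" = 0.02, solid = 0.73,
                    "pure ground glass" = 0.09, semiconsolidation = 0.08,
                    "part-solid" = 0.08),
    shape = c(irregular = 0.31, ovoid = 0.35, polygonal = 0.14,
              round = 0.20),
    margin_conspicuity = c("well marginated" = 0.84,
                           "poorly marginated" = 0.16),
    binary = c(reticulation = 0.88, cyst_like_spaces = 0.14,
               necrosis = 0.004, eccentric_calcification = 0.03,
               cavitation = 0.004, bronchiectasis = 0.03,
               airway_cutoff = 0.07, vascular_convergence = 0.10,
               pleural_retraction = 0.80, pleural_attachment = 0.53,
               emphysema = 0.12, septal_stretching = 0.70)
  )
}

#' Default per-feature missingness of the phantom cohort
#'
#' Airway cutoff is mostly unannotated, mirroring its dominant missingness in
#' the motivating cohort; the frequently annotated general features are
#' nearly complete.
#'
#' @export
phantom_missingness <- function() {
  m <- c(margin = 0.02, consistency = 0.02, shape = 0.02,
         margin_conspicuity = 0.05, reticulation = 0.05,
         cyst_like_spaces = 0.05, necrosis = 0.05,
         eccentric_calcification = 0.02, cavitation = 0.05,
         bronchiectasis = 0.05, airway_cutoff = 0.71,
         vascular_convergence = 0.05, pleural_retraction = 0.05,
         pleural_attachment = 0.05, emphysema = 0.05,
         septal_stretching = 0.05)
  m
}

#' Label-model coefficients of the phantom cohort
#'
#' Logistic coefficients on semantic indicators (missing features contribute
#' 0) plus a standardized radius term `0.8 * (r - 6) / 3`.
#'
#' @export
phantom_beta <- function() {
  c(intercept = -2.0, spiculated = 2.0, `ill-defined` = 1.0, smooth = -1.0,
    `pure ground glass` = 0.5, eccentric_calcification = -1.5,
    vascular_convergence = 1.0, radius = 0.8)
}

#' Sample one semantic record from the configured marginals
#'
#' @param cfg A [phantom_config].
#' @param seed Seed for the draw.
#' @param mask_missing Apply the configured missingness mask.
#' @return A `semantic_record`.
#' @export
sample_semantics <- function(cfg, seed = NULL, mask_missing = TRUE) {
  m <- cfg$marginals
  with_seed(seed, {
    spic <- stats::runif(1) < m$margin[["spiculated"]]
    lob <- stats::runif(1) < m$margin[["lobulated"]]
    illd <- stats::runif(1) < m$margin[["ill-defined"]]
    smooth <- !spic && stats::runif(1) < m$margin[["smooth"]]
    margin <- c("smooth", "lobulated", "spiculated", "ill-defined")[
      c(smooth, lob, spic, illd)]
    if (!length(margin)) margin <- "smooth"
    consistency <- sample(names(m$consistency), 1,
                          prob = m$consistency / sum(m$consistency))
    shape <- sample(names(m$shape), 1, prob = m$shape / sum(m$shape))
    consp <- sample(names(m$margin_conspicuity), 1,
                    prob = m$margin_conspicuity)
    values <- list(margin = margin, consistency = consistency, shape = shape,
                   margin_conspicuity = consp)
    for (nm in names(m$binary)) {
      pres <- stats::runif(1) < m$binary[[nm]]
      if (nm == "eccentric_calcification" &&
          consistency == "pure ground glass") {
        pres <- FALSE
      }
      values[[nm]] <- pres
    }
    if (mask_missing) {
      for (nm in names(values)) {
        pm <- cfg$missingness[[nm]]
        if (!is.null(pm) && stats::runif(1) < pm) values[[nm]] <- NA
      }
    }
    semantic_record(values)
  })
}

# smooth angular modulation: sum of random directional lobes
angular_lobes <- function(U, n_lobes, amp, power) {
  g <- numeric(nrow(U))
  for (j in seq_len(n_lobes)) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    a <- stats::runif(1, 0.5, 1) * amp
    g <- g + a * (U %*% d)^power
  }
  as.vector(g)
}

consistency_hu <- function(consistency) {
  switch(consistency,
    solid = 30, "part-solid" = 30, "pure ground glass" = -620,
    semiconsolidation = -350, "peri-cystic" = 30, 30)
}

#' Render a phantom CT volume from a semantic record
#'
#' Background Gaussian lung texture plus a radial implicit nodule: the base
#' sphere radius is modulated by shape-class angular noise and lobulation
#' lobes; spiculation adds Poisson(8) radial spikes 2-6 mm long; an
#' ill-defined margin widens the edge blending to sigma 1.5 mm. Interior
#' attenuation follows consistency (solid about +30 HU, pure ground glass
#' about -620 HU, part-solid a ground-glass shell with a solid core), with
#' optional eccentric calcification (+400 HU sphere offset at least r/2),
#' cyst-like spaces (-800 HU interior sphere), and a pleural plate (0 HU slab
#' tangent to the nodule).
#'
#' @param rec A `semantic_record` (missing general features fall back to
#'   smooth / solid / ovoid defaults).
#' @param cfg A [phantom_config].
#' @param seed Seed for the render noise.
#' @param radius_mm Optional fixed radius; drawn from the config range when
#'   NULL.
#' @return List with `vol` (a [ct_volume]), `centroid_mm`, and `params`
#'   (ground-truth render parameters).
#' @export
render_volume <- function(rec, cfg, seed = NULL, radius_mm = NULL) {
  v <- rec$values
  margin <- if (length(v$margin) == 1L && is.na(v$margin)) "smooth"
    else v$margin
  if (all(c("spiculated", "smooth") %in% margin)) {
    stop("inconsistent record: margin cannot be both spiculated and smooth")
  }
  consistency <- if (length(v$consistency) == 1L && is.na(v$consistency)) {
    "solid"
  } else v$consistency
  shape <- if (length(v$shape) == 1L && is.na(v$shape)) "ovoid" else v$shape
  has <- function(nm) isTRUE(v[[nm]])

  n <- cfg$vol_size
  with_seed(seed, {
    r <- radius_mm %||% stats::runif(1, cfg$radius_range[1],
                                     cfg$radius_range[2])
    r <- min(r, n / 2 - 1)
    centre <- rep((n + 1) / 2, 3) + stats::runif(3, -1.5, 1.5)
    vox <- array(stats::rnorm(n^3, cfg$bg_mean, cfg$bg_sd), dim = rep(n, 3))

    ax <- seq_len(n)
    X <- rep(ax, times = n * n) - centre[1]
    Y <- rep(rep(ax, each = n), times = n) - centre[2]
    Z <- rep(ax, each = n * n) - centre[3]
    dist <- sqrt(X^2 + Y^2 + Z^2)
    U <- cbind(X, Y, Z) / pmax(dist, 1e-9)

    g <- numeric(n^3)
    if (shape == "irregular") g <- g + angular_lobes(U, 8, 0.18, 5)
    if (shape == "polygonal") g <- g + angular_lobes(U, 5, 0.15, 4)
    if (shape == "ovoid") {
      d0 <- stats::rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
      g <- g + 0.25 * as.vector((U %*% d0)^2) - 0.12
    }
    if ("lobulated" %in% margin) g <- g + angular_lobes(U, 4, 0.25, 3)
    r_eff <- r * (1 + g)

    sigma <- if ("ill-defined" %in% margin) 1.5 else 0.5
    alpha <- pmin(pmax(0.5 + (r_eff - dist) / (2 * sigma), 0), 1)

    n_spikes <- 0L
    if ("spiculated" %in% margin) {
      n_spikes <- stats::rpois(1, 8)
      for (s in seq_len(n_spikes)) {
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        len <- stats::runif(1, 2, 6)
        t <- cbind(X, Y, Z) %*% d
        radial <- sqrt(pmax(dist^2 - as.vector(t)^2, 0))
        spike <- as.vector(t) > 0.4 * r & as.vector(t) < r + len &
          radial < 1.1
        alpha[spike] <- pmax(alpha[spike], 0.85)
      }
    }

    hu_in <- consistency_hu(consistency) + stats::rnorm(n^3, 0, 20)
    if (consistency == "part-solid") {
      hu_in[dist > 0.55 * r] <- -620 + stats::rnorm(sum(dist > 0.55 * r), 0, 20)
    }
    vox_flat <- as.vector(vox) * (1 - alpha) + hu_in * alpha

    calc_centre <- NULL
    if (has("eccentric_calcification")) {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      off <- stats::runif(1, 0.5, 0.8) * r
      calc_centre <- centre + d * off
      cr <- stats::runif(1, 1, 2)
      cd <- sqrt((X - d[1] * off)^2 + (Y - d[2] * off)^2 + (Z - d[3] * off)^2)
      vox_flat[cd < cr] <- 400
    }
    if (has("cyst_like_spaces") || consistency == "peri-cystic") {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      off <- stats::runif(1, 0, 0.4) * r
      cr <- max(r / 3, 1.5)
      cd <- sqrt((X - d[1] * off)^2 + (Y - d[2] * off)^2 + (Z - d[3] * off)^2)
      vox_flat[cd < cr & alpha > 0.5] <- -800
    }
    if (has("pleural_attachment")) {
      axis <- sample.int(3, 1)
      coord <- list(X, Y, Z)[[axis]]
      side <- sample(c(-1, 1), 1)
      plate <- side * coord > r & side * coord < r + 4
      vox_flat[plate] <- 0
    }

    vox <- array(vox_flat, dim = rep(n, 3))
    vol <- ct_volume(vox, spacing = c(1, 1, 1), origin = c(0, 0, 0))
    list(vol = vol, centroid_mm = centre - 1,
         params = list(radius = r, n_spikes = n_spikes, sigma_edge = sigma,
                       hu_core = consistency_hu(consistency),
                       calc_centre = calc_centre))
  })
}

#' Draw an outcome label from the semantic logistic model
#'
#' `label ~ Bernoulli(sigmoid(beta' x))` on the semantic indicators
#' (spiculated, ill-defined, smooth margin; pure-ground-glass consistency;
#' eccentric calcification; vascular convergence) plus the standardized
#' radius term; MISSING features contribute 0.
#'
#' @param rec A `semantic_record`.
#' @param radius_mm Rendered nodule radius (mm).
#' @param beta Coefficients, see [phantom_beta].
#' @param seed Seed for the Bernoulli draw.
#' @return List with `label` (0/1) and `prob`.
#' @export
assign_label <- function(rec, radius_mm = 6, beta = phantom_beta(),
                         seed = NULL) {
  v <- rec$values
  margin <- if (length(v$margin) == 1L && is.na(v$margin)) character(0)
    else v$margin
  consistency <- if (length(v$consistency) == 1L && is.na(v$consistency)) ""
    else v$consistency
  eta <- beta[["intercept"]] +
    beta[["spiculated"]] * ("spiculated" %in% margin) +
    beta[["ill-defined"]] * ("ill-defined" %in% margin) +
    beta[["smooth"]] * ("smooth" %in% margin) +
    beta[["pure ground glass"]] * (consistency == "pure ground glass") +
    beta[["eccentric_calcification"]] * isTRUE(v$eccentric_calcification) +
    beta[["vascular_convergence"]] * isTRUE(v$vascular_convergence) +
    beta[["radius"]] * (radius_mm - 6) / 3
  prob <- sigmoid(eta)
  label <- with_seed(seed, as.integer(stats::runif(1) < prob))
  list(label = label, prob = prob, eta = eta)
}

phantom_case <- function(cfg, i) {
  rec <- sample_semantics(cfg, seed = derive_seed(cfg$seed, "sem", i))
  rnd <- render_volume(rec, cfg, seed = derive_seed(cfg$seed, "render", i))
  lab <- assign_label(rec, rnd$params$radius, cfg$beta,
                      seed = derive_seed(cfg$seed, "label", i))
  rec$patient_id <- sprintf("P%04d", i)
  rec$nodule_id <- sprintf("P%04d_n1", i)
  list(patient_id = rec$patient_id, nodule_id = rec$nodule_id,
       vol = rnd$vol, centroid_mm = rnd$centroid_mm, record = rec,
       label = lab$label, prob = lab$prob, params = rnd$params)
}

#' Generate a phantom dataset on disk
#'
#' Writes one NIfTI volume per case plus a nodule manifest CSV
#' (`patient_id, nodule_id, image_path, x_mm, y_mm, z_mm, label`) and a
#' semantics CSV in the formats the preprocessing and text modules read.
#' Byte-reproducible from the config seed.
#'
#' @param cfg A [phantom_config].
#' @param out_dir Output directory (must not already contain a manifest).
#' @return Invisibly, the manifest data.frame.
#' @export
generate_dataset <- function(cfg, out_dir) {
  if (file.exists(file.path(out_dir, "manifest.csv"))) {
    stop("output manifest already exists in ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  recs <- list()
  for (i in seq_len(cfg$n_cases)) {
    cs <- phantom_case(cfg, i)
    img_path <- file.path(out_dir, paste0(cs$patient_id, ".nii.gz"))
    write_ct_nifti(cs$vol, img_path)
    rows[[i]] <- data.frame(
      patient_id = cs$patient_id, nodule_id = cs$nodule_id,
      image_path = img_path, x_mm = cs$centroid_mm[1],
      y_mm = cs$centroid_mm[2], z_mm = cs$centroid_mm[3], label = cs$label
    )
    recs[[i]] <- cs$record
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  write_semantics_csv(recs, file.path(out_dir, "semantics.csv"))
  invisible(manifest)
}

#' Generate an in-memory phantom training dataset
#'
#' Renders each case, crops around the nodule centroid, extracts the nine
#' views, and keeps only what the training loop needs (views at the model
#' input resolution, record, label), so large cohorts fit in memory.
#'
#' @param cfg A [phantom_config].
#' @param input Model input resolution.
#' @return List with `data` (a `nodule_dataset`) and `meta` (per-case
#'   data.frame of patient_id, label, radius, prob).
#' @export
phantom_dataset <- function(cfg, input) {
  entries <- vector("list", cfg$n_cases)
  meta <- vector("list", cfg$n_cases)
  for (i in seq_len(cfg$n_cases)) {
    cs <- phantom_case(cfg, i)
    crop <- crop_and_normalize(cs$vol, cs$centroid_mm)
    planes <- extract_nine_views(crop)$planes
    entries[[i]] <- list(
      patient_id = cs$patient_id, nodule_id = cs$nodule_id,
      label = cs$label, views = planes_to_vmat(planes, input),
      record = cs$record, report = render_report(cs$record)
    )
    meta[[i]] <- data.frame(patient_id = cs$patient_id, label = cs$label,
                            radius = cs$params$radius, prob = cs$prob)
  }
  list(data = structure(list(entries = entries, input = input),
                        class = "nodule_dataset"),
       meta = do.call(rbind, meta))
}
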