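#' Training-time augmentation policy for nodule crops
#'
#' Volumetric augmentation applied to the normalized 3D crop before view
#' extraction, in the order jitter -> flip -> rotation -> noise -> gamma.
#' Noise and gamma act on normalized intensities; values are re-clipped to
#' \[0, 1\] afterwards. A zero-magnitude policy reproduces the deterministic
#' crop exactly.
#'
#' @param jitter_max_mm Maximum per-axis uniform centroid jitter (mm).
#' @param flip_prob Per-axis independent flip probability.
#' @param max_rotation_deg Maximum rotation magnitude about a random
#'   coordinate axis (degrees).
#' @param noise_mean,noise_sd Additive Gaussian noise moments (normalized
#'   intensity units).
#' @param log_gamma_range Range of `u`; intensities are raised to `exp(u)`,
#'   so values near 0 leave contrast nearly unchanged.
#' @export
augmentation_policy <- function(jitter_max_mm = 5, flip_prob = 0.5,
                                max_rotation_deg = 10, noise_mean = 0,
                                noise_sd = 0.02,
                                log_gamma_range = c(-0.02, 0.02)) {
  stopifnot(jitter_max_mm >= 0, flip_prob >= 0, flip_prob <= 1,
            max_rotation_deg >= 0, noise_sd >= 0,
            length(log_gamma_range) == 2L,
            log_gamma_range[1] <= log_gamma_range[2])
  structure(
    list(jitter_max_mm = jitter_max_mm, flip_prob = flip_prob,
         max_rotation_deg = max_rotation_deg, noise_mean = noise_mean,
         noise_sd = noise_sd, log_gamma_range = log_gamma_range),
    class = "augmentation_policy"
  )
}

# zero-magnitude policies must take the exact deterministic path
policy_is_identity <- function(p) {
  p$jitter_max_mm == 0 && p$flip_prob == 0 && p$max_rotation_deg == 0 &&
    p$noise_sd == 0 && p$noise_mean == 0 &&
    all(p$log_gamma_range == 0)
}

rotate_crop <- function(cube, axis, theta_deg) {
  if (theta_deg == 0) return(cube)
  th <- theta_deg * pi / 180
  d <- dim(cube)
  centre <- (d + 1) / 2
  g1 <- seq_len(d[1]) - centre[1]
  g2 <- seq_len(d[2]) - centre[2]
  g3 <- seq_len(d[3]) - centre[3]
  pts <- cbind(
    rep(g1, times = d[2] * d[3]),
    rep(rep(g2, each = d[1]), times = d[3]),
    rep(g3, each = d[1] * d[2])
  )
  # inverse rotation of the sampling grid about the chosen axis
  ax <- setdiff(seq_len(3), axis)
  u <- pts[, ax[1]]; v <- pts[, ax[2]]
  pts[, ax[1]] <- cos(th) * u + sin(th) * v
  pts[, ax[2]] <- -sin(th) * u + cos(th) * v
  pts <- sweep(pts, 2, centre, "+")
  array(interp_trilinear(cube, pts, fill = 0), dim = d)
}

#' Augmented crop extraction
#'
#' Draws one augmentation realization: jitters the centroid uniformly within
#' +/- `jitter_max_mm` per axis, re-crops, then applies per-axis random flips,
#' a rotation of up to `max_rotation_deg` about a random coordinate axis,
#' additive Gaussian noise, and a log-gamma contrast adjustment.
#'
#' @param vol A 1 mm isotropic [ct_volume].
#' @param centroid_mm Nodule centroid (world mm).
#' @param policy An [augmentation_policy].
#' @param seed Optional seed making the draw reproducible.
#' @return A `nodule_crop`.
#' @export
augment_crop <- function(vol, centroid_mm, policy = augmentation_policy(),
                         seed = NULL) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (policy_is_identity(policy)) {
    return(crop_and_normalize(vol, centroid_mm))
  }
  with_seed(seed, {
    jit <- stats::runif(3, -policy$jitter_max_mm, policy$jitter_max_mm)
    crop <- crop_and_normalize(vol, centroid_mm + jit)
    cube <- crop$cube
    flips <- stats::runif(3) < policy$flip_prob
    if (flips[1]) cube <- cube[rev(seq_len(dim(cube)[1])), , , drop = FALSE]
    if (flips[2]) cube <- cube[, rev(seq_len(dim(cube)[2])), , drop = FALSE]
    if (flips[3]) cube <- cube[, , rev(seq_len(dim(cube)[3])), drop = FALSE]
    if (policy$max_rotation_deg > 0) {
      axis <- sample.int(3, 1)
      theta <- stats::runif(1, -policy$max_rotation_deg,
                            policy$max_rotation_deg)
      cube <- rotate_crop(cube, axis, theta)
    }
    if (policy$noise_sd > 0 || policy$noise_mean != 0) {
      cube <- cube + stats::rnorm(length(cube), policy$noise_mean,
                                  policy$noise_sd)
    }
    if (any(policy$log_gamma_range != 0)) {
      u <- stats::runif(1, policy$log_gamma_range[1],
                        policy$log_gamma_range[2])
      cube <- pmin(pmax(cube, 0), 1)^exp(u)
    }
    crop$cube <- array(pmin(pmax(cube, 0), 1), dim = dim(cube))
    crop$provenance$augmented <- TRUE
    crop
  })
}
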