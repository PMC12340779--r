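# View-space realization of the volumetric training augmentation.
#
# The nine section planes are the symmetry planes of the crop cube, so
# flipping the cube about any axis maps the view set onto itself: each
# flipped-cube view equals one of the original views under a dihedral
# (rotate/flip/transpose) in-plane transform. The mapping is computed once,
# numerically, from a probe crop and cached; training then applies exact
# volumetric flips to precomputed view stacks without touching the volume.
# Additive Gaussian noise and the log-gamma contrast adjustment act on
# intensities and are applied to the views directly.

.noduleclip_cache <- new.env(parent = emptyenv())

d4_ops <- c("id", "rot90", "rot180", "rot270", "t", "fliph", "flipv", "anti")

d4_transform <- function(M, op) {
  switch(op,
    id = M,
    rot90 = t(M[nrow(M):1, , drop = FALSE]),
    rot180 = M[nrow(M):1, ncol(M):1, drop = FALSE],
    rot270 = t(M)[nrow(M):1, , drop = FALSE],
    t = t(M),
    fliph = M[, ncol(M):1, drop = FALSE],
    flipv = M[nrow(M):1, , drop = FALSE],
    anti = t(M[nrow(M):1, ncol(M):1, drop = FALSE]),
    stop("unknown dihedral op")
  )
}

flip_cube <- function(cube, fx, fy, fz) {
  if (fx) cube <- cube[rev(seq_len(dim(cube)[1])), , , drop = FALSE]
  if (fy) cube <- cube[, rev(seq_len(dim(cube)[2])), , drop = FALSE]
  if (fz) cube <- cube[, , rev(seq_len(dim(cube)[3])), drop = FALSE]
  cube
}

# flip index 1..8 encodes (fx, fy, fz); entry k gives (view = j, op) such
# that views(flip(cube))[k] == d4(views(cube)[j], op)
view_flip_map <- function() {
  if (!is.null(.noduleclip_cache$flip_map)) return(.noduleclip_cache$flip_map)
  probe <- with_seed(20240101L, {
    array(stats::runif(CROP_SIZE^3), dim = rep(CROP_SIZE, 3L))
  })
  # smooth it slightly so interpolation is well-behaved but generic
  base <- extract_nine_views(structure(list(cube = probe),
                                       class = "nodule_crop"))$planes
  maps <- vector("list", 8L)
  for (f in seq_len(8L)) {
    bits <- as.logical(bitwAnd(f - 1L, c(1L, 2L, 4L)))
    fl <- extract_nine_views(structure(
      list(cube = flip_cube(probe, bits[1], bits[2], bits[3])),
      class = "nodule_crop"))$planes
    entry <- matrix(NA_integer_, 9L, 2L, dimnames = list(NULL, c("view", "op")))
    for (k in seq_len(9L)) {
      for (j in seq_len(9L)) {
        done <- FALSE
        for (o in seq_along(d4_ops)) {
          if (max(abs(d4_transform(base[, , j], d4_ops[o]) - fl[, , k])) <
              1e-8) {
            entry[k, ] <- c(j, o)
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    if (anyNA(entry)) stop("internal error: view flip map incomplete")
    maps[[f]] <- entry
  }
  .noduleclip_cache$flip_map <- maps
  maps
}

# permutation vectors realizing each dihedral op on a flattened s x s image
d4_pixel_perms <- function(s) {
  key <- paste0("d4perm_", s)
  if (!is.null(.noduleclip_cache[[key]])) return(.noduleclip_cache[[key]])
  ref <- matrix(seq_len(s * s), s, s)
  perms <- lapply(d4_ops, function(op) as.vector(d4_transform(ref, op)))
  names(perms) <- d4_ops
  .noduleclip_cache[[key]] <- perms
  perms
}

# Apply the volumetric-flip part of the augmentation to one nodule's view
# matrix (9 x s^2): view permutation + in-plane dihedral ops.
flip_view_matrix <- function(views, flip_prob = 0.5) {
  if (flip_prob <= 0) return(views)
  bits <- stats::runif(3) < flip_prob
  f <- 1L + sum(c(1L, 2L, 4L)[bits])
  if (f == 1L) return(views)
  s <- as.integer(sqrt(ncol(views)))
  map <- view_flip_map()[[f]]
  perms <- d4_pixel_perms(s)
  out <- views
  for (k in seq_len(9L)) {
    out[k, ] <- views[map[k, "view"], perms[[map[k, "op"]]]]
  }
  out
}

# Augment one nodule's precomputed view matrix (9 x s^2): volumetric flips
# realized as view permutation + in-plane dihedral ops, then additive
# Gaussian noise and a log-gamma contrast adjustment, re-clipped to [0, 1].
augment_view_matrix <- function(views, flip_prob = 0.5, noise_sd = 0.02,
                                log_gamma_range = c(-0.02, 0.02)) {
  views <- flip_view_matrix(views, flip_prob)
  if (noise_sd > 0) {
    views <- views + stats::rnorm(length(views), 0, noise_sd)
  }
  if (any(log_gamma_range != 0)) {
    u <- stats::runif(1, log_gamma_range[1], log_gamma_range[2])
    views <- pmin(pmax(views, 0), 1)^exp(u)
    return(views)
  }
  pmin(pmax(views, 0), 1)
}

# Batched augmentation of a stacked (B*9 x s^2) view matrix: per-nodule
# flips and gamma draws, one noise and clamp pass for the whole batch.
# Draw order (per entry: flips then gamma; then batch noise) is fixed so
# runs are reproducible under the step seed.
augment_view_batch <- function(Vmat, n_entries, flip_prob = 0.5,
                               noise_sd = 0.02,
                               log_gamma_range = c(-0.02, 0.02)) {
  for (i in seq_len(n_entries)) {
    rows <- (i - 1L) * 9L + 1:9
    Vmat[rows, ] <- flip_view_matrix(Vmat[rows, , drop = FALSE], flip_prob)
  }
  gam <- if (any(log_gamma_range != 0)) {
    exp(stats::runif(n_entries, log_gamma_range[1], log_gamma_range[2]))
  } else {
    rep(1, n_entries)
  }
  if (noise_sd > 0) {
    Vmat <- Vmat + stats::rnorm(length(Vmat), 0, noise_sd)
  }
  Vmat <- pmin(pmax(Vmat, 0), 1)
  if (any(gam != 1)) Vmat <- Vmat^rep(gam, each = 9L)
  Vmat
}
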