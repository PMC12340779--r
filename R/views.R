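# Nine-plane 2.5D view extraction.
#
# The nine section planes are the symmetry planes of the crop cube: three
# axis-aligned and six diagonal, all passing through the cube centre. Each is
# sampled on a 50 x 50 grid of 1 mm steps along two orthonormal in-plane unit
# vectors, so diagonal views keep the same physical scale (their corners fall
# outside the cube and take the padding value 0).

#' The nine section-plane frames
#'
#' Returns, for each of the nine planes, an orthonormal frame: the plane
#' normal and two in-plane unit vectors. The first in-plane axis is the
#' normalized projection of the lowest-index world axis not parallel to the
#' normal; the second completes a right-handed frame.
#'
#' @return List of 9 lists with elements `normal`, `e1`, `e2`.
#' @export
nine_plane_frames <- function() {
  normals <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1)
  )
  axes <- diag(3)
  lapply(seq_len(nrow(normals)), function(i) {
    n <- normals[i, ] / sqrt(sum(normals[i, ]^2))
    for (a in seq_len(3)) {
      ax <- axes[a, ]
      proj <- ax - sum(ax * n) * n
      if (sqrt(sum(proj^2)) > 1e-8) break
    }
    e1 <- proj / sqrt(sum(proj^2))
    e2 <- c(
      n[2] * e1[3] - n[3] * e1[2],
      n[3] * e1[1] - n[1] * e1[3],
      n[1] * e1[2] - n[2] * e1[1]
    )
    list(normal = n, e1 = e1, e2 = e2)
  })
}

#' Extract the nine planar views of a nodule crop
#'
#' Samples each of the [nine_plane_frames] planes through the cube centre on a
#' 50 x 50 grid at 1 mm spacing (trilinear interpolation; samples outside the
#' cube take 0, the normalized-air padding value).
#'
#' @param crop A `nodule_crop` from [crop_and_normalize].
#' @return List with `planes` (array 50 x 50 x 9) and `frames`.
#' @export
extract_nine_views <- function(crop) {
  stopifnot(inherits(crop, "nodule_crop"))
  cube <- crop$cube
  stopifnot(all(dim(cube) == CROP_SIZE))
  centre <- (CROP_SIZE + 1) / 2  # continuous cube centre, 1-based
  offs <- seq_len(CROP_SIZE) - centre  # -24.5 .. 24.5, symmetric
  frames <- nine_plane_frames()
  planes <- array(0, dim = c(CROP_SIZE, CROP_SIZE, 9L))
  uu <- rep(offs, times = CROP_SIZE)
  vv <- rep(offs, each = CROP_SIZE)
  for (k in seq_len(9L)) {
    f <- frames[[k]]
    pts <- cbind(
      centre + uu * f$e1[1] + vv * f$e2[1],
      centre + uu * f$e1[2] + vv * f$e2[2],
      centre + uu * f$e1[3] + vv * f$e2[3]
    )
    planes[, , k] <- interp_trilinear(cube, pts, fill = 0)
  }
  list(planes = planes, frames = frames)
}

# Per-channel standardization constants of the pretrained image-text model
# family's preprocessing; overridable via options(noduleclip.clip_mean/sd).
clip_channel_stats <- function() {
  list(
    mean = getOption("noduleclip.clip_mean",
                     c(0.48145466, 0.4578275, 0.40821073)),
    sd = getOption("noduleclip.clip_sd",
                   c(0.26862954, 0.26130258, 0.27577711))
  )
}

# Bilinear resize with the half-pixel-centre (align-corners-false) mapping;
# an identity when input and output sizes match.
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  sy <- h / out_h; sx <- w / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy + 0.5, 1), h)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx + 0.5, 1), w)
  y0 <- pmin(pmax(floor(yc), 1), h - 1L); y1 <- y0 + 1
  x0 <- pmin(pmax(floor(xc), 1), w - 1L); x1 <- x0 + 1
  fy <- yc - y0; fx <- xc - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y1, x0, drop = FALSE]
  c_ <- img[y0, x1, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + c_ * (1 - wy) * wx + d * wy * wx
}

#' Build the standardized nine-view stack
#'
#' Resizes each 50 x 50 plane to 224 x 224 (bilinear), replicates it to three
#' identical channels, and standardizes each channel with the fixed
#' preprocessing constants of the pretrained encoder family.
#'
#' @param views Output of [extract_nine_views] (or a 50x50x9 array).
#' @param size Output spatial size (default 224).
#' @return Object of class `view_stack`: list with `views`
#'   (size x size x 3 x 9 array) and `frames`.
#' @export
to_view_stack <- function(views, size = 224L) {
  planes <- if (is.list(views)) views$planes else views
  frames <- if (is.list(views)) views$frames else nine_plane_frames()
  if (length(dim(planes)) != 3L || dim(planes)[3] != 9L) {
    stop("expected 9 planes")
  }
  stats <- clip_channel_stats()
  out <- array(0, dim = c(size, size, 3L, 9L))
  for (k in seq_len(9L)) {
    r <- resize_bilinear(planes[, , k], size, size)
    for (ch in seq_len(3L)) {
      out[, , ch, k] <- (r - stats$mean[ch]) / stats$sd[ch]
    }
  }
  structure(list(views = out, frames = frames, size = size),
            class = "view_stack")
}

#' Preprocess one nodule end to end
#'
#' Convenience wrapper: resample to 1 mm, crop and normalize around the
#' centroid, extract nine views, and build the standardized stack.
#'
#' @param vol A [ct_volume].
#' @param centroid_mm Nodule centroid in world mm.
#' @param augment Optional [augmentation_policy]; `NULL` for the
#'   deterministic path.
#' @param seed Seed for the augmentation draw (ignored when `augment` is NULL).
#' @export
preprocess_nodule <- function(vol, centroid_mm, augment = NULL, seed = NULL) {
  vol1 <- resample_isotropic(vol, 1)
  crop <- if (is.null(augment)) {
    crop_and_normalize(vol1, centroid_mm)
  } else {
    augment_crop(vol1, centroid_mm, augment, seed = seed)
  }
  to_view_stack(extract_nine_views(crop))
}
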