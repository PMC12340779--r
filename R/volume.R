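#' CT volume container
#'
#' A 3D grid of Hounsfield Unit values with physical geometry. World
#' coordinates follow `world = origin + index * spacing` with 0-based voxel
#' indices (R arrays are addressed 1-based internally; the convention tag
#' records the mapping).
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing mm per axis, length-3, strictly positive.
#' @param origin world coordinate (mm) of voxel (0,0,0), length-3.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive finite values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be 3 finite values")
  }
  if (any(!is.finite(voxels))) stop("voxel values must all be finite")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         axis_order = "xyz0"),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("ct_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm, HU range", paste(signif(range(x$voxels), 4), collapse = ".."), "\n")
  invisible(x)
}

# world (mm) -> continuous 1-based voxel index
world_to_index <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

index_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# Trilinear interpolation of a 3D array at continuous 1-based indices.
# Points outside the grid take `fill`. Vectorized over rows of `pts`.
interp_trilinear <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, n)
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1L); x0[d[1] == 1L] <- 1L
  y0 <- pmin(pmax(floor(y), 1), max(d[2] - 1L, 1L))
  z0 <- pmin(pmax(floor(z), 1), max(d[3] - 1L, 1L))
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
  out[inside] <- v
  out
}

#' Resample a CT volume to isotropic spacing
#'
#' Trilinear resampling onto a grid with the requested spacing on every axis.
#' The new grid shares the volume's origin, so world coordinates of landmarks
#' are preserved; the physical extent is preserved to within one voxel.
#'
#' @param vol A [ct_volume].
#' @param target_spacing_mm Target spacing (mm), applied to all axes.
#' @param fill HU value for samples outside the source grid.
#' @return A [ct_volume] at isotropic spacing.
#' @export
resample_isotropic <- function(vol, target_spacing_mm = 1, fill = -1000) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_spacing_mm) || target_spacing_mm <= 0) {
    stop("target_spacing_mm must be positive")
  }
  if (all(abs(vol$spacing - target_spacing_mm) < 1e-9)) return(vol)
  d <- dim(vol$voxels)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(1L, as.integer(floor(extent / target_spacing_mm + 1e-9)) + 1L)
  g1 <- (seq_len(nd[1]) - 1) * target_spacing_mm / vol$spacing[1] + 1
  g2 <- (seq_len(nd[2]) - 1) * target_spacing_mm / vol$spacing[2] + 1
  g3 <- (seq_len(nd[3]) - 1) * target_spacing_mm / vol$spacing[3] + 1
  pts <- cbind(
    rep(g1, times = nd[2] * nd[3]),
    rep(rep(g2, each = nd[1]), times = nd[3]),
    rep(g3, each = nd[1] * nd[2])
  )
  vals <- interp_trilinear(vol$voxels, pts, fill = fill)
  ct_volume(array(vals, dim = nd), spacing = rep(target_spacing_mm, 3),
            origin = vol$origin)
}

#' Map HU to the unit interval used by the encoders
#'
#' Clips HU to \[-1000, 500\] and rescales linearly to \[0, 1\]:
#' `x -> (clip(x, -1000, 500) + 1000) / 1500`.
#'
#' @param hu Numeric HU values.
#' @export
normalize_hu <- function(hu) {
  (pmin(pmax(hu, -1000), 500) + 1000) / 1500
}

CROP_SIZE <- 50L

#' Crop a 50 mm cube around a nodule and normalize intensities
#'
#' Extracts a 50x50x50 voxel cube at 1 mm isotropic spacing centred on the
#' voxel nearest the supplied world-coordinate centroid. Samples outside the
#' volume are filled with -1000 HU (air) before windowing, so padding maps to
#' exactly 0 after [normalize_hu].
#'
#' @param vol A [ct_volume] at 1 mm isotropic spacing.
#' @param centroid_mm World coordinates (mm) of the nodule centroid.
#' @return An object of class `nodule_crop`: list with `cube` (50^3 array in
#'   \[0,1\]) and `provenance`.
#' @export
crop_and_normalize <- function(vol, centroid_mm) {
  stopifnot(inherits(vol, "ct_volume"))
  if (any(abs(vol$spacing - 1) > 1e-6)) {
    stop("crop_and_normalize expects a 1 mm isotropic volume; resample first")
  }
  d <- dim(vol$voxels)
  extent_lo <- vol$origin
  extent_hi <- vol$origin + (d - 1) * vol$spacing
  if (any(centroid_mm < extent_lo - 25) || any(centroid_mm > extent_hi + 25)) {
    stop("centroid lies more than 25 mm outside the volume extent; ",
         "the crop would contain no data")
  }
  centre_idx <- round(world_to_index(vol, centroid_mm))[1, ]
  # cube indices: centre voxel sits at crop position 25 of 1..50
  offs <- seq_len(CROP_SIZE) - 25L
  cube <- array(0, dim = rep(CROP_SIZE, 3L))
  i1 <- centre_idx[1] + offs; i2 <- centre_idx[2] + offs; i3 <- centre_idx[3] + offs
  ok1 <- i1 >= 1 & i1 <= d[1]; ok2 <- i2 >= 1 & i2 <= d[2]; ok3 <- i3 >= 1 & i3 <= d[3]
  hu <- array(-1000, dim = rep(CROP_SIZE, 3L))
  if (any(ok1) && any(ok2) && any(ok3)) {
    hu[which(ok1), which(ok2), which(ok3)] <-
      vol$voxels[i1[ok1], i2[ok2], i3[ok3], drop = FALSE]
  }
  cube[] <- normalize_hu(hu)
  structure(
    list(cube = cube,
         provenance = list(centroid_mm = as.numeric(centroid_mm),
                           centre_index0 = centre_idx - 1)),
    class = "nodule_crop"
  )
}

#' Read a NIfTI volume as a [ct_volume]
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  spacing <- as.numeric(RNifti::pixdim(img)[seq_len(3)])
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[seq_len(3), 4])
  # this package writes RAS volumes with a diagonal xform; only support those
  rot <- xf[seq_len(3), seq_len(3)]
  if (max(abs(rot - diag(spacing))) > 1e-4 * max(spacing)) {
    stop("only axis-aligned (diagonal xform) NIfTI volumes are supported")
  }
  ct_volume(vox, spacing = spacing, origin = origin)
}

#' Write a [ct_volume] to NIfTI
#'
#' @param vol A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_ct_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  xf <- diag(4)
  diag(xf)[seq_len(3)] <- vol$spacing
  xf[seq_len(3), 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
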