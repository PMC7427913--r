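#' CT volume with world coordinate mapping
#'
#' Container for a 3D grid of Hounsfield-unit (HU) values together with its
#' voxel-to-world mapping.  Voxel index `(i, j, k)` (0-based) has world
#' position `origin + orientation %*% (c(i, j, k) * spacing)` (mm), i.e. the
#' origin is the world position of the *center* of the first voxel and the
#' interpolation domain is the convex hull of voxel centers.
#'
#' @param data 3D numeric array of HU values (finite).
#' @param spacing length-3 positive numeric, voxel size per axis in mm.
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0) center.
#' @param orientation 3x3 direction matrix with orthonormal columns (world
#'   axes per voxel axis).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0),
                      orientation = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("`data` must have at least 2 voxels along every axis")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite HU values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector (mm)")
  if (!identical(dim(orientation), c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-9)
    stop("`orientation` must be a 3x3 matrix with orthonormal columns")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  HU range [%g, %g], origin (%s) mm\n",
              min(x$data), max(x$data),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z in mm)")
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates (mm)")
    matrix(p, nrow = 1L)
  }
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel coordinates are 0-based and continuous: the first voxel center is at
#' voxel coordinate `(0, 0, 0)`, the last at `dim(data) - 1`.  The two
#' transforms are exact mutual inverses.
#'
#' @param vol A [ct_volume()].
#' @param p A length-3 point or an N x 3 matrix of points.
#' @return An N x 3 matrix of transformed coordinates.
#' @export
world_to_voxel <- function(vol, p) {
  p <- as_point_matrix(p)
  v <- sweep(p, 2L, vol$origin) %*% vol$orientation
  sweep(v, 2L, vol$spacing, "/")
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, p) {
  p <- as_point_matrix(p)
  w <- sweep(p, 2L, vol$spacing, "*") %*% t(vol$orientation)
  sweep(w, 2L, vol$origin, "+")
}

in_sampling_domain <- function(vol, p, tol = 1e-9) {
  v <- world_to_voxel(vol, p)
  dm <- dim(vol$data)
  (v[, 1L] >= -tol & v[, 1L] <= dm[1L] - 1 + tol &
   v[, 2L] >= -tol & v[, 2L] <= dm[2L] - 1 + tol &
   v[, 3L] >= -tol & v[, 3L] <= dm[3L] - 1 + tol)
}

#' Trilinear sampling of a CT volume
#'
#' Samples HU values at arbitrary world points by trilinear interpolation of
#' the 8 surrounding voxel values in voxel space.  `sample_trilinear()` is the
#' strict sampler and signals an error for points outside the sampling domain
#' (hull of voxel centers); `sample_hu()` is the marching-friendly wrapper that
#' substitutes `outside_value` (water, 0 HU, by default) for such points, since
#' rays legitimately start outside the scanned block.
#'
#' @inheritParams world_to_voxel
#' @param outside_value HU value substituted for out-of-domain points by
#'   `sample_hu()`.
#' @return Numeric vector of interpolated HU values, one per point.
#' @export
sample_trilinear <- function(vol, p) {
  p <- as_point_matrix(p)
  inside <- in_sampling_domain(vol, p)
  if (!all(inside))
    stop(sprintf("%d point(s) outside volume sampling domain",
                 sum(!inside)))
  trilinear_core(vol, p)
}

#' @rdname sample_trilinear
#' @export
sample_hu <- function(vol, p, outside_value = 0) {
  p <- as_point_matrix(p)
  inside <- in_sampling_domain(vol, p)
  out <- rep_len(as.numeric(outside_value), nrow(p))
  if (any(inside))
    out[inside] <- trilinear_core(vol, p[inside, , drop = FALSE])
  out
}

trilinear_core <- function(vol, p) {
  v <- world_to_voxel(vol, p)
  dm <- dim(vol$data)
  # lower corner, clamped so points on the upper face use the last cell
  i0 <- pmax(pmin(floor(v[, 1L]), dm[1L] - 2), 0)
  j0 <- pmax(pmin(floor(v[, 2L]), dm[2L] - 2), 0)
  k0 <- pmax(pmin(floor(v[, 3L]), dm[3L] - 2), 0)
  fx <- v[, 1L] - i0
  fy <- v[, 2L] - j0
  fz <- v[, 3L] - k0
  nx <- dm[1L]; nxy <- dm[1L] * dm[2L]
  base <- 1 + i0 + j0 * nx + k0 * nxy
  d <- vol$data
  c000 <- d[base];             c100 <- d[base + 1]
  c010 <- d[base + nx];        c110 <- d[base + nx + 1]
  c001 <- d[base + nxy];       c101 <- d[base + nxy + 1]
  c011 <- d[base + nxy + nx];  c111 <- d[base + nxy + nx + 1]
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
  (c010 * (1 - fx) + c110 * fx) * fy       * (1 - fz) +
  (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
  (c011 * (1 - fx) + c111 * fx) * fy       * fz
}

#' Hounsfield-unit to sound-speed mapping
#'
#' Linear two-point map from CT attenuation to longitudinal sound speed:
#' water (`hu_water`, default 0 HU) maps to `c_water` and dense cortical bone
#' (`hu_bone` and above, default 1000 HU) maps to `c_bone_max`, with values
#' clamped to `[c_water, c_bone_max]`.  Defaults use the conventional fixed
#' speeds 1480 m/s (water) and 2900 m/s (skull bone).
#'
#' @param c_water Sound speed in water, m/s.
#' @param c_bone_max Sound speed of dense cortical bone, m/s.
#' @param hu_water HU value mapped to `c_water`.
#' @param hu_bone HU value at (and above) which speed is `c_bone_max`.
#' @return An object of class `speed_map`.
#' @export
speed_map <- function(c_water = 1480, c_bone_max = 2900,
                      hu_water = 0, hu_bone = 1000) {
  if (!(c_bone_max > c_water && c_water > 0))
    stop("require c_bone_max > c_water > 0")
  if (!(hu_bone > hu_water))
    stop("require hu_bone > hu_water")
  structure(list(c_water = c_water, c_bone_max = c_bone_max,
                 hu_water = hu_water, hu_bone = hu_bone),
            class = "speed_map")
}

#' @rdname speed_map
#' @param m A [speed_map()].
#' @param hu Numeric vector of HU values (finite).
#' @export
hu_to_speed <- function(m, hu) {
  stopifnot(inherits(m, "speed_map"))
  if (any(!is.finite(hu))) stop("non-finite HU value")
  f <- (hu - m$hu_water) / (m$hu_bone - m$hu_water)
  f <- pmin(pmax(f, 0), 1)
  m$c_water + (m$c_bone_max - m$c_water) * f
}

#' Read and write CT volumes as NIfTI-1
#'
#' `write_nifti()` stores the volume's affine (orientation, spacing, origin)
#' in the sform; `read_nifti()` reconstructs a [ct_volume()] from the file's
#' xform.  Round-trip write/read reproduces the data exactly and the
#' geometry to the single-precision accuracy of the NIfTI-1 header, for
#' volumes with orthonormal orientation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol A [ct_volume()].
#' @return `read_nifti()` returns a [ct_volume()]; `write_nifti()` returns
#'   `path` invisibly.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop(sprintf("non-3D image (%dD) in '%s'", length(dm), path))
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A <- unclass(aff)[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0))
    stop(sprintf("degenerate affine in '%s'", path))
  orientation <- sweep(A, 2L, spacing, "/")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop(sprintf("non-orthonormal affine in '%s' (shear not supported)", path))
  ct_volume(array(as.numeric(img), dim = dm), spacing,
            origin = unclass(aff)[1:3, 4], orientation = orientation)
}

#' @rdname read_nifti
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  aff <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
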