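#' Synthetic hemispherical phased-array transducer
#'
#' Distributes `n` elements over a spherical cap of half-angle
#' `cap_half_angle` (degrees) on a sphere of radius `radius` (mm) centered at
#' `focus`, using a Fibonacci-spiral layout so element density is uniform over
#' the cap.  The geometric focus of the array is the sphere center.  The
#' layout is deterministic; `seed` selects a reproducible azimuthal rotation
#' of the spiral.
#'
#' The default geometry emulates a clinical 1024-element, 150 mm radius
#' hemispherical brain transducer driven at 650 kHz.
#'
#' @param n Number of elements (>= 1).
#' @param radius Sphere radius, mm (> 0).
#' @param cap_half_angle Cap half-angle in degrees, in (0, 90].
#' @param f0 Driving frequency, Hz.
#' @param focus Geometric focus (sphere center), world mm.
#' @param axis Unit vector from the focus toward the cap pole (the array
#'   sits on this side of the focus).
#' @param seed Integer; rotates the spiral azimuth deterministically.
#' @return An object of class `transducer_array` with fields `elements`
#'   (n x 3 matrix, mm), `n_elements`, `f0`, `geometric_focus`, `active`.
#' @export
make_hemisphere_array <- function(n = 1024L, radius = 150,
                                  cap_half_angle = 90, f0 = 650e3,
                                  focus = c(0, 0, 0), axis = c(0, 0, -1),
                                  seed = 0L) {
  if (n < 1L) stop("`n` must be >= 1")
  if (radius <= 0) stop("`radius` must be > 0")
  if (cap_half_angle <= 0 || cap_half_angle > 90)
    stop("`cap_half_angle` must be in (0, 90] degrees")
  if (f0 <= 0) stop("`f0` must be > 0")
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal basis perpendicular to the cap axis
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  cap_rad <- cap_half_angle * pi / 180
  if (n == 1L) {
    cos_t <- 1
    phi <- 0
  } else {
    i <- seq_len(n) - 1L
    cos_t <- 1 - (1 - cos(cap_rad)) * (i + 0.5) / n
    golden <- pi * (3 - sqrt(5))
    phi <- i * golden + (as.integer(seed) %% 360L) * pi / 180
  }
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  pts <- focus[1L] + radius * (sin_t * cos(phi) * e1[1L] +
                               sin_t * sin(phi) * e2[1L] + cos_t * axis[1L])
  pts <- cbind(pts,
               focus[2L] + radius * (sin_t * cos(phi) * e1[2L] +
                                     sin_t * sin(phi) * e2[2L] +
                                     cos_t * axis[2L]),
               focus[3L] + radius * (sin_t * cos(phi) * e1[3L] +
                                     sin_t * sin(phi) * e2[3L] +
                                     cos_t * axis[3L]))
  colnames(pts) <- c("x_mm", "y_mm", "z_mm")
  transducer_array(pts, f0 = f0, geometric_focus = focus)
}

#' Transducer array constructor
#'
#' @param elements n x 3 matrix of element center world positions, mm.
#' @param f0 Driving frequency, Hz.
#' @param geometric_focus World point, mm.
#' @param active Logical vector of per-element on/off flags.
#' @return An object of class `transducer_array`.
#' @export
transducer_array <- function(elements, f0 = 650e3,
                             geometric_focus = c(0, 0, 0),
                             active = rep(TRUE, nrow(elements))) {
  elements <- as_point_matrix(elements)
  if (any(!is.finite(elements))) stop("element positions must be finite")
  if (f0 <= 0) stop("`f0` must be > 0")
  if (length(active) != nrow(elements))
    stop("`active` must have one flag per element")
  structure(list(elements = elements, n_elements = nrow(elements),
                 f0 = f0, geometric_focus = as.numeric(geometric_focus),
                 active = as.logical(active)),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf("<transducer_array> %d elements (%d active), f0 = %g kHz\n",
              x$n_elements, sum(x$active), x$f0 / 1e3))
  invisible(x)
}

#' Read/write transducer element coordinates as CSV
#'
#' CSV columns: `id`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param array A [transducer_array()].
#' @param path CSV file path.
#' @inheritParams transducer_array
#' @export
write_elements_csv <- function(array, path) {
  utils::write.csv(data.frame(id = seq_len(array$n_elements) - 1L,
                              x_mm = array$elements[, 1L],
                              y_mm = array$elements[, 2L],
                              z_mm = array$elements[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_elements_csv
#' @export
read_elements_csv <- function(path, f0 = 650e3,
                              geometric_focus = c(0, 0, 0)) {
  df <- utils::read.csv(path)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("element CSV must have columns id, x_mm, y_mm, z_mm")
  df <- df[order(df$id), , drop = FALSE]
  transducer_array(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                   f0 = f0, geometric_focus = geometric_focus)
}

#' Fiducial point set
#'
#' @param points K x 3 matrix of world positions, mm.
#' @param labels Character identifiers (default `fid1..fidK`).
#' @param min_separation_mm Minimum allowed pairwise distance.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL, min_separation_mm = 1) {
  points <- as_point_matrix(points)
  if (any(!is.finite(points))) stop("fiducial positions must be finite")
  if (is.null(labels)) labels <- paste0("fid", seq_len(nrow(points)))
  if (length(labels) != nrow(points))
    stop("one label per fiducial required")
  if (nrow(points) >= 2L) {
    dmin <- min(stats::dist(points))
    if (dmin < min_separation_mm)
      stop(sprintf("fiducials closer than %g mm (min distance %.3g mm)",
                   min_separation_mm, dmin))
  }
  structure(list(points = points, labels = as.character(labels)),
            class = "fiducial_set")
}

#' Detect spherical fiducial markers in a CT volume
#'
#' Binarizes the volume at `hu_threshold` (chosen above bone HU so only the
#' metallic markers survive), labels 26-connected components, applies a
#' granulometric size filter keeping components whose equivalent spherical
#' diameter lies within `tol_frac` of the nominal marker `diameter_mm`, and
#' returns the intensity-weighted centroid of each surviving component in
#' world mm.  Components are ordered lexicographically by centroid for
#' deterministic labeling.
#'
#' @param vol A [ct_volume()].
#' @param hu_threshold Binarization threshold, HU (default 2500, above
#'   cortical bone).
#' @param diameter_mm Nominal marker diameter, mm (default 2).
#' @param tol_frac Half-width of the accepted equivalent-diameter band as a
#'   fraction of `diameter_mm` (default 0.5).
#' @return A [fiducial_set()] of detected centroids.
#' @export
detect_fiducials <- function(vol, hu_threshold = 2500, diameter_mm = 2,
                             tol_frac = 0.5) {
  stopifnot(inherits(vol, "ct_volume"))
  dm <- dim(vol$data)
  lin <- which(vol$data >= hu_threshold)
  if (length(lin) == 0L) stop("no fiducials found")
  idx <- arrayInd(lin, dm)
  m <- nrow(idx)
  # 26-connectivity graph over foreground voxels (13 forward offsets)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1L] > 0 |
               (offs[, 1L] == 0 & offs[, 2L] > 0) |
               (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0), ,
               drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- idx + matrix(offs[o, ], m, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    nb_lin <- (nb[ok, 3L] - 1L) * dm[1L] * dm[2L] +
              (nb[ok, 2L] - 1L) * dm[1L] + nb[ok, 1L]
    hit <- match(nb_lin, lin)
    src <- which(ok)[!is.na(hit)]
    edges[[o]] <- cbind(src, hit[!is.na(hit)])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(m)]
  vox_vol <- prod(vol$spacing)
  centers <- list()
  for (cid in unique(comp)) {
    sel <- comp == cid
    d_eq <- 2 * (3 * sum(sel) * vox_vol / (4 * pi))^(1 / 3)
    if (abs(d_eq - diameter_mm) > tol_frac * diameter_mm) next
    w <- vol$data[lin[sel]]
    wpts <- voxel_to_world(vol, idx[sel, , drop = FALSE] - 1)
    centers[[length(centers) + 1L]] <- colSums(wpts * w) / sum(w)
  }
  if (length(centers) == 0L) stop("no fiducials found")
  centers <- do.call(rbind, centers)
  ord <- order(round(centers[, 3L], 6), round(centers[, 2L], 6),
               round(centers[, 1L], 6))
  fiducial_set(centers[ord, , drop = FALSE])
}

#' Read/write fiducial coordinates as CSV
#'
#' CSV columns: `id`, `x_mm`, `y_mm`, `z_mm`; rows are ordered by `id`
#' (registration corresponds fiducials by index).
#'
#' @param fids A [fiducial_set()].
#' @param path CSV file path.
#' @export
write_fiducials_csv <- function(fids, path) {
  stopifnot(inherits(fids, "fiducial_set"))
  utils::write.csv(data.frame(id = fids$labels,
                              x_mm = fids$points[, 1L],
                              y_mm = fids$points[, 2L],
                              z_mm = fids$points[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials_csv
#' @export
read_fiducials_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns id, x_mm, y_mm, z_mm")
  df <- df[order(df$id), , drop = FALSE]
  fiducial_set(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
               labels = as.character(df$id))
}

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 proper rotation matrix (orthonormal, det +1).
#' @param T Length-3 translation, mm.
#' @param rms_mm Optional registration residual carried as metadata.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), T = c(0, 0, 0), rms_mm = NA_real_) {
  R <- as.matrix(R)
  T <- as.numeric(T)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("`R` must be a proper rotation (R'R = I, det = +1)")
  if (length(T) != 3L || any(!is.finite(T)))
    stop("`T` must be a finite length-3 vector")
  structure(list(R = R, T = T, rms_mm = rms_mm), class = "rigid_transform")
}

#' Rigid fiducial registration by SVD
#'
#' Least-squares rigid transform mapping `src` fiducials onto `dst`
#' (correspondence by index): minimizes \eqn{\sum_i \|R s_i + T - d_i\|^2}
#' via the centered cross-covariance SVD (orthogonal Procrustes / Kabsch)
#' with determinant correction, so the result is always a proper rotation
#' even when noise favors a reflection.
#'
#' @param src,dst [fiducial_set()]s with equal counts K >= 3, matched by
#'   index, not all collinear.
#' @return A [rigid_transform()]; its `rms_mm` field holds the root mean
#'   square residual of the fit.
#' @export
register_svd <- function(src, dst) {
  stopifnot(inherits(src, "fiducial_set"), inherits(dst, "fiducial_set"))
  P <- src$points
  Q <- dst$points
  if (nrow(P) != nrow(Q)) stop("fiducial counts differ")
  if (nrow(P) < 3L) stop("at least 3 fiducials required")
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2L, pbar)
  Qc <- sweep(Q, 2L, qbar)
  H <- crossprod(Pc, Qc)              # sum (src_i - s̄)(dst_i - d̄)'
  sv <- svd(H)
  sP <- svd(Pc)$d
  if (sP[2L] < 1e-9 * max(sP[1L], 1))
    stop("degenerate (collinear) fiducial configuration")
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  T <- qbar - as.numeric(R %*% pbar)
  res <- sweep(P %*% t(R), 2L, T, "+") - Q
  rigid_transform(R, T, rms_mm = sqrt(mean(rowSums(res^2))))
}

#' Apply or invert a rigid transform
#'
#' `apply_transform()` maps points `p` to `R p + T`; `invert_transform()`
#' returns the inverse motion.
#'
#' @param t A [rigid_transform()].
#' @param p A length-3 point or N x 3 matrix, mm.
#' @return Transformed points (same shape convention as [world_to_voxel()]).
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- as_point_matrix(p)
  sweep(p %*% t(t$R), 2L, t$T, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$R), -as.numeric(t(t$R) %*% t$T))
}

#' Serialize a rigid transform to/from JSON
#'
#' JSON layout: `{"R": [[...],[...],[...]], "T": [tx, ty, tz]}` (row-major).
#'
#' @param t A [rigid_transform()].
#' @param path JSON file path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(R = unname(t$R), T = t$T),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(obj$R, obj$T)
}
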