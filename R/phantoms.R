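#' Parametric synthetic skull phantom
#'
#' Describes an analytic phantom geometry that can be rendered to a voxel CT
#' volume with [voxelize()] and, for slab and concentric-shell geometries,
#' interrogated in continuous space with [analytic_path()].  Supported kinds:
#'
#' * `flat_slab` / `tilted_slab`: a bone slab bounded by parallel planes.
#'   The outer face passes through `slab_point` with unit outward normal
#'   tilted `tilt_deg` about the y axis from `(0, 0, -1)` (facing an array
#'   on the -z side).  `layers` may split the total `thickness` into
#'   cortical/cancellous/cortical thicknesses.
#' * `spherical_shell`: homogeneous cortical shell between `r_inner` and
#'   `r_outer` about `center`.
#' * `shell_with_cancellous`: concentric shell with four radii
#'   `r1 < r2 < r3 < r4` (cortical r1-r2, cancellous r2-r3, cortical r3-r4),
#'   giving the characteristic two-HU-peak radial profile.
#' * `fiducial_frame`: water plus small high-HU spheres at
#'   `fiducial_centers` (diameter `fiducial_diameter`), optionally with an
#'   oversized `extra_blob = list(center=, diameter=)` distractor.
#'
#' Default layer HU values place cortical bone (1200) above the usual bone
#' threshold of 700 HU and cancellous bone (300) below it.
#'
#' @param kind Phantom kind (see above).
#' @param spacing Isotropic voxel spacing, mm.
#' @param bbox_lo,bbox_hi World corners of the rendered block, mm
#'   (kind-specific defaults when `NULL`).
#' @param hu_cortical,hu_cancellous,hu_water,hu_fiducial Layer HU values.
#' @param slab_point,tilt_deg,thickness,layers Slab geometry.
#' @param center,r_inner,r_outer,radii Shell geometry.
#' @param fiducial_centers,fiducial_diameter,extra_blob Fiducial geometry.
#' @param edge_width_mm Width of the linear partial-volume ramp applied at
#'   every layer interface, emulating the finite point-spread function of a
#'   CT scanner (boundary voxels carry intermediate HU, as in real scans).
#'   The default 1.0 mm models a typical bone-kernel CT PSF independently of
#'   voxel size; `0` renders hard edges where each voxel takes the analytic
#'   layer HU of its center.  The default cortical HU of 1400 places the
#'   700 HU bone threshold at the edge half-maximum, so threshold crossings
#'   localize the true geometric interface.
#' @param noise_sd Standard deviation of optional additive Gaussian HU
#'   noise (0 disables).
#' @param seed Seed for the noise (deterministic volumes for a fixed seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("flat_slab", "tilted_slab",
                                  "spherical_shell", "shell_with_cancellous",
                                  "fiducial_frame"),
                         spacing = 0.5, bbox_lo = NULL, bbox_hi = NULL,
                         hu_cortical = 1400, hu_cancellous = 300,
                         hu_water = 0, hu_fiducial = 3000,
                         slab_point = c(0, 0, -35), tilt_deg = 0,
                         thickness = 6, layers = NULL,
                         center = c(0, 0, 0), r_inner = 70, r_outer = 76,
                         radii = c(70, 72, 75, 77),
                         fiducial_centers = NULL, fiducial_diameter = 2,
                         extra_blob = NULL, edge_width_mm = 1.0,
                         noise_sd = 0, seed = 0L) {
  kind <- match.arg(kind)
  if (spacing <= 0) stop("`spacing` must be > 0")
  if (kind %in% c("flat_slab", "tilted_slab")) {
    if (kind == "flat_slab") tilt_deg <- 0
    if (!is.null(layers)) {
      if (length(layers) != 3L || any(layers <= 0))
        stop("`layers` must be 3 positive thicknesses")
      thickness <- sum(layers)
    }
    if (thickness <= 0) stop("`thickness` must be > 0")
    if (is.null(bbox_lo)) bbox_lo <- c(-45, -45, slab_point[3L] - 10)
    if (is.null(bbox_hi))
      bbox_hi <- c(45, 45, slab_point[3L] + thickness + 10)
  } else if (kind == "spherical_shell") {
    if (!(r_outer > r_inner && r_inner > 0))
      stop("require r_outer > r_inner > 0")
    if (is.null(bbox_lo)) bbox_lo <- center - (r_outer + 8)
    if (is.null(bbox_hi)) bbox_hi <- center + (r_outer + 8)
  } else if (kind == "shell_with_cancellous") {
    if (length(radii) != 4L || any(diff(radii) <= 0) || radii[1L] <= 0)
      stop("`radii` must be 4 increasing positive values")
    if (is.null(bbox_lo)) bbox_lo <- center - (radii[4L] + 8)
    if (is.null(bbox_hi)) bbox_hi <- center + (radii[4L] + 8)
  } else {
    if (is.null(fiducial_centers))
      fiducial_centers <- default_fiducial_frame()
    fiducial_centers <- as_point_matrix(fiducial_centers)
    if (is.null(bbox_lo))
      bbox_lo <- apply(fiducial_centers, 2L, min) - 8
    if (is.null(bbox_hi))
      bbox_hi <- apply(fiducial_centers, 2L, max) + 8
  }
  structure(list(kind = kind, spacing = spacing,
                 bbox_lo = as.numeric(bbox_lo),
                 bbox_hi = as.numeric(bbox_hi),
                 hu_cortical = hu_cortical, hu_cancellous = hu_cancellous,
                 hu_water = hu_water, hu_fiducial = hu_fiducial,
                 slab_point = as.numeric(slab_point), tilt_deg = tilt_deg,
                 thickness = thickness, layers = layers,
                 center = as.numeric(center), r_inner = r_inner,
                 r_outer = r_outer, radii = radii,
                 fiducial_centers = fiducial_centers,
                 fiducial_diameter = fiducial_diameter,
                 extra_blob = extra_blob,
                 edge_width_mm = edge_width_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default fiducial frame layout
#'
#' Eight marker positions on two squares at different heights, emulating a
#' skull fixing frame with embedded 2 mm tantalum spheres.
#'
#' @return An 8 x 3 matrix of world positions, mm.
#' @export
default_fiducial_frame <- function() {
  a <- 30.2   # deliberately off the voxel lattice
  rbind(cbind(c(a, -a, -a, a), c(a, a, -a, -a), -25.3),
        cbind(c(a, -a, -a, a) * 0.8, c(a, a, -a, -a) * 0.8, -5.1))
}

slab_outward_normal <- function(spec) {
  t <- spec$tilt_deg * pi / 180
  c(sin(t), 0, -cos(t))
}

thinnest_layer <- function(spec) {
  switch(spec$kind,
         flat_slab = ,
         tilted_slab = if (is.null(spec$layers)) spec$thickness
                       else min(spec$layers),
         spherical_shell = spec$r_outer - spec$r_inner,
         shell_with_cancellous = min(diff(spec$radii)),
         fiducial_frame = spec$fiducial_diameter)
}

# Piecewise-constant layer profile with linear partial-volume ramps of
# width w at each interface: HU(x) = levels[1] + sum_i (levels[i+1] -
# levels[i]) * clamp((x - edges[i])/w + 1/2, 0, 1).  w = 0 gives hard steps
# (x >= edge).
profile_hu <- function(x, edges, levels, w) {
  out <- array(levels[1L], dim = dim(x))
  for (i in seq_along(edges)) {
    step <- if (w > 0) pmin(pmax((x - edges[i]) / w + 0.5, 0), 1)
            else as.numeric(x >= edges[i])
    out <- out + (levels[i + 1L] - levels[i]) * step
  }
  out
}

#' Render a phantom to a voxel CT volume
#'
#' Each voxel takes the analytic layer HU at its center, with a linear
#' partial-volume ramp of width `edge_width_mm` across every interface
#' (emulating the CT acquisition point-spread function; set it to 0 for
#' hard edges).  Optional seeded Gaussian HU noise is added afterwards.
#' The result is deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [ct_volume()].
#' @export
voxelize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$spacing > thinnest_layer(spec))
    stop(sprintf("undersampled layer: spacing %g mm exceeds thinnest layer %g mm",
                 spec$spacing, thinnest_layer(spec)))
  n <- floor((spec$bbox_hi - spec$bbox_lo) / spec$spacing) + 1L
  ax <- lapply(1:3, function(a)
    spec$bbox_lo[a] + (seq_len(n[a]) - 1L) * spec$spacing)
  w <- spec$edge_width_mm
  hu <- switch(
    spec$kind,
    flat_slab = ,
    tilted_slab = {
      m <- slab_outward_normal(spec)
      # depth below the outer face, positive into the bone
      d0 <- sum(spec$slab_point * m)
      depth <- (d0 - outer(outer(ax[[1L]] * m[1L], ax[[2L]] * m[2L], "+"),
                           ax[[3L]] * m[3L], "+"))
      if (is.null(spec$layers)) {
        profile_hu(depth, c(0, spec$thickness),
                   c(spec$hu_water, spec$hu_cortical, spec$hu_water), w)
      } else {
        b <- cumsum(c(0, spec$layers))
        profile_hu(depth, b,
                   c(spec$hu_water, spec$hu_cortical, spec$hu_cancellous,
                     spec$hu_cortical, spec$hu_water), w)
      }
    },
    spherical_shell = {
      r <- sqrt(outer(outer((ax[[1L]] - spec$center[1L])^2,
                            (ax[[2L]] - spec$center[2L])^2, "+"),
                      (ax[[3L]] - spec$center[3L])^2, "+"))
      profile_hu(r, c(spec$r_inner, spec$r_outer),
                 c(spec$hu_water, spec$hu_cortical, spec$hu_water), w)
    },
    shell_with_cancellous = {
      r <- sqrt(outer(outer((ax[[1L]] - spec$center[1L])^2,
                            (ax[[2L]] - spec$center[2L])^2, "+"),
                      (ax[[3L]] - spec$center[3L])^2, "+"))
      profile_hu(r, spec$radii,
                 c(spec$hu_water, spec$hu_cortical, spec$hu_cancellous,
                   spec$hu_cortical, spec$hu_water), w)
    },
    fiducial_frame = {
      v <- array(spec$hu_water, dim = n)
      put_sphere <- function(v, ctr, diam, val) {
        rad <- diam / 2
        win <- lapply(1:3, function(a)
          which(abs(ax[[a]] - ctr[a]) <= rad + spec$spacing + w))
        if (any(lengths(win) == 0L)) return(v)
        r <- sqrt(outer(outer((ax[[1L]][win[[1L]]] - ctr[1L])^2,
                              (ax[[2L]][win[[2L]]] - ctr[2L])^2, "+"),
                        (ax[[3L]][win[[3L]]] - ctr[3L])^2, "+"))
        sub <- v[win[[1L]], win[[2L]], win[[3L]], drop = FALSE]
        sph <- profile_hu(r, rad, c(val, spec$hu_water), w)
        v[win[[1L]], win[[2L]], win[[3L]]] <- pmax(sub, sph)
        v
      }
      for (i in seq_len(nrow(spec$fiducial_centers)))
        v <- put_sphere(v, spec$fiducial_centers[i, ],
                        spec$fiducial_diameter, spec$hu_fiducial)
      if (!is.null(spec$extra_blob))
        v <- put_sphere(v, spec$extra_blob$center, spec$extra_blob$diameter,
                        spec$hu_fiducial)
      v
    })
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), sd = spec$noise_sd), dim = n)
  }
  ct_volume(hu, spacing = rep(spec$spacing, 3L), origin = spec$bbox_lo)
}

#' Closed-form refracted ray path through a phantom
#'
#' Exact Snell-refracted path lengths and travel phase for geometries with a
#' closed form, computed in continuous space independently of any voxel
#' sampling: slabs at arbitrary incidence, and concentric shells at normal
#' (radial) incidence.  Serves as the oracle for the voxel ray tracer and
#' the phase computation.
#'
#' The in-skull speed of the oracle mirrors the ray tracer's model: the
#' length-weighted mean of the HU-derived speed over the cortical layers
#' only (cancellous bone contributes path length but not to the average).
#' Refraction uses the fixed water/bone speeds of `speeds`.
#'
#' @param spec A [phantom_spec()] of kind `flat_slab`, `tilted_slab`,
#'   `spherical_shell` or `shell_with_cancellous`.
#' @param s0 Ray origin (element position), world mm.
#' @param target Target point, world mm.
#' @param speeds A [speed_map()].
#' @param f0 Driving frequency, Hz.
#' @return A list with `status` (`"ok"` or `"total_internal_reflection"`),
#'   segment lengths `d_w`, `d_s`, `d_b` (mm), angles `theta_i`, `theta_t`
#'   (radians, outer interface), interface points `s1`, `s2`, directions
#'   `h_w`, `h_s`, `h_b`, in-skull speed `c_ns` (m/s), phases `phi_aberr`,
#'   `phi_ref` and their difference `delta_phi` (radians, unwrapped), and
#'   `miss_distance` (mm).
#' @export
analytic_path <- function(spec, s0, target, speeds = speed_map(),
                          f0 = 650e3) {
  stopifnot(inherits(spec, "phantom_spec"))
  s0 <- as.numeric(s0)
  target <- as.numeric(target)
  u <- unit_vector(target - s0)
  phi_ref <- reference_phase(s0, target, f0, speeds$c_water)
  if (spec$kind %in% c("flat_slab", "tilted_slab")) {
    m <- slab_outward_normal(spec)
    denom <- sum(u * m)
    if (denom >= -1e-12)
      stop("ray does not enter the slab from the outer side")
    t_hit <- sum((spec$slab_point - s0) * m) / denom
    if (t_hit <= 0) stop("ray starts inside or beyond the slab")
    s1 <- s0 + t_hit * u
    r1 <- refract(u, m, speeds$c_water, speeds$c_bone_max)
    if (r1$status != "ok")
      return(list(status = "total_internal_reflection",
                  theta_i = r1$theta_i, theta_t = NA_real_,
                  d_w = t_hit, d_s = NA_real_, d_b = NA_real_,
                  s1 = s1, s2 = NULL, h_w = u, h_s = NULL, h_b = NULL,
                  c_ns = NA_real_, phi_aberr = NA_real_, phi_ref = phi_ref,
                  delta_phi = NA_real_, miss_distance = NA_real_))
    h_s <- r1$direction
    d_s <- spec$thickness / abs(sum(h_s * m))
    s2 <- s1 + d_s * h_s
    r2 <- refract(h_s, m, speeds$c_bone_max, speeds$c_water)
    h_b <- r2$direction                     # parallel to u for c_b = c_w
    if (is.null(spec$layers)) {
      c_ns <- hu_to_speed(speeds, spec$hu_cortical)
    } else {
      w <- spec$layers[c(1L, 3L)]
      c_ns <- sum(w * hu_to_speed(speeds, rep(spec$hu_cortical, 2L))) / sum(w)
    }
    d_b <- max(0, sum((target - s2) * h_b))
    closest <- s2 + d_b * h_b
    phi_aberr <- 2 * pi * f0 *
      ((t_hit * 1e-3) / speeds$c_water + (d_s * 1e-3) / c_ns +
       (d_b * 1e-3) / speeds$c_water)
    return(list(status = "ok", theta_i = r1$theta_i, theta_t = r1$theta_t,
                d_w = t_hit, d_s = d_s, d_b = d_b, s1 = s1, s2 = s2,
                h_w = u, h_s = h_s, h_b = h_b, c_ns = c_ns,
                phi_aberr = phi_aberr, phi_ref = phi_ref,
                delta_phi = phi_aberr - phi_ref,
                miss_distance = sqrt(sum((target - closest)^2))))
  }
  if (spec$kind %in% c("spherical_shell", "shell_with_cancellous")) {
    rr <- if (spec$kind == "spherical_shell")
      c(spec$r_inner, spec$r_outer) else spec$radii[c(1L, 4L)]
    rad <- spec$center - s0
    rdist <- sqrt(sum(rad^2))
    if (sqrt(sum((unit_vector(rad) - u)^2)) > 1e-9)
      stop("closed form requires normal (radial) incidence on the shell")
    if (rdist <= rr[2L]) stop("ray must start outside the outer radius")
    tdist <- sqrt(sum((target - spec$center)^2))
    if (tdist >= rr[1L]) stop("target must lie inside the inner radius")
    d_w <- rdist - rr[2L]
    d_s <- rr[2L] - rr[1L]
    d_b <- rr[1L] - tdist
    s1 <- s0 + d_w * u
    s2 <- s1 + d_s * u
    if (spec$kind == "spherical_shell") {
      c_ns <- hu_to_speed(speeds, spec$hu_cortical)
    } else {
      w <- diff(spec$radii)[c(1L, 3L)]
      c_ns <- sum(w * hu_to_speed(speeds, rep(spec$hu_cortical, 2L))) / sum(w)
    }
    phi_aberr <- 2 * pi * f0 *
      ((d_w * 1e-3) / speeds$c_water + (d_s * 1e-3) / c_ns +
       (d_b * 1e-3) / speeds$c_water)
    return(list(status = "ok", theta_i = 0, theta_t = 0,
                d_w = d_w, d_s = d_s, d_b = d_b, s1 = s1, s2 = s2,
                h_w = u, h_s = u, h_b = u, c_ns = c_ns,
                phi_aberr = phi_aberr, phi_ref = phi_ref,
                delta_phi = phi_aberr - phi_ref, miss_distance = 0))
  }
  stop(sprintf("no closed-form path for phantom kind '%s'", spec$kind))
}

#' Serialize a phantom spec and its ground truth
#'
#' `write_phantom_json()` stores the spec parameters; the ground-truth file
#' additionally carries analytic interface positions / fiducial centers and,
#' when an array and target are supplied, the per-element analytic phases.
#'
#' @param spec A [phantom_spec()].
#' @param path Output JSON path.
#' @param array Optional [transducer_array()].
#' @param target Optional target, world mm.
#' @param speeds A [speed_map()].
#' @export
write_phantom_json <- function(spec, path, array = NULL, target = NULL,
                               speeds = speed_map()) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- unclass(spec)
  out$fiducial_centers <- if (is.null(spec$fiducial_centers)) NULL
    else unname(spec$fiducial_centers)
  if (!is.null(array) && !is.null(target) &&
      spec$kind != "fiducial_frame") {
    ap <- lapply(seq_len(array$n_elements), function(i)
      tryCatch(analytic_path(spec, array$elements[i, ], target, speeds,
                             array$f0),
               error = function(e) NULL))
    ok <- !vapply(ap, is.null, TRUE)
    out$analytic <- list(
      target = as.numeric(target),
      element = which(ok) - 1L,
      status = vapply(ap[ok], `[[`, "", "status"),
      delta_phi_rad = vapply(ap[ok], function(p)
        if (p$status == "ok") p$delta_phi else NA_real_, 1))
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
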