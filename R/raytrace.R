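#' Ray-marching configuration
#'
#' @param step_mm Marching step along the ray, mm (default 0.1).
#' @param tau_skull HU threshold separating water/soft tissue from bone
#'   (default 700).  Entry uses `HU >= tau_skull`, exit `HU <= tau_skull`,
#'   both inclusive.
#' @param max_length_mm Maximum marched length per ray, mm.
#' @param exit_gap_mm A below-threshold run longer than this is interpreted
#'   as brain/water beyond the skull; shorter dips are treated as cancellous
#'   bone between the two cortical tables and bridged.
#' @param normal_flip If `TRUE` (default) surface normals are flipped to
#'   oppose the incident ray.
#' @return An object of class `march_config`.
#' @export
march_config <- function(step_mm = 0.1, tau_skull = 700,
                         max_length_mm = 300, exit_gap_mm = 10,
                         normal_flip = TRUE) {
  if (step_mm <= 0) stop("`step_mm` must be > 0")
  if (max_length_mm <= 0) stop("`max_length_mm` must be > 0")
  if (exit_gap_mm <= 0) stop("`exit_gap_mm` must be > 0")
  structure(list(step_mm = step_mm, tau_skull = tau_skull,
                 max_length_mm = max_length_mm, exit_gap_mm = exit_gap_mm,
                 normal_flip = isTRUE(normal_flip)),
            class = "march_config")
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Parametric range [t_lo, t_hi] (mm along the unit ray) over which
# s0 + t*h lies inside the volume's sampling domain; NULL if it never does.
ray_domain_range <- function(vol, s0, h) {
  v0 <- as.numeric(world_to_voxel(vol, s0))
  dv <- as.numeric((matrix(h, 1L) %*% vol$orientation)) / vol$spacing
  dm <- dim(vol$data)
  t_lo <- -Inf
  t_hi <- Inf
  for (a in 1:3) {
    if (abs(dv[a]) < 1e-14) {
      if (v0[a] < -1e-9 || v0[a] > dm[a] - 1 + 1e-9) return(NULL)
    } else {
      tt <- sort(c((0 - v0[a]) / dv[a], (dm[a] - 1 - v0[a]) / dv[a]))
      t_lo <- max(t_lo, tt[1L])
      t_hi <- min(t_hi, tt[2L])
    }
  }
  if (t_lo > t_hi) return(NULL)
  c(t_lo, t_hi)
}

#' First ray-skull collision by threshold marching
#'
#' Marches `p_k = s0 + k * step_mm * h` for `k = 1, 2, ...` and returns the
#' first sample whose trilinearly interpolated HU meets `HU >= tau_skull`.
#' Samples outside the scanned block are treated as water (0 HU), so the
#' localization error is at most one step along the ray.
#'
#' @param vol A [ct_volume()].
#' @param s0 Ray start, world mm (outside the skull).
#' @param h Unit direction vector.
#' @param cfg A [march_config()].
#' @return A list with `status` (`"ok"` or `"no_skull_hit"`), and for a hit
#'   `s1` (collision point), `steps` (step count `k`), `d_w` (mm from `s0`).
#' @export
find_first_collision <- function(vol, s0, h, cfg = march_config()) {
  s0 <- as.numeric(s0)
  h <- as.numeric(h)
  if (abs(sqrt(sum(h^2)) - 1) > 1e-9) stop("`h` must be unit length")
  rng <- ray_domain_range(vol, s0, h)
  if (is.null(rng))
    return(list(status = "no_skull_hit", s1 = NULL, steps = NA_integer_,
                d_w = NA_real_))
  k_max <- floor(cfg$max_length_mm / cfg$step_mm)
  k_lo <- max(1L, as.integer(ceiling(rng[1L] / cfg$step_mm)))
  k_hi <- min(k_max, as.integer(floor(rng[2L] / cfg$step_mm)) + 1L)
  if (k_lo > k_hi)
    return(list(status = "no_skull_hit", s1 = NULL, steps = NA_integer_,
                d_w = NA_real_))
  ks <- k_lo:k_hi
  pts <- cbind(s0[1L] + ks * cfg$step_mm * h[1L],
               s0[2L] + ks * cfg$step_mm * h[2L],
               s0[3L] + ks * cfg$step_mm * h[3L])
  hu <- sample_hu(vol, pts)
  hit <- which(hu >= cfg$tau_skull)
  if (length(hit) == 0L)
    return(list(status = "no_skull_hit", s1 = NULL, steps = NA_integer_,
                d_w = NA_real_))
  k <- ks[hit[1L]]
  list(status = "ok", s1 = s0 + k * cfg$step_mm * h, steps = k,
       d_w = k * cfg$step_mm)
}

#' Skull exit point and in-skull HU profile
#'
#' Marches from the outer collision point `s1` along the refracted in-skull
#' direction `h_s`, recording the HU profile every `step_mm`.  The exit
#' (second collision) is the first sample with `HU <= tau_skull` *after* the
#' last cortical sample of the skull: below-threshold dips shorter than
#' `exit_gap_mm` are bridged as cancellous bone, so the in-skull segment
#' spans both cortical tables.
#'
#' @inheritParams find_first_collision
#' @param s1 Outer collision point, world mm.
#' @param h_s Unit in-skull direction.
#' @return A list with `status` (`"ok"`, `"left_volume"` when bone is
#'   truncated at the scanned-block boundary, or `"no_inner_boundary"`),
#'   `s2`, `d_s` (mm), and `hu_profile` (samples from `s1` to `s2`
#'   inclusive).
#' @export
find_second_collision <- function(vol, s1, h_s, cfg = march_config()) {
  s1 <- as.numeric(s1)
  h_s <- as.numeric(h_s)
  if (abs(sqrt(sum(h_s^2)) - 1) > 1e-9) stop("`h_s` must be unit length")
  rng <- ray_domain_range(vol, s1, h_s)
  t_domain <- if (is.null(rng)) 0 else rng[2L]
  k_cap <- floor(min(cfg$max_length_mm,
                     t_domain + cfg$exit_gap_mm + cfg$step_mm) / cfg$step_mm)
  if (k_cap < 1L)
    return(list(status = "left_volume", s2 = NULL, d_s = NA_real_,
                hu_profile = numeric()))
  ks <- seq_len(k_cap)
  pts <- cbind(s1[1L] + ks * cfg$step_mm * h_s[1L],
               s1[2L] + ks * cfg$step_mm * h_s[2L],
               s1[3L] + ks * cfg$step_mm * h_s[3L])
  hu <- sample_hu(vol, pts)
  hu0 <- sample_hu(vol, s1)
  bone <- which(hu >= cfg$tau_skull)
  if (length(bone) == 0L) {
    last <- 0L                       # skull thinner than one step beyond s1
  } else {
    gaps <- diff(c(0L, bone)) * cfg$step_mm
    brk <- which(gaps > cfg$exit_gap_mm)
    last <- if (length(brk) == 0L) bone[length(bone)]
            else if (brk[1L] == 1L) 0L
            else bone[brk[1L] - 1L]
  }
  exit_k <- last + 1L
  if (exit_k * cfg$step_mm > cfg$max_length_mm)
    return(list(status = "no_inner_boundary", s2 = NULL, d_s = NA_real_,
                hu_profile = c(hu0, hu)))
  if (last >= 1L && last * cfg$step_mm >= t_domain - cfg$step_mm)
    return(list(status = "left_volume", s2 = NULL, d_s = NA_real_,
                hu_profile = c(hu0, hu[seq_len(last)])))
  if (exit_k > length(hu))
    return(list(status = "no_inner_boundary", s2 = NULL, d_s = NA_real_,
                hu_profile = c(hu0, hu)))
  list(status = "ok",
       s2 = s1 + exit_k * cfg$step_mm * h_s,
       d_s = exit_k * cfg$step_mm,
       hu_profile = c(hu0, hu[seq_len(exit_k)]))
}

#' Outer and inner cortical regions of an in-skull HU profile
#'
#' The skull's dense outer and inner tables appear as two HU peaks along the
#' in-skull ray segment, separated by a lower-HU cancellous dip.  This
#' locates the HU maximum in each half of the profile and returns the
#' contiguous run of samples with `HU >= tau` around each peak.  For
#' monotone/single-peak profiles without a dip the two regions coincide
#' (whole above-threshold profile).
#'
#' @param hu_profile Numeric vector of HU samples along the in-skull segment.
#' @param tau HU threshold (default 700).
#' @return A list with integer index vectors `outer` and `inner`.
#' @export
cortical_regions <- function(hu_profile, tau = 700) {
  n <- length(hu_profile)
  if (n == 0L) stop("empty HU profile")
  if (all(hu_profile < tau))
    stop("no profile sample reaches tau (inconsistent with a collision)")
  run_around <- function(peak) {
    lo <- peak
    while (lo > 1L && hu_profile[lo - 1L] >= tau) lo <- lo - 1L
    hi <- peak
    while (hi < n && hu_profile[hi + 1L] >= tau) hi <- hi + 1L
    lo:hi
  }
  mid <- as.integer(ceiling(n / 2))
  half1 <- 1:mid
  half2 <- if (mid < n) (mid + 1L):n else half1
  peak1 <- half1[which.max(hu_profile[half1])]
  peak2 <- half2[which.max(hu_profile[half2])]
  gpeak <- which.max(hu_profile)
  if (hu_profile[peak1] < tau) peak1 <- gpeak
  if (hu_profile[peak2] < tau) peak2 <- gpeak
  list(outer = run_around(peak1), inner = run_around(peak2))
}

# Zucker-Hummel 3x3x3 gradient kernels: value at offset (x, y, z) in
# {-1,0,1}^3 is x/sqrt(x^2+y^2+z^2) (resp. y/, z/), center 0 by symmetry.
zh_kernels <- local({
  off <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  r <- sqrt(rowSums(off^2))
  r[r == 0] <- 1
  list(x = array(off[, 1L] / r, dim = c(3, 3, 3)),
       y = array(off[, 2L] / r, dim = c(3, 3, 3)),
       z = array(off[, 3L] / r, dim = c(3, 3, 3)))
})

#' Surface normal at a collision point (Zucker-Hummel operators)
#'
#' Estimates the local image gradient with the three 3x3x3 Zucker-Hummel
#' edge operators applied to the HU neighborhood of the voxel nearest to
#' `p` (border voxels use edge replication), normalizes it, and flips the
#' sign so the normal opposes the incident direction `toward`
#' (`n . toward < 0`).  The gradient is computed in voxel axes and rotated
#' into world axes via the volume orientation.
#'
#' @param vol A [ct_volume()].
#' @param p Collision point, world mm.
#' @param toward Unit incident direction (the ray's travel direction).
#' @param flip Flip the normal against `toward` (default `TRUE`).
#' @return Unit normal vector (world axes).
#' @export
surface_normal <- function(vol, p, toward, flip = TRUE) {
  v <- round(as.numeric(world_to_voxel(vol, p))) + 1  # nearest voxel, 1-based
  dm <- dim(vol$data)
  ix <- pmin(pmax(v[1L] + (-1:1), 1L), dm[1L])
  iy <- pmin(pmax(v[2L] + (-1:1), 1L), dm[2L])
  iz <- pmin(pmax(v[3L] + (-1:1), 1L), dm[3L])
  nb <- vol$data[ix, iy, iz]
  g <- c(sum(zh_kernels$x * nb), sum(zh_kernels$y * nb),
         sum(zh_kernels$z * nb))
  g <- as.numeric(vol$orientation %*% g)   # voxel axes -> world axes
  gn <- sqrt(sum(g^2))
  if (gn < 1e-9 * max(1, max(abs(nb)))) stop("degenerate normal")
  g <- g / gn
  if (flip) {
    d <- sum(g * toward)
    if (abs(d) < 1e-12) stop("degenerate normal")
    if (d > 0) g <- -g
  }
  g
}

#' Vector-form Snell refraction
#'
#' Refracts a unit incident direction `h` at an interface with unit normal
#' `nrm` (oriented against the incidence, `nrm . h < 0`) between media with
#' sound speeds `c_in` and `c_out`:
#' \eqn{\sin\theta_T = (c_{out}/c_{in}) \sin\theta_I}, with the transmitted
#' ray in the plane of `h` and `nrm`.  When
#' \eqn{(c_{out}/c_{in})\sin\theta_I > 1} no transmitted ray exists and the
#' status is `"total_internal_reflection"`.
#'
#' @param h Unit incident direction.
#' @param nrm Unit surface normal with `nrm . h < 0`.
#' @param c_in,c_out Sound speeds of the incident and transmitting media,
#'   m/s.
#' @return A list with `status` (`"ok"` or `"total_internal_reflection"`),
#'   `direction` (unit transmitted vector, `NULL` under total reflection),
#'   and angles `theta_i`, `theta_t` (radians; `theta_t` is `NA` under total
#'   reflection).
#' @export
refract <- function(h, nrm, c_in, c_out) {
  h <- as.numeric(h)
  nrm <- as.numeric(nrm)
  if (abs(sqrt(sum(h^2)) - 1) > 1e-9 || abs(sqrt(sum(nrm^2)) - 1) > 1e-9)
    stop("`h` and `nrm` must be unit vectors")
  if (c_in <= 0 || c_out <= 0) stop("sound speeds must be positive")
  ci <- -sum(h * nrm)
  if (ci <= 0) stop("normal must oppose the incident ray (nrm . h < 0)")
  ci <- min(ci, 1)
  si2 <- max(0, 1 - ci^2)
  mu <- c_out / c_in
  st2 <- mu^2 * si2
  theta_i <- acos(ci)
  if (st2 > 1)
    return(list(status = "total_internal_reflection", direction = NULL,
                theta_i = theta_i, theta_t = NA_real_))
  ct <- sqrt(1 - st2)
  tdir <- mu * h + (mu * ci - ct) * nrm
  tdir <- tdir / sqrt(sum(tdir^2))
  list(status = "ok", direction = tdir, theta_i = theta_i,
       theta_t = asin(sqrt(st2)))
}

#' Critical incidence angle of an interface
#'
#' The incidence angle beyond which no transmitted ray exists,
#' `asin(c_in / c_out)`; defined only when `c_out > c_in` (e.g. water to
#' skull: `asin(1480/2900)` ~ 30.69 degrees).
#'
#' @inheritParams refract
#' @return Critical angle in radians (`Inf` when `c_out <= c_in`).
#' @export
critical_angle <- function(c_in, c_out) {
  if (c_out <= c_in) return(Inf)
  asin(c_in / c_out)
}

#' Trace one transducer element through the skull
#'
#' Composes the full per-element ray computation: aim at the target, march to
#' the outer skull surface, estimate the surface normal, refract
#' (water-to-skull, fixed `c_water`/`c_bone_max` Snell ratio), march through
#' the skull recording the HU profile, refract again (skull-to-brain,
#' `c_brain = c_water`), and terminate the brain segment at the closest
#' approach to the target: `d_b = max(0, (target - s2) . h_b)`.
#'
#' Per-element failures never throw; they are recorded in `status`:
#' `no_skull_hit` (pure water path; kept active downstream with water-only
#' phase), `exceeded_critical_angle` (incidence beyond
#' `asin(c_water/c_bone_max)` at either interface), `left_volume` (skull
#' truncated by the scanned-block boundary, or an unusable normal).
#'
#' @param vol A [ct_volume()].
#' @param array A [transducer_array()].
#' @param n Element index (1-based).
#' @param target Target point, world mm.
#' @param cfg A [march_config()].
#' @param speeds A [speed_map()].
#' @return An object of class `ray_path`.
#' @export
trace_element <- function(vol, array, n, target, cfg = march_config(),
                          speeds = speed_map()) {
  s0 <- as.numeric(array$elements[n, ])
  target <- as.numeric(target)
  h_w <- unit_vector(target - s0)
  path <- structure(
    list(element_index = n, s0 = s0, s1 = NULL, s2 = NULL,
         h_w = h_w, h_s = NULL, h_b = NULL, n1 = NULL, n2 = NULL,
         theta_I_ws = NA_real_, theta_T_ws = NA_real_,
         theta_I_sb = NA_real_, theta_T_sb = NA_real_,
         d_w = NA_real_, d_s = NA_real_, d_b = NA_real_,
         hu_profile = numeric(), miss_distance = NA_real_,
         target = target, status = "ok"),
    class = "ray_path")
  fc <- find_first_collision(vol, s0, h_w, cfg)
  if (fc$status != "ok") {
    path$status <- "no_skull_hit"
    path$d_w <- sqrt(sum((target - s0)^2))
    path$d_s <- 0
    path$d_b <- 0
    path$miss_distance <- 0
    return(path)
  }
  path$s1 <- fc$s1
  path$d_w <- fc$d_w
  n1 <- tryCatch(surface_normal(vol, fc$s1, h_w, flip = cfg$normal_flip),
                 error = function(e) NULL)
  if (is.null(n1)) {
    path$status <- "left_volume"
    return(path)
  }
  path$n1 <- n1
  r1 <- refract(h_w, n1, speeds$c_water, speeds$c_bone_max)
  path$theta_I_ws <- r1$theta_i
  path$theta_T_ws <- r1$theta_t
  if (r1$status != "ok") {
    path$status <- "exceeded_critical_angle"
    return(path)
  }
  path$h_s <- r1$direction
  sc <- find_second_collision(vol, fc$s1, r1$direction, cfg)
  path$hu_profile <- sc$hu_profile
  if (sc$status != "ok") {
    path$status <- "left_volume"
    return(path)
  }
  path$s2 <- sc$s2
  path$d_s <- sc$d_s
  n2 <- tryCatch(surface_normal(vol, sc$s2, r1$direction,
                                flip = cfg$normal_flip),
                 error = function(e) NULL)
  if (is.null(n2)) {
    path$status <- "left_volume"
    return(path)
  }
  path$n2 <- n2
  r2 <- refract(r1$direction, n2, speeds$c_bone_max, speeds$c_water)
  path$theta_I_sb <- r2$theta_i
  path$theta_T_sb <- r2$theta_t
  if (r2$status != "ok") {
    path$status <- "exceeded_critical_angle"
    return(path)
  }
  path$h_b <- r2$direction
  db_raw <- sum((target - sc$s2) * r2$direction)
  if (db_raw < 0)
    warning(sprintf("element %d: target behind skull exit; d_b clamped to 0",
                    n))
  path$d_b <- max(0, db_raw)
  closest <- sc$s2 + path$d_b * r2$direction
  path$miss_distance <- sqrt(sum((target - closest)^2))
  path
}

#' @export
print.ray_path <- function(x, ...) {
  cat(sprintf("<ray_path> element %d, status %s\n", x$element_index,
              x$status))
  if (x$status == "ok")
    cat(sprintf("  d_w %.2f / d_s %.2f / d_b %.2f mm, miss %.3f mm\n",
                x$d_w, x$d_s, x$d_b, x$miss_distance))
  invisible(x)
}

#' Trace every element of an array
#'
#' @inheritParams trace_element
#' @param indices Elements to trace (default all).
#' @return A list of [trace_element()] results (class `ray_trace`).
#' @export
trace_array <- function(vol, array, target, cfg = march_config(),
                        speeds = speed_map(),
                        indices = seq_len(array$n_elements)) {
  paths <- lapply(indices, function(n)
    trace_element(vol, array, n, target, cfg, speeds))
  class(paths) <- "ray_trace"
  paths
}

#' Tabulate traced rays
#'
#' One row per element: status, incidence/refraction angles in degrees,
#' segment lengths in mm, and the miss distance at the closest approach.
#'
#' @param paths A `ray_trace` (list of `ray_path`) from [trace_array()].
#' @return A data frame.
#' @export
ray_table <- function(paths) {
  rad2deg <- 180 / pi
  data.frame(
    element = vapply(paths, `[[`, 1L, "element_index"),
    status = vapply(paths, `[[`, "", "status"),
    theta_I_ws_deg = vapply(paths, `[[`, 1, "theta_I_ws") * rad2deg,
    theta_T_ws_deg = vapply(paths, `[[`, 1, "theta_T_ws") * rad2deg,
    theta_I_sb_deg = vapply(paths, `[[`, 1, "theta_I_sb") * rad2deg,
    theta_T_sb_deg = vapply(paths, `[[`, 1, "theta_T_sb") * rad2deg,
    d_w_mm = vapply(paths, `[[`, 1, "d_w"),
    d_s_mm = vapply(paths, `[[`, 1, "d_s"),
    d_b_mm = vapply(paths, `[[`, 1, "d_b"),
    miss_distance_mm = vapply(paths, `[[`, 1, "miss_distance"))
}

#' @rdname ray_table
#' @param path Output CSV path.
#' @export
write_rays_csv <- function(paths, path) {
  utils::write.csv(ray_table(paths), path, row.names = FALSE)
  invisible(path)
}
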