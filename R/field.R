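#' Sampling plane for field simulation
#'
#' A rectangular grid of points `center + a*u + b*v` with `a, b` spanning
#' `[-extent/2, extent/2]` in steps of `step_mm`.  Defaults mirror a typical
#' hydrophone raster: 0.25 mm step over a 10 x 10 mm window.  `"xy"` and
#' `"xz"` give the lateral and axial planes through `center`.
#'
#' @param center Plane center, world mm (usually the target).
#' @param orientation `"xy"`, `"xz"`, `"yz"`, or `"custom"` with explicit
#'   unit axes `u`, `v`.
#' @param extent_mm Side length of the square window, mm.
#' @param step_mm Grid step, mm.
#' @param u,v In-plane unit axes for `orientation = "custom"`.
#' @return An object of class `field_plane`.
#' @export
field_plane <- function(center, orientation = c("xy", "xz", "yz", "custom"),
                        extent_mm = 10, step_mm = 0.25,
                        u = NULL, v = NULL) {
  orientation <- match.arg(orientation)
  if (step_mm <= 0) stop("`step_mm` must be > 0")
  if (extent_mm <= 0) stop("`extent_mm` must be > 0")
  ax <- switch(orientation,
               xy = list(c(1, 0, 0), c(0, 1, 0)),
               xz = list(c(1, 0, 0), c(0, 0, 1)),
               yz = list(c(0, 1, 0), c(0, 0, 1)),
               custom = {
                 if (is.null(u) || is.null(v))
                   stop("custom plane needs unit axes `u` and `v`")
                 list(unit_vector(u), unit_vector(v))
               })
  offs <- seq(-extent_mm / 2, extent_mm / 2, by = step_mm)
  structure(list(center = as.numeric(center), u = ax[[1L]], v = ax[[2L]],
                 offsets = offs, step_mm = step_mm),
            class = "field_plane")
}

#' Monochromatic phased-summation acoustic field
#'
#' Free-space Rayleigh-style summation of the array's continuous-wave field
#' on a plane: \deqn{p(x) = \sum_n a_n / r_n \exp(i (k_w r_n + \phi_n))}
#' with \eqn{r_n = \|x - s_n\|} and \eqn{k_w = 2\pi f_0 / c_w}.  `phases`
#' carries the total per-element excitation + propagation offset beyond the
#' homogeneous water delay — typically an aberration screen `delta_phi`
#' plus a correction phase.  Elements that are inactive, have `NA` phase,
#' or zero amplitude are excluded from the sum.  No transmission loss or
#' attenuation is modeled (phase-only treatment).
#'
#' @param array A [transducer_array()].
#' @param phases Per-element phase offsets, radians (`NA` excludes).
#' @param plane A [field_plane()].
#' @param c_water Water sound speed, m/s.
#' @param amplitudes Optional per-element amplitudes (default 1).
#' @return An object of class `field_map`: complex `amplitude` and real
#'   `magnitude` grids (rows index `u` offsets, columns `v`), the `peak_mm`
#'   world location and `peak_value` magnitude, and `n_summed`.
#' @export
simulate_field <- function(array, phases, plane, c_water = 1480,
                           amplitudes = NULL) {
  stopifnot(inherits(array, "transducer_array"),
            inherits(plane, "field_plane"))
  if (length(phases) != array$n_elements)
    stop("`phases` must have one entry per element")
  if (is.null(amplitudes)) amplitudes <- rep(1, array$n_elements)
  use <- array$active & is.finite(phases) & amplitudes > 0
  if (!any(use)) stop("no active elements to sum")
  k_w <- 2 * pi * array$f0 / (c_water * 1e3)   # rad per mm
  offs <- plane$offsets
  grid <- expand.grid(a = offs, b = offs)
  pts <- cbind(plane$center[1L] + grid$a * plane$u[1L] + grid$b * plane$v[1L],
               plane$center[2L] + grid$a * plane$u[2L] + grid$b * plane$v[2L],
               plane$center[3L] + grid$a * plane$u[3L] + grid$b * plane$v[3L])
  S <- array$elements[use, , drop = FALSE]
  amp <- amplitudes[use]
  ph <- phases[use]
  acc <- complex(real = numeric(nrow(pts)), imaginary = numeric(nrow(pts)))
  for (j in seq_len(nrow(S))) {
    r <- sqrt((pts[, 1L] - S[j, 1L])^2 + (pts[, 2L] - S[j, 2L])^2 +
              (pts[, 3L] - S[j, 3L])^2)
    acc <- acc + (amp[j] / r) * exp(1i * (k_w * r + ph[j]))
  }
  m <- length(offs)
  A <- matrix(acc, m, m)
  mag <- Mod(A)
  pk <- arrayInd(which.max(mag), dim(mag))
  peak_mm <- plane$center + offs[pk[1L]] * plane$u + offs[pk[2L]] * plane$v
  structure(list(plane = plane, amplitude = A, magnitude = mag,
                 peak_mm = peak_mm, peak_value = max(mag),
                 n_summed = sum(use)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d grid, step %g mm, %d elements summed\n",
              nrow(x$magnitude), ncol(x$magnitude), x$plane$step_mm,
              x$n_summed))
  cat(sprintf("  peak %.4g at (%s) mm\n", x$peak_value,
              paste(sprintf("%.2f", x$peak_mm), collapse = ", ")))
  invisible(x)
}

#' Focal shift and pressure-gain metrics
#'
#' Compares corrected, uncorrected and free-field maps of the same plane:
#' the focal shift is the distance from each map's magnitude peak to the
#' intended target, and the gain is the corrected-to-uncorrected peak
#' ratio in percent (reported alongside the corrected-to-free-field ratio,
#' the refocusing ceiling).
#'
#' @param map_corrected,map_uncorrected,map_free [simulate_field()] outputs.
#' @param target Intended focus, world mm.
#' @return A list with `shift_corrected_mm`, `shift_uncorrected_mm`,
#'   `shift_free_mm`, `gain_percent`, `corrected_vs_free_percent`.
#' @export
focal_metrics <- function(map_corrected, map_uncorrected, map_free, target) {
  stopifnot(inherits(map_corrected, "field_map"),
            inherits(map_uncorrected, "field_map"),
            inherits(map_free, "field_map"))
  target <- as.numeric(target)
  shift <- function(m) sqrt(sum((m$peak_mm - target)^2))
  list(shift_corrected_mm = shift(map_corrected),
       shift_uncorrected_mm = shift(map_uncorrected),
       shift_free_mm = shift(map_free),
       gain_percent = 100 * map_corrected$peak_value /
         map_uncorrected$peak_value,
       corrected_vs_free_percent = 100 * map_corrected$peak_value /
         map_free$peak_value)
}

#' Analytic aberration screen for a phantom
#'
#' Per-element phase the phantom's skull adds relative to the homogeneous
#' water path to `target`, from the closed-form [analytic_path()] oracle
#' (`delta_phi = phi_aberr - phi_ref`).  Elements beyond the critical angle
#' get `NA` (excluded from field summation, mirroring channel deactivation).
#'
#' @inheritParams analytic_path
#' @param array A [transducer_array()].
#' @return Numeric vector of per-element phase offsets, radians.
#' @export
aberration_screen <- function(spec, array, target, speeds = speed_map()) {
  vapply(seq_len(array$n_elements), function(i) {
    p <- analytic_path(spec, array$elements[i, ], target, speeds, array$f0)
    if (p$status == "ok") p$delta_phi else NA_real_
  }, 1)
}

#' Export a field map as CSV
#'
#' Long format with in-plane offsets `a_mm`, `b_mm`, world coordinates and
#' the real, imaginary and magnitude values.
#'
#' @param map A [simulate_field()] result.
#' @param path Output CSV path.
#' @export
write_field_csv <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  offs <- map$plane$offsets
  grid <- expand.grid(a_mm = offs, b_mm = offs)
  pts <- cbind(map$plane$center[1L] + grid$a_mm * map$plane$u[1L] +
                 grid$b_mm * map$plane$v[1L],
               map$plane$center[2L] + grid$a_mm * map$plane$u[2L] +
                 grid$b_mm * map$plane$v[2L],
               map$plane$center[3L] + grid$a_mm * map$plane$u[3L] +
                 grid$b_mm * map$plane$v[3L])
  utils::write.csv(
    data.frame(grid, x_mm = pts[, 1L], y_mm = pts[, 2L], z_mm = pts[, 3L],
               re = as.vector(Re(map$amplitude)),
               im = as.vector(Im(map$amplitude)),
               magnitude = as.vector(map$magnitude)),
    path, row.names = FALSE)
  invisible(path)
}
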