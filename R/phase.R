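#' Wrap a phase to [-pi, pi)
#'
#' Half-open convention: `wrap_phase(pi)` is `-pi`, and
#' `wrap_phase(x + 2*pi*k) == wrap_phase(x)` for any integer `k`.
#'
#' @param x Phase(s), radians.
#' @return Wrapped phase(s) in `[-pi, pi)`.
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Per-segment averaged sound speeds for a traced ray
#'
#' Water and brain segments travel at `c_water` (the ex-vivo setup has
#' degassed water, not brain tissue, inside the skull).  The in-skull speed
#' `c_ns` is the mean HU-derived speed over the profile samples inside the
#' two cortical regions only: the cancellous dip is excluded, following the
#' two-peak construction of [cortical_regions()].
#'
#' @param path A `ray_path` with `status == "ok"` and a recorded HU profile.
#' @param speeds A [speed_map()].
#' @param regions Optional precomputed [cortical_regions()] result.
#' @param tau HU threshold used for the regions (default 700).
#' @return A list with `c_nw`, `c_ns`, `c_nb` (m/s).
#' @export
segment_speeds <- function(path, speeds = speed_map(), regions = NULL,
                           tau = 700) {
  stopifnot(inherits(path, "ray_path"))
  if (path$status != "ok")
    stop("segment speeds are defined only for status \"ok\" rays")
  if (length(path$hu_profile) == 0L)
    stop("ray path has no HU profile (water-only path?)")
  if (is.null(regions)) regions <- cortical_regions(path$hu_profile, tau)
  sel <- sort(unique(c(regions$outer, regions$inner)))
  if (length(sel) == 0L) stop("empty cortical regions")
  list(c_nw = speeds$c_water,
       c_ns = mean(hu_to_speed(speeds, path$hu_profile[sel])),
       c_nb = speeds$c_water)
}

#' Accumulated (aberrated) phase of a traced ray
#'
#' Total travel phase of the three-segment ray at the driving frequency:
#' \deqn{\phi_n = 2\pi f_0 (d_{n,w}/c_{n,w} + d_{n,s}/c_{n,s} +
#'   d_{n,b}/c_{n,b})}
#' with segment lengths in mm converted to meters internally.  The value is
#' the unwrapped total; see [correction_phase()] for the wrapped excitation
#' phase.
#'
#' @param path A `ray_path` with `status == "ok"` (or a water-only
#'   `no_skull_hit` path with `d_s = 0`).
#' @param seg A list with `c_nw`, `c_ns`, `c_nb` from [segment_speeds()]
#'   (for water-only paths, `c_ns` is unused).
#' @param f0 Driving frequency, Hz.
#' @return Unwrapped phase, radians.
#' @export
aberrated_phase <- function(path, seg, f0 = 650e3) {
  stopifnot(inherits(path, "ray_path"))
  if (any(unlist(seg) <= 0)) stop("non-positive segment speed")
  d_s_term <- if (path$d_s > 0) (path$d_s * 1e-3) / seg$c_ns else 0
  2 * pi * f0 * ((path$d_w * 1e-3) / seg$c_nw + d_s_term +
                 (path$d_b * 1e-3) / seg$c_nb)
}

#' Reference (homogeneous-water) phase of an element
#'
#' The phase a wave accumulates over the straight water path from the
#' element to the target; synchronizing all aberrated arrivals to this
#' reference refocuses the array.
#'
#' @param s0 Element position, world mm.
#' @param target Target point, world mm.
#' @param f0 Driving frequency, Hz.
#' @param c_water Water sound speed, m/s.
#' @return Unwrapped phase, radians.
#' @export
reference_phase <- function(s0, target, f0 = 650e3, c_water = 1480) {
  d <- sqrt(sum((as.numeric(target) - as.numeric(s0))^2))
  2 * pi * f0 * (d * 1e-3) / c_water
}

#' Per-element correction phase
#'
#' `wrap(phi_ref - phi_aberr)`: the excitation offset that makes the
#' skull-aberrated arrival synchronous with the homogeneous-water reference,
#' wrapped to the transducer's excitation range `[-pi, pi)`.
#'
#' @param phi_aberr Aberrated phase(s), radians.
#' @param phi_ref Reference phase(s), radians.
#' @return Correction phase(s) in `[-pi, pi)`.
#' @export
correction_phase <- function(phi_aberr, phi_ref) {
  if (any(!is.finite(phi_aberr)) || any(!is.finite(phi_ref)))
    stop("phases must be finite")
  wrap_phase(phi_ref - phi_aberr)
}

#' Build a full phase-correction table for a target
#'
#' Traces every element of the array through the CT volume, deactivates
#' channels whose rays exceed the critical angle or leave the scanned block,
#' and computes the wrapped correction phase of each active channel.
#' Elements whose ray never meets bone keep a pure water path (correction
#' 0); their count is reported separately.
#'
#' @param vol A [ct_volume()].
#' @param array A [transducer_array()].
#' @param target Target point, world mm.
#' @param cfg A [march_config()].
#' @param speeds A [speed_map()].
#' @return An object of class `phase_correction`: per-element vectors
#'   `phi_aberr`, `phi_corr`, `active`, `status`, `c_ns`, plus `n_active`,
#'   `f0`, `target`, and the traced `paths`.
#' @export
build_correction <- function(vol, array, target, cfg = march_config(),
                             speeds = speed_map()) {
  paths <- trace_array(vol, array, target, cfg, speeds)
  N <- array$n_elements
  phi_aberr <- rep(NA_real_, N)
  phi_corr <- rep(0, N)
  c_ns <- rep(NA_real_, N)
  active <- rep(FALSE, N)
  status <- character(N)
  for (i in seq_len(N)) {
    p <- paths[[i]]
    status[i] <- p$status
    phi_ref <- reference_phase(p$s0, target, array$f0, speeds$c_water)
    if (p$status == "ok") {
      seg <- segment_speeds(p, speeds, tau = cfg$tau_skull)
      c_ns[i] <- seg$c_ns
      phi_aberr[i] <- aberrated_phase(p, seg, array$f0)
      phi_corr[i] <- correction_phase(phi_aberr[i], phi_ref)
      active[i] <- TRUE
    } else if (p$status == "no_skull_hit") {
      # legitimate water window: water-only phase, zero correction
      seg <- list(c_nw = speeds$c_water, c_ns = speeds$c_water,
                  c_nb = speeds$c_water)
      phi_aberr[i] <- aberrated_phase(p, seg, array$f0)
      phi_corr[i] <- correction_phase(phi_aberr[i], phi_ref)
      active[i] <- TRUE
    }
  }
  active <- active & array$active
  phi_corr[!active] <- 0
  if (!any(active)) stop("target untreatable: zero active elements")
  structure(list(phi_aberr = phi_aberr, phi_corr = phi_corr,
                 active = active, status = status, c_ns = c_ns,
                 n_active = sum(active), f0 = array$f0,
                 target = as.numeric(target), paths = paths),
            class = "phase_correction")
}

#' @export
print.phase_correction <- function(x, ...) {
  cat(sprintf("<phase_correction> %d/%d channels active, f0 = %g kHz\n",
              x$n_active, length(x$active), x$f0 / 1e3))
  tab <- table(x$status)
  cat("  element status:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Export / read a phase-correction table as CSV
#'
#' CSV columns: `channel` (0-based), `active` (0/1), `phase_rad`,
#' `phase_deg`.  Inactive channels carry phase 0.  Reading validates
#' uniqueness of channel ids and the active/phase convention.
#'
#' @param pc A [build_correction()] result.
#' @param path CSV file path.
#' @export
export_correction <- function(pc, path) {
  stopifnot(inherits(pc, "phase_correction"))
  df <- data.frame(channel = seq_along(pc$phi_corr) - 1L,
                   active = as.integer(pc$active),
                   phase_rad = pc$phi_corr,
                   phase_deg = pc$phi_corr * 180 / pi)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_correction
#' @return `read_correction()` returns a data frame with columns `channel`,
#'   `active`, `phase_rad`, `phase_deg`.
#' @export
read_correction <- function(path) {
  df <- utils::read.csv(path)
  need <- c("channel", "active", "phase_rad", "phase_deg")
  if (!all(need %in% names(df)))
    stop("correction CSV must have columns channel, active, phase_rad, phase_deg")
  if (anyDuplicated(df$channel))
    stop("duplicate channel ids in correction file")
  df
}
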