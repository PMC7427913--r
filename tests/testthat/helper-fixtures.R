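# Shared phantom fixtures, built once per test run and cached.
# Geometry choices (documented in the methods vignette):
#  - slab studies: 0.25 mm voxels, 1 mm partial-volume edge, 150 mm array,
#    narrow cap so incidence stays within tilt + cap;
#  - shell studies: scaled-down concentric shell (radii 25/31 mm, 60 mm
#    array) at 0.25 mm voxels, keeping the volume desk-sized.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = fixture_env))
    assign(key, build(), envir = fixture_env)
  get(key, envir = fixture_env)
}

slab_spec <- function(tilt_deg, half_xy = 14, ...) {
  phantom_spec("tilted_slab", tilt_deg = tilt_deg, spacing = 0.25,
               bbox_lo = c(-half_xy, -half_xy, -45),
               bbox_hi = c(half_xy, half_xy, -19), ...)
}

slab_fixture <- function(tilt_deg, half_xy = 14) {
  key <- sprintf("slab_%g_%g", tilt_deg, half_xy)
  fixture(key, function() {
    spec <- slab_spec(tilt_deg, half_xy)
    list(spec = spec, vol = voxelize(spec))
  })
}

shell_fixture <- function() {
  fixture("shell", function() {
    spec <- phantom_spec("spherical_shell", r_inner = 25, r_outer = 31,
                         spacing = 0.25)
    list(spec = spec, vol = voxelize(spec),
         array = make_hemisphere_array(n = 64, radius = 60,
                                       cap_half_angle = 60))
  })
}

small_array <- function(n = 64, cap = 5, radius = 150)
  make_hemisphere_array(n = n, radius = radius, cap_half_angle = cap)

# uniform random unit vectors
random_directions <- function(n) {
  d <- matrix(stats::rnorm(3 * n), n, 3)
  d / sqrt(rowSums(d^2))
}

random_rotation <- function() {
  q <- svd(matrix(stats::rnorm(9), 3, 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

angle_deg <- function(a, b)
  acos(pmin(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
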