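test_that("first collision localizes a slab face to within one step", {
  fx <- slab_fixture(0)
  cfg <- march_config()
  # outer face at z = -35, approaching along +z
  fc <- find_first_collision(fx$vol, c(0, 0, -120), c(0, 0, 1), cfg)
  expect_equal(fc$status, "ok")
  expect_gte(fc$s1[3], -35 - cfg$step_mm)
  expect_lte(fc$s1[3], -35 + cfg$step_mm)
  expect_equal(fc$d_w, fc$steps * cfg$step_mm)
  # a ray that misses the slab block entirely
  miss <- find_first_collision(fx$vol, c(0, 0, -120), c(0, 0, -1), cfg)
  expect_equal(miss$status, "no_skull_hit")
})

test_that("threshold comparison is boundary-inclusive at exactly tau", {
  d <- array(0, dim = c(9, 9, 9))
  d[, , 5:9] <- 700                       # HU exactly at the threshold
  vol <- ct_volume(d, spacing = c(1, 1, 1), origin = c(-4, -4, -4))
  fc <- find_first_collision(vol, c(0, 0, -4), c(0, 0, 1),
                             march_config(step_mm = 0.5, max_length_mm = 20))
  expect_equal(fc$status, "ok")
})

test_that("halving the marching step never worsens collision localization", {
  fx <- slab_fixture(0)
  err <- vapply(c(0.4, 0.2, 0.1, 0.05), function(s) {
    fc <- find_first_collision(fx$vol, c(0, 0, -120), c(0, 0, 1),
                               march_config(step_mm = s))
    abs(fc$s1[3] - (-35))
  }, 1)
  expect_true(all(diff(err) <= 1e-9))
  expect_true(all(err <= c(0.4, 0.2, 0.1, 0.05) + 1e-9))
})

test_that("second collision spans the full skull including cancellous dips", {
  cfg <- march_config()
  # homogeneous 6 mm slab at normal incidence
  fx <- slab_fixture(0)
  fc <- find_first_collision(fx$vol, c(0, 0, -120), c(0, 0, 1), cfg)
  sc <- find_second_collision(fx$vol, fc$s1, c(0, 0, 1), cfg)
  expect_equal(sc$status, "ok")
  expect_gte(sc$d_s, 6 - 2 * cfg$step_mm)
  expect_lte(sc$d_s, 6 + 2 * cfg$step_mm)
  # layered cortical/cancellous/cortical slab: exit past the dip
  spec3 <- phantom_spec("flat_slab", spacing = 0.25, layers = c(2, 3, 2),
                        bbox_lo = c(-8, -8, -45), bbox_hi = c(8, 8, -19))
  vol3 <- voxelize(spec3)
  fc3 <- find_first_collision(vol3, c(0, 0, -120), c(0, 0, 1), cfg)
  sc3 <- find_second_collision(vol3, fc3$s1, c(0, 0, 1), cfg)
  expect_equal(sc3$status, "ok")
  expect_gte(sc3$d_s, 7 - 2 * cfg$step_mm)   # well past the 2 mm outer table
  expect_lte(sc3$d_s, 7 + 2 * cfg$step_mm)
  # the profile dips below tau in the middle yet exit is on the inner face
  mid <- sc3$hu_profile[seq(round(length(sc3$hu_profile) * 0.4),
                            round(length(sc3$hu_profile) * 0.6))]
  expect_true(any(mid < 700))
  # bone thicker than the marching budget
  short <- march_config(max_length_mm = 3)
  expect_equal(find_second_collision(fx$vol, fc$s1, c(0, 0, 1),
                                     short)$status,
               "no_inner_boundary")
})

test_that("cortical regions split two-peak profiles and degrade gracefully", {
  prof <- c(900, 1200, 300, 300, 1100, 800)
  cr <- cortical_regions(prof, tau = 700)
  expect_equal(cr$outer, 1:2)
  expect_equal(cr$inner, 5:6)
  # monotone single-peak profile: both regions are the whole profile
  mono <- c(800, 900, 1000, 1100)
  cr2 <- cortical_regions(mono, tau = 700)
  expect_equal(cr2$outer, 1:4)
  expect_equal(cr2$inner, 1:4)
  cr3 <- cortical_regions(750, tau = 700)
  expect_equal(cr3$outer, 1L)
  expect_equal(cr3$inner, 1L)
  expect_error(cortical_regions(c(100, 200), tau = 700), "tau")
})

test_that("Zucker-Hummel kernels match their closed form", {
  k <- skullray:::zh_kernels
  # offsets are {-1,0,1}^3 with array index = offset + 2
  expect_equal(k$x[3, 2, 2], 1)               # (1,0,0) -> 1
  expect_equal(k$x[3, 3, 3], 1 / sqrt(3))     # (1,1,1) -> 1/sqrt(3)
  expect_equal(k$x[2, , ], matrix(0, 3, 3))   # (0,y,z) -> 0
  expect_equal(k$x[2, 2, 2], 0)               # center defined as 0
  expect_equal(k$z[2, 2, 3], 1)
  expect_equal(aperm(k$y, c(2, 1, 3)), k$x)   # symmetry between operators
})

test_that("normals are axis-aligned on flat interfaces and flip against the ray", {
  d <- array(0, dim = c(11, 11, 11))
  d[, , 6:11] <- 1000                       # step up across z = z0
  vol <- ct_volume(d, spacing = c(1, 1, 1), origin = c(-5, -5, -5))
  # probe just below the water/bone step between z = -1 and z = 0
  n <- surface_normal(vol, c(0, 0, -0.4), toward = c(0, 0, 1))
  expect_equal(n, c(0, 0, -1), tolerance = 1e-12)
  n2 <- surface_normal(vol, c(0, 0, -0.4), toward = c(0, 0, -1))
  expect_equal(n2, c(0, 0, 1), tolerance = 1e-12)
  expect_error(surface_normal(vol, c(0, 0, -4), toward = c(0, 0, 1)),
               "degenerate")
})

test_that("normals ignore constant HU offsets", {
  fx <- shell_fixture()
  vol2 <- fx$vol
  vol2$data <- vol2$data + 50
  set.seed(31)
  dirs <- random_directions(20)
  for (i in 1:20) {
    p <- fx$spec$center + 31 * dirs[i, ]    # on the outer shell surface
    n1 <- surface_normal(fx$vol, p, -dirs[i, ])
    n2 <- surface_normal(vol2, p, -dirs[i, ])
    expect_lt(max(abs(n1 - n2)), 1e-6)
  }
})

test_that("shell surface normals agree with analytic radial directions", {
  fx <- shell_fixture()
  cfg <- march_config()
  set.seed(7)
  dirs <- random_directions(500)
  errs <- vapply(seq_len(500), function(i) {
    fc <- find_first_collision(fx$vol, 60 * dirs[i, ], -dirs[i, ], cfg)
    nrm <- surface_normal(fx$vol, fc$s1, -dirs[i, ])
    angle_deg(nrm, dirs[i, ])
  }, 1)
  expect_lte(max(errs), 5)
})

test_that("vector Snell refraction matches angles and detects total reflection", {
  # normal incidence: direction unchanged for any speed pair
  r0 <- refract(c(0, 0, 1), c(0, 0, -1), 1480, 2900)
  expect_equal(r0$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(r0$theta_i, 0)
  # 20 degrees water -> skull refracts to 42.08 degrees
  h <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  r1 <- refract(h, c(0, 0, -1), 1480, 2900)
  expect_equal(r1$theta_t * 180 / pi, 42.0755, tolerance = 1e-3)
  expect_equal(sin(r1$theta_i) / sin(r1$theta_t), 1480 / 2900,
               tolerance = 1e-12)
  # beyond the 30.69 degree critical angle
  h35 <- c(sin(35 * pi / 180), 0, cos(35 * pi / 180))
  expect_equal(refract(h35, c(0, 0, -1), 1480, 2900)$status,
               "total_internal_reflection")
  expect_equal(critical_angle(1480, 2900) * 180 / pi, 30.6852,
               tolerance = 1e-3)
  expect_error(refract(c(0, 0, 1), c(0, 0, 1), 1480, 2900), "oppose")
})

test_that("equal speeds make refraction the identity at any incidence", {
  set.seed(5)
  for (i in 1:50) {
    th <- runif(1, 0, 89.9) * pi / 180
    ph <- runif(1, 0, 2 * pi)
    h <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    r <- refract(h, c(0, 0, -1), 1540, 1540)
    expect_equal(r$direction, h, tolerance = 1e-9)
  }
})

test_that("traced rays satisfy both Snell ratios from their stored angles", {
  fx <- slab_fixture(10)
  arr <- small_array(n = 32, cap = 5)
  paths <- trace_array(fx$vol, arr, c(0, 0, 0))
  ok <- Filter(function(p) p$status == "ok", paths)
  expect_gt(length(ok), 0)
  for (p in ok) {
    expect_equal(sin(p$theta_I_ws) / sin(p$theta_T_ws), 1480 / 2900,
                 tolerance = 1e-9)
    expect_equal(sin(p$theta_I_sb) / sin(p$theta_T_sb), 2900 / 1480,
                 tolerance = 1e-9)
    expect_equal(p$d_w, sqrt(sum((p$s1 - p$s0)^2)), tolerance = 1e-9)
    expect_equal(p$d_s, sqrt(sum((p$s2 - p$s1)^2)), tolerance = 1e-9)
    for (v in list(p$h_w, p$h_s, p$h_b, p$n1, p$n2))
      expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
  }
})

test_that("steep slab incidence deactivates the element", {
  spec <- phantom_spec("tilted_slab", tilt_deg = 40, spacing = 0.25,
                       bbox_lo = c(-12, -12, -45), bbox_hi = c(12, 12, -19))
  vol <- voxelize(spec)
  arr <- small_array(n = 1, cap = 5)
  p <- trace_element(vol, arr, 1, c(0, 0, 0))
  expect_equal(p$status, "exceeded_critical_angle")
})

test_that("concentric shell gives normal incidence and a collinear brain leg", {
  fx <- shell_fixture()
  paths <- trace_array(fx$vol, fx$array, c(0, 0, 0),
                       indices = seq(1, 64, by = 4))
  for (p in paths) {
    expect_equal(p$status, "ok")
    expect_lt(p$theta_I_ws * 180 / pi, 2)
    expect_gt(sum(p$h_b * p$h_w), cos(2 * pi / 180))
    expect_lt(p$miss_distance, 0.5)
  }
})

test_that("target on the straight continuation of a normal ray has zero miss", {
  fx <- slab_fixture(0)
  arr <- transducer_array(matrix(c(0, 0, -150), 1), geometric_focus = c(0, 0, 0))
  p <- trace_element(fx$vol, arr, 1, c(0, 0, 0))
  expect_equal(p$status, "ok")
  expect_equal(p$miss_distance, 0, tolerance = 1e-9)
  expect_equal(p$d_b, sqrt(sum(p$s2^2)), tolerance = 1e-9)
})

test_that("ray tables export one labelled row per element", {
  fx <- slab_fixture(0)
  arr <- small_array(n = 8, cap = 5)
  paths <- trace_array(fx$vol, arr, c(0, 0, 0))
  tab <- ray_table(paths)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$status == "ok"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rays_csv(paths, f)
  expect_equal(read.csv(f)$d_s_mm, tab$d_s_mm, tolerance = 1e-9)
})
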