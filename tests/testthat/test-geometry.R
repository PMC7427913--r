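test_that("hemisphere array places elements on the cap deterministically", {
  arr <- make_hemisphere_array(n = 1024, radius = 150, cap_half_angle = 90)
  r <- sqrt(rowSums(sweep(arr$elements, 2, arr$geometric_focus)^2))
  expect_equal(r, rep(150, 1024), tolerance = 1e-9)
  # all on the cap side of the focus
  expect_true(all(arr$elements[, 3] < 0))
  one <- make_hemisphere_array(n = 1, radius = 150, cap_half_angle = 30)
  expect_equal(as.numeric(one$elements), c(0, 0, -150), tolerance = 1e-9)
  a1 <- make_hemisphere_array(n = 64, seed = 42)
  a2 <- make_hemisphere_array(n = 64, seed = 42)
  expect_identical(a1$elements, a2$elements)
  expect_error(make_hemisphere_array(n = 0), "n")
  expect_error(make_hemisphere_array(cap_half_angle = 120), "cap")
})

test_that("element CSV round trip preserves coordinates and order", {
  arr <- make_hemisphere_array(n = 32)
  f <- withr::local_tempfile(fileext = ".csv")
  write_elements_csv(arr, f)
  back <- read_elements_csv(f)
  expect_equal(back$elements, arr$elements, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fiducial detection recovers marker centroids and filters by size", {
  spec <- phantom_spec("fiducial_frame")
  truth <- spec$fiducial_centers
  vol <- voxelize(spec)
  det <- detect_fiducials(vol)
  expect_equal(nrow(det$points), 8)
  vox_diag <- sqrt(sum(vol$spacing^2))
  err <- vapply(seq_len(8), function(i) {
    min(sqrt(rowSums(sweep(det$points, 2, truth[i, ])^2)))
  }, 1)
  expect_true(all(err <= vox_diag))
  # a 10 mm blob passes the HU threshold but fails the granulometric band
  spec2 <- phantom_spec("fiducial_frame",
                        extra_blob = list(center = c(0, 0, -15),
                                          diameter = 10))
  det2 <- detect_fiducials(voxelize(spec2))
  expect_equal(nrow(det2$points), 8)
  # all-water volume
  expect_error(
    detect_fiducials(ct_volume(array(0, dim = c(8, 8, 8)),
                               spacing = c(1, 1, 1))),
    "no fiducials")
})

test_that("SVD registration recovers exact rigid motions", {
  pts <- fiducial_set(default_fiducial_frame())
  # identity
  t0 <- register_svd(pts, pts)
  expect_equal(t0$R, diag(3), tolerance = 1e-12)
  expect_equal(t0$T, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(t0$rms_mm, 0, tolerance = 1e-12)
  # 90 degrees about z plus translation
  Rz <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  Tv <- c(10, -5, 3)
  dst <- fiducial_set(sweep(pts$points %*% t(Rz), 2, Tv, "+"))
  tr <- register_svd(pts, dst)
  expect_equal(tr$R, Rz, tolerance = 1e-9)
  expect_equal(tr$T, Tv, tolerance = 1e-9)
  expect_equal(tr$rms_mm, 0, tolerance = 1e-9)
})

test_that("registration under noise stays within residual and angle bounds", {
  set.seed(1234)
  pts <- fiducial_set(default_fiducial_frame())   # K = 8
  worst_rms <- 0
  worst_rot <- 0
  for (i in 1:50) {
    R <- random_rotation()
    Tv <- rnorm(3, sd = 20)
    noisy <- sweep(pts$points %*% t(R), 2, Tv, "+") +
      matrix(rnorm(24, sd = 0.1), ncol = 3)
    tr <- register_svd(pts, fiducial_set(noisy))
    worst_rms <- max(worst_rms, tr$rms_mm)
    rot_err <- acos(pmin(1, (sum(diag(t(tr$R) %*% R)) - 1) / 2)) * 180 / pi
    worst_rot <- max(worst_rot, rot_err)
    # always a proper rotation, even with noise
    expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-9)
    expect_equal(det(tr$R), 1, tolerance = 1e-9)
  }
  expect_lte(worst_rms, 0.3)
  expect_lte(worst_rot, 0.5)
})

test_that("registration rejects degenerate input and mismatched sets", {
  line <- fiducial_set(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_error(register_svd(line, line), "collinear|degenerate")
  a <- fiducial_set(default_fiducial_frame())
  b <- fiducial_set(default_fiducial_frame()[1:4, ])
  expect_error(register_svd(a, b), "counts")
  expect_error(register_svd(b, b), NA)
  two <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_error(register_svd(two, two), "at least 3")
})

test_that("registration residual is invariant to consistent relabeling", {
  set.seed(9)
  src <- fiducial_set(matrix(rnorm(24, sd = 30), ncol = 3))
  R <- random_rotation()
  dst_pts <- sweep(src$points %*% t(R), 2, c(1, 2, 3), "+") +
    matrix(rnorm(24, sd = 0.2), ncol = 3)
  perm <- sample(8)
  r1 <- register_svd(src, fiducial_set(dst_pts))$rms_mm
  r2 <- register_svd(fiducial_set(src$points[perm, ]),
                     fiducial_set(dst_pts[perm, ]))$rms_mm
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("apply/invert transform compose to the identity", {
  tr <- rigid_transform(random_rotation(), c(4, -7, 2))
  p <- matrix(rnorm(30, sd = 50), ncol = 3)
  expect_equal(apply_transform(invert_transform(tr), apply_transform(tr, p)),
               p, tolerance = 1e-9)
  expect_equal(apply_transform(rigid_transform(), c(1, 2, 3)),
               matrix(c(1, 2, 3), 1), tolerance = 1e-12)
  expect_equal(apply_transform(rigid_transform(T = c(1, 2, 3)), c(0, 0, 0)),
               matrix(c(1, 2, 3), 1), tolerance = 1e-12)
})

test_that("transform and fiducial files round trip", {
  tr <- rigid_transform(random_rotation(), c(4, -7, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tr, f)
  back <- read_transform_json(f)
  expect_equal(back$R, tr$R, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$T, tr$T, tolerance = 1e-12)
  fids <- fiducial_set(default_fiducial_frame())
  g <- withr::local_tempfile(fileext = ".csv")
  write_fiducials_csv(fids, g)
  expect_equal(read_fiducials_csv(g)$points, fids$points,
               tolerance = 1e-12, ignore_attr = TRUE)
})
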