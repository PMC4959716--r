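test_that("affine9 composes rotations about its centre and inverts cleanly", {
  tf <- affine9(t = c(2, -1, 3), r = c(4, -2, 7), s = c(1.02, 0.97, 1.01),
                center = c(5, 5, 5))
  M <- affine9_matrix(tf)
  expect_equal(M %*% solve(M), diag(4), tolerance = 1e-9)
  # rotation centre is a fixed point of the rotation/scale part
  tf0 <- affine9(r = c(10, 20, 30), center = c(5, 5, 5))
  expect_equal(drop(apply_transform(tf0, matrix(c(5, 5, 5), 1))), c(5, 5, 5),
               tolerance = 1e-12)
  # matrix equals T(c) Rz Ry Rx S T(-c) composition built independently
  R <- maimap:::rot_matrix(tf$r)
  M2 <- diag(4); M2[1:3, 1:3] <- R %*% diag(tf$s)
  M2[1:3, 4] <- tf$center - M2[1:3, 1:3] %*% tf$center + tf$t
  expect_equal(M, M2, tolerance = 1e-12)
  expect_error(affine9(s = c(0, 1, 1)), "scales")
})

test_that("Euler angles recovered from rotation matrices", {
  for (r in list(c(3, -4, 5), c(-10, 15, 100), c(0, 0, 0))) {
    expect_equal(maimap:::euler_from_matrix(maimap:::rot_matrix(r)), r,
                 tolerance = 1e-9)
  }
})

test_that("metadata initial transform handles offsets and rotated frames", {
  a <- volume_image(array(0, c(10, 10, 5)), spacing = c(1, 1, 2))
  expect_equal(initial_transform_from_metadata(a, a)$t, c(0, 0, 0))
  b <- volume_image(array(0, c(10, 10, 5)), spacing = c(1, 1, 2),
                    origin = c(5, 0, 0))
  tf <- initial_transform_from_metadata(a, b)
  expect_equal(tf$t, c(5, 0, 0))
  expect_equal(tf$r, c(0, 0, 0)); expect_equal(tf$s, c(1, 1, 1))
  # rotated secondary frame: mapping equals the 4x4 frame composition
  Rz <- maimap:::rot_matrix(c(0, 0, 30))
  cvol <- volume_image(array(0, c(10, 10, 5)), affine = rbind(
    cbind(Rz %*% diag(c(1, 1, 2)), c(3, -2, 1)), c(0, 0, 0, 1)))
  tf2 <- initial_transform_from_metadata(a, cvol)
  # oracle: T(x) = c_sec + O_sec O_pri^T (x - c_pri)
  cp <- vol_center(a); cs <- vol_center(cvol)
  pts <- cbind(runif(10, 0, 9), runif(10, 0, 9), runif(10, 0, 8))
  want <- t(Rz %*% t(sweep(pts, 2, cp)) + cs)
  expect_equal(apply_transform(tf2, pts), want, tolerance = 1e-9)
  expect_error(initial_transform_from_metadata(list(affine = NULL), a),
               "metadata")
})

test_that("resampling is exact for identity, constants and linear ramps", {
  d <- c(12, 11, 6)
  co <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  ramp <- volume_image(array(co$i, d), spacing = c(1, 1, 1))
  same <- resample_volume(ramp, ramp, affine9())
  expect_equal(same$data, ramp$data, tolerance = 1e-12)
  expect_identical(same$affine, ramp$affine)
  # constant volume stays constant under any in-bounds transform
  const <- volume_image(array(7, d), spacing = c(1, 1, 1))
  shifted <- resample_volume(const, const, affine9(t = c(0.3, -0.2, 0.4)))
  inner <- shifted$data[2:11, 2:10, 2:5]
  expect_equal(range(inner), c(7, 7), tolerance = 1e-12)
  # half-voxel shift of a linear ramp shifts values by half a voxel
  half <- resample_volume(ramp, ramp, affine9(t = c(0.5, 0, 0)))
  expect_equal(half$data[3:10, , ], ramp$data[3:10, , ] + 0.5,
               tolerance = 1e-10)
  expect_error(resample_volume(ramp, ramp, affine9(s = c(1, 1, 1e-300))))
})

test_that("resample through a transform and its inverse returns smooth
           fields within interpolation error", {
  d <- c(24, 24, 12)
  co <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  smooth <- volume_image(array(sin(co$i / 4) * cos(co$j / 5) + co$k / 6, d),
                         spacing = c(1, 1, 1))
  tf <- affine9(t = c(1.3, -0.7, 0.4), r = c(0, 0, 5), s = c(1, 1, 1),
                center = vol_center(smooth))
  fwd <- resample_volume(smooth, smooth, tf)
  back <- resample_volume(fwd, smooth, solve(affine9_matrix(tf)))
  inner <- 5:20
  err <- abs(back$data[inner, inner, 4:9] - smooth$data[inner, inner, 4:9])
  # trilinear error is O(h^2 |f''|); h = 1, curvature ~ 1/16 here
  expect_lt(max(err), 0.06)
})

test_that("mutual information matches analytic cases", {
  # identical samples: MI equals the marginal histogram entropy
  set.seed(1)
  a <- rnorm(20000)
  mi <- mutual_information(a, a, bins = 32)
  ra <- quantile(a, c(0.01, 0.99), names = FALSE)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * 32), 0), 31)
  p <- tabulate(ia + 1, 32) / length(a)
  expect_equal(mi, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  # perfectly dependent binary: MI = ln 2
  x <- rep(c(0, 1), each = 50)
  expect_equal(mutual_information(x, x, bins = 2), log(2), tolerance = 1e-12)
  # independent samples: MI near zero
  set.seed(2)
  expect_lt(mutual_information(runif(1e5), runif(1e5), bins = 32), 0.02)
  # symmetry
  set.seed(3)
  u <- rnorm(5000); v <- u + rnorm(5000)
  expect_equal(mutual_information(u, v), mutual_information(v, u),
               tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "differ")
  expect_error(mutual_information(numeric(0), numeric(0)), "empty")
})

test_that("registration recovers identity and injected transforms", {
  spec <- small_spec(lesions = list(small_lesion()), seed = 31)
  ph <- generate_phantom(spec)
  # secondary equal to primary: transform close to identity
  res0 <- register_affine(ph$study$t2w, ph$study$t2w, max_iter = 30,
                          n_samples = 6000, coarse_init = FALSE)
  expect_lt(surface_tre(affine9(), res0$transform, spec$prostate_semiaxes),
            0.5)
  # injected translation + rotation on the DWI series (full-size phantom:
  # rotation recovery needs the full prostate extent for leverage)
  tf <- affine9(t = c(3.2, -1.5, 2.0), r = c(0, 0, 3))
  ph2 <- generate_phantom(phantom_spec(
    lesions = list(list(center = c(8, 5, 0), semiaxes = c(7, 6, 5),
                        gleason = 8)),
    misregistration = tf, seed = 31))
  res <- register_affine(ph2$study$t2w, ph2$study$dwi[[1]], max_iter = 80,
                         n_samples = 10000)
  sp <- vol_spacing(ph2$study$t2w)
  expect_lt(max(abs(res$transform$t - tf$t) / (0.5 * c(2.2, 2.2, 3))), 1)
  expect_equal(res$transform$r[3], 3, tolerance = 0.5)
  expect_gte(res$mi, 0)
})
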