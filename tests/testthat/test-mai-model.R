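test_that("feature assembly is standardized once, ordered, and flag-aware", {
  fx <- graded_fixture()
  lab <- fx$phantom$truth$labels$data
  idx <- which(lab >= 1)
  feats <- assemble_features(fx$maps, idx)
  expect_identical(colnames(feats), c("t2w_norm", "adc", "ktrans", "ve", "kep"))
  st <- attr(feats, "standardize")
  expect_equal(as.numeric(colMeans(feats)), rep(0, 5), tolerance = 1e-10)
  # a voxel exactly at the standardization centre maps to the zero vector
  raw <- assemble_features(fx$maps, idx, standardize = FALSE)
  centre_row <- sweep(matrix(st$center, 1), 2, st$center)
  expect_equal(as.numeric(centre_row / st$scale), rep(0, 5))
  expect_error(assemble_features(fx$maps, integer(0)), "empty mask")
  # flagged voxels are excluded
  flagged <- which(fx$maps$flags$data > 0)
  if (length(flagged))
    expect_error(assemble_features(fx$maps, flagged[1]), "flagged")
})

test_that("raw scores equal the kernel/linear formulas computed by hand", {
  centers <- rbind(rep(0, 5), c(1, 0, 0, 0, 0))
  model <- structure(list(centers = centers, widths = c(1, 2),
                          projection = diag(2), weights = c(0.5, -0.25),
                          bias = 0.1,
                          calibration = data.frame(raw = c(-1, 1),
                                                   mai = c(0.2, 0.8)),
                          standardize = list(center = rep(0, 5),
                                             scale = rep(1, 5)),
                          feature_names = c("t2w_norm", "adc", "ktrans",
                                            "ve", "kep")),
                     class = "mai_model")
  xs <- rbind(rep(0, 5), c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  # independent arithmetic: phi_k = exp(-d^2 / (2 w_k^2)), s = w . phi + b
  want <- c(0.5 * 1 - 0.25 * exp(-1 / 8) + 0.1,
            0.5 * exp(-0.5) - 0.25 * 1 + 0.1,
            0.5 * exp(-0.5) - 0.25 * exp(-2 / 8) + 0.1)
  expect_equal(raw_malignancy_score(xs, model), want, tolerance = 1e-12)
  # single kernel at distance w activates at exp(-1/2)
  m1 <- model; m1$centers <- matrix(rep(0, 5), 1); m1$widths <- 2
  m1$projection <- diag(1); m1$weights <- 1; m1$bias <- 0
  expect_equal(raw_malignancy_score(matrix(c(2, 0, 0, 0, 0), 1), m1),
               exp(-0.5), tolerance = 1e-12)
  # zero weights: score is the bias everywhere
  m0 <- model; m0$weights <- c(0, 0)
  expect_equal(raw_malignancy_score(xs, m0), rep(0.1, 3))
  expect_error(raw_malignancy_score(matrix(0, 1, 3), model), "mismatch")
})

test_that("calibration is monotone, clamped and Gleason-anchored", {
  model <- structure(list(calibration = data.frame(
    raw = c(-2, 0, 1, 3), mai = c(0.3, 0.6, 0.8, 1.0))), class = "mai_model")
  grid <- seq(-5, 6, length.out = 400)
  out <- calibrate_to_mai(grid, model)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(calibrate_to_mai(0, model), 0.6)       # Gleason-6 anchor node
  expect_equal(calibrate_to_mai(-10, model), 0.3)     # clamped below
  expect_equal(calibrate_to_mai(10, model), 1.0)
  bad <- model; bad$calibration$mai <- c(0.3, 0.8, 0.6, 1.0)
  expect_error(calibrate_to_mai(0, bad), "increasing")
  # the anchor policy itself
  expect_equal(gleason_anchor(6:10), seq(0.6, 1.0, by = 0.1))
  expect_equal(gleason_anchor(0), 0.3)
})

test_that("training orders separable classes and is seed-deterministic", {
  set.seed(20)
  n <- 400
  x <- rbind(matrix(rnorm(n * 5, 0, 0.4), n),
             matrix(rnorm(n * 5, 2, 0.4), n))
  labels <- rep(c(0L, 8L), each = n)
  m <- mai_train(x, labels, seed = 3)
  expect_equal(m$val_rank_error, 0)
  s <- predict(m, x, type = "raw")
  expect_gt(min(s[labels == 8]), max(s[labels == 0]))
  # determinism: identical serialized models from identical inputs
  m2 <- mai_train(x, labels, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_mai_model(m, f1); write_mai_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(mai_train(x, rep(0L, 2 * n)), "2 distinct")
  expect_error(mai_train(x, rep(3L, 2 * n)), "labels")
})

test_that("model serialization round-trips bit-exactly", {
  m <- trained_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_mai_model(m, path)
  back <- read_mai_model(path)
  expect_identical(back$centers, unname(m$centers))
  expect_identical(back$weights, m$weights)
  expect_identical(back$calibration$raw, m$calibration$raw)
  expect_identical(back$standardize$center, m$standardize$center)
  set.seed(30)
  probe <- matrix(rnorm(50), 10, 5,
                  dimnames = list(NULL, m$feature_names))
  expect_identical(predict(m, probe), predict(back, probe))
})

test_that("trained model ranks grades on the phantom and respects anchors", {
  fx <- graded_fixture()
  m <- trained_model()
  lab <- fx$phantom$truth$labels$data
  idx <- maimap:::voi_indices(dim(lab), small_voi())
  feats <- assemble_features(fx$maps, idx, standardize = FALSE)
  labs <- lab[attr(feats, "index")]
  mai <- predict(m, feats)
  med <- vapply(c(1, 6, 8), function(g) stats::median(mai[labs == g]),
                numeric(1))
  expect_true(all(diff(med) > 0))     # benign < G6 < G8
  expect_lt(abs(med[2] - 0.6), 0.05)  # G6 median at the 0.6 anchor
  expect_true(all(mai >= 0 & mai <= 1))
})

test_that("MAI map stays specific on a lesion-free phantom", {
  m <- trained_model()
  ph <- generate_phantom(small_spec(seed = 55))
  mai <- compute_mai_map(ph$study, m, voi = small_voi())
  lab <- ph$truth$labels$data
  expect_lt(mean(mai$data[lab == 1] >= 0.6), 0.05)
  expect_true(all(mai$data >= 0 & mai$data <= 1))
  expect_true(same_geometry(mai, ph$study$t2w))
  # and sensitive around a high-grade lesion
  fx <- graded_fixture()
  mai2 <- compute_mai_map(fx$phantom$study, m, voi = small_voi())
  lab2 <- fx$phantom$truth$labels$data
  expect_gt(stats::median(mai2$data[lab2 == 8]),
            stats::median(mai2$data[lab2 == 1]))
})
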