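test_that("mono-exponential DWI signal matches direct evaluation", {
  expect_equal(simulate_dwi_signal(100, 1.0e-3, 0), 100)
  expect_equal(simulate_dwi_signal(100, 1.0e-3, 800), 100 * exp(-0.8),
               tolerance = 1e-12)
  b7 <- c(0, 50, 100, 150, 200, 250, 800)
  s <- simulate_dwi_signal(100, 1.6e-3, b7)
  expect_length(s, 7)
  expect_true(all(diff(s) < 0))
  expect_error(simulate_dwi_signal(-1, 1e-3, 0), "non-negative")
})

test_that("Tofts forward model matches the step-AIF closed form", {
  td <- seq(0, 300, by = 0.5)
  cp <- rep(2, length(td))                 # constant plasma concentration
  for (par in list(c(0.25, 0.35), c(0.05, 0.2), c(0.6, 0.45))) {
    kep <- par[1] / par[2]
    expect_equal(tofts_forward(par[1], par[2], cp, td),
                 par[2] * 2 * (1 - exp(-kep * td / 60)), tolerance = 1e-6)
  }
  expect_equal(simulate_dce_curve(0, 0.3, cp, td), numeric(length(td)))
  expect_error(tofts_forward(0.2, 0, cp, td), "ve")
  expect_error(tofts_forward(0.2, 0.3, cp, rev(td)), "increasing")
})

test_that("phantom spec validates lesions, grades and spacings", {
  expect_error(small_spec(lesions = list(list(center = c(0, 0, 0),
                                              semiaxes = c(5, 5, 5),
                                              gleason = 5))), "Gleason")
  expect_error(small_spec(lesions = list(list(center = c(14, 0, 0),
                                              semiaxes = c(5, 5, 5),
                                              gleason = 7))), "outside")
  expect_error(phantom_spec(spacing = list(t2w = c(0, 1, 1),
                                           dwi = c(2, 2, 3),
                                           dce = c(1.6, 1.6, 1.5))), "spacing")
})

test_that("noiseless lesion-free phantom renders exactly mono-exponential DWI", {
  spec <- small_spec(noise_sd = c(t2w = 0, dwi = 0, dce = 0),
                     texture_amp = 0, seed = 3)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels
  dwi_vox <- classify <- NULL
  # benign voxel signals across b-values, compared against the forward model
  xyz <- voxel_grid_world(ph$study$dwi[[1]])
  rel <- sweep(sweep(xyz, 2, spec$prostate_center), 2,
               spec$prostate_semiaxes, "/")
  inside <- rowSums(rel^2) <= 1
  tt <- default_tissue_table()
  for (bi in seq_along(spec$b_values)) {
    expected <- simulate_dwi_signal(tt["benign", "s0_dwi"],
                                    tt["benign", "adc"], spec$b_values[bi])
    expect_equal(unique(ph$study$dwi[[bi]]$data[inside]), expected,
                 tolerance = 1e-12)
  }
})

test_that("rasterized lesion volume agrees with the ellipsoid volume", {
  les <- list(center = c(8, 5, 0), semiaxes = c(7, 6, 5), gleason = 7)
  ph <- generate_phantom(phantom_spec(lesions = list(les), seed = 9))
  lab <- ph$truth$labels
  vox_ml <- prod(vol_spacing(lab)) / 1000
  got <- sum(lab$data == 7) * vox_ml
  want <- 4 / 3 * pi * prod(les$semiaxes) / 1000
  # voxel-centre rasterization on an anisotropic grid: a few percent of the
  # ellipsoid volume (a single 1.68 mm^3 voxel is not attainable)
  expect_lt(abs(got - want), max(0.04 * want, vox_ml))
  expect_true(same_geometry(lab, ph$study$t2w))
})

test_that("same spec and seed give bit-identical phantoms and cores", {
  spec <- small_spec(lesions = list(small_lesion()), seed = 17)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$study$t2w$data, b$study$t2w$data)
  expect_identical(a$study$dwi[[3]]$data, b$study$dwi[[3]]$data)
  expect_identical(a$study$dce[[10]]$data, b$study$dce[[10]]$data)
  ca <- sample_biopsy_cores(a$truth, seed = 5)
  cb <- sample_biopsy_cores(b$truth, seed = 5)
  expect_identical(ca, cb)
})

test_that("biopsy cores read the ground truth and model missed lesions", {
  ph <- generate_phantom(small_spec(lesions = list(small_lesion(8)), seed = 2))
  lab <- ph$truth$labels
  # core fully inside the lesion, full effective length
  expect_equal(maimap:::core_truth_grade(lab, c(4, 2, -4), c(4, 2, 4), 1.0), 8L)
  # core through benign tissue only
  expect_equal(maimap:::core_truth_grade(lab, c(-10, -8, -4), c(-10, -8, 4), 1), 0L)
  # lesion only in the distal 20%: an effective fraction of 0.7 misses it
  # (lesion spans x in [-1.5, 9.5] at y=2,z=0; the 20 mm core runs x from
  # 25.5 down to 5.5, so only its last 4 mm overlap the lesion)
  entry <- c(25.5, 2, 0); tip <- c(5.5, 2, 0)
  expect_equal(maimap:::core_truth_grade(lab, entry, tip, 0.7), 0L)
  expect_equal(maimap:::core_truth_grade(lab, entry, tip, 1.0), 8L)
  expect_error(maimap:::core_truth_grade(lab, c(200, 0, 0), c(210, 0, 0), 1),
               "outside")
})

test_that("core plan size is enforced and the schema is complete", {
  ph <- generate_phantom(small_spec(seed = 4))
  expect_error(sample_biopsy_cores(ph$truth, n_cores = 10), "16")
  cores <- sample_biopsy_cores(ph$truth, n_cores = 20, seed = 8,
                               patient_id = "px")
  expect_equal(nrow(cores), 20)
  expect_true(all(c("patient_id", "core_id", "entry_x_mm", "tip_x_mm",
                    "effective_fraction", "gleason") %in% names(cores)))
  expect_true(all(cores$effective_fraction > 0 &
                  cores$effective_fraction <= 1))
  expect_true(all(cores$gleason %in% c(0L, 6:10)))
})

test_that("cohort generator hits the configured prevalence", {
  specs <- cohort_specs(n_patients = 200, prevalence = 0.467, seed = 21)
  frac <- mean(vapply(specs, function(s) length(s$lesions) > 0, logical(1)))
  expect_lt(abs(frac - 0.467), 0.05)
  # default cohort: 45 patients, 21 positive
  s45 <- cohort_specs(seed = 3)
  expect_length(s45, 45)
  expect_equal(sum(vapply(s45, function(s) length(s$lesions) > 0,
                          logical(1))), 21)
  grades <- unlist(lapply(s45, function(s)
    vapply(s$lesions, `[[`, numeric(1), "gleason")))
  expect_true(all(grades %in% 6:9))
})
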