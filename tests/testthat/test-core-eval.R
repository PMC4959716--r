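# MAI volume with a constant value, 1 mm isotropic, origin at corner
const_mai <- function(value, d = c(30, 30, 20)) {
  volume_image(array(value, d), spacing = c(1, 1, 1),
               origin = c(0, 0, 0), modality = "mai")
}

core_row <- function(entry, tip, eff = 1, gleason = 0)
  data.frame(patient_id = "p", core_id = "c1",
             entry_x_mm = entry[1], entry_y_mm = entry[2],
             entry_z_mm = entry[3], tip_x_mm = tip[1], tip_y_mm = tip[2],
             tip_z_mm = tip[3], effective_fraction = eff, gleason = gleason)

test_that("core profiles through constant and split fields", {
  prof <- extract_core_profile(const_mai(0.3), core_row(c(5, 15, 10),
                                                        c(22, 15, 10)))
  expect_equal(prof$max, 0.3)
  expect_equal(prof$mean, 0.3)
  expect_gte(prof$max, prof$mean)
  expect_equal(sum(prof$histogram), prof$n_samples)
  # half in 0.8, half in 0.0 along x (interpolated edge midpoint x = 14.5;
  # the 20 mm core is centred on it)
  vol <- const_mai(0)
  vol$data[1:15, , ] <- 0.8
  prof2 <- extract_core_profile(vol, core_row(c(4.5, 15, 10), c(24.5, 15, 10)),
                                radius_mm = 0)
  expect_equal(prof2$max, 0.8)
  expect_lt(abs(prof2$mean - 0.4), 0.02)   # one station of discretization
  # effective fraction truncates from the entry side
  prof3 <- extract_core_profile(vol, core_row(c(4.5, 15, 10), c(24.5, 15, 10),
                                              eff = 0.5), radius_mm = 0)
  expect_gt(prof3$mean, 0.75)
  expect_error(extract_core_profile(const_mai(0.5),
                                    core_row(c(100, 100, 100),
                                             c(120, 100, 100))),
               "in-volume")
})

test_that("dual-threshold core rule gates on both features with >= ties", {
  p <- function(mx, mn) structure(list(max = mx, mean = mn),
                                  class = "core_profile")
  expect_false(classify_core(p(0.59, 0.9)))
  expect_false(classify_core(p(0.9, 0.19)))
  expect_true(classify_core(p(0.9, 0.25)))
  expect_true(classify_core(p(0.6, 0.2)))    # exact ties count as positive
  expect_error(classify_core(p(0.9, 0.5), max_threshold = 1.2))
})

test_that("raising the mean threshold never creates a positive core", {
  fx <- graded_fixture()
  m <- trained_model()
  mai <- compute_mai_map(fx$phantom$study, m, voi = small_voi())
  cores <- sample_biopsy_cores(fx$phantom$truth, n_cores = 24, seed = 12)
  lesions <- detect_lesions(mai, min_volume_ml = 0.1)
  ev <- evaluate_cores(mai, cores, lesions)
  thr <- c(0.15, 0.2, 0.3, 0.4)
  pred <- vapply(thr, function(t)
    sum(ev$max_mai >= 0.6 & ev$mean_mai >= t), integer(1))
  expect_true(all(diff(pred) <= 0))
})

test_that("lesion detection applies the volume and mean-MAI filters", {
  expect_equal(nrow(detect_lesions(const_mai(0))), 0)
  # one blob of 600 voxels at MAI 0.9 with 1.68 mm^3 voxels -> 1.008 ml
  vol <- volume_image(array(0, c(40, 40, 12)), spacing = c(0.8, 0.7, 3))
  vol$data[11:20, 11:20, 5:10] <- 0.9          # 10*10*6 = 600 voxels
  les <- detect_lesions(vol)
  expect_equal(nrow(les), 1)
  expect_equal(les$n_voxels, 600)
  expect_equal(les$volume_ml, 600 * 0.8 * 0.7 * 3 / 1000, tolerance = 1e-12)
  expect_equal(les$max_mai, 0.9)
  # a 0.4 ml blob is excluded at the default 0.5 ml minimum
  vol2 <- volume_image(array(0, c(40, 40, 12)), spacing = c(0.8, 0.7, 3))
  vol2$data[11:18, 11:20, 5:7] <- 0.9          # 240 voxels = 0.403 ml
  expect_equal(nrow(detect_lesions(vol2)), 0)
  expect_equal(nrow(detect_lesions(vol2, min_volume_ml = 0.3)), 1)
  # mean-MAI filter: a big blob of lukewarm values is not a lesion
  vol3 <- volume_image(array(0, c(40, 40, 12)), spacing = c(0.8, 0.7, 3))
  vol3$data[5:30, 5:30, 3:10] <- 0.55
  expect_equal(nrow(detect_lesions(vol3, mai_threshold = 0.5)), 0)
})

test_that("26-connectivity joins diagonal neighbours", {
  mask <- array(FALSE, c(6, 6, 6))
  mask[2, 2, 2] <- TRUE
  mask[3, 3, 3] <- TRUE              # corner-touching: joined under 26-conn
  mask[6, 6, 6] <- FALSE
  mask[5, 5, 5] <- FALSE
  lab <- maimap:::label_components_26(mask)
  expect_equal(max(lab), 1L)
  mask[6, 1, 1] <- TRUE              # isolated voxel: second component
  lab2 <- maimap:::label_components_26(mask)
  expect_equal(max(lab2), 2L)
})

test_that("patient scoring maps every evidence combination to one category", {
  lesion_df <- function(ids) {
    df <- data.frame(lesion_id = 1L, n_voxels = 100, volume_ml = 1,
                     mean_mai = 0.8, max_mai = 0.9, centroid_x_mm = 0,
                     centroid_y_mm = 0, centroid_z_mm = 0)
    df <- df[rep(1, length(ids)), , drop = FALSE]
    df$lesion_id <- ids
    df
  }
  mk_cores <- function(gleason, predicted, lesion_id)
    data.frame(patient_id = "p", core_id = paste0("c", seq_along(gleason)),
               entry_x_mm = 0, entry_y_mm = 0, entry_z_mm = 0, tip_x_mm = 1,
               tip_y_mm = 0, tip_z_mm = 0, effective_fraction = 1,
               gleason = gleason, predicted = predicted,
               lesion_id = lesion_id)
  # exhaustive rule table: (lesion sampling x core pathology x core MAI)
  cases <- list(
    # 1. confirmed lesion: path+ and MAI+ core from it -> TP
    list(les = 1L, g = 7L, pr = TRUE, lid = 1L, want = "TP"),
    # 2. no lesions, all cores negative -> TN
    list(les = NULL, g = 0L, pr = FALSE, lid = 0L, want = "TN"),
    # 3. no lesions, pathology positive -> FN
    list(les = NULL, g = 8L, pr = FALSE, lid = 0L, want = "FN"),
    # 4. lesion sampled, core path-negative -> disproved -> FP
    list(les = 1L, g = 0L, pr = TRUE, lid = 1L, want = "FP"),
    # 5. lesion sampled, core path-positive but MAI-negative -> not
    #    confirmed -> FP
    list(les = 1L, g = 7L, pr = FALSE, lid = 1L, want = "FP"),
    # 6. lesion predicted but unsampled, other cores negative -> excluded,
    #    patient TN
    list(les = 1L, g = 0L, pr = FALSE, lid = 0L, want = "TN"),
    # 7. lesion unsampled, pathology positive elsewhere -> excluded -> FN
    list(les = 1L, g = 7L, pr = FALSE, lid = 0L, want = "FN"))
  for (cs in cases) {
    les <- lesion_df(if (is.null(cs$les)) integer(0) else cs$les)
    sc <- score_patient(les, mk_cores(cs$g, cs$pr, cs$lid))
    expect_equal(sc$category, cs$want,
                 info = paste("case", cs$want, cs$g, cs$pr, cs$lid))
  }
  # two lesions: one confirmed dominates a disproved one
  cores2 <- mk_cores(c(7L, 0L), c(TRUE, TRUE), c(1L, 2L))
  expect_equal(score_patient(lesion_df(c(1L, 2L)), cores2)$category, "TP")
  # unsampled + disproved: FP (the unsampled one is excluded, not rescuing)
  cores3 <- mk_cores(0L, TRUE, 2L)
  expect_equal(score_patient(lesion_df(c(1L, 2L)), cores3)$category, "FP")
  expect_error(score_patient(lesion_df(1L),
                             data.frame(gleason = 7)), "evaluated")
})

test_that("cores CSV round trip preserves the schema", {
  ph <- generate_phantom(small_spec(seed = 6))
  cores <- sample_biopsy_cores(ph$truth, n_cores = 18, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cores_csv(cores, path)
  back <- read_cores_csv(path)
  expect_equal(back$gleason, cores$gleason)
  expect_equal(back$entry_x_mm, cores$entry_x_mm, tolerance = 1e-12)
})
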