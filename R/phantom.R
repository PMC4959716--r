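#' Tissue parameter table for the digital prostate phantom
#'
#' One row per tissue class with the generative parameters used by the forward
#' models: baseline DWI signal `s0_dwi` (a.u.), apparent diffusion coefficient
#' `adc` (mm^2/s), Tofts `ktrans` (1/min) and `ve` (fraction), T2W base
#' intensity `t2w` (a.u.) and DCE baseline signal `s0_dce` (a.u.). Values are
#' generator configuration informed by the general prostate-MRI literature
#' (benign peripheral zone ADC around 1.6e-3 mm^2/s, Ktrans around 0.05/min;
#' tumour ADC decreasing and Ktrans increasing with Gleason grade); edit the
#' table to change the simulated contrast.
#'
#' @return data.frame with row names `background`, `benign`, `g6` ... `g10`.
#' @export
default_tissue_table <- function() {
  data.frame(
    row.names = c("background", "benign", "g6", "g7", "g8", "g9", "g10"),
    s0_dwi = c(60, 100, 100, 100, 100, 100, 100),
    adc    = c(2.0e-3, 1.6e-3, 1.20e-3, 1.00e-3, 0.85e-3, 0.70e-3, 0.60e-3),
    ktrans = c(0.02, 0.05, 0.15, 0.25, 0.35, 0.45, 0.55),
    ve     = c(0.30, 0.20, 0.30, 0.35, 0.40, 0.45, 0.50),
    t2w    = c(60, 120, 95, 85, 75, 68, 62),
    s0_dce = c(80, 100, 100, 100, 100, 100, 100))
}

#' Specification of one synthetic multiparametric prostate study
#'
#' Acquisition geometry defaults follow a 3T protocol: T2W 0.8 x 0.7 mm pixels
#' with 3 mm slices, DWI 2.2 x 2.2 x 3 mm with b-values
#' 0,50,100,150,200,250,800 s/mm^2, DCE 1.6 x 1.6 x 1.5 mm sampled every
#' 9.9 s. All grids share a patient-based world frame centred on the prostate.
#'
#' @param shape named list of 3-vectors: voxels per axis for `t2w`, `dwi`, `dce`.
#' @param spacing named list of 3-vectors: voxel spacing in mm per modality.
#' @param prostate_center world centre of the prostate ellipsoid (mm).
#' @param prostate_semiaxes ellipsoid semi-axes (mm); the default encloses
#'   about 45 cm^3.
#' @param lesions list of lesions, each `list(center=, semiaxes=, gleason=)`
#'   (mm, mm, integer 6..10). Must lie inside the prostate.
#' @param tissue tissue parameter table, see [default_tissue_table()].
#' @param noise_sd named vector of additive Gaussian noise SDs per modality
#'   (a.u.).
#' @param b_values DWI b-values (s/mm^2).
#' @param dce_interval_s DCE frame spacing (s).
#' @param dce_frames number of DCE frames.
#' @param aif list of arguments for [aif_biexponential()] (onset_s, dose, ...).
#' @param dce_gain signal-enhancement constant: DCE signal is
#'   `s0_dce * (1 + dce_gain * Ct)` with Ct in mmol/L.
#' @param misregistration optional [affine9()] transform injected into the DWI
#'   and DCE series (the transform that registration should recover), or NULL.
#' @param texture_amp amplitude of the smooth multiplicative intensity texture
#'   (a low-frequency sinusoidal field fixed in anatomy coordinates) applied
#'   to the T2W, DWI and DCE baseline signals. It stands in for internal
#'   anatomy so that registration is well conditioned; it cancels exactly in
#'   the ADC log-slope and in the DCE enhancement ratio. 0 disables it.
#' @param seed integer RNG seed; same spec + seed gives bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = list(t2w = c(72, 72, 16),
                                      dwi = c(26, 26, 16),
                                      dce = c(36, 36, 32)),
                         spacing = list(t2w = c(0.8, 0.7, 3.0),
                                        dwi = c(2.2, 2.2, 3.0),
                                        dce = c(1.6, 1.6, 1.5)),
                         prostate_center = c(0, 0, 0),
                         prostate_semiaxes = c(25, 21, 20.5),
                         lesions = list(),
                         tissue = default_tissue_table(),
                         noise_sd = c(t2w = 4, dwi = 2, dce = 2),
                         b_values = c(0, 50, 100, 150, 200, 250, 800),
                         dce_interval_s = 9.9,
                         dce_frames = 32,
                         aif = list(onset_s = 60, dose = 0.1),
                         dce_gain = 4.5,
                         misregistration = NULL,
                         texture_amp = 0.15,
                         seed = 1L) {
  for (m in c("t2w", "dwi", "dce")) {
    if (any(spacing[[m]] <= 0)) stop("spacings must be > 0")
    if (any(shape[[m]] < 2)) stop("grid shapes must be >= 2 per axis")
  }
  if (any(prostate_semiaxes <= 0)) stop("prostate semi-axes must be > 0")
  for (L in lesions) {
    if (!(L$gleason %in% 6:10)) stop("Gleason grade must be in 6..10")
    if (any(L$semiaxes <= 0)) stop("lesion semi-axes must be > 0")
    # conservative containment: bounding offsets inside the prostate ellipsoid
    rel <- (abs(L$center - prostate_center) + L$semiaxes) / prostate_semiaxes
    if (sum(rel^2) > 1 + 1e-9) stop("lesion ellipsoid outside the prostate")
  }
  if (any(tissue$ve <= 0 | tissue$ve > 1)) stop("tissue ve must be in (0,1]")
  if (dce_frames < 2) stop("need at least 2 DCE frames")
  structure(list(shape = shape, spacing = spacing,
                 prostate_center = prostate_center,
                 prostate_semiaxes = prostate_semiaxes, lesions = lesions,
                 tissue = tissue, noise_sd = noise_sd, b_values = b_values,
                 dce_interval_s = dce_interval_s, dce_frames = dce_frames,
                 aif = aif, dce_gain = dce_gain,
                 misregistration = misregistration,
                 texture_amp = texture_amp, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Mono-exponential diffusion-weighted signal
#'
#' S(b) = S0 exp(-b * ADC), the forward model underlying ADC mapping from
#' multi-b DWI.
#'
#' @param s0 signal at b = 0 (a.u.), >= 0.
#' @param adc apparent diffusion coefficient (mm^2/s), >= 0.
#' @param b b-value (s/mm^2), >= 0. Any argument may be a vector.
#' @return signal in a.u.
#' @export
simulate_dwi_signal <- function(s0, adc, b) {
  if (any(s0 < 0) || any(adc < 0) || any(b < 0))
    stop("s0, adc and b must be non-negative")
  s0 * exp(-b * adc)
}

#' Simulated DCE tissue concentration curve
#'
#' The two-compartment Tofts forward model; identical to [tofts_forward()]
#' (one shared implementation).
#'
#' @inheritParams tofts_forward
#' @export
simulate_dce_curve <- function(ktrans, ve, aif, times_s) {
  tofts_forward(ktrans, ve, aif, times_s)
}

# Centered grid affine: world frame centred on `center`, axis-aligned.
centered_affine <- function(shape, spacing, center = c(0, 0, 0)) {
  origin <- center - (shape - 1) * spacing / 2
  rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
}

# Classify world points into tissue classes. Returns integer codes:
# 0 background, 1 benign prostate, g = Gleason grade for lesion points.
classify_points <- function(xyz, spec) {
  lab <- integer(nrow(xyz))
  rel <- sweep(xyz, 2, spec$prostate_center)
  rel <- sweep(rel, 2, spec$prostate_semiaxes, "/")
  lab[rowSums(rel^2) <= 1] <- 1L
  for (L in spec$lesions) {
    rel <- sweep(xyz, 2, L$center)
    rel <- sweep(rel, 2, L$semiaxes, "/")
    inside <- rowSums(rel^2) <= 1
    lab[inside] <- pmax(lab[inside], as.integer(L$gleason))
  }
  lab
}

# label code -> row name of the tissue table
label_to_class <- function(lab) {
  cls <- rep("background", length(lab))
  cls[lab == 1L] <- "benign"
  cls[lab >= 6L] <- paste0("g", lab[lab >= 6L])
  cls
}

#' Generate one synthetic multiparametric study with ground truth
#'
#' Renders T2W, multi-b DWI and dynamic DCE volumes from the spec's tissue
#' table through the mono-exponential diffusion and Tofts forward models, adds
#' independent Gaussian noise per modality, and (optionally) injects a known
#' affine misregistration into the DWI/DCE series. The ground truth (label
#' volume, true parameter maps, injected transform) lives on the T2W grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `study` (fields `t2w`, `dwi` = list of
#'   [volume_image()] per b-value, `dce` = list per frame, `b_values`,
#'   `dce_times_s`, `aif`) and `truth` (fields `labels`, `maps`,
#'   `misregistration`, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    tt <- spec$tissue
    aff <- lapply(c(t2w = "t2w", dwi = "dwi", dce = "dce"), function(m)
      centered_affine(spec$shape[[m]], spec$spacing[[m]], spec$prostate_center))

    # anatomy coordinates: secondary modalities are rendered at T^-1(world) so
    # that resampling through the injected transform T re-aligns them
    misreg_inv <- if (!is.null(spec$misregistration))
      solve(affine9_matrix(spec$misregistration)) else NULL
    grid_world <- function(m, misreg = FALSE) {
      vol <- volume_image(array(0, spec$shape[[m]]), affine = aff[[m]])
      xyz <- voxel_grid_world(vol)
      if (misreg && !is.null(misreg_inv))
        xyz <- t(misreg_inv[1:3, 1:3] %*% t(xyz) + misreg_inv[1:3, 4])
      xyz
    }

    # --- truth on the T2W grid (primary frame: no misregistration) ---
    xyz_t2w <- grid_world("t2w")
    lab_t2w <- classify_points(xyz_t2w, spec)
    cls_t2w <- label_to_class(lab_t2w)
    labels <- volume_image(array(as.double(lab_t2w), spec$shape$t2w),
                           affine = aff$t2w, modality = "labels")
    true_map <- function(col, mod) volume_image(
      array(tt[cls_t2w, col], spec$shape$t2w), affine = aff$t2w, modality = mod)
    maps <- list(adc = true_map("adc", "adc"),
                 ktrans = true_map("ktrans", "ktrans"),
                 ve = true_map("ve", "ve"),
                 kep = volume_image(array(tt[cls_t2w, "ktrans"] /
                                          tt[cls_t2w, "ve"], spec$shape$t2w),
                                    affine = aff$t2w, modality = "kep"),
                 s0_dwi = true_map("s0_dwi", "s0"))

    noise <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    # smooth multiplicative texture, fixed in anatomy coordinates
    texture <- function(xyz) {
      if (spec$texture_amp == 0) return(1)
      1 + spec$texture_amp *
        sin(2 * pi * xyz[, 1] / 17 + 0.7) *
        sin(2 * pi * xyz[, 2] / 19 + 1.3) *
        sin(2 * pi * xyz[, 3] / 23 + 2.1)
    }

    # --- T2W ---
    n_t2w <- prod(spec$shape$t2w)
    tex_t2w <- texture(xyz_t2w)
    t2w <- volume_image(
      array(pmax(tt[cls_t2w, "t2w"] * tex_t2w +
                 noise(n_t2w, spec$noise_sd[["t2w"]]), 0),
            spec$shape$t2w), affine = aff$t2w, modality = "t2w")

    # --- DWI: one volume per b-value ---
    xyz_dwi <- grid_world("dwi", TRUE)
    cls_dwi <- label_to_class(classify_points(xyz_dwi, spec))
    tex_dwi <- texture(xyz_dwi)
    n_dwi <- prod(spec$shape$dwi)
    dwi <- lapply(spec$b_values, function(b) {
      s <- simulate_dwi_signal(tt[cls_dwi, "s0_dwi"], tt[cls_dwi, "adc"], b)
      volume_image(array(pmax(s * tex_dwi + noise(n_dwi, spec$noise_sd[["dwi"]]), 0),
                         spec$shape$dwi), affine = aff$dwi, modality = "dwi")
    })

    # --- DCE: per-class curves, one volume per frame ---
    times <- (seq_len(spec$dce_frames) - 1) * spec$dce_interval_s
    aifv <- do.call(aif_biexponential, c(list(times_s = times), spec$aif))
    curves <- sapply(rownames(tt), function(cl) {
      ct <- tofts_forward(tt[cl, "ktrans"], tt[cl, "ve"], aifv, times)
      tt[cl, "s0_dce"] * (1 + spec$dce_gain * ct)
    })  # frames x classes
    xyz_dce <- grid_world("dce", TRUE)
    cls_dce <- label_to_class(classify_points(xyz_dce, spec))
    tex_dce <- texture(xyz_dce)
    n_dce <- prod(spec$shape$dce)
    dce <- lapply(seq_len(spec$dce_frames), function(f)
      volume_image(array(pmax(curves[f, cls_dce] * tex_dce +
                              noise(n_dce, spec$noise_sd[["dce"]]), 0),
                         spec$shape$dce), affine = aff$dce, modality = "dce"))

    list(study = list(t2w = t2w, dwi = dwi, dce = dce,
                      b_values = spec$b_values, dce_times_s = times,
                      aif = aifv, dce_gain = spec$dce_gain,
                      aif_onset_s = spec$aif$onset_s %||% 60),
         truth = list(labels = labels, maps = maps,
                      misregistration = spec$misregistration, spec = spec))
  })
}

#' Simulate transperineal biopsy cores against a phantom's ground truth
#'
#' Cores are 3D segments (entry to tip) of nominal length, oriented roughly
#' along +z (the transperineal approach), combining targeted cores through each
#' lesion with a systematic grid over the prostate cross-section. A seeded
#' effective-length fraction (Beta(8,2), mean 0.8) truncates each core from
#' the entry side; the pathology result is the maximum ground-truth grade among
#' voxels intersected by the effective segment (sampled every 0.5 mm within a
#' 1 mm radius), or 0 when only benign tissue is hit. This reproduces the
#' false-negative mechanism of limited effective core length: a lesion touched
#' only by the truncated distal part of a core is missed.
#'
#' @param truth `truth` element from [generate_phantom()].
#' @param n_cores total cores to take, between 16 and 36.
#' @param targeted if TRUE, aim 2 cores at each true lesion first.
#' @param nominal_length_mm nominal core length (mm).
#' @param seed RNG seed.
#' @param patient_id identifier copied into the output.
#' @return data.frame with columns patient_id, core_id, entry_x/y/z_mm,
#'   tip_x/y/z_mm, effective_fraction, gleason (0 = negative).
#' @export
sample_biopsy_cores <- function(truth, n_cores = 24, targeted = TRUE,
                                nominal_length_mm = 17, seed = 1L,
                                patient_id = "p01") {
  if (n_cores < 16 || n_cores > 36)
    stop("core count must be between 16 and 36")
  spec <- truth$spec
  with_seed(seed, {
    L <- nominal_length_mm
    entries <- list()
    mk_core <- function(center_xy, z_mid) {
      jitter <- stats::rnorm(2, 0, 0.8)
      dir <- c(stats::rnorm(2, 0, 0.05), 1)
      dir <- dir / sqrt(sum(dir^2))
      entry <- c(center_xy + jitter, z_mid) - dir * L / 2
      list(entry = entry, tip = entry + dir * L)
    }
    if (targeted) for (les in spec$lesions)
      for (r in 1:2) entries <- c(entries, list(mk_core(les$center[1:2],
                                                        les$center[3])))
    n_sys <- n_cores - length(entries)
    if (n_sys < 0) { entries <- entries[seq_len(n_cores)]; n_sys <- 0 }
    # systematic grid over the prostate cross-section
    ax <- spec$prostate_semiaxes; ctr <- spec$prostate_center
    g <- ceiling(sqrt(n_sys * 2))
    gx <- seq(-0.8, 0.8, length.out = g)
    cand <- expand.grid(x = gx, y = gx)
    cand <- cand[cand$x^2 + cand$y^2 <= 0.81, , drop = FALSE]
    idx <- rep_len(seq_len(nrow(cand)), n_sys)
    for (i in idx)
      entries <- c(entries, list(mk_core(
        c(ctr[1] + cand$x[i] * ax[1], ctr[2] + cand$y[i] * ax[2]), ctr[3])))

    eff <- stats::rbeta(length(entries), 8, 2)
    lab <- truth$labels
    res <- lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      g6 <- core_truth_grade(lab, e$entry, e$tip, eff[i])
      data.frame(patient_id = patient_id,
                 core_id = sprintf("%s_c%02d", patient_id, i),
                 entry_x_mm = e$entry[1], entry_y_mm = e$entry[2],
                 entry_z_mm = e$entry[3],
                 tip_x_mm = e$tip[1], tip_y_mm = e$tip[2],
                 tip_z_mm = e$tip[3],
                 effective_fraction = eff[i], gleason = g6)
    })
    do.call(rbind, res)
  })
}

# Max ground-truth grade intersected by the effective segment of a core
# (entry -> entry + f*(tip-entry)), nearest-voxel lookup every 0.5 mm at the
# axis and 4 radial offsets of 1 mm. Returns 0 for benign/background only.
core_truth_grade <- function(labels, entry, tip, effective_fraction,
                             step_mm = 0.5, radius_mm = 1) {
  pts <- core_sample_points(entry, tip, effective_fraction, step_mm, radius_mm)
  ijk <- round(world_to_voxel(labels, pts))
  d <- dim(labels$data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  if (!any(ok)) stop("biopsy core entirely outside the label volume")
  v <- labels$data[1 + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])]
  g <- max(v)
  if (g >= 6) as.integer(g) else 0L
}

# Sample points along the effective segment: stations every step_mm, each with
# the axial point plus n_radial offsets at radius_mm (radius 0 = axis only).
core_sample_points <- function(entry, tip, effective_fraction = 1,
                               step_mm = 0.5, radius_mm = 1, n_radial = 4) {
  stopifnot(effective_fraction > 0, effective_fraction <= 1)
  end <- entry + effective_fraction * (tip - entry)
  len <- sqrt(sum((end - entry)^2))
  if (len == 0) stop("degenerate core: entry equals tip")
  nst <- max(2L, 1L + ceiling(len / step_mm))
  tfrac <- seq(0, 1, length.out = nst)
  axis_pts <- cbind(entry[1] + tfrac * (end[1] - entry[1]),
                    entry[2] + tfrac * (end[2] - entry[2]),
                    entry[3] + tfrac * (end[3] - entry[3]))
  if (radius_mm <= 0) return(axis_pts)
  u <- (end - entry) / len
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v1 <- a - sum(a * u) * u; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  ang <- 2 * pi * (seq_len(n_radial) - 1) / n_radial
  pts <- axis_pts
  for (t in ang) {
    off <- radius_mm * (cos(t) * v1 + sin(t) * v2)
    pts <- rbind(pts, sweep(axis_pts, 2, off, "+"))
  }
  pts
}

#' Build phantom specs for a synthetic patient cohort
#'
#' Emulates the study population: `n_patients` studies of which exactly
#' `round(prevalence * n_patients)` carry cancer (default 45 patients at 46.7%
#' prevalence, i.e. 21 positives), with 1-3 lesions per positive patient,
#' Gleason grades drawn from {6,7,8,9} with median 7, lesion volumes 0.4-2.5
#' cm^3 and per-patient prostate volumes between about 25 and 70 cm^3. Which
#' patients are positive is a seeded permutation, so the cohort prevalence is
#' exact by construction while patient order is random.
#'
#' @param n_patients cohort size.
#' @param prevalence fraction of cancer-positive patients.
#' @param seed cohort-level seed; each patient receives a derived seed.
#' @param misregister if TRUE each patient gets a small random injected
#'   misregistration (|t| <= 3 mm, |r| <= 3 deg).
#' @param base_semiaxes median prostate ellipsoid semi-axes (mm); lesion
#'   volumes scale with the implied prostate volume.
#' @param ... overrides passed on to [phantom_spec()] (e.g. `shape`,
#'   `noise_sd`).
#' @return list of `phantom_spec`, one per patient, with names p01, p02, ...
#' @export
cohort_specs <- function(n_patients = 45, prevalence = 0.467, seed = 1L,
                         misregister = FALSE,
                         base_semiaxes = c(25, 21, 20.5), ...) {
  n_pos <- round(n_patients * prevalence)
  with_seed(seed, {
    pos <- rep(FALSE, n_patients)
    pos[sample.int(n_patients, n_pos)] <- TRUE
    grades <- c(6, 7, 7, 8, 9)      # draw pool, median 7
    base_ax <- base_semiaxes
    rel_vol <- prod(base_ax) / prod(c(25, 21, 20.5))
    lapply(seq_len(n_patients), function(i) {
      pv_scale <- stats::runif(1, 0.82, 1.16)   # prostate volume ~25-70 cm^3
      ax <- base_ax * pv_scale
      lesions <- list()
      if (pos[i]) {
        n_les <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
        for (k in seq_len(n_les)) {
          vol_ml <- rel_vol * exp(stats::runif(1, log(0.4), log(2.5)))
          r <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
          aniso <- stats::runif(3, 0.8, 1.25)
          semi <- r * aniso / prod(aniso)^(1 / 3)
          ok <- FALSE
          for (try in 1:50) {
            u <- stats::runif(3, -0.6, 0.6)
            ctr <- u * ax
            if (sum(((abs(ctr) + semi) / ax)^2) <= 1) { ok <- TRUE; break }
          }
          if (!ok) ctr <- c(0, 0, 0)  # central placement always contained
          lesions <- c(lesions, list(list(center = ctr, semiaxes = semi,
                                          gleason = sample(grades, 1))))
        }
      }
      misreg <- NULL
      if (misregister)
        misreg <- affine9(t = stats::runif(3, -3, 3),
                          r = stats::runif(3, -3, 3),
                          s = stats::runif(3, 0.97, 1.03))
      phantom_spec(prostate_semiaxes = ax, prostate_center = c(0, 0, 0),
                   lesions = lesions, misregistration = misreg,
                   seed = child_seed(seed, i), ...)
    }) |> stats::setNames(sprintf("p%02d", seq_len(n_patients)))
  })
}
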