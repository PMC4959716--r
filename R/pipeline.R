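#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run. Round-trips through YAML/JSON.
#'
#' @param n_patients synthetic cohort size (simulation runs).
#' @param prevalence cancer prevalence of the simulated cohort.
#' @param max_threshold fixed max-MAI gate (default 0.6).
#' @param mean_threshold operating mean-MAI gate (default 0.2).
#' @param threshold_sweep mean-MAI thresholds for the ROC table.
#' @param voi VOI box (`list(x=,y=,z=)`, 0-based half-open) or NULL for an
#'   automatic box around the prostate.
#' @param register run MI affine registration (TRUE) or trust the volume
#'   geometry (FALSE).
#' @param misregister inject random misregistrations into the simulated
#'   studies (exercises the registration stage).
#' @param train_patients number of cohort patients whose voxels train the
#'   model (the remainder are evaluated only).
#' @param voxels_per_class training voxels subsampled per tissue class.
#' @param min_lesion_volume_ml minimum predicted-lesion volume (ml) for
#'   clinical relevance (default 0.5).
#' @param model_path optional path of a serialized model to reuse instead of
#'   training.
#' @param output_dir artifact directory.
#' @param seed master seed.
#' @param registration_options list passed to [register_affine()].
#' @param ... overrides stored as-is (e.g. `shape`, `noise_sd` forwarded to
#'   [phantom_spec()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 6, prevalence = 0.5,
                            max_threshold = 0.6, mean_threshold = 0.2,
                            threshold_sweep = c(0.15, 0.2, 0.3, 0.4),
                            voi = NULL, register = FALSE, misregister = FALSE,
                            train_patients = ceiling(n_patients / 2),
                            voxels_per_class = 400,
                            min_lesion_volume_ml = 0.5,
                            model_path = NULL, output_dir = tempfile("maimap_"),
                            seed = 1L,
                            registration_options = list(max_iter = 40,
                                                        n_samples = 8000),
                            ...) {
  thr <- c(max_threshold, mean_threshold, threshold_sweep)
  if (any(thr < 0 | thr > 1)) stop("thresholds must be in [0, 1]")
  structure(c(list(n_patients = n_patients, prevalence = prevalence,
                   max_threshold = max_threshold,
                   mean_threshold = mean_threshold,
                   threshold_sweep = threshold_sweep, voi = voi,
                   register = register, misregister = misregister,
                   train_patients = train_patients,
                   voxels_per_class = voxels_per_class,
                   min_lesion_volume_ml = min_lesion_volume_ml,
                   model_path = model_path, output_dir = output_dir,
                   seed = as.integer(seed),
                   registration_options = registration_options),
              list(...)), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#' @param config a [pipeline_config()].
#' @param path file ending in .yaml/.yml or .json.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

# automatic VOI: bounding box of the prostate ellipsoid plus margin, clipped
auto_voi <- function(spec, vol) {
  lo <- spec$prostate_center - spec$prostate_semiaxes - 3
  hi <- spec$prostate_center + spec$prostate_semiaxes + 3
  d <- dim(vol$data)
  ij <- world_to_voxel(vol, rbind(lo, hi))
  list(x = c(max(floor(min(ij[, 1])), 0), min(ceiling(max(ij[, 1])) + 1, d[1])),
       y = c(max(floor(min(ij[, 2])), 0), min(ceiling(max(ij[, 2])) + 1, d[2])),
       z = c(max(floor(min(ij[, 3])), 0), min(ceiling(max(ij[, 3])) + 1, d[3])))
}

# Stratified voxel subsample for training, seeded. The whole VOI is eligible:
# periprostatic background and benign prostate both carry the non-cancer
# label, so the classifier sees everything the VOI will contain at
# prediction time. Sampling is stratified over background / benign / each
# grade to keep the classes balanced.
training_voxels <- function(truth, maps, per_class, seed, voi = NULL) {
  lab <- truth$labels$data
  idx_all <- voi_indices(dim(lab), voi)
  feats <- assemble_features(maps, idx_all, standardize = FALSE)
  idx <- attr(feats, "index")
  strata <- lab[idx]                   # 0 bg, 1 benign, >=6 grades
  labs <- ifelse(strata >= 6, strata, 0)
  with_seed(seed, {
    take <- unlist(lapply(sort(unique(strata)), function(g) {
      w <- which(strata == g)
      if (length(w) > per_class) sample(w, per_class) else w
    }))
    list(x = feats[take, , drop = FALSE], labels = as.integer(labs[take]))
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a seeded phantom cohort, optionally registers the functional
#' series, computes parametric maps and MAI maps, trains (or loads) the MAI
#' model on the training patients, evaluates every patient's biopsy cores at
#' the configured threshold sweep, scores patients, and assembles the
#' diagnostic table. All artifacts are written under `config$output_dir`; the
#' machine-readable `summary.json` is byte-identical across reruns with the
#' same config and seed.
#'
#' @param config a [pipeline_config()].
#' @param progress print stage progress.
#' @return list with `model`, `sweep` (a `threshold_sweep`),
#'   `patients` (per-patient categories at each threshold), `cores`
#'   (all evaluated cores), `class_mai` (seeded per-class MAI voxel subsample
#'   against ground truth, for congruence checks) and `summary_path`.
#' @export
run_pipeline <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message(sprintf(...))

  extra <- config[setdiff(names(config), names(formals(pipeline_config)))]
  extra <- extra[setdiff(names(extra), "")]
  specs <- do.call(cohort_specs,
                   c(list(n_patients = config$n_patients,
                          prevalence = config$prevalence,
                          seed = config$seed,
                          misregister = config$misregister), extra))

  say("simulating %d patients", length(specs))
  phantoms <- lapply(specs, generate_phantom)
  cores_by_pt <- lapply(seq_along(phantoms), function(i)
    sample_biopsy_cores(phantoms[[i]]$truth,
                        n_cores = 16 + ((config$seed + i * 7) %% 21),
                        seed = child_seed(config$seed, 1000 + i),
                        patient_id = names(specs)[i]))

  say("computing parametric maps")
  maps_by_pt <- vector("list", length(phantoms))
  tf_by_pt <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    st <- phantoms[[i]]$study
    voi <- config$voi %||% auto_voi(specs[[i]], st$t2w)
    tf_dwi <- affine9(); tf_dce <- affine9()
    if (config$register) {
      ro <- config$registration_options
      tf_dwi <- do.call(register_affine,
                        c(list(st$t2w, st$dwi[[1]]), ro))$transform
      post <- which(st$dce_times_s >= (st$aif_onset_s %||% 60))[1]
      tf_dce <- do.call(register_affine,
                        c(list(st$t2w, st$dce[[post]]), ro))$transform
    }
    tf_by_pt[[i]] <- list(dwi = tf_dwi, dce = tf_dce)
    maps_by_pt[[i]] <- compute_parametric_maps(st, dwi_transform = tf_dwi,
                                               dce_transform = tf_dce,
                                               voi = voi)
  }

  if (!is.null(config$model_path)) {
    say("loading model %s", config$model_path)
    model <- read_mai_model(config$model_path)
  } else {
    say("training MAI model on %d patients", config$train_patients)
    tset <- lapply(seq_len(min(config$train_patients, length(phantoms))),
                   function(i) training_voxels(phantoms[[i]]$truth,
                                               maps_by_pt[[i]],
                                               config$voxels_per_class,
                                               child_seed(config$seed, 2000 + i),
                                               voi = config$voi %||%
                                                 auto_voi(specs[[i]],
                                                          phantoms[[i]]$study$t2w)))
    x <- do.call(rbind, lapply(tset, `[[`, "x"))
    labels <- unlist(lapply(tset, `[[`, "labels"))
    model <- mai_train(x, labels, standardize = TRUE,
                       seed = child_seed(config$seed, 3000))
  }
  write_mai_model(model, file.path(config$output_dir, "model.json"))

  say("scoring patients")
  sweep_thr <- config$threshold_sweep
  cats <- matrix(NA_character_, length(phantoms), length(sweep_thr),
                 dimnames = list(names(specs), paste0("thr", sweep_thr)))
  all_cores <- list()
  class_mai <- list()
  for (i in seq_along(phantoms)) {
    st <- phantoms[[i]]$study
    voi <- config$voi %||% auto_voi(specs[[i]], st$t2w)
    mai <- compute_mai_map(st, model, voi = voi, maps = maps_by_pt[[i]])
    # per-class MAI subsample against ground truth (for congruence checks)
    lab_i <- phantoms[[i]]$truth$labels$data
    vidx <- voi_indices(dim(lab_i), voi)
    class_mai[[i]] <- with_seed(child_seed(config$seed, 4000 + i), {
      strat <- lab_i[vidx]
      take <- unlist(lapply(sort(unique(strat)), function(g) {
        w <- which(strat == g)
        if (length(w) > 300) sample(w, 300) else w
      }))
      data.frame(patient = names(specs)[i], label = strat[take],
                 mai = mai$data[vidx[take]])
    })
    lesions <- detect_lesions(mai, mai_threshold = config$max_threshold,
                              min_volume_ml = config$min_lesion_volume_ml)
    ev0 <- evaluate_cores(mai, cores_by_pt[[i]], lesions,
                          max_threshold = config$max_threshold,
                          mean_threshold = config$mean_threshold)
    all_cores[[i]] <- ev0
    for (t in seq_along(sweep_thr)) {
      ev <- ev0
      ev$predicted <- ev$max_mai >= config$max_threshold &
                      ev$mean_mai >= sweep_thr[t]
      cats[i, t] <- score_patient(lesions, ev)$category
    }
  }
  cores_df <- do.call(rbind, all_cores)
  write_cores_csv(cores_df, file.path(config$output_dir, "cores.csv"))

  sweep <- threshold_sweep_table(cats, sweep_thr)
  summary_path <- file.path(config$output_dir, "summary.json")
  write_summary_json(sweep, cats, config, summary_path)
  say("done: %s", summary_path)
  list(model = model, sweep = sweep, patients = cats, cores = cores_df,
       class_mai = do.call(rbind, class_mai), summary_path = summary_path)
}

# deterministic machine-readable summary (sorted names, fixed precision)
write_summary_json <- function(sweep, cats, config, path) {
  per_thr <- lapply(seq_along(sweep$thresholds), function(i) {
    s <- sweep$summaries[[i]]; y <- sweep$youden[[i]]; cc <- sweep$counts[[i]]
    list(mean_threshold = sweep$thresholds[i],
         counts = list(TP = cc$tp, FN = cc$fn, TN = cc$tn, FP = cc$fp),
         sensitivity_pct = pct(s$estimate[["sensitivity"]]),
         sensitivity_ci_pct = as.numeric(pct(s$ci["sensitivity", ])),
         specificity_pct = pct(s$estimate[["specificity"]]),
         specificity_ci_pct = as.numeric(pct(s$ci["specificity", ])),
         accuracy_pct = pct(s$estimate[["accuracy"]]),
         accuracy_ci_pct = as.numeric(pct(s$ci["accuracy", ])),
         youden_pct = pct(y$j),
         youden_ci_pct = as.numeric(pct(y$ci)))
  })
  payload <- list(package = "maimap", seed = config$seed,
                  n_patients = nrow(cats),
                  max_threshold = config$max_threshold,
                  thresholds = per_thr,
                  auc = round_half_up(sweep$auc, 4),
                  optimum_mean_threshold = sweep$optimum,
                  patient_categories = apply(cats, 1, paste, collapse = ","))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Render an MAI overlay on a T2W slice as PNG
#'
#' Grayscale T2W with a blue-to-red colour map over MAI; voxels below the
#' display threshold stay fully transparent so only suspicious tissue is
#' coloured.
#'
#' @param t2w,mai [volume_image()]s sharing geometry.
#' @param slice 1-based slice index (third axis).
#' @param path output PNG path.
#' @param display_threshold MAI below this is not rendered (default 0.2, the
#'   lowest reported operating threshold).
#' @param alpha overlay opacity for shown voxels.
#' @return the path, invisibly.
#' @export
export_overlay <- function(t2w, mai, slice, path, display_threshold = 0.2,
                           alpha = 0.55) {
  if (!same_geometry(t2w, mai, tol = 1e-4)) stop("geometry mismatch")
  d <- dim(t2w$data)
  if (slice < 1 || slice > d[3]) stop("slice out of range")
  g <- t2w$data[, , slice]
  rng <- range(g); if (diff(rng) == 0) rng <- rng + c(0, 1)
  g <- (g - rng[1]) / diff(rng)
  m <- pmin(pmax(mai$data[, , slice], 0), 1)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))(as.vector(m))
  show <- as.vector(m >= display_threshold)
  r <- ifelse(show, (1 - alpha) * g + alpha * ramp[, 1] / 255, g)
  gr <- ifelse(show, (1 - alpha) * g + alpha * ramp[, 2] / 255, g)
  b <- ifelse(show, (1 - alpha) * g + alpha * ramp[, 3] / 255, g)
  # image rows = y, columns = x; transpose and flip for conventional display
  img <- array(0, c(d[2], d[1], 3))
  img[, , 1] <- t(matrix(r, d[1]))[d[2]:1, ]
  img[, , 2] <- t(matrix(gr, d[1]))[d[2]:1, ]
  img[, , 3] <- t(matrix(b, d[1]))[d[2]:1, ]
  png::writePNG(img, path)
  invisible(path)
}

#' Compact bundled demonstration cohort configuration
#'
#' A 6-patient pipeline configuration on reduced grids (48 x 48 x 12 T2W at
#' the standard spacings, with a correspondingly smaller prostate), sized so
#' that the complete pipeline runs in well under a minute. Used by the
#' examples and the end-to-end determinism checks.
#'
#' @param seed master seed.
#' @param output_dir artifact directory.
#' @param ... overrides for [pipeline_config()].
#' @export
fixture_config <- function(seed = 1L, output_dir = tempfile("maimap_demo_"),
                           ...) {
  pipeline_config(n_patients = 6, prevalence = 0.5, seed = seed,
                  output_dir = output_dir,
                  shape = list(t2w = c(48, 48, 12), dwi = c(18, 18, 12),
                               dce = c(24, 24, 24)),
                  base_semiaxes = c(15, 13, 12.5),
                  min_lesion_volume_ml = 0.12,
                  voxels_per_class = 300,
                  ...)
}
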