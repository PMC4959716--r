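#' MAI profile of a biopsy core
#'
#' Samples the MAI map along the core's effective segment (entry towards tip,
#' truncated by the effective-length fraction) at `step_mm` intervals. At each
#' station the map is read by trilinear interpolation and averaged over
#' `n_radial` offsets at `radius_mm` around the core axis (radius 0 samples
#' the axis only). The profile's summary features are its maximum and mean
#' MAI; a histogram over fixed bin edges 0, 0.05, ..., 1 is attached.
#'
#' @param mai MAI [volume_image()].
#' @param core one-row data.frame in the biopsy-core schema (see
#'   [sample_biopsy_cores()]) or a list with `entry`, `tip`,
#'   `effective_fraction`.
#' @param step_mm sampling step along the core (mm).
#' @param radius_mm radial averaging radius (mm).
#' @param n_radial number of radial offsets averaged per station.
#' @return object of class `core_profile`: list with `values` (per-station
#'   MAI), `max`, `mean`, `histogram`, `n_samples`.
#' @export
extract_core_profile <- function(mai, core, step_mm = 0.5, radius_mm = 1,
                                 n_radial = 4) {
  g <- core_geometry(core)
  pts <- core_sample_points(g$entry, g$tip, g$effective_fraction,
                            step_mm, radius_mm, n_radial)
  vals <- sample_world(mai, pts, fill = NA_real_)
  inside <- attr(vals, "inside")
  n_st <- nrow(pts) / (if (radius_mm > 0) n_radial + 1 else 1)
  vm <- matrix(vals, nrow = n_st)          # stations x (1 + n_radial) rings
  station <- rowMeans(vm, na.rm = TRUE)
  station <- station[is.finite(station)]
  if (length(station) == 0) stop("core has no in-volume samples")
  edges <- seq(0, 1, by = 0.05)
  structure(list(values = station, max = max(station), mean = mean(station),
                 histogram = graphics::hist(pmin(pmax(station, 0), 1),
                                            breaks = edges, plot = FALSE)$counts,
                 n_samples = length(station)), class = "core_profile")
}

core_geometry <- function(core) {
  if (is.data.frame(core))
    list(entry = c(core$entry_x_mm, core$entry_y_mm, core$entry_z_mm),
         tip = c(core$tip_x_mm, core$tip_y_mm, core$tip_z_mm),
         effective_fraction = core$effective_fraction)
  else core
}

#' @export
print.core_profile <- function(x, ...) {
  cat(sprintf("<core_profile> %d stations, max MAI %.3f, mean MAI %.3f\n",
              x$n_samples, x$max, x$mean))
  invisible(x)
}

#' Dual-threshold decision rule for a core profile
#'
#' A core is predicted pathology-positive iff its highest profile MAI reaches
#' `max_threshold` (default 0.6, the Gleason-6 level) and its mean profile MAI
#' reaches `mean_threshold` (default 0.2, the reported optimum). Ties use >=.
#'
#' @param profile a `core_profile`.
#' @param max_threshold,mean_threshold thresholds in [0, 1].
#' @return logical: predicted positive.
#' @export
classify_core <- function(profile, max_threshold = 0.6, mean_threshold = 0.2) {
  stopifnot(max_threshold >= 0, max_threshold <= 1,
            mean_threshold >= 0, mean_threshold <= 1)
  profile$max >= max_threshold && profile$mean >= mean_threshold
}

#' Detect predicted malignant lesions in an MAI map
#'
#' 26-connected components of voxels with MAI >= `mai_threshold`; a component
#' qualifies as a clinically relevant predicted lesion iff its mean MAI is at
#' least 0.6 and its volume (voxel count x voxel volume) is at least
#' `min_volume_ml`.
#'
#' @param mai MAI [volume_image()].
#' @param mai_threshold voxel inclusion threshold.
#' @param min_volume_ml minimum lesion volume (ml).
#' @return data.frame with one row per lesion: `lesion_id`, `n_voxels`,
#'   `volume_ml`, `mean_mai`, `max_mai`, `centroid_x/y/z_mm`; attribute
#'   `component_labels` holds the labelled volume (0 = none) so cores can be
#'   attributed to lesions.
#' @export
detect_lesions <- function(mai, mai_threshold = 0.6, min_volume_ml = 0.5) {
  stopifnot(mai_threshold >= 0, mai_threshold <= 1, min_volume_ml >= 0)
  mask <- mai$data >= mai_threshold
  lab <- label_components_26(mask)
  vox_ml <- prod(vol_spacing(mai)) / 1000
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- list(); keep_ids <- integer(0)
  for (id in ids) {
    idx <- which(lab == id)
    mean_mai <- mean(mai$data[idx])
    vol_ml <- length(idx) * vox_ml
    if (mean_mai >= 0.6 && vol_ml >= min_volume_ml) {
      ctr <- colMeans(voxel_to_world(mai, arrayInd(idx, dim(mai$data)) - 1L))
      keep_ids <- c(keep_ids, id)
      rows[[length(rows) + 1]] <- data.frame(
        lesion_id = id, n_voxels = length(idx), volume_ml = vol_ml,
        mean_mai = mean_mai, max_mai = max(mai$data[idx]),
        centroid_x_mm = ctr[1], centroid_y_mm = ctr[2], centroid_z_mm = ctr[3])
    }
  }
  lab[!(lab %in% keep_ids)] <- 0L
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0), n_voxels = integer(0),
               volume_ml = numeric(0), mean_mai = numeric(0),
               max_mai = numeric(0), centroid_x_mm = numeric(0),
               centroid_y_mm = numeric(0), centroid_z_mm = numeric(0))
  attr(out, "component_labels") <- lab
  out
}

# BFS connected-component labelling with 26-connectivity on a logical array.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  todo <- which(mask)
  cur <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      ijk <- arrayInd(queue, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(r)
        cbind(ijk[, 1] + off[r, 1], ijk[, 2] + off[r, 2], ijk[, 3] + off[r, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbi <- unique(nb[ok, 1] + d[1] * (nb[ok, 2] - 1) +
                    d[1] * d[2] * (nb[ok, 3] - 1))
      nbi <- nbi[mask[nbi] & lab[nbi] == 0L]
      lab[nbi] <- cur
      queue <- nbi
    }
  }
  lab
}

#' Evaluate all cores of one patient against an MAI map
#'
#' Extracts each core's MAI profile, applies the dual-threshold rule, and
#' attributes the core to a predicted lesion when any of its sample stations
#' falls inside that lesion's component.
#'
#' @param mai MAI [volume_image()].
#' @param cores biopsy-core data.frame ([sample_biopsy_cores()] schema).
#' @param lesions result of [detect_lesions()].
#' @param max_threshold,mean_threshold see [classify_core()].
#' @param step_mm,radius_mm see [extract_core_profile()].
#' @return `cores` augmented with columns `max_mai`, `mean_mai`, `predicted`
#'   (logical) and `lesion_id` (0 = none).
#' @export
evaluate_cores <- function(mai, cores, lesions,
                           max_threshold = 0.6, mean_threshold = 0.2,
                           step_mm = 0.5, radius_mm = 1) {
  lab <- attr(lesions, "component_labels")
  d <- dim(mai$data)
  out <- cores
  out$max_mai <- NA_real_; out$mean_mai <- NA_real_
  out$predicted <- FALSE; out$lesion_id <- 0L
  for (i in seq_len(nrow(cores))) {
    core <- cores[i, ]
    prof <- extract_core_profile(mai, core, step_mm, radius_mm)
    out$max_mai[i] <- prof$max
    out$mean_mai[i] <- prof$mean
    out$predicted[i] <- classify_core(prof, max_threshold, mean_threshold)
    g <- core_geometry(core)
    pts <- core_sample_points(g$entry, g$tip, g$effective_fraction,
                              step_mm, 0)
    ijk <- round(world_to_voxel(mai, pts))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
          ijk[, 3] >= 0 & ijk[, 3] < d[3]
    if (any(ok) && !is.null(lab)) {
      hits <- lab[1 + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])]
      hits <- hits[hits > 0]
      if (length(hits)) out$lesion_id[i] <- as.integer(hits[1])
    }
  }
  out
}

#' Patient-level scoring from predicted lesions and evaluated cores
#'
#' Lesion level: a predicted lesion is `confirmed` when at least one core
#' attributed to it is positive both in pathology (Gleason >= 6) and in the
#' MAI-based analysis; `disproved` when cores were taken from it but none is
#' pathology-positive-and-MAI-positive yet some were taken; `unsampled`
#' lesions (no cores) are excluded from the analysis. Patient level: at least
#' one confirmed lesion is a true positive; no (sampled) predicted lesions and
#' no pathology-positive cores is a true negative; no (sampled) predicted
#' lesions with pathology-positive cores is a false negative; every other
#' combination is a false positive.
#'
#' @param lesions [detect_lesions()] output.
#' @param cores [evaluate_cores()] output (with `gleason` and `predicted`).
#' @return object of class `patient_score`: list with `category` (one of
#'   "TP", "TN", "FP", "FN"), `lesion_status` data.frame and the evidence
#'   counts.
#' @export
score_patient <- function(lesions, cores) {
  if (!all(c("gleason", "predicted", "lesion_id") %in% names(cores)))
    stop("cores must be evaluated (evaluate_cores) before scoring")
  path_pos <- cores$gleason >= 6
  status <- character(0)
  if (nrow(lesions)) {
    status <- vapply(lesions$lesion_id, function(id) {
      sampled <- cores$lesion_id == id
      if (!any(sampled)) return("unsampled")
      if (any(sampled & path_pos & cores$predicted)) "confirmed" else "disproved"
    }, character(1))
  }
  considered <- status[status != "unsampled"]
  category <- if (any(considered == "confirmed")) "TP"
  else if (length(considered) == 0 && !any(path_pos)) "TN"
  else if (length(considered) == 0 && any(path_pos)) "FN"
  else "FP"
  structure(list(category = category,
                 lesion_status = data.frame(
                   lesion_id = if (nrow(lesions)) lesions$lesion_id else integer(0),
                   status = status),
                 n_path_positive_cores = sum(path_pos),
                 n_predicted_cores = sum(cores$predicted)),
            class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  cat(sprintf("<patient_score> %s (%d pathology-positive cores, %d predicted)\n",
              x$category, x$n_path_positive_cores, x$n_predicted_cores))
  invisible(x)
}

#' Write / read biopsy cores as CSV
#'
#' The exchange schema: patient_id, core_id, entry_x/y/z_mm, tip_x/y/z_mm,
#' effective_fraction, gleason (0 = negative), plus any evaluation columns
#' present (max_mai, mean_mai, predicted, lesion_id).
#'
#' @param cores data.frame of cores.
#' @param path CSV path.
#' @export
write_cores_csv <- function(cores, path) {
  utils::write.csv(cores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cores_csv
#' @export
read_cores_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
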