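#' Per-voxel ADC fit from multi-b DWI signals
#'
#' Ordinary least squares of log signal on b-value; `adc = -slope` clamped at
#' zero, `s0 = exp(intercept)`. Voxels with non-positive signals use only
#' their positive samples and are flagged; voxels with fewer than two usable
#' samples are flagged with adc = 0.
#'
#' @param signals numeric matrix (voxels x b-values) or vector (one voxel).
#' @param b_values b-values (s/mm^2), at least two distinct.
#' @return list with numeric vectors `adc` (mm^2/s), `s0` (a.u.) and integer
#'   `flag` (0 = clean, 1 = partial samples, 2 = unusable).
#' @export
fit_adc <- function(signals, b_values) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != length(b_values))
    stop("signals and b_values dimensions differ")
  if (length(unique(b_values)) < 2) stop("need at least 2 distinct b-values")
  if (any(signals < 0)) stop("signals must be >= 0")
  n <- nrow(signals)
  adc <- numeric(n); s0 <- numeric(n); flag <- integer(n)
  pos <- signals > 0
  clean <- rowSums(pos) == length(b_values)
  if (any(clean)) {
    ls <- log(signals[clean, , drop = FALSE])
    b <- b_values - mean(b_values)
    slope <- drop(ls %*% b) / sum(b * b)
    inter <- rowMeans(ls) - slope * mean(b_values)
    adc[clean] <- pmax(-slope, 0)
    s0[clean] <- exp(inter)
  }
  for (i in which(!clean)) {
    use <- pos[i, ]
    if (sum(use) < 2 || length(unique(b_values[use])) < 2) {
      flag[i] <- 2L
    } else {
      fitb <- b_values[use]
      ft <- stats::lm.fit(cbind(1, fitb), log(signals[i, use]))
      adc[i] <- max(-ft$coefficients[2], 0)
      s0[i] <- exp(ft$coefficients[1])
      flag[i] <- 1L
    }
  }
  list(adc = adc, s0 = s0, flag = flag)
}

#' Convert DCE signal to contrast concentration
#'
#' Signal enhancement over the pre-contrast baseline divided by a configured
#' proportionality constant: `Ct = (S - S_base) / (S_base * gain)`. Baseline
#' frames are those acquired before the arterial-input onset.
#'
#' @param signals matrix (voxels x frames) or vector.
#' @param times_s frame times (s).
#' @param onset_s bolus arrival time (s); frames strictly before it form the
#'   baseline.
#' @param gain enhancement-per-concentration constant (1/(mmol/L)).
#' @return matrix (voxels x frames) of concentrations (mmol/L).
#' @export
dce_concentration <- function(signals, times_s, onset_s = 60, gain = 4.5) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  base_idx <- which(times_s < onset_s)
  if (length(base_idx) < 1) stop("no pre-enhancement frames before onset")
  s_base <- rowMeans(signals[, base_idx, drop = FALSE])
  s_base[s_base <= 0] <- NA_real_
  (signals - s_base) / (s_base * gain)
}

#' Fit the two-compartment Tofts model per voxel
#'
#' Nonlinear least squares against [tofts_forward()] with bounds
#' ktrans in [0, 5]/min and ve in (0, 1], solved by variable projection:
#' for fixed kep the model is linear in ktrans, so a log-spaced kep grid is
#' profiled and the best cell refined by golden-section search (vectorized
#' across voxels, deterministic). When the unconstrained solution implies
#' ve > 1 the voxel is re-solved on the ve = 1 boundary. Voxels whose fit
#' fails (all-zero curve, no signal) are flagged and zeroed.
#'
#' @param curves concentration matrix (voxels x frames) or vector (mmol/L).
#' @param aif plasma concentration at `times_s` (vector or function).
#' @param times_s frame times (s), at least 5 frames.
#' @param kep_grid initial kep profile grid (1/min).
#' @param tol_rel relative golden-section tolerance on kep.
#' @return list of numeric vectors `ktrans` (1/min), `ve`, `kep` (1/min), and
#'   integer `flag` (0 = ok, 1 = boundary ve, 2 = failed/zero).
#' @export
fit_tofts <- function(curves, aif, times_s,
                      kep_grid = exp(seq(log(0.02), log(20), length.out = 40)),
                      tol_rel = 1e-7) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  if (length(times_s) < 5) stop("need at least 5 frames")
  if (is.function(aif)) aif <- aif(times_s)
  n <- nrow(curves)

  G <- tofts_kernel(aif, times_s, kep_grid)      # frames x grid
  gg <- colSums(G * G)
  num <- curves %*% G                            # voxels x grid
  kt_prof <- sweep(num, 2, gg, "/")
  kt_prof[kt_prof < 0] <- 0
  sse <- rowSums(curves^2) - 2 * kt_prof * num + sweep(kt_prof^2, 2, gg, "*")
  best <- max.col(-sse, ties.method = "first")

  lo <- kep_grid[pmax(best - 1, 1)]
  hi <- kep_grid[pmin(best + 1, length(kep_grid))]
  golden <- golden_profile(curves, aif, times_s, log(lo), log(hi), tol_rel)
  kep <- golden$kep; ktrans <- pmin(pmax(golden$ktrans, 0), 5)
  ve <- ifelse(kep > 0, ktrans / kep, 0)

  # boundary: ve > 1 not admissible; re-solve with kep = ktrans (ve = 1)
  flag <- integer(n)
  onb <- which(ve > 1)
  if (length(onb)) {
    gb <- golden_boundary(curves[onb, , drop = FALSE], aif, times_s, tol_rel)
    ktrans[onb] <- pmin(gb, 5); kep[onb] <- ktrans[onb]; ve[onb] <- 1
    flag[onb] <- 1L
  }
  dead <- rowSums(abs(curves)) == 0 | !is.finite(rowSums(curves)) | ktrans == 0
  ktrans[dead] <- 0; ve[dead] <- 0; kep[dead] <- 0
  flag[dead] <- ifelse(rowSums(abs(curves))[dead] == 0 |
                       !is.finite(rowSums(curves))[dead], 2L, flag[dead])
  ve <- pmin(ve, 1)
  list(ktrans = ktrans, ve = ve, kep = kep, flag = flag)
}

# Vectorized golden-section minimization (one objective evaluation per
# iteration, reusing the interior point). `f` maps a per-voxel coordinate
# vector to a per-voxel objective vector.
golden_vec <- function(f, a, b, tol) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (it in 1:80) {
    if (max(b - a) < tol) break
    use1 <- f1 < f2
    a_new <- ifelse(use1, a, x1); b_new <- ifelse(use1, x2, b)
    x1_new <- ifelse(use1, b_new - phi * (b_new - a_new), x2)
    x2_new <- ifelse(use1, x1, a_new + phi * (b_new - a_new))
    x_eval <- ifelse(use1, x1_new, x2_new)
    f_eval <- f(x_eval)
    f1_new <- ifelse(use1, f_eval, f2)
    f2_new <- ifelse(use1, f1, f_eval)
    a <- a_new; b <- b_new; x1 <- x1_new; x2 <- x2_new
    f1 <- f1_new; f2 <- f2_new
  }
  (a + b) / 2
}

# Golden-section maximization of the profiled fit over log(kep), vectorized
# across voxels. Returns per-voxel kep and its profiled (linear) ktrans.
golden_profile <- function(curves, aif, times_s, la, lb, tol_rel) {
  cc <- rowSums(curves^2)
  prof <- function(lk) {
    G <- tofts_kernel(aif, times_s, exp(lk))     # frames x voxels (per-voxel kep)
    gg <- colSums(G * G)
    num <- rowSums(curves * t(G))
    kt <- pmax(num / pmax(gg, 1e-300), 0)
    list(sse = cc - 2 * kt * num + kt^2 * gg, kt = kt)
  }
  lk <- golden_vec(function(x) prof(x)$sse, la, lb, tol_rel)
  res <- prof(lk)
  list(kep = exp(lk), ktrans = res$kt)
}

# 1-D golden search over ktrans with ve fixed at 1 (kep = ktrans).
golden_boundary <- function(curves, aif, times_s, tol_rel) {
  sse_at <- function(lk) {
    k <- exp(lk)
    G <- tofts_kernel(aif, times_s, k)           # frames x voxels
    fit <- t(G) * k                              # voxels x frames, Ct = k * g
    rowSums((curves - fit)^2)
  }
  lk <- golden_vec(sse_at, rep(log(1e-3), nrow(curves)),
                   rep(log(5), nrow(curves)), tol_rel)
  exp(lk)
}

#' Robust z-score normalization of T2W intensities
#'
#' Normalizes against the median and 1.4826 x MAD computed over a rectangular
#' volume of interest encompassing the prostate; invariant to positive affine
#' rescaling of the input by construction. A constant VOI (zero scale) is
#' flagged and zeros returned.
#'
#' @param t2w a [volume_image()].
#' @param voi integer box in 0-based half-open voxel indices,
#'   `list(x = c(x0, x1), y = c(y0, y1), z = c(z0, z1))`; NULL uses the whole
#'   volume.
#' @return list with `volume` (the normalized [volume_image()]) and `flag`
#'   (0 ok, 2 degenerate).
#' @export
normalize_t2w <- function(t2w, voi = NULL) {
  d <- dim(t2w$data)
  if (is.null(voi)) voi <- list(x = c(0, d[1]), y = c(0, d[2]), z = c(0, d[3]))
  ix <- (voi$x[1] + 1):voi$x[2]; iy <- (voi$y[1] + 1):voi$y[2]
  iz <- (voi$z[1] + 1):voi$z[2]
  if (voi$x[1] < 0 || voi$x[2] > d[1] || voi$y[1] < 0 || voi$y[2] > d[2] ||
      voi$z[1] < 0 || voi$z[2] > d[3] || voi$x[2] <= voi$x[1] ||
      voi$y[2] <= voi$y[1] || voi$z[2] <= voi$z[1])
    stop("VOI out of bounds or empty")
  sub <- t2w$data[ix, iy, iz]
  m <- stats::median(sub)
  s <- stats::mad(sub, constant = 1.4826)
  if (s == 0)
    return(list(volume = volume_image(array(0, d), affine = t2w$affine,
                                      modality = "t2w_norm"), flag = 2L))
  list(volume = volume_image((t2w$data - m) / s, affine = t2w$affine,
                             modality = "t2w_norm"), flag = 0L)
}

#' Compute all parametric maps on the T2W grid
#'
#' Step 2 of the automated analysis: resamples the (registered) DWI and DCE
#' series onto the T2W grid, fits ADC and Tofts parameters per voxel inside
#' the VOI, and normalizes T2W. All outputs share the T2W geometry.
#'
#' @param study study list from [generate_phantom()] (or assembled from
#'   [read_volume()] calls with the same fields).
#' @param dwi_transform,dce_transform [affine9()] transforms from registration
#'   (identity by default).
#' @param voi VOI box as in [normalize_t2w()]; also restricts the voxels that
#'   are fitted. NULL fits everything.
#' @param gain,onset_s DCE conversion constants, see [dce_concentration()].
#' @return object of class `parametric_maps`: list of [volume_image()]s
#'   `adc`, `s0`, `ktrans`, `ve`, `kep`, `t2w_norm` plus integer `flags`
#'   volume (bit 1 = ADC partial, bit 2 = Tofts failed/boundary).
#' @export
compute_parametric_maps <- function(study, dwi_transform = affine9(),
                                    dce_transform = affine9(), voi = NULL,
                                    gain = study$dce_gain %||% 4.5,
                                    onset_s = study$aif_onset_s %||% 60) {
  t2w <- study$t2w
  d <- dim(t2w$data)
  vox_idx <- voi_indices(d, voi)

  dwi_on_t2w <- vapply(study$dwi, function(v)
    resample_volume(v, t2w, dwi_transform)$data[vox_idx],
    numeric(length(vox_idx)))
  adc_fit <- fit_adc(dwi_on_t2w, study$b_values)

  dce_on_t2w <- vapply(study$dce, function(v)
    resample_volume(v, t2w, dce_transform)$data[vox_idx],
    numeric(length(vox_idx)))
  conc <- dce_concentration(dce_on_t2w, study$dce_times_s,
                            onset_s = onset_s, gain = gain)
  conc[!is.finite(conc)] <- 0
  tofts <- fit_tofts(conc, study$aif, study$dce_times_s)

  t2n <- normalize_t2w(t2w, voi = voi)

  blank <- function(vals, mod) {
    a <- array(0, d); a[vox_idx] <- vals
    volume_image(a, affine = t2w$affine, modality = mod)
  }
  flags <- array(0L, d)
  flags[vox_idx] <- as.integer(adc_fit$flag > 0) + 2L * as.integer(tofts$flag > 0)
  structure(list(adc = blank(adc_fit$adc, "adc"),
                 s0 = blank(adc_fit$s0, "s0"),
                 ktrans = blank(tofts$ktrans, "ktrans"),
                 ve = blank(tofts$ve, "ve"),
                 kep = blank(tofts$kep, "kep"),
                 t2w_norm = t2n$volume,
                 flags = volume_image(flags + 0, affine = t2w$affine,
                                      modality = "flags")),
            class = "parametric_maps")
}

# linear indices (1-based) of voxels inside a 0-based half-open VOI box
voi_indices <- function(d, voi) {
  if (is.null(voi)) return(seq_len(prod(d)))
  ix <- (voi$x[1] + 1):voi$x[2]; iy <- (voi$y[1] + 1):voi$y[2]
  iz <- (voi$z[1] + 1):voi$z[2]
  idx <- as.vector(outer(outer(ix, (iy - 1) * d[1], "+"),
                         (iz - 1) * d[1] * d[2], "+"))
  sort(idx)
}
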