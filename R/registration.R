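#' 9-degree-of-freedom affine transform
#'
#' World-to-world affine with translations (mm), rotations (degrees) and
#' per-axis scales, acting about a rotation `center` (mm):
#' `T(x) = center + Rz Ry Rx S (x - center) + t`.
#' Parameter order and units are fixed as (t mm, r degrees, s unitless).
#'
#' @param t length-3 translation (mm).
#' @param r length-3 rotation angles (degrees) about x, y, z.
#' @param s length-3 scales (> 0).
#' @param center rotation/scaling centre (mm).
#' @return object of class `affine9`.
#' @export
affine9 <- function(t = c(0, 0, 0), r = c(0, 0, 0), s = c(1, 1, 1),
                    center = c(0, 0, 0)) {
  if (any(s <= 0)) stop("scales must be > 0")
  structure(list(t = as.numeric(t), r = as.numeric(r), s = as.numeric(s),
                 center = as.numeric(center)), class = "affine9")
}

rot_matrix <- function(r_deg) {
  a <- r_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (degrees, Rz Ry Rx convention) from a rotation matrix.
euler_from_matrix <- function(R) {
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3]); rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2]); rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' 4x4 homogeneous matrix of an `affine9`
#' @param tf an [affine9()].
#' @return 4x4 matrix mapping homogeneous world coordinates.
#' @export
affine9_matrix <- function(tf) {
  A <- rot_matrix(tf$r) %*% diag(tf$s)
  off <- tf$center - A %*% tf$center + tf$t
  rbind(cbind(A, off), c(0, 0, 0, 1))
}

#' Apply an `affine9` (or 4x4 matrix) to world points
#' @param tf an [affine9()] or 4x4 matrix.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
apply_transform <- function(tf, xyz) {
  M <- if (inherits(tf, "affine9")) affine9_matrix(tf) else tf
  xyz <- matrix(xyz, ncol = 3)
  t(M[1:3, 1:3] %*% t(xyz) + M[1:3, 4])
}

#' @export
print.affine9 <- function(x, ...) {
  cat(sprintf("<affine9> t = (%s) mm, r = (%s) deg, s = (%s)\n",
              paste(signif(x$t, 4), collapse = ", "),
              paste(signif(x$r, 4), collapse = ", "),
              paste(signif(x$s, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize / deserialize an `affine9` as JSON
#' @param tf an [affine9()].
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(list(translation_mm = tf$t, rotation_deg = tf$r,
                            scale = tf$s, center_mm = tf$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine9(t = j$translation_mm, r = j$rotation_deg, s = j$scale,
          center = j$center_mm)
}

#' Metadata-based initial alignment of two volumes
#'
#' The starting guess for registration, computed purely from the frame of
#' reference and field of view carried in the volume geometry: the transform
#' maps the primary's field-of-view centre (and frame orientation) onto the
#' secondary's, `T(x) = c_sec + O_sec O_pri^T (x - c_pri)`. Volumes with
#' identical geometry metadata give the identity; origins differing by a pure
#' offset (equal grids, equal orientation) give that offset as translation.
#'
#' @param primary,secondary [volume_image()] objects carrying affines.
#' @return an [affine9()] with rotation centre at the primary volume centre.
#' @export
initial_transform_from_metadata <- function(primary, secondary) {
  if (is.null(primary$affine) || is.null(secondary$affine))
    stop("volumes must carry geometry metadata")
  Op <- vol_orientation(primary); Os <- vol_orientation(secondary)
  cp <- vol_center(primary); cs <- vol_center(secondary)
  Rrel <- Os %*% t(Op)
  # T(x) = cs + Rrel (x - cp); re-express about the primary centre
  affine9(t = cs - cp, r = euler_from_matrix(Rrel), s = c(1, 1, 1),
          center = cp)
}

#' Resample a volume onto a target grid through an affine transform
#'
#' For every voxel centre x of the target grid, the output takes the
#' trilinearly interpolated secondary intensity at world position T(x).
#' Voxels mapping outside the secondary get `fill`. The output geometry equals
#' the target grid exactly.
#'
#' @param secondary [volume_image()] to resample.
#' @param target [volume_image()] (or any object with an `affine` and data
#'   dims) defining the output grid.
#' @param transform an [affine9()] or 4x4 matrix (world to world). Identity by
#'   default.
#' @param fill fill value for out-of-bounds voxels.
#' @return a [volume_image()] on the target grid.
#' @export
resample_volume <- function(secondary, target, transform = affine9(),
                            fill = 0) {
  if (inherits(transform, "affine9") && any(transform$s < 1e-12))
    stop("degenerate transform: zero scale")
  xyz <- voxel_grid_world(target)
  xyz <- apply_transform(transform, xyz)
  vals <- sample_world(secondary, xyz, fill = fill)
  volume_image(array(as.numeric(vals), dim(target$data)),
               affine = target$affine, modality = secondary$modality)
}

#' Plug-in mutual information of two intensity samples
#'
#' MI from the joint histogram over `bins` equal-width bins per variable,
#' spanning each sample's 1st-99th percentile range:
#' `MI = sum p(i,j) ln [ p(i,j) / (p(i) p(j)) ]` in nats. Non-negative and
#' symmetric in its arguments.
#'
#' @param a,b numeric vectors of equal length (paired intensity samples).
#' @param bins number of bins per variable (>= 2).
#' @return mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (length(a) != length(b)) stop("sample counts differ")
  if (length(a) == 0) stop("empty overlap region")
  if (bins < 2) stop("need at least 2 bins")
  ra <- stats::quantile(a, c(0.01, 0.99), names = FALSE)
  rb <- stats::quantile(b, c(0.01, 0.99), names = FALSE)
  if (ra[1] == ra[2]) ra <- ra + c(-0.5, 0.5)
  if (rb[1] == rb[2]) rb <- rb + c(-0.5, 0.5)
  ia <- pmin(pmax(floor((a - ra[1]) / (ra[2] - ra[1]) * bins), 0), bins - 1)
  ib <- pmin(pmax(floor((b - rb[1]) / (rb[2] - rb[1]) * bins), 0), bins - 1)
  joint <- tabulate(1 + ia + bins * ib, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(pa, pb)[nz]))
}

# Objective closure: MI between primary sample intensities and secondary
# intensities interpolated at transformed sample positions (overlap only).
mi_objective <- function(primary, secondary, n_samples, bins) {
  d <- dim(primary$data)
  n_tot <- prod(d)
  idx <- if (n_tot > n_samples)
    unique(round(seq(1, n_tot, length.out = n_samples))) else seq_len(n_tot)
  xyz <- voxel_grid_world(primary, subset = idx)
  pvals <- primary$data[idx]
  Ainv <- solve(secondary$affine)
  function(par, center) {
    tf <- affine9(t = par[1:3], r = par[4:6], s = par[7:9], center = center)
    y <- apply_transform(tf, xyz)
    ijk <- t(Ainv[1:3, 1:3] %*% t(y) + Ainv[1:3, 4])
    sv <- interp_trilinear(secondary$data, ijk, fill = NA_real_)
    inside <- attr(sv, "inside")
    if (sum(inside) < 100) return(NA_real_)
    mutual_information(pvals[inside], sv[inside], bins = bins)
  }
}

#' Mutual-information affine registration (9 degrees of freedom)
#'
#' Maximizes the mutual information between the primary volume and the
#' transformed secondary over translations, rotations and scales, by
#' Polak-Ribiere nonlinear conjugate gradient with restarts, a backtracking
#' line search, and central finite-difference gradients. Parameters are
#' internally scaled so that 1 mm, 1 degree and 0.01 scale take equal steps.
#' Deterministic for fixed inputs and options.
#'
#' @param primary,secondary [volume_image()] objects; the secondary is mapped
#'   onto the primary's frame.
#' @param init optional [affine9()] starting transform; defaults to
#'   [initial_transform_from_metadata()].
#' @param bins histogram bins for the MI metric.
#' @param n_samples maximum number of primary voxels sampled for the metric.
#' @param max_iter conjugate-gradient iteration cap.
#' @param tol stop when the MI gain of an accepted step falls below this
#'   (nats).
#' @param coarse_init if TRUE, a first pass runs on a 2x downsampled primary
#'   grid to pull in large offsets cheaply.
#' @return list with `transform` ([affine9()]), `mi` (final metric, nats),
#'   `iterations`, `converged`, and `status` ("ok" or a warning tag).
#' @export
register_affine <- function(primary, secondary, init = NULL, bins = 32,
                            n_samples = 20000, max_iter = 200, tol = 1e-5,
                            coarse_init = TRUE) {
  center <- vol_center(primary)
  if (is.null(init)) init <- initial_transform_from_metadata(primary, secondary)
  par0 <- c(init$t, init$r, init$s)

  if (coarse_init) {
    ds <- primary$data[seq(1, dim(primary$data)[1], 2),
                       seq(1, dim(primary$data)[2], 2), , drop = FALSE]
    aff <- primary$affine
    aff[, 1:2] <- aff[, 1:2] * 2
    coarse <- volume_image(ds, affine = aff, modality = primary$modality)
    res0 <- cg_maximize(mi_objective(coarse, secondary, n_samples %/% 2, bins),
                        par0, center, max_iter = min(max_iter, 40), tol = tol * 10)
    par0 <- res0$par
  }
  f <- mi_objective(primary, secondary, n_samples, bins)
  if (is.na(f(par0, center)))
    stop("volumes do not overlap under the initial transform")
  res <- cg_maximize(f, par0, center, max_iter = max_iter, tol = tol)
  tf <- affine9(t = res$par[1:3], r = res$par[4:6], s = res$par[7:9],
                center = center)
  status <- if (res$diverged) "divergence: best-so-far returned" else "ok"
  if (res$diverged)
    warning("registration optimizer diverged; returning best transform found")
  list(transform = tf, mi = res$value, iterations = res$iter,
       converged = res$converged, status = status)
}

# Polak-Ribiere+ conjugate-gradient ascent with backtracking line search.
# `scales` makes one nominal step size serve all 9 DoF.
cg_maximize <- function(f, par, center, max_iter = 200, tol = 1e-5,
                        scales = c(rep(1, 3), rep(1, 3), rep(0.01, 3)),
                        step0 = 0.5, fd_h = 0.1) {
  u <- par / scales                      # work in scaled coordinates
  fu <- function(u) f(u * scales, center)
  grad <- function(u, f0) {
    g <- numeric(length(u))
    for (i in seq_along(u)) {
      up <- u; up[i] <- u[i] + fd_h
      um <- u; um[i] <- u[i] - fd_h
      fp <- fu(up); fm <- fu(um)
      g[i] <- if (is.na(fp) || is.na(fm)) 0 else (fp - fm) / (2 * fd_h)
    }
    g
  }
  f0 <- fu(u)
  best_u <- u; best_f <- f0
  g <- grad(u, f0); d <- g
  n_bad <- 0L; n_small <- 0L; iter <- 0L; converged <- FALSE; diverged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (sqrt(sum(g^2)) < 1e-10) { converged <- TRUE; break }
    # backtracking line search along d
    step <- step0; f_new <- NA_real_; u_new <- u
    repeat {
      cand <- u + step * d / max(sqrt(sum(d^2)), 1e-12)
      fc <- fu(cand)
      if (!is.na(fc) && fc > f0) { u_new <- cand; f_new <- fc; break }
      step <- step / 2
      if (step < 1e-6) break
    }
    if (is.na(f_new)) {                  # no uphill step along d: restart on g
      if (all(d == g)) { converged <- TRUE; break }
      d <- g
      next
    }
    gain <- f_new - f0
    u <- u_new
    g_new <- grad(u, f_new)
    beta <- max(0, sum(g_new * (g_new - g)) / max(sum(g * g), 1e-12))
    d <- g_new + beta * d
    if (sum(d * g_new) <= 0) d <- g_new  # ensure ascent direction
    g <- g_new; f0 <- f_new
    if (f0 > best_f) { best_f <- f0; best_u <- u; n_bad <- 0L }
    else n_bad <- n_bad + 1L
    if (n_bad >= 10L) { diverged <- TRUE; break }
    # CG can take small interim steps mid-run: stop only once the gain has
    # stayed below tol for 3 consecutive accepted iterations
    n_small <- if (gain < tol) n_small + 1L else 0L
    if (n_small >= 3L) { converged <- TRUE; break }
  }
  list(par = best_u * scales, value = best_f, iter = iter,
       converged = converged, diverged = diverged)
}
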