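#' 3D image volume with world-space geometry
#'
#' A `volume_image` wraps a 3D intensity array together with a 4x4 voxel-to-world
#' affine (in mm, right-handed patient frame, 0-based voxel indices) and a
#' modality tag. The affine is the single source of geometry truth: spacing,
#' origin and orientation are derived from it.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param affine 4x4 voxel-to-world matrix; alternatively supply `spacing`,
#'   `origin`, `orientation`.
#' @param spacing length-3 positive voxel spacing in mm (used if `affine` missing).
#' @param origin length-3 world position (mm) of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction-cosine matrix.
#' @param modality character tag, e.g. "t2w", "dwi", "dce".
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, affine = NULL, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), orientation = diag(3),
                         modality = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("intensities must be finite")
  if (is.null(affine)) {
    if (any(spacing <= 0)) stop("spacing must be > 0")
    check_orthonormal(orientation)
    affine <- rbind(cbind(orientation %*% diag(spacing), origin), c(0, 0, 0, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4, 4))) stop("`affine` must be 4x4")
    sp <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(sp <= 0)) stop("degenerate affine: zero spacing")
    check_orthonormal(affine[1:3, 1:3] %*% diag(1 / sp))
  }
  structure(list(data = data, affine = unname(affine), modality = modality),
            class = "volume_image")
}

check_orthonormal <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("orientation matrix is not orthonormal (tolerance 1e-6)")
  invisible(TRUE)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Voxel spacing (mm), world origin (mm) and orientation of a volume
#' @param vol a `volume_image`.
#' @return numeric vector (spacing, origin) or 3x3 matrix (orientation).
#' @export
vol_spacing <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' @rdname vol_spacing
#' @export
vol_origin <- function(vol) vol$affine[1:3, 4]

#' @rdname vol_spacing
#' @export
vol_orientation <- function(vol) vol$affine[1:3, 1:3] %*% diag(1 / vol_spacing(vol))

#' World centre of the field of view (mm)
#' @param vol a `volume_image`.
#' @export
vol_center <- function(vol) {
  ctr_vox <- (dim(vol$data) - 1) / 2
  drop(voxel_to_world(vol, matrix(ctr_vox, 1)))
}

#' Convert between 0-based voxel indices and world coordinates
#'
#' @param vol a `volume_image`.
#' @param ijk n x 3 matrix of 0-based continuous voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(vol$affine[1:3, 1:3] %*% t(ijk) + vol$affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(vol$affine[1:3, 1:3]) %*% (t(xyz) - vol$affine[1:3, 4]))
}

#' World coordinates of every voxel centre
#'
#' @param vol a `volume_image`.
#' @param subset optional integer vector of linear voxel indices (1-based).
#' @return n x 3 matrix of world coordinates in array (column-major) order.
#' @export
voxel_grid_world <- function(vol, subset = NULL) {
  d <- dim(vol$data)
  if (is.null(subset)) {
    ijk <- cbind(
      rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
      rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
      rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  } else {
    ijk <- arrayInd(subset, d) - 1L
  }
  voxel_to_world(vol, ijk)
}

#' Trilinear interpolation of a 3D array at continuous voxel coordinates
#'
#' Coordinates are 0-based voxel indices. Points outside the grid (beyond the
#' outermost voxel centres) receive `fill`.
#'
#' @param a 3D array.
#' @param ijk n x 3 matrix of 0-based continuous voxel indices.
#' @param fill value for out-of-bounds points.
#' @return numeric vector of length n, with attribute `inside` (logical).
#' @export
interp_trilinear <- function(a, ijk, fill = 0) {
  d <- dim(a)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
            k >= 0 & k <= d[3] - 1
  out <- rep(fill, length(i))
  if (any(inside)) {
    i <- i[inside]; j <- j[inside]; k <- k[inside]
    i0 <- pmin(floor(i), d[1] - 2); j0 <- pmin(floor(j), d[2] - 2)
    k0 <- pmin(floor(k), d[3] - 2)
    i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
    fx <- i - i0; fy <- j - j0; fz <- k - k0
    # linear index of the (i0,j0,k0) corner, 1-based
    base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
    s1 <- 1; s2 <- d[1]; s3 <- d[1] * d[2]
    v000 <- a[base];           v100 <- a[base + s1]
    v010 <- a[base + s2];      v110 <- a[base + s1 + s2]
    v001 <- a[base + s3];      v101 <- a[base + s1 + s3]
    v011 <- a[base + s2 + s3]; v111 <- a[base + s1 + s2 + s3]
    out[inside] <-
      v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
      v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
      v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
      v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  }
  attr(out, "inside") <- inside
  out
}

#' Sample a volume at world coordinates (mm) by trilinear interpolation
#' @inheritParams interp_trilinear
#' @param vol a `volume_image`.
#' @param xyz n x 3 matrix of world coordinates.
#' @export
sample_world <- function(vol, xyz, fill = 0) {
  interp_trilinear(vol$data, world_to_voxel(vol, xyz), fill = fill)
}

#' Test two volumes for identical geometry
#' @param a,b `volume_image` objects.
#' @param tol absolute tolerance on affine entries (mm scale).
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

#' Read and write volumes as NIfTI-1
#'
#' Geometry is carried by the NIfTI sform affine (converted to/from the
#' package's 0-based voxel convention, which matches NIfTI's). Data are stored
#' as float64, so intensities round-trip bit-exactly; the affine round-trips to
#' single precision (the NIfTI-1 header stores it as float32).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a `volume_image` (for writing).
#' @param modality modality tag to attach on read.
#' @return `read_volume` returns a `volume_image`; `write_volume` the path,
#'   invisibly.
#' @export
read_volume <- function(path, modality = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  a <- array(as.vector(a, mode = "double"), d)   # plain array, no header attrs
  volume_image(a, affine = aff, modality = modality)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %s  %d x %d x %d voxels, spacing %s mm\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(vol_spacing(x), 3), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(vol_origin(x), 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}
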