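#' Assemble standardized per-voxel feature vectors
#'
#' One feature vector per masked voxel, in the fixed component order
#' `t2w_norm, adc, ktrans, ve, kep`. Features are standardized (z-scored)
#' exactly once; the constants are either supplied (a trained model's) or
#' computed from the data and attached, so they can be stored with a model.
#' Voxels carrying fit flags are excluded and reported via the
#' `excluded` attribute.
#'
#' @param maps a `parametric_maps` object.
#' @param mask logical array on the T2W grid, or 1-based linear voxel indices.
#' @param standardize optional list with `center` and `scale` (length 5); NULL
#'   computes them from the masked voxels; FALSE returns raw (unstandardized)
#'   features, for pooling voxels across studies before training.
#' @return numeric matrix (voxels x 5) with attributes `standardize`,
#'   `index` (linear voxel indices retained) and `excluded` (count).
#' @export
assemble_features <- function(maps, mask, standardize = NULL) {
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) stop("empty mask")
  flg <- maps$flags$data[idx]
  keep <- flg == 0
  excluded <- sum(!keep)
  idx <- idx[keep]
  if (length(idx) == 0) stop("all masked voxels are flagged")
  x <- cbind(t2w_norm = maps$t2w_norm$data[idx],
             adc = maps$adc$data[idx],
             ktrans = maps$ktrans$data[idx],
             ve = maps$ve$data[idx],
             kep = maps$kep$data[idx])
  if (isFALSE(standardize))
    return(structure(x, standardize = NULL, index = idx, excluded = excluded))
  if (is.null(standardize)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    standardize <- list(center = ctr, scale = scl)
  }
  x <- sweep(sweep(x, 2, standardize$center), 2, standardize$scale, "/")
  structure(x, standardize = standardize, index = idx, excluded = excluded)
}

feature_names <- c("t2w_norm", "adc", "ktrans", "ve", "kep")

#' Raw malignancy score of feature vectors under an MAI model
#'
#' Steps 1-2 of the MAI algorithm: Gaussian radial-basis activations at the
#' model's kernel centres, projected into predictor space, then linearly
#' combined with a bias into one scalar per voxel.
#'
#' @param x standardized feature matrix (voxels x 5) as produced by
#'   [assemble_features()], or a single vector.
#' @param model a `mai_model`.
#' @return numeric vector of raw scores.
#' @export
raw_malignancy_score <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$centers))
    stop("feature dimension mismatch: expected ", ncol(model$centers))
  phi <- rbf_activations(x, model$centers, model$widths)
  z <- phi %*% model$projection
  drop(z %*% model$weights) + model$bias
}

rbf_activations <- function(x, centers, widths) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-sweep(d2, 2, 2 * widths^2, "/"))
}

#' Monotone calibration of a raw score to MAI
#'
#' Piecewise-linear interpolation through the model's strictly increasing
#' calibration nodes, clamped to [0, 1] and held constant beyond the outer
#' nodes. The nodes anchor Gleason grade g at MAI 0.6 + 0.1 (g - 6) (so the
#' lowest cancerous grade, 6, sits exactly at the 0.6 decision level and grade
#' 10 at 1.0) with benign tissue anchored below 0.6.
#'
#' @param raw numeric vector of raw scores.
#' @param model a `mai_model` with calibration nodes.
#' @return MAI values in [0, 1].
#' @export
calibrate_to_mai <- function(raw, model) {
  nodes <- model$calibration
  if (is.null(nodes) || nrow(nodes) < 1) stop("calibration nodes missing")
  validate_nodes(nodes)
  if (nrow(nodes) == 1) return(pmin(pmax(rep(nodes$mai, length(raw)), 0), 1))
  out <- stats::approx(nodes$raw, nodes$mai, xout = raw, rule = 2)$y
  pmin(pmax(out, 0), 1)
}

validate_nodes <- function(nodes) {
  if (nrow(nodes) > 1 &&
      (any(diff(nodes$raw) <= 0) || any(diff(nodes$mai) <= 0)))
    stop("calibration nodes must be strictly increasing in both coordinates")
  invisible(TRUE)
}

#' Gleason anchor MAI value
#'
#' The linear MAI-Gleason policy: grade g maps to 0.6 + 0.1 (g - 6) for
#' g in 6..10; benign maps to `benign`.
#' @param grade integer vector: 0 (benign) or 6..10.
#' @param benign anchor for benign tissue.
#' @export
gleason_anchor <- function(grade, benign = 0.3) {
  ifelse(grade >= 6, 0.6 + 0.1 * (grade - 6), benign)
}

#' Train the MAI model (two supervised phases)
#'
#' Phase 1 trains the preparation transform and linear classifier to order
#' voxels by malignancy grade: Gaussian kernels are grown dynamically by an
#' error-feedback rule (a new centre is placed at the sample contributing the
#' largest ranking loss), and after each growth step the linear weights are
#' refitted to minimize a logistic pairwise ranking loss over label-ordered
#' pairs (subsampled, seeded). Growth stops when the held-out ranking error
#' has not improved for `patience` rounds or `max_kernels` is reached; the
#' best-validating model is kept. Phase 2 freezes the phase-1 weights and fits
#' the monotone calibration nodes: class-median raw scores are mapped to the
#' Gleason anchors by isotonic (pool-adjacent-violators) regression, giving a
#' piecewise-linear monotone raw-to-MAI mapping that minimizes the squared
#' distance of the class medians to their anchors subject to monotonicity.
#'
#' @param x feature matrix (voxels x 5), standardized
#'   ([assemble_features()]) or raw with `standardize = TRUE`.
#' @param labels integer per voxel: 0 = benign, or Gleason grade 6..10.
#' @param standardize if TRUE, compute standardization constants from `x` and
#'   apply them (x is raw); if FALSE `x` is already standardized and the
#'   constants must be supplied via `constants`.
#' @param constants list(center, scale) when `standardize = FALSE`.
#' @param max_kernels cap on the number of grown kernels.
#' @param patience rounds without validation improvement before stopping.
#' @param n_pairs ranking pairs sampled per round.
#' @param val_fraction held-out fraction for the growth criterion.
#' @param lambda L2 penalty on the linear weights.
#' @param benign_anchor calibration anchor for benign tissue.
#' @param seed RNG seed; training is deterministic given data + seed.
#' @return object of class `mai_model`.
#' @export
mai_train <- function(x, labels, standardize = TRUE, constants = NULL,
                      max_kernels = 64, patience = 5, n_pairs = 20000,
                      val_fraction = 0.2, lambda = 1e-4,
                      benign_anchor = 0.3, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 6:10))) stop("labels must be 0 or 6..10")
  if (length(unique(labels)) < 2) stop("need at least 2 distinct label classes")
  if (nrow(x) != length(labels)) stop("x and labels lengths differ")
  if (standardize) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
    constants <- list(center = ctr, scale = scl)
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else if (is.null(constants)) {
    constants <- attr(x, "standardize")
    if (is.null(constants)) stop("supply standardization constants")
  }
  rank <- ifelse(labels == 0L, 0L, labels - 5L)   # benign < 6 < ... < 10

  with_seed(seed, {
    n <- nrow(x)
    val <- sample.int(n, max(1L, round(val_fraction * n)))
    tr <- setdiff(seq_len(n), val)

    # kernel width: median pairwise distance heuristic on a subsample
    sub <- if (length(tr) > 400) sample(tr, 400) else tr
    dd <- stats::dist(x[sub, , drop = FALSE])
    width0 <- max(stats::median(dd), 1e-6)

    # initial centres: one per class mean
    classes <- sort(unique(rank))
    centers <- t(vapply(classes, function(r)
      colMeans(x[tr, , drop = FALSE][rank[tr] == r, , drop = FALSE]),
      numeric(ncol(x))))
    pairs_tr <- sample_ordered_pairs(rank[tr], n_pairs)
    pairs_val <- sample_ordered_pairs(rank[val], min(n_pairs, 10000))

    w <- NULL
    best <- list(err = Inf, centers = centers, w = NULL, round = 0L)
    stall <- 0L; history <- data.frame()
    for (round in seq_len(max_kernels)) {
      widths <- rep(width0, nrow(centers))
      phi_tr <- rbf_activations(x[tr, , drop = FALSE], centers, widths)
      w0 <- c(if (!is.null(w)) w else numeric(0),
              rep(0, nrow(centers) - length(w)))
      w <- fit_ranking_weights(phi_tr, pairs_tr, w0, lambda)
      s_val <- drop(rbf_activations(x[val, , drop = FALSE], centers,
                                    widths) %*% w)
      err <- mean(s_val[pairs_val[, 2]] <= s_val[pairs_val[, 1]])
      history <- rbind(history, data.frame(round = round,
                                           kernels = nrow(centers),
                                           val_rank_error = err))
      if (err < best$err - 1e-6) {
        best <- list(err = err, centers = centers, w = w, round = round)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= patience || nrow(centers) >= max_kernels || err == 0) break
      # error feedback: new centre at the worst-contributing training sample
      s_tr <- drop(phi_tr %*% w)
      margin <- s_tr[pairs_tr[, 2]] - s_tr[pairs_tr[, 1]]
      pl <- log1p(exp(-pmin(pmax(margin, -50), 50)))
      contrib <- numeric(length(tr))
      agg <- rowsum(c(pl, pl), c(pairs_tr[, 1], pairs_tr[, 2]))
      contrib[as.integer(rownames(agg))] <- agg[, 1]
      ordm <- order(contrib, decreasing = TRUE)
      newc <- NULL
      for (cand in ordm) {
        p <- x[tr[cand], ]
        if (min(colSums((t(centers) - p)^2)) > (0.05 * width0)^2) {
          newc <- p; break
        }
      }
      if (is.null(newc)) break
      centers <- rbind(centers, newc)
    }
    centers <- best$centers; w <- best$w
    widths <- rep(width0, nrow(centers))

    model <- structure(list(
      centers = unname(centers), widths = widths,
      projection = diag(nrow(centers)), weights = w, bias = 0,
      calibration = NULL, standardize = constants,
      feature_names = feature_names, seed = as.integer(seed),
      history = history, val_rank_error = best$err), class = "mai_model")

    # ---- phase 2: monotone Gleason-anchored calibration ----
    raw_all <- raw_malignancy_score(x, model)
    grades <- sort(unique(labels))
    med <- vapply(grades, function(g) stats::median(raw_all[labels == g]),
                  numeric(1))
    anch <- gleason_anchor(grades, benign = benign_anchor)
    model$calibration <- make_calibration_nodes(med, anch)
    model
  })
}

# ordered pairs (i, j) with rank_i < rank_j, uniformly subsampled, seeded by
# the caller's RNG state
sample_ordered_pairs <- function(rank, m) {
  i <- sample.int(length(rank), 4 * m, replace = TRUE)
  j <- sample.int(length(rank), 4 * m, replace = TRUE)
  swap <- rank[i] > rank[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  keep <- rank[i] < rank[j]
  cbind(i, j)[keep, , drop = FALSE][seq_len(min(m, sum(keep))), , drop = FALSE]
}

# minimize mean logistic ranking loss + lambda ||w||^2 by BFGS (analytic grad)
fit_ranking_weights <- function(phi, pairs, w0, lambda) {
  D <- phi[pairs[, 2], , drop = FALSE] - phi[pairs[, 1], , drop = FALSE]
  m <- nrow(D)
  fn <- function(w) {
    u <- drop(D %*% w)
    mean(log1p(exp(-pmin(pmax(u, -50), 50)))) + lambda * sum(w^2)
  }
  gr <- function(w) {
    u <- drop(D %*% w)
    p <- 1 / (1 + exp(pmin(pmax(u, -50), 50)))
    drop(-crossprod(D, p)) / m + 2 * lambda * w
  }
  stats::optim(w0, fn, gr, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))$par
}

# Strictly increasing calibration nodes from class medians and anchors:
# sort by median, pool-adjacent-violators on the anchors, merge pooled runs.
make_calibration_nodes <- function(medians, anchors) {
  o <- order(medians)
  m <- medians[o]; a <- anchors[o]
  fit <- stats::isoreg(seq_along(a), a)$yf
  grp <- cumsum(c(1, diff(fit) > 1e-12))   # pooled runs share one node
  raw <- as.numeric(tapply(m, grp, mean))
  mai <- as.numeric(tapply(fit, grp, mean))
  nodes <- data.frame(raw = raw, mai = pmin(pmax(mai, 0), 1))
  # collapse any residual non-strict steps
  keep <- c(TRUE, diff(nodes$raw) > 0 & diff(nodes$mai) > 0)
  nodes <- nodes[keep, , drop = FALSE]
  validate_nodes(nodes)
  rownames(nodes) <- NULL
  nodes
}

#' @export
print.mai_model <- function(x, ...) {
  cat(sprintf("<mai_model> %d Gaussian kernels over %d features; %s\n",
              nrow(x$centers), ncol(x$centers),
              paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  validation ranking error %.4f; %d calibration nodes\n",
              x$val_rank_error, nrow(x$calibration)))
  invisible(x)
}

#' @export
summary.mai_model <- function(object, ...) {
  cat("Malignancy Attention Index model\n")
  print(object)
  cat("\nCalibration nodes (raw score -> MAI):\n")
  print(object$calibration, row.names = FALSE)
  cat("\nTraining history (tail):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mai_model <- function(object, ...) {
  stats::setNames(object$weights,
                  sprintf("kernel%02d", seq_along(object$weights)))
}

#' Predict MAI (or raw scores) for feature vectors
#'
#' @param object a `mai_model`.
#' @param newdata raw (unstandardized) feature matrix with the model's five
#'   components, or a matrix from [assemble_features()] with
#'   `standardized = TRUE`.
#' @param type "mai" for calibrated values in [0,1], "raw" for raw scores.
#' @param standardized set TRUE when `newdata` is already standardized.
#' @param ... unused.
#' @export
predict.mai_model <- function(object, newdata, type = c("mai", "raw"),
                              standardized = FALSE, ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!standardized)
    x <- sweep(sweep(x, 2, object$standardize$center), 2,
               object$standardize$scale, "/")
  raw <- raw_malignancy_score(x, object)
  if (type == "raw") raw else calibrate_to_mai(raw, object)
}

#' @export
plot.mai_model <- function(x, ...) {
  nodes <- x$calibration
  rng <- range(nodes$raw) + c(-1, 1) * diff(range(nodes$raw)) * 0.2
  grid <- seq(rng[1], rng[2], length.out = 200)
  plot(grid, calibrate_to_mai(grid, x), type = "l", ylim = c(0, 1),
       xlab = "raw malignancy score", ylab = "MAI",
       main = "Monotone Gleason-anchored calibration", ...)
  graphics::points(nodes$raw, nodes$mai, pch = 19)
  graphics::abline(h = 0.6, lty = 3)
  invisible(x)
}

#' Serialize an MAI model as versioned JSON
#'
#' Numeric fields are written at full precision (17 significant digits), so a
#' write-read round trip reproduces the model bit-exactly.
#'
#' @param model a `mai_model`.
#' @param path file path.
#' @export
write_mai_model <- function(model, path) {
  payload <- list(format = "maimap-model", version = 1L,
                  feature_names = model$feature_names,
                  centers = model$centers, widths = model$widths,
                  projection = model$projection, weights = model$weights,
                  bias = model$bias,
                  calibration = model$calibration,
                  standardize = model$standardize,
                  seed = model$seed,
                  val_rank_error = model$val_rank_error)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_mai_model
#' @export
read_mai_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "maimap-model")) stop("not an MAI model file")
  nodes <- as.data.frame(j$calibration)
  validate_nodes(nodes)
  as_mat <- function(v, nc) {
    if (is.matrix(v)) v else matrix(unlist(v), ncol = nc, byrow = TRUE)
  }
  structure(list(centers = unname(as_mat(j$centers, length(j$feature_names))),
                 widths = as.numeric(j$widths),
                 projection = unname(as_mat(j$projection, length(j$widths))),
                 weights = as.numeric(j$weights), bias = as.numeric(j$bias),
                 calibration = nodes,
                 standardize = list(
                   center = stats::setNames(unlist(j$standardize$center),
                                            unlist(j$feature_names)),
                   scale = stats::setNames(unlist(j$standardize$scale),
                                           unlist(j$feature_names))),
                 feature_names = unlist(j$feature_names),
                 seed = j$seed, history = NULL,
                 val_rank_error = j$val_rank_error), class = "mai_model")
}

#' Compute a pixel-wise MAI map for one study
#'
#' Orchestrates the three analysis steps: co-registration of DWI and DCE to
#' the T2W grid (optional if transforms are supplied or the series are already
#' aligned), computation of the parametric maps, and voxel-wise scoring plus
#' monotone calibration. Flagged voxels receive MAI 0.
#'
#' @param study study list (see [generate_phantom()]).
#' @param model a trained `mai_model`.
#' @param voi VOI box (see [normalize_t2w()]); scoring is restricted to it.
#' @param register if TRUE run [register_affine()] for DWI and DCE (the DCE
#'   transform is estimated on the first post-onset frame); if FALSE use
#'   identity transforms.
#' @param maps optionally, precomputed `parametric_maps` (skips steps 1-2).
#' @param ... options passed to [register_affine()].
#' @return a [volume_image()] of MAI in [0, 1] on the T2W grid, with
#'   attribute `maps` (the `parametric_maps`) and `transforms`.
#' @export
compute_mai_map <- function(study, model, voi = NULL, register = FALSE,
                            maps = NULL, ...) {
  tf_dwi <- affine9(); tf_dce <- affine9()
  if (is.null(maps)) {
    if (register) {
      tf_dwi <- register_affine(study$t2w, study$dwi[[1]], ...)$transform
      post <- which(study$dce_times_s >= (study$aif_onset_s %||% 60))[1]
      if (is.na(post)) post <- length(study$dce)
      tf_dce <- register_affine(study$t2w, study$dce[[post]], ...)$transform
    }
    maps <- compute_parametric_maps(study, dwi_transform = tf_dwi,
                                    dce_transform = tf_dce, voi = voi)
  }
  d <- dim(study$t2w$data)
  idx <- voi_indices(d, voi)
  feats <- assemble_features(maps, idx, standardize = model$standardize)
  mai_vals <- calibrate_to_mai(raw_malignancy_score(feats, model), model)
  out <- array(0, d)
  out[attr(feats, "index")] <- mai_vals
  vol <- volume_image(out, affine = study$t2w$affine, modality = "mai")
  attr(vol, "maps") <- maps
  attr(vol, "transforms") <- list(dwi = tf_dwi, dce = tf_dce)
  vol
}
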