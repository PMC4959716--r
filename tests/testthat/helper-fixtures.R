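# Shared fixtures, built once per test run (phantom generation and map
# fitting are the expensive steps).
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# compact study geometry used by most unit tests
small_spec <- function(lesions = list(), seed = 1L, ...) {
  phantom_spec(shape = list(t2w = c(48, 48, 12), dwi = c(18, 18, 12),
                            dce = c(24, 24, 24)),
               prostate_semiaxes = c(15, 13, 12.5),
               lesions = lesions, seed = seed, ...)
}

# one ~0.52 ml Gleason-8 lesion that fits the small prostate
small_lesion <- function(gleason = 8)
  list(center = c(4, 2, 0), semiaxes = c(5.5, 5, 4.5), gleason = gleason)

small_voi <- function() list(x = c(2, 46), y = c(4, 44), z = c(0, 12))

# phantom + maps with a G6 and a G8 lesion (training-grade fixture)
graded_fixture <- function() cached("graded", {
  spec <- small_spec(lesions = list(
    list(center = c(4, 2, 0), semiaxes = c(5.5, 5, 4.5), gleason = 8),
    list(center = c(-5, -3, 2), semiaxes = c(4.5, 4, 3.5), gleason = 6)),
    seed = 42)
  ph <- generate_phantom(spec)
  maps <- compute_parametric_maps(ph$study, voi = small_voi())
  list(spec = spec, phantom = ph, maps = maps)
})

# trained model on the graded fixture
trained_model <- function() cached("model", {
  fx <- graded_fixture()
  lab <- fx$phantom$truth$labels$data
  idx <- maimap:::voi_indices(dim(lab), small_voi())
  feats <- assemble_features(fx$maps, idx, standardize = FALSE)
  strata <- lab[attr(feats, "index")]
  labs <- ifelse(strata >= 6, strata, 0)
  take <- local({
    set.seed(123)
    unlist(lapply(sort(unique(strata)), function(g) {
      w <- which(strata == g)
      if (length(w) > 600) sample(w, 600) else w
    }))
  })
  mai_train(feats[take, ], as.integer(labs[take]), standardize = TRUE,
            seed = 7)
})

# median surface target-registration error between two transforms (mm)
surface_tre <- function(tf_true, tf_rec, semiaxes) {
  theta <- seq(0, 2 * pi, length.out = 16)
  phi <- seq(0.25, pi - 0.25, length.out = 8)
  pts <- do.call(rbind, lapply(phi, function(p)
    cbind(semiaxes[1] * sin(p) * cos(theta),
          semiaxes[2] * sin(p) * sin(theta),
          semiaxes[3] * cos(p))))
  a <- apply_transform(affine9_matrix(tf_true), pts)
  b <- apply_transform(affine9_matrix(tf_rec), pts)
  stats::median(sqrt(rowSums((a - b)^2)))
}

round2 <- function(x) floor(abs(x) * 100 + 0.5 + 1e-12) / 100 * sign(x)
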