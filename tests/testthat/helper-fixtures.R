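# Shared fixtures. Expensive objects (the full phantom benchmark and the
# trained networks) are built once per test session and cached, so the
# acceptance-level checks and the unit-level checks reuse one training run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small grid for fast architecture-level tests
tiny_grid <- function() WavelengthGrid(421, 9, 34L)

tiny_trunk_cfg <- function(in_ch = 2L)
  acunetConfig(m = 34L, in_ch = in_ch, K = 5L, channels = c(4L, 6L, 8L, 10L),
               kernels = c(5L, 5L, 3L, 3L), fc_sizes = c(16L, 8L))

tiny_library <- function(seed = NULL) makeEndmembers(tiny_grid(), seed = seed)

# full-size benchmark objects (acceptance scale)
bench_grid <- function() WavelengthGrid()

bench_library <- function() fixture("bench_B", function() makeEndmembers(bench_grid()))

bench_phantom <- function() fixture("bench_phantom", function()
  generatePhantomDataset(bench_library(), n_per_vial = 200L, seed = 11))

bench_split <- function() fixture("bench_split", function()
  splitByGroup(bench_phantom(), 0.15, seed = 11))

bench_opt <- function() optimConfig(epochs = 20L, batch = 256L)

bench_acunet <- function() fixture("bench_acunet", function()
  trainAcunet(bench_split()$train, bench_library(), opt = bench_opt(),
              seed = 11))

bench_acusa <- function() fixture("bench_acusa", function() {
  B <- bench_library()
  train <- bench_split()$train
  cfg <- acusaConfig()
  model <- buildAcusa(cfg, B, seed = 11)
  aug <- augmentMixtures(B, 4000L, noiseModel(0.01, 0), seed = 12)
  pool <- cbind(fluoSpectra(train), aug$spectra)
  tgt <- cbind(fluoSpectra(train), aug$clean)
  model <- trainStage1(pool, model, targets = tgt,
                       opt = optimConfig(epochs = 8L, batch = 256L), seed = 11)
  trainStage2(train, model, opt = optimConfig(epochs = 12L, batch = 256L),
              seed = 11)
})

# projected-gradient NNLS oracle, independent of the package's solver
pg_nnls <- function(Bm, phi, iters = 5000L, tol = 1e-12) {
  step <- 1 / max(eigen(crossprod(Bm), only.values = TRUE)$values)
  z <- rep(0, ncol(Bm))
  obj_old <- Inf
  for (i in seq_len(iters)) {
    z <- pmax(z - step * drop(crossprod(Bm, Bm %*% z - phi)), 0)
    obj <- sum((Bm %*% z - phi)^2)
    if (abs(obj_old - obj) < tol * max(1, obj)) break
    obj_old <- obj
  }
  list(z = z, objective = obj)
}

nnls_objective <- function(Bm, phi, z) sum((Bm %*% z - phi)^2)

cv_of <- function(v) stats::sd(v) / mean(v)

# per-band coefficient of variation averaged over bands with usable signal
mean_band_cv <- function(mat) {
  mu <- rowMeans(mat)
  keep <- mu > 0.05 * max(mu)
  mean(apply(mat[keep, , drop = FALSE], 1, stats::sd) / mu[keep])
}
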