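test_that("the fixed decoder maps unit abundances to endmember columns", {
  B <- tiny_library()
  Bm <- endmemberMatrix(B)
  model <- buildAcusa(acusaConfig(hu_cfg = tiny_trunk_cfg(in_ch = 1L)), B,
                      seed = 2)
  # the decoder is B itself with no trainable parameters
  for (k in 1:5) {
    ek <- replace(rep(0, 5), k, 1)
    expect_equal(mixSpectra(B, ek), unname(Bm[, k]))
  }
  expect_identical(model@state$Bm, Bm)
  # a rank-deficient library is rejected
  Bbad <- Bm; Bbad[, 2] <- Bbad[, 1]
  g <- tiny_grid()
  expect_error(EndmemberLibrary(Bbad, g), "independent")
})

test_that("the twin encoder shares every weight with the HU encoder", {
  B <- tiny_library()
  cfg <- acusaConfig(hu_cfg = tiny_trunk_cfg(in_ch = 1L))
  model <- buildAcusa(cfg, B, seed = 4)
  spectra <- endmemberMatrix(B)
  # twin logits are the HU encoder's pre-activation output on the same input
  lg <- twinLogits(model, spectra)
  z <- huEncode(model, spectra)
  phin <- fluorounmix:::.unit_cols(spectra)
  lg2 <- fluorounmix:::.trunk_forward(
    model@params$hu, array(phin, c(34, 5, 1)), cfg$hu_cfg)$logits
  expect_equal(unname(z), unname(pmax(lg2, 0)), tolerance = 1e-12)
  # normalization module output has length m and is non-negative
  x <- array(abs(rnorm(34 * 3 * 2)), c(34, 3, 2))
  nf <- fluorounmix:::.norm_forward(model@params$norm, x, cfg)
  expect_equal(dim(nf$y), c(34L, 3L, 1L))
  expect_true(all(nf$y >= 0))
})

test_that("endmember cross-entropy has its closed forms and invariances", {
  # a dominant logit gives -log softmax_max
  phi <- c(10, 0, 0, 0, 0)
  expect_equal(endmemberCrossEntropy(phi, 1),
               -log(exp(10) / sum(exp(phi))), tolerance = 1e-9)
  expect_lt(endmemberCrossEntropy(phi, 1), 2e-4)
  # uniform logits give log K for every target
  for (k in 1:5) expect_equal(endmemberCrossEntropy(rep(1.3, 5), k), log(5),
                              tolerance = 1e-12)
  # shift invariance of the softmax
  set.seed(12)
  phi <- rnorm(5)
  expect_equal(endmemberCrossEntropy(phi + 17.3, 3),
               endmemberCrossEntropy(phi, 3), tolerance = 1e-9)
  # log-sum-exp stabilization survives extreme logits
  expect_true(is.finite(endmemberCrossEntropy(c(1e4, 0, 0, 0, 0), 2)))
})

test_that("augmented mixtures live in the endmember column space", {
  B <- tiny_library()
  Bm <- endmemberMatrix(B)
  aug <- augmentMixtures(B, 50L, noiseModel(0, 0), seed = 5)
  # noise-free mixtures project onto span(B) with negligible residual
  proj <- Bm %*% solve(crossprod(Bm), crossprod(Bm, aug$spectra))
  expect_lt(max(abs(proj - aug$spectra)), 1e-10)
  expect_equal(aug$spectra, aug$clean)
  # empty request and determinism
  expect_equal(ncol(augmentMixtures(B, 0L, seed = 5)$spectra), 0L)
  expect_identical(augmentMixtures(B, 20L, seed = 9),
                   augmentMixtures(B, 20L, seed = 9))
})

test_that("stage 1 learns endmember identification on synthetic mixtures", {
  B <- tiny_library()
  cfg <- acusaConfig(hu_cfg = tiny_trunk_cfg(in_ch = 1L))
  model <- buildAcusa(cfg, B, seed = 17)
  aug <- augmentMixtures(B, 1500L, noiseModel(0.01, 0), seed = 18)
  model0 <- model
  model <- trainStage1(aug$spectra, model, targets = aug$clean,
                       opt = optimConfig(epochs = 30L, batch = 128L),
                       seed = 17)
  h <- subset(trainingHistory(model), stage == "stage1")$loss
  expect_true(all(is.finite(h)))
  expect_lt(h[length(h)], h[1])
  # the twin classifies all K pure endmember spectra with positive margin
  lg <- twinLogits(model, endmemberMatrix(B))
  expect_equal(apply(lg, 2, which.max), 1:5)
  margins <- vapply(1:5, function(k)
    lg[k, k] - max(lg[-k, k]), numeric(1))
  expect_true(all(margins > 0))
  # reconstruction of clean held-out mixtures beats the injected noise floor
  held <- augmentMixtures(B, 200L, noiseModel(0, 0), seed = 30)
  recon_mse <- function(mod) {
    z <- huEncode(mod, held$spectra)
    recon <- fluorounmix:::.unit_cols(endmemberMatrix(B) %*% z)
    tgt <- fluorounmix:::.unit_cols(held$clean)
    mean(colMeans((recon - tgt)^2))
  }
  mse <- recon_mse(model)
  # reconstruction on clean held-out mixtures: far below the untrained
  # encoder, and small in absolute terms (the bound reflects what this
  # deliberately small test architecture reaches in 30 epochs; the
  # full-size model is checked on the benchmark in the acceptance suite)
  expect_lt(mse, 0.25 * recon_mse(model0))
  expect_lt(mse, 2e-3)
})

test_that("stage 2 trains only the normalization module", {
  B <- tiny_library()
  cfg <- acusaConfig(hu_cfg = tiny_trunk_cfg(in_ch = 1L))
  model <- buildAcusa(cfg, B, seed = 21)
  aug <- augmentMixtures(B, 800L, noiseModel(0.01, 0), seed = 22)
  model <- trainStage1(aug$spectra, model, targets = aug$clean,
                       opt = optimConfig(epochs = 6L, batch = 128L), seed = 21)
  hu_before <- model@params$hu
  ds <- generatePhantomDataset(B, n_per_vial = 4L, seed = 23)
  model2 <- trainStage2(ds, model, opt = optimConfig(epochs = 6L, batch = 64L),
                        seed = 21)
  # frozen contract: byte-identical HU parameters across stage 2
  expect_identical(model2@params$hu, hu_before)
  expect_false(identical(model2@params$norm, model@params$norm))
  h2 <- subset(trainingHistory(model2), stage == "stage2")$loss
  expect_true(all(is.finite(h2)))
  # unlabeled input is rejected
  un <- generateUnlabeledDataset(B, n = 8L, seed = 1)
  expect_error(trainStage2(un, model), "labeled")
})

test_that("prediction exposes the corrected spectrum and composes g then f", {
  B <- tiny_library()
  cfg <- acusaConfig(hu_cfg = tiny_trunk_cfg(in_ch = 1L))
  model <- buildAcusa(cfg, B, seed = 25)
  ds <- generatePhantomDataset(B, n_per_vial = 2L, seed = 26)
  out <- predictAcusa(model, ds)
  expect_true(all(out$corrected >= 0))
  expect_true(all(out$z >= 0))
  expect_equal(dim(out$corrected), c(34L, ncol(ds)))
  # pipeline equals the manual composition g then f
  xb <- fluorounmix:::.stack_input(fluoSpectra(ds), refSpectra(ds), 1:5)
  gout <- fluorounmix:::.norm_forward(model@params$norm, xb, cfg)$y
  zman <- pmax(fluorounmix:::.trunk_forward(model@params$hu, gout,
                                            cfg$hu_cfg)$logits, 0)
  expect_equal(unname(out$z[, 1:5]), unname(zman), tolerance = 1e-9)
})
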