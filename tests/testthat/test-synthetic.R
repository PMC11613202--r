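test_that("the endmember library has the documented peaks and full rank", {
  g <- bench_grid()
  B <- makeEndmembers(g)
  wl <- wavelengths(g)
  Bm <- endmemberMatrix(B)
  expect_equal(endmemberNames(B),
               c("ppix634", "ppix620", "lipofuscin", "nadh", "flavins"))
  expect_lte(abs(wl[which.max(Bm[, "ppix634"])] - 634), 3)
  expect_lte(abs(wl[which.max(Bm[, "ppix620"])] - 620), 3)
  expect_true(all(apply(Bm, 2, max) == 1))
  expect_gt(min(svd(Bm)$d), 1e-6)
  # seeded perturbation is deterministic and stays within bounds
  B1 <- makeEndmembers(g, seed = 5)
  B2 <- makeEndmembers(g, seed = 5)
  expect_identical(endmemberMatrix(B1), endmemberMatrix(B2))
  expect_lte(abs(wl[which.max(endmemberMatrix(B1)[, "ppix634"])] - 634), 5)
  small <- WavelengthGrid(500, 3, 20L)
  expect_error(makeEndmembers(small), "cover")
})

test_that("reflectance and attenuation follow the stated functional forms", {
  g <- bench_grid()
  o1 <- opticalProperties(42, 11.6, geom = 1)
  o2 <- opticalProperties(42, 11.6, geom = 2.5)
  R1 <- reflectanceCurve(o1, g); R2 <- reflectanceCurve(o2, g)
  A1 <- attenuationCurve(o1, g); A2 <- attenuationCurve(o2, g)
  expect_true(all(R1 > 0) && all(A1 > 0))
  # R is linear in geom; A scales as geom^(1 + 0.7) by construction
  expect_equal(R2, 2.5 * R1, tolerance = 1e-12)
  expect_equal(A2, 2.5^1.7 * A1, tolerance = 1e-12)
  # vanishing absorption pushes R to the geometric factor everywhere
  tiny_mua <- opticalProperties(1e-9, 11.6, geom = 1.3)
  expect_equal(reflectanceCurve(tiny_mua, g), rep(1.3, 104),
               tolerance = 1e-6)
  # composing the helpers reproduces the attenuation formula exactly
  wl <- wavelengths(g)
  sel <- wl >= 620 & wl <= 640
  expect_equal(A1, R1^0.7 * mean(R1[sel]), tolerance = 1e-12)
})

test_that("simulated pairs reduce to the linear model without attenuation", {
  g <- bench_grid()
  B <- bench_library()
  z <- c(1, 0.5, 0, 0.2, 0.1)
  o <- opticalProperties(1e-9, 11.6, geom = 1)
  p <- simulatePair(z, B, o, noiseModel(0, 0), seed = 3)
  clean <- mixSpectra(B, z)
  ratio <- p$phi_fluo / clean
  ratio <- ratio[clean > 1e-6]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  # reproducible under the seed
  p2 <- simulatePair(z, B, o, noiseModel(0.05, 10), seed = 3)
  p3 <- simulatePair(z, B, o, noiseModel(0.05, 10), seed = 3)
  expect_identical(p2, p3)
})

test_that("noisy simulation is unbiased about the noiseless spectrum", {
  g <- WavelengthGrid(421, 15, 21L)   # coarse grid keeps the draw cheap
  B <- makeEndmembers(g)
  z <- c(1.5, 0, 0.2, 0, 0.1)
  o <- opticalProperties(42, 11.6, 1)
  clean <- fluorounmix:::.forward_block(matrix(z), B, o, g)$fluo
  nm <- noiseModel(gaussian_sd = 0.02, poisson_scale = 200)
  draws <- vapply(1:10000, function(s)
    simulatePair(z, B, o, nm, seed = s)$phi_fluo, numeric(21))
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  # per band the Monte-Carlo mean sits within 4 SE of the noiseless value;
  # bands whose clean signal is comparable to the read noise are excluded
  # because the zero-clipping stage truncates their noise distribution
  keep <- drop(clean) > 5 * nm$gaussian_sd
  expect_gte(sum(keep), 8)
  expect_true(all(abs(rowMeans(draws) - drop(clean))[keep] < 4 * se[keep]))
})

test_that("the phantom dataset reproduces the vial design", {
  B <- bench_library()
  ds <- generatePhantomDataset(B, n_per_vial = 10L, seed = 4)
  expect_equal(ncol(ds), 45L * 10L)
  expect_equal(length(unique(groupIds(ds))), 45L)
  expect_true(all(ppixConc(ds) %in% c(0.0, 0.2, 0.6, 1.25, 2.5)))
  expect_true(all(unitTags(ds) == "ug_per_ml"))
  # identical inputs give identical outputs (generator is a pure function)
  ds2 <- generatePhantomDataset(B, n_per_vial = 10L, seed = 4)
  expect_identical(fluoSpectra(ds), fluoSpectra(ds2))
  # within one vial the noiseless spectra are identical
  nl <- generatePhantomDataset(B, n_per_vial = 5L, seed = 4,
                               noise = noiseModel(0, 0))
  v <- fluoSpectra(nl)[, groupIds(nl) == groupIds(nl)[1]]
  expect_lt(max(abs(v - v[, 1])), 1e-12)
})

test_that("the homogenate dataset has per-sample optics and zero-PpIX purity", {
  B <- bench_library()
  ds <- generatePbhDataset(B, n_per_sample = 8L, samples_per_conc = 4L,
                           seed = 6)
  expect_equal(length(unique(groupIds(ds))), 7L * 4L)
  expect_equal(ncol(ds), 7L * 4L * 8L)
  expect_true(all(unitTags(ds) == "pmol_per_mg"))
  expect_setequal(unique(ppixConc(ds)), c(0, 0.5, 0.75, 1, 2, 3, 4))
  # zero-concentration samples carry no PpIX in either photostate: their
  # noiseless spectra contain no energy in a PpIX-only contrast
  nl <- generatePbhDataset(B, n_per_sample = 3L, samples_per_conc = 2L,
                           seed = 6, noise = noiseModel(0, 0),
                           conc_jitter_cv = 0)
  zero <- nl[, ppixConc(nl) == 0]
  z <- nnlsUnmix(correctDualBand(zero), bench_library())
  # the residual spectral tilt of the correction leaks only marginally
  # into the PpIX components relative to the real autofluorescence
  expect_lt(max(z[1:2, ]), 0.1 * max(z[3:5, ]))
  # group-wise optics differ: reflectance spectra vary across groups
  refs <- vapply(unique(groupIds(nl)), function(gid)
    refSpectra(nl)[, which(groupIds(nl) == gid)[1]], numeric(104))
  expect_gt(mean(apply(refs, 1, stats::var)), 0)
})

test_that("the unlabeled generator draws sparse seeded mixtures", {
  B <- bench_library()
  ds <- generateUnlabeledDataset(B, n = 400L, seed = 7)
  expect_true(all(is.na(ppixConc(ds))))
  expect_true(all(unitTags(ds) == "unlabeled"))
  ds2 <- generateUnlabeledDataset(B, n = 400L, seed = 7)
  expect_identical(fluoSpectra(ds), fluoSpectra(ds2))
  # support size: Binomial(5, 0.6) mean 3, sd sqrt(1.2); recover the support
  # by unmixing the noise-free unattenuated mixtures
  aug <- augmentMixtures(B, 600L, noiseModel(0, 0), seed = 8)
  sizes <- colSums(aug$z > 0)
  se <- sqrt(5 * 0.6 * 0.4 / 600)
  expect_lt(abs(mean(sizes) - 3), 3 * se)
})

test_that("rendered cubes round-trip through the preprocessing pipeline", {
  B <- bench_library()
  ds <- generatePhantomDataset(B, n_per_vial = 1L, seed = 9,
                               noise = noiseModel(0, 0))[, 1:36]
  cubes <- renderCubes(ds, H = 10, W = 10, seed = 9, dark_sd = 0.01)
  expect_identical(renderCubes(ds, H = 10, W = 10, seed = 9, dark_sd = 0.01),
                   cubes)
  mask <- maskForeground(binPixels(subtractDark(cubes$white, cubes$dark), 1L))
  # the dark border is excluded
  expect_false(any(mask[1, ]) || any(mask[, 1]) ||
                 any(mask[10, ]) || any(mask[, 10]))
  pairs <- extractPairs(cubes$fluo, cubes$white, cubes$dark, b = 1L)
  expect_equal(ncol(pairs), 36L)
  # recovered spectra match the originals to noise tolerance
  ord <- order(SummarizedExperiment::colData(pairs)$px_row,
               SummarizedExperiment::colData(pairs)$px_col)
  got <- fluoSpectra(pairs)[, ord]
  want <- fluoSpectra(ds)
  expect_lt(max(abs(got - want)), 0.1)
  expect_lt(mean(abs(got - want)), 0.02)
})
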