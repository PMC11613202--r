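test_that("the linear mixing model matches an explicit per-endmember sum", {
  B <- tiny_library()
  Bm <- endmemberMatrix(B)
  K <- ncol(Bm)
  expect_equal(mixSpectra(B, rep(0, K)), rep(0, nrow(Bm)))
  for (k in seq_len(K)) {
    ek <- replace(rep(0, K), k, 1)
    expect_equal(mixSpectra(B, ek), unname(Bm[, k]))
  }
  set.seed(7)
  z <- runif(K, 0, 3)
  loop <- rep(0, nrow(Bm))
  for (k in seq_len(K)) loop <- loop + z[k] * Bm[, k]
  expect_equal(mixSpectra(B, z), loop, tolerance = 1e-12)
  expect_error(mixSpectra(B, rep(1, K + 1)), "match K")
})

test_that("NNLS recovers noiseless mixtures and respects the cone", {
  B <- tiny_library()
  Bm <- endmemberMatrix(B)
  set.seed(8)
  for (i in 1:20) {
    z_true <- runif(5) * rbinom(5, 1, 0.7)
    z <- nnlsUnmix(mixSpectra(B, z_true), B)
    expect_lt(max(abs(z - z_true)), 1e-8)
  }
  # an anti-correlated spectrum maps to the zero vector
  z0 <- nnlsUnmix(-Bm[, 1], B)
  expect_equal(unname(z0), rep(0, 5))
  pg <- pg_nnls(Bm, -Bm[, 1])
  expect_gte(pg$objective + 1e-9, nnls_objective(Bm, -Bm[, 1], z0))
  expect_error(nnlsUnmix(c(NA, rep(1, 33)), B), "non-finite")
})

test_that("NNLS matches a dense grid search on a tiny instance", {
  set.seed(10)
  g <- WavelengthGrid(500, 10, 5L)
  Bm <- matrix(runif(10), 5, 2)
  Bm <- sweep(Bm, 2, apply(Bm, 2, max), "/")
  colnames(Bm) <- c("u", "v")
  B <- EndmemberLibrary(Bm, g)
  phi <- drop(Bm %*% c(1.2, 0.4)) + rnorm(5, sd = 0.05)
  z <- nnlsUnmix(phi, B)
  zz <- seq(0, 3, by = 1e-3)
  best <- Inf
  # separable profile: for each z1 the optimal z2 on the grid
  for (a in zz) {
    r <- phi - Bm[, 1] * a
    b <- zz[which.min(abs(zz - max(0, sum(Bm[, 2] * r) / sum(Bm[, 2]^2))))]
    o <- sum((Bm %*% c(a, b) - phi)^2)
    if (o < best) best <- o
  }
  expect_lt(nnls_objective(Bm, phi, z), best + 1e-9)
})

test_that("NNLS objective matches the projected-gradient oracle", {
  B <- bench_library()
  Bm <- endmemberMatrix(B)
  set.seed(12)
  for (i in 1:25) {
    z_true <- runif(5) * rbinom(5, 1, 0.6)
    phi <- drop(Bm %*% z_true) + rnorm(104, sd = 0.01)
    z <- nnlsUnmix(phi, B)
    expect_true(all(z >= 0))
    pg <- pg_nnls(Bm, phi)
    expect_lt(nnls_objective(Bm, phi, z) - pg$objective, 1e-6)
    # and beats the clipped unconstrained least-squares solution
    ls_clip <- pmax(drop(solve(crossprod(Bm), crossprod(Bm, phi))), 0)
    expect_lte(nnls_objective(Bm, phi, z),
               nnls_objective(Bm, phi, ls_clip) + 1e-12)
  }
})

test_that("dual-band factors follow the closed forms", {
  g <- WavelengthGrid(421, 3, 104L)
  ones <- rep(1, 104)
  # band edges on grid nodes (451-481 and 610-640 nm), both width 30 nm
  cfg <- dualBandConfig(band_a = c(451, 481), band_b = c(610, 640),
                        exponent = 1)
  expect_equal(dualBandFactor(ones, g, cfg), 30 * 30, tolerance = 1e-9)
  cfg0 <- dualBandConfig(band_a = c(451, 481), band_b = c(610, 640),
                         exponent = 0)
  expect_equal(dualBandFactor(ones, g, cfg0), 30, tolerance = 1e-9)

  # random smooth spectrum vs a fine-grid quadrature oracle
  set.seed(13)
  coef <- rnorm(5, sd = 0.2)
  f <- function(wl) 1 + 0.5 * sin(wl / 40) + colSums(coef * rbind(
    sin(wl / 17), cos(wl / 29), sin(wl / 53), cos(wl / 71), sin(wl / 97)))
  cfg7 <- dualBandConfig(exponent = 0.7)
  s <- dualBandFactor(f(wavelengths(g)), g, cfg7)
  fine <- function(a, b) {
    # trapezoid on the same nodes the native grid uses, then Richardson-style
    # refinement with 1000x subdivision of the node polyline
    wl <- wavelengths(g)
    sel <- wl >= a & wl <= b
    x <- wl[sel]; y <- f(wl)[sel]
    xs <- seq(min(x), max(x), length.out = 1000 * length(x))
    pracma::trapz(xs, approx(x, y, xout = xs)$y)
  }
  oracle <- fine(450, 480)^0.7 * fine(620, 640)
  expect_lt(abs(s - oracle) / oracle, 1e-6)

  expect_error(dualBandFactor(rep(0, 104), g), "non-positive")
})

test_that("dual-band correction is scale-equivariant and cancels geometry", {
  g <- bench_grid()
  B <- bench_library()
  z <- c(1.25, 0, 0, 0, 0.05)
  o1 <- opticalProperties(42, 11.6, geom = 1)
  p1 <- simulatePair(z, B, o1, noiseModel(0, 0), seed = 1)
  x1 <- SpectraSet(cbind(p1$phi_fluo), cbind(p1$phi_ref), g)
  # scaling phi_fluo by alpha scales the corrected spectrum by alpha
  alpha <- 3.7
  xa <- SpectraSet(cbind(alpha * p1$phi_fluo), cbind(p1$phi_ref), g)
  expect_equal(correctDualBand(xa), alpha * correctDualBand(x1),
               tolerance = 1e-12)
  # a pair differing only in the geometric factor corrects identically
  o2 <- opticalProperties(42, 11.6, geom = 2.4)
  p2 <- simulatePair(z, B, o2, noiseModel(0, 0), seed = 1)
  x2 <- SpectraSet(cbind(p2$phi_fluo), cbind(p2$phi_ref), g)
  expect_equal(correctDualBand(x2), correctDualBand(x1), tolerance = 1e-9)
})

test_that("the classical pipeline recovers abundances through attenuation", {
  g <- bench_grid()
  B <- bench_library()
  # geometry-only variation: every pixel with the same z yields the same
  # abundances regardless of geom, and the PpIX estimate is perfectly
  # linear in the true concentration (the correction is sufficient here)
  cs <- c(0.2, 0.6, 1.25, 2.5)
  geoms <- c(0.6, 1, 1.9, 0.8)
  fl <- NULL; rf <- NULL
  for (i in seq_along(cs)) for (gm in geoms) {
    p <- simulatePair(c(cs[i], 0, 0, 0, 0.05), B,
                      opticalProperties(42, 11.6, gm),
                      noiseModel(0, 0), seed = 1)
    fl <- cbind(fl, p$phi_fluo); rf <- cbind(rf, p$phi_ref)
  }
  x <- SpectraSet(fl, rf, g, c_ppix = rep(cs, each = length(geoms)),
                  unit_tag = "ug_per_ml")
  out <- classicalPipeline(x, B)
  for (i in seq_along(cs)) {
    blk <- out$z[, (i - 1) * 4 + 1:4]
    expect_lt(max(abs(blk - blk[, 1])), 1e-8)   # geom fully cancelled
  }
  expect_equal(pearsonR(out$z[1, ], ppixConc(x)), 1, tolerance = 1e-6)

  # zero fluorescence maps to the zero abundance vector
  x0 <- SpectraSet(matrix(0, 104, 1), rf[, 1, drop = FALSE], g)
  expect_equal(unname(classicalPipeline(x0, B)$z[, 1]), rep(0, 5))

  # pure attenuated PpIX634 stays on the first component
  p <- simulatePair(c(1, 0, 0, 0, 0), B, opticalProperties(18, 14.5, 0.5),
                    noiseModel(0, 0), seed = 2)
  zp <- classicalPipeline(SpectraSet(cbind(p$phi_fluo), cbind(p$phi_ref), g),
                          B)$z[, 1]
  expect_lt(max(zp[-1]) / zp[1], 5e-2)
})
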