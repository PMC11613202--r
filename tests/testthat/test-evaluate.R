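test_that("correlation, RMSE and calibration behave as defined", {
  truth <- c(0, 0.5, 1.2, 2.5, 3)
  expect_equal(pearsonR(truth, truth), 1)
  expect_equal(pearsonR(-truth, truth), -1)
  # affine invariance
  expect_equal(pearsonR(2 * truth + 1, truth), 1, tolerance = 1e-12)
  expect_error(pearsonR(rep(1, 5), truth), "variance")
  expect_error(pearsonR(truth, truth[-1]), "lengths")
  expect_error(pearsonR(1, 2), "at least 2")

  expect_equal(rmseMetric(truth, truth), 0)
  expect_equal(rmseMetric(truth + 1, truth), 1)
  # least-squares calibration of a doubled prediction is exactly 0.5
  expect_equal(fitCalibration(2 * truth, truth), 0.5, tolerance = 1e-12)
  expect_equal(rmseMetric(2 * truth, truth,
                          calibration = fitCalibration(2 * truth, truth)),
               0, tolerance = 1e-12)
})

test_that("reconstruction MSE equals the explicit double mean", {
  set.seed(41)
  m <- 12; n <- 10
  recon <- matrix(rnorm(m * n), m)
  meas <- matrix(rnorm(m * n), m)
  got <- reconstructionMse(recon, meas, normalized = FALSE)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + mean((recon[, i] - meas[, i])^2)
  expect_equal(got, acc / n, tolerance = 1e-12)
  expect_equal(reconstructionMse(meas, meas), 0)
  # constant per-band offset c gives c^2
  expect_equal(reconstructionMse(meas + 0.3, meas, normalized = FALSE),
               0.09, tolerance = 1e-12)
})

test_that("the false-positive rate counts exceedances and is monotone", {
  expect_equal(falsePositiveRate(rep(0, 40), eps = 0.01), 0)
  expect_equal(falsePositiveRate(rep(0, 40), eps = -1), 1)
  set.seed(43)
  pred <- c(runif(13, 0.2, 1), runif(87, 0, 0.05))
  expect_equal(falsePositiveRate(pred, eps = 0.1), 13 / 100)
  # non-increasing in the threshold
  eps_grid <- seq(-0.1, 1.1, by = 0.05)
  fprs <- vapply(eps_grid, function(e) falsePositiveRate(pred, e), 1)
  expect_true(all(diff(fprs) <= 0))
  expect_error(falsePositiveRate(numeric(0), 0.1), "empty")
})

test_that("the KS statistic matches direct CDF enumeration", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  ks <- ks2Sample(a, b)
  expect_equal(ks$statistic, 0.5, tolerance = 1e-12)
  expect_equal(ks2Sample(a, a)$statistic, 0)
  expect_equal(ks2Sample(1:50, 101:150)$statistic, 1)
  expect_lt(ks2Sample(1:50, 101:150)$p, 0.05)
  expect_error(ks2Sample(numeric(0), a), "empty")
})

test_that("group splits never straddle and hit the target fraction", {
  B <- bench_library()
  ds <- generatePhantomDataset(B, n_per_vial = 6L, seed = 44)
  sp <- splitByGroup(ds, 0.15, seed = 3)
  expect_length(intersect(sp$train_groups, sp$test_groups), 0L)
  expect_setequal(c(sp$train_groups, sp$test_groups), unique(groupIds(ds)))
  expect_length(intersect(unique(groupIds(sp$train)),
                          unique(groupIds(sp$test))), 0L)
  # 45 equal vials at 15%: six or seven test vials
  expect_true(length(sp$test_groups) %in% 6:7)
  # empty test side at fraction zero
  sp0 <- splitByGroup(ds, 0, seed = 3)
  expect_equal(ncol(sp0$test), 0L)
  # deterministic under the seed
  sp2 <- splitByGroup(ds, 0.15, seed = 3)
  expect_identical(sp$test_groups, sp2$test_groups)
  one <- ds[, groupIds(ds) == groupIds(ds)[1]]
  expect_error(splitByGroup(one, 0.15, 1), "2 groups")
})

test_that("the classical method scores R = 1 on geometry-only data", {
  g <- bench_grid()
  B <- bench_library()
  set.seed(46)
  fl <- NULL; rf <- NULL; cc <- NULL; gid <- NULL
  for (ci in seq_along(c(0.2, 0.6, 1.25, 2.5))) {
    cval <- c(0.2, 0.6, 1.25, 2.5)[ci]
    for (r in 1:6) {
      p <- simulatePair(c(cval, 0, 0, 0, 0.05), B,
                        opticalProperties(42, 11.6, runif(1, 0.5, 2)),
                        noiseModel(0, 0), seed = r)
      fl <- cbind(fl, p$phi_fluo); rf <- cbind(rf, p$phi_ref)
      # groups cut across concentrations so every split side spans the range
      cc <- c(cc, cval); gid <- c(gid, sprintf("rep%d", r))
    }
  }
  x <- SpectraSet(fl, rf, g, group_id = gid, c_ppix = cc,
                  unit_tag = "ug_per_ml")
  res <- evaluateMethod("classical", x, B, seed = 5)
  expect_equal(res$report$pearson_r, 1, tolerance = 1e-6)
  rep <- res$report
  expect_true(all(is.finite(c(rep$pearson_r, rep$rmse, rep$remse, rep$n))))
  expect_match(rep$split_description, "split by group")
})

test_that("competing methods are evaluated on identical test groups", {
  B <- bench_library()
  ds <- generatePhantomDataset(B, n_per_vial = 8L, seed = 47)
  res <- evaluateMethods(c("classical", "pls"), ds, B, seed = 6)
  expect_identical(sort(res$classical$split$test_groups),
                   sort(res$pls$split$test_groups))
  expect_identical(res$classical$truth, res$pls$truth)
  expect_true(is.finite(res$pls$report$pearson_r))
})

test_that("abundance maps scatter predictions onto the masked plane", {
  g <- tiny_grid()
  B <- tiny_library()
  ds <- generatePhantomDataset(B, n_per_vial = 1L, seed = 48,
                               noise = noiseModel(0, 0))[, 1:20]
  cubes <- renderCubes(ds, H = 9, W = 9, seed = 48)
  pairs <- extractPairs(cubes$fluo, cubes$white, cubes$dark, b = 1L)
  z <- classicalPipeline(pairs, B)$z
  maps <- abundanceMap(z, pairs, dims = c(9L, 9L))
  expect_named(maps, endmemberNames(B))
  img <- maps$ppix634
  expect_equal(dim(img), c(9L, 9L))
  expect_equal(sum(!is.na(img)), ncol(pairs))
  expect_true(all(is.na(img[1, ])))   # border is background
  # constant predictions give a constant (masked) image
  zc <- z; zc[1, ] <- 2
  expect_equal(unique(stats::na.omit(c(abundanceMap(zc, pairs,
                                                    c(9L, 9L))$ppix634))), 2)
  # rendering writes a PNG
  path <- tempfile(fileext = ".png")
  writeAbundanceMapPng(img, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
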