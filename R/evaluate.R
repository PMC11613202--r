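#' @include classical.R acunet.R acusa.R baselines.R
NULL

#' Pearson correlation between predicted and true concentrations
#'
#' @param pred,truth numeric vectors of equal length >= 2 with nonzero
#'   variance
#' @return Pearson correlation in [-1, 1]
#' @export
pearsonR <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("lengths differ")
  if (length(pred) < 2L) stop("need at least 2 observations")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop("zero variance input")
  stats::cor(pred, truth)
}

#' Least-squares calibration scale
#'
#' The single factor a minimizing \code{||a * pred - truth||^2}, fit on a
#' training split and applied before RMSE in physical units.
#'
#' @param pred,truth numeric vectors
#' @export
fitCalibration <- function(pred, truth) {
  ss <- sum(pred^2)
  if (ss == 0) return(0)
  sum(pred * truth) / ss
}

#' Root-mean-square concentration error
#'
#' @param pred,truth numeric vectors
#' @param calibration optional scale applied to \code{pred} first (fit it
#'   on training data with \code{\link{fitCalibration}})
#' @export
rmseMetric <- function(pred, truth, calibration = NULL) {
  if (length(pred) != length(truth)) stop("lengths differ")
  if (!is.null(calibration)) pred <- pred * calibration
  sqrt(mean((pred - truth)^2))
}

#' Mean squared reconstruction error (ReMSE)
#'
#' Mean over pixels of the mean squared per-band difference between the
#' model reconstruction and the measured spectrum; both sides unit-l2
#' normalized when \code{normalized} is TRUE.
#'
#' @param recon,measured m x n matrices
#' @param normalized normalize both sides column-wise first
#' @export
reconstructionMse <- function(recon, measured, normalized = TRUE) {
  recon <- as.matrix(recon); measured <- as.matrix(measured)
  if (!identical(dim(recon), dim(measured))) stop("dimensions differ")
  if (normalized) {
    recon <- .unit_cols(recon)
    measured <- .unit_cols(measured)
  }
  mean(colMeans((recon - measured)^2))
}

#' False-positive rate on PpIX-free spectra
#'
#' Fraction of predictions exceeding the tolerance \code{eps} among
#' spectra with zero expected PpIX. NNLS produces exact zeros but any
#' rectified network needs a tolerance; the package default elsewhere is
#' 1 percent of the maximum training-set prediction.
#'
#' @param pred_ppix predictions on truly PpIX-free spectra
#' @param eps decision threshold
#' @export
falsePositiveRate <- function(pred_ppix, eps) {
  if (length(pred_ppix) == 0L) stop("empty prediction list")
  mean(pred_ppix > eps)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the empirical CDFs with the asymptotic p value;
#' p < 0.05 is the conventional significance level.
#'
#' @param a,b numeric samples
#' @return list with \code{statistic} and \code{p}
#' @export
ks2Sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Split a SpectraSet by group
#'
#' Whole vials / homogenate samples / biopsies are assigned to one side so
#' no group straddles the split (pixel-level splits leak the shared
#' underlying spectrum). The achieved test fraction is within one group of
#' the target. Deterministic under the seed.
#'
#' @param x a \linkS4class{SpectraSet}
#' @param test_frac target fraction of pixels in the test side
#' @param seed integer seed
#' @return list with \code{train}, \code{test} (SpectraSets) and the
#'   group id vectors \code{train_groups}, \code{test_groups}
#' @export
splitByGroup <- function(x, test_frac = 0.15, seed = 1) {
  gids <- groupIds(x)
  groups <- unique(gids)
  if (length(groups) < 2L) stop("need at least 2 groups to split")
  if (test_frac < 0 || test_frac >= 1) stop("test_frac must be in [0, 1)")
  sizes <- table(gids)[groups]
  ord <- withr::with_seed(as.integer(seed), sample(groups))
  if (test_frac == 0) {
    test_set <- character(0)
  } else {
    cum <- cumsum(as.numeric(sizes[ord])) / ncol(x)
    k <- which(cum >= test_frac)[1]
    if (k > 1L && abs(cum[k - 1L] - test_frac) < abs(cum[k] - test_frac))
      k <- k - 1L
    test_set <- ord[seq_len(k)]
  }
  in_test <- gids %in% test_set
  list(train = x[, !in_test], test = x[, in_test],
       train_groups = setdiff(groups, test_set), test_groups = test_set)
}

#' Evaluate one method on a labeled dataset
#'
#' Splits by group (or reuses a supplied split so competing methods see
#' identical test pixels), trains/fits the method on the training side,
#' and reports Pearson R, R^2, calibrated RMSE, ReMSE, and the
#' false-positive rate on the zero-concentration test pixels.
#'
#' @param method "classical", "acunet", "acusa", "pls" or "mlp"
#' @param x labeled \linkS4class{SpectraSet}
#' @param B an \linkS4class{EndmemberLibrary}
#' @param seed integer seed (split, initialization, batch order)
#' @param split optional result of \code{\link{splitByGroup}} to reuse
#' @param opt an \code{\link{optimConfig}} for the learned methods
#' @param fpr_frac false-positive tolerance as a fraction of the maximum
#'   training-set prediction
#' @param ... extra arguments passed to the trainer
#' @return list with the metrics, the trained model, the predictions and
#'   the split used
#' @export
evaluateMethod <- function(method, x, B, seed = 1, split = NULL,
                           opt = optimConfig(), fpr_frac = 0.01, ...) {
  method <- match.arg(method, c("classical", "acunet", "acusa", "pls", "mlp"))
  if (is.null(split)) split <- splitByGroup(x, 0.15, seed)
  train <- split$train; test <- split$test
  model <- NULL
  pred_fun <- switch(method,
    classical = {
      function(s) {
        out <- classicalPipeline(s, B)
        list(conc = out$z[1, ], recon = out$recon, measured = out$corrected)
      }
    },
    acunet = {
      model <- trainAcunet(train, B, cfg = acunetConfig(m = nrow(x)),
                           opt = opt, seed = seed, ...)
      function(s) {
        out <- predictAbundance(model, s)
        list(conc = out$z[1, ], recon = out$recon, measured = fluoSpectra(s))
      }
    },
    acusa = {
      model <- .train_acusa_pipeline(train, B, opt = opt, seed = seed, ...)
      function(s) {
        out <- predictAcusa(model, s)
        list(conc = out$z[1, ], recon = out$recon, measured = fluoSpectra(s))
      }
    },
    pls = {
      model <- fitPls(train, ...)
      function(s) list(conc = predictConcentration(model, s),
                       recon = NULL, measured = NULL)
    },
    mlp = {
      model <- trainMlp(train, B, opt = opt, seed = seed, ...)
      function(s) {
        out <- predictAbundance(model, s)
        list(conc = out$z[1, ], recon = out$recon, measured = fluoSpectra(s))
      }
    })
  tr <- pred_fun(train)
  te <- pred_fun(test)
  truth <- ppixConc(test)
  cal <- fitCalibration(tr$conc, ppixConc(train))
  eps <- fpr_frac * max(tr$conc)
  zero_idx <- which(truth == 0)
  report <- list(
    method = method,
    pearson_r = pearsonR(te$conc, truth),
    r_squared = pearsonR(te$conc, truth)^2,
    rmse = rmseMetric(te$conc, truth, calibration = cal),
    remse = if (is.null(te$recon)) NA_real_ else
      reconstructionMse(te$recon, te$measured, normalized = TRUE),
    fpr = if (length(zero_idx)) falsePositiveRate(te$conc[zero_idx], eps)
          else NA_real_,
    fpr_threshold = eps,
    calibration = cal,
    n = ncol(test),
    split_description = sprintf("split by group: %d train / %d test groups",
                                length(split$train_groups),
                                length(split$test_groups))
  )
  list(report = report, model = model, predictions = te$conc, truth = truth,
       split = split)
}

# Convenience: full ACU-SA training pipeline from a labeled training set --
# stage 1 on unit-normalized measured spectra plus synthetic augmentation,
# stage 2 on the labels.
.train_acusa_pipeline <- function(train, B, opt = optimConfig(), seed = 1,
                                  cfg = NULL, augment_n = NULL,
                                  stage1_opt = NULL, label_frac = 1) {
  if (is.null(cfg)) cfg <- acusaConfig(hu_cfg = acunetConfig(m = nrow(train),
                                                             in_ch = 1L))
  if (is.null(augment_n)) augment_n <- cfg$augment_n
  if (is.null(stage1_opt)) stage1_opt <- opt
  model <- buildAcusa(cfg, B, seed)
  aug <- augmentMixtures(B, augment_n, cfg$augment_noise, seed = seed + 1L)
  pool <- cbind(fluoSpectra(train), aug$spectra)
  tgt <- cbind(fluoSpectra(train), aug$clean)
  model <- trainStage1(pool, model, targets = tgt, opt = stage1_opt,
                       seed = seed)
  lab <- train
  if (label_frac < 1) {
    sp <- splitByGroup(train, test_frac = label_frac, seed = seed + 2L)
    lab <- sp$test
  }
  trainStage2(lab, model, opt = opt, seed = seed)
}

#' Evaluate several methods on one shared split
#'
#' @param methods character vector of method names
#' @inheritParams evaluateMethod
#' @return named list of \code{evaluateMethod} results; all methods see
#'   identical train/test group sets
#' @export
evaluateMethods <- function(methods, x, B, seed = 1, opt = optimConfig(),
                            ...) {
  split <- splitByGroup(x, 0.15, seed)
  out <- lapply(methods, function(mth)
    evaluateMethod(mth, x, B, seed = seed, split = split, opt = opt, ...))
  names(out) <- methods
  out
}

#' Per-endmember abundance maps
#'
#' Scatters per-pixel abundances back onto the binned image plane using
#' the pixel coordinates stored by \code{\link{extractPairs}}; background
#' pixels are NA.
#'
#' @param z K x n abundance matrix
#' @param x the \linkS4class{SpectraSet} the abundances were predicted
#'   from (must carry \code{px_row}/\code{px_col})
#' @param dims c(H', W') of the binned image
#' @return named list of H' x W' matrices, NA off-sample
#' @export
abundanceMap <- function(z, x, dims) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("px_row", "px_col") %in% colnames(cd)))
    stop("x carries no pixel coordinates; was it made by extractPairs()?")
  idx <- cbind(cd$px_row, cd$px_col)
  out <- lapply(seq_len(nrow(z)), function(k) {
    img <- matrix(NA_real_, dims[1], dims[2])
    img[idx] <- z[k, ]
    img
  })
  names(out) <- rownames(z)
  out
}

#' Render an abundance map to a PNG file
#'
#' Fixed viridis-like colormap; NA background is transparent.
#'
#' @param img numeric matrix from \code{\link{abundanceMap}}
#' @param path output PNG path
#' @param zlim optional c(min, max) color range
#' @export
writeAbundanceMapPng <- function(img, path, zlim = NULL) {
  if (is.null(zlim)) zlim <- range(img, na.rm = TRUE)
  if (diff(zlim) == 0) zlim[2] <- zlim[1] + 1
  pal <- grDevices::hcl.colors(256, "viridis")
  sc <- pmin(pmax((img - zlim[1]) / diff(zlim), 0), 1)
  ci <- matrix(1L + as.integer(round(sc * 255)), nrow(img), ncol(img))
  rgb <- grDevices::col2rgb(pal) / 255
  arr <- array(0, c(nrow(img), ncol(img), 4))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ci], nrow(img))
  arr[, , 4] <- !is.na(img)
  arr[is.na(arr)] <- 0
  png::writePNG(arr, path)
  invisible(path)
}
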