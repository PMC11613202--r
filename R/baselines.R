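#' @include nn-engine.R SpectraSet.R
NULL

#' MLP baseline configuration
#'
#' The naive fully connected comparison model: input is the horizontally
#' stacked fluorescence + reflectance spectrum (length 2m), hidden sizes
#' 8, K, 8, output length m. The size-K bottleneck is rectified and read
#' as the abundance vector; the final output is the reconstruction head.
#'
#' @param m number of bands
#' @param K number of endmembers (bottleneck width)
#' @param hidden hidden sizes; the middle entry must equal K
#' @export
mlpConfig <- function(m = 104L, K = 5L, hidden = c(8L, K, 8L)) {
  if (length(hidden) != 3L || hidden[2] != K)
    stop("hidden must be length 3 with the middle size equal to K")
  list(m = as.integer(m), K = as.integer(K), hidden = as.integer(hidden))
}

.pls_features <- function(x) {
  X <- t(rbind(fluoSpectra(x), refSpectra(x)))
  colnames(X) <- c(paste0("f", seq_len(nrow(x))), paste0("w", seq_len(nrow(x))))
  X
}

.mlp_init <- function(cfg, seed) {
  withr::with_seed(as.integer(seed), {
    sizes <- c(2L * cfg$m, cfg$hidden, cfg$m)
    p <- list()
    for (j in seq_len(length(sizes) - 1L)) {
      p[[sprintf("W%d", j)]] <- .he_mat(sizes[j], sizes[j + 1])
      p[[sprintf("b%d", j)]] <- rep(0, sizes[j + 1])
    }
    # damped weights into and out of the rectified bottleneck plus positive
    # biases: strong early reconstruction gradients otherwise push the
    # whole abundance bottleneck permanently below zero
    p[["W2"]] <- p[["W2"]] * 0.1
    p[["W3"]] <- p[["W3"]] * 0.1
    p[["b2"]] <- rep(0.5, cfg$K)
    p[["b4"]] <- rep(0.1, cfg$m)
    p[["ls.c"]] <- 0
    p[["ls.rec"]] <- 0
    p
  })
}

.mlp_forward <- function(p, x) {
  h1 <- nn_relu_ip(.dense_fwd(x, p$W1, p$b1))
  zr <- nn_relu_ip(.dense_fwd(h1, p$W2, p$b2))
  h3 <- nn_relu_ip(.dense_fwd(zr, p$W3, p$b3))
  out <- nn_relu_ip(.dense_fwd(h3, p$W4, p$b4))
  list(z = zr, out = out, cache = list(x = x, h1 = h1, zr = zr, h3 = h3))
}

#' Train the naive MLP baseline
#'
#' Same loss, optimizer and schedule contracts as ACU-Net: the rectified
#' K-bottleneck is supervised on the concentration label, the final
#' output on the unit-normalized fluorescence spectrum, with learned
#' homoscedastic log-sigma weights.
#'
#' @param x labeled \linkS4class{SpectraSet}
#' @param B an \linkS4class{EndmemberLibrary} (names/recon bookkeeping)
#' @param cfg an \code{\link{mlpConfig}}
#' @param opt an \code{\link{optimConfig}}
#' @param seed integer seed
#' @param sigma_floor lower bound on learned sigmas
#' @return a trained \linkS4class{FluoroModel} of kind "mlp"
#' @export
trainMlp <- function(x, B, cfg = NULL, opt = optimConfig(), seed = 1,
                     sigma_floor = 1e-3) {
  cvec <- ppixConc(x)
  if (anyNA(cvec)) stop("training set contains unlabeled pairs")
  m <- nrow(x)
  if (is.null(cfg)) cfg <- mlpConfig(m = m, K = ncol(endmemberMatrix(B)))
  p <- .mlp_init(cfg, seed)
  fluo <- fluoSpectra(x); ref <- refSpectra(x)
  feats <- rbind(fluo, ref)
  phi_t <- .unit_cols(fluo)
  st <- .adamw_init(p)
  ls_floor <- log(sigma_floor)
  step_fn <- function(idx, lr) {
    xb <- feats[, idx, drop = FALSE]
    fw <- .mlp_forward(p, xb)
    N <- length(idx)
    sC2 <- exp(2 * p[["ls.c"]]); sR2 <- exp(2 * p[["ls.rec"]])
    rc <- (fw$z[1, ] - cvec[idx])^2
    resid <- fw$out - phi_t[, idx, drop = FALSE]
    rr <- colSums(resid^2)
    loss <- mean(rc) / (2 * sC2) + mean(rr) / (2 * sR2) +
      p[["ls.c"]] + p[["ls.rec"]]
    ca <- fw$cache
    dout <- nn_relu_bwd_ip(resid / (sR2 * N), fw$out)
    bk4 <- .dense_bwd(dout, ca$h3, p$W4)
    dh3 <- nn_relu_bwd_ip(bk4$dx, ca$h3)
    bk3 <- .dense_bwd(dh3, ca$zr, p$W3)
    dz <- bk3$dx
    dz[1, ] <- dz[1, ] + (fw$z[1, ] - cvec[idx]) / (sC2 * N)
    dzp <- nn_relu_bwd_ip(dz, ca$zr)
    bk2 <- .dense_bwd(dzp, ca$h1, p$W2)
    dh1 <- nn_relu_bwd_ip(bk2$dx, ca$h1)
    bk1 <- .dense_bwd(dh1, ca$x, p$W1)
    g <- list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
              W3 = bk3$dW, b3 = bk3$db, W4 = bk4$dW, b4 = bk4$db,
              ls.c = 1 - mean(rc) / sC2, ls.rec = 1 - mean(rr) / sR2)
    upd <- .adamw_step(p, g, st, lr, opt$weight_decay)
    upd$p[["ls.c"]] <- max(upd$p[["ls.c"]], ls_floor)
    upd$p[["ls.rec"]] <- max(upd$p[["ls.rec"]], ls_floor)
    p <<- upd$p
    st <<- upd$st
    loss
  }
  hist <- .sgd_loop(ncol(x), opt, seed, step_fn)
  new("FluoroModel", kind = "mlp", config = list(arch = cfg),
      params = p,
      state = list(Bm = endmemberMatrix(B), names = endmemberNames(B),
                   sigma_c = exp(p[["ls.c"]]), sigma_rec = exp(p[["ls.rec"]])),
      history = data.frame(epoch = seq_along(hist), loss = hist))
}

.predict_mlp <- function(model, x, batch = 4096L) {
  p <- model@params
  feats <- rbind(fluoSpectra(x), refSpectra(x))
  fw <- .mlp_forward(p, feats)
  z <- fw$z
  rownames(z) <- model@state$names
  zh <- relativeAbundance(z)
  list(z = z, z_hat = zh, recon = model@state$Bm %*% zh,
       reconstruction_head = fw$out)
}

#' Fit the partial least-squares concentration baseline
#'
#' NIPALS PLS regression of the concentration label on the concatenated
#' (fluorescence, reflectance) feature vector; representative of the
#' PCA-family methods used as literature baselines. Predicts concentration
#' only.
#'
#' @param x labeled \linkS4class{SpectraSet}
#' @param n_components number of latent components
#' @return a \linkS4class{FluoroModel} of kind "pls"
#' @export
fitPls <- function(x, n_components = 8L) {
  cvec <- ppixConc(x)
  if (anyNA(cvec)) stop("PLS requires labeled pairs")
  X <- .pls_features(x)
  if (n_components > min(nrow(X), ncol(X)))
    stop("n_components exceeds min(n_samples, 2m)")
  fit <- mixOmics::pls(X, matrix(cvec, ncol = 1), ncomp = n_components,
                       mode = "regression", scale = FALSE)
  new("FluoroModel", kind = "pls",
      config = list(n_components = as.integer(n_components)),
      params = list(fit = fit), state = list(), history = data.frame())
}

#' Predict PpIX concentration with any trained model
#'
#' Unified concentration read-out: the PpIX634 abundance for the learned
#' unmixing models, the regression output for PLS.
#'
#' @param model a trained \linkS4class{FluoroModel}
#' @param x a \linkS4class{SpectraSet}
#' @return numeric vector of length ncol(x)
#' @export
predictConcentration <- function(model, x) {
  switch(model@kind,
         pls = {
           X <- .pls_features(x)
           pr <- stats::predict(model@params$fit, newdata = X)
           as.numeric(pr$predict[, 1, model@config$n_components])
         },
         acunet = predictAbundance(model, x)$z[1, ],
         mlp = predictAbundance(model, x)$z[1, ],
         acusa = predictAcusa(model, x)$z[1, ])
}
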