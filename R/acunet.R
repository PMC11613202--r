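#' @include nn-engine.R classical.R
NULL

#' ACU-Net multi-task loss for one sample
#'
#' Homoscedastic-uncertainty-weighted sum of the concentration error on
#' the PpIX634 abundance and the normalized spectral reconstruction error:
#' \deqn{L = (z_1 - c)^2 / (2 \sigma_C^2) +
#'       ||B \hat z - \tilde\phi||^2 / (2 \sigma_{rec}^2) +
#'       \log(\sigma_C \sigma_{rec})}
#' with \eqn{\hat z = z/||z||_2} and \eqn{\tilde\phi} the unit-l2
#' fluorescence spectrum (both sides share scale so strong PpIX spectra do
#' not dominate). A zero-norm measured spectrum leaves the target as the
#' zero vector.
#'
#' Both sides of the reconstruction term live on the unit sphere: the
#' reconstruction \eqn{B \hat z} is itself l2-normalized before comparison
#' (a raw \eqn{B \hat z} has norm well above 1 on a 104-band grid, and the
#' resulting scale mismatch creates spurious loss minima).
#'
#' @param z non-negative abundance vector (element 1 = PpIX634)
#' @param c_ppix known concentration label
#' @param phi_fluo measured fluorescence spectrum
#' @param B an \linkS4class{EndmemberLibrary}
#' @param sigma_c,sigma_rec task uncertainty weights (> 0)
#' @return scalar loss
#' @export
acunetLoss <- function(z, c_ppix, phi_fluo, B, sigma_c = 1, sigma_rec = 1) {
  stopifnot(sigma_c > 0, sigma_rec > 0)
  nrm <- sqrt(sum(phi_fluo^2))
  phit <- if (nrm > 0) phi_fluo / nrm else phi_fluo * 0
  rec <- drop(endmemberMatrix(B) %*% relativeAbundance(z))
  rn <- sqrt(sum(rec^2))
  if (rn > 0) rec <- rec / rn
  (z[1] - c_ppix)^2 / (2 * sigma_c^2) +
    sum((rec - phit)^2) / (2 * sigma_rec^2) +
    log(sigma_c * sigma_rec)
}

# Batched loss head: loss value, gradient w.r.t. pre-activation logits and
# w.r.t. the two log-sigma weights. Targets phi_t are unit-normalized.
# The reconstruction is compared on the unit sphere: unit(B z) vs the
# unit-normalized measured spectrum (unit(B z) = unit(B zhat), so the
# reported reconstructions B zhat are the same object up to scale).
.acunet_head <- function(logits, cvec, phi_t, Bm, ls_c, ls_rec) {
  N <- ncol(logits)
  mask <- logits > 0
  z <- logits * mask
  y <- Bm %*% z
  ynorm <- sqrt(colSums(y^2))
  u <- sweep(y, 2, ifelse(ynorm > 0, ynorm, 1), "/")
  resid <- u - phi_t
  rc <- (z[1, ] - cvec)^2
  rr <- colSums(resid^2)
  sC2 <- exp(2 * ls_c); sR2 <- exp(2 * ls_rec)
  loss <- mean(rc) / (2 * sC2) + mean(rr) / (2 * sR2) + ls_c + ls_rec
  gy <- .normalize_bwd(resid / (sR2 * N), y, u, ynorm)
  dz <- crossprod(Bm, gy)
  dz[1, ] <- dz[1, ] + (z[1, ] - cvec) / (sC2 * N)
  list(loss = loss,
       dlogits = dz * mask,
       d_ls_c = 1 - mean(rc) / sC2,
       d_ls_rec = 1 - mean(rr) / sR2)
}

#' Initialize an untrained ACU-Net
#'
#' He-initialized weights for the stacked two-channel residual 1D CNN;
#' the rectified final layer guarantees non-negative abundances.
#'
#' @param cfg an \code{\link{acunetConfig}}
#' @param B an \linkS4class{EndmemberLibrary} (stored for reconstruction)
#' @param seed integer seed for the initialization
#' @return an untrained \linkS4class{FluoroModel} of kind "acunet"
#' @export
buildAcunet <- function(cfg = acunetConfig(), B, seed = 1) {
  if (cfg$K != ncol(endmemberMatrix(B)))
    stop("cfg$K must match the endmember count")
  if (cfg$m != nrow(endmemberMatrix(B)))
    stop("cfg$m must match the endmember grid")
  p <- .trunk_init(cfg, seed)
  p[["ls.c"]] <- 0   # log sigma_C
  p[["ls.rec"]] <- 0 # log sigma_rec
  new("FluoroModel", kind = "acunet", config = list(arch = cfg),
      params = p,
      state = list(Bm = endmemberMatrix(B), names = endmemberNames(B)),
      history = data.frame())
}

#' Train ACU-Net on labeled spectra
#'
#' Minimizes the mean \code{\link{acunetLoss}} with AdamW; the two
#' log-sigma loss weights are optimized jointly with the network weights
#' (floored at \code{sigma_floor}). The learning rate halves on training
#' loss plateau. Deterministic for a fixed seed.
#'
#' @param x labeled \linkS4class{SpectraSet}
#' @param B an \linkS4class{EndmemberLibrary}
#' @param cfg an \code{\link{acunetConfig}}
#' @param opt an \code{\link{optimConfig}}
#' @param seed integer seed (initialization + batch order)
#' @param sigma_floor lower bound on the learned sigmas
#' @param model optionally continue training an existing model
#' @return a trained \linkS4class{FluoroModel} with per-epoch history
#' @export
trainAcunet <- function(x, B, cfg = acunetConfig(), opt = optimConfig(),
                        seed = 1, sigma_floor = 1e-3, model = NULL) {
  cvec <- ppixConc(x)
  if (anyNA(cvec)) stop("training set contains unlabeled pairs")
  if (is.null(model)) model <- buildAcunet(cfg, B, seed)
  cfg <- model@config$arch
  p <- .copy_params(model@params)   # AdamW updates arrays in place
  fluo <- fluoSpectra(x); ref <- refSpectra(x)
  phi_t <- .unit_cols(fluo)
  Bm <- model@state$Bm
  st <- .adamw_init(p)
  ls_floor <- log(sigma_floor)
  step_fn <- function(idx, lr) {
    xb <- .stack_input(fluo, ref, idx)
    fw <- .trunk_forward(p, xb, cfg)
    hd <- .acunet_head(fw$logits, cvec[idx], phi_t[, idx, drop = FALSE],
                       Bm, p[["ls.c"]], p[["ls.rec"]])
    bk <- .trunk_backward(p, hd$dlogits, fw$cache, cfg)
    g <- bk$grads
    g[["ls.c"]] <- hd$d_ls_c
    g[["ls.rec"]] <- hd$d_ls_rec
    upd <- .adamw_step(p, g, st, lr, opt$weight_decay)
    upd$p[["ls.c"]] <- max(upd$p[["ls.c"]], ls_floor)
    upd$p[["ls.rec"]] <- max(upd$p[["ls.rec"]], ls_floor)
    p <<- upd$p
    st <<- upd$st
    hd$loss
  }
  hist <- .sgd_loop(ncol(x), opt, seed, step_fn)
  initialize(model, params = p,
             history = data.frame(epoch = seq_along(hist), loss = hist),
             state = c(model@state[c("Bm", "names")],
                       list(sigma_c = exp(p[["ls.c"]]),
                            sigma_rec = exp(p[["ls.rec"]]))))
}

#' Predict abundances with a trained ACU-Net (or the MLP baseline)
#'
#' @param model a trained \linkS4class{FluoroModel}
#' @param x a \linkS4class{SpectraSet}
#' @param batch forward-pass chunk size
#' @return list with \code{z} (K x n non-negative abundances), \code{z_hat}
#'   (unit-l2), and \code{recon} (m x n normalized reconstructions B z_hat)
#' @export
predictAbundance <- function(model, x, batch = 1024L) {
  switch(model@kind,
         acunet = .predict_acunet(model, x, batch),
         mlp = .predict_mlp(model, x, batch),
         stop("predictAbundance supports kinds 'acunet' and 'mlp'"))
}

.predict_acunet <- function(model, x, batch = 1024L) {
  cfg <- model@config$arch
  fluo <- fluoSpectra(x); ref <- refSpectra(x)
  n <- ncol(fluo)
  z <- matrix(0, cfg$K, n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    fw <- .trunk_forward(model@params, .stack_input(fluo, ref, idx), cfg)
    z[, idx] <- pmax(fw$logits, 0)
  }
  rownames(z) <- model@state$names
  zh <- relativeAbundance(z)
  list(z = z, z_hat = zh, recon = model@state$Bm %*% zh)
}

#' @describeIn buildAcunet model family accessor
#' @param x a FluoroModel
#' @export
setMethod("modelKind", "FluoroModel", function(x) x@kind)

#' @describeIn buildAcunet per-epoch training history
#' @export
setMethod("trainingHistory", "FluoroModel", function(x) x@history)

#' @describeIn buildAcunet learned homoscedastic sigma weights
#' @export
setMethod("lossWeights", "FluoroModel", function(x) {
  s <- x@state
  s[grep("^sigma", names(s))]
})
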