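#' @include nn-engine.R acunet.R synthetic.R
NULL

#' ACU-SA architecture configuration
#'
#' The hyperspectral-unmixing (HU) encoder reuses the ACU-Net trunk with a
#' single input channel; the normalization module is a shallow 1D CNN
#' (default 4 same-convolution layers, channels 16/16/8/1, kernel 5, no
#' residual blocks) mapping the stacked raw spectra to one corrected
#' spectrum.
#'
#' @param hu_cfg trunk config for the HU encoder (in_ch must be 1)
#' @param norm_channels output channels of the normalization layers; must
#'   end in 1
#' @param norm_kernel odd kernel size of the normalization convolutions
#' @param augment_n default number of synthetic mixtures for stage 1
#' @param augment_noise \code{\link{noiseModel}} for the augmentation
#' @export
acusaConfig <- function(hu_cfg = acunetConfig(in_ch = 1L),
                        norm_channels = c(16L, 16L, 8L, 1L),
                        norm_kernel = 5L, augment_n = 4000L,
                        augment_noise = noiseModel(0.01, 0)) {
  if (hu_cfg$in_ch != 1L) stop("HU encoder takes a single (corrected) channel")
  if (utils::tail(norm_channels, 1) != 1L)
    stop("norm_channels must end in 1 (a single corrected spectrum)")
  if (norm_kernel %% 2L == 0L) stop("norm_kernel must be odd")
  list(hu_cfg = hu_cfg, norm_channels = as.integer(norm_channels),
       norm_kernel = as.integer(norm_kernel),
       augment_n = as.integer(augment_n), augment_noise = augment_noise)
}

# The normalization CNN is initialized as a noisy passthrough of the
# fluorescence channel: the center tap of a dedicated feature carries the
# input straight to the output, with small He-scaled perturbations around
# it. The composed network then starts in the input regime the frozen HU
# encoder was trained on; a generic He start either explodes (huge initial
# corrected spectra) or collapses into the dead all-zero corner where the
# stage-2 loss freezes at the label variance.
.norm_init <- function(cfg, seed) {
  withr::with_seed(as.integer(seed), {
    p <- list()
    chans <- c(2L, cfg$norm_channels)
    k <- cfg$norm_kernel
    center <- (k - 1L) %/% 2L
    nl <- length(cfg$norm_channels)
    for (j in seq_len(nl)) {
      W <- .he_mat(k * chans[j], chans[j + 1]) * 0.1
      # passthrough tap: channel/feature 1 of the input -> feature 1
      W[center + 1L, 1L] <- W[center + 1L, 1L] + 1
      p[[sprintf("n%d.W", j)]] <- W
      p[[sprintf("n%d.b", j)]] <- rep(0.02, chans[j + 1])
    }
    p
  })
}

.norm_forward <- function(p, x, cfg) {
  ca <- list()
  h <- x
  k <- cfg$norm_kernel
  for (j in seq_along(cfg$norm_channels)) {
    cv <- .conv_fwd(h, p[[sprintf("n%d.W", j)]], p[[sprintf("n%d.b", j)]], k)
    h <- nn_relu_ip(cv$y)   # final ReLU keeps the corrected spectrum >= 0
    ca[[j]] <- list(x = cv$x, y = h)
  }
  list(y = h, cache = ca)
}

.norm_backward <- function(p, dy, ca, cfg) {
  g <- list()
  k <- cfg$norm_kernel
  dh <- dy
  for (j in rev(seq_along(cfg$norm_channels))) {
    dh <- nn_relu_bwd_ip(dh, ca[[j]]$y)
    bk <- .conv_bwd(dh, ca[[j]], p[[sprintf("n%d.W", j)]], k)
    g[[sprintf("n%d.W", j)]] <- bk$dW
    g[[sprintf("n%d.b", j)]] <- bk$db
    dh <- bk$dx
  }
  list(grads = g, dx = dh)
}

#' Softmax cross-entropy against a one-hot endmember target
#'
#' \code{-log(exp(phi_k) / sum_j exp(phi_j))}, evaluated with the
#' log-sum-exp trick. Invariant under adding a constant to all logits.
#'
#' @param phi logit vector of length K (twin-encoder output)
#' @param k index of the true endmember
#' @return scalar cross-entropy
#' @export
endmemberCrossEntropy <- function(phi, k) {
  stopifnot(all(is.finite(phi)), k >= 1, k <= length(phi))
  mx <- max(phi)
  (mx + log(sum(exp(phi - mx)))) - phi[k]
}

#' Random endmember mixtures for stage-1 augmentation
#'
#' Corrected-domain spectra \code{B z + noise} with sparse random
#' abundances (each endmember present with probability 0.6, Dirichlet
#' magnitudes, lognormal total) and no attenuation -- these live in the
#' domain the normalization module is trained to produce.
#'
#' @param B an \linkS4class{EndmemberLibrary}
#' @param n number of mixtures
#' @param noise a \code{\link{noiseModel}}
#' @param seed integer seed
#' @param present_prob per-endmember presence probability
#' @return list with \code{spectra} (m x n, noisy), \code{clean} (m x n)
#'   and \code{z} (K x n true abundances)
#' @export
augmentMixtures <- function(B, n, noise = noiseModel(0.01, 0), seed = 1,
                            present_prob = 0.6) {
  K <- ncol(endmemberMatrix(B))
  if (n == 0L)
    return(list(spectra = matrix(0, nrow(endmemberMatrix(B)), 0),
                clean = matrix(0, nrow(endmemberMatrix(B)), 0),
                z = matrix(0, K, 0)))
  withr::with_seed(as.integer(seed), {
    support <- matrix(stats::rbinom(K * n, 1, present_prob), K, n)
    w <- matrix(stats::rgamma(K * n, shape = 1), K, n) * support
    tot <- colSums(w)
    w <- sweep(w, 2, ifelse(tot > 0, tot, 1), "/")
    z <- sweep(w, 2, stats::rlnorm(n, 0, 0.5), "*")
    clean <- endmemberMatrix(B) %*% z
    list(spectra = .apply_noise(clean, noise), clean = clean, z = z)
  })
}

#' Initialize an untrained ACU-SA
#'
#' Builds the weight-shared Siamese HU encoder (rectified output for
#' abundances, softmax view for the twin), the fixed linear decoder (the
#' endmember matrix B, no trainable parameters) and the shallow
#' normalization CNN.
#'
#' @param cfg an \code{\link{acusaConfig}}
#' @param B an \linkS4class{EndmemberLibrary}; must have full column rank
#' @param seed integer seed
#' @return an untrained \linkS4class{FluoroModel} of kind "acusa"
#' @export
buildAcusa <- function(cfg = acusaConfig(), B, seed = 1) {
  Bm <- endmemberMatrix(B)
  if (qr(Bm)$rank < ncol(Bm)) stop("endmember matrix must have full column rank")
  if (cfg$hu_cfg$K != ncol(Bm) || cfg$hu_cfg$m != nrow(Bm))
    stop("HU encoder dimensions must match the endmember library")
  p <- list(hu = .trunk_init(cfg$hu_cfg, seed),
            norm = .norm_init(cfg, as.integer(seed) + 1L))
  p[["ls.eg"]] <- 0
  p[["ls.rec"]] <- 0
  new("FluoroModel", kind = "acusa", config = list(arch = cfg),
      params = p,
      state = list(Bm = Bm, names = endmemberNames(B)),
      history = data.frame())
}

#' HU-encoder abundances for corrected-domain spectra
#'
#' @param model an "acusa" \linkS4class{FluoroModel}
#' @param spectra m x n matrix of corrected-domain spectra (unit-l2
#'   normalization is applied internally)
#' @return K x n non-negative abundance matrix
#' @export
huEncode <- function(model, spectra, batch = 2048L) {
  cfg <- model@config$arch$hu_cfg
  phin <- .unit_cols(as.matrix(spectra))
  n <- ncol(phin)
  z <- matrix(0, cfg$K, n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    xb <- array(phin[, idx, drop = FALSE], c(nrow(phin), length(idx), 1L))
    z[, idx] <- pmax(.trunk_forward(model@params$hu, xb, cfg)$logits, 0)
  }
  rownames(z) <- model@state$names
  z
}

#' Twin-encoder logits for given spectra
#'
#' The twin shares all weights with the HU encoder but exposes the
#' pre-activation logits, to be read through a softmax. Feeding the K pure
#' endmember spectra should yield a one-hot-dominant K x K matrix after
#' stage-1 training.
#'
#' @param model an "acusa" \linkS4class{FluoroModel}
#' @param spectra m x n matrix
#' @return K x n logit matrix
#' @export
twinLogits <- function(model, spectra) {
  cfg <- model@config$arch$hu_cfg
  spectra <- as.matrix(spectra)
  xb <- array(spectra, c(nrow(spectra), ncol(spectra), 1L))
  .trunk_forward(model@params$hu, xb, cfg)$logits
}

#' Stage 1: self-supervised training of the HU autoencoder
#'
#' Minimizes the endmember-guided loss: softmax cross-entropy of the twin
#' encoder on the K pure (unit-peak) endmember spectra (recomputed every
#' batch), plus the fixed-decoder reconstruction error
#' \code{||B z - phi_hat||^2} against the unit-normalized target spectrum.
#' The decoder output is deliberately not normalized here: with no
#' concentration anchor in this stage, the reconstruction is what pins
#' down the absolute abundance scale the frozen encoder carries into
#' stage 2. Both terms are weighted by learned homoscedastic log-sigmas.
#' Labels, if present in the pool, are ignored.
#'
#' @param spectra m x n matrix of corrected-domain training spectra
#'   (real unlabeled data and/or \code{\link{augmentMixtures}} output)
#' @param model an "acusa" \linkS4class{FluoroModel}
#' @param targets optional m x n clean reconstruction targets (defaults to
#'   the inputs; pass the clean mixtures for augmented spectra)
#' @param opt an \code{\link{optimConfig}}
#' @param seed integer seed
#' @param sigma_floor lower bound on learned sigmas
#' @return the model with a trained HU module and stage-1 history
#' @export
trainStage1 <- function(spectra, model, targets = NULL, opt = optimConfig(),
                        seed = 1, sigma_floor = 1e-3) {
  cfg <- model@config$arch$hu_cfg
  Bm <- model@state$Bm
  K <- ncol(Bm)
  phin <- .unit_cols(as.matrix(spectra))
  tgt <- if (is.null(targets)) phin else .unit_cols(as.matrix(targets))
  m <- nrow(phin)
  pure <- array(Bm, c(m, K, 1L))   # unit-peak endmember spectra
  p <- model@params
  p$hu <- .copy_params(p$hu)       # AdamW updates arrays in place
  st <- .adamw_init(c(p$hu, p["ls.eg"], p["ls.rec"]))
  ls_floor <- log(sigma_floor)
  onehot <- diag(K)
  step_fn <- function(idx, lr) {
    xb <- array(phin[, idx, drop = FALSE], c(m, length(idx), 1L))
    fw <- .trunk_forward(p$hu, xb, cfg)
    N <- length(idx)
    mask <- fw$logits > 0
    z <- fw$logits * mask
    # the decoder output B z is compared unnormalized against the unit-norm
    # input spectrum: with no competing anchor this pins down the abundance
    # scale (||z|| ~ 1/||B dir||), which stage 2's frozen encoder relies on
    resid <- Bm %*% z - tgt[, idx, drop = FALSE]
    rr <- colSums(resid^2)
    # twin pass on the pure endmember spectra
    fw_tw <- .trunk_forward(p$hu, pure, cfg)
    lg <- fw_tw$logits
    mx <- apply(lg, 2, max)
    lse <- mx + log(colSums(exp(sweep(lg, 2, mx))))
    ce <- lse - diag(lg)
    pr <- sweep(exp(sweep(lg, 2, lse)), 2, 1, "*")
    sE2 <- exp(2 * p[["ls.eg"]]); sR2 <- exp(2 * p[["ls.rec"]])
    loss <- sum(ce) / (2 * K * sE2) + mean(rr) / (2 * sR2) +
      p[["ls.eg"]] + p[["ls.rec"]]
    dz <- crossprod(Bm, resid) / (sR2 * N)
    bk <- .trunk_backward(p$hu, dz * mask, fw$cache, cfg)
    dlg <- (pr - onehot) / (2 * K * sE2)
    bk_tw <- .trunk_backward(p$hu, dlg, fw_tw$cache, cfg)
    g <- bk$grads
    for (nm in names(g)) g[[nm]] <- g[[nm]] + bk_tw$grads[[nm]]
    g[["ls.eg"]] <- 1 - sum(ce) / (K * sE2)
    g[["ls.rec"]] <- 1 - mean(rr) / sR2
    ph <- c(p$hu, p["ls.eg"], p["ls.rec"])
    upd <- .adamw_step(ph, g, st, lr, opt$weight_decay)
    st <<- upd$st
    p$hu <<- upd$p[names(p$hu)]
    p[["ls.eg"]] <<- max(upd$p[["ls.eg"]], ls_floor)
    p[["ls.rec"]] <<- max(upd$p[["ls.rec"]], ls_floor)
    loss
  }
  hist <- .sgd_loop(ncol(phin), opt, seed, step_fn)
  h <- rbind(model@history,
             data.frame(epoch = seq_along(hist), loss = hist,
                        stage = "stage1"))
  initialize(model, params = p, history = h,
             state = c(model@state[c("Bm", "names")],
                       list(sigma_eg = exp(p[["ls.eg"]]),
                            sigma_rec = exp(p[["ls.rec"]]))))
}

#' Stage 2: supervised training of the normalization module
#'
#' Freezes the HU module and trains only the shallow normalization CNN so
#' that the PpIX634 abundance of the composed network matches the labels:
#' \code{L = ([f(g(phi_fluo, phi_ref))]_1 - c)^2}. The HU parameters are
#' byte-identical before and after.
#'
#' @param x labeled \linkS4class{SpectraSet}
#' @param model an "acusa" model with a stage-1-trained HU module
#' @param opt an \code{\link{optimConfig}}
#' @param seed integer seed
#' @return the model with a trained normalization module
#' @export
trainStage2 <- function(x, model, opt = optimConfig(), seed = 1) {
  cvec <- ppixConc(x)
  if (anyNA(cvec)) stop("stage 2 requires labeled pairs")
  cfg <- model@config$arch
  hu_cfg <- cfg$hu_cfg
  p <- model@params
  p$norm <- .copy_params(p$norm)   # AdamW updates arrays in place
  hu_frozen <- p$hu
  fluo <- fluoSpectra(x); ref <- refSpectra(x)
  # calibrate the initial corrected-spectrum scale to the unit-norm regime
  # the HU encoder was trained in (LSUV-style, on a probe batch)
  probe <- seq_len(min(ncol(x), 512L))
  gout <- .norm_forward(p$norm, .stack_input(fluo, ref, probe), cfg)$y
  med <- stats::median(sqrt(colSums(matrix(gout, nrow(fluo))^2)))
  if (is.finite(med) && med > 0) {
    nl <- length(cfg$norm_channels)
    p$norm[[sprintf("n%d.W", nl)]] <- p$norm[[sprintf("n%d.W", nl)]] / med
    p$norm[[sprintf("n%d.b", nl)]] <- p$norm[[sprintf("n%d.b", nl)]] / med
  }
  st <- .adamw_init(p$norm)
  step_fn <- function(idx, lr) {
    N <- length(idx)
    xb <- .stack_input(fluo, ref, idx)
    nf <- .norm_forward(p$norm, xb, cfg)
    fw <- .trunk_forward(hu_frozen, nf$y, hu_cfg)
    mask <- fw$logits > 0
    z1 <- pmax(fw$logits[1, ], 0)
    r <- z1 - cvec[idx]
    loss <- mean(r^2)
    dlg <- matrix(0, hu_cfg$K, N)
    dlg[1, ] <- 2 * r / N
    bk_hu <- .trunk_backward(hu_frozen, dlg * mask, fw$cache, hu_cfg)
    bk_nm <- .norm_backward(p$norm, bk_hu$dx, nf$cache, cfg)
    upd <- .adamw_step(p$norm, .clip_grads(bk_nm$grads, 10), st, lr,
                       opt$weight_decay)
    p$norm <<- upd$p
    st <<- upd$st
    loss
  }
  hist <- .sgd_loop(ncol(x), opt, seed, step_fn)
  stopifnot(identical(p$hu, hu_frozen))  # frozen contract
  h <- rbind(model@history,
             data.frame(epoch = seq_along(hist), loss = hist,
                        stage = "stage2"))
  initialize(model, params = p, history = h)
}

#' Predict with a trained ACU-SA
#'
#' Runs the normalization module, exposes its intermediate corrected
#' spectrum (the model's interpretability handle), then unmixes it with
#' the frozen HU encoder.
#'
#' @param model a trained "acusa" \linkS4class{FluoroModel}
#' @param x a \linkS4class{SpectraSet}
#' @param batch forward-pass chunk size
#' @return list with \code{corrected} (m x n, non-negative), \code{z}
#'   (K x n), \code{z_hat} and \code{recon} (m x n, B z_hat)
#' @export
predictAcusa <- function(model, x, batch = 1024L) {
  cfg <- model@config$arch
  hu_cfg <- cfg$hu_cfg
  fluo <- fluoSpectra(x); ref <- refSpectra(x)
  n <- ncol(fluo); m <- nrow(fluo)
  corrected <- matrix(0, m, n)
  z <- matrix(0, hu_cfg$K, n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    nf <- .norm_forward(model@params$norm, .stack_input(fluo, ref, idx), cfg)
    corrected[, idx] <- matrix(nf$y, m, length(idx))
    z[, idx] <- pmax(.trunk_forward(model@params$hu, nf$y, hu_cfg)$logits, 0)
  }
  rownames(z) <- model@state$names
  zh <- relativeAbundance(z)
  list(corrected = corrected, z = z, z_hat = zh, recon = model@state$Bm %*% zh)
}
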