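#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Minimal 1D-CNN engine. Activations are (L, N, C) arrays (band, sample,
# channel); convolution weights are (k * Cin) x Cout matrices so forward and
# backward passes are single GEMMs around the im2col/col2im kernels in src/.
# Everything is double precision and strictly single-threaded deterministic.
# ---------------------------------------------------------------------------

.conv_fwd <- function(x, W, b, k) {
  list(y = nn_conv1d_fwd(x, W, b), x = x)
}

.conv_bwd <- function(dy, cache, W, k) {
  nn_conv1d_bwd(cache$x, dy, W)
}

.relu_fwd <- function(x) list(y = nn_relu_ip(x))

.pool_fwd <- function(x, p) nn_maxpool1d(x, p)

.pool_bwd <- function(dy, idx, L) nn_maxpool1d_bwd(dy, idx, L)

.dense_fwd <- function(x, W, b) crossprod(W, x) + b   # x (F,N) -> (Fo,N)

.dense_bwd <- function(dy, x, W) {
  list(dx = W %*% dy, dW = x %*% t(dy), db = rowSums(dy))
}

# -- trunk: the shared residual CNN body -----------------------------------

#' ACU-Net architecture configuration
#'
#' Four residual blocks of same-convolutions (kernel 5 in the first two
#' blocks, 3 in the last two), each followed by max-pooling(2) and a
#' channel-doubling transition convolution; then three fully connected
#' layers down to the K abundances, rectified at the output.
#'
#' @param m number of spectral bands
#' @param in_ch input channels (2 = stacked fluorescence + white light)
#' @param K number of endmembers
#' @param channels feature channels per block
#' @param kernels odd convolution kernel size per block
#' @param convs_per_block same-convolutions inside each residual block
#' @param pool max-pooling width after each block
#' @param fc_sizes hidden sizes of the two fully connected layers before
#'   the K-dimensional output
#' @return validated config list
#' @export
acunetConfig <- function(m = 104L, in_ch = 2L, K = 5L,
                         channels = c(16L, 32L, 64L, 128L),
                         kernels = c(5L, 5L, 3L, 3L),
                         convs_per_block = 2L, pool = 2L,
                         fc_sizes = c(256L, 64L)) {
  nb <- length(channels)
  if (length(kernels) != nb) stop("kernels must have one entry per block")
  if (any(kernels %% 2L == 0L)) stop("kernels must be odd (same-convolution)")
  if (any(c(m, in_ch, K, channels, kernels, convs_per_block, pool, fc_sizes) <= 0))
    stop("all config sizes must be positive")
  L <- m
  for (i in seq_len(nb)) {
    L <- L %/% pool
    if (L < 1L) stop(sprintf("m = %d too small for %d poolings of width %d",
                             m, nb, pool))
  }
  list(m = as.integer(m), in_ch = as.integer(in_ch), K = as.integer(K),
       channels = as.integer(channels), kernels = as.integer(kernels),
       convs_per_block = as.integer(convs_per_block), pool = as.integer(pool),
       fc_sizes = as.integer(fc_sizes), n_blocks = nb, flat = L * channels[nb])
}

.he_mat <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

.trunk_init <- function(cfg, seed) {
  withr::with_seed(as.integer(seed), {
    p <- list()
    k1 <- cfg$kernels[1]
    p[["stem.W"]] <- .he_mat(k1 * cfg$in_ch, cfg$channels[1])
    p[["stem.b"]] <- rep(0, cfg$channels[1])
    for (b in seq_len(cfg$n_blocks)) {
      ch <- cfg$channels[b]; k <- cfg$kernels[b]
      for (j in seq_len(cfg$convs_per_block)) {
        p[[sprintf("b%d.c%d.W", b, j)]] <- .he_mat(k * ch, ch)
        p[[sprintf("b%d.c%d.b", b, j)]] <- rep(0, ch)
      }
      if (b < cfg$n_blocks) {
        kn <- cfg$kernels[b + 1]
        p[[sprintf("t%d.W", b)]] <- .he_mat(kn * ch, cfg$channels[b + 1])
        p[[sprintf("t%d.b", b)]] <- rep(0, cfg$channels[b + 1])
      }
    }
    sizes <- c(cfg$flat, cfg$fc_sizes, cfg$K)
    nfc <- length(sizes) - 1L
    for (j in seq_len(nfc)) {
      p[[sprintf("fc%d.W", j)]] <- .he_mat(sizes[j], sizes[j + 1])
      p[[sprintf("fc%d.b", j)]] <- rep(0, sizes[j + 1])
    }
    # small weights + a modest positive bias on the rectified abundance
    # head keep every output alive at initialization (a dead output unit
    # gets no concentration gradient at all) while keeping the initial
    # decoder output B z near the unit-norm scale of its targets
    p[[sprintf("fc%d.W", nfc)]] <- p[[sprintf("fc%d.W", nfc)]] * 0.1
    p[[sprintf("fc%d.b", nfc)]] <- rep(0.1, cfg$K)
    p
  })
}

# Forward pass to pre-activation logits (K, N). Returns caches for backward:
# ReLU masks are recovered from the cached activations themselves, and the
# ReLU-before-pool gradient is applied at pooled resolution (valid because
# the pooled maxima are positive exactly where the pre-pool winners are).
.trunk_forward <- function(p, x, cfg) {
  ca <- list()
  cv <- .conv_fwd(x, p[["stem.W"]], p[["stem.b"]], cfg$kernels[1])
  h <- nn_relu_ip(cv$y)
  ca$stem <- list(x = cv$x, y = h)
  for (b in seq_len(cfg$n_blocks)) {
    k <- cfg$kernels[b]
    resin <- h
    bc <- list()
    for (j in seq_len(cfg$convs_per_block)) {
      cv <- .conv_fwd(h, p[[sprintf("b%d.c%d.W", b, j)]],
                      p[[sprintf("b%d.c%d.b", b, j)]], k)
      h <- cv$y
      rec <- list(x = cv$x)
      if (j < cfg$convs_per_block) {
        h <- nn_relu_ip(h); rec$y <- h
      }
      bc[[j]] <- rec
    }
    h <- nn_relu_ip(h + resin)
    pl <- .pool_fwd(h, cfg$pool)
    ca[[sprintf("b%d", b)]] <- list(convs = bc, pool_idx = pl$idx,
                                    pool_Lin = dim(h)[1], pool_y = pl$y)
    h <- pl$y
    if (b < cfg$n_blocks) {
      cv <- .conv_fwd(h, p[[sprintf("t%d.W", b)]], p[[sprintf("t%d.b", b)]],
                      cfg$kernels[b + 1])
      h <- nn_relu_ip(cv$y)
      ca[[sprintf("t%d", b)]] <- list(x = cv$x, y = h)
    }
  }
  d <- dim(h)
  flat <- matrix(aperm(h, c(1, 3, 2)), d[1] * d[3], d[2])
  ca$flat_dim <- d
  a <- flat
  nfc <- length(cfg$fc_sizes) + 1L
  for (j in seq_len(nfc)) {
    pre <- .dense_fwd(a, p[[sprintf("fc%d.W", j)]], p[[sprintf("fc%d.b", j)]])
    if (j < nfc) {
      y <- nn_relu_ip(pre)
      ca[[sprintf("fc%d", j)]] <- list(x = a, y = y)
      a <- y
    } else {
      ca[[sprintf("fc%d", j)]] <- list(x = a)
      a <- pre
    }
  }
  list(logits = a, cache = ca)
}

# Backward from dlogits (K, N); returns named grads and the input gradient.
.trunk_backward <- function(p, dlogits, ca, cfg) {
  g <- list()
  nfc <- length(cfg$fc_sizes) + 1L
  da <- dlogits
  for (j in rev(seq_len(nfc))) {
    cc <- ca[[sprintf("fc%d", j)]]
    bk <- .dense_bwd(da, cc$x, p[[sprintf("fc%d.W", j)]])
    g[[sprintf("fc%d.W", j)]] <- bk$dW
    g[[sprintf("fc%d.b", j)]] <- bk$db
    da <- bk$dx
    if (j > 1L) da <- nn_relu_bwd_ip(da, ca[[sprintf("fc%d", j - 1L)]]$y)
  }
  d <- ca$flat_dim
  dh <- aperm(array(da, c(d[1], d[3], d[2])), c(1, 3, 2))
  for (b in rev(seq_len(cfg$n_blocks))) {
    if (b < cfg$n_blocks) {
      tc <- ca[[sprintf("t%d", b)]]
      dh <- nn_relu_bwd_ip(dh, tc$y)
      bk <- .conv_bwd(dh, tc, p[[sprintf("t%d.W", b)]], cfg$kernels[b + 1])
      g[[sprintf("t%d.W", b)]] <- bk$dW
      g[[sprintf("t%d.b", b)]] <- bk$db
      dh <- bk$dx
    }
    bc <- ca[[sprintf("b%d", b)]]
    dh <- nn_relu_bwd_ip(dh, bc$pool_y)   # pooled-resolution ReLU gradient
    dh <- .pool_bwd(dh, bc$pool_idx, bc$pool_Lin)
    dres <- dh                         # residual branch gradient
    k <- cfg$kernels[b]
    for (j in rev(seq_len(cfg$convs_per_block))) {
      cc <- bc$convs[[j]]
      if (j < cfg$convs_per_block) dh <- nn_relu_bwd_ip(dh, cc$y)
      bk <- .conv_bwd(dh, cc, p[[sprintf("b%d.c%d.W", b, j)]], k)
      g[[sprintf("b%d.c%d.W", b, j)]] <- bk$dW
      g[[sprintf("b%d.c%d.b", b, j)]] <- bk$db
      dh <- bk$dx
    }
    dh <- dh + dres
  }
  dh <- nn_relu_bwd_ip(dh, ca$stem$y)
  bk <- .conv_bwd(dh, ca$stem, p[["stem.W"]], cfg$kernels[1])
  g[["stem.W"]] <- bk$dW
  g[["stem.b"]] <- bk$db
  list(grads = g, dx = bk$dx)
}

# -- AdamW ------------------------------------------------------------------

.adamw_init <- function(p) {
  list(m = lapply(p, function(a) a * 0), v = lapply(p, function(a) a * 0),
       t = 0L)
}

# Parameter arrays are updated in place (they are private to the training
# loop; trainers deep-copy the model parameters before the first step).
# Length-1 parameters (the log-sigma loss weights) go through ordinary R
# arithmetic so no shared scalar is ever mutated.
.adamw_step <- function(p, g, st, lr, wd = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    if (length(p[[nm]]) == 1L) {
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
      p[[nm]] <- p[[nm]] - lr * ((st$m[[nm]] / bc1) /
                                   (sqrt(st$v[[nm]] / bc2) + eps) + wd * p[[nm]])
    } else {
      nn_adamw(p[[nm]], g[[nm]], st$m[[nm]], st$v[[nm]], lr, wd,
               beta1, beta2, eps, bc1, bc2)
    }
  }
  list(p = p, st = st)
}

.copy_params <- function(p) lapply(p, function(a) a * 1)

# Global-norm gradient clipping: rescales the whole gradient list when its
# joint l2 norm exceeds max_norm (stabilizes the composed stage-2 problem).
.clip_grads <- function(g, max_norm) {
  total <- sqrt(sum(vapply(g, function(a) sum(a^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    g <- lapply(g, function(a) a * sc)
  }
  g
}

#' Optimizer configuration for the learned models
#'
#' AdamW with a reduce-on-plateau schedule: the learning rate is halved
#' when the epoch training loss has not improved by \code{improve_tol} for
#' \code{patience} epochs; training stops at \code{epochs} or when the
#' learning rate falls below \code{min_lr}.
#'
#' @param lr initial learning rate
#' @param epochs maximum epochs
#' @param batch minibatch size
#' @param weight_decay decoupled weight decay
#' @param patience plateau patience in epochs
#' @param factor learning-rate reduction factor
#' @param improve_tol minimum loss improvement that resets the plateau
#' @param min_lr stop when lr falls below this
#' @export
optimConfig <- function(lr = 1e-3, epochs = 200L, batch = 256L,
                        weight_decay = 1e-4, patience = 10L, factor = 0.5,
                        improve_tol = 1e-4, min_lr = 1e-6) {
  list(lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
       weight_decay = weight_decay, patience = as.integer(patience),
       factor = factor, improve_tol = improve_tol, min_lr = min_lr)
}

# Generic seeded minibatch loop with the plateau schedule. step_fn(idx, lr)
# must perform one update on global state captured in its environment and
# return the batch loss.
.sgd_loop <- function(n, opt, seed, step_fn, epoch_hook = NULL) {
  lr <- opt$lr
  best <- Inf
  wait <- 0L
  history <- numeric(0)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(opt$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = opt$batch)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + opt$batch - 1L, n)]
        ep_loss <- ep_loss + step_fn(idx, lr) * length(idx)
      }
      ep_loss <- ep_loss / n
      history <- c(history, ep_loss)
      if (!is.null(epoch_hook)) epoch_hook(ep, ep_loss, lr)
      if (ep_loss < best - opt$improve_tol) {
        best <- ep_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= opt$patience) {
          lr <- lr * opt$factor
          wait <- 0L
        }
      }
      if (lr < opt$min_lr) break
    }
  })
  history
}

# Stack fluorescence + reflectance into an (m, N, 2) input tensor.
.stack_input <- function(fluo, ref, idx = NULL) {
  if (!is.null(idx)) { fluo <- fluo[, idx, drop = FALSE]; ref <- ref[, idx, drop = FALSE] }
  m <- nrow(fluo)
  out <- array(0, c(m, ncol(fluo), 2L))
  out[, , 1L] <- fluo
  out[, , 2L] <- ref
  out
}

.unit_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  sweep(x, 2, ifelse(nrm > 0, nrm, 1), "/")
}

# Jacobian-vector product of z -> z/||z|| applied column-wise:
# dz = (g - zhat (zhat.g)) / ||z||, zero where ||z|| = 0.
.normalize_bwd <- function(g, z, zhat, norms) {
  proj <- colSums(zhat * g)
  out <- (g - sweep(zhat, 2, proj, "*"))
  sweep(out, 2, ifelse(norms > 0, 1 / norms, 0), "*")
}
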