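#' @include AllClasses.R AllGenerics.R EndmemberLibrary.R SpectraSet.R classical.R
NULL

#' Optical properties of a sample
#'
#' Absorption at the 405 nm excitation wavelength, reduced scattering at
#' 635 nm, and a dimensionless geometric factor (distance/angle to the
#' objective). The phantom study grid spans mua 18-60 cm^-1 and mus' for
#' 8.7-14.5 cm^-1.
#'
#' @param mua_405 absorption coefficient at 405 nm, cm^-1
#' @param musp_635 reduced scattering coefficient at 635 nm, cm^-1
#' @param geom geometric collection factor (> 0)
#' @export
opticalProperties <- function(mua_405, musp_635, geom = 1) {
  stopifnot(mua_405 > 0, musp_635 > 0, geom > 0)
  structure(list(mua_405 = mua_405, musp_635 = musp_635, geom = geom),
            class = "OpticalProperties")
}

#' Measurement noise model
#'
#' Optional Poisson shot-noise stage (applied first; \code{poisson_scale}
#' photons per count, 0 disables) followed by additive Gaussian read noise
#' in counts. Results are clipped at zero.
#'
#' @param gaussian_sd Gaussian read-noise SD in counts
#' @param poisson_scale photons per count for the shot-noise stage
#' @export
noiseModel <- function(gaussian_sd = 0.01, poisson_scale = 0) {
  stopifnot(is.finite(gaussian_sd), gaussian_sd >= 0,
            is.finite(poisson_scale), poisson_scale >= 0)
  structure(list(gaussian_sd = gaussian_sd, poisson_scale = poisson_scale),
            class = "NoiseModel")
}

.default_endmember_params <- function() {
  list(
    ppix634 = list(centers = c(634, 704), widths = c(10, 20), heights = c(1, 0.35)),
    ppix620 = list(centers = 620, widths = 12, heights = 1),
    lipofuscin = list(centers = 500, widths = 55, heights = 1),
    nadh = list(centers = 460, widths = 60, heights = 1),
    flavins = list(centers = 525, widths = 45, heights = 1)
  )
}

#' Parametric endmember library for the five brain fluorophores
#'
#' Builds Gaussian-peak emission models for PpIX634 (634 nm main peak,
#' sigma 10 nm, plus a 0.35-height vibronic shoulder at 704 nm), PpIX620
#' (620 nm, sigma 12 nm) and three broad autofluorophores (lipofuscin,
#' NADH, flavins; peaks near 500, 460, 525 nm, sigma 35-60 nm). The seed
#' jitters peak centers by up to +/-2 nm and widths by +/-10% so tests can
#' probe robustness to library misspecification; \code{seed = NULL} gives
#' the unperturbed library.
#'
#' @param grid a \linkS4class{WavelengthGrid} covering 421-730 nm
#' @param seed integer seed for the perturbation, or NULL for none
#' @return an \linkS4class{EndmemberLibrary} with K = 5
#' @export
makeEndmembers <- function(grid = WavelengthGrid(), seed = NULL) {
  wl <- wavelengths(grid)
  pars <- .default_endmember_params()
  centers_all <- unlist(lapply(pars, `[[`, "centers"))
  if (min(wl) > min(centers_all) || max(wl) < max(centers_all))
    stop("grid does not cover the endmember emission peaks")
  perturb <- function(p) {
    p$centers <- p$centers + stats::runif(length(p$centers), -2, 2)
    p$widths <- p$widths * stats::runif(length(p$widths), 0.9, 1.1)
    p
  }
  build <- function(p) {
    v <- rep(0, length(wl))
    for (i in seq_along(p$centers))
      v <- v + p$heights[i] * exp(-0.5 * ((wl - p$centers[i]) / p$widths[i])^2)
    v
  }
  if (!is.null(seed)) {
    pars <- withr::with_seed(as.integer(seed), lapply(pars, perturb))
  }
  B <- vapply(pars, build, numeric(length(wl)))
  EndmemberLibrary(B, grid, names = names(pars))
}

.mua_lambda <- function(optics, wl) optics$mua_405 * exp(-(wl - 405) / 120)
.musp_lambda <- function(optics, wl) optics$musp_635 * (wl / 635)^(-1)

#' Diffuse reflectance curve of the synthetic forward model
#'
#' \code{R(lambda) = geom * mus'(lambda) / (mua(lambda) + mus'(lambda))}
#' with exponential-decay absorption (scale 120 nm, anchored at 405 nm)
#' and power-law reduced scattering (anchored at 635 nm). Linear in the
#' geometric factor.
#'
#' @param optics an \code{\link{opticalProperties}}
#' @param grid a \linkS4class{WavelengthGrid}
#' @return positive vector of length m
#' @export
reflectanceCurve <- function(optics, grid) {
  wl <- wavelengths(grid)
  mua <- .mua_lambda(optics, wl)
  musp <- .musp_lambda(optics, wl)
  optics$geom * musp / (mua + musp)
}

#' Fluorescence attenuation curve of the synthetic forward model
#'
#' \code{A(lambda) = R(lambda)^0.7 * mean(R over 620-640 nm)}, built so
#' the default dual-band corrector (bands 450-480 / 620-640, exponent 0.7)
#' cancels the geometric factor exactly and wavelength-dependent optics
#' only approximately -- leaving residual structure that learned
#' correctors can exploit. Scales as geom^1.7.
#'
#' @inheritParams reflectanceCurve
#' @return positive vector of length m
#' @export
attenuationCurve <- function(optics, grid) {
  R <- reflectanceCurve(optics, grid)
  wl <- wavelengths(grid)
  sel <- wl >= 620 & wl <= 640
  R^0.7 * mean(R[sel])
}

.apply_noise <- function(clean, noise) {
  x <- clean
  if (noise$poisson_scale > 0) {
    x <- stats::rpois(length(x), lambda = pmax(x, 0) * noise$poisson_scale) /
      noise$poisson_scale
    dim(x) <- dim(clean)
  }
  if (noise$gaussian_sd > 0)
    x <- x + stats::rnorm(length(x), sd = noise$gaussian_sd)
  pmax(x, 0)
}

# Clean (noise-free) forward model for a block of pixels sharing optics.
.forward_block <- function(zmat, B, optics, grid) {
  A <- attenuationCurve(optics, grid)
  R <- reflectanceCurve(optics, grid)
  fluo <- (endmemberMatrix(B) %*% zmat) * A
  ref <- matrix(R, nrow = length(R), ncol = ncol(zmat))
  list(fluo = fluo, ref = ref)
}

#' Simulate one measured spectrum pair
#'
#' \code{phi_fluo = A(lambda) * (B z) + noise},
#' \code{phi_ref = R(lambda) * W(lambda) + noise} with a flat unit
#' illuminant W. The Poisson stage precedes the Gaussian stage; results
#' are clipped at zero.
#'
#' @param z abundance vector of length K
#' @param B an \linkS4class{EndmemberLibrary}
#' @param optics an \code{\link{opticalProperties}}
#' @param noise a \code{\link{noiseModel}}
#' @param seed integer seed
#' @return list with \code{phi_fluo} and \code{phi_ref} vectors
#' @export
simulatePair <- function(z, B, optics, noise = noiseModel(), seed = 1) {
  grid <- spectraGrid(B)
  clean <- .forward_block(matrix(z, ncol = 1), B, optics, grid)
  withr::with_seed(as.integer(seed), {
    list(phi_fluo = drop(.apply_noise(clean$fluo, noise)),
         phi_ref = drop(.apply_noise(clean$ref, noise)))
  })
}

.phantom_conc <- c(0.0, 0.2, 0.6, 1.25, 2.5)     # ug/mL
.phantom_mua <- c(18, 42, 60)                     # cm^-1 at 405 nm
.phantom_musp <- c(8.7, 11.6, 14.5)               # cm^-1 at 635 nm
.pbh_conc <- c(0.0, 0.5, 0.75, 1.0, 2.0, 3.0, 4.0)  # pmol/mg

.simulate_groups <- function(groups, B, noise, seed, unit_tag) {
  grid <- spectraGrid(B)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(groups, function(g) {
      clean <- .forward_block(g$z, B, g$optics, grid)
      list(fluo = .apply_noise(clean$fluo, noise),
           ref = .apply_noise(clean$ref, noise),
           gid = rep(g$id, ncol(g$z)),
           c = rep(g$c, length.out = ncol(g$z)))
    })
    SpectraSet(
      do.call(cbind, lapply(parts, `[[`, "fluo")),
      do.call(cbind, lapply(parts, `[[`, "ref")),
      grid,
      group_id = unlist(lapply(parts, `[[`, "gid")),
      c_ppix = if (identical(unit_tag, "unlabeled")) NULL else
        unlist(lapply(parts, `[[`, "c")),
      unit_tag = unit_tag
    )
  })
}

#' Synthetic liquid-phantom dataset
#'
#' Emulates the vial study: PpIX at (0, 0.2, 0.6, 1.25, 2.5) ug/mL crossed
#' with a 3 x 3 optical grid (mua 18/42/60 cm^-1, mus' 8.7/11.6/14.5
#' cm^-1) = 45 vials, \code{n_per_vial} binned pixels each. Within a vial
#' the underlying abundances and optics are shared, so noiseless spectra
#' are identical -- the identifiability assumption behind attenuation
#' correction. A small fixed background autofluorescence (0.05 on flavins)
#' emulates the dye/solvent background.
#'
#' @param B an \linkS4class{EndmemberLibrary} (K = 5, phantom order)
#' @param n_per_vial pixels per vial (default 200)
#' @param seed integer seed
#' @param noise a \code{\link{noiseModel}}
#' @param background_flavins fixed flavins background abundance
#' @return labeled \linkS4class{SpectraSet} (unit ug_per_ml)
#' @export
generatePhantomDataset <- function(B, n_per_vial = 200L, seed = 1,
                                   noise = noiseModel(),
                                   background_flavins = 0.05) {
  K <- ncol(endmemberMatrix(B))
  groups <- list()
  for (ci in seq_along(.phantom_conc)) for (ai in seq_along(.phantom_mua))
    for (si in seq_along(.phantom_musp)) {
      cc <- .phantom_conc[ci]
      z <- rep(0, K); z[1] <- cc; z[5] <- background_flavins
      groups[[length(groups) + 1L]] <- list(
        id = sprintf("vial_c%d_a%d_s%d", ci, ai, si),
        z = matrix(z, K, n_per_vial),
        c = cc,
        optics = opticalProperties(.phantom_mua[ai], .phantom_musp[si], 1))
    }
  .simulate_groups(groups, B, noise, seed, "ug_per_ml")
}

#' Synthetic pig-brain-homogenate dataset
#'
#' Seven PpIX concentrations (0, 0.5, 0.75, 1, 2, 3, 4 pmol/mg) times
#' \code{samples_per_conc} homogenate samples. Each sample draws its own
#' optics uniformly from the phantom ranges +/-20% and its own
#' autofluorescence abundances (lipofuscin/NADH/flavins ~ lognormal,
#' median 0.2). Per-pixel concentration jitter (default 5% CV) emulates
#' imperfect homogenization; labels carry the nominal per-sample value,
#' which is only exact on average. PpIX620 is simulated at 25% of the
#' PpIX634 abundance (photostate equilibrium), so zero-PpIX samples have
#' both photostates at zero.
#'
#' @param B an \linkS4class{EndmemberLibrary}
#' @param n_per_sample pixels per homogenate sample
#' @param samples_per_conc samples per concentration
#' @param seed integer seed
#' @param noise a \code{\link{noiseModel}}
#' @param conc_jitter_cv per-pixel concentration CV
#' @return labeled \linkS4class{SpectraSet} (unit pmol_per_mg)
#' @export
generatePbhDataset <- function(B, n_per_sample = 150L, samples_per_conc = 4L,
                               seed = 1, noise = noiseModel(),
                               conc_jitter_cv = 0.05) {
  K <- ncol(endmemberMatrix(B))
  groups <- withr::with_seed(as.integer(seed) + 1L, {
    out <- list()
    for (ci in seq_along(.pbh_conc)) for (si in seq_len(samples_per_conc)) {
      cc <- .pbh_conc[ci]
      cpx <- pmax(cc * (1 + stats::rnorm(n_per_sample, sd = conc_jitter_cv)), 0)
      auto <- stats::rlnorm(3, meanlog = log(0.2), sdlog = 0.5)
      z <- matrix(0, K, n_per_sample)
      z[1, ] <- cpx
      z[2, ] <- 0.25 * cpx
      z[3:5, ] <- auto
      out[[length(out) + 1L]] <- list(
        id = sprintf("pbh_c%d_r%d", ci, si),
        z = z, c = cc,
        optics = opticalProperties(
          stats::runif(1, 0.8 * min(.phantom_mua), 1.2 * max(.phantom_mua)),
          stats::runif(1, 0.8 * min(.phantom_musp), 1.2 * max(.phantom_musp)),
          stats::runif(1, 0.8, 1.2)))
    }
    out
  })
  .simulate_groups(groups, B, noise, seed, "pmol_per_mg")
}

#' Synthetic unlabeled human-like dataset
#'
#' Sparse random mixtures: each endmember is present with probability 0.6;
#' present magnitudes are Dirichlet-distributed across the support and
#' scaled by a lognormal total. Optics (including geometry) vary per
#' pixel, emulating heterogeneous tissue under freehand imaging.
#'
#' @param B an \linkS4class{EndmemberLibrary}
#' @param n number of pixels
#' @param seed integer seed
#' @param noise a \code{\link{noiseModel}}
#' @param present_prob per-endmember presence probability
#' @return unlabeled \linkS4class{SpectraSet}
#' @export
generateUnlabeledDataset <- function(B, n = 5000L, seed = 1,
                                     noise = noiseModel(),
                                     present_prob = 0.6) {
  K <- ncol(endmemberMatrix(B))
  grid <- spectraGrid(B)
  withr::with_seed(as.integer(seed), {
    support <- matrix(stats::rbinom(K * n, 1, present_prob), K, n)
    w <- matrix(stats::rgamma(K * n, shape = 1), K, n) * support
    tot <- colSums(w)
    w <- sweep(w, 2, ifelse(tot > 0, tot, 1), "/")
    z <- sweep(w, 2, stats::rlnorm(n, 0, 0.5), "*")
    mua <- stats::runif(n, 0.8 * min(.phantom_mua), 1.2 * max(.phantom_mua))
    musp <- stats::runif(n, 0.8 * min(.phantom_musp), 1.2 * max(.phantom_musp))
    geom <- stats::runif(n, 0.5, 1.5)
    # vectorized per-pixel forward model
    wl <- wavelengths(grid)
    mua_mat <- exp(-(wl - 405) / 120) %o% mua
    musp_mat <- (wl / 635)^(-1) %o% musp
    ref <- sweep(musp_mat / (mua_mat + musp_mat), 2, geom, "*")
    sel <- wl >= 620 & wl <= 640
    A <- ref^0.7 * rep(colMeans(ref[sel, , drop = FALSE]), each = length(wl))
    fluo <- (endmemberMatrix(B) %*% z) * A
    SpectraSet(.apply_noise(fluo, noise), .apply_noise(ref, noise), grid,
               group_id = "human_like", unit_tag = "unlabeled")
  })
}

#' Render a SpectraSet as a cube triplet
#'
#' Tiles the pixels row-major into the interior of an H x W image with a
#' dark border, adds a constant dark offset plus Gaussian sensor noise,
#' and emits matching fluorescence / white / dark cubes for preprocessing
#' round-trip tests (extract with \code{b = 1}).
#'
#' @param x a \linkS4class{SpectraSet}
#' @param H,W image dimensions; interior must hold \code{ncol(x)} pixels
#' @param seed integer seed for the sensor noise
#' @param border dark border width in pixels
#' @param dark_level constant dark offset in counts
#' @param dark_sd sensor noise SD in counts
#' @return list of \code{fluo}, \code{white}, \code{dark}
#'   \linkS4class{HyperCube}s plus the ground-truth \code{positions}
#'   (n x 2 row/col) matrix
#' @export
renderCubes <- function(x, H, W, seed = 1, border = 2L, dark_level = 5,
                        dark_sd = 0.02) {
  m <- nrow(x); n <- ncol(x)
  Hi <- H - 2L * border; Wi <- W - 2L * border
  if (Hi < 1L || Wi < 1L || Hi * Wi < n)
    stop("image interior too small for the number of pixels")
  f <- array(0, c(m, H, W)); w <- array(0, c(m, H, W))
  fl <- fluoSpectra(x); rf <- refSpectra(x)
  pos <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    r <- border + 1L + (i - 1L) %/% Wi
    cc <- border + 1L + (i - 1L) %% Wi
    f[, r, cc] <- fl[, i]
    w[, r, cc] <- rf[, i]
    pos[i, ] <- c(r, cc)
  }
  grid <- spectraGrid(x)
  withr::with_seed(as.integer(seed), {
    dk <- array(dark_level + stats::rnorm(m * H * W, sd = dark_sd), c(m, H, W))
    fc <- f + dark_level + array(stats::rnorm(m * H * W, sd = dark_sd), c(m, H, W))
    wc <- w + dark_level + array(stats::rnorm(m * H * W, sd = dark_sd), c(m, H, W))
    list(fluo = HyperCube(pmax(fc, 0), grid, "fluorescence"),
         white = HyperCube(pmax(wc, 0), grid, "white"),
         dark = HyperCube(pmax(dk, 0), grid, "dark"),
         positions = pos)
  })
}
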