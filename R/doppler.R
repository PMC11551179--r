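#' @title High-sensitivity Doppler velocimetry (jSTdOCT)
#' @description
#' The joint spectral and time domain processing chain: a zero-phase
#' high-pass filter along the time dimension suppresses the DC peak from
#' static and partial-volume scatterers, a zero-padded Fourier transform
#' yields an interpolated Doppler power spectrum (DPS) per voxel, and a
#' modified Gaussian is fit to every spectrum.  The fit's peak position is
#' the Doppler shift `mu`, its standard deviation `sigma`; the axial
#' velocity follows as `vz = lambda0 mu / (2 n)` and the transverse speed
#' as `vtransv = kappa sigma`, combined into the total speed by the
#' Euclidean norm.
#'
#' The fitted model is a wrap-aware Gaussian: the Gaussian is periodically
#' summed over the aliased frequency axis, the known power response of the
#' forward-backward high-pass filter is compensated, and the spectral
#' offset is pinned to a robust noise-floor quantile.  The fitted width is
#' deconvolved from the finite-window tone response before conversion to a
#' transverse speed.
#' @name doppler-velocimetry
NULL

## High-pass Butterworth design shared by all stages.
.hpFilter <- function(fs, cutoff, order = 2L) {
  signal::butter(order, cutoff / (fs / 2), type = "high")
}

## Zero-phase high-pass along the time dimension (columns): the squared
## Butterworth magnitude response applied spectrally.  This is the ideal
## zero-phase equivalent of forward-backward IIR filtering, has no edge
## transients on short M-mode series, and removes a constant (static)
## component exactly (it occupies only the zero-frequency bin).
.hpApply <- function(x, fs, cutoff) {
  nt <- nrow(x)
  bf <- .hpFilter(fs, cutoff)
  h2 <- sqrt(.hpPowerResponse(bf, .fftFreqs(nt, fs), fs))  # |H|^2
  mvfft(mvfft(x) * h2, inverse = TRUE) / nt
}

## Power response |H|^4 of the forward-backward filter at frequencies f,
## evaluated from the filter polynomials (two passes -> |H|^2 amplitude).
.hpPowerResponse <- function(bf, f, fs) {
  w <- 2 * pi * abs(f) / fs
  zi <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  h <- as.vector((zi %*% bf$b) / (zi %*% bf$a))
  r <- Mod(h)^4
  r[!is.finite(r)] <- 0
  r
}

## Frequency axes: natural FFT order and the ascending (-fs/2, fs/2] axis.
.fftFreqs <- function(n, fs) {
  f <- (seq_len(n) - 1) / n * fs
  f[f >= fs / 2] <- f[f >= fs / 2] - fs
  f
}

.dopplerEnv <- new.env(parent = emptyenv())

## Exact expected padded periodogram of the processing chain for a
## Gaussian spectral envelope: per-source-bin power (envelope times the
## squared filter power response) convolved with the finite-window
## Dirichlet kernel on the padded axis.
.expectedDps <- function(fD, sigma, protocol, calibration) {
  nt <- protocol@nRepeats; fs <- protocol@ascanRate
  npad <- calibration@nPad
  fg <- .fftFreqs(nt, fs)
  bf <- .hpFilter(fs, calibration@highpassCutoff)
  h4 <- .hpPowerResponse(bf, fg, fs)
  env2 <- wrappedGaussian(fg, fD, sigma, fs) * h4
  j <- 0:(npad - 1)
  sn <- sin(pi * j / npad)
  d2 <- ifelse(sn < 1e-12, 1, (sin(pi * nt * j / npad) / (nt * sn))^2)
  out <- numeric(npad)
  for (k in which(env2 > max(env2) * 1e-6)) {
    sh <- round((k - 1) * npad / nt)
    out <- out + env2[k] * d2[((j - sh) %% npad) + 1]
  }
  out
}

## Response map of the sigma estimate: the median of the estimator over
## seeded speckle realizations of the full chain (synthesis, high-pass,
## zero-padded periodogram, averaging over the protocol's volumes, fit),
## on a (mu, sigma) reference grid.  Inverted per voxel to deconvolve
## finite-window broadening, notch truncation and the saturation of wide
## spectra.  Cached per protocol/calibration.
.responseMap <- function(protocol, calibration, nreps = 32L,
                         binStride = 4L) {
  key <- paste("map", protocol@ascanRate, protocol@nRepeats,
               protocol@nVolumes, calibration@nPad,
               calibration@highpassCutoff, binStride, sep = "|")
  if (!is.null(.dopplerEnv[[key]])) return(.dopplerEnv[[key]])
  fs <- protocol@ascanRate
  nt <- protocol@nRepeats
  npad <- calibration@nPad
  nav <- protocol@nVolumes
  f <- sort(.fftFreqs(npad, fs))
  ord <- order(.fftFreqs(npad, fs))
  sub <- seq(1L, length(f), by = as.integer(binStride))
  f <- f[sub]
  bf <- .hpFilter(fs, calibration@highpassCutoff)
  resp <- .hpPowerResponse(bf, f, fs)
  muGrid <- c(0.05, 0.1, 0.2, 0.3, 0.4) * fs
  sgGrid <- exp(seq(log(20), log(0.43 * fs), length.out = 18))
  fitted <- matrix(NA_real_, length(muGrid), length(sgGrid))
  oneFit <- function(mu, sg, seed) {
    P <- 0
    for (k in seq_len(nav)) {
      withSeed(deriveSeed(seed, k), {
        x <- synthesizeVoxelSeries(nt, fs, mu, sg, 1, 0, 10^(-10 / 20))
      })
      x <- .hpApply(as.matrix(x), fs, calibration@highpassCutoff)
      P <- P + Mod(mvfft(rbind(x, matrix(0, npad - nt, 1))))^2
    }
    .fitOneSpectrum((as.vector(P)[ord] / nav)[sub], f, fs,
                    calibration@highpassCutoff, resp)[["sigma"]]
  }
  for (i in seq_along(muGrid))
    for (j in seq_along(sgGrid)) {
      v <- vapply(seq_len(nreps), function(r)
        oneFit(muGrid[i], sgGrid[j], 1e5 + 977 * (i * 100 + j) + r),
        numeric(1))
      fitted[i, j] <- median(v, na.rm = TRUE)
    }
  ## enforce monotone response curves so they are invertible
  for (i in seq_along(muGrid)) {
    ok <- is.finite(fitted[i, ])
    if (any(ok)) fitted[i, ok] <- cummax(fitted[i, ok])
  }
  .dopplerEnv[[key]] <- list(mu = muGrid, sigma = sgGrid, fitted = fitted)
  .dopplerEnv[[key]]
}

## Invert the response map: raw fitted sigma -> deconvolved sigma, at the
## voxel's fitted |mu| (linear blend of the two nearest mu rows).
.correctSigma <- function(sigmaRaw, muHat, map) {
  rows <- which(apply(map$fitted, 1L, function(r) sum(is.finite(r)) >= 2))
  if (!length(rows)) return(sigmaRaw)
  m <- abs(muHat)
  mus <- map$mu[rows]
  if (length(rows) == 1L || m <= mus[1L]) {
    curve <- map$fitted[rows[1L], ]
  } else if (m >= mus[length(mus)]) {
    curve <- map$fitted[rows[length(rows)], ]
  } else {
    i <- findInterval(m, mus)
    w <- (m - mus[i]) / (mus[i + 1L] - mus[i])
    curve <- (1 - w) * map$fitted[rows[i], ] + w * map$fitted[rows[i + 1L], ]
  }
  ok <- is.finite(curve)
  if (sum(ok) < 2) return(sigmaRaw)
  approx(curve[ok], map$sigma[ok], xout = sigmaRaw, rule = 2,
         ties = "ordered")$y
}

#' Compute per-voxel Doppler power spectra
#'
#' High-pass filters each voxel's time series along the time dimension
#' (zero-phase, 270 Hz cutoff by default), Fourier-transforms with
#' zero-padding to the calibration length, and returns power spectra on
#' the ascending frequency axis together with the per-voxel spectral
#' maximum `D_max` for the whole volume.  Several volumes (a list) are
#' averaged on the power spectra.  `D_max` is evaluated on the
#' natural-resolution (unpadded) power spectrum: it serves as an
#' intensity surrogate for thresholding and registration, and skipping
#' the interpolating zero-pad for the non-fitted voxels keeps full-volume
#' sweeps cheap.
#'
#' @param mmode an [MModeVolume-class] or a list of them (averaged).
#' @param voxels linear voxel indices whose spectra to keep (default all).
#' @param highpass set `FALSE` to skip the DC suppression (diagnostic).
#' @param chunkSize voxels per FFT block.
#' @return A [DopplerSpectraVolume-class].
#' @export
computeDps <- function(mmode, voxels = NULL, highpass = TRUE,
                       chunkSize = 4096L) {
  vols <- if (is(mmode, "MModeVolume")) list(mmode) else mmode
  m1 <- vols[[1L]]
  protocol <- m1@protocol; calibration <- m1@calibration
  nt <- protocol@nRepeats; fs <- protocol@ascanRate
  npad <- calibration@nPad
  if (npad < nt) stop("nPad must be at least the number of repeats")
  dims <- m1@grid@dim
  nvox <- prod(dims)
  if (is.null(voxels)) voxels <- seq_len(nvox)
  voxels <- as.integer(voxels)
  ford <- .fftFreqs(npad, fs)
  ord <- order(ford)
  dmax <- array(0, dims)
  keepPower <- matrix(0, length(voxels), npad)
  keepPos <- match(seq_len(nvox), voxels)
  for (v in vols) {
    sm <- matrix(aperm(v@samples, c(4, 1, 2, 3)), nrow = nt)
    for (start in seq(1L, nvox, by = chunkSize)) {
      idx <- start:min(start + chunkSize - 1L, nvox)
      x <- sm[, idx, drop = FALSE]
      if (highpass) x <- .hpApply(x, fs, calibration@highpassCutoff)
      Pnat <- Mod(mvfft(x))^2
      dmax[idx] <- dmax[idx] + apply(Pnat, 2L, max)
      sel <- which(!is.na(keepPos[idx]))
      if (length(sel)) {
        P <- Mod(mvfft(rbind(x[, sel, drop = FALSE],
                             matrix(0, npad - nt, length(sel)))))^2
        keepPower[keepPos[idx][sel], ] <-
          keepPower[keepPos[idx][sel], , drop = FALSE] +
          t(P[ord, , drop = FALSE])
      }
    }
  }
  nav <- length(vols)
  new("DopplerSpectraVolume", power = keepPower / nav,
      frequencies = ford[ord], voxelIndex = voxels, dmax = dmax / nav,
      grid = m1@grid, protocol = protocol, calibration = calibration,
      highpassed = highpass)
}

## Fit one power spectrum (ascending frequency axis).  Returns A, mu,
## sigma (raw, not window-deconvolved), offset, r2; NA on failure.
## R^2 is evaluated at the acquisition's natural spectral resolution:
## data and model are boxcar-smoothed over the finite-window response
## width before comparison, so speckle fluctuations that no estimator
## could fit do not drown the goodness measure.
.fitOneSpectrum <- function(p, f, fs, cutoff, resp,
                            offsetQuantile = 0.1, model = "wrapped",
                            r2Smooth = 1L) {
  ## compensate the filter's power response, but only where it is well
  ## above zero: dividing deeply attenuated notch bins amplifies residual
  ## junk into spurious DC peaks
  keep <- if (cutoff > 0) abs(f) > cutoff & resp >= 0.1 else rep(TRUE, length(f))
  pc <- p[keep] / resp[keep]
  fk <- f[keep]
  if (!any(pc > 0))
    return(c(A = NA, mu = NA, sigma = NA, offset = NA, r2 = NA, code = 2))
  cfix <- unname(quantile(pc, offsetQuantile))
  q25 <- unname(quantile(pc, 0.25))
  w <- pmax(pc - q25, 0)
  if (sum(w) <= 0)
    return(c(A = NA, mu = NA, sigma = NA, offset = NA, r2 = NA, code = 2))
  z <- sum(w * exp(2i * pi * fk / fs)) / sum(w)
  mu0 <- Arg(z) * fs / (2 * pi)
  s0 <- fs / (2 * pi) * sqrt(pmax(-2 * log(pmax(Mod(z), 1e-12)), 1e-6))
  s0 <- min(max(s0, 30), fs / 2)
  wg <- if (model == "wrapped") {
    function(fx, mu, s) wrappedGaussian(fx, mu, s, fs)
  } else {
    function(fx, mu, s) exp(-(fx - mu)^2 / (2 * s^2))
  }
  ## noise voxels legitimately exhaust the iteration budget; that is a
  ## rejected fit, not a user-facing condition
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(pc ~ A * wg(fk, mu, s) + cfix,
      start = list(A = max(pc) - cfix, mu = mu0, s = s0),
      lower = c(0, -fs, 5), upper = c(Inf, fs, fs),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit))
    return(c(A = NA, mu = NA, sigma = NA, offset = NA, r2 = NA, code = 1))
  ## wide spectra fill the whole axis, so a noise-floor quantile swallows
  ## signal; free the offset in that regime (it is well conditioned there,
  ## while near the DC notch the fixed floor avoids the sigma-offset
  ## degeneracy of narrow spectra)
  if (abs(coef(fit)[["s"]]) > 0.065 * fs) {
    cf1 <- coef(fit)
    ## the quantile floor over-estimates the true noise floor when the
    ## spectrum fills the axis, so the offset may only move DOWN from it;
    ## letting it rise absorbs the flat signal and collapses sigma
    fit2 <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(pc ~ A * wg(fk, mu, s) + c0,
        start = list(A = cf1[["A"]], mu = cf1[["mu"]], s = cf1[["s"]],
                     c0 = cfix),
        lower = c(0, -fs, 5, 0), upper = c(Inf, fs, fs, cfix + 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      cfix <- coef(fit2)[["c0"]]
    }
  }
  cf <- coef(fit)
  mu <- ((cf[["mu"]] + fs / 2) %% fs) - fs / 2
  sm <- function(x) {
    if (r2Smooth <= 1L) return(x)
    k <- rep(1 / r2Smooth, r2Smooth)
    as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
  }
  ps <- sm(pc); ms <- sm(predict(fit))
  sst <- sum((ps - mean(ps))^2)
  r2 <- if (sst > 0) 1 - sum((ps - ms)^2) / sst else -Inf
  c(A = cf[["A"]], mu = mu, sigma = abs(cf[["s"]]), offset = cfix,
    r2 = r2, code = 0)
}

#' Fit the modified Gaussian to every Doppler spectrum
#'
#' Nonlinear least squares per voxel, initialized from circular spectral
#' moments.  Voxels whose fit fails are marked invalid (never an error).
#' The stored `sigma` is deconvolved from the chain's deterministic
#' response (finite-window broadening and notch truncation), computed by
#' applying the estimator to the chain's exact expected spectra over a
#' reference grid and inverting; set `windowCorrection = FALSE` for the
#' raw fitted width.
#'
#' @param dps a [DopplerSpectraVolume-class].
#' @param offsetQuantile quantile of the compensated spectrum used as the
#'   fixed noise-floor offset.
#' @param model `"wrapped"` (default, periodically summed Gaussian) or
#'   `"plain"`.
#' @param binStride fit every `binStride`-th frequency bin (the zero-padded
#'   spectrum is heavily oversampled; 2 keeps the fit well-determined).
#' @param windowCorrection deconvolve the chain's deterministic spectral
#'   response from sigma.
#' @return A [DopplerFitVolume-class].
#' @export
fitDps <- function(dps, offsetQuantile = 0.1, model = c("wrapped", "plain"),
                   binStride = 4L, windowCorrection = TRUE) {
  model <- match.arg(model)
  protocol <- dps@protocol; calibration <- dps@calibration
  fs <- protocol@ascanRate
  dims <- dps@grid@dim
  mk <- function(x) array(x, dims)
  A <- mk(NA_real_); mu <- mk(NA_real_); sg <- mk(NA_real_)
  off <- mk(NA_real_); r2 <- mk(NA_real_)
  valid <- mk(FALSE); reason <- mk(0L)
  f <- dps@frequencies
  sub <- seq(1L, length(f), by = as.integer(binStride))
  hp <- isTRUE(dps@highpassed)
  cutoff <- if (hp) calibration@highpassCutoff else 0
  resp <- if (hp) {
    bf <- .hpFilter(fs, calibration@highpassCutoff)
    .hpPowerResponse(bf, f[sub], fs)
  } else rep(1, length(sub))
  rmap <- if (windowCorrection)
    .responseMap(protocol, calibration, binStride = as.integer(binStride))
  else NULL
  ## natural resolution (fs / nRepeats) expressed in fitted bins, x5
  r2Smooth <- max(1L, as.integer(round(
    5 * length(f) / (protocol@nRepeats * binStride))))
  for (r in seq_len(nrow(dps@power))) {
    i <- dps@voxelIndex[r]
    ft <- .fitOneSpectrum(dps@power[r, sub], f[sub], fs,
                          cutoff, resp, offsetQuantile, model, r2Smooth)
    reason[i] <- as.integer(ft[["code"]])
    if (ft[["code"]] == 0) {
      A[i] <- ft[["A"]]; off[i] <- ft[["offset"]]; r2[i] <- ft[["r2"]]
      mu[i] <- ft[["mu"]]
      sg[i] <- if (is.null(rmap)) ft[["sigma"]] else
        .correctSigma(ft[["sigma"]], ft[["mu"]], rmap)
      valid[i] <- TRUE
    }
  }
  new("DopplerFitVolume", A = A, mu = mu, sigma = sg, offset = off,
      r2 = r2, valid = valid, reason = reason, dmax = dps@dmax,
      grid = dps@grid, protocol = protocol, calibration = calibration)
}

#' Validate fitted voxels
#'
#' A voxel is kept iff its fit quality `R^2` reaches `r2Min`, its `D_max`
#' exceeds an adaptive per-depth-slice Otsu threshold on `log D_max`
#' (rejecting remaining static-tissue voxels), and its spread and shift
#' lie within physical bounds.  Voxels with `|mu| > aliasFraction * fs`
#' are aliased (wrapped fits are not unwrapped); their wrapped shift has
#' the wrong sign and magnitude, so they are rejected with reason code 4.
#'
#' @param fits a [DopplerFitVolume-class].
#' @param r2Min minimum goodness of fit.
#' @param sigmaBounds physical bounds on sigma (Hz).
#' @param aliasFraction aliasing flag threshold as a fraction of `fs`.
#' @param adaptive apply the per-depth-slice intensity threshold.
#' @return The updated [DopplerFitVolume-class] (`valid` and `reason`).
#' @export
validateVoxels <- function(fits, r2Min = 0.8,
                           sigmaBounds = c(5, Inf),
                           aliasFraction = 0.45, adaptive = TRUE) {
  fs <- fits@protocol@ascanRate
  ok <- is.finite(fits@r2) & fits@r2 >= r2Min &
        is.finite(fits@sigma) & fits@sigma > sigmaBounds[1] &
        fits@sigma < sigmaBounds[2]
  if (adaptive) {
    dims <- fits@grid@dim
    thr <- numeric(dims[1])
    for (z in seq_len(dims[1])) {
      sl <- log(pmax(fits@dmax[z, , ], .Machine$double.xmin))
      thr[z] <- otsuThreshold(as.vector(sl))
    }
    pass <- log(pmax(fits@dmax, .Machine$double.xmin)) >=
            array(thr, dims)       # recycles along z (first index)
    ok <- ok & pass
  }
  newReason <- fits@reason
  newReason[fits@valid & !ok] <- 3L
  aliasFlag <- ok & is.finite(fits@mu) & abs(fits@mu) > aliasFraction * fs
  newReason[aliasFlag] <- 4L
  fits@valid <- ok & !aliasFlag
  fits@reason <- newReason
  fits
}

#' Convert fitted spectra to velocities
#'
#' `vz = lambda0 mu / (2 n)` (signed), `vtransv = kappa sigma`, and
#' `vtot` as the Euclidean norm; invalid voxels carry `NA`.
#'
#' @param fits a [DopplerFitVolume-class].
#' @param calibration a [SystemCalibration-class]; defaults to the one
#'   stored with the fits.
#' @return A [VelocityField-class] (mm/s).
#' @export
toVelocities <- function(fits, calibration = fits@calibration) {
  dims <- fits@grid@dim
  vz <- array(NA_real_, dims); vt <- array(NA_real_, dims)
  vtot <- array(NA_real_, dims)
  v <- fits@valid
  vz[v] <- calibration@lambda0 * fits@mu[v] /
           (2 * calibration@refractiveIndex) * 1e3      # m/s -> mm/s
  vt[v] <- calibration@kappa * fits@sigma[v] / 1000     # um/s -> mm/s
  vtot[v] <- sqrt(vz[v]^2 + vt[v]^2)
  new("VelocityField", vz = vz, vtransv = vt, vtot = vtot, valid = v,
      grid = fits@grid)
}

#' Transverse velocity from the Doppler spectral spread
#'
#' The plain conversion `vtransv = kappa * sigma`, in mm/s.
#'
#' @param sigma spectral spread (Hz).
#' @param calibration a [SystemCalibration-class].
#' @return Transverse speed in mm/s.
#' @examples
#' transverseVelocity(3817)   # 12.2 mm/s
#' @export
transverseVelocity <- function(sigma, calibration = systemCalibration()) {
  calibration@kappa * sigma / 1000
}

#' Axial velocity from the Doppler shift
#'
#' `vz = lambda0 mu / (2 n)`, in mm/s (signed).
#'
#' @param mu Doppler shift (Hz).
#' @param calibration a [SystemCalibration-class].
#' @return Axial velocity in mm/s.
#' @examples
#' axialVelocity(2119)   # about 1.05 mm/s
#' @export
axialVelocity <- function(mu, calibration = systemCalibration()) {
  calibration@lambda0 * mu / (2 * calibration@refractiveIndex) * 1e3
}

#' Run the full Doppler processing chain on simulated or loaded volumes
#'
#' Convenience driver: spectra (optionally averaged over volumes), fits on
#' the voxels whose `D_max` passes the adaptive threshold (or all voxels),
#' validation, velocities.
#'
#' @param mmode an [MModeVolume-class] or list of them.
#' @param fitWhere `"adaptive"` fits only voxels above the per-depth
#'   D_max threshold, `"all"` fits everything, or a vector of linear
#'   voxel indices.
#' @param r2Min,offsetQuantile,binStride passed through.
#' @return A list with `fits` ([DopplerFitVolume-class]) and `velocity`
#'   ([VelocityField-class]).
#' @export
dopplerPipeline <- function(mmode, fitWhere = "adaptive", r2Min = 0.8,
                            offsetQuantile = 0.1, binStride = 4L) {
  vols <- if (is(mmode, "MModeVolume")) list(mmode) else mmode
  dims <- vols[[1L]]@grid@dim
  nvox <- prod(dims)
  if (is.numeric(fitWhere)) {
    voxels <- as.integer(fitWhere)
  } else if (identical(fitWhere, "all")) {
    voxels <- seq_len(nvox)
  } else {
    ## cheap pre-pass: D_max only, then adaptive per-slice selection
    pre <- computeDps(vols, voxels = integer(0))
    thr <- numeric(dims[1])
    for (z in seq_len(dims[1]))
      thr[z] <- otsuThreshold(as.vector(log(pmax(pre@dmax[z, , ],
                                                 .Machine$double.xmin))))
    sel <- log(pmax(pre@dmax, .Machine$double.xmin)) >= array(thr, dims)
    voxels <- which(sel)
  }
  dps <- computeDps(vols, voxels = voxels)
  fits <- fitDps(dps, offsetQuantile = offsetQuantile,
                 binStride = binStride)
  fits <- validateVoxels(fits, r2Min = r2Min)
  list(fits = fits, velocity = toVelocities(fits))
}
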