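#' @title OCT signal simulation
#' @description
#' Synthesizes M-mode Doppler acquisitions and repeated-B-scan angiography
#' series from a rasterized velocity field with the spectral statistics the
#' velocimetry stage assumes: at each perfused voxel the dynamic signal is
#' a complex Gaussian process whose one-sided power spectrum is Gaussian
#' with mean set by the axial velocity (`f_D = 2 n v_z / lambda0`) and
#' standard deviation set by the transverse speed (`sigma = v_t / kappa`);
#' static tissue contributes a constant-phase component, and complex white
#' noise is added.  Doppler shifts beyond the Nyquist range are wrapped
#' (aliasing is reproduced, not hidden) and flagged in the metadata.
#' @name oct-simulation
NULL

## Default amplitude / noise model for the simulators.  `snrDb` is the
## power ratio of a foreground voxel's dynamic signal to the additive
## complex noise; intralipid-enhanced vessels are bright, hence 20 dB.
#' Default simulator noise model
#'
#' @param snrDb dynamic-signal-to-noise power ratio of perfused voxels, dB.
#' @param signalAmp dynamic amplitude of perfused voxels.
#' @param staticAmp constant-phase amplitude of static-tissue voxels.
#' @param partialVolumeStatic static amplitude added to perfused voxels
#'   (mimics static/dynamic blending where capillary diameters approach
#'   the voxel size).
#' @return A named list understood by the simulators.
#' @export
noiseModel <- function(snrDb = 20, signalAmp = 1, staticAmp = 1,
                       partialVolumeStatic = 0) {
  list(snrDb = snrDb, signalAmp = signalAmp, staticAmp = staticAmp,
       partialVolumeStatic = partialVolumeStatic)
}

## Synthesize one voxel's complex time series.  The dynamic part shapes
## complex white noise with the wrapped Gaussian spectral envelope in the
## frequency domain and inverse-transforms it, which gives exactly the
## spectral statistics assumed by the fitting model.
synthesizeVoxelSeries <- function(nt, fs, fD, sigmaF, dynamicAmp,
                                  staticAmp, noiseSd) {
  x <- complex(real = rnorm(nt), imaginary = rnorm(nt)) * (noiseSd / sqrt(2))
  if (staticAmp > 0)
    x <- x + staticAmp * exp(2i * pi * runif(1))
  if (dynamicAmp > 0) {
    if (sigmaF < 1e-6) {                       # degenerate: pure tone
      ph <- 2 * pi * runif(1)
      x <- x + dynamicAmp * exp(1i * (2 * pi * fD * (0:(nt - 1)) / fs + ph))
    } else {
      fgrid <- (seq_len(nt) - 1) / nt * fs
      fgrid[fgrid >= fs / 2] <- fgrid[fgrid >= fs / 2] - fs
      env <- sqrt(wrappedGaussian(fgrid, fD, sigmaF, fs))
      w <- complex(real = rnorm(nt), imaginary = rnorm(nt)) / sqrt(2)
      gp <- fft(env * w, inverse = TRUE)
      x <- x + gp * (dynamicAmp / sqrt(sum(env^2)))
    }
  }
  x
}

## Gaussian periodically summed over the aliased frequency axis.
wrappedGaussian <- function(f, mu, sigma, fs, kmax = 2L) {
  out <- 0
  for (k in -kmax:kmax)
    out <- out + exp(-(f + k * fs - mu)^2 / (2 * sigma^2))
  out
}

## Doppler conversion constants: mm/s <-> Hz.
dopplerShiftHz <- function(vzMms, calibration) {
  2 * calibration@refractiveIndex * (vzMms * 1e-3) / calibration@lambda0
}
spreadHz <- function(vtMms, calibration) {
  vtMms * 1000 / calibration@kappa
}

#' Simulate an M-mode Doppler acquisition
#'
#' @param mask a [SegmentationMask-class] marking perfused voxels.
#' @param velocity 4-d array `[z, x, y, 3]` of velocity components (mm/s,
#'   axes z/x/y), e.g. from [rasterizeNetwork()].
#' @param protocol an [AcquisitionProtocol-class] (M-mode defaults).
#' @param calibration a [SystemCalibration-class].
#' @param noise list from [noiseModel()].
#' @param seed integer; each voxel derives its own deterministic stream, so
#'   results do not depend on processing order or chunking.
#' @return An [MModeVolume-class]; `metadata$aliasedVoxels` counts voxels
#'   whose Doppler shift exceeded the Nyquist range and was wrapped.
#' @export
simulateMMode <- function(mask, velocity, protocol = dopplerProtocol(),
                          calibration = systemCalibration(),
                          noise = noiseModel(), seed = 1L) {
  grid <- mask@grid
  stopifnot(all(dim(velocity)[1:3] == grid@dim))
  nt <- protocol@nRepeats
  dims <- grid@dim
  nvox <- prod(dims)
  res <- .simulateMModeChunk(seq_len(nvox), mask@values, velocity, protocol,
                             calibration, noise, seed)
  samples <- array(res$series, c(nt, dims))    # [t, z, x, y]
  samples <- aperm(samples, c(2, 3, 4, 1))
  new("MModeVolume", samples = samples, grid = grid, protocol = protocol,
      calibration = calibration,
      metadata = list(aliasedVoxels = res$aliased, seed = seed))
}

## Simulate the time series for a set of linear voxel indices; returns a
## nt x nvox complex matrix.  Shared by simulateMMode and the streaming
## acquisition-to-fit driver.
.simulateMModeChunk <- function(voxels, maskValues, velocity, protocol,
                                calibration, noise, seed) {
  nt <- protocol@nRepeats
  fs <- protocol@ascanRate
  nvox <- length(maskValues)
  noiseSd <- noise$signalAmp * 10^(-noise$snrDb / 20)
  out <- matrix(complex(real = 0, imaginary = 0), nt, length(voxels))
  aliased <- 0L
  vz <- velocity[, , , 1, drop = FALSE]
  vx <- velocity[, , , 2, drop = FALSE]
  vy <- velocity[, , , 3, drop = FALSE]
  for (j in seq_along(voxels)) {
    i <- voxels[j]
    set.seed(deriveSeed(seed, i))
    if (maskValues[i]) {
      fD <- dopplerShiftHz(vz[i], calibration)
      if (abs(fD) > fs / 2) aliased <- aliased + 1L
      sg <- spreadHz(sqrt(vx[i]^2 + vy[i]^2), calibration)
      out[, j] <- synthesizeVoxelSeries(nt, fs, fD, sg, noise$signalAmp,
                                        noise$partialVolumeStatic, noiseSd)
    } else {
      out[, j] <- synthesizeVoxelSeries(nt, fs, 0, 0, 0, noise$staticAmp,
                                        noiseSd)
    }
  }
  list(series = out, aliased = aliased)
}

#' Simulate a repeated-B-scan angiography series
#'
#' Perfused voxels decorrelate between repeats at a rate increasing with
#' the local speed (AR(1) with coefficient `exp(-speed / decorrSpeed)`);
#' static voxels repeat up to the additive noise.
#'
#' @inheritParams simulateMMode
#' @param protocol an [AcquisitionProtocol-class] (angiography defaults).
#' @param decorrSpeed speed scale (mm/s) of inter-repeat decorrelation.
#' @return A [BScanSeries-class].
#' @export
simulateBScanSeries <- function(mask, velocity,
                                protocol = angiographyProtocol(),
                                noise = noiseModel(), decorrSpeed = 1,
                                seed = 1L) {
  grid <- mask@grid
  stopifnot(all(dim(velocity)[1:3] == grid@dim))
  nr <- protocol@nRepeats
  dims <- grid@dim
  nvox <- prod(dims)
  speed <- sqrt(velocity[, , , 1]^2 + velocity[, , , 2]^2 +
                velocity[, , , 3]^2)
  noiseSd <- noise$signalAmp * 10^(-noise$snrDb / 20)
  samples <- array(complex(real = 0, imaginary = 0), c(nr, dims))
  msk <- mask@values
  for (i in seq_len(nvox)) {
    set.seed(deriveSeed(seed, i))
    if (msk[i]) {
      rho <- exp(-speed[i] / decorrSpeed)
      s <- complex(real = numeric(nr), imaginary = numeric(nr))
      s[1] <- complex(real = rnorm(1), imaginary = rnorm(1)) / sqrt(2)
      if (nr > 1)
        for (r in 2:nr)
          s[r] <- rho * s[r - 1] + sqrt(1 - rho^2) *
                  complex(real = rnorm(1), imaginary = rnorm(1)) / sqrt(2)
      s <- s * noise$signalAmp
    } else {
      s <- rep(noise$staticAmp * exp(2i * pi * runif(1)), nr)
    }
    s <- s + complex(real = rnorm(nr), imaginary = rnorm(nr)) *
         (noiseSd / sqrt(2))
    samples[(i - 1) * nr + seq_len(nr)] <- s   # fills [r, voxel i]
  }
  new("BScanSeries", samples = samples, grid = grid, protocol = protocol)
}

#' Simulate a Doppler acquisition and accumulate its spectra in one pass
#'
#' Streaming equivalent of [simulateMMode()] followed by [computeDps()]
#' over several averaged volumes: voxel time series are synthesized in
#' chunks, high-pass filtered, transformed and accumulated, so no full
#' M-mode volume is ever held in memory.  Per-voxel deterministic seeding
#' makes the result identical to the in-memory path.
#'
#' @inheritParams simulateMMode
#' @param seeds one seed per simulated volume (their spectra are
#'   averaged).
#' @param voxels linear voxel indices whose spectra to keep.
#' @param highpass apply the DC-suppressing high-pass.
#' @param chunkSize voxels per block.
#' @param sweep `"all"` computes `D_max` for every voxel (needed by the
#'   adaptive validation threshold); `"kept"` only visits the kept voxels.
#' @return A [DopplerSpectraVolume-class].
#' @export
simulateAndComputeDps <- function(mask, velocity,
                                  protocol = dopplerProtocol(),
                                  calibration = systemCalibration(),
                                  noise = noiseModel(), seeds = 1:3,
                                  voxels = NULL, highpass = TRUE,
                                  chunkSize = 4096L,
                                  sweep = c("all", "kept")) {
  sweep <- match.arg(sweep)
  grid <- mask@grid
  dims <- grid@dim
  nvox <- prod(dims)
  nt <- protocol@nRepeats
  fs <- protocol@ascanRate
  npad <- calibration@nPad
  if (npad < nt) stop("nPad must be at least the number of repeats")
  if (is.null(voxels)) voxels <- seq_len(nvox)
  voxels <- as.integer(voxels)
  ford <- .fftFreqs(npad, fs)
  ord <- order(ford)
  dmax <- array(0, dims)
  keepPower <- matrix(0, length(voxels), npad)
  keepPos <- match(seq_len(nvox), voxels)
  mv <- mask@values
  sweepIdx <- if (sweep == "all") seq_len(nvox) else sort(voxels)
  for (sd in seeds) {
    for (start in seq(1L, length(sweepIdx), by = chunkSize)) {
      idx <- sweepIdx[start:min(start + chunkSize - 1L, length(sweepIdx))]
      x <- .simulateMModeChunk(idx, mv, velocity, protocol, calibration,
                               noise, sd)$series
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
  nav <- length(seeds)
  new("DopplerSpectraVolume", power = keepPower / nav,
      frequencies = ford[ord], voxelIndex = voxels, dmax = dmax / nav,
      grid = grid, protocol = protocol, calibration = calibration,
      highpassed = highpass)
}
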