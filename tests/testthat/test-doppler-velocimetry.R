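test_that("the high-pass removes a DC-only series almost completely", {
  grid <- voxelGrid(c(1, 1, 1), 4)
  mask <- new("SegmentationMask", values = array(FALSE, c(1, 1, 1)),
              grid = grid, provenance = "synthetic")
  vel <- array(0, c(1, 1, 1, 3))
  mm <- simulateMMode(mask, vel,
                      noise = noiseModel(snrDb = Inf, staticAmp = 1),
                      seed = 2)
  raw <- computeDps(mm, highpass = FALSE)
  filt <- computeDps(mm, highpass = TRUE)
  expect_lt(sum(filt@power[1, ]), 1e-3 * sum(raw@power[1, ]))
})

test_that("a 5 kHz tone lands on the right zero-padded bin", {
  prot <- dopplerProtocol()
  cal <- systemCalibration()
  nt <- prot@nRepeats
  tone <- exp(2i * pi * 5000 * (0:(nt - 1)) / prot@ascanRate)
  samples <- array(tone, c(1, 1, 1, nt))
  mm <- new("MModeVolume", samples = samples,
            grid = voxelGrid(c(1, 1, 1), 4), protocol = prot,
            calibration = cal, metadata = list())
  dps <- computeDps(mm)
  pk <- dps@frequencies[which.max(dps@power[1, ])]
  expect_lt(abs(pk - 5000), prot@ascanRate / cal@nPad + 1e-9)
})

test_that("nPad below the series length is rejected", {
  mm <- simVoxelAcquisition(1, 1, seed = 1, nVolumes = 1)[[1]]
  mm@calibration <- systemCalibration(nPad = 128L)
  expect_error(computeDps(mm), "nPad")
})

test_that("the fit reproduces a noiseless synthetic Gaussian spectrum", {
  prot <- dopplerProtocol()
  cal <- systemCalibration()
  f <- sort(vascuflow:::.fftFreqs(cal@nPad, prot@ascanRate))
  p <- exp(-(f - 1000)^2 / (2 * 500^2))
  dps <- new("DopplerSpectraVolume", power = rbind(p), frequencies = f,
             voxelIndex = 1L, dmax = array(max(p), c(1, 1, 1)),
             grid = voxelGrid(c(1, 1, 1), 4), protocol = prot,
             calibration = cal, highpassed = FALSE)
  fit <- fitDps(dps, windowCorrection = FALSE, binStride = 1L)
  expect_equal(fit@mu[1], 1000, tolerance = 1e-3)
  expect_equal(fit@sigma[1], 500, tolerance = 1e-3)
  expect_gt(fit@r2[1], 0.999)
})

test_that("artery-like spectra are recovered within 5%", {
  ## mu = 2119 Hz, sigma = 3817 Hz used as simulation ground truth
  cal <- systemCalibration()
  vz <- axialVelocity(2119, cal)
  vt <- transverseVelocity(3817, cal)
  r <- vapply(1:5, function(sd)
    fitVoxel(vz, vt, snrDb = 20, seed = sd), numeric(3))
  expect_lt(abs(median(r["mu", ]) - 2119) / 2119, 0.05)
  expect_lt(abs(median(r["sigma", ]) - 3817) / 3817, 0.05)
})

test_that("flat noise spectra fit badly and are invalidated", {
  grid <- voxelGrid(c(1, 1, 1), 4)
  mask <- new("SegmentationMask", values = array(FALSE, c(1, 1, 1)),
              grid = grid, provenance = "synthetic")
  vel <- array(0, c(1, 1, 1, 3))
  r2s <- vapply(1:20, function(sd) {
    mm <- simulateMMode(mask, vel,
                        noise = noiseModel(snrDb = 0, staticAmp = 0),
                        seed = 100 + sd)
    f <- fitDps(computeDps(mm))
    f@r2[1]
  }, numeric(1))
  expect_lt(median(r2s, na.rm = TRUE), 0.5)
  mm <- simulateMMode(mask, vel, noise = noiseModel(snrDb = 0,
                                                    staticAmp = 0),
                      seed = 1)
  f <- validateVoxels(fitDps(computeDps(mm)), adaptive = FALSE)
  expect_false(f@valid[1])
})

test_that("an all-zero spectrum is marked invalid with a reason code", {
  prot <- dopplerProtocol()
  cal <- systemCalibration()
  f <- sort(vascuflow:::.fftFreqs(cal@nPad, prot@ascanRate))
  dps <- new("DopplerSpectraVolume", power = rbind(rep(0, length(f))),
             frequencies = f, voxelIndex = 1L,
             dmax = array(0, c(1, 1, 1)),
             grid = voxelGrid(c(1, 1, 1), 4), protocol = prot,
             calibration = cal, highpassed = TRUE)
  fit <- fitDps(dps)
  expect_false(fit@valid[1])
  expect_equal(fit@reason[1], 2L)
})

test_that("fitted parameters agree with spectral moments on clean input", {
  ## oracle equivalence on a noiseless single-voxel input: the chain's
  ## exact expected spectrum (no speckle, no additive noise); moments are
  ## evaluated on the spectral support, since the finite-window leakage
  ## tails fall off as 1/f^2 and unrestricted second moments measure the
  ## window, not the flow
  cal <- systemCalibration()
  prot <- dopplerProtocol()
  muT <- 4000; sgT <- 500
  P <- vascuflow:::.expectedDps(muT, sgT, prot, cal)
  f0 <- vascuflow:::.fftFreqs(cal@nPad, prot@ascanRate)
  ord <- order(f0)
  f <- f0[ord]; p <- P[ord]
  dps <- new("DopplerSpectraVolume", power = rbind(p), frequencies = f,
             voxelIndex = 1L, dmax = array(max(p), c(1, 1, 1)),
             grid = voxelGrid(c(1, 1, 1), 4), protocol = prot,
             calibration = cal, highpassed = TRUE)
  supp <- abs(f - f[which.max(p)]) <= 5 * sgT
  muM <- sum(p[supp] * f[supp]) / sum(p[supp])
  sdM <- sqrt(sum(p[supp] * (f[supp] - muM)^2) / sum(p[supp]))
  fit <- fitDps(dps, windowCorrection = FALSE)
  binHz <- prot@ascanRate / cal@nPad
  expect_lt(abs(fit@mu[1] - muM), binHz)
  expect_lt(abs(fit@sigma[1] - sdM), 4 * binHz)
})

test_that("fitted spread increases monotonically with transverse speed", {
  vts <- seq(1, 19, length.out = 10)
  sig <- vapply(vts, function(vt) {
    r <- vapply(1:3, function(sd) fitVoxel(1, vt, seed = sd)["sigma"],
                numeric(1))
    median(r)
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("voxel validation separates flow from static tissue", {
  ## 50% flow / 50% static voxels, classified by R^2 + adaptive D_max
  sp <- networkSpec(levels = 2L, domain = c(160, 160, 160),
                    arteryRootRadius = 10, seed = 31)
  g <- generateNetwork(sp)
  fs <- solveNetworkFlow(g, sp)
  grid <- voxelGrid(c(20, 20, 20), 8)
  ras <- suppressWarnings(rasterizeNetwork(g, fs, grid))
  msk <- ras$mask@values
  fg <- which(msk)
  bg <- which(!msk)
  set.seed(1)
  pick <- c(fg[seq_len(min(150, length(fg)))],
            sample(bg, min(150, length(fg))))
  mm <- lapply(1:3, function(k)
    simulateMMode(ras$mask, ras$velocity, noise = noiseModel(), seed = k))
  dps <- computeDps(mm, voxels = pick)
  fits <- validateVoxels(fitDps(dps))
  truth <- msk[pick]
  pred <- fits@valid[pick]
  expect_gt(mean(pred == truth), 0.95)
})

test_that("velocity conversion follows the calibration identities", {
  cal <- systemCalibration()
  ## worked example: sigma = 3817 Hz -> 12.2 mm/s transverse
  expect_equal(round(transverseVelocity(3817, cal), 1), 12.2)
  ## axial closed form at mu = 2119 Hz
  expect_equal(axialVelocity(2119, cal), 1.0476, tolerance = 1e-3)
  ## 3-4-5 triangle through toVelocities
  dims <- c(1L, 1L, 1L)
  mkArr <- function(v) array(v, dims)
  muFor <- function(v) 2 * cal@refractiveIndex * v * 1e-3 / cal@lambda0
  fits <- new("DopplerFitVolume",
              A = mkArr(1), mu = mkArr(muFor(3)),
              sigma = mkArr(4 * 1000 / cal@kappa), offset = mkArr(0),
              r2 = mkArr(0.99), valid = mkArr(TRUE), reason = mkArr(0L),
              dmax = mkArr(1), grid = voxelGrid(dims, 4),
              protocol = dopplerProtocol(), calibration = cal)
  v <- toVelocities(fits)
  expect_equal(v@vz[1], 3, tolerance = 1e-9)
  expect_equal(v@vtransv[1], 4, tolerance = 1e-9)
  expect_equal(v@vtot[1], 5, tolerance = 1e-9)
  ## Euclidean identity holds exactly on valid voxels (class validity)
  expect_true(validObject(v))
})
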