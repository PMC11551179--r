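test_that("a pure axial flow produces a Doppler tone at 2 n vz / lambda0", {
  cal <- systemCalibration()
  vz <- 1000 * cal@lambda0 / (2 * cal@refractiveIndex) * 1e3  # fD = 1 kHz
  mm <- simVoxelAcquisition(vz, 0, snrDb = Inf, seed = 2, nVolumes = 1)
  dps <- computeDps(mm)
  pk <- dps@frequencies[which.max(dps@power[1, ])]
  binHz <- mm[[1]]@protocol@ascanRate / cal@nPad
  expect_lt(abs(pk - 1000), binHz + 1e-9)
})

test_that("a static voxel concentrates all power at zero frequency", {
  grid <- voxelGrid(c(1, 1, 1), 4)
  mask <- new("SegmentationMask", values = array(FALSE, c(1, 1, 1)),
              grid = grid, provenance = "synthetic")
  vel <- array(0, c(1, 1, 1, 3))
  mm <- simulateMMode(mask, vel, noise = noiseModel(snrDb = Inf,
                                                    staticAmp = 1),
                      seed = 5)
  dps <- computeDps(mm, highpass = FALSE)
  pk <- dps@frequencies[which.max(dps@power[1, ])]
  expect_equal(pk, 0, tolerance = 1e-9)
})

test_that("the simulated spectral width matches the transverse calibration", {
  ## moment oracle over 200 realizations: sample spectral std vs target
  cal <- systemCalibration()
  prot <- dopplerProtocol()
  target <- 2000                                  # Hz
  vt <- transverseVelocity(target, cal)
  mm <- lapply(1:200, function(k)
    simVoxelAcquisition(0, vt, snrDb = 40, seed = 1000 + k,
                        nVolumes = 1)[[1]])
  dps <- computeDps(mm, highpass = FALSE)
  p <- dps@power[1, ]
  f <- dps@frequencies
  mu <- sum(p * f) / sum(p)
  sdv <- sqrt(sum(p * (f - mu)^2) / sum(p))
  ## window broadening adds ~40 Hz in quadrature at this width
  expect_lt(abs(sdv - target) / target, 0.05)
})

test_that("super-Nyquist Doppler shifts wrap and are flagged", {
  cal <- systemCalibration()
  vzAlias <- 0.6 * 23000 * cal@lambda0 / (2 * cal@refractiveIndex) * 1e3
  mm <- simVoxelAcquisition(vzAlias, 0.5, seed = 3, nVolumes = 1)
  expect_equal(mm[[1]]@metadata$aliasedVoxels, 1L)
  dps <- computeDps(mm)
  pk <- dps@frequencies[which.max(dps@power[1, ])]
  expect_lt(pk, 0)   # wrapped onto the negative side
})

test_that("M-mode simulation is deterministic and chunk-order independent", {
  sp <- networkSpec(levels = 1L, domain = c(150, 150, 150),
                    arteryRootRadius = 8, seed = 5)
  g <- generateNetwork(sp)
  fs <- solveNetworkFlow(g, sp)
  grid <- voxelGrid(c(24, 24, 24), 6)
  ras <- suppressWarnings(rasterizeNetwork(g, fs, grid))
  m1 <- simulateMMode(ras$mask, ras$velocity, seed = 7)
  m2 <- simulateMMode(ras$mask, ras$velocity, seed = 7)
  expect_identical(m1@samples, m2@samples)
  m3 <- simulateMMode(ras$mask, ras$velocity, seed = 8)
  expect_false(identical(m1@samples, m3@samples))
})

test_that("B-scan repeats decorrelate with flow and replicate when static", {
  sp <- networkSpec(levels = 1L, domain = c(150, 150, 150),
                    arteryRootRadius = 8, seed = 5)
  g <- generateNetwork(sp)
  fs <- solveNetworkFlow(g, sp)
  grid <- voxelGrid(c(24, 24, 24), 6)
  ras <- suppressWarnings(rasterizeNetwork(g, fs, grid))
  bs <- simulateBScanSeries(ras$mask, ras$velocity,
                            noise = noiseModel(snrDb = 30), seed = 4)
  expect_identical(bs@samples,
                   simulateBScanSeries(ras$mask, ras$velocity,
                                       noise = noiseModel(snrDb = 30),
                                       seed = 4)@samples)
  ## static-only volume: inter-repeat variance at the noise floor
  mask0 <- new("SegmentationMask",
               values = array(FALSE, c(8, 8, 8)),
               grid = voxelGrid(c(8, 8, 8), 2), provenance = "synthetic")
  vel0 <- array(0, c(8, 8, 8, 3))
  bs0 <- simulateBScanSeries(mask0, vel0,
                             noise = noiseModel(snrDb = 30), seed = 4)
  repVar <- mean(apply(bs0@samples, 2:4, function(x) var(Mod(x))))
  noiseVar <- (10^(-30 / 20))^2
  expect_lt(repVar, 3 * noiseVar)
  ## perfused voxels decorrelate more than static ones
  corrOf <- function(bsc, sel) {
    d <- dim(bsc@samples)
    v <- matrix(bsc@samples, d[1])[, sel, drop = FALSE]
    mean(abs(colSums(Conj(v[-d[1], ]) * v[-1, ])) /
         colSums(Mod(v[-d[1], ])^2))
  }
  fast <- which(ras$mask@values &
                sqrt(apply(ras$velocity^2, 1:3, sum)) > 2)
  static <- which(!ras$mask@values)[1:200]
  expect_lt(corrOf(bs, fast), corrOf(bs, static))
})
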