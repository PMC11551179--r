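## Shared fixtures: tiny networks, single-voxel acquisitions, and helpers
## used across the suite.  Everything is generated in code.

## single-voxel M-mode acquisition for a given (vz, vt) in mm/s
simVoxelAcquisition <- function(vz, vt, snrDb = 20, seed = 1,
                                nVolumes = 3,
                                noise = noiseModel(snrDb = snrDb)) {
  grid <- voxelGrid(c(1, 1, 1), 4)
  mask <- new("SegmentationMask", values = array(TRUE, c(1, 1, 1)),
              grid = grid, provenance = "synthetic")
  vel <- array(0, c(1, 1, 1, 3))
  vel[1, 1, 1, 1] <- vz
  vel[1, 1, 1, 2] <- vt
  lapply(seq_len(nVolumes), function(k)
    simulateMMode(mask, vel, noise = noise, seed = seed * 101 + k))
}

## fitted (mu, sigma, r2) for one (vz, vt) pair, one seed
fitVoxel <- function(vz, vt, snrDb = 20, seed = 1, highpass = TRUE, ...) {
  mm <- simVoxelAcquisition(vz, vt, snrDb = snrDb, seed = seed)
  fits <- fitDps(computeDps(mm, highpass = highpass), ...)
  c(mu = fits@mu[1], sigma = fits@sigma[1], r2 = fits@r2[1])
}

## straight vertical cylinder of given radius as a VesselGraph
cylinderGraph <- function(radius, length = 80, centerXY = c(40, 40),
                          label = "unlabeled") {
  nodes <- data.frame(id = 1:2, z = c(5, 5 + length),
                      x = rep(centerXY[1], 2), y = rep(centerXY[2], 2))
  pts <- cbind(seq(5, 5 + length, length.out = 17),
               centerXY[1], centerXY[2])
  seg <- vesselSegment(1L, 1L, 2L, pts, rep(radius, 17), label = label)
  vesselGraph(nodes, list(seg),
              metadata = list(inletNodes = 1L, outletNodes = 2L))
}

## small Y-shaped tree (one bifurcation) as a VesselGraph
yTreeGraph <- function(radius = 5) {
  nodes <- data.frame(id = 1:4,
                      z = c(10, 60, 110, 110),
                      x = c(64, 64, 34, 94),
                      y = c(64, 64, 64, 64))
  seg <- function(id, a, b) {
    pts <- cbind(seq(nodes$z[a], nodes$z[b], length.out = 9),
                 seq(nodes$x[a], nodes$x[b], length.out = 9),
                 seq(nodes$y[a], nodes$y[b], length.out = 9))
    vesselSegment(id, a, b, pts, rep(radius, 9))
  }
  vesselGraph(nodes, list(seg(1L, 1L, 2L), seg(2L, 2L, 3L),
                          seg(3L, 2L, 4L)))
}

## a conservation-consistent ground-truth network with velocities
groundTruthNetwork <- function(seed = 1, spec = networkSpec(seed = seed)) {
  g <- generateNetwork(spec)
  fs <- solveNetworkFlow(g, spec)
  list(graph = setSegmentVelocitiesFromFlow(g, fs), flow = fs, spec = spec)
}

## blank the fraction of segments most orthogonal to the beam
blankMostOrthogonal <- function(graph, fraction = 0.08) {
  tz <- vapply(graph@segments, vascuflow:::segmentMeanTangentZ, numeric(1))
  nb <- ceiling(fraction * length(graph@segments))
  blank <- order(abs(tz))[seq_len(nb)]
  for (k in blank) {
    graph@segments[[k]]$vtot <- NA_real_
    graph@segments[[k]]$vz <- NA_real_
    graph@segments[[k]]$direction <- "unknown"
    graph@segments[[k]]$source <- "unset"
  }
  list(graph = graph, blanked = blank)
}
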