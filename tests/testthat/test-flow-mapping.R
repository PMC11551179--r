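test_that("registration of identical volumes is the identity", {
  set.seed(4)
  v <- array(rnorm(20^3), c(20, 20, 20))
  A <- registerVolumes(v, v)
  expect_equal(A, diag(4), tolerance = 1e-6)
})

test_that("a known integer shift is recovered to sub-voxel accuracy", {
  set.seed(5)
  base <- array(0, c(32, 32, 32))
  for (k in 1:40) {
    p <- sample(4:28, 3)
    base[p[1] + (-1:1), p[2] + (-1:1), p[3] + (-1:1)] <- runif(1, 0.5, 1)
  }
  shifted <- array(0, c(32, 32, 32))
  shifted[3:32, 4:32, 2:32] <- base[1:30, 1:29, 1:31]
  A <- registerVolumes(base, shifted)
  expect_equal(A[1:3, 4], c(2, 3, 1), tolerance = 0.5)
})

test_that("the top-fraction sphere mean picks the fastest samples", {
  ## samples {1..10} in the sphere: top-30% mean is mean(8,9,10) = 9
  dims <- c(3L, 12L, 3L)
  grid <- voxelGrid(dims, 1)
  vt <- array(NA_real_, dims); vz <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  vt[2, 2:11, 2] <- 1:10
  vz[2, 2:11, 2] <- 0
  valid[2, 2:11, 2] <- TRUE
  field <- new("VelocityField", vz = vz, vtransv = vt, vtot = vt,
               valid = valid, grid = grid)   # vz = 0, so vtot = vtransv
  nodes <- data.frame(id = 1:2, z = c(1, 1), x = c(5.5, 6.5), y = c(1, 1))
  seg <- vesselSegment(1L, 1L, 2L, rbind(c(1, 5.5, 1), c(1, 6.5, 1)),
                       c(6, 6))
  g <- vesselGraph(nodes, list(seg))
  g2 <- mapVelocitiesToGraph(g, field, topFraction = 0.3, window = 1L)
  expect_equal(segmentTable(g2)$vtot, 9)
})

test_that("a uniform field maps to the segment's speed", {
  g <- cylinderGraph(5, length = 40, centerXY = c(24, 24))
  grid <- voxelGrid(c(48, 48, 48), 2)
  ras <- rasterizeNetwork(
    g, new("FlowState", flows = c(`1` = 1),
           pressures = c(`1` = 1, `2` = 0), velocities = c(`1` = 5)),
    grid)
  field <- rasterToVelocityField(ras)
  g2 <- mapVelocitiesToGraph(g, field)
  expect_equal(segmentTable(g2)$vtot, 5, tolerance = 1e-6)
})

test_that("direction votes follow the sign convention", {
  mk <- function(vzSign) {
    g <- cylinderGraph(5, length = 40, centerXY = c(24, 24))
    grid <- voxelGrid(c(48, 48, 48), 2)
    v <- 4 * vzSign
    ras <- rasterizeNetwork(
      g, new("FlowState", flows = c(`1` = 1),
             pressures = c(`1` = 1, `2` = 0),
             velocities = c(`1` = v)), grid)
    field <- rasterToVelocityField(ras)
    ## signed axial component: rasterizer stores tangent * speed
    assignFlowDirections(mapVelocitiesToGraph(g, field))
  }
  ## descending polyline (tangent_z > 0), positive vz: start -> end
  expect_equal(segmentTable(mk(+1))$direction, "s2e")
  expect_equal(segmentTable(mk(-1))$direction, "e2s")
  ## fully horizontal vessel: no vote, unknown
  nodes <- data.frame(id = 1:2, z = c(24, 24), x = c(8, 40), y = c(24, 24))
  pts <- cbind(24, seq(8, 40, length.out = 9), 24)
  g <- vesselGraph(nodes, list(vesselSegment(1L, 1L, 2L, pts, rep(5, 9))))
  grid <- voxelGrid(c(48, 48, 48), 2)
  ras <- rasterizeNetwork(g, new("FlowState", flows = c(`1` = 1),
                                 pressures = c(`1` = 1, `2` = 0),
                                 velocities = c(`1` = 5)), grid)
  g2 <- assignFlowDirections(
    mapVelocitiesToGraph(g, rasterToVelocityField(ras)))
  expect_equal(segmentTable(g2)$direction, "unknown")
})

test_that("conservation recovery solves the worked three-vessel balance", {
  ## inflow d=10 um at 4 mm/s, outflow d=6 um at 2 mm/s, unknown d=8 um:
  ## Q balance gives 82 pi um^2 mm/s over 16 pi um^2 -> 5.125 mm/s out
  nodes <- data.frame(id = 1:4, z = c(0, 10, 20, 20),
                      x = c(0, 0, 10, -10), y = c(0, 0, 0, 0))
  mkseg <- function(id, a, b, r, v, dir) {
    pts <- rbind(as.numeric(nodes[a, 2:4]), as.numeric(nodes[b, 2:4]))
    s <- vesselSegment(id, a, b, pts, c(r, r), vtot = v, direction = dir,
                       source = if (is.na(v)) "unset" else "measured")
    s
  }
  g <- vesselGraph(nodes, list(
    mkseg(1L, 1L, 2L, 5, 4, "s2e"),      # inflow into node 2
    mkseg(2L, 2L, 3L, 3, 2, "s2e"),      # outflow
    mkseg(3L, 2L, 4L, 4, NA_real_, "unknown")))
  out <- recoverMissingVelocities(g)
  s3 <- segments(out)[[3]]
  expect_equal(s3$vtot, 5.125, tolerance = 1e-12)
  expect_equal(s3$direction, "s2e")      # away from node 2
  expect_equal(s3$source, "recovered")
})

test_that("segments between two undetermined nodes stay unset", {
  nodes <- data.frame(id = 1:4, z = 0:3 * 10, x = 0, y = 0)
  mkseg <- function(id, a, b, v) {
    pts <- rbind(as.numeric(nodes[a, 2:4]), as.numeric(nodes[b, 2:4]))
    vesselSegment(id, a, b, pts, c(3, 3), vtot = v,
                  direction = if (is.na(v)) "unknown" else "s2e",
                  source = if (is.na(v)) "unset" else "measured")
  }
  ## chain with two adjacent unknowns in the middle and open chain ends:
  ## the end nodes give no equations, the middle node has two unknowns
  g <- vesselGraph(nodes, list(mkseg(1L, 1L, 2L, NA_real_),
                               mkseg(2L, 2L, 3L, NA_real_),
                               mkseg(3L, 3L, 4L, NA_real_)))
  out <- recoverMissingVelocities(g)
  expect_true(all(is.na(segmentTable(out)$vtot)))
})

test_that("recovery never touches measured segments and is idempotent", {
  net <- groundTruthNetwork(seed = 2,
                            spec = networkSpec(levels = 4L,
                                               domain = c(300, 400, 400),
                                               seed = 2))
  bl <- blankMostOrthogonal(net$graph, 0.08)
  rec <- recoverMissingVelocities(bl$graph)
  stM <- segmentTable(bl$graph)
  stR <- segmentTable(rec)
  keep <- !is.na(stM$vtot)
  expect_identical(stR$vtot[keep], stM$vtot[keep])
  expect_identical(stR$direction[keep], stM$direction[keep])
  rec2 <- recoverMissingVelocities(rec)
  expect_identical(segmentTable(rec2), segmentTable(rec))
})

test_that("recovered speeds and directions match the hidden ground truth", {
  net <- groundTruthNetwork(seed = 3,
                            spec = networkSpec(levels = 5L,
                                               domain = c(400, 600, 600),
                                               seed = 3))
  truth <- segmentTable(net$graph)
  bl <- blankMostOrthogonal(net$graph, 0.08)
  rec <- recoverMissingVelocities(bl$graph)
  st <- segmentTable(rec)
  r <- bl$blanked
  relErr <- abs(st$vtot[r] - truth$vtot[r]) / pmax(truth$vtot[r], 1e-9)
  expect_lt(median(relErr, na.rm = TRUE), 1e-9)
  expect_gt(mean(st$direction[r] == truth$direction[r]), 0.95)
})
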