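test_that("a solid cylinder thins to a single chain with two endpoints", {
  g <- cylinderGraph(5, length = 60, centerXY = c(32, 32))
  grid <- voxelGrid(c(40, 32, 32), 2)
  ras <- rasterizeNetwork(g, grid = grid)
  sk <- skeletonize(ras$mask)
  expect_equal(length(sk@chains), 1L)
  expect_equal(nrow(sk@junctions), 0L)
  expect_equal(nrow(sk@endpoints), 2L)
})

test_that("a rasterized Y-tree keeps one junction and three endpoints", {
  g <- yTreeGraph(radius = 5)
  grid <- voxelGrid(c(64, 64, 64), 2)
  ras <- rasterizeNetwork(g, grid = grid)
  sk <- skeletonize(ras$mask)
  bg <- buildGraph(sk)
  expect_equal(nSegments(bg), 3L)
  expect_equal(nNodes(bg), 4L)
  st <- segmentTable(bg)
  deg <- table(c(st$start, st$end))
  expect_equal(sort(as.integer(deg)), c(1L, 1L, 1L, 3L))
})

test_that("spherical blobs collapse to at most one chain", {
  m <- array(FALSE, c(24, 24, 24))
  ctr <- c(12, 12, 12)
  for (i in 1:24) for (j in 1:24) for (k in 1:24)
    if (sum((c(i, j, k) - ctr)^2) <= 64) m[i, j, k] <- TRUE
  mask <- new("SegmentationMask", values = m,
              grid = voxelGrid(c(24, 24, 24), 1),
              provenance = "synthetic")
  sk <- skeletonize(mask, pruneStrength = 3)
  expect_lte(length(sk@chains), 1L)
})

test_that("graph geometry: lengths, tortuosity and node degrees", {
  ## straight chain of 100 um
  g <- cylinderGraph(4, length = 100, centerXY = c(24, 24))
  st <- segmentTable(g)
  expect_equal(st$length, 100)
  expect_equal(st$tortuosity, 1)
  ## semicircular arc has tortuosity pi/2
  th <- seq(0, pi, length.out = 41)
  pts <- cbind(20 + 10 * sin(th), 30 + 10 * cos(th), 20)
  nodes <- data.frame(id = 1:2, z = pts[c(1, 41), 1],
                      x = pts[c(1, 41), 2], y = pts[c(1, 41), 3])
  arc <- vesselSegment(1L, 1L, 2L, pts, rep(2, 41))
  expect_equal(arc$tortuosity, pi / 2, tolerance = 1e-3)
  ## reconstructed graphs: endpoints have degree 1, junctions >= 3
  gy <- yTreeGraph(5)
  ras <- rasterizeNetwork(gy, grid = voxelGrid(c(64, 64, 64), 2))
  bg <- buildGraph(skeletonize(ras$mask))
  st <- segmentTable(bg)
  deg <- table(c(st$start, st$end))
  expect_true(all(deg == 1L | deg >= 3L))
})

test_that("tree topology round-trips through rasterization and thinning", {
  ## trees with clearly separated branches (> 4 voxel clearance)
  done <- 0; seed <- 0
  while (done < 3 && seed < 20) {
    seed <- seed + 1
    sp <- networkSpec(kind = "cortical", domain = c(300, 300, 300),
                      nArteries = 1L, nVeins = 0L, levels = 2L,
                      arteryRootRadius = 6, seed = seed)
    g <- generateNetwork(sp)
    if (interBranchClearance(g, voxel = 2) <= 4) next
    done <- done + 1
    ras <- rasterizeNetwork(g, grid = voxelGrid(c(150, 150, 150), 2))
    bg <- buildGraph(skeletonize(ras$mask))
    expect_equal(nNodes(bg), nNodes(g))
    expect_equal(nSegments(bg), nSegments(g))
    ## segment lengths within 10% (matched by sorted order)
    expect_equal(sort(segmentTable(bg)$length),
                 sort(segmentTable(g)$length), tolerance = 0.1)
  }
  expect_gte(done, 3)
})

test_that("diameters are recovered from cross-section profiles", {
  ## cylinder of known diameter rasterized at 1 um, profile fit FWHM
  g <- cylinderGraph(4, length = 40, centerXY = c(30, 30))
  grid <- voxelGrid(c(50, 60, 60), 1)
  ras <- rasterizeNetwork(g, grid = grid)
  angio <- new("AngiogramVolume", values = ras$mask@values * 1.0,
               grid = grid)
  ## provisional radius off by 30% to make the fit do the work
  g@segments[[1]]$radii <- rep(5.2, length(g@segments[[1]]$radii))
  g2 <- fitDiameters(g, angio)
  expect_equal(segmentTable(g2)$meanDiameter, 8, tolerance = 0.12)
  expect_false("diameter-fallback" %in% g2@segments[[1]]$flags)
})

test_that("pure-noise profiles are rejected and flagged as fallback", {
  g <- cylinderGraph(4, length = 30, centerXY = c(20, 20))
  grid <- voxelGrid(c(40, 40, 40), 1)
  set.seed(2)
  angio <- new("AngiogramVolume",
               values = array(runif(40^3), c(40, 40, 40)), grid = grid)
  g2 <- fitDiameters(g, angio)
  expect_true("diameter-fallback" %in% g2@segments[[1]]$flags)
})

test_that("a Gaussian cross-section gives the analytic FWHM diameter", {
  ## profile sigma 1.699 um -> FWHM 4.0 um
  grid <- voxelGrid(c(30, 40, 40), 1)
  vals <- array(0, c(30, 40, 40))
  for (x in 1:40) for (y in 1:40)
    vals[, x, y] <- exp(-((x - 20)^2 + (y - 20)^2) / (2 * 1.699^2))
  angio <- new("AngiogramVolume", values = vals, grid = grid)
  g <- cylinderGraph(2, length = 20, centerXY = c(19, 19))
  g2 <- fitDiameters(g, angio)
  expect_equal(segmentTable(g2)$meanDiameter, 4.0, tolerance = 0.05)
})
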