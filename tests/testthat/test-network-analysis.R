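## three-segment chain with diameters 20, 14, 10 um
chainGraph <- function(diams = c(20, 14, 10), vts = NULL) {
  n <- length(diams) + 1L
  nodes <- data.frame(id = seq_len(n), z = 10, x = seq_len(n) * 50, y = 10)
  segs <- lapply(seq_along(diams), function(k) {
    pts <- rbind(as.numeric(nodes[k, 2:4]), as.numeric(nodes[k + 1, 2:4]))
    vesselSegment(k, k, k + 1L, pts, rep(diams[k] / 2, 2),
                  vtot = if (is.null(vts)) NA_real_ else vts[k])
  })
  vesselGraph(nodes, segs)
}

test_that("labels propagate from seeds and halt at pre-capillaries", {
  g <- chainGraph(c(20, 14, 10))
  g <- propagateVesselLabels(g, arterySeeds = 1L)
  expect_equal(segmentTable(g)$label, c("artery", "artery", "capillary"))
})

test_that("without seeds everything becomes capillary, with a warning", {
  g <- chainGraph()
  expect_warning(g <- propagateVesselLabels(g), "seeds")
  expect_true(all(segmentTable(g)$label == "capillary"))
})

test_that("conflicting labels meeting at a node stay capillary", {
  g <- chainGraph(c(20, 16, 20))
  expect_warning(g <- propagateVesselLabels(g, arterySeeds = 1L,
                                            veinSeeds = 3L),
                 "meet")
  expect_equal(segmentTable(g)$label, c("artery", "capillary", "vein"))
})

test_that("propagated labels match the generator's ground truth", {
  g <- generateNetwork(networkSpec(levels = 5L, domain = c(400, 600, 600),
                                   seed = 17))
  truth <- segmentTable(g)$label
  g2 <- g
  for (k in seq_along(g2@segments)) g2@segments[[k]]$label <- "unlabeled"
  seeds <- g@metadata$pialSegments
  sp <- g@metadata$spec
  g2 <- propagateVesselLabels(g2, seeds[seq_len(sp@nArteries)],
                              seeds[-seq_len(sp@nArteries)])
  got <- segmentTable(g2)$label
  nonCap <- truth != "capillary"
  expect_gte(mean(got[nonCap] == truth[nonCap]), 0.95)
})

test_that("branching orders count segment hops to each pial tree", {
  g <- chainGraph(c(20, 10, 10, 10, 20))
  g <- propagateVesselLabels(g, arterySeeds = 1L, veinSeeds = 5L)
  bo <- computeBranchingOrders(g)
  expect_equal(bo$arterialOrder, c(0, 1, 2, 3, 4))
  expect_equal(bo$venousOrder, c(4, 3, 2, 1, 0))
  ## middle capillary: orders (2, 2)
  expect_equal(bo$arterialOrder[3], 2)
  expect_equal(bo$venousOrder[3], 2)
})

test_that("adjacent segments' branching orders differ by at most one", {
  g <- generateNetwork(networkSpec(levels = 4L, domain = c(300, 500, 500),
                                   seed = 23))
  bo <- computeBranchingOrders(g)
  adj <- segmentAdjacency(g)
  el <- igraph::as_edgelist(adj)
  dA <- abs(bo$arterialOrder[el[, 1]] - bo$arterialOrder[el[, 2]])
  expect_true(all(dA <= 1, na.rm = TRUE))
})

test_that("a single arteriovenous path reproduces its own profile", {
  g <- chainGraph(c(20, 10, 10, 10, 20), vts = c(10, 5, 2, 6, 8))
  g <- propagateVesselLabels(g, arterySeeds = 1L, veinSeeds = 5L)
  pp <- arteriovenousPathProfiles(g)
  expect_equal(pp@nPaths, 3L)      # one per capillary segment, same path
  expect_equal(pp@median[1], 10)   # arterial end
  expect_equal(pp@median[21], 8)   # venous end
  ## interpolation through the capillary values
  expect_equal(pp@median[11], 2, tolerance = 0.6)
  expect_true(all(pp@mad == 0))    # identical paths: no dispersion
})

test_that("paths with fewer than three capillary segments are rejected", {
  g <- chainGraph(c(20, 10, 10, 20), vts = c(10, 5, 5, 8))
  g <- propagateVesselLabels(g, arterySeeds = 1L, veinSeeds = 4L)
  expect_warning(pp <- arteriovenousPathProfiles(g), "no qualifying")
  expect_equal(pp@nPaths, 0L)
})

test_that("profile medians ignore path enumeration order", {
  g <- generateNetwork(networkSpec(levels = 4L, domain = c(300, 500, 500),
                                   seed = 29))
  sp <- g@metadata$spec
  fs <- solveNetworkFlow(g, sp)
  g <- setSegmentVelocitiesFromFlow(g, fs)
  p1 <- arteriovenousPathProfiles(g)
  gRev <- g
  gRev@segments <- rev(gRev@segments)
  p2 <- arteriovenousPathProfiles(gRev)
  expect_equal(p1@median, p2@median, tolerance = 1e-9)
})

test_that("multi-network histograms carry mean heights and standard errors", {
  gs <- lapply(c(31, 32, 33), function(sd) {
    g <- generateNetwork(networkSpec(levels = 4L,
                                     domain = c(300, 500, 500), seed = sd))
    sp <- g@metadata$spec
    setSegmentVelocitiesFromFlow(g, solveNetworkFlow(g, sp))
  })
  pp <- arteriovenousPathProfiles(gs)
  expect_gt(pp@nPaths, 0)
  expect_true(all(pp@lengthHistogram$se >= 0))
  expect_equal(sum(pp@lengthHistogram$mean) * 3, length(pp@pathLengths),
               tolerance = 1e-9)
})

test_that("node degree over a growing axial window matches hand counts", {
  g <- yTreeGraph(5)        # junction at z = 60, leaves at 110
  full <- nodeDegreeVsAxialFov(g, 150)
  expect_equal(full$meanDegree, 1.5)   # degrees 1,3,1,1
  cut <- nodeDegreeVsAxialFov(g, 30)   # window above the junction
  expect_equal(cut$meanDegree, 1.0)    # chain fragment: all endpoints
  ## window beyond the graph extent returns the full value
  expect_equal(nodeDegreeVsAxialFov(g, 1e5)$meanDegree, 1.5)
})

test_that("the node-degree curve survives serialization round-trips", {
  g <- generateNetwork(networkSpec(levels = 4L, domain = c(300, 500, 500),
                                   seed = 37))
  depths <- seq(50, 300, length.out = 6)
  c1 <- nodeDegreeVsAxialFov(g, depths)
  path <- tempfile(fileext = ".json")
  writeVesselGraph(g, path)
  g2 <- readVesselGraph(path)
  c2 <- nodeDegreeVsAxialFov(g2, depths)
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("network summaries partition volume across classes", {
  g <- chainGraph(c(20, 20), vts = c(5, 5))
  g@segments[[1]]$label <- "artery"
  g@segments[[2]]$label <- "vein"
  sm <- networkSummaries(g)
  expect_equal(sort(sm$classVolumes$fraction), c(0.5, 0.5))
  expect_equal(sum(sm$classVolumes$fraction), 1, tolerance = 1e-9)
  expect_equal(sm$unsetFraction, 0)
  ## velocity-volume table computed within each class
  expect_true(all(sm$velocityVolume$relativeVolume <= 1 + 1e-12))
  g2 <- generateNetwork(networkSpec(levels = 3L,
                                    domain = c(300, 400, 400), seed = 41))
  sm2 <- networkSummaries(g2)
  expect_equal(sum(sm2$classVolumes$fraction), 1, tolerance = 1e-9)
  expect_equal(sm2$unsetFraction, 1)   # no velocities assigned yet
})

test_that("ex vivo node/edge tables load with their nodes preserved", {
  nodesCsv <- tempfile(fileext = ".csv")
  edgesCsv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1:4, z = c(0, 50, 100, 100),
                       x = c(0, 0, 40, -40), y = 0), nodesCsv,
            row.names = FALSE)
  write.csv(data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                       radius = c(5, 3, 3)), edgesCsv, row.names = FALSE)
  g <- readExVivoGraph(nodesCsv, edgesCsv)
  expect_equal(nNodes(g), 4L)
  expect_equal(nSegments(g), 3L)
  nd <- nodeDegreeVsAxialFov(g, 200)
  expect_equal(nd$meanDegree, 1.5)
})
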