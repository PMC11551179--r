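#' Generate a synthetic vascular network
#'
#' Builds a ground-truth [VesselGraph-class] from a [NetworkSpec-class].
#' The `cortical` kind grows one L-shaped root vessel per pial artery/vein
#' (a horizontal stretch inside the surface band followed by a diving or
#' ascending limb), attaches a recursive bifurcating tree with Murray-law
#' radii below each root, and joins arterial to venous terminals through
#' jittered capillary chains so that every capillary lies on an
#' artery-to-vein path.  The `tube-phantom` kind returns a single straight
#' cylinder at the configured inclination.
#'
#' Segment class labels are assigned from the generated geometry: tree
#' segments with mean diameter of at least 12 um carry their tree's class
#' (`artery`/`vein`), thinner tree branches and all connecting chains are
#' `capillary`.
#'
#' @param spec a [NetworkSpec-class].
#' @return A [VesselGraph-class] with metadata fields `inletNodes`,
#'   `outletNodes`, `pialSegments` (root segment ids per class) and `spec`.
#' @examples
#' g <- generateNetwork(networkSpec(levels = 2L, seed = 7))
#' nSegments(g)
#' @export
generateNetwork <- function(spec) {
  validObject(spec)
  if (spec@kind == "tube-phantom") return(.generateTube(spec))
  withSeed(spec@seed, .generateCortical(spec))
}

.generateTube <- function(spec) {
  th <- spec@tubeAngle * pi / 180
  d <- spec@domain
  len <- 0.9 * d[2] / cos(th)
  if (len * sin(th) > 0.9 * d[1])
    len <- 0.9 * d[1] / max(sin(th), 1e-9)
  dir <- c(sin(th), cos(th), 0)            # (z, x, y)
  mid <- d / 2
  p0 <- mid - dir * len / 2
  p1 <- mid + dir * len / 2
  pts <- resamplePolyline(rbind(p0, p1), 5)
  r <- rep(spec@tubeDiameter / 2, nrow(pts))
  nodes <- data.frame(id = 1:2,
                      z = c(p0[1], p1[1]), x = c(p0[2], p1[2]),
                      y = c(p0[3], p1[3]))
  seg <- vesselSegment(1L, 1L, 2L, pts, r, label = "unlabeled")
  vesselGraph(nodes, list(seg),
              metadata = list(inletNodes = 1L, outletNodes = 2L,
                              pialSegments = integer(), spec = spec))
}

.generateCortical <- function(spec) {
  d <- spec@domain
  margin <- 8
  nTerm <- (spec@nArteries + spec@nVeins) * 2^spec@levels
  if (nTerm * 20^2 > 1.2 * d[2] * d[3])
    stop("network spec too dense: ", nTerm, " terminals will not fit a ",
         d[2], " x ", d[3], " um surface; reduce levels or root counts")

  env <- new.env()
  env$nodes <- list(); env$segs <- list()
  env$nid <- 0L; env$sid <- 0L
  addNode <- function(pos) {
    env$nid <- env$nid + 1L
    env$nodes[[env$nid]] <- pos
    env$nid
  }
  addSeg <- function(a, b, pts, radii, label) {
    env$sid <- env$sid + 1L
    env$segs[[env$sid]] <- vesselSegment(env$sid, a, b, pts, radii,
                                         label = label)
    env$sid
  }
  clamp <- function(p) pmin(pmax(p, margin), d - margin)
  shrink <- 2^(-1 / spec@murrayExponent)

  growTree <- function(rootPos, inward, rootR, class) {
    ## L-shaped root: pial stretch in the surface band, then a diving limb
    pialZ <- margin
    reach <- 0.22 * min(d[2], d[3])
    bendXY <- clamp(c(pialZ, rootPos[2] + inward[1] * reach,
                      rootPos[3] + inward[2] * reach))
    diveZ <- 0.35 * d[1] + runif(1, -0.05, 0.05) * d[1]
    bottom <- clamp(c(diveZ, bendXY[2], bendXY[3]))
    pts <- rbind(c(pialZ, rootPos[2], rootPos[3]), bendXY, bottom)
    pts <- resamplePolyline(pts, 8)
    n0 <- addNode(pts[1L, ]); n1 <- addNode(pts[nrow(pts), ])
    rr <- seq(rootR, rootR * 0.95, length.out = nrow(pts))
    rootSeg <- addSeg(n0, n1, pts, rr, class)
    terminals <- list()
    recurse <- function(node, pos, dir, r, level) {
      if (level >= spec@levels) {
        terminals[[length(terminals) + 1L]] <<- list(node = node, pos = pos,
                                                     radius = r)
        return(invisible())
      }
      rChild <- r * shrink
      ## split plane: random perpendicular to the current direction
      pvec <- c(-dir[2], dir[1], 0) + runif(3, -0.3, 0.3)
      pvec <- pvec - dir * sum(pvec * dir)
      pvec <- pvec / max(sqrt(sum(pvec^2)), 1e-9)
      for (sgn in c(-1, 1)) {
        ang <- (35 + runif(1, -8, 8)) * pi / 180
        cd <- cos(ang) * dir + sin(ang) * sgn * pvec
        cd[1] <- abs(cd[1]) * 0.6 + 0.25        # keep descending into depth
        cd <- cd / sqrt(sum(cd^2))
        len <- min(max(10 * rChild, 25), 70)
        to <- clamp(pos + cd * len)
        pts <- resamplePolyline(rbind(pos, to), 8)
        rr <- seq(rChild, rChild * 0.92, length.out = nrow(pts))
        nTo <- addNode(pts[nrow(pts), ])
        label <- if (2 * mean(rr) >= 12) class else "capillary"
        addSeg(node, nTo, pts, rr, label)
        recurse(nTo, pts[nrow(pts), ], cd, rChild, level + 1L)
      }
    }
    recurse(n1, pts[nrow(pts), ], c(1, 0, 0), rootR, 0L)
    list(rootNode = n0, rootSeg = rootSeg, terminals = terminals)
  }

  ## pial roots: arteries along one lateral edge, veins along the other
  rootsA <- list(); rootsV <- list()
  for (i in seq_len(spec@nArteries)) {
    y <- d[3] * i / (spec@nArteries + 1)
    rootsA[[i]] <- growTree(c(margin, margin, y), c(1, 0),
                            spec@arteryRootRadius, "artery")
  }
  for (i in seq_len(spec@nVeins)) {
    y <- d[3] * i / (spec@nVeins + 1)
    rootsV[[i]] <- growTree(c(margin, d[2] - margin, y), c(-1, 0),
                            spec@veinRootRadius, "vein")
  }
  aTerms <- do.call(c, lapply(rootsA, `[[`, "terminals"))
  vTerms <- do.call(c, lapply(rootsV, `[[`, "terminals"))
  if (!length(vTerms) && spec@nVeins > 0L)
    stop("no venous terminals generated")

  capillaryChain <- function(aT, vT) {
    k <- max(1L, spec@capillaryChainLength)
    base <- rbind(aT$pos, vT$pos)
    way <- resamplePolyline(base, sqrt(sum((vT$pos - aT$pos)^2)) / k)
    way <- way[round(seq(1, nrow(way), length.out = k + 1L)), , drop = FALSE]
    prevNode <- aT$node; prevPos <- aT$pos
    for (j in seq_len(k)) {
      to <- way[j + 1L, ]
      if (j < k) to <- clamp(to + c(runif(1, -12, 12), runif(1, -12, 12),
                                    runif(1, -12, 12)))
      midp <- clamp((prevPos + to) / 2 +
                    c(runif(1, -8, 8), runif(1, -8, 8), runif(1, -8, 8)))
      pts <- resamplePolyline(rbind(prevPos, midp, to), 6)
      node <- if (j == k) vT$node else addNode(to)
      pts[nrow(pts), ] <- if (j == k) vT$pos else to
      addSeg(prevNode, node, pts, rep(spec@capillaryRadius, nrow(pts)),
             "capillary")
      prevNode <- node; prevPos <- pts[nrow(pts), ]
    }
  }

  if (length(vTerms)) {
    vPos <- t(vapply(vTerms, function(t) t$pos, numeric(3)))
    vUsed <- logical(length(vTerms))
    for (aT in aTerms) {
      dd <- sqrt(colSums((t(vPos) - aT$pos)^2))
      pick <- order(dd)[seq_len(min(spec@capillariesPerTerminal,
                                    length(vTerms)))]
      for (p in pick) { capillaryChain(aT, vTerms[[p]]); vUsed[p] <- TRUE }
    }
    ## connect leftover venous terminals so no leaf is flowless
    if (length(aTerms)) {
      aPos <- t(vapply(aTerms, function(t) t$pos, numeric(3)))
      for (p in which(!vUsed)) {
        dd <- sqrt(colSums((t(aPos) - vTerms[[p]]$pos)^2))
        capillaryChain(aTerms[[which.min(dd)]], vTerms[[p]])
      }
    }
  }

  ## guarantee one connected component: bridge any separated
  ## artery/vein territory with an extra capillary connection between the
  ## closest arterial/venous terminal pair across components
  if (length(aTerms) && length(vTerms)) {
    repeat {
      el <- t(vapply(env$segs, function(s) c(s$start, s$end), integer(2)))
      ig <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                        directed = FALSE)
      comp <- igraph::components(ig)$membership
      if (max(comp) == 1L) break
      compOf <- function(node) unname(comp[as.character(node)])
      best <- NULL; bestD <- Inf
      for (aT in aTerms) for (vT in vTerms) {
        if (compOf(aT$node) == compOf(vT$node)) next
        dd <- sqrt(sum((aT$pos - vT$pos)^2))
        if (dd < bestD) { bestD <- dd; best <- list(aT, vT) }
      }
      if (is.null(best)) break
      capillaryChain(best[[1L]], best[[2L]])
    }
  }

  pos <- do.call(rbind, env$nodes)
  nodes <- data.frame(id = seq_len(env$nid), z = pos[, 1], x = pos[, 2],
                      y = pos[, 3])
  g <- vesselGraph(nodes, env$segs,
    metadata = list(
      inletNodes = vapply(rootsA, `[[`, integer(1), "rootNode"),
      outletNodes = vapply(rootsV, `[[`, integer(1), "rootNode"),
      pialSegments = c(vapply(rootsA, `[[`, integer(1), "rootSeg"),
                       vapply(rootsV, `[[`, integer(1), "rootSeg")),
      spec = spec))
  validObject(g)
  g
}

#' Minimum clearance between non-adjacent branches
#'
#' Minimum over all segment pairs that do not share a node of the
#' surface-to-surface distance (closest polyline point distance minus
#' both local radii).  Skeleton-based graph reconstruction recovers the
#' generator's topology exactly only when branches are clearly separated
#' on the voxel grid; this clearance, expressed in voxels, is the
#' condition to check.
#'
#' @param graph a [VesselGraph-class].
#' @param voxel voxel size (um) to express the clearance in voxel units.
#' @return Numeric scalar (voxels); `Inf` for graphs with < 2 segments.
#' @export
interBranchClearance <- function(graph, voxel = 1) {
  segs <- graph@segments
  n <- length(segs)
  if (n < 2L) return(Inf)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    si <- segs[[i]]
    for (j in (i + 1L):n) {
      sj <- segs[[j]]
      if (length(intersect(c(si$start, si$end), c(sj$start, sj$end))))
        next
      pi_ <- si$points; pj <- sj$points
      for (k in seq_len(nrow(pi_))) {
        d <- sqrt(colSums((t(pj) - pi_[k, ])^2)) - si$radii[k] - sj$radii
        best <- min(best, min(d))
      }
    }
  }
  best / voxel
}
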