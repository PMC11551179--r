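#' Build a vessel graph from a skeleton
#'
#' Nodes are assigned to all skeleton bifurcation and endpoint voxels
#' (adjacent junction voxels collapse into one node at their centroid);
#' the remaining skeleton chains become segments with polylines in
#' physical micrometres, arc length, tortuosity (arc length over chord)
#' and a provisional radius profile from the distance transform.  One
#' connected node of each segment is arbitrarily assigned to be the start.
#'
#' Inside thick junction regions the thinning can split one bifurcation
#' into a small cluster of nearby junctions linked by very short chains
#' (the bulge artifact); chains between two junctions shorter than
#' `pruneStrength` times the local radius are therefore contracted, their
#' end nodes merged at the centroid.
#'
#' @param skeleton a [Skeleton-class].
#' @param pruneStrength junction-chain contraction threshold, in
#'   multiples of the local radius.
#' @return A [VesselGraph-class].
#' @export
buildGraph <- function(skeleton, pruneStrength = 3) {
  grid <- skeleton@grid
  dims <- grid@dim
  chains <- skeleton@chains
  if (!length(chains)) stop("skeleton has no chains")
  lin <- function(p) p[, 1] + dims[1] * ((p[, 2] - 1) + dims[2] * (p[, 3] - 1))

  ## cluster labels for junction voxels; endpoints get their own nodes
  juncLin <- if (nrow(skeleton@junctions)) lin(skeleton@junctions) else
             integer(0)
  juncMask <- array(FALSE, dims); juncMask[juncLin] <- TRUE
  clab <- array(.cc26(as.vector(juncMask), dims), dims)
  nJunc <- max(clab)

  nodePos <- list(); nodeKey <- new.env(parent = emptyenv())
  addNodeFor <- function(p) {
    l <- lin(rbind(p))
    key <- if (juncMask[l]) paste0("j", clab[l]) else paste0("e", l)
    id <- nodeKey[[key]]
    if (!is.null(id)) return(id)
    pos <- if (juncMask[l]) {
      members <- which(clab == clab[l])
      colMeans(voxelToWorld(grid, arrayInd(members, dims)))
    } else {
      as.numeric(voxelToWorld(grid, rbind(p)))
    }
    id <- length(nodePos) + 1L
    nodePos[[id]] <<- pos
    nodeKey[[key]] <- id
    id
  }

  segs <- list()
  for (cc in chains) {
    pts <- cc$points
    a <- addNodeFor(pts[1L, ])
    b <- addNodeFor(pts[nrow(pts), ])
    w <- voxelToWorld(grid, pts)
    ## snap polyline ends onto the (possibly clustered) node positions
    w[1L, ] <- nodePos[[a]]
    w[nrow(w), ] <- nodePos[[b]]
    radii <- pmax(cc$radii, min(grid@spacing) / 2)
    segs[[length(segs) + 1L]] <-
      vesselSegment(length(segs) + 1L, a, b, w, radii)
  }
  pos <- do.call(rbind, nodePos)
  nodes <- data.frame(id = seq_along(nodePos), z = pos[, 1], x = pos[, 2],
                      y = pos[, 3])
  res <- .contractJunctionChains(nodes, segs, pruneStrength)
  g <- vesselGraph(res$nodes, res$segs, metadata = list(grid = grid))
  validObject(g)
  g
}

## Merge junction pairs linked by chains shorter than
## pruneStrength x local radius (split-bifurcation artifact of thinning
## in thick junction regions).
.contractJunctionChains <- function(nodes, segs, pruneStrength) {
  repeat {
    deg <- table(c(vapply(segs, `[[`, integer(1), "start"),
                   vapply(segs, `[[`, integer(1), "end")))
    victim <- 0L
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (s$start == s$end) next
      if (s$length >= pruneStrength * mean(s$radii)) next
      if (deg[as.character(s$start)] >= 3L &&
          deg[as.character(s$end)] >= 3L) { victim <- k; break }
    }
    if (!victim) break
    s <- segs[[victim]]
    a <- s$start; b <- s$end
    ia <- match(a, nodes$id); ib <- match(b, nodes$id)
    newPos <- colMeans(as.matrix(nodes[c(ia, ib), c("z", "x", "y")]))
    nodes[ia, c("z", "x", "y")] <- as.list(newPos)
    nodes <- nodes[-ib, , drop = FALSE]
    segs <- segs[-victim]
    segs <- lapply(segs, function(t) {
      ch <- FALSE
      if (t$start %in% c(a, b)) { t$start <- a; t$points[1L, ] <- newPos
                                  ch <- TRUE }
      if (t$end %in% c(a, b)) { t$end <- a
                                t$points[nrow(t$points), ] <- newPos
                                ch <- TRUE }
      if (ch) vesselSegment(t$id, t$start, t$end, t$points, t$radii,
                            label = t$label, vtot = t$vtot, vz = t$vz,
                            direction = t$direction, source = t$source)
      else t
    })
    ## drop artifact self-loops created by the merge: a loop inside a
    ## junction bulge has circumference of at most ~2 pi r
    segs <- Filter(function(t) !(t$start == t$end &&
                                 t$length < 2 * pi * pruneStrength / 3 *
                                            max(t$radii)), segs)
  }
  ## renumber segment ids to stay contiguous
  for (k in seq_along(segs)) segs[[k]]$id <- k
  list(nodes = nodes, segs = segs)
}
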