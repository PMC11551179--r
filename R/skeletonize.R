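#' Skeletonize a binary vessel mask
#'
#' 3-d homotopic thinning to a one-voxel-thick curve skeleton: foreground
#' voxels are visited in increasing distance-transform order and deleted
#' while they are topologically simple and not chain endpoints, so the
#' object's connectivity is preserved and centerlines survive.  Terminal
#' spurs shorter than `pruneStrength` times the local vessel radius (the
#' bulge-size analogue, default 3) are then pruned, re-thinning until
#' stable.  Deterministic given the mask.
#'
#' @param mask a [SegmentationMask-class].
#' @param pruneStrength spur-pruning strength; a terminal branch is
#'   removed if its length is below `pruneStrength` x local radius.
#' @return A [Skeleton-class]; chain radii come from the Euclidean
#'   distance transform (in um).
#' @export
skeletonize <- function(mask, pruneStrength = 3) {
  m <- mask@values
  if (!any(m)) stop("mask is empty")
  dims <- dim(m)
  sp <- mask@grid@spacing
  edt <- array(.edt3d(as.vector(m), dims, sp), dims)
  sk <- array(.thin3d(as.vector(m), dims, as.vector(edt)), dims)
  repeat {
    ch <- .traceChains(sk, edt, mask@grid)
    drop <- vapply(ch$chains, function(cc) {
      cc$kind %in% c("spur", "isolated") &&
        cc$lengthUm < pruneStrength * cc$rootRadiusUm
    }, logical(1))
    if (!any(drop)) break
    for (cc in ch$chains[drop]) {
      rows <- seq_len(nrow(cc$points))
      if (cc$kind == "spur") rows <- rows[-cc$anchorRow]
      sk[cc$points[rows, , drop = FALSE]] <- FALSE
    }
    sk <- array(.thin3d(as.vector(sk), dims, as.vector(edt)), dims)
  }
  ch <- .traceChains(sk, edt, mask@grid)
  new("Skeleton", chains = ch$chains, junctions = ch$junctions,
      endpoints = ch$endpoints, skeletonMask = sk, grid = mask@grid)
}

## Decompose a skeleton mask into ordered voxel chains between node
## voxels (junction voxels have >= 3 skeleton neighbours, endpoints
## <= 1).  Adjacent junction voxels are clustered; chains between voxels
## of the same cluster are dropped.  Each chain records voxel coordinates,
## EDT radii (um), its physical length, and a terminal classification:
## "chain" (junction to junction), "spur" (junction to endpoint) or
## "isolated" (endpoint to endpoint).
.traceChains <- function(sk, edt, grid) {
  dims <- dim(sk)
  sp <- grid@spacing
  empty <- list(chains = list(), junctions = matrix(0L, 0, 3),
                endpoints = matrix(0L, 0, 3),
                junctionLabels = array(0L, dims))
  vox <- which(sk)
  if (!length(vox)) return(empty)
  nb <- array(.neighborCount26(as.vector(sk), dims), dims)
  coord <- arrayInd(vox, dims)
  cnt <- nb[vox]
  isJunc <- cnt >= 3L
  isEnd <- cnt <= 1L
  lin <- function(p) p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
  nodeSet <- new.env(parent = emptyenv())
  for (v in vox[isJunc | isEnd]) nodeSet[[as.character(v)]] <- TRUE
  isNodeLin <- function(l) !is.null(nodeSet[[as.character(l)]])
  juncMask <- array(FALSE, dims); juncMask[vox[isJunc]] <- TRUE
  clab <- array(.cc26(as.vector(juncMask), dims), dims)

  off <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  fgNeighbors <- function(p) {
    cand <- sweep(off, 2L, p, "+")
    ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
          cand[, 1] <= dims[1] & cand[, 2] <= dims[2] & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    cand[sk[cand], , drop = FALSE]
  }

  usedLeg <- new.env(parent = emptyenv())
  chains <- list()
  starts <- coord[isJunc | isEnd, , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    p0 <- starts[i, ]
    l0 <- lin(p0)
    for (q in seq_len(nrow(off))) {
      p1 <- p0 + off[q, ]
      if (any(p1 < 1) || any(p1 > dims)) next
      l1 <- lin(p1)
      if (!sk[l1]) next
      if (juncMask[l0] && juncMask[l1] && clab[l0] == clab[l1]) next
      if (!is.null(usedLeg[[paste(l0, l1)]])) next
      ## walk from p0 through p1 until the next node voxel
      path <- list(p0, p1)
      prev <- p0; cur <- p1; lcur <- l1
      while (!isNodeLin(lcur)) {
        nbs <- fgNeighbors(cur)
        nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2] &
                     nbs[, 3] == prev[3]), , drop = FALSE]
        if (!nrow(nbs)) break
        if (nrow(nbs) > 1L) {
          ## a chain voxel should have one continuation; if the thinning
          ## left a diagonal shortcut, prefer a node voxel
          nd <- vapply(seq_len(nrow(nbs)),
                       function(k) isNodeLin(lin(nbs[k, ])), logical(1))
          nbs <- nbs[order(!nd), , drop = FALSE]
        }
        prev <- cur
        cur <- as.integer(nbs[1L, ])
        lcur <- lin(cur)
        path[[length(path) + 1L]] <- cur
      }
      pts <- do.call(rbind, path)
      npn <- nrow(pts)
      usedLeg[[paste(l0, l1)]] <- TRUE
      usedLeg[[paste(lin(pts[npn, ]), lin(pts[npn - 1L, ]))]] <- TRUE
      w <- sweep(pts, 2L, sp, "*")
      lengthUm <- sum(sqrt(rowSums((w[-1L, , drop = FALSE] -
                                    w[-npn, , drop = FALSE])^2)))
      pend <- pts[npn, ]
      startIsJunc <- juncMask[l0]
      endIsJunc <- juncMask[lin(pend)]
      kind <- if (startIsJunc && endIsJunc) "chain"
              else if (startIsJunc || endIsJunc) "spur"
              else "isolated"
      anchorRow <- if (startIsJunc) 1L else if (endIsJunc) npn else 1L
      chains[[length(chains) + 1L]] <- list(
        points = pts, radii = edt[pts], lengthUm = lengthUm, kind = kind,
        anchorRow = anchorRow, rootRadiusUm = edt[rbind(pts[anchorRow, ])])
    }
  }
  list(chains = chains, junctions = coord[isJunc, , drop = FALSE],
       endpoints = coord[isEnd, , drop = FALSE], junctionLabels = clab)
}
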