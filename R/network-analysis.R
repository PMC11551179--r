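#' Segment adjacency as an igraph line graph
#'
#' Two segments are adjacent when they share a node.  Used by label
#' propagation, branching orders and path profiles.
#'
#' @param graph a [VesselGraph-class].
#' @return An igraph object whose vertices are segment indices.
#' @export
segmentAdjacency <- function(graph) {
  segs <- graph@segments
  n <- length(segs)
  byNode <- list()
  for (k in seq_len(n)) {
    s <- segs[[k]]
    for (nd in c(s$start, s$end)) {
      key <- as.character(nd)
      byNode[[key]] <- c(byNode[[key]], k)
    }
  }
  edges <- integer(0)
  for (ks in byNode) {
    if (length(ks) < 2L) next
    pr <- t(combn(ks, 2L))
    edges <- c(edges, t(pr))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Propagate artery/vein labels from pial seeds
#'
#' Breadth-first propagation of the seed labels over the segment
#' adjacency, halting at pre-capillaries (median diameter below
#' `stopDiameter`, default 12 um); unreached segments become capillaries.
#' When both labels reach an unlabeled segment in the same round the
#' propagation stops there, the segment stays capillary, and the conflict
#' is logged as a warning.
#'
#' @param graph a [VesselGraph-class] with diameters.
#' @param arterySeeds,veinSeeds segment ids of the manually labeled (or
#'   ground-truth) pial vessels.
#' @param stopDiameter pre-capillary halting diameter (um).
#' @return The graph with `label` set on every segment.
#' @export
propagateVesselLabels <- function(graph, arterySeeds = integer(0),
                                  veinSeeds = integer(0),
                                  stopDiameter = 12) {
  segs <- graph@segments
  ids <- vapply(segs, `[[`, integer(1), "id")
  n <- length(segs)
  lab <- rep(NA_character_, n)
  if (!length(arterySeeds) && !length(veinSeeds)) {
    warning("no artery or vein seeds; labeling every segment capillary")
    for (k in seq_len(n)) segs[[k]]$label <- "capillary"
    graph@segments <- segs
    return(graph)
  }
  adj <- segmentAdjacency(graph)
  medDiam <- vapply(segs, `[[`, numeric(1), "medianDiameter")
  lab[match(arterySeeds, ids)] <- "artery"
  lab[match(veinSeeds, ids)] <- "vein"
  frontier <- which(!is.na(lab))
  while (length(frontier)) {
    nbrs <- adjacent_vertices_int(adj, frontier)
    claims <- list()
    for (i in seq_along(frontier)) {
      f <- frontier[i]
      for (nb in nbrs[[i]]) {
        if (!is.na(lab[nb])) next
        if (medDiam[nb] < stopDiameter) next     # pre-capillary: halt
        claims[[as.character(nb)]] <- union(claims[[as.character(nb)]],
                                            lab[f])
      }
    }
    newFront <- integer(0)
    for (key in names(claims)) {
      nb <- as.integer(key)
      cl <- claims[[key]]
      if (length(cl) > 1L) {
        warning(sprintf(
          "artery and vein labels meet at segment %d; kept capillary",
          ids[nb]))
        next
      }
      lab[nb] <- cl
      newFront <- c(newFront, nb)
    }
    frontier <- newFront
  }
  lab[is.na(lab)] <- "capillary"
  for (k in seq_len(n)) segs[[k]]$label <- lab[k]
  graph@segments <- segs
  graph
}

## igraph neighbor lists as plain integer vectors
adjacent_vertices_int <- function(g, vs) {
  lapply(igraph::adjacent_vertices(g, vs), as.integer)
}

#' Arterial and venous branching orders
#'
#' Each segment's order towards a class is the minimum number of segment
#' hops to reach any segment of that class (0 for members of the class
#' itself); unreachable classes give `NA`.
#'
#' @param graph a labeled [VesselGraph-class].
#' @return data.frame with `id`, `arterialOrder`, `venousOrder`.
#' @export
computeBranchingOrders <- function(graph) {
  segs <- graph@segments
  ids <- vapply(segs, `[[`, integer(1), "id")
  lab <- vapply(segs, `[[`, character(1), "label")
  adj <- segmentAdjacency(graph)
  orderTo <- function(class) {
    src <- which(lab == class)
    if (!length(src)) return(rep(NA_real_, length(segs)))
    d <- igraph::distances(adj, v = src)
    apply(d, 2L, min)
  }
  data.frame(id = ids,
             arterialOrder = orderTo("artery"),
             venousOrder = orderTo("vein"))
}

#' Arteriovenous path velocity profiles
#'
#' For every capillary segment the shortest (hop-count) paths to the
#' closest artery and closest vein segment are combined into one
#' artery-to-vein path; paths with fewer than `minCapillaries` capillary
#' segments are rejected (they are usually falsely allocated direct
#' artery-vein connections).  Each path's segment velocities are placed
#' at normalized cumulative hop positions on `[0, 1]` (0 = arterial end),
#' linearly interpolated onto a common grid, and summarized per grid
#' point by the median and the median absolute deviation across paths.
#' With several graphs the paths are pooled for the profile, while the
#' path-length histogram reports the mean bar height across graphs with
#' its standard error.
#'
#' @param graphs a [VesselGraph-class] or list of them.
#' @param nGrid number of grid points on `[0, 1]`.
#' @param minCapillaries minimum capillary segments per path.
#' @return A [PathProfile-class].
#' @export
arteriovenousPathProfiles <- function(graphs, nGrid = 21L,
                                      minCapillaries = 3L) {
  if (is(graphs, "VesselGraph")) graphs <- list(graphs)
  pos <- seq(0, 1, length.out = nGrid)
  curves <- list()
  lengthsBySrc <- list()
  for (g in graphs) {
    pp <- .graphPaths(g, minCapillaries)
    lengthsBySrc[[length(lengthsBySrc) + 1L]] <- pp$lengths
    for (pth in pp$paths) {
      v <- pth$vtot
      x <- pth$positions
      ok <- !is.na(v)
      if (sum(ok) < 2L) next
      curves[[length(curves) + 1L]] <-
        approx(x[ok], v[ok], xout = pos, rule = 2)$y
    }
  }
  if (!length(curves)) {
    warning("no qualifying arteriovenous paths")
    return(new("PathProfile", positions = pos,
               median = rep(NA_real_, nGrid), mad = rep(NA_real_, nGrid),
               nPaths = 0L, pathLengths = integer(0),
               lengthHistogram = data.frame(order = integer(),
                                            mean = numeric(),
                                            se = numeric())))
  }
  cm <- do.call(rbind, curves)
  med <- apply(cm, 2L, median, na.rm = TRUE)
  md <- apply(cm, 2L, mad, na.rm = TRUE, constant = 1)
  allLen <- unlist(lengthsBySrc)
  maxLen <- max(allLen)
  counts <- vapply(lengthsBySrc, function(l)
    tabulate(l, nbins = maxLen), numeric(maxLen))
  counts <- matrix(counts, nrow = maxLen)
  hist <- data.frame(order = seq_len(maxLen),
                     mean = rowMeans(counts),
                     se = apply(counts, 1L, function(r)
                       if (length(r) > 1L) sd(r) / sqrt(length(r)) else 0))
  new("PathProfile", positions = pos, median = med, mad = md,
      nPaths = length(curves), pathLengths = as.integer(allLen),
      lengthHistogram = hist)
}

.graphPaths <- function(graph, minCapillaries) {
  segs <- graph@segments
  lab <- vapply(segs, `[[`, character(1), "label")
  vtot <- vapply(segs, function(s) as.numeric(s$vtot)[1], numeric(1))
  adj <- segmentAdjacency(graph)
  caps <- which(lab == "capillary")
  arts <- which(lab == "artery")
  veins <- which(lab == "vein")
  out <- list(); lens <- integer(0)
  if (!length(caps) || !length(arts) || !length(veins))
    return(list(paths = out, lengths = lens))
  dA <- igraph::distances(adj, v = arts, to = caps)
  dV <- igraph::distances(adj, v = veins, to = caps)
  for (j in seq_along(caps)) {
    ai <- arts[which.min(dA[, j])]
    vi <- veins[which.min(dV[, j])]
    if (!is.finite(min(dA[, j])) || !is.finite(min(dV[, j]))) next
    pA <- igraph::shortest_paths(adj, from = caps[j], to = ai)$vpath[[1]]
    pV <- igraph::shortest_paths(adj, from = caps[j], to = vi)$vpath[[1]]
    path <- c(rev(as.integer(pA)), as.integer(pV)[-1L])
    if (sum(lab[path] == "capillary") < minCapillaries) next
    m <- length(path)
    out[[length(out) + 1L]] <- list(
      segments = path,
      positions = if (m > 1L) (seq_len(m) - 1) / (m - 1) else 0.5,
      vtot = vtot[path])
    lens <- c(lens, m)
  }
  list(paths = out, lengths = lens)
}

#' Mean node degree over a growing axial field of view
#'
#' For each axial window (anchored at the top/pial surface and growing
#' into depth) segments crossing the lower window boundary are cut and
#' the cut points become degree-1 endpoints; the curve reports the mean
#' degree over all retained nodes.  Narrow windows sever network
#' interconnections, so the curve grows towards the full-network value.
#'
#' @param graph a [VesselGraph-class].
#' @param depths axial window extents in um (measured from `zTop`).
#' @param zTop anchoring depth; defaults to the shallowest node.
#' @return data.frame with `depth` and `meanDegree`.
#' @export
nodeDegreeVsAxialFov <- function(graph, depths, zTop = NULL) {
  nd <- graph@nodes
  if (is.null(zTop)) zTop <- min(nd$z)
  segs <- graph@segments
  out <- data.frame(depth = depths, meanDegree = NA_real_)
  for (i in seq_along(depths)) {
    zMax <- zTop + depths[i]
    inside <- setNames(nd$z >= zTop - 1e-9 & nd$z <= zMax, nd$id)
    deg <- setNames(numeric(nrow(nd)), nd$id)
    nCut <- 0L
    for (s in segs) {
      sIn <- inside[as.character(s$start)]
      eIn <- inside[as.character(s$end)]
      if (sIn && eIn) {
        deg[as.character(s$start)] <- deg[as.character(s$start)] + 1
        deg[as.character(s$end)] <- deg[as.character(s$end)] + 1
      } else if (sIn || eIn) {
        ## boundary-crossing segment: cut, the cut point becomes a
        ## degree-1 endpoint and the inside node keeps its stub
        nCut <- nCut + 1L
        keep <- if (sIn) s$start else s$end
        deg[as.character(keep)] <- deg[as.character(keep)] + 1
      }
    }
    nNode <- sum(inside) + nCut
    out$meanDegree[i] <- if (nNode > 0)
      (sum(deg[inside]) + nCut) / nNode else NA_real_
  }
  out
}

#' Network summary tables
#'
#' Per-segment histograms of mean diameter and total velocity, per-class
#' perfused volume (`sum pi r^2 L`) and volume fractions, the
#' velocity-versus-relative-perfused-volume table computed within each
#' vessel class, and the fraction of segments without a velocity.
#'
#' @param graph a labeled [VesselGraph-class].
#' @param diameterBreaks,velocityBreaks histogram breaks (passed to
#'   [hist()]; default `"Sturges"`).
#' @return A list with `segments`, `diameterHistogram`,
#'   `velocityHistogram`, `classVolumes`, `velocityVolume` and
#'   `unsetFraction`.
#' @export
networkSummaries <- function(graph, diameterBreaks = "Sturges",
                             velocityBreaks = "Sturges") {
  st <- segmentTable(graph)
  segs <- graph@segments
  vol <- vapply(segs, function(s) {
    p <- s$points; r <- s$radii
    ds <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2))
    rm <- (r[-1L] + r[-length(r)]) / 2
    sum(pi * rm^2 * ds)
  }, numeric(1))
  st$volume <- vol
  dh <- hist(st$meanDiameter, breaks = diameterBreaks, plot = FALSE)
  vset <- st$vtot[!is.na(st$vtot)]
  vh <- if (length(vset)) hist(vset, breaks = velocityBreaks, plot = FALSE)
        else NULL
  cls <- split(seq_len(nrow(st)), st$label)
  classVolumes <- data.frame(
    label = names(cls),
    volume = vapply(cls, function(i) sum(vol[i]), numeric(1)))
  classVolumes$fraction <- classVolumes$volume / sum(classVolumes$volume)
  velocityVolume <- do.call(rbind, lapply(names(cls), function(cl) {
    i <- cls[[cl]]
    i <- i[!is.na(st$vtot[i])]
    if (!length(i)) return(NULL)
    o <- i[order(st$vtot[i])]
    data.frame(label = cl, vtot = st$vtot[o],
               relativeVolume = cumsum(vol[o]) / sum(vol[o]))
  }))
  list(segments = st,
       diameterHistogram = data.frame(mid = dh$mids, count = dh$counts),
       velocityHistogram = if (is.null(vh)) NULL else
         data.frame(mid = vh$mids, count = vh$counts),
       classVolumes = classVolumes,
       velocityVolume = velocityVolume,
       unsetFraction = unsetVelocityFraction(graph))
}

#' Read an ex vivo vascular graph from node/edge tables
#'
#' Reader for published ex vivo cortical graph datasets exported as CSV
#' node and edge tables: nodes with 3-d coordinates, edges as node-index
#' pairs with optional radius.  The dataset's own node definition is
#' preserved (no nodes are inserted or removed).
#'
#' @param nodesFile CSV with columns `id`, `z`, `x`, `y` (um).
#' @param edgesFile CSV with columns `from`, `to` and optional `radius`.
#' @return A [VesselGraph-class].
#' @export
readExVivoGraph <- function(nodesFile, edgesFile) {
  nd <- utils::read.csv(nodesFile)
  ed <- utils::read.csv(edgesFile)
  stopifnot(all(c("id", "z", "x", "y") %in% names(nd)),
            all(c("from", "to") %in% names(ed)))
  segs <- vector("list", nrow(ed))
  for (k in seq_len(nrow(ed))) {
    a <- nd[match(ed$from[k], nd$id), ]
    b <- nd[match(ed$to[k], nd$id), ]
    r <- if ("radius" %in% names(ed)) ed$radius[k] else 3
    pts <- rbind(c(a$z, a$x, a$y), c(b$z, b$x, b$y))
    segs[[k]] <- vesselSegment(k, a$id, b$id, pts, rep(r, 2L))
  }
  vesselGraph(nd[, c("id", "z", "x", "y")], segs,
              metadata = list(source = "ex-vivo"))
}
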