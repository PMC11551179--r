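#' Solve steady Poiseuille flow on a vessel graph
#'
#' Computes nodal pressures and signed segment flows by solving the linear
#' conservation system with Poiseuille segment conductances.  Each segment's
#' hydraulic resistance is integrated along its polyline,
#' `R = sum 8 eta ds / (pi r^4)`, so tapered radius profiles are honoured.
#' Dirichlet pressures are imposed at the inlet (pial artery) and outlet
#' (pial vein) nodes; at every interior node the signed flows sum to zero
#' up to solver precision.
#'
#' @param graph a [VesselGraph-class].
#' @param spec the [NetworkSpec-class] providing viscosity and boundary
#'   pressures.
#' @param inlets,outlets node ids; default taken from the graph metadata.
#' @return A [FlowState-class]; flows in um^3/s (positive = start to end),
#'   pressures in Pa, mean velocities in mm/s.
#' @examples
#' sp <- networkSpec(levels = 1L, seed = 2)
#' g <- generateNetwork(sp)
#' fs <- solveNetworkFlow(g, sp)
#' @export
solveNetworkFlow <- function(graph, spec,
                             inlets = graph@metadata$inletNodes,
                             outlets = graph@metadata$outletNodes) {
  segs <- graph@segments
  if (!length(segs)) stop("graph has no segments")
  if (!length(inlets) || !length(outlets))
    stop("need at least one inlet and one outlet node")
  ids <- graph@nodes$id
  nid <- seq_along(ids)
  names(nid) <- as.character(ids)

  ## connectivity: every component must touch a boundary node
  el <- t(vapply(segs, function(s) c(s$start, s$end), integer(2)))
  ig <- igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2), directed = FALSE)
  comp <- igraph::components(ig)
  bnd <- as.character(c(inlets, outlets))
  compWithBnd <- unique(comp$membership[bnd[bnd %in%
                                            names(comp$membership)]])
  bad <- setdiff(seq_len(comp$no), compWithBnd)
  if (length(bad)) {
    members <- names(comp$membership)[comp$membership == bad[1L]]
    stop("isolated subgraph with no boundary node; component contains nodes ",
         paste(utils::head(members, 5L), collapse = ", "),
         if (length(members) > 5L) ", ...")
  }

  ## conductance per segment (um^3 / (s Pa)): resistance integrated along
  ## the polyline with midpoint radii
  cond <- vapply(segs, function(s) {
    p <- s$points; r <- s$radii
    ds <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2))
    rm <- (r[-1L] + r[-length(r)]) / 2
    res <- sum(8 * spec@viscosity * ds / (pi * rm^4))
    1 / res
  }, numeric(1))

  n <- length(ids)
  i1 <- nid[as.character(el[, 1])]
  i2 <- nid[as.character(el[, 2])]
  L <- Matrix::sparseMatrix(
    i = c(i1, i2, i1, i2), j = c(i1, i2, i2, i1),
    x = c(cond, cond, -cond, -cond), dims = c(n, n))
  isBnd <- ids %in% c(inlets, outlets)
  pBnd <- ifelse(ids[isBnd] %in% inlets, spec@inletPressure,
                 spec@outletPressure)
  p <- numeric(n)
  p[isBnd] <- pBnd
  free <- which(!isBnd)
  if (length(free)) {
    rhs <- -L[free, isBnd, drop = FALSE] %*% pBnd
    sol <- tryCatch(
      Matrix::solve(L[free, free, drop = FALSE], rhs),
      error = function(e) stop("pressure system is singular: ",
                               conditionMessage(e)))
    p[free] <- as.numeric(sol)
  }
  Q <- cond * (p[i1] - p[i2])
  rmean <- vapply(segs, function(s) mean(s$radii), numeric(1))
  v <- Q / (pi * rmean^2) / 1000            # um/s -> mm/s
  segIds <- vapply(segs, `[[`, integer(1), "id")
  new("FlowState",
      flows = setNames(Q, segIds),
      pressures = setNames(p, ids),
      velocities = setNames(v, segIds))
}

#' Residual of mass conservation at interior nodes
#'
#' Maximum absolute net flow at interior (non-boundary) nodes, normalized
#' by the mean absolute segment flow; a solved [FlowState-class] should be
#' at machine precision.
#'
#' @param graph a [VesselGraph-class].
#' @param flow a [FlowState-class].
#' @param boundary node ids excluded from the check (defaults to the
#'   metadata inlets/outlets).
#' @return Numeric scalar.
#' @export
conservationResidual <- function(graph, flow,
                                 boundary = c(graph@metadata$inletNodes,
                                              graph@metadata$outletNodes)) {
  net <- setNames(numeric(nrow(graph@nodes)), graph@nodes$id)
  for (s in graph@segments) {
    q <- flow@flows[as.character(s$id)]
    net[as.character(s$start)] <- net[as.character(s$start)] - q
    net[as.character(s$end)] <- net[as.character(s$end)] + q
  }
  interior <- setdiff(names(net), as.character(boundary))
  if (!length(interior)) return(0)
  max(abs(net[interior])) / mean(abs(flow@flows))
}

#' Copy solved flows onto the graph's segment velocity records
#'
#' Writes each segment's ground-truth total speed, signed axial velocity
#' and flow direction from a [FlowState-class], marking them as measured.
#' Used to endow synthetic networks with reference velocities.
#'
#' @param graph a [VesselGraph-class].
#' @param flow a [FlowState-class] for the same graph.
#' @return The annotated [VesselGraph-class].
#' @export
setSegmentVelocitiesFromFlow <- function(graph, flow) {
  graph@segments <- lapply(graph@segments, function(s) {
    v <- flow@velocities[as.character(s$id)]
    tz <- segmentMeanTangentZ(s)
    s$vtot <- abs(v)
    s$vz <- v * tz
    s$direction <- if (abs(v) < 1e-12) "unknown" else
                   if (v > 0) "s2e" else "e2s"
    s$source <- "measured"
    s
  })
  graph
}

## Mean z-component of the unit tangent along a segment polyline,
## oriented start -> end, weighted by arc length.
segmentMeanTangentZ <- function(s) {
  p <- s$points
  dp <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  ds <- sqrt(rowSums(dp^2))
  keep <- ds > 0
  if (!any(keep)) return(0)
  sum(dp[keep, 1]) / sum(ds[keep])
}
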