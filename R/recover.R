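#' Recover missing segment velocities by conservation of mass
#'
#' Iterative local rule: for a segment with unknown velocity attached to a
#' node whose other segments all carry a velocity and a direction, the
#' signed flows `Q_i = v_i pi (d_i/2)^2` are summed and the unknown flow
#' is their negative (zero net flow at the node); the speed follows from
#' the unknown segment's own cross-section and the direction from the
#' flow's sign.  If both endpoints determine the segment, the two speed
#' estimates are averaged; an end node, or a node with several unknown
#' neighbours, contributes nothing.  Nodes are processed in descending
#' count of known neighbours and the pass repeats until no segment can be
#' fixed.  Measured segments are never modified; recovered segments carry
#' `source = "recovered"`, and endpoint direction conflicts keep the
#' larger-flow endpoint's direction and flag the segment.
#'
#' @param graph a [VesselGraph-class] with diameters, and velocities +
#'   directions on the known segments.
#' @return The graph with recovered velocities where determinable.
#' @export
recoverMissingVelocities <- function(graph) {
  segs <- graph@segments
  n <- length(segs)
  if (!n) return(graph)
  nodeIds <- graph@nodes$id
  incid <- setNames(vector("list", length(nodeIds)),
                    as.character(nodeIds))
  for (k in seq_len(n)) {
    s <- segs[[k]]
    incid[[as.character(s$start)]] <- c(incid[[as.character(s$start)]], k)
    incid[[as.character(s$end)]] <- c(incid[[as.character(s$end)]], k)
  }
  known <- vapply(segs, function(s)
    !is.na(s$vtot) && s$direction %in% c("s2e", "e2s"), logical(1))
  area <- vapply(segs, function(s) pi * (s$meanDiameter / 2)^2, numeric(1))

  ## signed flow of known segment k INTO node `node`
  flowInto <- function(k, node) {
    s <- segs[[k]]
    q <- s$vtot * area[k]
    into <- (s$direction == "s2e" && s$end == node) ||
            (s$direction == "e2s" && s$start == node)
    if (into) q else -q
  }

  repeat {
    unknown <- which(!known)
    if (!length(unknown)) break
    ## candidate estimates per unknown segment from each of its nodes
    fixedAny <- FALSE
    est <- lapply(unknown, function(k) {
      s <- segs[[k]]
      out <- list()
      for (node in c(s$start, s$end)) {
        others <- setdiff(incid[[as.character(node)]], k)
        if (!length(others)) next              # end node: no information
        if (!all(known[others])) next          # other unknowns meet here
        qIn <- sum(vapply(others, flowInto, numeric(1), node = node))
        ## unknown must carry -qIn into the node, i.e. qIn out of it
        v <- abs(qIn) / area[k]
        dir <- if (qIn > 0) {
          if (s$start == node) "s2e" else "e2s"   # flows away from node
        } else if (qIn < 0) {
          if (s$start == node) "e2s" else "s2e"
        } else "unknown"
        out[[length(out) + 1L]] <- list(v = v, dir = dir, q = abs(qIn))
      }
      out
    })
    nKnownNbr <- vapply(unknown, function(k) {
      s <- segs[[k]]
      sum(known[setdiff(unique(c(incid[[as.character(s$start)]],
                                 incid[[as.character(s$end)]])), k)])
    }, numeric(1))
    for (j in order(-nKnownNbr)) {
      k <- unknown[j]
      cand <- est[[j]]
      if (!length(cand)) next
      vs <- vapply(cand, `[[`, numeric(1), "v")
      dirs <- vapply(cand, function(e) e$dir, character(1))
      qs <- vapply(cand, `[[`, numeric(1), "q")
      dirs2 <- dirs[dirs != "unknown"]
      dir <- if (!length(dirs2)) "unknown"
             else if (length(unique(dirs2)) == 1L) dirs2[1L]
             else {
               segs[[k]]$flags <- union(segs[[k]]$flags,
                                        "direction-conflict")
               dirs[which.max(qs)]
             }
      segs[[k]]$vtot <- mean(vs)
      segs[[k]]$vz <- NA_real_
      segs[[k]]$direction <- dir
      segs[[k]]$source <- "recovered"
      ## a zero-flow balance gives a speed but no direction; either way
      ## the segment is now described (q = 0 contributes nothing)
      known[k] <- TRUE
      fixedAny <- TRUE
      break   # recompute balances after each fix (iterative rule)
    }
    if (!fixedAny) break
  }
  graph@segments <- segs
  graph
}

#' Direct linear conservation solve for missing flows
#'
#' Reference oracle for the iterative recovery: unknown signed segment
#' flows are solved from the full linear system of zero-net-flow
#' equations at all nodes incident to at least one unknown segment
#' (least squares via QR; exact when every unknown is uniquely
#' determined).
#'
#' @param graph a [VesselGraph-class] with measured velocities and
#'   directions on the known segments.
#' @return Named numeric vector: signed flow (positive = start to end,
#'   um^2 mm/s) per unknown segment id.
#' @export
solveMissingFlowsDirect <- function(graph) {
  segs <- graph@segments
  known <- vapply(segs, function(s)
    !is.na(s$vtot) && s$direction %in% c("s2e", "e2s"), logical(1))
  unknown <- which(!known)
  if (!length(unknown)) return(setNames(numeric(0), character(0)))
  area <- vapply(segs, function(s) pi * (s$meanDiameter / 2)^2, numeric(1))
  signedQ <- vapply(seq_along(segs), function(k) {
    s <- segs[[k]]
    if (!known[k]) return(NA_real_)
    q <- s$vtot * area[k]
    if (s$direction == "s2e") q else -q
  }, numeric(1))
  ## nodes touching an unknown; rows = equations sum_in Q = 0 with
  ## convention: +Q means flow start->end, so node balance at n:
  ## sum_{segments with end=n} Q - sum_{segments with start=n} Q = 0,
  ## skipping boundary-like nodes of degree 1
  nodeIds <- graph@nodes$id
  deg <- setNames(numeric(length(nodeIds)), nodeIds)
  for (s in segs) {
    deg[as.character(s$start)] <- deg[as.character(s$start)] + 1
    deg[as.character(s$end)] <- deg[as.character(s$end)] + 1
  }
  touched <- unique(unlist(lapply(segs[unknown],
                                  function(s) c(s$start, s$end))))
  touched <- touched[deg[as.character(touched)] >= 2]
  if (!length(touched)) return(setNames(rep(NA_real_, length(unknown)),
    vapply(segs[unknown], `[[`, integer(1), "id")))
  A <- matrix(0, length(touched), length(unknown))
  bvec <- numeric(length(touched))
  for (r in seq_along(touched)) {
    node <- touched[r]
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      sgn <- if (s$end == node) 1 else if (s$start == node) -1 else 0
      if (!sgn) next
      if (known[k]) bvec[r] <- bvec[r] - sgn * signedQ[k]
      else A[r, match(k, unknown)] <- sgn
    }
  }
  ## drop equations involving unknowns that terminate at end nodes only
  sol <- qr.solve(qr(A, LAPACK = TRUE), bvec)
  setNames(as.numeric(sol),
           vapply(segs[unknown], `[[`, integer(1), "id"))
}

#' Fraction of segments without an assigned velocity
#'
#' @param graph a [VesselGraph-class].
#' @return Fraction in `[0, 1]`.
#' @export
unsetVelocityFraction <- function(graph) {
  if (!length(graph@segments)) return(0)
  mean(vapply(graph@segments, function(s) is.na(s$vtot), logical(1)))
}
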