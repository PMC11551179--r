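#' Register a Doppler D_max volume to an angiogram
#'
#' Estimates a 3-d affine transform (returned as a 4x4 matrix mapping
#' voxel coordinates of `moving` into `fixed`) that maximizes intensity
#' similarity.  Translation is initialized by FFT phase correlation with
#' sub-voxel refinement; an optional affine refinement maximizes the
#' normalized cross-correlation.  Co-simulated volumes on one grid return
#' the identity; on optimization failure the identity is returned with a
#' warning.
#'
#' @param moving,fixed numeric 3-d arrays (e.g. D_max and angiogram).
#' @param refine run the affine refinement after phase correlation.
#' @return A 4x4 affine matrix; serialize with [saveRDS()] or as JSON.
#' @export
registerVolumes <- function(moving, fixed, refine = FALSE) {
  stopifnot(all(dim(moving) == dim(fixed)))
  d <- dim(moving)
  out <- diag(4)
  sh <- tryCatch(.phaseShift(moving, fixed), error = function(e) NULL)
  if (is.null(sh)) {
    warning("phase correlation failed; returning identity transform")
    return(out)
  }
  out[1:3, 4] <- sh
  if (refine) {
    nccFor <- function(par) {
      A <- diag(4)
      A[1:3, ] <- matrix(par, 3, 4)
      -.nccAffine(moving, fixed, A)
    }
    p0 <- as.vector(out[1:3, ])
    opt <- tryCatch(optim(p0, nccFor, method = "Nelder-Mead",
                          control = list(maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      out[1:3, ] <- matrix(opt$par, 3, 4)
    } else {
      warning("affine refinement failed; keeping phase-correlation result")
    }
  }
  out
}

.phaseShift <- function(a, b) {
  d <- dim(a)
  Fa <- fft(a); Fb <- fft(b)
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Re(fft(R, inverse = TRUE))
  pk <- which.max(cc)
  ix <- arrayInd(pk, d)
  sh <- ix - 1L
  sh <- ifelse(sh > d / 2, sh - d, sh)
  ## sub-voxel refinement: separable parabola through the peak
  out <- numeric(3)
  for (ax in 1:3) {
    sel <- lapply(seq_along(d), function(k) ix[k])
    lo <- sel; hi <- sel
    lo[[ax]] <- ((ix[ax] - 2L) %% d[ax]) + 1L
    hi[[ax]] <- (ix[ax] %% d[ax]) + 1L
    y0 <- cc[lo[[1]], lo[[2]], lo[[3]]]
    y1 <- cc[sel[[1]], sel[[2]], sel[[3]]]
    y2 <- cc[hi[[1]], hi[[2]], hi[[3]]]
    den <- y0 - 2 * y1 + y2
    out[ax] <- sh[ax] + if (abs(den) > 1e-12)
      0.5 * (y0 - y2) / den else 0
  }
  out
}

.nccAffine <- function(moving, fixed, A) {
  d <- dim(fixed)
  sub <- pmax(1L, floor(d / 32L))
  gz <- seq(1L, d[1], by = sub[1])
  gx <- seq(1L, d[2], by = sub[2])
  gy <- seq(1L, d[3], by = sub[3])
  g <- as.matrix(expand.grid(gz, gx, gy))
  src <- cbind(g, 1) %*% t(A[1:3, ])
  mv <- trilinear(moving, src, outside = NA)
  fv <- fixed[g]
  ok <- !is.na(mv)
  if (sum(ok) < 10) return(-Inf)
  suppressWarnings(cor(mv[ok], fv[ok]))
}

#' Map voxel velocities onto the graph segments
#'
#' For every skeleton polyline point the valid total and axial velocity
#' samples inside a sphere of the locally fitted radius are gathered; the
#' point's total velocity is the mean of the highest `topFraction` of the
#' samples (the partial-volume compromise for a speed magnitude), while
#' the signed axial value is the in-sphere median (robust to a faster
#' neighbouring vessel intruding into the sphere).  Profiles are smoothed
#' with a moving average along the segment, and the segment total
#' velocity is the median over its points.  Segments with no valid sample
#' anywhere are left unset.
#'
#' Polyline end points (shared junction positions) are skipped when the
#' segment has interior points, since their spheres overlap neighbouring
#' vessels.
#'
#' @param graph a [VesselGraph-class] registered to the velocity grid.
#' @param field a [VelocityField-class].
#' @param topFraction fraction of highest in-sphere samples averaged.
#' @param window moving-average window along the segment.
#' @return The graph with per-segment `vtot`, `vz` (signed along start to
#'   end after direction assignment; here the raw axial mean), velocity
#'   profiles in `velocitySamples`, and `source = "measured"` where set.
#' @export
mapVelocitiesToGraph <- function(graph, field, topFraction = 0.3,
                                 window = 5L) {
  grid <- field@grid
  vtot <- field@vtot; vz <- field@vz; valid <- field@valid
  dims <- grid@dim
  graph@segments <- lapply(graph@segments, function(s) {
    pts <- s$points
    np <- nrow(pts)
    vox <- worldToVoxel(grid, pts)
    vT <- rep(NA_real_, np); vZ <- rep(NA_real_, np)
    ## polyline end points sit on shared junction nodes whose spheres
    ## overlap the neighbouring vessels; skip them when the segment has
    ## interior points of its own
    inner <- if (np >= 4L) 2:(np - 1L) else seq_len(np)
    for (i in inner) {
      ## sphere of the locally fitted radius; thin vessels reduce to the
      ## nearest voxel (inflating the sphere drags in neighbours)
      offs <- ballOffsets(s$radii[i] / min(grid@spacing))
      ctr <- round(vox[i, ])
      cand <- sweep(offs, 2L, ctr, "+")
      ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
            cand[, 1] <= dims[1] & cand[, 2] <= dims[2] &
            cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      li <- cand[, 1] + dims[1] * ((cand[, 2] - 1) + dims[2] *
                                   (cand[, 3] - 1))
      li <- li[valid[li]]
      if (!length(li)) next
      vt <- vtot[li]
      ord <- order(vt, decreasing = TRUE)
      k <- max(1L, ceiling(topFraction * length(li)))
      pick <- li[ord[seq_len(k)]]
      vT[i] <- mean(vtot[pick])
      ## the signed axial component uses the in-sphere median: the top
      ## fraction is the right partial-volume compromise for a speed
      ## magnitude, but for a signed quantity it preferentially selects a
      ## faster intruding neighbour and flips the sign
      vZ[i] <- median(vz[li])
    }
    vTs <- movingAverage(vT, window)
    vZs <- movingAverage(vZ, window)
    s$velocitySamples <- list(vtot = vT, vz = vZ,
                              vtotSmooth = vTs, vzSmooth = vZs)
    if (any(!is.na(vTs))) {
      s$vtot <- median(vTs, na.rm = TRUE)
      s$vz <- mean(vZs, na.rm = TRUE)
      s$source <- "measured"
    } else {
      s$vtot <- NA_real_
      s$vz <- NA_real_
      s$source <- "unset"
    }
    s
  })
  graph
}

#' Assign flow directions from the axial Doppler component
#'
#' At each polyline point with a meaningful axial orientation
#' (`|tangent_z| >= tangentFloor`) and a valid axial velocity sample, the
#' sign of the measured axial velocity is compared with the sign of the
#' local skeleton tangent's z-component (taken along the arbitrary start
#' to end orientation): agreement votes for start-to-end flow,
#' disagreement for the reverse.  Votes are weighted by
#' `|vz| * |tangent_z|` and the majority sets the segment's direction;
#' segments with no votes stay `"unknown"`.
#'
#' Points whose total-velocity sample exceeds `outlierFactor` times the
#' segment's median sample are excluded from the vote: such samples come
#' from a faster neighbouring vessel intruding into the sampling sphere,
#' and their sign says nothing about this segment's flow.
#'
#' @param graph a [VesselGraph-class] after [mapVelocitiesToGraph()].
#' @param tangentFloor minimum `|tangent_z|` for a point to vote.
#' @param outlierFactor profile outlier gate (multiples of the median
#'   total-velocity sample); `Inf` disables.
#' @return The graph with `direction` set per segment.
#' @export
assignFlowDirections <- function(graph, tangentFloor = 0.1,
                                 outlierFactor = 2) {
  graph@segments <- lapply(graph@segments, function(s) {
    vs <- s$velocitySamples
    if (is.null(vs)) return(s)
    pts <- s$points
    np <- nrow(pts)
    tg <- rbind(pts[2L, ] - pts[1L, ],
                if (np > 2L) pts[3:np, , drop = FALSE] -
                             pts[1:(np - 2L), , drop = FALSE],
                pts[np, ] - pts[np - 1L, ])
    tz <- tg[, 1] / pmax(sqrt(rowSums(tg^2)), 1e-12)
    vz <- vs$vzSmooth
    use <- !is.na(vz) & abs(tz) >= tangentFloor
    if (is.finite(outlierFactor) && any(!is.na(vs$vtot))) {
      medv <- median(vs$vtot, na.rm = TRUE)
      use <- use & (is.na(vs$vtot) | vs$vtot <= outlierFactor * medv)
    }
    if (!any(use)) {
      s$direction <- "unknown"
      return(s)
    }
    wt <- abs(vz[use]) * abs(tz[use])
    vote <- sign(vz[use]) * sign(tz[use])
    score <- sum(wt * vote)
    s$direction <- if (score > 0) "s2e" else if (score < 0) "e2s"
                   else "unknown"
    s
  })
  graph
}
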