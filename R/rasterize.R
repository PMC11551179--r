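#' Rasterize a vessel graph into voxel volumes
#'
#' Produces a binary segmentation mask (voxel foreground iff within the
#' local radius of some segment polyline) and a per-voxel 3-component
#' velocity field.  The velocity at a foreground voxel is the local
#' segment tangent scaled by the local speed; with the parabolic profile
#' the speed at radial offset `rho` is `2 vbar (1 - (rho/r)^2)`, as
#' expected for laminar flow in larger vessels, and the plug profile uses
#' the cross-section mean speed everywhere.  Vessels thinner than one
#' voxel are rasterized at least one voxel wide (with a warning).
#'
#' @param graph a [VesselGraph-class].
#' @param flow optional [FlowState-class]; segments without flow get zero
#'   velocity.
#' @param grid a [VoxelGrid-class]; voxel size should be at most half the
#'   smallest vessel radius that must be resolved.
#' @param profile `"plug"` or `"parabolic"`.
#' @return A list with elements `mask` ([SegmentationMask-class]),
#'   `velocity` (4-d array `[z, x, y, 3]`, mm/s, components along z/x/y)
#'   and `segmentId` (integer 3-d array, 0 = background).
#' @examples
#' sp <- networkSpec(kind = "tube-phantom", tubeDiameter = 20,
#'                   domain = c(64, 64, 64))
#' g <- generateNetwork(sp)
#' ras <- rasterizeNetwork(g, grid = voxelGrid(c(32, 32, 32), 2))
#' @export
rasterizeNetwork <- function(graph, flow = NULL, grid,
                             profile = c("plug", "parabolic")) {
  profile <- match.arg(profile)
  dims <- grid@dim
  sp <- grid@spacing
  mask <- array(FALSE, dims)
  segid <- array(0L, dims)
  vel <- array(0, c(dims, 3L))
  best <- array(Inf, dims)                  # distance of claiming sample
  minHalf <- 0.51 * max(sp)
  warned <- FALSE
  nvox <- prod(dims)

  for (s in graph@segments) {
    v <- if (is.null(flow)) 0 else
      unname(flow@velocities[as.character(s$id)])
    if (is.na(v)) v <- 0
    step <- 0.5 * min(sp)
    pts <- resamplePolyline(s$points, step)
    radii <- resampleProfile(s$points, s$radii, step)
    if (any(radii < minHalf) && !warned) {
      warning("grid too coarse for the thinnest vessels; ",
              "rasterizing them at least one voxel wide")
      warned <- TRUE
    }
    ## tangent per sample (central differences along the polyline)
    np <- nrow(pts)
    tg <- rbind(pts[2L, ] - pts[1L, ],
                if (np > 2L) pts[3:np, , drop = FALSE] -
                             pts[1:(np - 2L), , drop = FALSE],
                pts[np, ] - pts[np - 1L, ])
    tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
    vox <- worldToVoxel(grid, pts)
    for (i in seq_len(np)) {
      r <- radii[i]
      rEff <- max(r, minHalf)
      ri <- ceiling(rEff / sp)
      zr <- seq.int(-ri[1], ri[1]); xr <- seq.int(-ri[2], ri[2])
      yr <- seq.int(-ri[3], ri[3])
      cz <- round(vox[i, 1]); cx <- round(vox[i, 2]); cy <- round(vox[i, 3])
      zz <- cz + zr; xx <- cx + xr; yy <- cy + yr
      kz <- zz >= 1 & zz <= dims[1]
      kx <- xx >= 1 & xx <= dims[2]
      ky <- yy >= 1 & yy <= dims[3]
      if (!any(kz) || !any(kx) || !any(ky)) next
      zz <- zz[kz]; xx <- xx[kx]; yy <- yy[ky]
      ## world offsets of candidate voxel centres from the sample point
      wz <- (zz - vox[i, 1]) * sp[1]
      wx <- (xx - vox[i, 2]) * sp[2]
      wy <- (yy - vox[i, 3]) * sp[3]
      nz <- length(zz); nx <- length(xx); ny <- length(yy)
      dz <- rep(wz, times = nx * ny)
      dx <- rep(rep(wx, each = nz), times = ny)
      dy <- rep(wy, each = nz * nx)
      d2 <- dz^2 + dx^2 + dy^2
      inside <- d2 <= rEff^2
      if (!any(inside)) next
      iz <- rep(zz, times = nx * ny)[inside]
      ix <- rep(rep(xx, each = nz), times = ny)[inside]
      iy <- rep(yy, each = nz * nx)[inside]
      lin <- iz + dims[1] * ((ix - 1) + dims[2] * (iy - 1))
      closer <- d2[inside] < best[lin]
      if (!any(closer)) { mask[lin] <- TRUE; next }
      linc <- lin[closer]
      mask[lin] <- TRUE
      best[linc] <- d2[inside][closer]
      segid[linc] <- s$id
      along <- dz[inside][closer] * tg[i, 1] + dx[inside][closer] *
               tg[i, 2] + dy[inside][closer] * tg[i, 3]
      rho2 <- pmax(d2[inside][closer] - along^2, 0)
      speed <- if (profile == "parabolic")
        2 * v * pmax(1 - rho2 / rEff^2, 0) else rep(v, length(linc))
      vel[linc] <- speed * tg[i, 1]
      vel[linc + nvox] <- speed * tg[i, 2]
      vel[linc + 2 * nvox] <- speed * tg[i, 3]
    }
  }
  list(mask = new("SegmentationMask", values = mask, grid = grid,
                  provenance = "synthetic"),
       velocity = vel, segmentId = segid)
}

#' Convert a rasterized 3-component velocity field to a VelocityField
#'
#' Splits the vector field into the signed axial component and the
#' transverse magnitude, with the mask as validity.
#'
#' @param raster result of [rasterizeNetwork()].
#' @return A [VelocityField-class].
#' @export
rasterToVelocityField <- function(raster) {
  vel <- raster$velocity
  msk <- raster$mask@values
  vz <- vel[, , , 1]
  vtr <- sqrt(vel[, , , 2]^2 + vel[, , , 3]^2)
  vtot <- sqrt(vz^2 + vtr^2)
  vz[!msk] <- NA_real_; vtr[!msk] <- NA_real_; vtot[!msk] <- NA_real_
  new("VelocityField", vz = vz, vtransv = vtr, vtot = vtot,
      valid = msk, grid = raster$mask@grid)
}
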