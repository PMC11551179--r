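## Grid geometry helpers.  World coordinates are micrometres along (z, x, y);
## voxel coordinates are 1-based continuous array positions.

#' Convert between world and voxel coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @param points n x 3 matrix (z, x, y).
#' @return n x 3 matrix in the other coordinate system.
#' @export
worldToVoxel <- function(grid, points) {
  points <- rbind(points)
  sweep(sweep(points, 2L, grid@origin, "-"), 2L, grid@spacing, "/") + 1
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, points) {
  points <- rbind(points)
  sweep(sweep(points - 1, 2L, grid@spacing, "*"), 2L, grid@origin, "+")
}

## Trilinear interpolation of a 3-d array at continuous voxel coordinates
## (n x 3, 1-based).  Out-of-volume samples return `outside`.
trilinear <- function(vol, vox, outside = 0) {
  d <- dim(vol)
  n <- nrow(vox)
  lo <- floor(vox)
  fr <- vox - lo
  val <- numeric(n)
  inb <- lo[, 1] >= 1 & lo[, 2] >= 1 & lo[, 3] >= 1 &
         lo[, 1] <= d[1] - 1 & lo[, 2] <= d[2] - 1 & lo[, 3] <= d[3] - 1
  ## clamp samples on the boundary face into the last cell
  edge <- !inb & vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
          vox[, 1] <= d[1] & vox[, 2] <= d[2] & vox[, 3] <= d[3]
  if (any(edge)) {
    lo[edge, ] <- pmin(lo[edge, , drop = FALSE],
                       matrix(d - 1L, sum(edge), 3, byrow = TRUE))
    lo[edge, ] <- pmax(lo[edge, , drop = FALSE], 1)
    fr[edge, ] <- pmin(pmax(vox[edge, , drop = FALSE] -
                            lo[edge, , drop = FALSE], 0), 1)
  }
  use <- inb | edge
  if (any(use)) {
    l <- lo[use, , drop = FALSE]; f <- fr[use, , drop = FALSE]
    idx <- function(dz, dx, dy)
      (l[, 1] + dz) + d[1] * ((l[, 2] + dx - 1) + d[2] * (l[, 3] + dy - 1))
    acc <- numeric(sum(use))
    for (dz in 0:1) for (dx in 0:1) for (dy in 0:1) {
      w <- (if (dz) f[, 1] else 1 - f[, 1]) *
           (if (dx) f[, 2] else 1 - f[, 2]) *
           (if (dy) f[, 3] else 1 - f[, 3])
      acc <- acc + w * vol[idx(dz, dx, dy)]
    }
    val[use] <- acc
  }
  val[!use] <- outside
  val
}

## Integer offsets of voxels within a ball of radius r (voxel units),
## returned as an m x 3 matrix including the origin.
ballOffsets <- function(r) {
  ri <- max(0L, floor(r))
  ax <- seq.int(-ri, ri)
  g <- as.matrix(expand.grid(dz = ax, dx = ax, dy = ax))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

## Resample a polyline (n x 3) to approximately uniform arc-length spacing.
resamplePolyline <- function(points, spacing) {
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(steps))
  total <- s[length(s)]
  if (total <= spacing)
    return(points[c(1L, nrow(points)), , drop = FALSE])
  t <- seq(0, total, by = spacing)
  if (t[length(t)] < total) t <- c(t, total)
  out <- matrix(0, length(t), 3L)
  for (j in 1:3) out[, j] <- approx(s, points[, j], xout = t)$y
  out
}

## Linear interpolation of a per-point profile (e.g. radii) onto the
## resampled arc-length positions used by resamplePolyline.
resampleProfile <- function(points, profile, spacing) {
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(steps))
  total <- s[length(s)]
  if (total <= spacing) return(profile[c(1L, length(profile))])
  t <- seq(0, total, by = spacing)
  if (t[length(t)] < total) t <- c(t, total)
  approx(s, profile, xout = t)$y
}

## Centered moving average with window w (odd), ends handled by shrinking
## the window; NA values are ignored.
movingAverage <- function(x, w = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  h <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    v <- x[j]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

## Otsu threshold on a numeric vector (256-bin histogram).
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

## Deterministic per-unit seed derived from a base seed (kept < 2^31).
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 11939) %%
             2147483647)
}

## Run code with a local RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
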