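#' Compute a decorrelation angiogram from repeated B-scans
#'
#' Per-voxel inter-repeat decorrelation contrast: the mean magnitude of
#' consecutive complex differences after global bulk-phase correction,
#' averaged over repeat pairs.  Moving blood decorrelates between repeats,
#' static tissue does not.
#'
#' @param series a [BScanSeries-class].
#' @return An [AngiogramVolume-class].
#' @export
computeAngiogram <- function(series) {
  d <- dim(series@samples)
  nr <- d[1L]
  if (nr < 2L) stop("need at least 2 repeats to compute an angiogram")
  acc <- array(0, d[2:4])
  for (r in seq_len(nr - 1L)) {
    a <- array(series@samples[r, , , ], d[2:4])
    b <- array(series@samples[r + 1L, , , ], d[2:4])
    ## global bulk-phase between the two repeats
    ph <- Arg(sum(Conj(a) * b))
    acc <- acc + Mod(b * exp(-1i * ph) - a)
  }
  new("AngiogramVolume", values = acc / (nr - 1L), grid = series@grid)
}

## Cubic structuring element (Chebyshev ball of half-width `radius`),
## the usual choice for binary smoothing on anisotropic voxel grids.
.ballKernel <- function(radius) {
  r <- max(0L, floor(radius))
  ax <- seq.int(-r, r)
  as.matrix(expand.grid(dz = ax, dx = ax, dy = ax))
}

.shiftOr <- function(x, off, op = `|`, fill = FALSE) {
  d <- dim(x)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    sh <- x
    for (ax in 1:3) {
      s <- off[k, ax]
      if (s == 0) next
      idx <- seq_len(d[ax])
      src <- idx - s
      ok <- src >= 1 & src <= d[ax]
      perm <- vector("list", 3); perm[[ax]] <- idx[ok]
      tgt <- vector("list", 3); tgt[[ax]] <- src[ok]
      full <- lapply(d, seq_len)
      argsT <- full; argsT[[ax]] <- idx[ok]
      argsS <- full; argsS[[ax]] <- src[ok]
      tmp <- array(fill, d)
      tmp[argsT[[1]], argsT[[2]], argsT[[3]]] <-
        sh[argsS[[1]], argsS[[2]], argsS[[3]]]
      sh <- tmp
    }
    out <- if (is.null(out)) sh else op(out, sh)
  }
  out
}

#' Binary dilation, erosion and closing for 3-d masks
#'
#' The structuring element is a cube of half-width `radius` voxels.
#'
#' @param x logical 3-d array.
#' @param radius structuring-element half-width in voxels.
#' @return Logical 3-d array.
#' @export
dilate3d <- function(x, radius = 1) {
  .shiftOr(x, .ballKernel(radius), `|`, FALSE)
}

#' @rdname dilate3d
#' @export
erode3d <- function(x, radius = 1) {
  !.shiftOr(!x, .ballKernel(radius), `|`, TRUE)
}

#' @rdname dilate3d
#' @export
close3d <- function(x, radius = 1) erode3d(dilate3d(x, radius), radius)

#' Remove small connected components from a mask
#'
#' 26-connected components below `minVoxels` are dropped.
#'
#' @param x logical 3-d array.
#' @param minVoxels minimum component size.
#' @return Logical 3-d array.
#' @export
removeSmallComponents <- function(x, minVoxels = 27L) {
  lab <- array(.cc26(as.vector(x), dim(x)), dim(x))
  if (!max(lab)) return(x)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVoxels)
  array(lab %in% keep, dim(x))
}

#' Segment vessels from an angiogram
#'
#' Baseline thresholding segmentation: adaptive (Otsu) or fixed threshold
#' on the flow contrast, removal of small components, and morphological
#' closing for smoothing.  Externally produced masks (e.g. from a trained
#' segmentation network) can be passed through [importMask()] so that
#' downstream stages are agnostic to the mask's origin.
#'
#' @param angio an [AngiogramVolume-class].
#' @param threshold `"otsu"` or a numeric threshold.
#' @param minVoxels small-component removal size.
#' @param closingRadius radius of the morphological closing (voxels);
#'   0 disables.
#' @return A [SegmentationMask-class] with provenance
#'   `"internal-threshold"`.
#' @export
segmentVessels <- function(angio, threshold = "otsu", minVoxels = 27L,
                           closingRadius = 1) {
  v <- angio@values
  thr <- if (identical(threshold, "otsu")) otsuThreshold(as.vector(v))
         else as.numeric(threshold)
  m <- v > thr
  if (!any(m)) {
    warning("empty foreground after thresholding; returning empty mask")
    return(new("SegmentationMask", values = array(FALSE, dim(v)),
               grid = angio@grid, provenance = "internal-threshold"))
  }
  if (minVoxels > 1L) m <- removeSmallComponents(m, minVoxels)
  if (closingRadius > 0) m <- close3d(m, closingRadius)
  new("SegmentationMask", values = m, grid = angio@grid,
      provenance = "internal-threshold")
}

#' Wrap an externally produced binary volume as a segmentation mask
#'
#' External masks (e.g. the output of a trained 3D segmentation network)
#' pass through morphological closing only.
#'
#' @param values logical (or 0/1) 3-d array.
#' @param grid a [VoxelGrid-class].
#' @param closingRadius closing radius in voxels; 0 disables.
#' @return A [SegmentationMask-class] with provenance `"external"`.
#' @export
importMask <- function(values, grid, closingRadius = 1) {
  m <- array(as.logical(values), dim(values))
  if (closingRadius > 0) m <- close3d(m, closingRadius)
  new("SegmentationMask", values = m, grid = grid, provenance = "external")
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical arrays or [SegmentationMask-class] objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "SegmentationMask")) a <- a@values
  if (is(b, "SegmentationMask")) b <- b@values
  2 * sum(a & b) / (sum(a) + sum(b))
}
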