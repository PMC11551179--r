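#' Write and read vessel graphs as JSON
#'
#' The JSON schema has a `nodes` array (`id`, `z`, `x`, `y` in um) and a
#' `segments` array (`id`, `start`, `end`, `points` as an n x 3 array,
#' `radii`, `label`, `vtot`, `vz`, `direction`, `source`, `flags`), plus
#' free-form `metadata` (the generator specification and grid are
#' dropped).  Velocities,
#' directions and sources round-trip exactly.
#'
#' @param graph a [VesselGraph-class].
#' @param path file path.
#' @return `writeVesselGraph` returns the path invisibly;
#'   `readVesselGraph` returns the graph.
#' @export
writeVesselGraph <- function(graph, path) {
  segs <- lapply(graph@segments, function(s) {
    list(id = s$id, start = s$start, end = s$end,
         points = unname(s$points), radii = s$radii, label = s$label,
         vtot = s$vtot, vz = s$vz, direction = s$direction,
         source = s$source, flags = s$flags)
  })
  obj <- list(format = "vascuflow-graph", version = 1L,
              nodes = graph@nodes, segments = segs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeVesselGraph
#' @export
readVesselGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "vascuflow-graph"))
    stop("not a vascuflow graph file")
  segRows <- obj$segments
  segs <- lapply(seq_len(nrow(segRows)), function(k) {
    r <- segRows[k, ]
    s <- vesselSegment(r$id, r$start, r$end, r$points[[1L]],
                       unlist(r$radii),
                       label = r$label,
                       vtot = ifelse(is.null(r$vtot) || is.na(r$vtot),
                                     NA_real_, r$vtot),
                       vz = ifelse(is.null(r$vz) || is.na(r$vz),
                                   NA_real_, r$vz),
                       direction = r$direction, source = r$source)
    fl <- unlist(r$flags)
    s$flags <- if (is.null(fl)) character() else as.character(fl)
    s
  })
  vesselGraph(obj$nodes, segs)
}

#' Export a vessel graph to GraphML
#'
#' Nodes carry their coordinates; edges carry length, mean diameter,
#' tortuosity, label, velocities, direction and source.  Polylines are
#' not representable in GraphML; use the JSON schema for a lossless
#' round-trip.
#'
#' @param graph a [VesselGraph-class].
#' @param path file path.
#' @export
writeGraphML <- function(graph, path) {
  st <- segmentTable(graph)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(st$start), to = as.character(st$end),
               segId = st$id, length = st$length,
               meanDiameter = st$meanDiameter,
               tortuosity = st$tortuosity,
               label = st$label, vtot = st$vtot, vz = st$vz,
               direction = st$direction, source = st$source),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph@nodes$id),
                          z = graph@nodes$z, x = graph@nodes$x,
                          y = graph@nodes$y))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Volume I/O: TIFF and NIfTI with voxel-size metadata
#'
#' Masks and scalar volumes are written as multi-page 32-bit TIFF (one
#' page per depth slice) or NIfTI (voxel size in the header, um stored as
#' mm/1000).  A JSON sidecar with the grid geometry accompanies TIFF
#' output.
#'
#' @param x a [SegmentationMask-class], [AngiogramVolume-class] or
#'   numeric/logical 3-d array.
#' @param path output path (`.tif` or `.nii`/`.nii.gz`).
#' @param grid the [VoxelGrid-class] (taken from `x` when available).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path, grid = NULL) {
  if (is(x, "SegmentationMask") || is(x, "AngiogramVolume")) {
    grid <- x@grid
    x <- x@values
  }
  if (is.null(grid)) grid <- voxelGrid(dim(x))
  vals <- x * 1.0
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(vals)[1]), function(z)
      matrix(vals[z, , ], dim(vals)[2], dim(vals)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    reduce = FALSE)
    jsonlite::write_json(
      list(dim = grid@dim, spacingUm = grid@spacing,
           originUm = grid@origin),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    img <- RNifti::asNifti(aperm(vals, c(2, 3, 1)),
                           pixdim = grid@spacing[c(2, 3, 1)] / 1000)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @rdname writeVolume
#' @param as `"array"`, `"mask"` or `"angiogram"`.
#' @export
readVolume <- function(path, as = c("array", "mask", "angiogram")) {
  as <- match.arg(as)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1],
                      dim(pages[[1]])[2]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    meta <- paste0(path, ".json")
    grid <- if (file.exists(meta)) {
      m <- jsonlite::read_json(meta, simplifyVector = TRUE)
      voxelGrid(m$dim, m$spacingUm, m$originUm)
    } else voxelGrid(dim(arr))
  } else {
    img <- RNifti::readNifti(path)
    arr <- aperm(as.array(img), c(3, 1, 2))
    pd <- RNifti::pixdim(img)
    grid <- voxelGrid(dim(arr), c(pd[3], pd[1], pd[2]) * 1000)
  }
  switch(as,
    array = arr,
    mask = new("SegmentationMask", values = array(arr > 0.5, dim(arr)),
               grid = grid, provenance = "external"),
    angiogram = new("AngiogramVolume", values = arr, grid = grid))
}

#' Complex M-mode volume I/O as paired NIfTI files
#'
#' The complex samples are stored as two 4-d NIfTI volumes (real and
#' imaginary parts, time as the 4th dimension) plus a JSON sidecar with
#' the protocol and calibration.
#'
#' @param mmode an [MModeVolume-class].
#' @param basePath path prefix; writes `<base>_real.nii.gz`,
#'   `<base>_imag.nii.gz`, `<base>.json`.
#' @return The base path, invisibly.
#' @export
writeMMode <- function(mmode, basePath) {
  re <- aperm(Re(mmode@samples), c(2, 3, 1, 4))
  im <- aperm(Im(mmode@samples), c(2, 3, 1, 4))
  sp <- mmode@grid@spacing
  RNifti::writeNifti(RNifti::asNifti(re, pixdim = sp[c(2, 3, 1)] / 1000),
                     paste0(basePath, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(im, pixdim = sp[c(2, 3, 1)] / 1000),
                     paste0(basePath, "_imag.nii.gz"))
  p <- mmode@protocol; cal <- mmode@calibration
  jsonlite::write_json(list(
    grid = list(dim = mmode@grid@dim, spacingUm = sp,
                originUm = mmode@grid@origin),
    protocol = list(ascanRate = p@ascanRate, nRepeats = p@nRepeats,
                    pixelSize = p@pixelSize, nVolumes = p@nVolumes),
    calibration = list(lambda0 = cal@lambda0,
                       refractiveIndex = cal@refractiveIndex,
                       kappa = cal@kappa,
                       highpassCutoff = cal@highpassCutoff,
                       nPad = cal@nPad),
    metadata = mmode@metadata),
    paste0(basePath, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(basePath)
}

#' @rdname writeMMode
#' @export
readMMode <- function(basePath) {
  re <- as.array(RNifti::readNifti(paste0(basePath, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(basePath, "_imag.nii.gz")))
  m <- jsonlite::read_json(paste0(basePath, ".json"),
                           simplifyVector = TRUE)
  samples <- complex(real = re, imaginary = im)
  dim(samples) <- dim(re)
  samples <- aperm(samples, c(3, 1, 2, 4))
  grid <- voxelGrid(m$grid$dim, m$grid$spacingUm, m$grid$originUm)
  new("MModeVolume", samples = samples,
      grid = grid,
      protocol = dopplerProtocol(m$protocol$ascanRate,
                                 m$protocol$nRepeats,
                                 m$protocol$pixelSize,
                                 m$protocol$nVolumes),
      calibration = systemCalibration(m$calibration$lambda0,
                                      m$calibration$refractiveIndex,
                                      m$calibration$kappa,
                                      m$calibration$highpassCutoff,
                                      m$calibration$nPad),
      metadata = as.list(m$metadata))
}
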