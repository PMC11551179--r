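#' @name accessors
#' @title Accessors for vascuflow containers
#'
#' @description Slot access for the S4 containers: node and segment tables,
#' counts, grids and value arrays.
#'
#' @param x,object a vascuflow S4 object.
#' @param ... unused.
NULL

setGeneric("nNodes", function(x) standardGeneric("nNodes"))
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
setGeneric("segments", function(x) standardGeneric("segments"))
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @aliases nNodes
#' @export
setMethod("nNodes", "VesselGraph", function(x) nrow(x@nodes))

#' @rdname accessors
#' @aliases nSegments
#' @export
setMethod("nSegments", "VesselGraph", function(x) length(x@segments))

#' @rdname accessors
#' @aliases nodeTable
#' @export
setMethod("nodeTable", "VesselGraph", function(x) x@nodes)

#' @rdname accessors
#' @aliases segments
#' @export
setMethod("segments", "VesselGraph", function(x) x@segments)

#' @rdname accessors
#' @aliases segmentTable
#' @export
setMethod("segmentTable", "VesselGraph", function(x) {
  segs <- x@segments
  if (!length(segs))
    return(data.frame(id = integer(), start = integer(), end = integer(),
                      label = character(), length = numeric(),
                      meanDiameter = numeric(), medianDiameter = numeric(),
                      tortuosity = numeric(), vtot = numeric(),
                      vz = numeric(), direction = character(),
                      source = character()))
  data.frame(
    id = vapply(segs, `[[`, integer(1), "id"),
    start = vapply(segs, `[[`, integer(1), "start"),
    end = vapply(segs, `[[`, integer(1), "end"),
    label = vapply(segs, `[[`, character(1), "label"),
    length = vapply(segs, `[[`, numeric(1), "length"),
    meanDiameter = vapply(segs, `[[`, numeric(1), "meanDiameter"),
    medianDiameter = vapply(segs, `[[`, numeric(1), "medianDiameter"),
    tortuosity = vapply(segs, `[[`, numeric(1), "tortuosity"),
    vtot = vapply(segs, function(s) as.numeric(s$vtot)[1], numeric(1)),
    vz = vapply(segs, function(s) as.numeric(s$vz)[1], numeric(1)),
    direction = vapply(segs, `[[`, character(1), "direction"),
    source = vapply(segs, `[[`, character(1), "source"))
})

#' @rdname accessors
#' @aliases voxelSize
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridOf", "SegmentationMask", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "AngiogramVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "VelocityField", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "MModeVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("gridOf", "DopplerFitVolume", function(x) x@grid)

#' @rdname accessors
#' @aliases values
#' @export
setMethod("values", "SegmentationMask", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "AngiogramVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s voxels, spacing %s um\n",
              paste(object@dim, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x ")))
})

#' @rdname accessors
#' @export
setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec <%s> domain %s um, seed %d\n", object@kind,
              paste(object@domain, collapse = " x "), object@seed))
  if (object@kind == "cortical")
    cat(sprintf("  %d arteries, %d veins, %d levels, capillary chains of %d\n",
                object@nArteries, object@nVeins, object@levels,
                object@capillaryChainLength))
  else
    cat(sprintf("  tube diameter %g um at %g degrees\n",
                object@tubeDiameter, object@tubeAngle))
})

#' @rdname accessors
#' @export
setMethod("show", "VesselGraph", function(object) {
  st <- segmentTable(object)
  cat(sprintf("VesselGraph: %d nodes, %d segments\n",
              nNodes(object), nSegments(object)))
  if (nrow(st)) {
    cat("  labels: ")
    print(table(st$label))
    cat(sprintf("  velocity set on %d/%d segments\n",
                sum(!is.na(st$vtot)), nrow(st)))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "FlowState", function(object) {
  cat(sprintf("FlowState: %d segment flows, %d nodal pressures\n",
              length(object@flows), length(object@pressures)))
  if (length(object@velocities))
    cat(sprintf("  |v| range %.3g - %.3g mm/s\n",
                min(abs(object@velocities)), max(abs(object@velocities))))
})

#' @rdname accessors
#' @export
setMethod("show", "MModeVolume", function(object) {
  d <- dim(object@samples)
  cat(sprintf("MModeVolume %d x %d x %d voxels, %d repeats at %g kHz\n",
              d[1], d[2], d[3], d[4], object@protocol@ascanRate / 1000))
})

#' @rdname accessors
#' @export
setMethod("show", "DopplerFitVolume", function(object) {
  cat(sprintf("DopplerFitVolume %s: %d fitted, %d valid\n",
              paste(object@grid@dim, collapse = " x "),
              sum(is.finite(object@mu)), sum(object@valid)))
})

#' @rdname accessors
#' @export
setMethod("show", "VelocityField", function(object) {
  v <- object@vtot[object@valid]
  cat(sprintf("VelocityField %s: %d valid voxels",
              paste(object@grid@dim, collapse = " x "), length(v)))
  if (length(v)) cat(sprintf(", vtot %.2f - %.2f mm/s", min(v), max(v)))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("show", "PathProfile", function(object) {
  cat(sprintf("PathProfile: %d paths on %d grid points\n",
              object@nPaths, length(object@positions)))
})
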