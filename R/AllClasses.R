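#' @import methods
#' @importFrom stats approx coef cor fft mad median mvfft optim predict
#'   quantile rnorm runif sd setNames
#' @importFrom graphics hist
#' @importFrom utils combn head read.csv tail
#' @useDynLib vascuflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Axis convention shared by every class in the package:
## axis 1 = z (depth, increasing into the tissue), axis 2 = x, axis 3 = y.
## All physical coordinates are micrometres; voxel indices are 1-based in R
## user space (converted to 0-based only inside the C++ kernels).

#' Voxel grid geometry
#'
#' Describes the geometry of a volumetric image: array dimensions
#' (z, x, y), isotropic or anisotropic voxel spacing in micrometres, and the
#' world coordinate of the centre of the first voxel.
#'
#' @slot dim integer(3), array extent along (z, x, y).
#' @slot spacing numeric(3), voxel size in micrometres along (z, x, y).
#' @slot origin numeric(3), world position (micrometres) of voxel (1,1,1).
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(dim = "integer", spacing = "numeric", origin = "numeric"),
  prototype(dim = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite numbers")
  TRUE
})

#' Specification of a synthetic vascular network
#'
#' Parameter object consumed by [generateNetwork()].  The `cortical` kind
#' emulates the cortical hierarchy: pial arteries and veins confined to a
#' surface band, diving arterioles and ascending venules, recursive
#' bifurcating trees with Murray-law radii, and a capillary mesh connecting
#' arterial to venous terminals.  The `tube-phantom` kind produces a single
#' straight cylinder at a configurable inclination, mirroring flow-phantom
#' experiments with 180 um tubing.
#'
#' @slot kind character, `"cortical"` or `"tube-phantom"`.
#' @slot domain numeric(3), domain size in micrometres (z, x, y).
#' @slot nArteries,nVeins integer, number of pial roots per class.
#' @slot levels integer, bifurcation depth of each tree (0 = unbranched).
#' @slot capillariesPerTerminal integer, capillary connections started per
#'   arterial terminal.
#' @slot capillaryChainLength integer, number of capillary segments per
#'   connection.
#' @slot arteryRootRadius,veinRootRadius,capillaryRadius numeric,
#'   radii in micrometres.
#' @slot murrayExponent numeric, radius exponent at bifurcations
#'   (parent^g = sum child^g).
#' @slot inletPressure,outletPressure numeric, boundary pressures in Pa.
#' @slot viscosity numeric, dynamic blood viscosity in Pa s.
#' @slot tubeDiameter,tubeAngle numeric, phantom tube inner diameter (um)
#'   and inclination from the transverse plane (degrees).
#' @slot seed integer, RNG seed; fixes the generated network bit-for-bit.
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(kind = "character", domain = "numeric",
    nArteries = "integer", nVeins = "integer", levels = "integer",
    capillariesPerTerminal = "integer", capillaryChainLength = "integer",
    arteryRootRadius = "numeric", veinRootRadius = "numeric",
    capillaryRadius = "numeric", murrayExponent = "numeric",
    inletPressure = "numeric", outletPressure = "numeric",
    viscosity = "numeric", tubeDiameter = "numeric", tubeAngle = "numeric",
    seed = "integer"))

setValidity("NetworkSpec", function(object) {
  if (!object@kind %in% c("cortical", "tube-phantom"))
    return("kind must be 'cortical' or 'tube-phantom'")
  if (any(object@domain <= 0)) return("domain sizes must be positive")
  if (object@kind == "cortical") {
    if (object@nArteries < 1L) return("need at least one pial artery")
    if (any(c(object@arteryRootRadius, object@veinRootRadius,
              object@capillaryRadius) <= 0))
      return("radii must be positive")
    if (object@murrayExponent <= 0) return("murrayExponent must be positive")
  }
  if (object@kind == "tube-phantom" && object@tubeDiameter <= 0)
    return("tubeDiameter must be positive")
  if (object@viscosity <= 0) return("viscosity must be positive")
  if (object@inletPressure <= object@outletPressure)
    return("inletPressure must exceed outletPressure")
  TRUE
})

#' Vascular network graph
#'
#' Nodes are bifurcation points and endpoints; segments are the vessel
#' stretches between them, each carrying an ordered polyline with a radius
#' profile, a class label, a velocity record and a flow direction.  The
#' choice of which connected node is the "start" of a segment is arbitrary
#' but persisted; flow directions are expressed relative to it.
#'
#' @slot nodes data.frame with columns `id`, `z`, `x`, `y` (micrometres).
#' @slot segments list of segment records (see [vesselSegment()]).
#' @slot metadata list of free-form annotations.
#' @exportClass VesselGraph
setClass("VesselGraph",
  representation(nodes = "data.frame", segments = "list", metadata = "list"),
  prototype(nodes = data.frame(id = integer(), z = numeric(),
                               x = numeric(), y = numeric()),
            segments = list(), metadata = list()))

setValidity("VesselGraph", function(object) {
  nd <- object@nodes
  if (!all(c("id", "z", "x", "y") %in% names(nd)))
    return("nodes needs columns id, z, x, y")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  for (s in object@segments) {
    if (!all(c(s$start, s$end) %in% nd$id))
      return(sprintf("segment %s references unknown nodes", s$id))
    if (nrow(s$points) < 2L)
      return(sprintf("segment %s polyline needs >= 2 points", s$id))
    if (length(s$radii) != nrow(s$points))
      return(sprintf("segment %s radius profile length mismatch", s$id))
    if (any(s$radii <= 0))
      return(sprintf("segment %s has non-positive radii", s$id))
    p0 <- as.numeric(nd[match(s$start, nd$id), c("z", "x", "y")])
    p1 <- as.numeric(nd[match(s$end,   nd$id), c("z", "x", "y")])
    if (max(abs(s$points[1L, ] - p0)) > 1e-6 ||
        max(abs(s$points[nrow(s$points), ] - p1)) > 1e-6)
      return(sprintf("segment %s polyline endpoints differ from node positions",
                     s$id))
    if (!s$direction %in% c("s2e", "e2s", "unknown"))
      return(sprintf("segment %s has invalid direction", s$id))
  }
  TRUE
})

#' Steady-state flow solution on a vessel graph
#'
#' Signed volumetric flow per segment (positive = start to end), nodal
#' pressures, and the cross-section mean velocity per segment.
#'
#' @slot flows named numeric, Q per segment id in um^3/s.
#' @slot pressures named numeric, Pa per node id.
#' @slot velocities named numeric, signed mean velocity per segment in mm/s
#'   (positive = start to end).
#' @exportClass FlowState
setClass("FlowState",
  representation(flows = "numeric", pressures = "numeric",
                 velocities = "numeric"))

#' Acquisition protocol parameters
#'
#' Scan timing for the two acquisition modes: M-mode Doppler (repeated
#' A-scans at each lateral position) and repeated-B-scan angiography.
#'
#' @slot ascanRate numeric, A-scan rate in Hz.
#' @slot nRepeats integer, A-scans per position (M-mode) or B-scan repeats
#'   (angiography).
#' @slot pixelSize numeric, lateral pixel size in micrometres.
#' @slot nVolumes integer, number of Doppler volumes acquired for averaging.
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(ascanRate = "numeric", nRepeats = "integer",
                 pixelSize = "numeric", nVolumes = "integer"))

setValidity("AcquisitionProtocol", function(object) {
  if (object@ascanRate <= 0) return("ascanRate must be positive")
  if (object@nRepeats < 2L) return("need at least 2 repeats")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (object@nVolumes < 1L) return("nVolumes must be >= 1")
  TRUE
})

#' System calibration constants
#'
#' Optical and spectral constants used to convert Doppler spectrum
#' parameters to velocities.
#'
#' @slot lambda0 numeric, centre wavelength in metres.
#' @slot refractiveIndex numeric, tissue refractive index.
#' @slot kappa numeric, transverse calibration in (um/s) per Hz of spectral
#'   spread; the default reproduces the printed worked example
#'   (sigma = 3817 Hz maps to 12.2 mm/s).
#' @slot highpassCutoff numeric, time-domain high-pass cutoff in Hz.
#' @slot nPad integer, zero-padded spectrum length.
#' @exportClass SystemCalibration
setClass("SystemCalibration",
  representation(lambda0 = "numeric", refractiveIndex = "numeric",
                 kappa = "numeric", highpassCutoff = "numeric",
                 nPad = "integer"))

setValidity("SystemCalibration", function(object) {
  vals <- c(object@lambda0, object@refractiveIndex, object@kappa,
            object@highpassCutoff, object@nPad)
  if (any(vals <= 0)) return("all calibration constants must be positive")
  TRUE
})

#' Complex M-mode volume
#'
#' Complex OCT samples indexed `[z, x, y, t]`, the repeated A-scans at every
#' lateral position treated as a time series.
#'
#' @slot samples complex 4-d array.
#' @slot grid a [VoxelGrid-class].
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot calibration a [SystemCalibration-class].
#' @slot metadata list (e.g. aliasing flags from the simulator).
#' @exportClass MModeVolume
setClass("MModeVolume",
  representation(samples = "array", grid = "VoxelGrid",
                 protocol = "AcquisitionProtocol",
                 calibration = "SystemCalibration", metadata = "list"))

setValidity("MModeVolume", function(object) {
  d <- dim(object@samples)
  if (length(d) != 4L) return("samples must be a 4-d [z,x,y,t] array")
  if (!all(d[1:3] == object@grid@dim)) return("samples do not match grid dim")
  if (d[4L] != object@protocol@nRepeats)
    return("time dimension must equal protocol nRepeats")
  if (!is.complex(object@samples)) return("samples must be complex")
  TRUE
})

#' Repeated B-scan series
#'
#' Complex OCT samples indexed `[repeat, z, x, y]` from an angiography
#' acquisition.
#'
#' @slot samples complex 4-d array `[repeat, z, x, y]`.
#' @slot grid a [VoxelGrid-class].
#' @slot protocol an [AcquisitionProtocol-class].
#' @exportClass BScanSeries
setClass("BScanSeries",
  representation(samples = "array", grid = "VoxelGrid",
                 protocol = "AcquisitionProtocol"))

setValidity("BScanSeries", function(object) {
  d <- dim(object@samples)
  if (length(d) != 4L) return("samples must be a 4-d [repeat,z,x,y] array")
  if (d[1L] != object@protocol@nRepeats)
    return("first dimension must equal protocol repeats")
  if (!all(d[2:4] == object@grid@dim)) return("samples do not match grid dim")
  TRUE
})

#' Doppler power spectra for a set of voxels
#'
#' Power spectra on the zero-padded frequency axis spanning
#' (-fs/2, fs/2], stored as a matrix (voxels in rows) together with the
#' voxel index into the originating grid, plus the per-voxel spectral
#' maximum D_max for the whole volume.
#'
#' @slot power numeric matrix, `nVoxel x nPad`, non-negative.
#' @slot frequencies numeric, frequency axis in Hz (ascending).
#' @slot voxelIndex integer, linear indices of the rows in the grid.
#' @slot dmax numeric 3-d array, per-voxel spectral maximum.
#' @slot grid a [VoxelGrid-class].
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot calibration a [SystemCalibration-class].
#' @slot highpassed logical, whether the DC-suppressing high-pass filter
#'   was applied before transforming.
#' @exportClass DopplerSpectraVolume
setClass("DopplerSpectraVolume",
  representation(power = "matrix", frequencies = "numeric",
                 voxelIndex = "integer", dmax = "array", grid = "VoxelGrid",
                 protocol = "AcquisitionProtocol",
                 calibration = "SystemCalibration", highpassed = "logical"),
  prototype(highpassed = TRUE))

setValidity("DopplerSpectraVolume", function(object) {
  if (nrow(object@power) != length(object@voxelIndex))
    return("power rows must match voxelIndex")
  if (ncol(object@power) != length(object@frequencies))
    return("power columns must match frequency axis")
  if (any(object@power < 0)) return("power must be non-negative")
  if (is.unsorted(object@frequencies)) return("frequency axis must ascend")
  TRUE
})

#' Fitted Doppler spectrum parameters per voxel
#'
#' Modified-Gaussian fit parameters for every processed voxel: amplitude,
#' Doppler shift mu (Hz, signed), spread sigma (Hz), noise-floor offset,
#' goodness of fit R^2 and a validity flag, plus the D_max volume.
#'
#' @slot A,mu,sigma,offset,r2 numeric 3-d arrays (NA where not fitted).
#' @slot valid logical 3-d array.
#' @slot reason integer 3-d array of failure codes (0 ok, 1 fit failure,
#'   2 empty spectrum, 3 rejected by validation, 4 aliasing flag).
#' @slot dmax numeric 3-d array.
#' @slot grid a [VoxelGrid-class].
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot calibration a [SystemCalibration-class].
#' @exportClass DopplerFitVolume
setClass("DopplerFitVolume",
  representation(A = "array", mu = "array", sigma = "array",
                 offset = "array", r2 = "array", valid = "array",
                 reason = "array", dmax = "array", grid = "VoxelGrid",
                 protocol = "AcquisitionProtocol",
                 calibration = "SystemCalibration"))

setValidity("DopplerFitVolume", function(object) {
  d <- object@grid@dim
  for (nm in c("A", "mu", "sigma", "offset", "r2", "valid", "reason", "dmax"))
    if (!all(dim(slot(object, nm)) == d))
      return(sprintf("slot %s does not match grid dim", nm))
  ok <- object@valid & is.finite(object@sigma)
  if (any(object@sigma[ok] <= 0, na.rm = TRUE))
    return("valid voxels must have sigma > 0")
  TRUE
})

#' Per-voxel velocity field
#'
#' Signed axial velocity, non-negative transverse and total speed in mm/s,
#' with a validity mask.  On valid voxels `vtot = sqrt(vz^2 + vtransv^2)`
#' holds exactly.
#'
#' @slot vz,vtransv,vtot numeric 3-d arrays (mm/s, NA where invalid).
#' @slot valid logical 3-d array.
#' @slot grid a [VoxelGrid-class].
#' @exportClass VelocityField
setClass("VelocityField",
  representation(vz = "array", vtransv = "array", vtot = "array",
                 valid = "array", grid = "VoxelGrid"))

setValidity("VelocityField", function(object) {
  d <- object@grid@dim
  for (nm in c("vz", "vtransv", "vtot", "valid"))
    if (!all(dim(slot(object, nm)) == d))
      return(sprintf("slot %s does not match grid dim", nm))
  v <- object@valid
  if (any(object@vtransv[v] < 0, na.rm = TRUE))
    return("vtransv must be >= 0 on valid voxels")
  err <- abs(object@vtot[v] -
             sqrt(object@vz[v]^2 + object@vtransv[v]^2))
  if (any(err > 1e-9, na.rm = TRUE))
    return("vtot must equal the Euclidean norm of (vz, vtransv)")
  TRUE
})

#' Flow-contrast angiogram volume
#'
#' Non-negative inter-repeat decorrelation contrast per voxel.
#'
#' @slot values numeric 3-d array, >= 0.
#' @slot grid a [VoxelGrid-class].
#' @exportClass AngiogramVolume
setClass("AngiogramVolume",
  representation(values = "array", grid = "VoxelGrid"))

setValidity("AngiogramVolume", function(object) {
  if (!all(dim(object@values) == object@grid@dim))
    return("values do not match grid dim")
  if (any(object@values < 0, na.rm = TRUE)) return("values must be >= 0")
  TRUE
})

#' Binary vessel segmentation mask
#'
#' @slot values logical 3-d array.
#' @slot grid a [VoxelGrid-class].
#' @slot provenance character, `"internal-threshold"` or `"external"`.
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(values = "array", grid = "VoxelGrid",
                 provenance = "character"))

setValidity("SegmentationMask", function(object) {
  if (!is.logical(object@values)) return("mask values must be logical")
  if (!all(dim(object@values) == object@grid@dim))
    return("values do not match grid dim")
  if (!object@provenance %in% c("internal-threshold", "external", "synthetic"))
    return("provenance must be internal-threshold, external or synthetic")
  TRUE
})

#' One-voxel-thick centerline skeleton
#'
#' Ordered 26-connected voxel chains between junctions and endpoints,
#' together with the local radius (from the distance transform) at every
#' skeleton voxel.
#'
#' @slot chains list; each element a list with `points` (n x 3 integer
#'   voxel coordinates), `radii` (voxel units) and the chain's terminal
#'   classification.
#' @slot junctions,endpoints integer matrices of voxel coordinates.
#' @slot skeletonMask logical 3-d array.
#' @slot grid a [VoxelGrid-class].
#' @exportClass Skeleton
setClass("Skeleton",
  representation(chains = "list", junctions = "matrix",
                 endpoints = "matrix", skeletonMask = "array",
                 grid = "VoxelGrid"))

#' Arteriovenous path velocity profile
#'
#' Median total-velocity profile over all normalized artery-to-vein paths,
#' on a common position grid with 0 = arterial side and 1 = venous side,
#' with the median absolute deviation band, the number of contributing
#' paths and the unnormalized path lengths (in segments).
#'
#' @slot positions numeric, grid on `[0, 1]`.
#' @slot median,mad numeric, per grid point (mm/s).
#' @slot nPaths integer.
#' @slot pathLengths integer, per-path segment counts.
#' @slot lengthHistogram data.frame with `order`, `mean` and `se` columns
#'   (mean bar height across graphs with its standard error).
#' @exportClass PathProfile
setClass("PathProfile",
  representation(positions = "numeric", median = "numeric", mad = "numeric",
                 nPaths = "integer", pathLengths = "integer",
                 lengthHistogram = "data.frame"))

setValidity("PathProfile", function(object) {
  if (length(object@positions) &&
      (abs(object@positions[1L]) > 1e-12 ||
       abs(object@positions[length(object@positions)] - 1) > 1e-12))
    return("position grid must span [0, 1]")
  if (any(object@mad < 0, na.rm = TRUE)) return("MAD must be >= 0")
  TRUE
})
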