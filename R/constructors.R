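#' Create a voxel grid
#'
#' @param dim integer(3) array extent along (z, x, y).
#' @param spacing voxel size in micrometres; recycled to length 3.
#' @param origin world position (um) of the centre of voxel (1,1,1).
#' @return A [VoxelGrid-class].
#' @examples
#' voxelGrid(c(64, 64, 64), spacing = 4)
#' @export
voxelGrid <- function(dim, spacing = 1, origin = c(0, 0, 0)) {
  new("VoxelGrid", dim = as.integer(dim), spacing = rep_len(spacing, 3L),
      origin = rep_len(origin, 3L))
}

#' Create a synthetic network specification
#'
#' Defaults describe a desk-scale cortical block: two pial arteries and two
#' pial veins feeding bifurcating trees of depth seven whose terminals are
#' joined pairwise through five-segment capillary chains.  Radii follow
#' Murray's law with exponent 3; the structural defaults and boundary
#' pressures put the Poiseuille solution in the physiological regime
#' (capillary speeds roughly 0.5-5 mm/s, pial arteries up to ~20 mm/s).
#'
#' @param kind `"cortical"` or `"tube-phantom"`.
#' @param domain domain size in micrometres (z, x, y).
#' @param nArteries,nVeins number of pial roots.
#' @param levels bifurcation depth of each tree (0 = single root vessel).
#' @param capillariesPerTerminal capillary connections per arterial terminal.
#' @param capillaryChainLength capillary segments per connection.
#' @param arteryRootRadius,veinRootRadius,capillaryRadius radii (um).
#' @param murrayExponent bifurcation radius exponent.
#' @param inletPressure,outletPressure boundary pressures (Pa).
#' @param viscosity blood viscosity (Pa s).
#' @param tubeDiameter,tubeAngle phantom tube diameter (um) and inclination
#'   from the transverse plane (degrees).
#' @param seed RNG seed; identical spec + seed reproduces the network
#'   bit-for-bit.
#' @return A [NetworkSpec-class].
#' @examples
#' networkSpec(seed = 1)
#' networkSpec(kind = "tube-phantom", tubeDiameter = 180, tubeAngle = 8)
#' @export
networkSpec <- function(kind = c("cortical", "tube-phantom"),
                        domain = c(400, 800, 800),
                        nArteries = 2L, nVeins = 2L, levels = 7L,
                        capillariesPerTerminal = 2L,
                        capillaryChainLength = 5L,
                        arteryRootRadius = 16, veinRootRadius = 20,
                        capillaryRadius = 2.5, murrayExponent = 3,
                        inletPressure = 8000, outletPressure = 2000,
                        viscosity = 3e-3,
                        tubeDiameter = 180, tubeAngle = 8,
                        seed = 1L) {
  kind <- match.arg(kind)
  new("NetworkSpec", kind = kind, domain = as.numeric(domain),
      nArteries = as.integer(nArteries), nVeins = as.integer(nVeins),
      levels = as.integer(levels),
      capillariesPerTerminal = as.integer(capillariesPerTerminal),
      capillaryChainLength = as.integer(capillaryChainLength),
      arteryRootRadius = arteryRootRadius, veinRootRadius = veinRootRadius,
      capillaryRadius = capillaryRadius, murrayExponent = murrayExponent,
      inletPressure = inletPressure, outletPressure = outletPressure,
      viscosity = viscosity, tubeDiameter = tubeDiameter,
      tubeAngle = tubeAngle, seed = as.integer(seed))
}

#' Create a vessel segment record
#'
#' @param id segment identifier (integer).
#' @param start,end node ids; which node is the start is arbitrary but
#'   persisted, and directions are expressed relative to it.
#' @param points n x 3 matrix of polyline coordinates (z, x, y) in um.
#' @param radii radius profile in um, one value per polyline point.
#' @param label vessel class.
#' @param vtot,vz segment velocities in mm/s (`NA` = unset); `vz` is signed
#'   along start to end.
#' @param direction `"s2e"`, `"e2s"` or `"unknown"`.
#' @param source `"measured"`, `"recovered"` or `"unset"`.
#' @return A list with derived fields `length`, `meanDiameter`, `tortuosity`.
#' @export
vesselSegment <- function(id, start, end, points, radii,
                          label = "unlabeled", vtot = NA_real_,
                          vz = NA_real_, direction = "unknown",
                          source = "unset") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L,
            length(radii) == nrow(points))
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  len <- sum(steps)
  chord <- sqrt(sum((points[nrow(points), ] - points[1L, ])^2))
  list(id = as.integer(id), start = as.integer(start), end = as.integer(end),
       points = points, radii = as.numeric(radii), label = label,
       vtot = vtot, vz = vz, direction = direction, source = source,
       length = len, meanDiameter = 2 * mean(radii),
       medianDiameter = 2 * median(radii),
       tortuosity = if (chord > 0) len / chord else Inf,
       flags = character())
}

#' Assemble a vessel graph
#'
#' @param nodes data.frame with `id`, `z`, `x`, `y` columns.
#' @param segments list of records from [vesselSegment()].
#' @param metadata free-form list.
#' @return A [VesselGraph-class].
#' @export
vesselGraph <- function(nodes, segments, metadata = list()) {
  nodes$id <- as.integer(nodes$id)
  new("VesselGraph", nodes = nodes, segments = segments, metadata = metadata)
}

#' Acquisition protocols
#'
#' `dopplerProtocol()` is the M-mode Doppler default (23 kHz A-scan rate,
#' 250 repeats per position, 4 um lateral pixels, three volumes averaged);
#' `angiographyProtocol()` is the repeated-B-scan default (46 kHz, 8
#' repeats, 2 um pixels).
#'
#' @param ascanRate A-scan rate (Hz).
#' @param nRepeats repeats per position.
#' @param pixelSize lateral pixel size (um).
#' @param nVolumes Doppler volumes acquired for averaging.
#' @return An [AcquisitionProtocol-class].
#' @export
dopplerProtocol <- function(ascanRate = 23000, nRepeats = 250L,
                            pixelSize = 4, nVolumes = 3L) {
  new("AcquisitionProtocol", ascanRate = ascanRate,
      nRepeats = as.integer(nRepeats), pixelSize = pixelSize,
      nVolumes = as.integer(nVolumes))
}

#' @rdname dopplerProtocol
#' @export
angiographyProtocol <- function(ascanRate = 46000, nRepeats = 8L,
                                pixelSize = 2, nVolumes = 1L) {
  new("AcquisitionProtocol", ascanRate = ascanRate,
      nRepeats = as.integer(nRepeats), pixelSize = pixelSize,
      nVolumes = as.integer(nVolumes))
}

#' System calibration constants
#'
#' The transverse calibration `kappa` converts the Doppler spectral spread
#' to a transverse speed, `vtransv = kappa * sigma`; its default is the
#' ratio of the worked example values (12.2 mm/s at sigma = 3817 Hz,
#' i.e. 3.196 (um/s)/Hz).
#'
#' @param lambda0 centre wavelength (m).
#' @param refractiveIndex tissue refractive index.
#' @param kappa transverse calibration, (um/s) per Hz.
#' @param highpassCutoff time-domain high-pass cutoff (Hz).
#' @param nPad zero-padded spectrum length.
#' @return A [SystemCalibration-class].
#' @examples
#' systemCalibration()
#' @export
systemCalibration <- function(lambda0 = 1315e-9, refractiveIndex = 1.33,
                              kappa = 3.196, highpassCutoff = 270,
                              nPad = 4096L) {
  new("SystemCalibration", lambda0 = lambda0,
      refractiveIndex = refractiveIndex, kappa = kappa,
      highpassCutoff = highpassCutoff, nPad = as.integer(nPad))
}
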