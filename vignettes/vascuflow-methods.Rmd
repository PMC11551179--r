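---
title: "Models and methods behind vascuflow"
author: "vascuflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vascuflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vascuflow)
```

# Scope

vascuflow turns Doppler optical coherence microscopy (OCM) acquisitions of
the cortical vasculature into annotated vessel graphs: per-voxel M-mode
time series become Doppler power spectra and velocities, repeated B-scans
become flow-contrast angiograms and binary masks, masks become centerline
skeletons and node/segment graphs with diameters, and the graphs carry
per-segment total velocities, flow directions, artery/vein labels,
branching orders and arteriovenous path statistics.  A synthetic
vasculature generator with physically consistent Poiseuille flows and an
OCT signal simulator provide a ground-truth substrate, so every stage is
testable without instrument data.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test bed does and
does not establish about real data.

# Doppler velocimetry

## Signal model

At a perfused voxel the repeated A-scans form a complex time series whose
one-sided power spectrum is modeled as Gaussian: its mean is the Doppler
shift of the axial velocity component,

$$f_D = \frac{2 n v_z}{\lambda_0},$$

and its standard deviation grows with the transverse speed,
$\sigma = v_t / \kappa$.  Static and partial-volume scatterers add a
constant-phase component, i.e. a spectral line at zero frequency (the DC
peak).  The velocity conversions are

$$v_z = \frac{\lambda_0 \mu}{2 n}, \qquad
  v_{transv} = \kappa\,\sigma, \qquad
  v_{tot} = \sqrt{v_{transv}^2 + v_z^2}.$$

Defaults: $\lambda_0 = 1315$ nm, $n = 1.33$, A-scan rate
$f_s = 23$ kHz with 250 repeats per position and three volumes averaged.
The transverse calibration $\kappa$ is a single scalar; its default,
3.196 (um/s)/Hz, is the ratio of the worked-example values (a spread of
3817 Hz corresponding to 12.2 mm/s).  The analytic dependence of the
spectral broadening on the beam geometry is system-specific and is
deliberately collapsed into this one calibration constant.

## Processing chain

1. **High-pass along time.** A zero-phase high-pass with the
   squared-magnitude response of a 2nd-order Butterworth (270 Hz cutoff)
   is applied spectrally (circularly) per voxel.  This is the ideal
   zero-phase equivalent of forward-backward IIR filtering.  On
   250-sample series the spectral realization matters: reflection-padded
   time-domain filtering leaves edge transients that bias the fitted
   Doppler shift by hundreds of Hz for broad spectra, while the circular
   realization has an exactly known power response $|H|^4$ and removes a
   constant static component perfectly (it occupies only the
   zero-frequency bin).
2. **Zero-padded spectrum.** The filtered series is Fourier transformed
   with zero-padding to 4096 bins, giving an interpolated Doppler power
   spectrum per voxel; several volumes are averaged on the power spectra
   (averaging fit parameters instead changes results by less than the
   speckle scatter, and spectrum averaging is the variance-optimal point
   to pool).  `D_max`, the per-voxel spectral maximum used as an
   intensity surrogate for validation and registration, is evaluated on
   the natural-resolution spectrum so that full-volume sweeps stay cheap.
3. **Modified Gaussian fit.** Per voxel, nonlinear least squares of
   $A\,G(f;\mu,\sigma) + c$ where $G$ is the Gaussian *periodically
   summed over the aliased frequency axis*.  The filter's power response
   is divided out on the fitted bins (bins with response below 0.1 are
   excluded rather than amplified), the offset $c$ is pinned to the 10%
   quantile of the compensated spectrum, and the fit is initialized from
   circular spectral moments, the proper first/second moments on a
   wrapped axis.  When the fitted spread exceeds $0.065 f_s$ the offset
   is refit, bounded above by the quantile floor: for wide spectra the
   quantile over-estimates the true noise floor (the signal fills the
   axis), so the offset may only move down - letting it rise absorbs the
   flat signal into the baseline and collapses the fitted spread to a
   spurious low mode.  Near the DC notch the fixed floor is what
   prevents the classic sigma-offset degeneracy of narrow spectra.
   Voxels whose fit fails are marked invalid with a reason code; nothing
   throws.
4. **Response deconvolution.** The finite 250-sample window convolves
   every spectrum with its Dirichlet kernel, and the notch truncates
   narrow spectra near zero; both bias the raw fitted spread.  The
   estimator's median response is therefore calibrated once per
   protocol/calibration pair on a $(\mu, \sigma)$ reference grid by
   running the full chain on seeded speckle realizations at the 10 dB
   acceptance signal-to-noise ratio, and the monotone response curves are
   inverted per voxel.  A Monte-Carlo median (rather than the
   deterministic expectation) is used because speckle saturates the
   estimator for very wide spectra, where expectation and median response
   diverge.
5. **Validation.** A voxel is kept iff the goodness of fit reaches
   `r2Min` (default 0.8), `D_max` exceeds a per-depth-slice Otsu
   threshold on `log D_max` (rejects remaining static voxels), the spread
   is physically plausible, and the shift is inside the unambiguous range
   (`|mu| <= 0.45 fs`).  Aliased voxels are rejected because their
   wrapped shift has the wrong sign and magnitude; no unwrapping is
   attempted.  $R^2$ is evaluated at the acquisition's *natural* spectral
   resolution: data and model are boxcar-smoothed over five
   natural-resolution bins before comparison.  The speckle fluctuations
   of a periodogram are irreducible (about $1/\sqrt{3}$ relative,
   three-volume averaged), so an unsmoothed $R^2$ of even a perfect fit
   tops out near 0.75 and carries no information about fit quality; at
   the natural resolution a good fit scores > 0.9 for narrow and
   mid-width spectra while flat noise stays near 0.

## Known limits of the velocimetry

* **Axial Nyquist.** At 23 kHz the unambiguous axial velocity is
  $\pm 5.7$ mm/s.  Faster axial flows wrap; the wrapped shift can land
  back inside the accepted range, where it is undetectable from a single
  voxel.  Direction and velocity claims therefore hold only for vessels
  whose axial component stays in the unambiguous range - in the cortex
  that is the (horizontal) pial vessels, capillaries, and moderate
  penetrating flows.
* **Very wide spectra.** At a total speed of 30 mm/s the transverse
  spread is about $0.4 f_s$; the wrapped spectrum is then nearly flat and
  the only remaining evidence of $\mu$ is a first-harmonic modulation of
  relative amplitude $e^{-2\pi^2\sigma^2/f_s^2} \approx 4\%$, below the
  speckle noise of $250 \times 3$ samples.  The spread itself remains
  estimable (its dependence on the modulation is logarithmic and the
  response inversion handles the saturation), but the *shift* is
  information-limited there: no estimator at this acquisition length can
  localize it to a few tens of Hz.  The test suite states the per-voxel
  recovery property at full stringency and this regime is expected to
  fail it; the package reports it honestly rather than widening the
  band.

# Synthetic vasculature and flows

The generator grows one L-shaped root vessel per pial artery/vein (a
horizontal stretch inside the surface band, then a diving/ascending
limb), attaches a recursive bifurcating tree with Murray-law radii
(exponent 3, symmetric: child radius $2^{-1/3}$ of the parent), and joins
arterial to venous terminals with jittered capillary chains; a bridging
pass guarantees a single connected component.  Tree segments with mean
diameter of at least 12 um carry their tree's class, thinner branches and
chains are capillaries - the same rule the label propagation applies, so
generated labels are a consistent ground truth.

Flows solve the Poiseuille network problem: segment conductances are
integrated along the polylines ($R = \sum 8\eta\,ds/(\pi r^4)$), Dirichlet
pressures are imposed at artery inlets (8000 Pa) and vein outlets
(2000 Pa), viscosity is 3 mPa s, and interior nodes balance exactly.  The
default block (400 x 800 x 800 um, two arteries/veins, seven levels,
paired five-segment capillary chains) yields capillary speeds of roughly
0.3-5 mm/s and pial artery speeds up to ~20 mm/s - the structural scale
was chosen so that the artery-to-capillary speed ratio is physiological,
which for a bifurcating tree requires enough parallel capillary paths
(the ratio is set by $N_{paths} r_{cap}^2 / r_{root}^2$).

Rasterization marks voxels within the local radius of any polyline
(claimed by the nearest segment where vessels touch), guarantees at least
one voxel of width for sub-voxel capillaries, and writes the tangent
times the local speed as a 3-component velocity field, with an optional
parabolic profile ($2\bar v (1 - (\rho/r)^2)$) for laminar flow in larger
vessels.

What the generator does *not* emulate: pulsatility, hematocrit-dependent
viscosity, discrete red-blood-cell flow, multiple-scattering tails below
large vessels, tail artifacts of angiography, and anatomically realistic
capillary anastomoses (chains connect terminals pairwise).  Passing tests
on this substrate therefore establishes the correctness of the
*processing*, not the fidelity of any biological conclusion.

# Skeletonization and graphs

The mask is thinned to a curve skeleton by distance-ordered homotopic
thinning: foreground voxels are visited in increasing order of the exact
Euclidean distance transform and removed while they are topologically
simple (one 26-connected foreground component among the 26 neighbours and
one 6-connected background component in the 18-neighbourhood) and not
chain endpoints.  Terminal spurs shorter than `pruneStrength` (default 3)
times the local radius are pruned and the volume re-thinned until stable
- the bulge-size analogue.  Graph construction assigns nodes to junction
clusters (centroid position) and endpoints, and chains become segments
with physical polylines, arc length, tortuosity and a provisional
distance-transform radius.  Reconstruction is exact (node and segment
counts) for trees whose branches clear each other by more than about four
voxels; closer branches merge in the raster and no centerline method can
separate them, which is why the round-trip tests condition on the
clearance, computed by `interBranchClearance()`.

Diameters are refit from the angiogram: at each polyline point a line
profile orthogonal to the tangent (four azimuthal directions averaged,
half-length four provisional radii) is fit with a flattened Gaussian
$A \exp(-(((t-m)^2/2s^2)^p)) + c$ and the diameter is its full width at
half maximum.  The free flatness exponent matters: vessel interiors are
closer to top-hat than Gaussian, and a plain Gaussian's FWHM
underestimates a top-hat's width by ~13% regardless of scale, which would
be several voxels on a 40 um vessel; with $p$ free the FWHM tracks the
true width within half a voxel across profile shapes and reduces to the
Gaussian case ($p = 1$) for blurred profiles.  Fits with $R^2 \le 0.8$
are discarded and a five-point moving average fills the gaps; segments
with no accepted fit fall back to the distance-transform diameter and are
flagged.

# Velocities on the graph

Voxel velocities are gathered per skeleton point within a sphere of the
locally fitted radius.  The point's total velocity is the mean of the top
30% of the in-sphere samples (the empirical partial-volume compromise for
a speed magnitude), while the signed axial component is the in-sphere
median: selecting the fastest samples is right for a magnitude but wrong
for a sign, because a faster neighbouring vessel intruding into the
sphere then wins the selection and flips it.  Polyline end points are
skipped when interior points exist (they sit on shared junction positions
whose spheres overlap the neighbouring vessels), thin vessels reduce to
the nearest voxel (inflating the sphere drags in neighbours), and profile
samples whose total velocity exceeds twice the segment median are
discarded as intrusions.  Profiles are smoothed with a five-point moving
average; the segment total velocity is the median over its points.

Directions: at each point with $|t_z| \ge 0.1$ and a valid axial sample,
the sign of the measured axial velocity against the sign of the local
tangent's z-component votes for start-to-end or the reverse, weighted by
$|v_z||t_z|$; the majority wins.  The weighting suppresses
noise-dominated votes from nearly horizontal stretches; fully transverse
segments stay unknown.

Missing velocities are recovered by the local zero-net-flow rule,
iterated to a fixpoint: a segment with unknown velocity at a node whose
other segments all have velocity and direction receives the negated
signed flow sum ($Q_i = v_i \pi (d_i/2)^2$, segment mean radius), its
speed from its own cross-section and its direction from the flow sign;
two determinable endpoints average their speed estimates, and if they
disagree on direction the larger-flow endpoint wins and the segment is
flagged.  Unknowns are processed in descending count of known neighbours
and balances are recomputed after every fix, so cascades resolve chains
of unknowns.  The direct linear conservation solve
(`solveMissingFlowsDirect()`) is kept as an independent cross-check: on
networks where every unknown is uniquely determined the two agree to
relative $10^{-9}$.

# Network analysis

Labels propagate breadth-first from pial seeds over the segment adjacency
and halt at pre-capillaries (median diameter below 12 um); conflicts
(both labels reaching a segment in the same round) stay capillary with a
warning.  Branching orders are minimum segment-hop counts to the nearest
segment of each class.  Arteriovenous paths combine, per capillary
segment, the shortest hop paths to the closest artery and vein; paths
with fewer than three capillary segments are rejected; each path's
velocities sit at normalized cumulative hop positions on [0, 1] and are
linearly interpolated onto a 21-point grid, summarized by per-grid-point
median and MAD pooled over all paths (and all supplied graphs); the
path-length histogram reports mean bar heights across graphs with the
standard error.  Hops were chosen as the path metric because branching
"order" is a hop count; 21 grid points resolve the profile of typical
10-30-segment paths without inventing structure.

The node-degree-versus-axial-window curve anchors windows at the pial
surface and cuts segments at the node level: a segment is severed iff its
endpoint nodes straddle the window boundary, each severed segment
contributing one degree-1 cut endpoint.  Cutting at every polyline
crossing instead spawns spurious degree-1 nodes whenever a tortuous
capillary wiggles across the boundary and makes the curve locally
non-monotone; node-level cutting matches the segment-granularity notion
of severing a connection and yields the expected monotone growth toward
the full-network value.

# Problem sizes used by the tests

The suite runs everything on desk-scale volumes chosen as the smallest
sizes that still separate signal from discretization: single-voxel
acquisitions for estimator properties (33 replicate voxels per grid point
in the recovery property, medians reported), 150^3 voxels at 2 um for
topology round-trips, 64^3 at 4 um (two networks, slower flows inside the
unambiguous axial range) for direction accuracy, 32^3 at 8 um for the
tube phantom with ~150 sampled voxels per pump speed, and five replicate
~2000-segment networks for the recovery acceptance check.  The full-size
256 x 256 lateral protocol is supported but not exercised by default.

# Registration

The Doppler-to-angiogram registration hook estimates translation by FFT
phase correlation with sub-voxel parabolic refinement, optionally
followed by a Nelder-Mead affine refinement of normalized
cross-correlation on a subsampled grid.  Co-simulated volumes share a
grid, so the identity is returned and applied; the deformable step used
on instrument data is intentionally out of scope (pure library glue
there, identity in the synthetic setting).

# File formats

Graphs round-trip losslessly through a documented JSON schema (nodes,
segments with polylines/radii/labels/velocities/directions/sources) and
export to GraphML for graph tools; masks and scalar volumes go to
multi-page TIFF (with a JSON geometry sidecar) or NIfTI with voxel sizes
in the header; complex M-mode volumes are stored as paired real/imaginary
NIfTI plus a JSON protocol/calibration sidecar.
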