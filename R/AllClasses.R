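# Class definitions for the TIRF quantification chain. Constructors live
# next to the operations that produce each class; validity is enforced here.

#' OpticalConfig: TIRF instrument geometry
#'
#' Bundles the optical parameters that determine the evanescent field:
#' vacuum wavelength of the excitation laser (nm), refractive indices of
#' the imaging solution and the coverslip, and the incidence angle of the
#' beam (degrees, measured from the normal). All user-facing angles are in
#' degrees; radians are used internally only.
#'
#' @slot wavelength numeric(1), vacuum wavelength in nm, > 0.
#' @slot nSolution numeric(1), refractive index of the solution (>= 1).
#' @slot nCoverslip numeric(1), refractive index of the coverslip,
#'   strictly greater than `nSolution` (total internal reflection
#'   requires the denser medium on the incident side).
#' @slot incidenceAngle numeric(1), incidence angle in degrees, in (0, 90).
#'
#' @seealso [opticalConfig()], [penetrationDepth()]
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  slots = c(
    wavelength = "numeric",
    nSolution = "numeric",
    nCoverslip = "numeric",
    incidenceAngle = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1L || object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive value (nm)")
  if (length(object@nSolution) != 1L || object@nSolution < 1)
    msg <- c(msg, "nSolution must be a single refractive index >= 1")
  if (length(object@nCoverslip) != 1L ||
      object@nCoverslip <= object@nSolution)
    msg <- c(msg, "nCoverslip must exceed nSolution")
  if (length(object@incidenceAngle) != 1L ||
      object@incidenceAngle <= 0 || object@incidenceAngle >= 90)
    msg <- c(msg, "incidenceAngle must lie in (0, 90) degrees")
  if (length(msg)) msg else TRUE
})

#' EvanescentField: derived field constants
#'
#' Critical angle (degrees), characteristic penetration depth d (nm) and
#' illumination decay constant tau = 1/d (per nm) of the evanescent field
#' produced by an [OpticalConfig-class].
#'
#' @slot criticalAngle numeric(1), degrees.
#' @slot depth numeric(1), nm; illumination falls to 1/e at this depth.
#' @slot decay numeric(1), per nm; exactly `1/depth`.
#'
#' @seealso [penetrationDepth()], [illuminationProfile()]
#' @exportClass EvanescentField
setClass("EvanescentField",
  slots = c(criticalAngle = "numeric", depth = "numeric", decay = "numeric")
)

setValidity("EvanescentField", function(object) {
  msg <- character()
  if (length(object@depth) != 1L || object@depth <= 0)
    msg <- c(msg, "depth must be a single positive length (nm)")
  if (length(object@decay) != 1L ||
      abs(object@decay * object@depth - 1) > 1e-9)
    msg <- c(msg, "decay must equal 1/depth")
  if (length(object@criticalAngle) != 1L ||
      object@criticalAngle <= 0 || object@criticalAngle >= 90)
    msg <- c(msg, "criticalAngle must lie in (0, 90) degrees")
  if (length(msg)) msg else TRUE
})

#' LayerGrid: discretized illumination profile
#'
#' The cytosol above the coverslip is discretized into `nLayers` layers of
#' `layerThickness` nm each (layer 0 holds the membrane and associated
#' proteins). `illumination` gives the relative excitation intensity of
#' each layer, sampled at the layer's coverslip-proximal edge so that the
#' membrane layer has intensity exactly 1.
#'
#' @slot layerThickness numeric(1), nm (default grid uses 10 nm, the
#'   approximate size of a PH-domain biosensor).
#' @slot nLayers integer(1), number of layers (default grid uses 50,
#'   beyond which the field is negligible).
#' @slot illumination numeric vector of per-layer relative intensities;
#'   positive, non-increasing, first element 1.
#'
#' @seealso [illuminationProfile()], [membraneFraction()]
#' @exportClass LayerGrid
setClass("LayerGrid",
  slots = c(
    layerThickness = "numeric",
    nLayers = "integer",
    illumination = "numeric"
  )
)

setValidity("LayerGrid", function(object) {
  msg <- character()
  if (length(object@layerThickness) != 1L || object@layerThickness <= 0)
    msg <- c(msg, "layerThickness must be a single positive length (nm)")
  if (length(object@nLayers) != 1L || object@nLayers < 1L)
    msg <- c(msg, "nLayers must be at least 1")
  I <- object@illumination
  if (length(I) != object@nLayers)
    msg <- c(msg, "length(illumination) must equal nLayers")
  if (any(I <= 0))
    msg <- c(msg, "illumination must be strictly positive")
  if (length(I) && abs(I[1L] - 1) > 1e-12)
    msg <- c(msg, "illumination[1] (membrane layer) must be 1")
  if (length(I) > 1L && any(diff(I) > 0))
    msg <- c(msg, "illumination must be non-increasing with depth")
  if (length(msg)) msg else TRUE
})

#' RestingState: resting per-layer probe density
#'
#' Number of biosensor molecules per layer, m, at rest, under the
#' normalization that total baseline fluorescence F_initial = B * m *
#' sum(I) equals 1 (single-molecule brightness B is fixed to 1 by that
#' normalization).
#'
#' @slot density numeric(1), molecules per layer (m > 0).
#' @slot brightness numeric(1), per-molecule emission, fixed to 1.
#' @slot grid the [LayerGrid-class] the density was solved on.
#'
#' @seealso [solveRestingDensity()]
#' @exportClass RestingState
setClass("RestingState",
  slots = c(density = "numeric", brightness = "numeric", grid = "LayerGrid")
)

setValidity("RestingState", function(object) {
  msg <- character()
  if (length(object@density) != 1L || object@density <= 0)
    msg <- c(msg, "density (m) must be a single positive value")
  f0 <- object@brightness * object@density * sum(object@grid@illumination)
  if (abs(f0 - 1) > 1e-9)
    msg <- c(msg, "brightness * density * sum(illumination) must equal 1")
  if (length(msg)) msg else TRUE
})

#' TranslocationEstimate: inverted fold-change
#'
#' Result of inverting measured fold-changes F into recruited molecules
#' delta-m and the membrane enrichment ratio R_m = (m + delta_m)/m under a
#' named redistribution scenario. Slots are parallel vectors (one element
#' per input fold-change).
#'
#' @slot foldChange numeric, measured normalized fold-changes F.
#' @slot deltaM numeric, molecules recruited to the membrane layer.
#' @slot membraneRatio numeric, membrane enrichment ratio R_m.
#' @slot scenario character(1), `"fixed_total"` (recruited molecules are
#'   drawn evenly from all layers of a fixed pool) or `"fixed_cytosol"`
#'   (molecules are added to the membrane layer, cytosolic layers
#'   unchanged).
#'
#' @seealso [estimateTranslocation()]
#' @exportClass TranslocationEstimate
setClass("TranslocationEstimate",
  slots = c(
    foldChange = "numeric",
    deltaM = "numeric",
    membraneRatio = "numeric",
    scenario = "character"
  )
)

setValidity("TranslocationEstimate", function(object) {
  msg <- character()
  n <- length(object@foldChange)
  if (length(object@deltaM) != n || length(object@membraneRatio) != n)
    msg <- c(msg, "foldChange, deltaM and membraneRatio must be parallel")
  if (length(object@scenario) != 1L ||
      !object@scenario %in% c("fixed_total", "fixed_cytosol"))
    msg <- c(msg, "scenario must be 'fixed_total' or 'fixed_cytosol'")
  unit <- abs(object@foldChange - 1) < 1e-12
  if (any(unit & abs(object@deltaM) > 1e-9) ||
      any(unit & abs(object@membraneRatio - 1) > 1e-9))
    msg <- c(msg, "foldChange == 1 must imply deltaM == 0 and ratio == 1")
  if (length(msg)) msg else TRUE
})

#' TirfStack: a single-channel time-lapse image stack
#'
#' Frames are stored as a numeric array `(rows, cols, frames)` in camera
#' units, with a constant frame interval.
#'
#' @slot frames numeric array, dim = (height, width, >= 2 frames),
#'   non-negative.
#' @slot channelLabel character(1), e.g. `"biosensor"` or `"channel"`.
#' @slot frameInterval numeric(1), seconds between frames (> 0).
#' @slot startTime numeric(1), acquisition time of the first frame in
#'   seconds (on whatever clock the experiment uses; traces are later
#'   re-expressed relative to treatment application).
#'
#' @seealso [tirfStack()], [extractTrace()], [footprintTrace()]
#' @exportClass TirfStack
setClass("TirfStack",
  slots = c(
    frames = "array",
    channelLabel = "character",
    frameInterval = "numeric",
    startTime = "numeric"
  )
)

setValidity("TirfStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array (rows, cols, frames)")
  else if (d[3L] < 2L)
    msg <- c(msg, "a stack needs at least 2 frames")
  if (any(object@frames < 0))
    msg <- c(msg, "frame intensities must be non-negative")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive duration (s)")
  if (length(object@channelLabel) != 1L)
    msg <- c(msg, "channelLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' RoiSet: footprint and background regions of interest
#'
#' Two disjoint, non-empty boolean masks over the image plane: the cell
#' footprint and a background region used for offset subtraction.
#'
#' @slot cellMask logical matrix.
#' @slot backgroundMask logical matrix, same dimensions, disjoint from
#'   `cellMask`.
#'
#' @seealso [roiSet()], [polygonMask()], [footprintTrace()]
#' @exportClass RoiSet
setClass("RoiSet",
  slots = c(cellMask = "matrix", backgroundMask = "matrix")
)

setValidity("RoiSet", function(object) {
  msg <- character()
  cm <- object@cellMask
  bm <- object@backgroundMask
  if (!is.logical(cm) || !is.logical(bm))
    msg <- c(msg, "masks must be logical matrices")
  else {
    if (!identical(dim(cm), dim(bm)))
      msg <- c(msg, "masks must share dimensions")
    else if (any(cm & bm))
      msg <- c(msg, "cell and background masks must be disjoint")
    if (!any(cm) || !any(bm))
      msg <- c(msg, "masks must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' FootprintTrace: one cell's processed time course
#'
#' Parallel vectors holding a footprint's mean-intensity time course at
#' each processing stage: raw ROI mean, background ROI mean, the
#' background-corrected difference, and the baseline-normalized trace
#' (dimensionless; baseline window mean = 1). Time is in seconds relative
#' to treatment application (t = 0).
#'
#' @slot time numeric, seconds relative to application.
#' @slot raw numeric, camera units.
#' @slot background numeric, camera units.
#' @slot corrected numeric, camera units.
#' @slot normalized numeric, dimensionless.
#'
#' @seealso [footprintTrace()], [windowSummary()]
#' @exportClass FootprintTrace
setClass("FootprintTrace",
  slots = c(
    time = "numeric",
    raw = "numeric",
    background = "numeric",
    corrected = "numeric",
    normalized = "numeric"
  )
)

setValidity("FootprintTrace", function(object) {
  n <- length(object@time)
  ok <- length(object@raw) == n && length(object@background) == n &&
    length(object@corrected) == n && length(object@normalized) == n
  if (!ok) "all trace vectors must have equal length" else TRUE
})

#' TreatmentWindow: a summary window relative to application
#'
#' Half-open interval `[start, end)` in minutes relative to treatment
#' application, over which a normalized trace is averaged.
#'
#' @slot start numeric(1), minutes, >= 0.
#' @slot end numeric(1), minutes, > start.
#'
#' @seealso [treatmentWindow()], [windowPresets()], [windowSummary()]
#' @exportClass TreatmentWindow
setClass("TreatmentWindow", slots = c(start = "numeric", end = "numeric"))

setValidity("TreatmentWindow", function(object) {
  if (length(object@start) != 1L || length(object@end) != 1L ||
      object@start < 0 || object@start >= object@end)
    "window must satisfy 0 <= start < end (minutes)" else TRUE
})

#' Cohort: per-cell window summaries for one condition
#'
#' @slot condition character(1) label, e.g. `"responder"` or `"vehicle"`.
#' @slot values numeric vector of per-cell window summaries (finite,
#'   length >= 1).
#'
#' @seealso [cohort()], [summarizeCohorts()], [compareCohorts()]
#' @exportClass Cohort
setClass("Cohort", slots = c(condition = "character", values = "numeric"))

setValidity("Cohort", function(object) {
  msg <- character()
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (length(object@values) < 1L || any(!is.finite(object@values)))
    msg <- c(msg, "values must be a non-empty finite vector")
  if (length(msg)) msg else TRUE
})

#' KineticParams: per-cell recruitment kinetics
#'
#' Parameters of the simulated recruitment time course: after `delay`
#' seconds the recruited-molecule count rises exponentially (time constant
#' `riseTau`) toward `amplitude`, then relaxes with time constant
#' `decayTau` toward `plateauFraction * amplitude`. `plateauFraction = 1`
#' gives a monotone, non-reversing rise.
#'
#' @slot amplitude numeric(1), peak recruited molecules (>= 0).
#' @slot delay numeric(1), seconds after application before onset (>= 0).
#' @slot riseTau numeric(1), seconds (> 0).
#' @slot decayTau numeric(1), seconds (> 0; may be `Inf`).
#' @slot plateauFraction numeric(1), in (0, 1].
#'
#' @seealso [kineticParams()], [recruitmentCurve()]
#' @exportClass KineticParams
setClass("KineticParams",
  slots = c(
    amplitude = "numeric",
    delay = "numeric",
    riseTau = "numeric",
    decayTau = "numeric",
    plateauFraction = "numeric"
  )
)

setValidity("KineticParams", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1L || object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single value >= 0")
  if (length(object@delay) != 1L || object@delay < 0)
    msg <- c(msg, "delay must be >= 0 seconds")
  if (length(object@riseTau) != 1L || object@riseTau <= 0)
    msg <- c(msg, "riseTau must be > 0 seconds")
  if (length(object@decayTau) != 1L || object@decayTau <= 0)
    msg <- c(msg, "decayTau must be > 0 seconds (Inf allowed)")
  if (length(object@plateauFraction) != 1L ||
      object@plateauFraction <= 0 || object@plateauFraction > 1)
    msg <- c(msg, "plateauFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: recipe for one simulated condition
#'
#' Describes how per-cell response amplitudes are drawn for one simulated
#' condition. Amplitudes are log-normal (right-skewed, as translocation
#' responses are in practice) with the given log-mean and log-sd, scaled
#' by `direction` (+1 for recruitment, -1 for a decline below baseline as
#' under kinase inhibition); `template` records which named preset built
#' the spec.
#'
#' @slot condition character(1) label.
#' @slot nCells integer(1), >= 1.
#' @slot template character(1), one of `"responder"`, `"vehicle"`,
#'   `"inhibitor"`, `"custom"`.
#' @slot amplitudeMeanlog,amplitudeSdlog numeric(1), log-normal parameters
#'   of the per-cell amplitude magnitude (an amplitude of exactly 0 is
#'   expressed as `amplitudeMeanlog = -Inf`).
#' @slot direction numeric(1), +1 or -1.
#' @slot kinetics [KineticParams-class] shared by all cells of the
#'   condition (its `amplitude` slot is overridden per cell).
#'
#' @seealso [cohortSpec()], [generateCohorts()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  slots = c(
    condition = "character",
    nCells = "integer",
    template = "character",
    amplitudeMeanlog = "numeric",
    amplitudeSdlog = "numeric",
    direction = "numeric",
    kinetics = "KineticParams"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nCells) != 1L || object@nCells < 1L)
    msg <- c(msg, "nCells must be >= 1")
  if (length(object@amplitudeSdlog) != 1L || object@amplitudeSdlog < 0)
    msg <- c(msg, "amplitudeSdlog must be >= 0")
  if (!object@direction %in% c(-1, 1))
    msg <- c(msg, "direction must be +1 or -1")
  if (length(msg)) msg else TRUE
})
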