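# Layered-cytosol redistribution model: invert a baseline-normalized
# fold-change F into recruited molecules delta-m and the membrane
# enrichment ratio R_m, or run the same equations forward for simulation.
#
# Baseline: F_initial = B * sum_i m * I_i, normalized to 1 (so B = 1 and
# m = 1 / sum(I)). After stimulation, delta-m molecules occupy the
# membrane layer. Two bookkeeping scenarios for where they came from:
#   fixed_total:   F = dm*I_0 + sum_i (m - dm/N) * I_i
#                  (fixed pool, drawn evenly from all N layers)
#   fixed_cytosol: F = (m + dm)*I_0 + sum_{i>0} m * I_i
#                  (added at the membrane, cytosolic layers unchanged)
# Both are affine in dm, so closed forms are exact.

.scenarios <- c("fixed_total", "fixed_cytosol")

#' Solve the resting per-layer probe density
#'
#' With baseline fluorescence normalized to 1 and a uniform resting
#' distribution of the probe over all layers, the per-layer molecule
#' count is `m = 1 / sum(illumination)` (single-molecule brightness B is
#' absorbed by the normalization and fixed to 1).
#'
#' @param grid a [LayerGrid-class].
#' @return A [RestingState-class].
#' @examples
#' solveRestingDensity(illuminationProfile(0.008)) # m about 0.078
#' @export
solveRestingDensity <- function(grid) {
  stopifnot(is(grid, "LayerGrid"))
  new("RestingState",
    density = 1 / sum(grid@illumination), brightness = 1, grid = grid)
}

#' @rdname solveRestingDensity
#' @param object a [RestingState-class].
#' @export
setMethod("restingDensity", "RestingState", function(object) object@density)

#' @rdname solveRestingDensity
#' @export
setMethod("layerGrid", "RestingState", function(object) object@grid)

# shared scenario algebra: F = intercept + slope * dm, with I0 = I[1]
.scenarioSlope <- function(resting, scenario) {
  I <- resting@grid@illumination
  N <- resting@grid@nLayers
  switch(scenario,
    fixed_total = I[1L] - sum(I) / N,
    fixed_cytosol = I[1L]
  )
}

#' Invert a fold-change into recruited molecules
#'
#' Solves the redistribution equation for the number of molecules
#' delta-m moved to the membrane layer given a measured normalized
#' fold-change F. Both scenario equations are affine in delta-m, so the
#' closed-form solution is exact.
#'
#' Fold-changes below 1 describe depletion of the probe from the field
#' (for example under kinase inhibition) and are outside the
#' redistribution model; they are rejected unless `allowDepletion = TRUE`,
#' which extrapolates to negative delta-m with a warning. Under
#' `fixed_total`, the fold-change also may not exceed the value reached
#' when every molecule in the pool sits at the membrane
#' (`N * m * I[0]`), beyond which the implied cytosolic density is
#' negative.
#'
#' @param foldChange numeric vector of measured fold-changes F.
#' @param resting a [RestingState-class].
#' @param scenario `"fixed_total"` or `"fixed_cytosol"`.
#' @param allowDepletion accept F < 1 (delta-m < 0) with a warning.
#' @return Numeric vector of delta-m values, parallel to `foldChange`.
#' @examples
#' rest <- solveRestingDensity(illuminationProfile(0.008))
#' solveDeltaM(1.54, rest, "fixed_total")   # about 0.73
#' solveDeltaM(1.54, rest, "fixed_cytosol") # 0.54
#' @export
solveDeltaM <- function(foldChange, resting,
                        scenario = c("fixed_total", "fixed_cytosol"),
                        allowDepletion = FALSE) {
  stopifnot(is(resting, "RestingState"), is.numeric(foldChange))
  scenario <- match.arg(scenario)
  if (any(!is.finite(foldChange)))
    stop("fold-changes must be finite")
  if (any(foldChange < 1)) {
    if (!allowDepletion)
      stop("depletion not modeled: fold-change below 1 ",
           "(use allowDepletion = TRUE to extrapolate)")
    warning("fold-change below 1: extrapolating to negative delta-m ",
            "(probe depletion)")
  }
  slope <- .scenarioSlope(resting, scenario)
  if (abs(slope) < 1e-14)
    stop("degenerate grid: fold-change does not depend on delta-m ",
         "under the ", scenario, " scenario")
  dm <- (foldChange - 1) / slope
  if (scenario == "fixed_total") {
    dmMax <- resting@grid@nLayers * resting@density
    if (any(dm > dmMax + 1e-12))
      stop("fold-change above the fixed_total maximum (",
           format(1 + slope * dmMax),
           "): implies negative cytosolic density")
  }
  dm
}

#' Forward fold-change from recruited molecules
#'
#' Evaluates the scenario's redistribution equation: the exact inverse of
#' [solveDeltaM()]. Used by the synthetic-data generator and in
#' round-trip tests.
#'
#' @param resting a [RestingState-class].
#' @param deltaM numeric vector of recruited-molecule counts.
#' @inheritParams solveDeltaM
#' @return Numeric vector of fold-changes F.
#' @examples
#' rest <- solveRestingDensity(illuminationProfile(0.008))
#' forwardFoldChange(rest, 0.54, "fixed_cytosol") # 1.54
#' @export
forwardFoldChange <- function(resting, deltaM,
                              scenario = c("fixed_total", "fixed_cytosol"),
                              allowDepletion = FALSE) {
  stopifnot(is(resting, "RestingState"), is.numeric(deltaM))
  scenario <- match.arg(scenario)
  if (any(deltaM < 0) && !allowDepletion)
    stop("depletion not modeled: delta-m below 0 ",
         "(use allowDepletion = TRUE)")
  if (scenario == "fixed_total") {
    dmMax <- resting@grid@nLayers * resting@density
    if (any(deltaM > dmMax + 1e-12))
      stop("delta-m above the pool size ", format(dmMax),
           ": implies negative cytosolic density")
  }
  1 + .scenarioSlope(resting, scenario) * deltaM
}

#' Membrane enrichment ratio
#'
#' `R_m = (m + delta_m) / m`: the ratio of membrane-layer molecules after
#' versus before stimulation — the model's headline output. The
#' illumination of the membrane layer cancels, so R_m is independent of
#' absolute brightness and of the baseline fluorescence of the cell.
#'
#' @param object a [RestingState-class] (with `deltaM` supplied), or a
#'   [TranslocationEstimate-class] (accessor).
#' @param deltaM recruited-molecule count(s), >= 0 (RestingState method).
#' @param ... unused.
#' @return Numeric R_m value(s).
#' @examples
#' rest <- solveRestingDensity(illuminationProfile(0.008))
#' membraneRatio(rest, deltaM = 0.725) # about 10
#' @export
setMethod("membraneRatio", "RestingState", function(object, deltaM, ...) {
  stopifnot(is.numeric(deltaM))
  (object@density + deltaM) / object@density
})

#' Estimate membrane translocation from measured fold-changes
#'
#' One-step wrapper: solves delta-m for each fold-change and computes the
#' membrane enrichment ratio R_m under the requested scenario.
#'
#' @inheritParams solveDeltaM
#' @return A [TranslocationEstimate-class]; coerce with `as.data.frame()`
#'   for a tidy table.
#' @examples
#' rest <- solveRestingDensity(illuminationProfile(0.008))
#' est <- estimateTranslocation(c(1, 1.54), rest, "fixed_total")
#' as.data.frame(est)
#' @export
estimateTranslocation <- function(foldChange, resting,
                                  scenario = c("fixed_total",
                                               "fixed_cytosol"),
                                  allowDepletion = FALSE) {
  scenario <- match.arg(scenario)
  dm <- solveDeltaM(foldChange, resting, scenario,
                    allowDepletion = allowDepletion)
  new("TranslocationEstimate",
    foldChange = as.numeric(foldChange),
    deltaM = dm,
    membraneRatio = membraneRatio(resting, dm),
    scenario = scenario
  )
}

#' @rdname estimateTranslocation
#' @param object a [TranslocationEstimate-class].
#' @export
setMethod("foldChange", "TranslocationEstimate", function(object)
  object@foldChange)

#' @rdname estimateTranslocation
#' @export
setMethod("deltaM", "TranslocationEstimate", function(object) object@deltaM)

#' @rdname estimateTranslocation
#' @export
setMethod("membraneRatio", "TranslocationEstimate", function(object, ...)
  object@membraneRatio)

#' @rdname estimateTranslocation
#' @export
setMethod("scenario", "TranslocationEstimate", function(object)
  object@scenario)

#' @rdname estimateTranslocation
#' @param x a [TranslocationEstimate-class].
#' @param row.names,optional,... passed over from the generic; unused.
#' @exportS3Method base::as.data.frame
as.data.frame.TranslocationEstimate <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(
    fold_change = x@foldChange,
    delta_m = x@deltaM,
    membrane_ratio = x@membraneRatio,
    scenario = x@scenario,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "RestingState", function(object) {
  cat("RestingState: m = ", sprintf("%.4f", object@density),
      " molecules/layer (B = ", object@brightness, ", ",
      object@grid@nLayers, " layers)\n", sep = "")
})

setMethod("show", "TranslocationEstimate", function(object) {
  cat("TranslocationEstimate (", object@scenario, "), ",
      length(object@foldChange), " value(s)\n", sep = "")
  print(utils::head(as.data.frame(object), 6L))
  if (length(object@foldChange) > 6L) cat("  ...\n")
})
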