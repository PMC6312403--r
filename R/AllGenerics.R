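# Generics. Accessor generics are grouped here; operation generics that
# dispatch on more than one input class are declared here too.

#' @export
setGeneric("criticalAngle", function(object, ...)
  standardGeneric("criticalAngle"))

#' @export
setGeneric("depth", function(object) standardGeneric("depth"))

#' @export
setGeneric("decay", function(object) standardGeneric("decay"))

#' @export
setGeneric("illuminationProfile", function(object, ...)
  standardGeneric("illuminationProfile"))

#' @export
setGeneric("illumination", function(object) standardGeneric("illumination"))

#' @export
setGeneric("layerThickness", function(object)
  standardGeneric("layerThickness"))

#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))

#' @export
setGeneric("restingDensity", function(object)
  standardGeneric("restingDensity"))

#' @export
setGeneric("layerGrid", function(object) standardGeneric("layerGrid"))

#' @export
setGeneric("foldChange", function(object) standardGeneric("foldChange"))

#' @export
setGeneric("deltaM", function(object) standardGeneric("deltaM"))

#' @export
setGeneric("scenario", function(object) standardGeneric("scenario"))

#' @export
setGeneric("membraneRatio", function(object, ...)
  standardGeneric("membraneRatio"))

#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))

#' @export
setGeneric("frameInterval", function(object)
  standardGeneric("frameInterval"))

#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @export
setGeneric("backgroundMask", function(object)
  standardGeneric("backgroundMask"))

#' @export
setGeneric("windowSummary", function(x, window, ...)
  standardGeneric("windowSummary"))

#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @export
setGeneric("cohortValues", function(object) standardGeneric("cohortValues"))
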