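# Evanescent-field optics: critical angle, penetration depth, and the
# discretized per-layer illumination profile.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct an optical configuration
#'
#' Defaults describe a typical objective-type TIRF setup: a 447 nm laser,
#' saline solution (n = 1.33) above a glass coverslip (n = 1.53), and a
#' 63 degree incidence angle.
#'
#' @param wavelength vacuum wavelength in nm.
#' @param nSolution refractive index of the solution.
#' @param nCoverslip refractive index of the coverslip.
#' @param incidenceAngle incidence angle in degrees.
#' @return An [OpticalConfig-class] object.
#' @examples
#' opticalConfig()
#' opticalConfig(wavelength = 514, incidenceAngle = 65)
#' @export
opticalConfig <- function(wavelength = 447, nSolution = 1.33,
                          nCoverslip = 1.53, incidenceAngle = 63) {
  new("OpticalConfig",
    wavelength = as.numeric(wavelength),
    nSolution = as.numeric(nSolution),
    nCoverslip = as.numeric(nCoverslip),
    incidenceAngle = as.numeric(incidenceAngle)
  )
}

#' Critical angle for total internal reflection
#'
#' The minimum incidence angle at which light traveling in the coverslip
#' is totally internally reflected at the solution interface:
#' `asin(nSolution / nCoverslip)`, returned in degrees.
#'
#' @param object either the solution refractive index (numeric), an
#'   [OpticalConfig-class], or an [EvanescentField-class] (accessor for
#'   the angle the field was computed with).
#' @param nCoverslip coverslip refractive index (numeric method only).
#' @param ... unused.
#' @return Critical angle in degrees.
#' @examples
#' criticalAngle(1.0, sqrt(2)) # 45
#' criticalAngle(opticalConfig())
#' @export
setMethod("criticalAngle", "numeric", function(object, nCoverslip, ...) {
  nSolution <- object
  if (length(nSolution) != 1L || length(nCoverslip) != 1L ||
      nSolution <= 0 || nCoverslip <= 0)
    stop("refractive indices must be single positive values")
  if (nSolution >= nCoverslip)
    stop("total internal reflection impossible: ",
         "nSolution must be less than nCoverslip")
  rad2deg(asin(nSolution / nCoverslip))
})

#' @rdname criticalAngle-numeric-method
#' @export
setMethod("criticalAngle", "OpticalConfig", function(object, ...) {
  criticalAngle(object@nSolution, object@nCoverslip)
})

#' @rdname criticalAngle-numeric-method
#' @export
setMethod("criticalAngle", "EvanescentField", function(object, ...) {
  object@criticalAngle
})

#' Penetration depth of the evanescent field
#'
#' For incidence above the critical angle, the evanescent illumination
#' decays as `exp(-h/d)` with distance `h` from the coverslip, where the
#' characteristic depth is
#' \deqn{d = \frac{\lambda_0}{4 \pi n_3}
#'   \left(\sin^2\theta - \sin^2\theta_c\right)^{-1/2}}
#' with \eqn{\lambda_0} the vacuum wavelength, \eqn{n_3} the coverslip
#' index, \eqn{\theta} the incidence angle and \eqn{\theta_c} the critical
#' angle. The decay constant is \eqn{\tau = 1/d}.
#'
#' By default the critical angle is computed from the configured
#' refractive indices; `criticalAngleOverride` substitutes an externally
#' supplied value (in degrees) instead, for reproducing published
#' calculations whose printed critical angle differs from the one implied
#' by their printed indices.
#'
#' @param config an [OpticalConfig-class].
#' @param criticalAngleOverride optional critical angle in degrees.
#' @return An [EvanescentField-class] with the critical angle used, the
#'   depth `d` (nm) and the decay constant `tau = 1/d` (per nm).
#' @examples
#' penetrationDepth(opticalConfig()) # d about 119 nm
#' penetrationDepth(opticalConfig(), criticalAngleOverride = 60.8)
#' @export
penetrationDepth <- function(config, criticalAngleOverride = NULL) {
  stopifnot(is(config, "OpticalConfig"))
  thetaC <- if (is.null(criticalAngleOverride)) {
    criticalAngle(config)
  } else {
    stopifnot(is.numeric(criticalAngleOverride),
              length(criticalAngleOverride) == 1L)
    as.numeric(criticalAngleOverride)
  }
  theta <- config@incidenceAngle
  if (theta <= thetaC)
    stop("no evanescent field: sub-critical incidence (theta = ",
         format(theta), " <= thetaC = ", format(thetaC), " degrees)")
  s2 <- sin(deg2rad(theta))^2 - sin(deg2rad(thetaC))^2
  d <- config@wavelength / (4 * pi * config@nCoverslip) / sqrt(s2)
  new("EvanescentField", criticalAngle = thetaC, depth = d, decay = 1 / d)
}

#' @rdname penetrationDepth
#' @param object an [EvanescentField-class].
#' @export
setMethod("depth", "EvanescentField", function(object) object@depth)

#' @rdname penetrationDepth
#' @export
setMethod("decay", "EvanescentField", function(object) object@decay)

#' Discretize the illumination profile into molecular layers
#'
#' Relative illumination of layer i (i = 0, 1, ...) is
#' `exp(-tau * i * layerThickness)`: each layer is sampled at its
#' coverslip-proximal edge, so the membrane layer (i = 0) has intensity
#' exactly 1. The default 50 layers of 10 nm span the distance at which
#' the field has become negligible; a warning is issued when the requested
#' truncation discards more than 5 percent of the infinite-series
#' illumination.
#'
#' @param object an [EvanescentField-class], or the decay constant `tau`
#'   (per nm) directly.
#' @param layerThickness layer height in nm (default 10, the approximate
#'   size of a PH-domain probe).
#' @param nLayers number of layers (default 50).
#' @param ... unused.
#' @return A [LayerGrid-class].
#' @examples
#' grid <- illuminationProfile(0.008)
#' sum(illumination(grid)) # about 12.77
#' @export
setMethod("illuminationProfile", "EvanescentField",
  function(object, layerThickness = 10, nLayers = 50, ...) {
    illuminationProfile(object@decay,
      layerThickness = layerThickness, nLayers = nLayers)
  })

#' @rdname illuminationProfile-EvanescentField-method
#' @export
setMethod("illuminationProfile", "numeric",
  function(object, layerThickness = 10, nLayers = 50, ...) {
    tau <- object
    if (length(tau) != 1L || tau < 0)
      stop("decay constant tau must be a single value >= 0")
    if (length(layerThickness) != 1L || layerThickness <= 0 ||
        length(nLayers) != 1L || nLayers < 1)
      stop("invalid grid: need layerThickness > 0 and nLayers >= 1")
    nLayers <- as.integer(nLayers)
    r <- exp(-tau * layerThickness)
    if (r^nLayers > 0.05)
      warning("grid truncation discards ",
              sprintf("%.1f%%", 100 * r^nLayers),
              " of the infinite-series illumination; ",
              "consider more layers")
    new("LayerGrid",
      layerThickness = as.numeric(layerThickness),
      nLayers = nLayers,
      illumination = exp(-tau * layerThickness * (seq_len(nLayers) - 1))
    )
  })

#' @rdname illuminationProfile-EvanescentField-method
#' @export
setMethod("illumination", "LayerGrid", function(object) object@illumination)

#' @rdname illuminationProfile-EvanescentField-method
#' @export
setMethod("layerThickness", "LayerGrid", function(object)
  object@layerThickness)

#' @rdname illuminationProfile-EvanescentField-method
#' @export
setMethod("nLayers", "LayerGrid", function(object) object@nLayers)

#' Fraction of total illumination collected from the membrane layer
#'
#' `I[0] / sum(I)`: under a uniform resting probe distribution this is
#' the fraction of the recorded baseline fluorescence that originates
#' from the membrane layer. If a `nominal` fraction is supplied (for
#' example a value quoted elsewhere for the same optics) and the computed
#' fraction differs from it by more than 5 percent relative, the
#' discrepancy is reported via `message()`; the computed value is always
#' returned.
#'
#' @param grid a [LayerGrid-class].
#' @param nominal optional fraction to check against.
#' @return The computed membrane fraction (dimensionless).
#' @examples
#' membraneFraction(illuminationProfile(0.008)) # about 0.078
#' @export
membraneFraction <- function(grid, nominal = NULL) {
  stopifnot(is(grid, "LayerGrid"))
  frac <- grid@illumination[1L] / sum(grid@illumination)
  if (!is.null(nominal) && abs(frac - nominal) > 0.05 * nominal)
    message("computed membrane fraction ", sprintf("%.4f", frac),
            " differs from the nominal ", sprintf("%.4f", nominal),
            "; reporting the computed value")
  frac
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n",
      "  wavelength:     ", object@wavelength, " nm\n",
      "  n (solution):   ", object@nSolution, "\n",
      "  n (coverslip):  ", object@nCoverslip, "\n",
      "  incidence:      ", object@incidenceAngle, " deg ",
      "(critical: ", sprintf("%.2f", criticalAngle(object)), " deg)\n",
      sep = "")
})

setMethod("show", "EvanescentField", function(object) {
  cat("EvanescentField\n",
      "  critical angle: ", sprintf("%.2f", object@criticalAngle),
      " deg\n",
      "  depth d:        ", sprintf("%.1f", object@depth), " nm\n",
      "  decay tau:      ", sprintf("%.5f", object@decay), " per nm\n",
      sep = "")
})

setMethod("show", "LayerGrid", function(object) {
  cat("LayerGrid: ", object@nLayers, " layers of ",
      object@layerThickness, " nm\n",
      "  total illumination: ", sprintf("%.3f", sum(object@illumination)),
      "\n",
      "  membrane fraction:  ",
      sprintf("%.4f", object@illumination[1L] / sum(object@illumination)),
      "\n", sep = "")
})
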