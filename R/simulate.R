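# Synthetic TIRF data generator: per-cell recruitment kinetics, layered
# fluorescence through the forward redistribution model, rendered noisy
# image stacks, and whole condition cohorts with ground truth.

#' Construct recruitment kinetics
#'
#' @param amplitude peak recruited molecules (>= 0).
#' @param delay onset delay after application (s).
#' @param riseTau rise time constant (s).
#' @param decayTau relaxation time constant (s); `Inf` for no relaxation.
#' @param plateauFraction fraction of the peak retained at steady state,
#'   in (0, 1]; 1 gives a monotone non-reversing rise.
#' @return A [KineticParams-class].
#' @export
kineticParams <- function(amplitude, delay = 20, riseTau = 60,
                          decayTau = 300, plateauFraction = 0.7) {
  new("KineticParams",
    amplitude = as.numeric(amplitude), delay = as.numeric(delay),
    riseTau = as.numeric(riseTau), decayTau = as.numeric(decayTau),
    plateauFraction = as.numeric(plateauFraction)
  )
}

#' Recruited-molecule time course
#'
#' Zero before `delay`, then an exponential rise toward the peak
#' amplitude with a partial exponential relaxation toward
#' `plateauFraction * amplitude`:
#' \deqn{\Delta m(t) = A \left(1 - e^{-(t - t_0)/\tau_r}\right)
#'   \left(p + (1 - p) e^{-(t - t_0)/\tau_d}\right)}
#' This is the simplest shape consistent with the two response classes
#' seen in practice: a biosensor that peaks and partially relaxes
#' (p < 1) and channel trafficking that rises without reversal (p = 1).
#'
#' @param params a [KineticParams-class].
#' @param time numeric vector, seconds relative to application.
#' @return Numeric vector of recruited-molecule counts, >= 0.
#' @export
recruitmentCurve <- function(params, time) {
  stopifnot(is(params, "KineticParams"), is.numeric(time))
  tt <- time - params@delay
  p <- params@plateauFraction
  out <- params@amplitude * (1 - exp(-tt / params@riseTau)) *
    (p + (1 - p) * exp(-tt / params@decayTau))
  out[tt < 0] <- 0
  out
}

#' Cell and background geometry for rendering
#'
#' An elliptical footprint plus a rectangular background region placed
#' away from the cell.
#'
#' @param dim frame dimensions (rows, cols).
#' @param center ellipse center (row, col), 1-based pixel coordinates.
#' @param radii ellipse radii (rows, cols) in pixels.
#' @param backgroundOrigin top-left corner (row, col) of the background
#'   rectangle.
#' @param backgroundSize rectangle size (rows, cols).
#' @return A list consumed by [renderStack()].
#' @export
renderGeometry <- function(dim = c(64L, 64L), center = c(32.5, 24.5),
                           radii = c(12, 16),
                           backgroundOrigin = c(8L, 46L),
                           backgroundSize = c(32L, 16L)) {
  list(dim = as.integer(dim), center = as.numeric(center),
       radii = as.numeric(radii),
       backgroundOrigin = as.integer(backgroundOrigin),
       backgroundSize = as.integer(backgroundSize))
}

#' Camera noise model
#'
#' Scaled-Poisson photon (shot) noise plus additive Gaussian read noise:
#' a pixel with mean intensity u (camera units) is drawn as
#' `Poisson(u * photonsPerUnit) / photonsPerUnit + N(0, readSd)`.
#' Defaults give a single-frame footprint-mean coefficient of variation
#' of roughly 1 percent for the default rendering levels.
#' `photonsPerUnit = 0` disables shot noise; `readSd = 0` disables read
#' noise.
#'
#' @param photonsPerUnit detected photons per camera unit (>= 0).
#' @param readSd read-noise standard deviation in camera units (>= 0).
#' @return A list consumed by [renderStack()].
#' @export
cameraNoise <- function(photonsPerUnit = 0.15, readSd = 1) {
  if (photonsPerUnit < 0 || readSd < 0)
    stop("noise parameters must be >= 0")
  list(photonsPerUnit = photonsPerUnit, readSd = readSd)
}

.restoreSeed <- function() {
  # snapshot the RNG state; returns a function restoring it
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  function() {
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Render a synthetic TIRF stack for one cell
#'
#' Fluorescence inside the footprint follows the forward redistribution
#' model: pixel mean = `backgroundLevel + baselineLevel * F(t)`, with
#' `F(t) = forwardFoldChange(resting, direction * recruitmentCurve(t))`.
#' Pixels outside the footprint sit at the camera offset
#' `backgroundLevel`. Camera noise is applied per pixel; the seed fully
#' determines the output.
#'
#' @param kinetics a [KineticParams-class].
#' @param resting a [RestingState-class].
#' @param times frame times, seconds relative to application (must
#'   include pre-application baseline frames).
#' @param geometry see [renderGeometry()].
#' @param noise see [cameraNoise()]; `NULL` for a noiseless render.
#' @param baselineLevel footprint fluorescence above offset at baseline
#'   (camera units).
#' @param backgroundLevel camera offset level (camera units).
#' @param scenario redistribution scenario for the forward model.
#' @param direction +1 for recruitment, -1 for depletion below baseline.
#' @param channel channel label for the stack.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return List with elements `stack` ([TirfStack-class]), `rois`
#'   ([RoiSet-class]) and `truth` (list: `time`, `foldChange`, `deltaM`,
#'   `kinetics`, `scenario`).
#' @export
renderStack <- function(kinetics, resting, times,
                        geometry = renderGeometry(),
                        noise = cameraNoise(),
                        baselineLevel = 100, backgroundLevel = 20,
                        scenario = c("fixed_total", "fixed_cytosol"),
                        direction = 1, channel = "biosensor",
                        seed = NULL) {
  stopifnot(is(kinetics, "KineticParams"), is(resting, "RestingState"),
            is.numeric(times), length(times) >= 2L)
  scenario <- match.arg(scenario)
  d <- geometry$dim
  if (any(geometry$center + geometry$radii > d + 0.5) ||
      any(geometry$backgroundOrigin + geometry$backgroundSize - 1L > d))
    stop("geometry larger than frame")
  if (!is.null(seed)) {
    restore <- .restoreSeed()
    on.exit(restore())
    set.seed(as.integer(seed))
  }

  dm <- direction * recruitmentCurve(kinetics, times)
  F <- forwardFoldChange(resting, dm, scenario,
                         allowDepletion = direction < 0)

  row <- matrix(seq_len(d[1L]), d[1L], d[2L])
  col <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  cell <- ((row - geometry$center[1L]) / geometry$radii[1L])^2 +
    ((col - geometry$center[2L]) / geometry$radii[2L])^2 <= 1
  bg <- row >= geometry$backgroundOrigin[1L] &
    row < geometry$backgroundOrigin[1L] + geometry$backgroundSize[1L] &
    col >= geometry$backgroundOrigin[2L] &
    col < geometry$backgroundOrigin[2L] + geometry$backgroundSize[2L]
  rois <- roiSet(cell, bg)

  nt <- length(times)
  mu <- array(backgroundLevel, dim = c(d, nt))
  cellIdx <- which(cell)
  for (t in seq_len(nt))
    mu[, , t][cellIdx] <- backgroundLevel + baselineLevel * F[t]

  px <- mu
  if (!is.null(noise)) {
    if (noise$photonsPerUnit < 0 || noise$readSd < 0)
      stop("noise parameters must be >= 0")
    if (noise$photonsPerUnit > 0)
      px[] <- rpois(length(mu), mu * noise$photonsPerUnit) /
        noise$photonsPerUnit
    if (noise$readSd > 0)
      px[] <- px + rnorm(length(mu), 0, noise$readSd)
    px[px < 0] <- 0
  }

  list(
    stack = tirfStack(px, channel = channel,
                      frameInterval = diff(times[1:2]),
                      startTime = times[1L]),
    rois = rois,
    truth = list(time = times, foldChange = F, deltaM = dm,
                 kinetics = kinetics, scenario = scenario)
  )
}

#' Construct a cohort specification
#'
#' Named templates encode the three condition archetypes of a
#' translocation experiment: `responder` (right-skewed, log-normal
#' positive amplitudes calibrated so the cohort window mean lands near a
#' 1.5-fold change), `vehicle` (no response: amplitude 0), and
#' `inhibitor` (a mild decline below baseline, as when the kinase
#' producing the probe's target lipid is blocked — window means around
#' 0.9). `custom` leaves every field to the caller.
#'
#' @param condition condition label.
#' @param nCells number of cells.
#' @param template one of `"responder"`, `"vehicle"`, `"inhibitor"`,
#'   `"custom"`.
#' @param amplitudeMeanlog,amplitudeSdlog log-normal parameters of the
#'   per-cell amplitude magnitude; override the template.
#' @param direction +1 (recruitment) or -1 (decline); overrides the
#'   template.
#' @param kinetics [KineticParams-class] shared by the cohort (amplitude
#'   slot overridden per cell); overrides the template.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(condition, nCells,
                       template = c("responder", "vehicle", "inhibitor",
                                    "custom"),
                       amplitudeMeanlog = NULL, amplitudeSdlog = NULL,
                       direction = NULL, kinetics = NULL) {
  template <- match.arg(template)
  defaults <- switch(template,
    responder = list(meanlog = log(0.75), sdlog = 0.6, dir = 1,
      kin = kineticParams(1, delay = 20, riseTau = 60, decayTau = 300,
                          plateauFraction = 0.7)),
    vehicle = list(meanlog = -Inf, sdlog = 0, dir = 1,
      kin = kineticParams(1, delay = 20, riseTau = 60, decayTau = 300,
                          plateauFraction = 0.7)),
    inhibitor = list(meanlog = log(0.17), sdlog = 0.3, dir = -1,
      kin = kineticParams(1, delay = 20, riseTau = 120, decayTau = Inf,
                          plateauFraction = 1)),
    custom = list(meanlog = NA_real_, sdlog = NA_real_, dir = 1,
      kin = kineticParams(1))
  )
  new("CohortSpec",
    condition = as.character(condition), nCells = as.integer(nCells),
    template = template,
    amplitudeMeanlog = as.numeric(
      if (is.null(amplitudeMeanlog)) defaults$meanlog
      else amplitudeMeanlog),
    amplitudeSdlog = as.numeric(
      if (is.null(amplitudeSdlog)) defaults$sdlog else amplitudeSdlog),
    direction = as.numeric(
      if (is.null(direction)) defaults$dir else direction),
    kinetics = if (is.null(kinetics)) defaults$kin else kinetics
  )
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec '", object@condition, "' (", object@template, "): n = ",
      object@nCells, ", direction ", object@direction, "\n", sep = "")
})

#' The default three-condition experiment
#'
#' Cohort sizes mirror a typical translocation study: a large responder
#' cohort, a small vehicle cohort, and an intermediate inhibitor cohort.
#'
#' @param nResponder,nVehicle,nInhibitor cells per condition.
#' @return List of [CohortSpec-class] objects.
#' @export
defaultExperiment <- function(nResponder = 100, nVehicle = 20,
                              nInhibitor = 60) {
  list(
    cohortSpec("responder", nResponder, "responder"),
    cohortSpec("vehicle", nVehicle, "vehicle"),
    cohortSpec("inhibitor", nInhibitor, "inhibitor")
  )
}

.defaultResting <- function() {
  solveRestingDensity(
    illuminationProfile(penetrationDepth(opticalConfig()))
  )
}

#' Generate ground-truthed condition cohorts
#'
#' Draws per-cell amplitudes for each [CohortSpec-class], synthesizes
#' the fold-change trajectory through the forward redistribution model,
#' and recovers per-cell window summaries through the real pipeline.
#' Two paths are available: `method = "render"` renders noisy image
#' stacks and runs the full image pipeline ([renderStack()],
#' [footprintTrace()]); `method = "trace"` is a fast path that skips
#' image rendering and perturbs the fold-change trace directly with
#' multiplicative Gaussian noise of standard deviation `traceNoiseSd`
#' (flagged in the output as `method`).
#'
#' Ground truth per cell is the noiseless window-mean fold-change and
#' the membrane ratio obtained by inverting it.
#'
#' @param specs list of [CohortSpec-class] objects.
#' @param resting a [RestingState-class]; default: the 50 x 10 nm grid of
#'   the default optics ([opticalConfig()]).
#' @param window summary window ([treatmentWindow()] or preset name).
#' @param baselineDuration baseline window length (s).
#' @param frameInterval seconds per frame.
#' @param preTime,postTime seconds of acquisition before and after
#'   application.
#' @param method `"trace"` (fast) or `"render"` (full image pipeline).
#' @param traceNoiseSd per-frame multiplicative noise of the fast path.
#' @param noise camera noise for the render path ([cameraNoise()]).
#' @param scenario forward-model scenario.
#' @param seed integer seed; fully determines the output.
#' @return List with `summaries` (data.frame: cell_id, condition,
#'   summary_value), `truth` (data.frame: cell_id, condition, amplitude,
#'   true_fold_change, true_membrane_ratio), `method`, `window` and
#'   `resting`.
#' @export
generateCohorts <- function(specs, resting = .defaultResting(),
                            window = "biosensor_late",
                            baselineDuration = 60, frameInterval = 10,
                            preTime = 120, postTime = 600,
                            method = c("trace", "render"),
                            traceNoiseSd = 0.01, noise = cameraNoise(),
                            scenario = "fixed_total", seed = NULL) {
  if (is(specs, "CohortSpec")) specs <- list(specs)
  stopifnot(all(vapply(specs, is, logical(1), "CohortSpec")))
  method <- match.arg(method)
  window <- .resolveWindow(window)
  if (!is.null(seed)) {
    restore <- .restoreSeed()
    on.exit(restore())
    set.seed(as.integer(seed))
  }
  times <- seq(-preTime, postTime, by = frameInterval)
  slope <- .scenarioSlope(resting, scenario)

  summaries <- list()
  truth <- list()
  for (spec in specs) {
    # all amplitudes are drawn before any measurement noise, so the two
    # methods see identical per-cell ground truth under the same seed
    amps <- if (is.finite(spec@amplitudeMeanlog)) {
      rlnorm(spec@nCells, spec@amplitudeMeanlog, spec@amplitudeSdlog)
    } else {
      rep(0, spec@nCells)
    }
    if (spec@direction > 0 && scenario == "fixed_total")
      # recruitment cannot exceed the fixed pool
      amps <- pmin(amps, resting@grid@nLayers * resting@density)
    for (i in seq_len(spec@nCells)) {
      amp <- amps[i]
      kp <- spec@kinetics
      kp@amplitude <- amp
      dm <- spec@direction * recruitmentCurve(kp, times)
      F <- forwardFoldChange(resting, dm, scenario,
                             allowDepletion = spec@direction < 0)
      trueF <- windowSummary(F, window, time = times)
      trueRm <- 1 + ((trueF - 1) / slope) / resting@density

      obs <- if (method == "trace") {
        F * (1 + rnorm(length(F), 0, traceNoiseSd))
      } else {
        rs <- renderStack(kp, resting, times, noise = noise,
                          scenario = scenario,
                          direction = spec@direction)
        tr <- footprintTrace(rs$stack, rs$rois, applicationTime = 0,
                             baselineDuration = baselineDuration)
        tr@normalized
      }
      if (method == "trace")
        obs <- normalizeBaseline(obs, times, baselineDuration)

      id <- paste0(spec@condition, "_", sprintf("%03d", i))
      summaries[[id]] <- data.frame(
        cell_id = id, condition = spec@condition,
        summary_value = windowSummary(obs, window, time = times),
        stringsAsFactors = FALSE
      )
      truth[[id]] <- data.frame(
        cell_id = id, condition = spec@condition, amplitude = amp,
        true_fold_change = trueF, true_membrane_ratio = trueRm,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
    truth = do.call(rbind, c(truth, make.row.names = FALSE)),
    method = method, window = window, resting = resting
  )
}
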