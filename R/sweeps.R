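## Shared worker: one classified run. Runs to tEnd; if more than one front
## remains (metastable competing peaks), the run is continued to extendTo
## with the stimulus already switched off (uniform post-stimulus input).
## Individual run failures are reported as a row with an error message, so
## a sweep always completes.
.classifiedRun <- function(shape, length, width, protocol, params,
                           nMesh, tEnd, extendTo, dtMax, recordBy,
                           threshold, absTol = 1e-9, relTol = 1e-7,
                           verbose = FALSE) {
  out <- data.frame(shape = shape, length = length, width = width,
                    direction = protocol@direction, tEnd = tEnd,
                    extended = FALSE, label = NA_character_,
                    axis = NA_character_, axisLength = NA_character_,
                    pattern = NA_character_, frontCount = NA_integer_,
                    deltaC = NA_real_, onsetTime = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  res <- try({
    geom <- makeShape(shape, length, width, nMesh)
    cfg <- solverConfig(tEnd = tEnd, dtMax = dtMax, absTol = absTol,
                        relTol = relTol,
                        recordTimes = seq(0, tEnd, by = recordBy))
    traj <- simulatePolarity(geom, params, protocol, cfg, verbose = verbose)
    onset <- onsetOfReversal(traj, protocol)
    if (countFronts(traj, threshold) > 1 && extendTo > tEnd) {
      quiet <- stimulusProtocol(protocol@direction,
                                intercept = protocol@postRate, slope = 0,
                                duration = 1, postRate = protocol@postRate)
      cfg2 <- solverConfig(tEnd = extendTo - tEnd, dtMax = dtMax,
                           absTol = absTol, relTol = relTol,
                           recordTimes = seq(0, extendTo - tEnd,
                                             by = recordBy))
      traj <- simulatePolarity(geom, params, quiet, cfg2,
                               initial = traj@finalState, verbose = verbose)
      out$extended <- TRUE
      out$tEnd <- extendTo
    }
    pat <- classifyPattern(traj, protocol, geom, threshold = threshold)
    out$label <- pat@label
    out$axis <- pat@axis
    out$axisLength <- pat@axisLength
    out$pattern <- pat@patternName
    out$frontCount <- pat@frontCount
    out$deltaC <- pat@deltaC
    out$onsetTime <- onset
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    out$error <- conditionMessage(attr(res, "condition"))
  out
}

#' Aspect-ratio sweep over cell length and width
#'
#' Runs one classified simulation per (length, width) combination of a
#' shape under a fixed stimulus, reproducing the systematic size/aspect
#' exploration. Runs whose final state still holds more than one
#' polarization front at \code{tEnd} are automatically continued to
#' \code{extendTo} seconds (stimulus off) before classification.
#'
#' @param shape shape name, see [makeShape()].
#' @param lengths,widths numeric vectors of extents in micrometres (the
#'   sweep covers their cartesian product).
#' @param protocol a [StimulusProtocol-class].
#' @param params a [PolarityParams-class].
#' @param nMesh grid resolution per run.
#' @param tEnd,extendTo run length and extension horizon (s).
#' @param dtMax splitting step (s).
#' @param recordBy record cadence (s).
#' @param threshold front-counting threshold (uM).
#' @param absTol,relTol solver tolerances per run (see [solverConfig()]);
#'   long categorical sweeps may use looser values than the quantitative
#'   defaults.
#' @param verbose print one line per run.
#' @return data.frame with one row per run: geometry, classification label,
#'   axis, combined pattern name, front count, deltaC, onset time, and an
#'   \code{error} column (\code{NA} on success).
#' @export
aspectRatioSweep <- function(shape, lengths, widths,
                             protocol = stimulusProtocol(),
                             params = polarityParams(), nMesh = 110,
                             tEnd = 1000, extendTo = 3000, dtMax = 0.25,
                             recordBy = 5, threshold = 3, absTol = 1e-9,
                             relTol = 1e-7, verbose = FALSE) {
  grid <- expand.grid(length = lengths, width = widths)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    if (verbose)
      message(sprintf("aspect sweep: %s %g x %g um", shape,
                      grid$length[k], grid$width[k]))
    .classifiedRun(shape, grid$length[k], grid$width[k], protocol, params,
                   nMesh, tEnd, extendTo, dtMax, recordBy, threshold,
                   absTol, relTol)
  })
  do.call(rbind, rows)
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Varies one parameter per series over the given values, at standard
#' geometry and stimulus, and classifies each run. By default both the
#' reference symmetric shape (50 um circle) and asymmetric shape (50 x 30
#' um teardrop) are analyzed.
#'
#' @param series named list: parameter symbol -> numeric vector of values,
#'   e.g. \code{list(n = c(1, 4, 8), d_C = c(0.01, 0.1, 1, 10))}.
#' @param shapes character vector of shape names.
#' @param dims named list of \code{c(length, width)} per shape; defaults to
#'   50 x 50 for symmetric and 50 x 30 for the drop shapes.
#' @inheritParams aspectRatioSweep
#' @return data.frame with one row per (shape, parameter, value).
#' @export
sensitivity1d <- function(series, shapes = c("circle", "teardrop"),
                          dims = NULL, protocol = stimulusProtocol(),
                          params = polarityParams(), nMesh = 110,
                          tEnd = 1000, extendTo = 3000, dtMax = 0.25,
                          recordBy = 5, threshold = 3, absTol = 1e-9,
                          relTol = 1e-7, verbose = FALSE) {
  if (is.null(names(series)) || any(names(series) == ""))
    stop("'series' must be a named list of parameter value vectors")
  if (is.null(dims))
    dims <- lapply(setNames(shapes, shapes), function(s)
      if (s %in% c("circle", "square")) c(50, 50) else c(50, 30))
  rows <- list()
  for (shape in shapes) {
    d <- dims[[shape]]
    for (pname in names(series)) for (val in series[[pname]]) {
      if (verbose)
        message(sprintf("sensitivity: %s, %s = %g", shape, pname, val))
      p <- params
      param(p, pname) <- val
      row <- .classifiedRun(shape, d[1], d[2], protocol, p, nMesh, tEnd,
                            extendTo, dtMax, recordBy, threshold,
                            absTol, relTol)
      row$parameter <- pname
      row$value <- val
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Phase diagram over (a1, d_C) at fixed Hill coefficients
#'
#' Classifies the polarization outcome on the cartesian grid of
#' Rho-inhibition strength \code{a1} and Cdc42 inactivation rate \code{d_C},
#' one slice per Hill coefficient \code{n}, for a given shape. The default
#' grids cover the values used in the published exploration (both 2 and
#' 2.25 as the high \code{a1}).
#'
#' @param nLevels Hill coefficients (slices).
#' @param a1Values,dValues grid values for \code{a1} (uM) and \code{d_C}
#'   (1/s).
#' @param shape shape name.
#' @param length,width shape extent (um).
#' @inheritParams aspectRatioSweep
#' @return data.frame with columns \code{n}, \code{a1}, \code{d}, the
#'   classification columns and \code{error}; every sampled point carries a
#'   label.
#' @export
phaseDiagram <- function(nLevels = c(1, 4, 8),
                         a1Values = c(0.5, 1.25, 2, 2.25),
                         dValues = c(0.01, 0.1, 1, 10),
                         shape = "circle", length = 50, width = 50,
                         protocol = stimulusProtocol(),
                         params = polarityParams(), nMesh = 110,
                         tEnd = 1000, extendTo = 3000, dtMax = 0.25,
                         recordBy = 5, threshold = 3, absTol = 1e-9,
                         relTol = 1e-7, verbose = FALSE) {
  grid <- expand.grid(n = nLevels, a1 = a1Values, d = dValues)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    if (verbose)
      message(sprintf("phase diagram: n = %g, a1 = %g, d = %g",
                      grid$n[k], grid$a1[k], grid$d[k]))
    p <- params
    param(p, "n") <- grid$n[k]
    param(p, "a1") <- grid$a1[k]
    param(p, "d_C") <- grid$d[k]
    row <- .classifiedRun(shape, length, width, protocol, p, nMesh, tEnd,
                          extendTo, dtMax, recordBy, threshold,
                          absTol, relTol)
    cbind(grid[k, , drop = FALSE], row, row.names = NULL)
  })
  do.call(rbind, rows)
}
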