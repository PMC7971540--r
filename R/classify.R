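#' Maximum-tracking series of a run
#'
#' @param trajectory a [PolarityTrajectory-class].
#' @return data.frame with columns \code{t} (s), \code{value} (uM),
#'   \code{x}, \code{y} (um, centroid of tied cells when the maximum is a
#'   plateau) and \code{degenerate}.
#' @export
trackMaximum <- function(trajectory) {
  data.frame(t = trajectory@times, value = trajectory@maxValue,
             x = trajectory@maxX, y = trajectory@maxY,
             degenerate = trajectory@degenerate)
}

#' Onset of the reverse shift of the Cdc42 maximum
#'
#' Finds the first record time at which the position of the active-Cdc42
#' maximum has retreated, opposite to the stimulus direction, by more than
#' one grid cell. The default rule measures retreat from the running extreme
#' of the position (the most advanced point reached so far), so that a brief
#' advance followed by retreat is still detected; \code{rule = "initial"}
#' instead measures retreat from the position at the first record time.
#'
#' @param trajectory a [PolarityTrajectory-class] from a directional
#'   stimulus with at least two record times.
#' @param protocol the stimulus protocol (default: the one stored on the
#'   trajectory).
#' @param rule \code{"extreme"} (default) or \code{"initial"}.
#' @return onset time in seconds, or \code{NA} if the maximum never
#'   retreats.
#' @export
onsetOfReversal <- function(trajectory, protocol = trajectory@protocol,
                            rule = c("extreme", "initial")) {
  rule <- match.arg(rule)
  if (length(trajectory@times) < 2L)
    stop("need at least two record times")
  h <- trajectory@geometry@h
  ## signed advance coordinate: grows towards the stimulated front
  s <- switch(protocol@direction,
    "L-R" = trajectory@maxX,
    "R-L" = -trajectory@maxX,
    "U-D" = -trajectory@maxY
  )
  ref <- if (rule == "extreme") cummax(s) else s[1L]
  hit <- which(ref - s > h)
  if (length(hit)) trajectory@times[hit[1L]] else NA_real_
}

#' Main-axis concentration drop from the maximum to the front
#'
#' Computes the difference between the maximal active-Cdc42 concentration
#' along the cell's main (horizontal) axis and its value at the front
#' extremity of that axis (the right end for an L-R stimulus, the left end
#' for R-L). A small value indicates a broad front reaching the membrane; a
#' large value indicates a maximum detached from the front.
#'
#' @param trajectory a [PolarityTrajectory-class].
#' @param time record time at which to evaluate (default: the last one);
#'   the nearest record time is used.
#' @param protocol stimulus protocol (default: stored on the trajectory);
#'   determines which end of the axis is the front.
#' @return concentration difference in uM (always >= 0).
#' @export
deltaC <- function(trajectory, time = max(trajectory@times),
                   protocol = trajectory@protocol) {
  k <- which.min(abs(trajectory@times - time))
  prof <- trajectory@profiles[k, ]
  front <- switch(protocol@direction,
    "R-L" = which.min(trajectory@profileX),
    which.max(trajectory@profileX)     # L-R and U-D: right end
  )
  max(prof) - prof[front]
}

#' Count disjoint polarization fronts
#'
#' Counts the 4-connected components of the super-level set
#' \code{C > threshold} of active Cdc42 over the cell interior. The
#' threshold corresponds to the white display level of the activity maps
#' (3 uM for standard-size runs; 8 uM for the large-cell regime).
#'
#' @param state a [StateField-class] (or a [PolarityTrajectory-class],
#'   whose final state is used).
#' @param threshold concentration threshold in uM (> 0, default 3).
#' @return integer number of fronts (0 if the field is everywhere below
#'   threshold).
#' @export
countFronts <- function(state, threshold = 3) {
  if (is(state, "PolarityTrajectory")) state <- state@finalState
  if (!(threshold > 0)) stop("threshold must be > 0")
  g <- state@geometry
  above <- matrix(FALSE, g@nx, g@ny)
  above[g@inside] <- state@values[, "C"] > threshold
  .nComponents4(above)
}

#' Classify the polarization outcome of a run
#'
#' Applies the categorical rules to the final state of a trajectory:
#' \itemize{
#'   \item \code{"uniform"} if the final max-min range of active Cdc42 is
#'     below \code{uniformTol} (default 0.01 uM);
#'   \item otherwise the final polarization axis is the axis (x or y) along
#'     which the projected field has the larger range; the outcome is
#'     \code{"normal"} if the final maximum lies within \code{edgeCells}
#'     grid cells of the cell extremity at the stimulated front along that
#'     axis (either extremity when the axis is the new, perpendicular one),
#'     and \code{"reverse"} otherwise.
#' }
#' The axis is reported as \code{"initial"} (the stimulus axis) or
#' \code{"new"}, and as the \code{"longer"} or \code{"shorter"} axis of the
#' shape, yielding the six combined pattern labels for directional runs.
#'
#' @param trajectory a [PolarityTrajectory-class] from a completed run.
#' @param protocol,geometry default to those stored on the trajectory.
#' @param threshold front-counting threshold (uM), see [countFronts()].
#' @param uniformTol max-min range below which the field counts as uniform
#'   (uM).
#' @param edgeCells how many grid cells from the extremity still count as
#'   "at" the extremity (default 2).
#' @return A [PolarityPattern-class].
#' @export
classifyPattern <- function(trajectory, protocol = trajectory@protocol,
                            geometry = trajectory@geometry, threshold = 3,
                            uniformTol = 0.01, edgeCells = 2) {
  Cv <- trajectory@finalState@values[, "C"]
  coords <- interiorCoords(geometry)
  h <- geometry@h
  k <- length(trajectory@times)
  fronts <- countFronts(trajectory@finalState, threshold)
  dC <- deltaC(trajectory, protocol = protocol)
  onset <- onsetOfReversal(trajectory, protocol)

  if (max(Cv) - min(Cv) < uniformTol) {
    return(new("PolarityPattern", label = "uniform", axis = NA_character_,
               axisLength = NA_character_, patternName = "uniform",
               frontCount = as.integer(fronts), deltaC = dC,
               onsetTime = onset))
  }

  ## steeper axis: larger range of the field projected (averaged) on x / y
  projRange <- function(pos) {
    m <- tapply(Cv, factor(round(pos / h)), mean)
    max(m) - min(m)
  }
  rx <- projRange(coords[, 1L])
  ry <- projRange(coords[, 2L])
  axisDim <- if (rx >= ry) "x" else "y"
  stimDim <- if (protocol@direction == "U-D") "y" else "x"
  axis <- if (axisDim == stimDim) "initial" else "new"
  extent <- if (axisDim == "x") geometry@length else geometry@width
  other <- if (axisDim == "x") geometry@width else geometry@length
  axisLength <- if (extent >= other) "longer" else "shorter"

  ## position of the final maximum along the polarization axis, versus the
  ## mask extremity at the stimulated front (or either end on the new axis)
  pos <- if (axisDim == "x") trajectory@maxX[k] else trajectory@maxY[k]
  lo <- min(coords[, if (axisDim == "x") 1L else 2L])
  hi <- max(coords[, if (axisDim == "x") 1L else 2L])
  tol <- edgeCells * h
  atEnd <- if (axis == "initial") {
    frontHigh <- switch(protocol@direction,
                        "L-R" = TRUE, "R-L" = FALSE, "U-D" = FALSE)
    if (frontHigh) (hi - pos) <= tol else (pos - lo) <= tol
  } else {
    (hi - pos) <= tol || (pos - lo) <= tol
  }
  label <- if (atEnd) "normal" else "reverse"
  patternName <- sprintf("%s, %s %s axis",
                         if (label == "reverse") "reverse polarization"
                         else "polarization",
                         axisLength, axis)
  new("PolarityPattern", label = label, axis = axis,
      axisLength = axisLength, patternName = patternName,
      frontCount = as.integer(fronts), deltaC = dC, onsetTime = onset)
}

setMethod("show", "PolarityPattern", function(object) {
  cat(sprintf("PolarityPattern: %s\n", object@patternName))
  cat(sprintf("  fronts = %d, deltaC = %.4g uM, onset = %s\n",
              object@frontCount, object@deltaC,
              if (is.na(object@onsetTime)) "none"
              else sprintf("%g s", object@onsetTime)))
})
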