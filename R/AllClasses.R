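#' @import methods
#' @importFrom stats setNames
NULL

## Species held in a StateField, in storage order. Active GTPases first
## (membrane-bound, slow diffusion), then inactive (cytosolic, fast), then
## the three phosphoinositides (membrane, intermediate).
.SPECIES <- c("C", "Ci", "R", "Ri", "rho", "rhoi", "P1", "P2", "P3")

#' Rasterized cell-shape mask on a regular grid
#'
#' A \code{CellGeometry} holds the interior of a static 2D cell shape as a
#' boolean mask over a regular square-cell grid, together with the physical
#' grid spacing and the shape's bounding-box dimensions. Coordinates are
#' measured in micrometres from the left (x) and bottom (y) edges of the
#' shape's bounding box; cell centres sit at \code{(i - 1/2) h} offsets.
#'
#' @slot nx,ny integer, number of grid cells along x and y.
#' @slot h numeric, grid spacing in micrometres (equal in x and y).
#' @slot inside logical matrix (\code{nx} by \code{ny}); \code{TRUE} marks
#'   cells belonging to the cell interior.
#' @slot shapeName character label, e.g. \code{"circle"} or \code{"teardrop"}.
#' @slot length,width numeric, shape extent along x and y in micrometres.
#' @slot x,y numeric vectors of cell-centre coordinates (micrometres from the
#'   shape's left/bottom bounding-box edge).
#'
#' @seealso [makeShape()], [importMask()]
#' @export
setClass("CellGeometry",
  representation(
    nx = "integer", ny = "integer", h = "numeric",
    inside = "matrix", shapeName = "character",
    length = "numeric", width = "numeric",
    x = "numeric", y = "numeric"
  )
)

setValidity("CellGeometry", function(object) {
  msg <- character()
  ins <- object@inside
  if (!is.logical(ins)) msg <- c(msg, "'inside' must be a logical matrix")
  if (nrow(ins) != object@nx || ncol(ins) != object@ny)
    msg <- c(msg, "'inside' dimensions must match nx, ny")
  if (!any(ins)) msg <- c(msg, "mask is empty")
  if (object@h <= 0) msg <- c(msg, "grid spacing h must be positive")
  if (any(ins)) {
    if (.nComponents4(ins) != 1L)
      msg <- c(msg, "mask interior must be a single 4-connected component")
    ## bounding box of the raster must agree with the declared length/width
    ## to within one grid cell per side
    ix <- range(which(rowSums(ins) > 0))
    iy <- range(which(colSums(ins) > 0))
    bbL <- (ix[2] - ix[1] + 1) * object@h
    bbW <- (iy[2] - iy[1] + 1) * object@h
    if (abs(bbL - object@length) > 2 * object@h)
      msg <- c(msg, "raster x-extent disagrees with 'length'")
    if (abs(bbW - object@width) > 2 * object@h)
      msg <- c(msg, "raster y-extent disagrees with 'width'")
  }
  if (length(msg)) msg else TRUE
})

#' Kinetic parameter set for the polarization model
#'
#' Named collection of all rate constants, Hill coefficients, diffusion
#' coefficients and basal levels of the nine-species Rho GTPase /
#' phosphoinositide network. Defaults reproduce the standard parameterization
#' of the model (see [polarityParams()] for the list of symbols and values).
#'
#' @slot values named numeric vector of parameter values.
#' @seealso [polarityParams()], [param()]
#' @export
setClass("PolarityParams", representation(values = "numeric"))

setValidity("PolarityParams", function(object) {
  v <- object@values
  msg <- character()
  missing <- setdiff(names(.defaultParamValues()), names(v))
  if (length(missing))
    msg <- c(msg, paste("missing parameters:", paste(missing, collapse = ", ")))
  unknown <- setdiff(names(v), names(.defaultParamValues()))
  if (length(unknown))
    msg <- c(msg, paste("unknown parameters:", paste(unknown, collapse = ", ")))
  if (!length(msg)) {
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all parameter values must be finite and >= 0")
    else {
      if (v["f"] > 1) msg <- c(msg, "feedback strength f must lie in [0, 1]")
      if (v["D_m"] >= v["D_mc"])
        msg <- c(msg, "active-form diffusion D_m must be smaller than inactive-form D_mc")
      if (any(v[c("C_tot", "R_tot", "rho_tot")] == 0))
        msg <- c(msg, "total GTPase levels must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Transient graded Cdc42 activation stimulus
#'
#' Describes the initial polarization protocol: a spatially linear Cdc42
#' activation rate applied for a fixed duration, after which the rate drops
#' to a uniform baseline. The \code{direction} names the axis and sense of
#' the gradient; the second letter marks the prospective cell front (the
#' high-activation end): \code{"L-R"} puts the front at the right (+x),
#' \code{"R-L"} at the left, \code{"U-D"} at the bottom.
#'
#' @slot direction one of \code{"L-R"}, \code{"R-L"}, \code{"U-D"}.
#' @slot intercept numeric, activation rate at the low end (uM/s).
#' @slot slope numeric, spatial gradient of the rate (uM/s per um).
#' @slot duration numeric, stimulus duration in seconds (\code{Inf} for a
#'   sustained stimulus).
#' @slot postRate numeric, uniform activation rate after the stimulus (uM/s).
#' @seealso [stimulusProtocol()], [cdc42InputRate()]
#' @export
setClass("StimulusProtocol",
  representation(direction = "character", intercept = "numeric",
                 slope = "numeric", duration = "numeric", postRate = "numeric")
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!object@direction %in% c("L-R", "R-L", "U-D"))
    msg <- c(msg, "direction must be one of 'L-R', 'R-L', 'U-D'")
  if (object@intercept < 0 || object@slope < 0)
    msg <- c(msg, "intercept and slope must be >= 0")
  if (!(object@duration > 0))
    msg <- c(msg, "duration must be positive (Inf for sustained)")
  if (object@postRate < 0) msg <- c(msg, "postRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-integration settings for the PDE solver
#'
#' @slot dtMax numeric, largest splitting step (s).
#' @slot absTol,relTol numeric, local error tolerances for the reaction
#'   integrator (uM and relative).
#' @slot tEnd numeric, final time (s).
#' @slot recordTimes numeric, times at which the spatial maximum and the
#'   main-axis profile are recorded; also hard step targets.
#' @slot snapshotTimes numeric, times at which full nine-species snapshots
#'   are kept.
#' @seealso [solverConfig()], [simulatePolarity()]
#' @export
setClass("SolverConfig",
  representation(dtMax = "numeric", absTol = "numeric", relTol = "numeric",
                 tEnd = "numeric", recordTimes = "numeric",
                 snapshotTimes = "numeric")
)

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (object@dtMax <= 0) msg <- c(msg, "dtMax must be positive")
  if (object@absTol <= 0 || object@relTol <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (object@tEnd <= 0) msg <- c(msg, "tEnd must be positive")
  if (any(object@recordTimes < 0) || any(object@recordTimes > object@tEnd))
    msg <- c(msg, "recordTimes must lie in [0, tEnd]")
  if (length(msg)) msg else TRUE
})

#' Nine-species concentration state over a cell mask
#'
#' Concentrations (uM) of active/inactive Cdc42 (\code{C}, \code{Ci}), Rac
#' (\code{R}, \code{Ri}) and Rho (\code{rho}, \code{rhoi}) and of the three
#' phosphoinositides (\code{P1}, \code{P2}, \code{P3}), one row per interior
#' grid cell of the associated geometry.
#'
#' @slot values numeric matrix, interior cells by species (columns named as
#'   above).
#' @slot geometry the [CellGeometry-class] the state lives on.
#' @seealso [initialState()], [speciesField()]
#' @export
setClass("StateField",
  representation(values = "matrix", geometry = "CellGeometry")
)

setValidity("StateField", function(object) {
  msg <- character()
  if (!identical(colnames(object@values), .SPECIES))
    msg <- c(msg, "state columns must be C, Ci, R, Ri, rho, rhoi, P1, P2, P3")
  if (nrow(object@values) != sum(object@geometry@inside))
    msg <- c(msg, "state rows must match the number of interior cells")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "state must be finite everywhere")
  if (any(object@values < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Recorded outcome of a polarization simulation
#'
#' Holds the maximum-tracking series of active Cdc42 (time, value, position),
#' main-axis concentration profiles at the record times, optional full
#' snapshots, the final state, and a structured solver log (step count,
#' per-GTPase relative mass drift, clipping events).
#'
#' @slot times numeric, record times (s), strictly increasing.
#' @slot maxValue numeric, spatial maximum of active Cdc42 at each record
#'   time (uM).
#' @slot maxX,maxY numeric, position of the maximum (um from the shape's
#'   left/bottom edge; centroid of the tied cells when degenerate).
#' @slot degenerate logical, whether the maximum was a plateau (tie-broken
#'   by centroid).
#' @slot profiles numeric matrix, record times by main-axis cells: active
#'   Cdc42 along the horizontal midline.
#' @slot profileX numeric, x-coordinates of the main-axis cells (um).
#' @slot snapshots named list of state matrices at the snapshot times.
#' @slot finalState [StateField-class] at \code{tEnd}.
#' @slot geometry,protocol,params the inputs the run was made from.
#' @slot log list with elements \code{nSteps}, \code{massDrift} (named, per
#'   GTPase), \code{minValue}, \code{nClipped}.
#' @seealso [simulatePolarity()], [trackMaximum()], [classifyPattern()]
#' @export
setClass("PolarityTrajectory",
  representation(times = "numeric", maxValue = "numeric",
                 maxX = "numeric", maxY = "numeric", degenerate = "logical",
                 profiles = "matrix", profileX = "numeric",
                 snapshots = "list", finalState = "StateField",
                 geometry = "CellGeometry", protocol = "StimulusProtocol",
                 params = "PolarityParams", log = "list")
)

setValidity("PolarityTrajectory", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "record times must be strictly increasing")
  n <- length(object@times)
  if (length(object@maxValue) != n || length(object@maxX) != n ||
      length(object@maxY) != n)
    msg <- c(msg, "max-tracking series must have one entry per record time")
  if (length(msg)) msg else TRUE
})

#' Categorical polarization outcome of a run
#'
#' The classification assigns one of three labels: \code{"uniform"} (final
#' max-min range of active Cdc42 below 0.01 uM), \code{"normal"}
#' (polarization: the final maximum sits at an extremity of the cell along
#' the final polarization axis) or \code{"reverse"} (the maximum has shifted
#' away from the extremity). The polarization axis is \code{"initial"} if
#' the final gradient is steeper along the stimulus axis than perpendicular
#' to it, otherwise \code{"new"}; \code{axisLength} says whether that axis
#' is the longer or shorter axis of the shape.
#'
#' @slot label one of \code{"uniform"}, \code{"normal"}, \code{"reverse"}.
#' @slot axis \code{"initial"} or \code{"new"} (\code{NA} for uniform).
#' @slot axisLength \code{"longer"} or \code{"shorter"} (\code{NA} for
#'   uniform).
#' @slot patternName combined six-category label, e.g.
#'   \code{"reverse polarization, longer new axis"}.
#' @slot frontCount integer, number of disjoint high-Cdc42 regions.
#' @slot deltaC numeric, maximum minus front-extremity concentration along
#'   the main axis (uM).
#' @slot onsetTime numeric, onset of the reverse shift of the maximum (s;
#'   \code{NA} if it never retreats).
#' @seealso [classifyPattern()]
#' @export
setClass("PolarityPattern",
  representation(label = "character", axis = "character",
                 axisLength = "character", patternName = "character",
                 frontCount = "integer", deltaC = "numeric",
                 onsetTime = "numeric")
)

setValidity("PolarityPattern", function(object) {
  msg <- character()
  if (!object@label %in% c("uniform", "normal", "reverse"))
    msg <- c(msg, "label must be 'uniform', 'normal' or 'reverse'")
  if (object@frontCount < 0L) msg <- c(msg, "frontCount must be >= 0")
  if (!is.na(object@deltaC) && object@deltaC < -1e-12)
    msg <- c(msg, "deltaC must be >= 0")
  if (length(msg)) msg else TRUE
})
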