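#' Construct a stimulus protocol
#'
#' The standard protocol applies a Cdc42 activation rate rising linearly
#' from \code{intercept} at the back of the cell by \code{slope} per
#' micrometre towards the front, for \code{duration} seconds; afterwards the
#' rate is a uniform \code{postRate}. The second letter of \code{direction}
#' names the prospective front: \code{"L-R"} puts the high-activation end at
#' the right edge, \code{"R-L"} at the left, \code{"U-D"} at the bottom.
#'
#' @param direction \code{"L-R"} (default), \code{"R-L"} or \code{"U-D"}.
#' @param intercept activation rate at the low end (uM/s, default 2.6).
#' @param slope spatial gradient (uM/s per um, default 0.05).
#' @param duration stimulus duration (s, default 10; \code{Inf} or
#'   \code{"sustained"} for a sustained stimulus).
#' @param postRate uniform activation rate after the stimulus (uM/s,
#'   default 2.95).
#' @return A [StimulusProtocol-class].
#' @examples
#' stimulusProtocol()                         # the standard 10 s L-R gradient
#' stimulusProtocol("U-D", duration = "sustained")
#' @export
stimulusProtocol <- function(direction = "L-R", intercept = 2.6,
                             slope = 0.05, duration = 10, postRate = 2.95) {
  if (identical(duration, "sustained")) duration <- Inf
  new("StimulusProtocol", direction = direction, intercept = intercept,
      slope = slope, duration = duration, postRate = postRate)
}

#' Spatial Cdc42 activation rate of a stimulus
#'
#' Evaluates the Cdc42 activation input at position(s) \code{(x, y)} and
#' time \code{t}. While the stimulus lasts the rate is
#' \code{intercept + slope * s} with \code{s} the distance from the back of
#' the cell along the stimulus axis (x from the left edge for \code{"L-R"},
#' mirrored for \code{"R-L"}, distance from the top for \code{"U-D"});
#' afterwards it is the uniform \code{postRate}.
#'
#' @param x,y position(s) in micrometres from the shape's left/bottom edge.
#' @param t time (s).
#' @param protocol a [StimulusProtocol-class].
#' @param geometry a [CellGeometry-class] (provides the cell extent used to
#'   mirror the gradient, and the point-inside check).
#' @param check if \code{TRUE} (default) reject points outside the mask.
#' @return activation rate(s) in uM/s.
#' @examples
#' geom <- makeShape("circle", 50, 50, 110)
#' cdc42InputRate(0, 25, 5, stimulusProtocol(), geom)    # 2.6
#' cdc42InputRate(50, 25, 5, stimulusProtocol(), geom)   # 5.1
#' cdc42InputRate(25, 25, 11, stimulusProtocol(), geom)  # 2.95
#' @export
cdc42InputRate <- function(x, y, t, protocol, geometry, check = TRUE) {
  if (check) {
    ## a point belongs to every closed cell containing it, so points on a
    ## cell edge (e.g. exactly on the mask boundary) are accepted when any
    ## adjacent cell is interior
    h <- geometry@h
    cand <- function(pos, centres, nmax) {
      i0 <- pmin(pmax(round((pos - centres[1]) / h) + 1, 1L), nmax)
      lapply(c(-1L, 0L, 1L), function(d) {
        i <- pmin(pmax(i0 + d, 1L), nmax)
        ok <- abs(pos - centres[i]) <= h / 2 + 1e-9
        list(i = i, ok = ok)
      })
    }
    cx <- cand(x, geometry@x, geometry@nx)
    cy <- cand(y, geometry@y, geometry@ny)
    hit <- rep(FALSE, max(length(x), length(y)))
    for (a in cx) for (b in cy)
      hit <- hit | (a$ok & b$ok & geometry@inside[cbind(a$i, b$i)])
    if (any(!hit)) stop("point(s) outside the cell mask")
  }
  if (any(t < 0)) stop("t must be >= 0")
  s <- switch(protocol@direction,
    "L-R" = x,
    "R-L" = geometry@length - x,
    "U-D" = geometry@width - y,
    stop("unknown stimulus direction")
  )
  n <- max(length(t), length(s))
  tt <- rep_len(t, n)
  ss <- rep_len(s, n)
  ifelse(tt <= protocol@duration,
         protocol@intercept + protocol@slope * ss,
         protocol@postRate)
}

## Activation-input vector over all interior cells at time t (internal,
## called once per splitting step by the solver).
.stimulusField <- function(coords, t, protocol, geometry) {
  cdc42InputRate(coords[, 1L], coords[, 2L], t, protocol, geometry,
                 check = FALSE)
}

#' Uniform initial state of a run
#'
#' Builds the standard initial condition: every species uniform over the
#' cell interior at the resting-cell concentrations (active/inactive Cdc42
#' 1/1.4, Rac 3/4.5, Rho 1.25/1.85, PIP 55, PIP2 30, PIP3 0.05 uM). The
#' per-GTPase sums equal the parameter totals exactly.
#'
#' @param geometry a [CellGeometry-class].
#' @param params a [PolarityParams-class] (held for consistency checks; the
#'   initial concentrations themselves are protocol-independent).
#' @return A [StateField-class].
#' @export
initialState <- function(geometry, params) {
  y0 <- .initialValues()
  n <- sum(geometry@inside)
  vals <- matrix(rep(y0, each = n), nrow = n,
                 dimnames = list(NULL, .SPECIES))
  new("StateField", values = vals, geometry = geometry)
}

#' @describeIn StateField extract one species as a full-grid matrix
#'   (\code{NA} outside the mask).
#' @param state a \code{StateField}.
#' @param species one of \code{"C"}, \code{"Ci"}, \code{"R"}, \code{"Ri"},
#'   \code{"rho"}, \code{"rhoi"}, \code{"P1"}, \code{"P2"}, \code{"P3"}.
#' @export
speciesField <- function(state, species) {
  species <- match.arg(species, .SPECIES)
  g <- state@geometry
  m <- matrix(NA_real_, g@nx, g@ny)
  m[g@inside] <- state@values[, species]
  m
}

setMethod("show", "StimulusProtocol", function(object) {
  dur <- if (is.finite(object@duration))
    sprintf("%g s", object@duration) else "sustained"
  cat(sprintf(
    "StimulusProtocol %s: rate %g + %g*s uM/s for %s, then %g uM/s\n",
    object@direction, object@intercept, object@slope, dur, object@postRate))
})

setMethod("show", "StateField", function(object) {
  cat(sprintf("StateField: %d interior cells x %d species (uM)\n",
              nrow(object@values), ncol(object@values)))
  rng <- apply(object@values, 2L, range)
  cat("  ranges:\n")
  for (s in .SPECIES)
    cat(sprintf("    %-5s [%.4g, %.4g]\n", s, rng[1L, s], rng[2L, s]))
})
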