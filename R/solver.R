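#' Time-integration settings
#'
#' @param tEnd final time (s).
#' @param dtMax largest operator-splitting step (s, default 0.25). Record
#'   times, the stimulus switch-off and \code{tEnd} are always hit exactly;
#'   intervals between them are subdivided uniformly.
#' @param absTol,relTol local error tolerances of the adaptive reaction
#'   integrator (defaults 1e-9 uM and 1e-7).
#' @param recordTimes times at which the spatial maximum and main-axis
#'   profile are recorded (default: every second from 0 to \code{tEnd}).
#' @param snapshotTimes times at which full nine-species snapshots are kept
#'   (default: \code{tEnd} only).
#' @return A [SolverConfig-class].
#' @export
solverConfig <- function(tEnd = 1000, dtMax = 0.25, absTol = 1e-9,
                         relTol = 1e-7, recordTimes = NULL,
                         snapshotTimes = tEnd) {
  if (is.null(recordTimes)) recordTimes <- seq(0, tEnd, by = 1)
  new("SolverConfig", dtMax = dtMax, absTol = absTol, relTol = relTol,
      tEnd = tEnd, recordTimes = sort(unique(recordTimes)),
      snapshotTimes = sort(unique(snapshotTimes)))
}

#' Finite-volume diffusion operator on a cell mask
#'
#' Builds the standard 5-point finite-volume Laplacian, scaled by
#' \code{D / h^2}, over the interior cells of a mask. Faces between an
#' interior cell and the exterior carry zero flux (no-flux boundary), so
#' every row of the operator sums to zero and total mass is conserved
#' exactly under the discrete flow.
#'
#' @param geometry a [CellGeometry-class].
#' @param D diffusion coefficient (um^2/s, >= 0).
#' @return a sparse symmetric matrix (class \code{dgCMatrix}) acting on the
#'   vector of interior-cell concentrations (ordering as
#'   [interiorCoords()]).
#' @examples
#' geom <- makeShape("rectangle", 20, 10, 30)
#' L <- buildDiffusionOperator(geom, 1)
#' max(abs(Matrix::rowSums(L)))   # 0: discrete conservation
#' @export
buildDiffusionOperator <- function(geometry, D) {
  if (D < 0) stop("D must be >= 0")
  ins <- geometry@inside
  if (!any(ins)) stop("empty mask")
  nx <- geometry@nx; ny <- geometry@ny
  id <- matrix(0L, nx, ny)
  id[ins] <- seq_len(sum(ins))
  ij <- which(ins, arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  me <- id[ins]
  pairs <- function(di, dj) {
    ok <- i + di >= 1L & i + di <= nx & j + dj >= 1L & j + dj <= ny
    nb <- integer(length(me))
    nb[ok] <- id[cbind(i[ok] + di, j[ok] + dj)]
    keep <- nb > 0L
    cbind(me[keep], nb[keep])
  }
  pp <- rbind(pairs(-1L, 0L), pairs(1L, 0L), pairs(0L, -1L), pairs(0L, 1L))
  deg <- tabulate(pp[, 1L], nbins = length(me))
  Matrix::sparseMatrix(
    i = c(pp[, 1L], seq_along(me)),
    j = c(pp[, 2L], seq_along(me)),
    x = (D / geometry@h^2) * c(rep(1, nrow(pp)), -deg),
    dims = c(length(me), length(me))
  )
}

## ---- adaptive reaction step ----------------------------------------------
## The reaction term is pointwise, so between diffusion half-steps every
## grid cell is an independent 9-dimensional ODE system. Cells are advanced
## in compiled code (src/react.cpp) with an embedded Cash-Karp 4(5) pair and
## a per-cell adaptive substep: cells sitting on a pinned front, where the
## PIP3 feedback drives activation rates to O(10^2) s^-1, subcycle finely
## while the calm bulk takes a few substeps, and each cell's step size is
## carried across splitting steps. Local error is controlled per species
## against absTol/relTol.

## parameter vector in the fixed order expected by the compiled kernel
.reactParVector <- function(v) {
  unname(v[c("C_tot", "R_tot", "rho_tot", "I_R", "I_rho", "a1", "a2", "n",
             "f", "alpha", "beta", "d_C", "d_R", "d_rho", "R_b", "rho_b",
             "I_P1", "delta_P1", "kappa12", "kappa21", "kappa23", "kappa32",
             "P_3b")])
}

## ---- main driver ----------------------------------------------------------

#' Simulate the polarization model on a cell shape
#'
#' Advances the nine-species reaction-diffusion system from the uniform
#' initial state to \code{tEnd} under a stimulus protocol, on the interior
#' of a rasterized cell shape with no-flux boundaries. Time stepping is
#' Strang operator splitting: a trapezoidal (Crank-Nicolson) diffusion half
#' step with pre-factorized sparse Cholesky solves, a full reaction step
#' integrated per cell by an embedded adaptive Runge-Kutta pair in compiled
#' code, and a second diffusion half step. Both sub-flows conserve each
#' GTPase total exactly (up to round-off), so per-GTPase mass drift over a
#' run is at machine precision.
#'
#' At every record time the spatial maximum of active Cdc42, its position
#' (centroid of tied cells when degenerate) and the main-axis concentration
#' profile are stored; full snapshots of all nine fields are kept at the
#' snapshot times.
#'
#' @param geometry a [CellGeometry-class].
#' @param params a [PolarityParams-class] (default: standard values).
#' @param protocol a [StimulusProtocol-class] (default: standard 10 s L-R
#'   gradient).
#' @param config a [SolverConfig-class] (default: \code{tEnd} 1000 s,
#'   records every second).
#' @param initial optional [StateField-class] to start from (default: the
#'   uniform resting state), e.g. to continue a run.
#' @param verbose print progress messages.
#' @return A [PolarityTrajectory-class].
#' @examples
#' geom <- makeShape("circle", 20, 20, 36)
#' traj <- simulatePolarity(geom, config = solverConfig(tEnd = 5))
#' trackMaximum(traj)[1:3, ]
#' @export
simulatePolarity <- function(geometry, params = polarityParams(),
                             protocol = stimulusProtocol(),
                             config = solverConfig(), initial = NULL,
                             verbose = FALSE) {
  v <- params@values
  coords <- interiorCoords(geometry)
  n <- nrow(coords)
  Y <- if (is.null(initial)) initialState(geometry, params)@values else {
    stopifnot(nrow(initial@values) == n)
    initial@values
  }

  ## diffusion groups: one Laplacian scaling and factor cache per distinct D
  groups <- list(
    list(cols = c(1L, 3L, 5L), D = v[["D_m"]]),   # active GTPases
    list(cols = c(2L, 4L, 6L), D = v[["D_mc"]]),  # inactive GTPases
    list(cols = c(7L, 8L, 9L), D = v[["D_P"]])    # phosphoinositides
  )
  L1 <- buildDiffusionOperator(geometry, 1)
  Ident <- Matrix::Diagonal(n)
  factors <- new.env(parent = emptyenv())
  ## trapezoidal (Crank-Nicolson) sub-flow over dt2: second-order accurate,
  ## unconditionally stable, and mass-conserving to round-off (row sums of
  ## L are zero on both sides of the solve)
  getFactor <- function(D, dt2) {
    key <- sprintf("%.12g_%.12g", D, dt2)
    f <- factors[[key]]
    if (is.null(f)) {
      f <- list(
        chol = Matrix::Cholesky(
          Matrix::forceSymmetric(Ident - (dt2 * D / 2) * L1), LDL = FALSE),
        expl = Ident + (dt2 * D / 2) * L1)
      factors[[key]] <- f
    }
    f
  }
  diffuseHalf <- function(Y, dt2) {
    for (g in groups) {
      if (g$D == 0) next
      f <- getFactor(g$D, dt2)
      Y[, g$cols] <- as.matrix(
        Matrix::solve(f$chol, f$expl %*% Y[, g$cols, drop = FALSE]))
    }
    Y
  }

  ## record-time bookkeeping
  recT <- config@recordTimes
  snapT <- config@snapshotTimes
  targets <- sort(unique(c(recT, snapT, config@tEnd,
                           if (is.finite(protocol@duration) &&
                               protocol@duration < config@tEnd)
                             protocol@duration)))
  targets <- targets[targets > 0]
  nRec <- length(recT)
  maxValue <- maxX <- maxY <- numeric(nRec)
  degenerate <- logical(nRec)
  jMid <- which.min(abs(geometry@y - geometry@width / 2))
  axisCells <- which(geometry@inside[, jMid])
  ## row index within the interior-cell ordering (column-major over inside)
  id <- matrix(0L, geometry@nx, geometry@ny)
  id[geometry@inside] <- seq_len(n)
  axisRows <- id[cbind(axisCells, jMid)]
  profiles <- matrix(NA_real_, nRec, length(axisRows))
  profileX <- geometry@x[axisCells]
  snapshots <- vector("list", length(snapT))
  names(snapshots) <- as.character(snapT)

  h2 <- geometry@h^2
  mass0 <- c(C = sum(Y[, 1L] + Y[, 2L]), R = sum(Y[, 3L] + Y[, 4L]),
             rho = sum(Y[, 5L] + Y[, 6L])) * h2
  massDrift <- c(C = 0, R = 0, rho = 0)
  nClipped <- 0L
  minSeen <- Inf
  nSteps <- 0L

  record <- function(k) {
    Cv <- Y[, 1L]
    mx <- max(Cv)
    tied <- which(Cv >= mx - config@absTol)
    maxValue[k] <<- mx
    maxX[k] <<- mean(coords[tied, 1L])
    maxY[k] <<- mean(coords[tied, 2L])
    degenerate[k] <<- length(tied) > 1L
    profiles[k, ] <<- Cv[axisRows]
  }
  kRec <- 1L
  if (recT[1L] == 0) { record(1L); kRec <- 2L }
  kSnap <- 1L
  while (kSnap <= length(snapT) && snapT[kSnap] == 0) {
    snapshots[[kSnap]] <- Y
    kSnap <- kSnap + 1L
  }

  tNow <- 0
  hReact <- rep(config@dtMax, n)   # per-cell substep, carried across steps
  nEvalTot <- 0
  pv <- .reactParVector(v)
  for (tb in targets) {
    nSub <- max(1L, ceiling((tb - tNow) / config@dtMax - 1e-9))
    dt <- (tb - tNow) / nSub
    for (s in seq_len(nSub)) {
      Ic <- rep_len(.stimulusField(coords, tNow + dt / 2, protocol,
                                   geometry), n)
      Y <- diffuseHalf(Y, dt / 2)
      react <- .reactCellsCpp(Y, Ic, pv, dt, config@absTol, config@relTol,
                              hReact)
      Y[] <- react$Y
      hReact <- react$hNext
      nEvalTot <- nEvalTot + react$nEval
      Y <- diffuseHalf(Y, dt / 2)
      mn <- min(Y)
      if (mn < minSeen) minSeen <- mn
      if (mn < 0) {
        if (mn < -1e-3)
          stop(sprintf("field went negative (%.3g) at t = %.6g s", mn,
                       tNow + dt))
        nClipped <- nClipped + sum(Y < 0)
        Y[Y < 0] <- 0
      }
      if (any(!is.finite(Y)))
        stop(sprintf("non-finite field values at t = %.6g s", tNow + dt))
      tNow <- tNow + dt
      nSteps <- nSteps + 1L
    }
    tNow <- tb                      # avoid drift from repeated addition
    mass <- c(C = sum(Y[, 1L] + Y[, 2L]), R = sum(Y[, 3L] + Y[, 4L]),
              rho = sum(Y[, 5L] + Y[, 6L])) * h2
    massDrift <- pmax(massDrift, abs(mass - mass0) / mass0)
    if (kRec <= nRec && abs(recT[kRec] - tb) < 1e-9) {
      record(kRec); kRec <- kRec + 1L
    }
    if (kSnap <= length(snapT) && abs(snapT[kSnap] - tb) < 1e-9) {
      snapshots[[kSnap]] <- Y
      kSnap <- kSnap + 1L
    }
    if (verbose && (tb %% 100 == 0 || tb == config@tEnd))
      message(sprintf("  t = %6.1f s  maxC = %.4f uM", tb, max(Y[, 1L])))
  }

  keep <- seq_len(kRec - 1L)
  colnames(Y) <- .SPECIES
  new("PolarityTrajectory",
      times = recT[keep], maxValue = maxValue[keep],
      maxX = maxX[keep], maxY = maxY[keep], degenerate = degenerate[keep],
      profiles = profiles[keep, , drop = FALSE], profileX = profileX,
      snapshots = snapshots[!vapply(snapshots, is.null, TRUE)],
      finalState = new("StateField", values = Y, geometry = geometry),
      geometry = geometry, protocol = protocol, params = params,
      log = list(nSteps = nSteps, nEval = nEvalTot, massDrift = massDrift,
                 minValue = minSeen, nClipped = nClipped))
}

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(
    "SolverConfig: tEnd = %g s, dtMax = %g s, tol = (%.2g, %.2g), %d record times\n",
    object@tEnd, object@dtMax, object@absTol, object@relTol,
    length(object@recordTimes)))
})

setMethod("show", "PolarityTrajectory", function(object) {
  cat(sprintf(
    "PolarityTrajectory: '%s' %g x %g um, %s stimulus, %d record times to %g s\n",
    object@geometry@shapeName, object@geometry@length, object@geometry@width,
    object@protocol@direction, length(object@times), max(object@times)))
  k <- length(object@times)
  cat(sprintf("  final max Cdc42 %.4g uM at (%.3g, %.3g) um\n",
              object@maxValue[k], object@maxX[k], object@maxY[k]))
  cat(sprintf("  %d steps, max GTPase mass drift %.3g, min field %.3g uM\n",
              object@log$nSteps, max(object@log$massDrift),
              object@log$minValue))
})
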