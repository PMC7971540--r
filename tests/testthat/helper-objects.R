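## Build a StateField with a prescribed active-Cdc42 field (other species
## at their uniform initial values).
fieldWithC <- function(geometry, Cfun) {
  st <- initialState(geometry, polarityParams())
  xy <- interiorCoords(geometry)
  st@values[, "C"] <- Cfun(xy[, 1], xy[, 2])
  st
}

## Assemble a PolarityTrajectory from a list of active-Cdc42 full-field
## functions (one per record time), mimicking what the solver records.
## Lets classification rules be tested on hand-designed fields.
syntheticTrajectory <- function(geometry, times, Cfuns,
                                protocol = stimulusProtocol(),
                                absTol = 1e-9) {
  xy <- interiorCoords(geometry)
  jMid <- which.min(abs(geometry@y - geometry@width / 2))
  ins <- insideMask(geometry)
  id <- matrix(0L, geometry@nx, geometry@ny)
  id[ins] <- seq_len(sum(ins))
  axisCells <- which(ins[, jMid])
  axisRows <- id[cbind(axisCells, jMid)]
  n <- length(times)
  maxValue <- maxX <- maxY <- numeric(n)
  degenerate <- logical(n)
  profiles <- matrix(NA_real_, n, length(axisRows))
  last <- NULL
  for (k in seq_len(n)) {
    Cv <- Cfuns[[k]](xy[, 1], xy[, 2])
    mx <- max(Cv)
    tied <- which(Cv >= mx - absTol)
    maxValue[k] <- mx
    maxX[k] <- mean(xy[tied, 1])
    maxY[k] <- mean(xy[tied, 2])
    degenerate[k] <- length(tied) > 1
    profiles[k, ] <- Cv[axisRows]
    last <- Cv
  }
  st <- initialState(geometry, polarityParams())
  st@values[, "C"] <- last
  new("PolarityTrajectory", times = times, maxValue = maxValue,
      maxX = maxX, maxY = maxY, degenerate = degenerate,
      profiles = profiles, profileX = geometry@x[axisCells],
      snapshots = list(), finalState = st, geometry = geometry,
      protocol = protocol, params = polarityParams(),
      log = list(nSteps = 0L, massDrift = c(C = 0, R = 0, rho = 0),
                 minValue = 0, nClipped = 0L))
}
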