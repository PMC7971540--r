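geomR <- makeShape("rectangle", 40, 20, 60)
geomC <- makeShape("circle", 40, 40, 60)

test_that("the tracked maximum sits at the extremity of a monotone field", {
  tr <- syntheticTrajectory(geomR, c(0, 1), list(
    function(x, y) 1 + 0 * x,
    function(x, y) 1 + 0.1 * x))
  tm <- trackMaximum(tr)
  ## uniform field: degenerate plateau, centroid position
  expect_true(tm$degenerate[1])
  expect_equal(tm$x[1], 20, tolerance = 1e-6)
  ## monotone-in-x field: right extremity (whole column tied -> degenerate,
  ## centroid on the midline)
  expect_true(tm$degenerate[2])
  expect_equal(tm$x[2], max(interiorCoords(geomR)[, 1]))
  expect_equal(tm$y[2], 10, tolerance = 1e-9)
})

test_that("onset of reversal detects retreat from the running extreme", {
  h <- spacing(geomR)
  ## max advances to the right edge, then retreats by 3 um
  posToFun <- function(x0) function(x, y)
    exp(-((x - x0)^2 + (y - 10)^2) / 8)
  tr <- syntheticTrajectory(geomR, 0:4, lapply(c(10, 30, 38, 38, 35), posToFun))
  expect_equal(onsetOfReversal(tr), 4)
  ## a monotone advance never triggers
  tr2 <- syntheticTrajectory(geomR, 0:2, lapply(c(10, 20, 30), posToFun))
  expect_true(is.na(onsetOfReversal(tr2)))
  ## sub-cell jitter does not trigger
  tr3 <- syntheticTrajectory(geomR, 0:2,
                             lapply(c(30, 30 - 0.4 * h, 30), posToFun))
  expect_true(is.na(onsetOfReversal(tr3)))
  ## R-L stimulus: retreat means moving right
  trRL <- syntheticTrajectory(geomR, 0:2, lapply(c(30, 5, 9), posToFun),
                              protocol = stimulusProtocol("R-L"))
  expect_equal(onsetOfReversal(trRL), 2)
  ## alternative rule: retreat from the initial position
  tr4 <- syntheticTrajectory(geomR, 0:2, lapply(c(30, 35, 28), posToFun))
  expect_equal(onsetOfReversal(tr4), 2)
  expect_equal(onsetOfReversal(tr4, rule = "initial"), 2)
  tr5 <- syntheticTrajectory(geomR, 0:2, lapply(c(20, 35, 22), posToFun))
  expect_equal(onsetOfReversal(tr5), 2)         # retreat from extreme at 35
  expect_true(is.na(onsetOfReversal(tr5, rule = "initial")))
})

test_that("deltaC measures the drop from the axis maximum to the front", {
  ## uniform field: 0; max at the front: 0
  trU <- syntheticTrajectory(geomR, c(0, 1), rep(list(function(x, y) 2 + 0 * x), 2))
  expect_equal(deltaC(trU), 0)
  trF <- syntheticTrajectory(geomR, c(0, 1), rep(list(function(x, y) 1 + 0.05 * x), 2))
  expect_equal(deltaC(trF), 0)
  ## interior hump 1 uM above the front value
  trH <- syntheticTrajectory(geomR, c(0, 1), rep(list(function(x, y)
    2 + 1 * pmax(0, 1 - abs(x - 20) / 15) ), 2))
  front <- 2 + pmax(0, 1 - abs(max(interiorCoords(geomR)[, 1]) - 20) / 15)
  expect_equal(deltaC(trH), max(2 + pmax(0, 1 - abs(interiorCoords(geomR)[, 1] - 20) / 15)) - front,
               tolerance = 1e-9)
  expect_gte(deltaC(trH), 0)
  ## R-L protocol reads the left end as the front
  expect_equal(deltaC(trF, protocol = stimulusProtocol("R-L")),
               0.05 * diff(range(interiorCoords(geomR)[, 1])))
})

test_that("front counting uses 4-connected super-level components", {
  bump <- function(cx, cy) function(x, y)
    4 * exp(-((x - cx)^2 + (y - cy)^2) / 4)
  one <- fieldWithC(geomC, bump(20, 20))
  expect_equal(countFronts(one, 3), 1)
  two <- fieldWithC(geomC, function(x, y)
    bump(10, 20)(x, y) + bump(30, 20)(x, y))
  expect_equal(countFronts(two, 3), 2)
  below <- fieldWithC(geomC, function(x, y) 0.5 + 0 * x)
  expect_equal(countFronts(below, 3), 0)
  expect_error(countFronts(one, 0), "threshold")
})

test_that("classification separates uniform, normal and reverse outcomes", {
  mkTraj <- function(geom, funs, prot = stimulusProtocol(), times = 0:(length(funs) - 1))
    syntheticTrajectory(geom, times, funs, protocol = prot)
  ## constant field -> uniform
  u <- mkTraj(geomR, rep(list(function(x, y) 1 + 0 * x), 2))
  pu <- classifyPattern(u)
  expect_equal(pu@label, "uniform")
  expect_lte(pu@frontCount, 1)
  ## final max at the stimulated front edge -> normal, initial axis
  nrm <- mkTraj(geomR, rep(list(function(x, y) 1 + 0.05 * x), 2))
  pn <- classifyPattern(nrm)
  expect_equal(pn@label, "normal")
  expect_equal(pn@axis, "initial")
  expect_equal(pn@axisLength, "longer")
  expect_equal(pn@patternName, "polarization, longer initial axis")
  ## interior maximum away from the front -> reverse
  rev <- mkTraj(geomR, rep(list(function(x, y)
    exp(-((x - 15)^2 + (y - 10)^2) / 20)), 2))
  expect_equal(classifyPattern(rev)@label, "reverse")
  ## gradient turned to the perpendicular axis -> new axis
  turned <- mkTraj(geomR, rep(list(function(x, y) 1 + 0.05 * y), 2))
  pt <- classifyPattern(turned)
  expect_equal(pt@axis, "new")
  expect_equal(pt@label, "normal")     # at an extremity of the new axis
  expect_equal(pt@axisLength, "shorter")
})

test_that("classification is invariant under mirror reflection", {
  ## reflect both the field and the protocol about the vertical midline
  f <- function(x, y) exp(-((x - 12)^2 + (y - 10)^2) / 10)
  fm <- function(x, y) f(40 - x, y)
  a <- classifyPattern(syntheticTrajectory(geomR, 0:1, list(f, f),
                                           protocol = stimulusProtocol("L-R")))
  b <- classifyPattern(syntheticTrajectory(geomR, 0:1, list(fm, fm),
                                           protocol = stimulusProtocol("R-L")))
  expect_equal(a@label, b@label)
  expect_equal(a@axis, b@axis)
  expect_equal(a@patternName, b@patternName)
})
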