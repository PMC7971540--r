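basalState <- function(n = 1) {
  vals <- c(C = 1, Ci = 1.4, R = 3, Ri = 4.5, rho = 1.25, rhoi = 1.85,
            P1 = 50, P2 = 30, P3 = 0.05)
  matrix(rep(vals, each = n), nrow = n, dimnames = list(NULL, names(vals)))
}

test_that("activation rates reproduce hand-evaluated basal values", {
  p <- polarityParams()
  q <- activationRates(1, 3, 1.25, 0.05, p)
  ## at basal Rho = a1 the Hill factor is 1/2; at basal PIP3 the feedback
  ## factor is exactly 1
  expect_equal(q$Q_C, 2.95 / 2)
  expect_equal(q$Q_R, 0.5 + 4.5 * 1)
  expect_equal(q$Q_rho, (3.3 + 0.3 * 3) / 2)
})

test_that("PIP3 feedback behaves as specified", {
  p <- polarityParams()
  ## f = 0: no feedback, any PIP3
  p0 <- polarityParams(f = 0)
  for (P3 in c(0, 0.05, 1)) {
    q <- activationRates(1, 3, 1.25, P3, p0)
    expect_equal(q$Q_C, 1.475)
    expect_equal(q$Q_R, 5)
  }
  ## at P3 = P_3b rates are independent of f
  for (f in c(0, 0.25, 0.7, 1)) {
    pf <- polarityParams(f = f)
    q <- activationRates(1, 3, 1.25, 0.05, pf)
    expect_equal(q$Q_C, 1.475)
  }
  ## continuity in f: rates are linear in f at fixed state
  fs <- seq(0, 1, by = 0.1)
  qc <- vapply(fs, function(f)
    activationRates(1, 3, 1.25, 0.1, polarityParams(f = f))$Q_C, 0)
  expect_equal(diff(qc), rep(diff(qc)[1], 10))
  ## Rho activation is PI-independent
  expect_equal(activationRates(1, 3, 1.25, 5, p)$Q_rho,
               activationRates(1, 3, 1.25, 0, p)$Q_rho)
  ## strong Rho shuts down Cdc42 activation
  expect_lt(activationRates(1, 3, 1e4, 0.05, p)$Q_C, 1e-8)
  expect_error(activationRates(-1, 3, 1.25, 0.05, p), ">= 0")
})

test_that("GTPase reaction rates match hand evaluation and conserve totals", {
  p <- polarityParams()
  st <- basalState()
  q <- activationRates(st[, "C"], st[, "R"], st[, "rho"], st[, "P3"], p)
  d <- gtpaseReactionRates(st, q$Q_C, q$Q_R, q$Q_rho, p)
  expect_equal(d[, "C"], 1.475 * (1.4 / 2.4) - 1, tolerance = 1e-12)
  expect_equal(d[, "R"], 0)   # Q_R * (Ri/R_tot) = 5 * 0.6 = 3 = d_R * R
  ## pointwise active+inactive conservation on random states
  set.seed(11)
  for (k in 1:20) {
    st <- matrix(runif(9, 0, 5), 1,
                 dimnames = list(NULL, colnames(basalState())))
    q <- activationRates(st[, "C"], st[, "R"], st[, "rho"], st[, "P3"], p)
    d <- gtpaseReactionRates(st, q$Q_C, q$Q_R, q$Q_rho, p)
    expect_identical(d[, "C"] + d[, "Ci"], 0)
    expect_identical(d[, "R"] + d[, "Ri"], 0)
    expect_identical(d[, "rho"] + d[, "rhoi"], 0)
  }
})

test_that("basal phosphoinositide levels are an exact fixed point", {
  p <- polarityParams()
  d <- piReactionRates(basalState(), p)
  expect_equal(max(abs(d)), 0, tolerance = 1e-14)
  ## PIP2 <-> PIP3 fluxes balance at basal: 0.0072 * 30 = 4.32 * 0.05
  expect_equal(param(p, "kappa23") * 30, param(p, "kappa32") * 0.05)
  ## with input and conversions off, PIP decays exponentially
  p0 <- polarityParams(I_P1 = 0, kappa12 = 0, kappa21 = 0, kappa23 = 0,
                       kappa32 = 0)
  d0 <- piReactionRates(basalState(), p0)
  expect_equal(d0[, "P1"], -0.21 * 50)
  expect_equal(d0[, "P2"], 0)
})

test_that("analytic PI steady state matches an independent linear solve", {
  p <- polarityParams()
  expect_equal(unname(piSteadyState(p)), c(50, 30, 0.05), tolerance = 1e-14)
  ## off-basal Rac/Rho: compare with solving the linear system directly
  v <- paramValues(p)
  for (Rrho in list(c(4, 0.8), c(2, 2), c(6, 0.3))) {
    gR <- (1 + Rrho[1] / v["R_b"]) / 2
    gr <- (1 + Rrho[2] / v["rho_b"]) / 2
    A <- rbind(
      c(-v["delta_P1"] - v["kappa12"] * gR, v["kappa21"], 0),
      c(v["kappa12"] * gR, -v["kappa21"] - v["kappa23"] * gR,
        v["kappa32"] * gr),
      c(0, v["kappa23"] * gR, -v["kappa32"] * gr))
    ref <- solve(A, c(-v["I_P1"], 0, 0))
    expect_equal(unname(piSteadyState(p, Rrho[1], Rrho[2])), unname(ref),
                 tolerance = 1e-10)
    ## and it really is a fixed point of the rate function
    st <- basalState()
    st[, c("R", "rho")] <- Rrho
    st[, c("P1", "P2", "P3")] <- ref
    expect_lt(max(abs(piReactionRates(st, p))), 1e-12)
  }
})

test_that("well-mixed integration settles at a reproducible fixed point", {
  p <- polarityParams()
  ss <- wellmixedSteadyState(p)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-8)
  ## the same point is reached from a strongly polarized start with the
  ## same conserved GTPase totals (monostable regime)
  init <- c(C = 2, Ci = 0.4, R = 5, Ri = 2.5, rho = 0.4, rhoi = 2.7,
            P1 = 40, P2 = 40, P3 = 0.2)
  ss2 <- wellmixedSteadyState(p, init = init)
  expect_equal(ss2$state, ss$state, tolerance = 1e-6)
  ## no activation input: active forms vanish
  ssOff <- wellmixedSteadyState(
    polarityParams(I_R = 0, I_rho = 0, alpha = 0, beta = 0), I_C = 0)
  expect_lt(max(ssOff$state[c("C", "R", "rho")]), 1e-6)
})

test_that("parameter sets validate their invariants", {
  expect_error(polarityParams(f = 1.5), "f must lie")
  expect_error(polarityParams(D_m = 60), "D_m must be smaller")
  expect_error(polarityParams(a1 = -1), "finite and >= 0")
  expect_error(polarityParams(bogus = 1), "unknown parameter")
  p <- polarityParams()
  param(p, "n") <- 4
  expect_equal(param(p, "n"), 4)
  expect_error(param(p, "nope"))
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- polarityParams(f = 0.1, n = 8)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeParams(p, f)
  expect_identical(paramValues(readParams(f)), paramValues(p))
  writeLines(c("a1 = 2.0", "# comment", "", "f = 0.8"), f)
  p2 <- readParams(f)
  expect_equal(param(p2, "a1"), 2)
  expect_equal(param(p2, "I_C"), 2.95)   # omitted keys keep defaults
  writeLines("banana = 1", f)
  expect_error(readParams(f), "unknown parameter")
})
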