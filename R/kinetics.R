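## ---- reaction kinetics of the nine-species network ------------------------
##
## Active GTPase G in {C (Cdc42), R (Rac), rho (Rho)} obeys
##   dG/dt  =  Q_G * (Gi / G_tot) - d_G * G          (+ diffusion, solver.R)
##   dGi/dt = -Q_G * (Gi / G_tot) + d_G * G
## so each activation/inactivation pair conserves G + Gi pointwise.
## Activation rates carry the mutual Cdc42-Rho inhibition (Hill form) and the
## PIP3 feedback on Cdc42 and Rac (factor (1-f) + f*P3/P_3b; Rho activation
## is PI-independent). Phosphoinositide conversion steps are modulated by
## Rac (PI5K, PI3K steps) and Rho (PTEN step) through (1 + X/X_b)/2 factors
## that equal 1 at basal X.

#' Activation rates of Cdc42, Rac and Rho
#'
#' Evaluates the three activation rates, including the mutual
#' Cdc42--Rho Hill inhibition and the PIP3 feedback factor
#' \code{(1 - f) + f * P3 / P_3b} on Cdc42 and Rac (Rho activation is
#' independent of the phosphoinositides). All arguments are vectorized.
#'
#' @param C,R,rho active Cdc42, Rac, Rho concentrations (uM).
#' @param P3 PIP3 concentration (uM); at basal \code{P3 = P_3b} the feedback
#'   factor is exactly 1 for any \code{f}.
#' @param params a [PolarityParams-class].
#' @param I_C optional override of the Cdc42 activation input (uM/s), used
#'   while a graded stimulus is applied; defaults to the parameter
#'   \code{I_C}. May be a vector (one value per location).
#' @return list with components \code{Q_C}, \code{Q_R}, \code{Q_rho} (uM/s).
#' @examples
#' p <- polarityParams()
#' activationRates(1, 3, 1.25, 0.05, p)   # basal: 1.475, 5.0, 2.1
#' @export
activationRates <- function(C, R, rho, P3, params, I_C = param(params, "I_C")) {
  if (any(C < 0) || any(R < 0) || any(rho < 0) || any(P3 < 0))
    stop("concentrations must be >= 0")
  v <- params@values
  fb <- (1 - v[["f"]]) + v[["f"]] * P3 / v[["P_3b"]]
  list(
    Q_C = I_C / (1 + (rho / v[["a1"]])^v[["n"]]) * fb,
    Q_R = (v[["I_R"]] + v[["alpha"]] * C) * fb,
    Q_rho = (v[["I_rho"]] + v[["beta"]] * R) / (1 + (C / v[["a2"]])^v[["n"]])
  )
}

#' Reaction time-derivatives of the six GTPase fields
#'
#' @param state numeric matrix with (at least) columns \code{C}, \code{Ci},
#'   \code{R}, \code{Ri}, \code{rho}, \code{rhoi} (uM), one row per location,
#'   or a [StateField-class].
#' @param Q_C,Q_R,Q_rho activation rates (uM/s), e.g. from
#'   [activationRates()].
#' @param params a [PolarityParams-class].
#' @return matrix with columns \code{C}, \code{Ci}, \code{R}, \code{Ri},
#'   \code{rho}, \code{rhoi}: reaction rates of change (uM/s). Active and
#'   inactive rates are exact negatives, so each total is conserved.
#' @export
gtpaseReactionRates <- function(state, Q_C, Q_R, Q_rho, params) {
  Y <- if (is(state, "StateField")) state@values else state
  v <- params@values
  dC <- Q_C * (Y[, "Ci"] / v[["C_tot"]]) - v[["d_C"]] * Y[, "C"]
  dR <- Q_R * (Y[, "Ri"] / v[["R_tot"]]) - v[["d_R"]] * Y[, "R"]
  dr <- Q_rho * (Y[, "rhoi"] / v[["rho_tot"]]) - v[["d_rho"]] * Y[, "rho"]
  cbind(C = dC, Ci = -dC, R = dR, Ri = -dR, rho = dr, rhoi = -dr)
}

#' Reaction time-derivatives of the phosphoinositide fields
#'
#' Linear interconversion chain PIP <-> PIP2 <-> PIP3 with constant PIP
#' input \code{I_P1} and decay \code{delta_P1}; the forward steps are
#' amplified by Rac and the PIP3 -> PIP2 step by Rho, each through a
#' \code{(1 + X/X_b)/2} factor equal to 1 at basal.
#'
#' @inheritParams gtpaseReactionRates
#' @param state matrix with columns \code{R}, \code{rho}, \code{P1},
#'   \code{P2}, \code{P3}, or a [StateField-class].
#' @return matrix with columns \code{P1}, \code{P2}, \code{P3} (uM/s).
#' @export
piReactionRates <- function(state, params) {
  Y <- if (is(state, "StateField")) state@values else state
  v <- params@values
  gR <- (1 + Y[, "R"] / v[["R_b"]]) / 2
  gr <- (1 + Y[, "rho"] / v[["rho_b"]]) / 2
  to2 <- v[["kappa12"]] * gR * Y[, "P1"]    # PIP  -> PIP2 (PI5K, Rac-boosted)
  to1 <- v[["kappa21"]] * Y[, "P2"]         # PIP2 -> PIP
  to3 <- v[["kappa23"]] * gR * Y[, "P2"]    # PIP2 -> PIP3 (PI3K, Rac-boosted)
  back2 <- v[["kappa32"]] * gr * Y[, "P3"]  # PIP3 -> PIP2 (PTEN, Rho-boosted)
  cbind(P1 = v[["I_P1"]] - v[["delta_P1"]] * Y[, "P1"] + to1 - to2,
        P2 = -to1 + to2 - to3 + back2,
        P3 = to3 - back2)
}

## Integer Hill powers by repeated multiplication (the library pow() is the
## single most expensive operation in the RHS otherwise); general exponents
## fall back to `^`.
.ipow <- function(x, n) {
  if (n == trunc(n) && n >= 1 && n <= 12) {
    out <- x
    for (k in seq_len(n - 1)) out <- out * x
    out
  } else x^n
}

## Fast internal RHS over an n x 9 state matrix; `Ic` is the (possibly
## spatially varying) Cdc42 activation input during the stimulus. Kept free
## of S4 dispatch and validity checks -- it runs millions of times.
## Transient negative stage values (possible inside embedded RK stages) are
## harmless here for integer Hill exponents; non-finite results are caught
## by the step controller.
.reactionRHS <- function(Y, Ic, v) {
  C <- Y[, 1L]; Ci <- Y[, 2L]; R <- Y[, 3L]; Ri <- Y[, 4L]
  rho <- Y[, 5L]; rhoi <- Y[, 6L]
  P1 <- Y[, 7L]; P2 <- Y[, 8L]; P3 <- Y[, 9L]
  n <- v[["n"]]
  fb <- (1 - v[["f"]]) + (v[["f"]] / v[["P_3b"]]) * P3
  QC <- Ic / (1 + .ipow(rho / v[["a1"]], n)) * fb
  QR <- (v[["I_R"]] + v[["alpha"]] * C) * fb
  Qr <- (v[["I_rho"]] + v[["beta"]] * R) / (1 + .ipow(C / v[["a2"]], n))
  dC <- QC * (Ci / v[["C_tot"]]) - v[["d_C"]] * C
  dR <- QR * (Ri / v[["R_tot"]]) - v[["d_R"]] * R
  dr <- Qr * (rhoi / v[["rho_tot"]]) - v[["d_rho"]] * rho
  gR <- (1 + R / v[["R_b"]]) / 2
  gr <- (1 + rho / v[["rho_b"]]) / 2
  to2 <- v[["kappa12"]] * gR * P1
  to1 <- v[["kappa21"]] * P2
  to3 <- v[["kappa23"]] * gR * P2
  back2 <- v[["kappa32"]] * gr * P3
  cbind(dC, -dC, dR, -dR, dr, -dr,
        v[["I_P1"]] - v[["delta_P1"]] * P1 + to1 - to2,
        -to1 + to2 - to3 + back2,
        to3 - back2)
}

## Standard uniform initial concentrations (uM): slightly supra-basal PIP.
.initialValues <- function() {
  c(C = 1, Ci = 1.4, R = 3, Ri = 4.5, rho = 1.25, rhoi = 1.85,
    P1 = 55, P2 = 30, P3 = 0.05)
}

#' Space-free steady state of the reaction network
#'
#' Integrates the well-mixed (reaction-only) nine-species system from the
#' standard uniform initial concentrations with a constant Cdc42 activation
#' input, and returns the fixed point it settles to. Serves as the reference
#' for the PDE solver in the zero-diffusion limit and as a check on the
#' basal operating point of the network.
#'
#' @param params a [PolarityParams-class].
#' @param I_C constant Cdc42 activation input (uM/s); defaults to the
#'   parameter value.
#' @param tMax integration horizon (s).
#' @param residTol convergence criterion on the derivative norm (uM/s).
#' @param init optional named initial concentrations (defaults to the
#'   standard uniform initials).
#' @return list with \code{state} (named 9-vector, uM), \code{residual}
#'   (max absolute derivative, uM/s) and \code{converged} (logical). A
#'   non-converged integration (e.g. an oscillatory parameter regime) is
#'   reported with a warning, not an error.
#' @examples
#' ss <- wellmixedSteadyState(polarityParams())
#' ss$state[c("C", "R", "rho")]    # near the basal levels (1, 3, 1.25)
#' @export
wellmixedSteadyState <- function(params, I_C = param(params, "I_C"),
                                 tMax = 5000, residTol = 1e-8, init = NULL) {
  v <- params@values
  y0 <- if (is.null(init)) .initialValues() else init[.SPECIES]
  dyn <- function(t, y, p) {
    list(as.vector(.reactionRHS(matrix(y, 1L, 9L), I_C, v)))
  }
  sol <- deSolve::lsoda(y0, times = c(0, tMax), func = dyn, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  y <- setNames(as.numeric(sol[nrow(sol), -1L]), .SPECIES)
  resid <- max(abs(.reactionRHS(matrix(y, 1L, 9L), I_C, v)))
  converged <- resid < residTol
  if (!converged)
    warning(sprintf(
      "no fixed point within t = %g s (residual %.3g uM/s); the parameter regime may be oscillatory",
      tMax, resid))
  list(state = y, residual = resid, converged = converged)
}

#' Analytic steady state of the phosphoinositide subsystem
#'
#' For fixed active Rac and Rho levels the PI chain is linear and its fixed
#' point is available in closed form: \code{P1 = I_P1 / delta_P1},
#' \code{P2 = kappa12 gR P1 / kappa21}, \code{P3 = kappa23 gR P2 /
#' (kappa32 gr)} with \code{gR}, \code{gr} the Rac/Rho modulation factors.
#' At basal Rac and Rho the calibrated rates return the basal PI levels
#' exactly.
#'
#' @param params a [PolarityParams-class].
#' @param R,rho active Rac and Rho levels (uM); default basal.
#' @return named numeric vector \code{(P1, P2, P3)} (uM).
#' @examples
#' piSteadyState(polarityParams())   # exactly (50, 30, 0.05)
#' @export
piSteadyState <- function(params, R = param(params, "R_b"),
                          rho = param(params, "rho_b")) {
  v <- params@values
  gR <- (1 + R / v[["R_b"]]) / 2
  gr <- (1 + rho / v[["rho_b"]]) / 2
  P1 <- v[["I_P1"]] / v[["delta_P1"]]
  P2 <- v[["kappa12"]] * gR * P1 / v[["kappa21"]]
  P3 <- v[["kappa23"]] * gR * P2 / (v[["kappa32"]] * gr)
  c(P1 = P1, P2 = P2, P3 = P3)
}
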