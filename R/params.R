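## Default parameter values of the polarization model.
##
## The phosphoinositide interconversion steps are catalysed by PI5K, PI3K and
## PTEN, which are well-mixed at a fixed level; they are folded into
## effective first-order baseline rates kappa12, kappa23, kappa32 (s^-1).
## kappa23 and kappa32 are the printed second-order rates times the 10 uM
## enzyme level; kappa12 is calibrated so that the basal phosphoinositide
## levels (P_1b, P_2b, P_3b) = (50, 30, 0.05) uM are an exact fixed point of
## the PI subsystem at basal Rac and Rho:
##   kappa12 = (I_P1 + kappa21 * P_2b - delta_P1 * P_1b) / P_1b = 0.0084 s^-1.
## (The literal 10 uM folding of the PI5K step would put basal PIP at
## 3000 uM, inconsistent with the stated basal level of 30 uM.)
.defaultParamValues <- function() {
  c(
    C_tot = 2.4, R_tot = 7.5, rho_tot = 3.1,      # total GTPase levels (uM)
    I_C = 2.95, I_R = 0.5, I_rho = 3.3,           # baseline activation (uM/s)
    a1 = 1.25,                                    # Rho level, half-max inhibition of Cdc42 (uM)
    a2 = 1,                                       # Cdc42 level, half-max inhibition of Rho (uM)
    n = 3,                                        # Hill coefficient, mutual inhibition
    f = 0.4,                                      # PIP3 feedback strength, in [0, 1]
    alpha = 4.5,                                  # Cdc42-dependent Rac activation (1/s)
    beta = 0.3,                                   # Rac-dependent Rho activation (1/s)
    d_C = 1, d_R = 1, d_rho = 1,                  # inactivation rates (1/s)
    D_m = 0.1, D_mc = 50,                         # diffusion, active / inactive (um^2/s)
    C_b = 1, R_b = 3, rho_b = 1.25,               # basal active levels (uM)
    I_P1 = 10.5,                                  # PIP input rate (uM/s)
    delta_P1 = 0.21,                              # PIP decay rate (1/s)
    kappa12 = 0.0084,                             # PIP -> PIP2 baseline (1/s, calibrated)
    kappa21 = 0.014,                              # PIP2 -> PIP (1/s)
    kappa23 = 0.0072,                             # PIP2 -> PIP3 baseline (1/s, = 0.00072 x 10 uM PI3K)
    kappa32 = 4.32,                               # PIP3 -> PIP2 baseline (1/s, = 0.432 x 10 uM PTEN)
    D_P = 5,                                      # PI diffusion (um^2/s)
    P_1b = 50, P_2b = 30, P_3b = 0.05             # basal PI levels (uM)
  )
}

#' Construct a parameter set for the polarization model
#'
#' Returns the standard parameterization of the nine-species model, with any
#' named value overridden. Symbols follow the model's conventions:
#' totals \code{C_tot}, \code{R_tot}, \code{rho_tot}; activation inputs
#' \code{I_C}, \code{I_R}, \code{I_rho}; mutual-inhibition constants
#' \code{a1}, \code{a2} and Hill coefficient \code{n}; PIP3 feedback strength
#' \code{f}; cross-activation \code{alpha}, \code{beta}; inactivation rates
#' \code{d_C}, \code{d_R}, \code{d_rho}; diffusion \code{D_m} (active),
#' \code{D_mc} (inactive), \code{D_P} (phosphoinositides); basal levels
#' \code{C_b}, \code{R_b}, \code{rho_b}, \code{P_1b}, \code{P_2b},
#' \code{P_3b}; and the phosphoinositide turnover constants \code{I_P1},
#' \code{delta_P1}, \code{kappa12}, \code{kappa21}, \code{kappa23},
#' \code{kappa32} (effective first-order baselines with the well-mixed
#' kinases/phosphatase folded in; \code{kappa12} is calibrated so the basal
#' PI levels are an exact fixed point).
#'
#' @param ... named numeric overrides, e.g. \code{polarityParams(f = 0,
#'   n = 4)}. Unknown names are an error.
#' @return A [PolarityParams-class].
#' @examples
#' p <- polarityParams()
#' param(p, "a1")
#' p0 <- polarityParams(f = 0)
#' @export
polarityParams <- function(...) {
  v <- .defaultParamValues()
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(over), names(v))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    v[names(over)] <- as.numeric(over)
  }
  new("PolarityParams", values = v)
}

#' Read or write a single parameter
#'
#' @param params a [PolarityParams-class].
#' @param name parameter symbol, e.g. \code{"a1"}.
#' @param value replacement value.
#' @return \code{param} returns the numeric value; \code{param<-} the
#'   modified parameter set.
#' @export
param <- function(params, name) {
  if (!name %in% names(params@values)) stop("unknown parameter: ", name)
  unname(params@values[name])
}

#' @rdname param
#' @export
`param<-` <- function(params, name, value) {
  if (!name %in% names(params@values)) stop("unknown parameter: ", name)
  params@values[name] <- value
  validObject(params)
  params
}

#' @describeIn PolarityParams all values as a named numeric vector.
#' @param object,params a \code{PolarityParams}.
#' @export
paramValues <- function(params) params@values

#' Read a parameter file
#'
#' Parses a flat \code{key = value} text file (one assignment per line;
#' blank lines and lines starting with \code{#} ignored). Keys must be known
#' parameter symbols; omitted keys keep their defaults.
#'
#' @param file path to the parameter file.
#' @return A [PolarityParams-class].
#' @seealso [writeParams()]
#' @export
readParams <- function(file) {
  lines <- readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(polarityParams())
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed parameter line(s); expected 'key = value'")
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
  if (any(is.na(vals))) stop("non-numeric parameter value(s)")
  do.call(polarityParams, as.list(setNames(vals, keys)))
}

#' Write a parameter file
#'
#' @param params a [PolarityParams-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeParams <- function(params, file) {
  writeLines(sprintf("%s = %.17g", names(params@values), params@values), file)
  invisible(file)
}

setMethod("show", "PolarityParams", function(object) {
  cat("PolarityParams (", length(object@values), " values)\n", sep = "")
  dev <- object@values != .defaultParamValues()
  if (any(dev)) {
    cat("  non-default:",
        paste(sprintf("%s = %.4g", names(object@values)[dev],
                      object@values[dev]), collapse = ", "), "\n")
  } else cat("  all values at the standard defaults\n")
})
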