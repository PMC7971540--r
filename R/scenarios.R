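## ---- run configuration ----------------------------------------------------

#' Assemble a reproducible run configuration
#'
#' A run configuration bundles the geometry, parameter overrides, stimulus
#' protocol and solver settings of a single simulation in one serializable
#' list, so that a run can be reproduced exactly from its config file. The
#' model is fully deterministic; the \code{seed} field is reserved for
#' future stochastic extensions and is carried but unused.
#'
#' @param shape,length,width,nMesh geometry block (see [makeShape()]).
#' @param maskFile,pixelSize alternative geometry block: path to a binary
#'   PNG mask and its physical pixel size in micrometres (see
#'   [importMask()]); overrides the parametric shape when given.
#' @param params named list of parameter overrides (empty = defaults).
#' @param direction,intercept,slope,duration,postRate protocol block; pass
#'   \code{duration = "sustained"} for a sustained stimulus.
#' @param tEnd,dtMax,absTol,relTol,recordBy solver block.
#' @param threshold front-display threshold (uM).
#' @param scenario optional scenario name.
#' @param seed reserved, unused (the model has no randomness).
#' @return a \code{runConfig} list.
#' @seealso [writeRunConfig()], [readRunConfig()], [runFromConfig()]
#' @export
runConfig <- function(shape = "teardrop", length = 50, width = 30,
                      nMesh = 110, maskFile = NULL, pixelSize = NULL,
                      params = list(), direction = "L-R",
                      intercept = 2.6, slope = 0.05, duration = 10,
                      postRate = 2.95, tEnd = 1000, dtMax = 0.25,
                      absTol = 1e-9, relTol = 1e-7, recordBy = 1,
                      threshold = 3, scenario = NULL, seed = NULL) {
  structure(list(
    geometry = list(shape = shape, length = length, width = width,
                    nMesh = nMesh, maskFile = maskFile,
                    pixelSize = pixelSize),
    params = params,
    protocol = list(direction = direction, intercept = intercept,
                    slope = slope, duration = duration, postRate = postRate),
    solver = list(tEnd = tEnd, dtMax = dtMax, absTol = absTol,
                  relTol = relTol, recordBy = recordBy),
    outputs = list(threshold = threshold),
    scenario = scenario, seed = seed
  ), class = "runConfig")
}

#' @rdname runConfig
#' @param config a \code{runConfig}.
#' @param file YAML path.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(runConfig, c(cfg$geometry, list(params = cfg$params),
                       cfg$protocol, cfg$solver, cfg$outputs,
                       list(scenario = cfg$scenario, seed = cfg$seed)))
}

## Short content hash of a config (md5 of its canonical YAML text), used to
## stamp every output file of a run.
.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeRunConfig(config, tf)
  substr(unname(tools::md5sum(tf)), 1L, 8L)
}

#' Execute a run configuration and write its artifacts
#'
#' Builds the objects described by a [runConfig()], runs the simulation and
#' writes, under \code{outDir}: a copy of the config (YAML), the
#' maximum-tracking summary as CSV (time, max value, max position, deltaC),
#' the classification row as CSV, per-species final-state matrices as CSV,
#' and a rendered PNG of the final active-Cdc42 field with the white
#' super-level region at the configured threshold. All file names carry the
#' config hash, so re-running a config overwrites its own artifacts.
#'
#' @param config a \code{runConfig} list, or the path to a YAML config.
#' @param outDir output directory (created if needed).
#' @param verbose print progress.
#' @return (invisibly) a list with the trajectory, the classification and
#'   the vector of files written.
#' @export
runFromConfig <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(config$seed) && verbose)
    message("note: 'seed' is reserved and unused (deterministic model)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  pfx <- function(name) file.path(outDir, paste0(hash, "_", name))

  geom <- if (!is.null(config$geometry$maskFile)) {
    importMask(config$geometry$maskFile, config$geometry$pixelSize,
               shapeName = config$geometry$shape)
  } else {
    makeShape(config$geometry$shape, config$geometry$length,
              config$geometry$width, config$geometry$nMesh)
  }
  pars <- do.call(polarityParams, config$params)
  prot <- stimulusProtocol(config$protocol$direction,
                           config$protocol$intercept, config$protocol$slope,
                           config$protocol$duration, config$protocol$postRate)
  cfg <- solverConfig(tEnd = config$solver$tEnd,
                      dtMax = config$solver$dtMax,
                      absTol = config$solver$absTol,
                      relTol = config$solver$relTol,
                      recordTimes = seq(0, config$solver$tEnd,
                                        by = config$solver$recordBy))
  traj <- simulatePolarity(geom, pars, prot, cfg, verbose = verbose)
  pat <- classifyPattern(traj, threshold = config$outputs$threshold)

  files <- character()
  f <- pfx("config.yaml"); writeRunConfig(config, f); files <- c(files, f)
  track <- trackMaximum(traj)
  track$deltaC <- vapply(track$t, function(t) deltaC(traj, t), 0)
  f <- pfx("max_tracking.csv")
  utils::write.csv(track, f, row.names = FALSE); files <- c(files, f)
  cls <- data.frame(shape = geom@shapeName, length = geom@length,
                    width = geom@width, direction = prot@direction,
                    label = pat@label, axis = pat@axis,
                    pattern = pat@patternName, frontCount = pat@frontCount,
                    deltaC = pat@deltaC, onsetTime = pat@onsetTime,
                    massDrift = max(traj@log$massDrift),
                    nSteps = traj@log$nSteps)
  f <- pfx("classification.csv")
  utils::write.csv(cls, f, row.names = FALSE); files <- c(files, f)
  for (sp in .SPECIES) {
    f <- pfx(sprintf("final_%s.csv", sp))
    utils::write.table(speciesField(traj@finalState, sp), f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  f <- pfx("final_C.png")
  grDevices::png(f, width = 600, height = 600)
  plotField(traj@finalState, "C", threshold = config$outputs$threshold,
            main = sprintf("%s %gx%g, %s, t = %g s", geom@shapeName,
                           geom@length, geom@width, prot@direction,
                           cfg@tEnd))
  grDevices::dev.off()
  files <- c(files, f)
  invisible(list(trajectory = traj, pattern = pat, files = files))
}

## ---- rendering ------------------------------------------------------------

#' Render a concentration field
#'
#' Draws one species of a [StateField-class] as a filled activity map;
#' cells above \code{threshold} are drawn white, matching the display
#' convention of the activity figures (thresholds 3 or 8 uM).
#'
#' @param state a [StateField-class].
#' @param species species name (default active Cdc42).
#' @param threshold white display level (uM), or \code{NULL} for none.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the full-grid matrix drawn.
#' @export
plotField <- function(state, species = "C", threshold = 3, main = species,
                      ...) {
  g <- state@geometry
  m <- speciesField(state, species)
  pal <- grDevices::hcl.colors(64, "viridis")
  zmax <- max(m, na.rm = TRUE)
  if (!is.null(threshold) && zmax > threshold) {
    m2 <- pmin(m, threshold)
    graphics::image(g@x, g@y, m2, col = pal, asp = 1, xlab = "x (um)",
                    ylab = "y (um)", main = main, ...)
    over <- which(!is.na(m) & m > threshold, arr.ind = TRUE)
    graphics::rect(g@x[over[, 1]] - g@h / 2, g@y[over[, 2]] - g@h / 2,
                   g@x[over[, 1]] + g@h / 2, g@y[over[, 2]] + g@h / 2,
                   col = "white", border = NA)
  } else {
    graphics::image(g@x, g@y, m, col = pal, asp = 1, xlab = "x (um)",
                    ylab = "y (um)", main = main, ...)
  }
  invisible(m)
}

## ---- packaged scenarios ---------------------------------------------------

.SCENARIOS <- c("fig4_teardrop_timecourse", "fig5_direction_grid",
                "fig6_strength_duration", "fig7_max_tracking",
                "fig8_aspect_ratio", "fig9_sensitivity",
                "fig10_phase_diagram")

#' Run a packaged end-to-end scenario
#'
#' Executes one of the named study scenarios and writes its aggregated CSV
#' tables (and rendered panels where applicable) under \code{outDir}. The
#' full-scale defaults reproduce the published experiments and can take
#' hours; \code{nMesh}, \code{tEnd} and the scenario-specific arguments
#' (\code{shapes}, \code{lengths}, \code{widths}, ...) allow scaled-down
#' runs.
#'
#' Scenarios: \code{fig4_teardrop_timecourse} (nine-species snapshots of a
#' 50 um teardrop), \code{fig5_direction_grid} (all shapes under L-R, R-L,
#' U-D), \code{fig6_strength_duration} (intercept/slope/duration variants),
#' \code{fig7_max_tracking} (maximum-tracking series for all shapes, L-R
#' and R-L), \code{fig8_aspect_ratio} (length x width sweep),
#' \code{fig9_sensitivity} (one-at-a-time parameter series),
#' \code{fig10_phase_diagram} ((a1, d_C) grids at n = 1, 4, 8).
#'
#' @param name scenario name, one of the above.
#' @param outDir output directory.
#' @param nMesh grid resolution.
#' @param tEnd simulation horizon (s).
#' @param verbose print progress.
#' @param ... scenario-specific overrides (e.g. \code{shapes},
#'   \code{lengths}, \code{widths}, \code{snapshotTimes}).
#' @return (invisibly) the scenario's summary data.frame.
#' @export
runScenario <- function(name, outDir, nMesh = 110, tEnd = 1000,
                        verbose = FALSE, ...) {
  name <- match.arg(name, .SCENARIOS)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dots <- list(...)
  arg <- function(key, default) if (!is.null(dots[[key]])) dots[[key]] else default
  allShapes <- c("circle", "square", "rectangle", "teardrop",
                 "narrow_drop", "wide_drop", "triangle")
  dimsOf <- function(s) switch(s,
    circle = , square = c(50, 50), rectangle = c(50, 30),
    teardrop = c(50, 30), narrow_drop = c(50, 20), wide_drop = c(50, 45),
    triangle = c(50, 40))
  res <- switch(name,
    fig4_teardrop_timecourse = {
      snapT <- arg("snapshotTimes", c(1, 10, 30, 100, 500, tEnd))
      snapT <- snapT[snapT <= tEnd]
      geom <- makeShape("teardrop", 50, 30, nMesh)
      cfg <- solverConfig(tEnd = tEnd, recordTimes = seq(0, tEnd, 1),
                          snapshotTimes = snapT)
      traj <- simulatePolarity(geom, config = cfg, verbose = verbose)
      for (tn in names(traj@snapshots)) {
        snap <- new("StateField", values = traj@snapshots[[tn]],
                    geometry = geom)
        grDevices::png(file.path(outDir, sprintf("fig4_t%s.png", tn)),
                       width = 1200, height = 900)
        graphics::par(mfrow = c(3, 3), mar = c(2, 2, 2, 1))
        for (sp in .SPECIES)
          plotField(snap, sp, threshold = 3,
                    main = sprintf("%s, t = %s s", sp, tn))
        grDevices::dev.off()
        for (sp in .SPECIES)
          utils::write.table(speciesField(snap, sp),
                             file.path(outDir,
                                       sprintf("fig4_t%s_%s.csv", tn, sp)),
                             sep = ",", row.names = FALSE, col.names = FALSE)
      }
      trackMaximum(traj)
    },
    fig5_direction_grid = {
      shapes <- arg("shapes", allShapes)
      rows <- list()
      for (s in shapes) for (dir in c("L-R", "R-L", "U-D")) {
        d <- dimsOf(s)
        rows[[length(rows) + 1L]] <- .classifiedRun(
          s, d[1], d[2], stimulusProtocol(dir), polarityParams(), nMesh,
          tEnd, extendTo = tEnd, dtMax = 0.25, recordBy = 5, threshold = 3,
          verbose = verbose)
      }
      do.call(rbind, rows)
    },
    fig6_strength_duration = {
      shapes <- arg("shapes", c("circle", "teardrop"))
      intercepts <- arg("intercepts", c(1.6, 2.6, 3.6))
      slopes <- arg("slopes", c(0.025, 0.05, 0.1))
      durations <- arg("durations", c(5, 10, 20, Inf))
      rows <- list()
      for (s in shapes) {
        d <- dimsOf(s)
        for (b in intercepts) for (m in slopes) {
          r <- .classifiedRun(s, d[1], d[2],
                              stimulusProtocol("L-R", b, m), polarityParams(),
                              nMesh, tEnd, tEnd, 0.25, 5, 3, verbose)
          r$intercept <- b; r$slope <- m; r$duration <- 10
          rows[[length(rows) + 1L]] <- r
        }
        for (tau in durations) {
          r <- .classifiedRun(s, d[1], d[2],
                              stimulusProtocol("L-R", duration = tau),
                              polarityParams(), nMesh, tEnd, tEnd, 0.25, 5,
                              3, verbose)
          r$intercept <- 2.6; r$slope <- 0.05; r$duration <- tau
          rows[[length(rows) + 1L]] <- r
        }
      }
      do.call(rbind, rows)
    },
    fig7_max_tracking = {
      shapes <- arg("shapes", allShapes)
      rows <- list()
      for (s in shapes) for (dir in c("L-R", "R-L")) {
        d <- dimsOf(s)
        geom <- makeShape(s, d[1], d[2], nMesh)
        traj <- simulatePolarity(geom, protocol = stimulusProtocol(dir),
                                 config = solverConfig(tEnd = tEnd),
                                 verbose = verbose)
        tr <- trackMaximum(traj)
        tr$shape <- s; tr$direction <- dir
        tr$deltaC30 <- deltaC(traj, 30)
        rows[[length(rows) + 1L]] <- tr
      }
      do.call(rbind, rows)
    },
    fig8_aspect_ratio = {
      shapes <- arg("shapes", c("teardrop", "rectangle", "ellipse"))
      lengths <- arg("lengths", seq(10, 90, 10))
      widths <- arg("widths", seq(10, 90, 10))
      do.call(rbind, lapply(shapes, function(s)
        aspectRatioSweep(s, lengths, widths, nMesh = nMesh, tEnd = tEnd,
                         verbose = verbose)))
    },
    fig9_sensitivity = {
      series <- arg("series", list(
        f = c(0, 0.1, 0.8), n = c(1, 4, 8),
        d_C = c(0.01, 0.1, 10), d_R = c(0.01, 0.1, 10),
        d_rho = c(0.01, 0.1, 10), a1 = c(0.5, 2, 2.25),
        D_m = c(0.01, 1), D_mc = c(5, 500), D_P = c(5, 500)))
      sensitivity1d(series, shapes = arg("shapes", c("circle", "teardrop")),
                    nMesh = nMesh, tEnd = tEnd, verbose = verbose)
    },
    fig10_phase_diagram = {
      shapes <- arg("shapes", c("circle", "teardrop"))
      do.call(rbind, lapply(shapes, function(s) {
        d <- dimsOf(s)
        pd <- phaseDiagram(arg("nLevels", c(1, 4, 8)),
                           arg("a1Values", c(0.5, 1.25, 2, 2.25)),
                           arg("dValues", c(0.01, 0.1, 1, 10)),
                           shape = s, length = d[1], width = d[2],
                           nMesh = nMesh, tEnd = tEnd, verbose = verbose)
        pd$shape <- s
        pd
      }))
    }
  )
  utils::write.csv(res, file.path(outDir, paste0(name, ".csv")),
                   row.names = FALSE)
  invisible(res)
}
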