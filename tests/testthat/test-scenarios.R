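test_that("run configs round-trip through YAML and drive a full run", {
  cfg <- runConfig(shape = "circle", length = 16, width = 16, nMesh = 28,
                   params = list(f = 0.2), tEnd = 6, recordBy = 2,
                   dtMax = 0.5)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeRunConfig(cfg, f)
  cfg2 <- readRunConfig(f)
  expect_equal(cfg2$geometry, cfg$geometry)
  expect_equal(cfg2$params$f, 0.2)
  expect_equal(cfg2$solver$tEnd, 6)

  out <- file.path(tempdir(), "sp-run-test")
  res <- runFromConfig(cfg, out)
  expect_true(all(file.exists(res$files)))
  expect_true(any(grepl("max_tracking[.]csv$", res$files)))
  expect_true(any(grepl("classification[.]csv$", res$files)))
  expect_true(any(grepl("final_C[.]png$", res$files)))
  track <- read.csv(res$files[grepl("max_tracking", res$files)])
  expect_equal(track$t, seq(0, 6, 2))
  ## deterministic pipeline: rerunning overwrites with identical content
  sum1 <- tools::md5sum(res$files[grepl("max_tracking", res$files)])
  res2 <- runFromConfig(cfg, out)
  expect_identical(unname(tools::md5sum(res2$files[grepl("max_tracking", res2$files)])),
                   unname(sum1))
  unlink(out, recursive = TRUE)
})

test_that("output files are stamped with the config hash", {
  cfg <- runConfig(shape = "circle", length = 16, width = 16, nMesh = 28,
                   tEnd = 4, recordBy = 2, dtMax = 0.5)
  out <- file.path(tempdir(), "sp-hash-test")
  res <- runFromConfig(cfg, out)
  hashes <- unique(sub("_.*$", "", basename(res$files)))
  expect_length(hashes, 1)
  expect_match(hashes, "^[0-9a-f]{8}$")
  unlink(out, recursive = TRUE)
})

test_that("named scenarios write their aggregated tables", {
  out <- file.path(tempdir(), "sp-scenario-test")
  res <- runScenario("fig7_max_tracking", out, nMesh = 28, tEnd = 6,
                     shapes = c("circle"))
  expect_true(file.exists(file.path(out, "fig7_max_tracking.csv")))
  expect_setequal(unique(res$direction), c("L-R", "R-L"))
  res4 <- runScenario("fig4_teardrop_timecourse", out, nMesh = 28, tEnd = 4,
                      snapshotTimes = c(1, 4))
  expect_true(file.exists(file.path(out, "fig4_t4_C.csv")))
  expect_true(file.exists(file.path(out, "fig4_t1.png")))
  expect_error(runScenario("fig99", out), "arg")
  unlink(out, recursive = TRUE)
})

test_that("field rendering returns the drawn matrix with the mask as NA", {
  g <- makeShape("teardrop", 16, 10, 28)
  st <- initialState(g, polarityParams())
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  m <- plotField(st, "C", threshold = 3)
  grDevices::dev.off()
  unlink(f)
  expect_equal(dim(m), c(28, 28))
  expect_true(all(is.na(m[!insideMask(g)])))
  expect_equal(unique(m[insideMask(g)]), 1)
})
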