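test_that("rasterized areas match analytic areas and improve with resolution", {
  cases <- list(
    list(shape = "circle", L = 50, W = 50, area = pi * 25^2),
    list(shape = "ellipse", L = 50, W = 30, area = pi * 25 * 15),
    list(shape = "rectangle", L = 50, W = 30, area = 50 * 30)
  )
  for (cs in cases) {
    err <- vapply(c(110L, 220L), function(nm) {
      g <- makeShape(cs$shape, cs$L, cs$W, nm)
      abs(maskArea(g) - cs$area) / cs$area
    }, 0)
    expect_lt(err[1], 0.02)
    expect_lte(err[2], err[1] / 2 + 1e-12)
  }
})

test_that("bounding boxes agree with the requested dimensions", {
  for (shape in c("rectangle", "circle", "teardrop", "narrow_drop",
                  "wide_drop", "triangle")) {
    L <- if (shape == "circle") 40 else 50
    W <- if (shape == "circle") 40 else 30
    g <- makeShape(shape, L, W, 110)
    ins <- insideMask(g)
    h <- spacing(g)
    ix <- range(which(rowSums(ins) > 0))
    iy <- range(which(colSums(ins) > 0))
    expect_lt(abs((ix[2] - ix[1] + 1) * h - L), 1.5 * h)
    expect_lt(abs((iy[2] - iy[1] + 1) * h - W), 1.5 * h)
    ## longest extent plus 2-cell margin spans the mesh
    expect_equal(max(L, W) / h + 2, 110)
  }
})

test_that("masks are single 4-connected components with the right symmetries", {
  mirrorX <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  mirrorY <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  for (shape in c("circle", "ellipse", "square", "rectangle")) {
    g <- makeShape(shape, 48, if (shape %in% c("circle", "square")) 48 else 26,
                   96)
    ins <- insideMask(g)
    expect_identical(ins, mirrorY(ins), label = paste(shape, "h-mirror"))
    expect_identical(ins, mirrorX(ins), label = paste(shape, "v-mirror"))
  }
  for (shape in c("teardrop", "narrow_drop", "wide_drop", "triangle")) {
    g <- makeShape(shape, 50, 30, 110)
    ins <- insideMask(g)
    expect_identical(ins, mirrorY(ins), label = paste(shape, "h-mirror"))
    ## asymmetric along x: differs from its left-right mirror in >= 1% of cells
    expect_gt(sum(ins != mirrorX(ins)) / sum(ins), 0.01)
  }
})

test_that("drop variants differ from each other at equal bounding box", {
  g1 <- makeShape("teardrop", 50, 30, 110)
  g2 <- makeShape("narrow_drop", 50, 30, 110)
  g3 <- makeShape("wide_drop", 50, 30, 110)
  expect_gt(sum(insideMask(g1) != insideMask(g2)), 0)
  expect_lt(maskArea(g2), maskArea(g1))
  expect_gt(maskArea(g3), maskArea(g1))
})

test_that("degenerate and unknown shapes are rejected", {
  expect_error(makeShape("hexagon", 50, 50, 110), "arg")
  expect_error(makeShape("rectangle", 50, 1, 110), "degenerate")
  expect_error(makeShape("rectangle", 50, 30, 10), "nMesh")
  expect_error(makeShape("rectangle", -5, 30, 110))
})

test_that("mask export/import round-trips exactly", {
  g <- makeShape("triangle", 50, 40, 110)
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  exportMask(g, f)
  g2 <- importMask(f, pixelSize = spacing(g), shapeName = "triangle")
  expect_identical(insideMask(g2), insideMask(g))
  expect_equal(spacing(g2), spacing(g))
  ## coordinates are anchored at the bounding box in both
  expect_equal(min(interiorCoords(g2)[, 1]), min(interiorCoords(g)[, 1]))
})

test_that("import rejects empty and multi-component images", {
  blank <- matrix(FALSE, 20, 20)
  expect_error(importMask(blank, 1), "empty")
  two <- blank
  two[2:4, 2:4] <- TRUE
  two[10:12, 10:12] <- TRUE
  expect_error(importMask(two, 1), "single 4-connected")
  ## diagonal touching does not connect under 4-connectivity
  diag2 <- blank
  diag2[5, 5] <- TRUE
  diag2[6, 6] <- TRUE
  expect_error(importMask(diag2, 1), "single 4-connected")
})
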