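## ---- 4-connected component labelling -------------------------------------
## Used both for mask validity and for counting polarization fronts. The
## classification rules are defined on 4-connectivity, so this is implemented
## directly (a simple scanline flood fill) rather than delegated to an image
## package with a different neighbourhood convention.

.label4 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nextLab <- 0L
  queue <- integer(sum(mask))
  for (s in which(mask & lab == 0L)) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    lab[s] <- nextLab
    queue[1L] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      i <- ((cur - 1L) %% nx) + 1L
      j <- ((cur - 1L) %/% nx) + 1L
      if (i > 1L) { nb <- cur - 1L
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; tail <- tail + 1L; queue[tail] <- nb } }
      if (i < nx) { nb <- cur + 1L
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; tail <- tail + 1L; queue[tail] <- nb } }
      if (j > 1L) { nb <- cur - nx
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; tail <- tail + 1L; queue[tail] <- nb } }
      if (j < ny) { nb <- cur + nx
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; tail <- tail + 1L; queue[tail] <- nb } }
    }
  }
  lab
}

.nComponents4 <- function(mask) max(.label4(mask))

## ---- analytic shape outlines ---------------------------------------------
## Every outline is defined on the unit bounding box [0, L] x [0, W] and
## evaluated at cell centres. All shapes are mirror-symmetric about the
## horizontal midline y = W/2; the "symmetric" shapes are additionally
## mirror-symmetric about the vertical midline. The drop family (teardrop,
## narrow_drop, wide_drop) is a blunt elliptical cap at +x joined to a tail
## tapering to a point at -x; the tail half-width follows (x / xt)^p with
## p = 1 (straight flanks), p > 1 (concave, narrow) or p < 1 (convex, wide).

.SHAPES <- c("circle", "ellipse", "square", "rectangle",
             "teardrop", "narrow_drop", "wide_drop", "triangle")

## `xrel`, `yrel` are cell-centre offsets from the shape centre. They are
## exactly antisymmetric under mirroring (built as integer half-offsets times
## h), so mirror-image cells give bit-identical inclusion tests and rasterized
## masks carry the exact mirror symmetries of the analytic outlines.
.shapeInside <- function(shape, xrel, yrel, L, W, h) {
  XR <- outer(xrel, rep(1, length(yrel)))
  AY <- outer(rep(1, length(xrel)), abs(yrel))
  X <- XR + L / 2                 # distance from the shape's left edge
  ## tapered outlines (drop tails, triangle apex) get a minimum half-width of
  ## one half cell so that the raster carries the point all the way to the
  ## apex: sub-cell-thin tips are represented by a one-cell-wide spine
  taper <- function(halfW) {
    AY <= pmax(halfW, (h / 2) * (halfW > 0)) & X >= 0 & X <= L
  }
  drop <- function(p) {
    a <- min(L, W) / 2            # x-semiaxis of the blunt cap
    x0 <- L - a                   # cap centre; tail spans [0, x0]
    halfW <- ifelse(X >= x0,
                    (W / 2) * sqrt(pmax(0, 1 - ((X - x0) / a)^2)),
                    (W / 2) * (pmax(X, 0) / x0)^p)
    taper(halfW)
  }
  switch(shape,
    circle = ,
    ellipse = (2 * XR / L)^2 + (2 * AY / W)^2 <= 1,
    square = ,
    rectangle = abs(XR) <= L / 2 & AY <= W / 2,
    teardrop = drop(1),
    narrow_drop = drop(1.6),
    wide_drop = drop(0.6),
    triangle = taper(ifelse(X >= 0, (W / 2) * (X / L), -1)),
    stop("unknown shape name: ", shape)
  )
}

## ---- constructors ---------------------------------------------------------

#' Generate a rasterized cell-shape mask
#'
#' Rasterizes one of the built-in cell outlines onto a regular square-cell
#' grid of \code{nMesh} x \code{nMesh} elements. The grid spacing is chosen
#' so that the longest shape extent plus a two-cell margin spans the mesh,
#' and the shape is centred. Symmetric shapes (\code{circle}, \code{ellipse},
#' \code{square}, \code{rectangle}) have two mirror axes; the asymmetric
#' shapes (\code{teardrop}, \code{narrow_drop}, \code{wide_drop},
#' \code{triangle}) have a single horizontal mirror axis, with the blunt end
#' at +x and the point or apex at -x.
#'
#' @param shape character, one of \code{"circle"}, \code{"ellipse"},
#'   \code{"square"}, \code{"rectangle"}, \code{"teardrop"},
#'   \code{"narrow_drop"}, \code{"wide_drop"}, \code{"triangle"}.
#' @param length,width shape extent along x and y in micrometres.
#' @param nMesh integer >= 20, number of grid cells per axis (default 110).
#' @return A [CellGeometry-class].
#' @examples
#' geom <- makeShape("circle", 50, 50, nMesh = 110)
#' maskArea(geom)        # close to pi * 25^2
#' @export
makeShape <- function(shape, length, width, nMesh = 110L) {
  shape <- match.arg(shape, .SHAPES)
  if (!(length > 0) || !(width > 0)) stop("length and width must be positive")
  nMesh <- as.integer(nMesh)
  if (nMesh < 20L) stop("nMesh must be at least 20")
  ext <- max(length, width)
  h <- ext / (nMesh - 2L)          # longest extent + 2-cell margin = nMesh cells
  if (length < 3 * h || width < 3 * h)
    stop("degenerate dimensions: length and width must be at least 3 grid cells")
  ## cell-centre offsets from the grid centre (exactly antisymmetric), then
  ## shifted so the origin sits at the shape's left/bottom bounding-box edge
  rel <- (seq_len(nMesh) - (nMesh + 1) / 2) * h
  x <- rel + length / 2
  y <- rel + width / 2
  inside <- .shapeInside(shape, rel, rel, length, width, h)
  new("CellGeometry", nx = nMesh, ny = nMesh, h = h, inside = inside,
      shapeName = shape, length = length, width = width, x = x, y = y)
}

#' Import a cell mask from a binary raster
#'
#' Builds a [CellGeometry-class] from an 8-bit grayscale PNG file (foreground
#' = gray value above 127) or directly from a logical matrix, with a given
#' physical pixel size. The image must contain exactly one 4-connected
#' foreground component. Image rows are read top-to-bottom and flipped so
#' that +y points upward.
#'
#' @param image path to a PNG file, or a logical/numeric matrix (rows = y
#'   from top, as stored in an image file).
#' @param pixelSize physical size of one pixel in micrometres.
#' @param shapeName label stored on the resulting geometry.
#' @return A [CellGeometry-class].
#' @seealso [exportMask()]
#' @export
importMask <- function(image, pixelSize, shapeName = "imported") {
  if (is.character(image)) {
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    fg <- img > (127 / 255)
  } else {
    fg <- if (is.logical(image)) image else image > 127
  }
  ## image convention: row 1 = top; flip to +y up, transpose to [x, y]
  inside <- t(fg[rev(seq_len(nrow(fg))), , drop = FALSE])
  if (!any(inside)) stop("empty foreground: no pixel above threshold")
  if (.nComponents4(inside) != 1L)
    stop("foreground must be a single 4-connected component")
  ix <- range(which(rowSums(inside) > 0))
  iy <- range(which(colSums(inside) > 0))
  L <- (ix[2] - ix[1] + 1) * pixelSize
  W <- (iy[2] - iy[1] + 1) * pixelSize
  nx <- nrow(inside); ny <- ncol(inside)
  x <- (seq_len(nx) - 0.5) * pixelSize - (ix[1] - 1) * pixelSize
  y <- (seq_len(ny) - 0.5) * pixelSize - (iy[1] - 1) * pixelSize
  new("CellGeometry", nx = nx, ny = ny, h = pixelSize, inside = inside,
      shapeName = shapeName, length = L, width = W, x = x, y = y)
}

#' Export a cell mask to an 8-bit grayscale PNG
#'
#' Foreground (interior) pixels are written as white (255), background as
#' black, using the image convention (first row = top). A mask written with
#' \code{exportMask} and re-read with [importMask()] at the same pixel size
#' reproduces the mask exactly.
#'
#' @param geometry a [CellGeometry-class].
#' @param file output PNG path.
#' @return \code{file}, invisibly.
#' @export
exportMask <- function(geometry, file) {
  m <- t(geometry@inside)[rev(seq_len(geometry@ny)), , drop = FALSE]
  png::writePNG(m * 1.0, target = file)
  invisible(file)
}

## ---- accessors ------------------------------------------------------------

#' @describeIn CellGeometry logical interior mask (nx by ny matrix).
#' @param object,geometry a \code{CellGeometry}.
#' @aliases insideMask
#' @export
insideMask <- function(geometry) geometry@inside

#' @describeIn CellGeometry grid spacing in micrometres.
#' @export
spacing <- function(geometry) geometry@h

#' @describeIn CellGeometry shape label.
#' @export
shapeName <- function(geometry) geometry@shapeName

#' @describeIn CellGeometry number of interior cells.
#' @export
nInterior <- function(geometry) sum(geometry@inside)

#' @describeIn CellGeometry rasterized area in square micrometres
#'   (interior cell count times \code{h^2}).
#' @export
maskArea <- function(geometry) sum(geometry@inside) * geometry@h^2

#' @describeIn CellGeometry cell-centre coordinates of the interior cells,
#'   as a two-column matrix (um from the shape's left/bottom edge).
#' @export
interiorCoords <- function(geometry) {
  idx <- which(geometry@inside, arr.ind = TRUE)
  cbind(x = geometry@x[idx[, 1]], y = geometry@y[idx[, 2]])
}

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry '%s': %.4g um x %.4g um on a %d x %d grid (h = %.4g um)\n",
    object@shapeName, object@length, object@width, object@nx, object@ny,
    object@h))
  cat(sprintf("  %d interior cells, area %.4g um^2\n",
              sum(object@inside), maskArea(object)))
})
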