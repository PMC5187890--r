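#' Extract an intensity profile along a line crossing the membrane
#'
#' Samples the image along the segment from `pStart` to `pEnd` by bilinear
#' interpolation at (approximately) unit-pixel spacing: `ceiling(L) + 1`
#' evenly spaced samples including both endpoints, so that reversing the
#' endpoints yields the reversed profile.  Coordinates are 0-based pixel
#' centres, `x` along columns and `y` along rows.
#'
#' A matched cell-free background line of the same number of samples can be
#' extracted in the same call via `bgStart`/`bgEnd`, mirroring the manual
#' workflow of measuring the background along the same distance.
#'
#' @param image numeric matrix (rows = y).
#' @param pStart,pEnd numeric `c(x, y)` endpoints, inside the image.
#' @param bgStart,bgEnd optional endpoints of the background line.
#' @param cellId,lineId identifiers.
#' @return a [LineProfile-class].
#' @examples
#' img <- generateCellImage(0.5, blurSdPx = 0, noiseSd = 0)
#' ln <- img$lines[img$lines$role == "cell", ][1, ]
#' extractProfile(img$image, c(ln$x0, ln$y0), c(ln$x1, ln$y1))
#' @export
extractProfile <- function(image, pStart, pEnd, bgStart = NULL,
                           bgEnd = NULL, cellId = "cell1",
                           lineId = "line1") {
  len <- sqrt(sum((pEnd - pStart)^2))
  if (len == 0) stop("zero-length line")
  n <- as.integer(ceiling(len)) + 1L
  sampleLine <- function(p0, p1) {
    xs <- seq(p0[1], p1[1], length.out = n)
    ys <- seq(p0[2], p1[2], length.out = n)
    if (any(xs < 0 | xs > ncol(image) - 1 | ys < 0 | ys > nrow(image) - 1))
      stop("line endpoints must lie inside the image bounds")
    bilinear(image, xs, ys)
  }
  bg <- if (!is.null(bgStart)) sampleLine(bgStart, bgEnd) else numeric(0)
  new("LineProfile",
      positions = seq(0, len, length.out = n),
      intensities = sampleLine(pStart, pEnd),
      background = bg,
      cellId = as.character(cellId), lineId = as.character(lineId))
}

## bilinear interpolation at 0-based pixel-centre coordinates
bilinear <- function(image, xs, ys) {
  x0 <- pmin(floor(xs), ncol(image) - 2)
  y0 <- pmin(floor(ys), nrow(image) - 2)
  fx <- xs - x0
  fy <- ys - y0
  i <- function(r, c) image[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * i(y0, x0) + fx * (1 - fy) * i(y0, x0 + 1) +
    (1 - fx) * fy * i(y0 + 1, x0) + fx * fy * i(y0 + 1, x0 + 1)
}

#' Relative membrane expression from one line profile
#'
#' Implements the line-profile score: the mean background intensity is
#' subtracted from the peak intensity along the line and the difference is
#' divided by the maximal fluorescence,
#' `value = (max(profile) - mean(background)) / imageMax`, clipped to
#' `[0, 1]`.  The peak is the maximum sample on the line (no sub-pixel
#' refinement).  By default the normalisation constant is per-image (the
#' caller passes the analysed image's maximal fluorescence); setting
#' `normalize = "profile"` instead divides by the profile's own maximum.
#'
#' @param profile a [LineProfile-class] with a background attached.
#' @param imageMax maximal fluorescence, a.u. (required for
#'   `normalize = "image"`).
#' @param normalize `"image"` (default) or `"profile"`.
#' @return a single value in `[0, 1]` with logical attribute `clipped`
#'   (TRUE when the raw value fell outside `[0, 1]`, e.g. background above
#'   the peak).
#' @examples
#' p <- new("LineProfile", positions = 0:2, intensities = c(30, 100, 30),
#'          background = rep(20, 3), cellId = "c", lineId = "l")
#' relativeMembraneExpression(p, imageMax = 160)  # 0.5
#' @export
relativeMembraneExpression <- function(profile, imageMax = NULL,
                                       normalize = c("image", "profile")) {
  normalize <- match.arg(normalize)
  stopifnot(is(profile, "LineProfile"))
  if (length(profile@background) == 0L)
    stop("profile has no background line attached")
  if (normalize == "profile") imageMax <- max(profile@intensities)
  if (is.null(imageMax) || imageMax <= 0)
    stop("imageMax must be a positive number")
  raw <- (max(profile@intensities) - mean(profile@background)) / imageMax
  value <- min(max(raw, 0), 1)
  if (raw < 0)
    warning("background exceeds the peak; value clipped to 0")
  attr(value, "clipped") <- raw < 0 || raw > 1
  value
}

#' Aggregate per-line expression values into per-cell and cohort statistics
#'
#' Each cell's value is the mean over its profile lines (three in the
#' reference workflow; other counts are included with a warning), and the
#' cohort mean and SD are computed across cells, not across pooled lines.
#' Fewer than 30 cells triggers a warning, not a failure.
#'
#' @param perLine data.frame with columns `cellId`, `lineId`, `value` (each
#'   value in `[0, 1]`), e.g. assembled from
#'   [relativeMembraneExpression()] results.
#' @return a [MembraneExpression-class].
#' @export
aggregateCells <- function(perLine) {
  stopifnot(all(c("cellId", "lineId", "value") %in% names(perLine)))
  if (nrow(perLine) == 0L) stop("need >= 1 cell")
  clipped <- perLine$value < 0 | perLine$value > 1
  perLine$value <- pmin(pmax(perLine$value, 0), 1)
  cells <- split(perLine, perLine$cellId)
  nl <- vapply(cells, nrow, 0L)
  if (any(nl != 3L))
    warning(sum(nl != 3L), " cell(s) with a line count other than 3")
  perCell <- data.frame(cellId = names(cells),
                        value = vapply(cells, function(g) mean(g$value),
                                       numeric(1)),
                        nLines = nl, row.names = NULL)
  if (nrow(perCell) < 30L)
    warning("cohort statistics from fewer than 30 cells (n = ",
            nrow(perCell), ")")
  new("MembraneExpression", perLine = perLine, perCell = perCell,
      cohortMean = mean(perCell$value),
      cohortSd = if (nrow(perCell) > 1L) stats::sd(perCell$value)
                 else NA_real_,
      nCells = nrow(perCell), nClipped = as.integer(sum(clipped)))
}

#' Quantify membrane expression of an image from a table of profile lines
#'
#' Convenience chain over [extractProfile()],
#' [relativeMembraneExpression()] and [aggregateCells()].  `lines` uses the
#' package's lines interchange layout: columns `cellId`, `lineId`, `role`
#' (`cell` or `background`), `x0`, `y0`, `x1`, `y1`; each cell line is
#' paired with the background line sharing its `(cellId, lineId)`.
#'
#' @param image numeric matrix.
#' @param lines data.frame as described above.
#' @param imageMax maximal fluorescence; defaults to the image maximum
#'   (per-image normalisation).
#' @param normalize passed to [relativeMembraneExpression()].
#' @return a [MembraneExpression-class].
#' @examples
#' img <- generateCellImage(0.37, blurSdPx = 0, noiseSd = 0)
#' quantifyMembrane(img$image, img$lines,
#'                  imageMax = img$groundTruth$imageMax)
#' @export
quantifyMembrane <- function(image, lines, imageMax = max(image),
                             normalize = "image") {
  cellLines <- lines[lines$role == "cell", , drop = FALSE]
  bgLines <- lines[lines$role == "background", , drop = FALSE]
  vals <- lapply(seq_len(nrow(cellLines)), function(i) {
    cl <- cellLines[i, ]
    bg <- bgLines[bgLines$cellId == cl$cellId &
                    bgLines$lineId == cl$lineId, , drop = FALSE]
    if (nrow(bg) != 1L)
      stop("no unique background line for ", cl$cellId, "/", cl$lineId)
    pr <- extractProfile(image, c(cl$x0, cl$y0), c(cl$x1, cl$y1),
                         bgStart = c(bg$x0, bg$y0), bgEnd = c(bg$x1, bg$y1),
                         cellId = cl$cellId, lineId = cl$lineId)
    data.frame(cellId = cl$cellId, lineId = cl$lineId,
               value = as.numeric(relativeMembraneExpression(
                 pr, imageMax = imageMax, normalize = normalize)))
  })
  aggregateCells(do.call(rbind, vals))
}
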