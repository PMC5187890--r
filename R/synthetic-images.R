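#' Generate a synthetic fluorescence image of a cell with a membrane ring
#'
#' Renders a bright annulus (the GFP-tagged channel at the plasma membrane)
#' on a uniform background, so that the noiseless, unblurred image satisfies
#' the line-profile quantification identity exactly: the ring's peak
#' intensity is `background + expressionTrue * imageMax`, hence
#' `(peak - background)/imageMax = expressionTrue`.  Optional Gaussian blur
#' emulates the microscope point-spread function and additive Gaussian noise
#' the camera.
#'
#' Coordinates are 0-based pixel centres.  Alongside the image the generator
#' returns the ground-truth annulus mask (pre-blur), three suggested profile
#' lines through the cell centre (0, 60 and 120 degrees) with matched
#' cell-free background lines along the top edge, and the generative
#' parameters.
#'
#' @param expressionTrue true relative membrane expression in `[0, 1]`.
#' @param size image side, pixels (square image).
#' @param radiusPx ring radius, pixels; must be positive and smaller than
#'   half the image size.
#' @param ringWidthPx radial width of the annulus, pixels.
#' @param background background intensity, a.u.; must be below `imageMax`.
#' @param imageMax maximal fluorescence used for normalisation, a.u.
#' @param blurSdPx Gaussian blur SD, pixels (0 = none).
#' @param noiseSd additive Gaussian noise SD, a.u. (0 = none).
#' @param seed integer seed for the noise.
#' @param cellId identifier stamped on the suggested lines.
#' @return list with elements `image` (numeric matrix, rows = y), `mask`
#'   (logical matrix, the unblurred annulus), `lines` (data.frame of
#'   suggested cell and background lines: cellId, lineId, role, x0, y0, x1,
#'   y1), and `groundTruth` (named list).
#' @examples
#' img <- generateCellImage(0.5, blurSdPx = 0, noiseSd = 0)
#' max(img$image)  # background + 0.5 * imageMax
#' @export
generateCellImage <- function(expressionTrue, size = 64, radiusPx = 12,
                              ringWidthPx = 5, background = 20,
                              imageMax = 160, blurSdPx = 1, noiseSd = 2,
                              seed = NULL, cellId = "cell1") {
  if (expressionTrue < 0 || expressionTrue > 1)
    stop("expressionTrue must lie in [0, 1]")
  if (radiusPx <= 0 || radiusPx >= size / 2)
    stop("radiusPx must be positive and smaller than the image half-size")
  if (background >= imageMax) stop("background must be below imageMax")

  centre <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), nrow = size)   # column index
  ys <- matrix(rep(0:(size - 1), times = size), nrow = size)  # row index
  r <- sqrt((xs - centre)^2 + (ys - centre)^2)
  mask <- abs(r - radiusPx) <= ringWidthPx / 2
  img <- matrix(background, size, size)
  img[mask] <- background + expressionTrue * imageMax

  if (blurSdPx > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = blurSdPx))
  if (noiseSd > 0)
    img <- img + withSeed(seed, function()
      matrix(stats::rnorm(size^2, sd = noiseSd), size, size))

  ## three diameters through the centre plus matched background lines far
  ## from the ring (top edge); lines span the full ring on both sides
  half <- radiusPx + min(ringWidthPx, 6)
  angles <- c(0, 60, 120) * pi / 180
  lines <- do.call(rbind, lapply(seq_along(angles), function(i) {
    dx <- cos(angles[i]) * half
    dy <- sin(angles[i]) * half
    cellLine <- data.frame(cellId = cellId,
                           lineId = paste0("line", i), role = "cell",
                           x0 = centre - dx, y0 = centre - dy,
                           x1 = centre + dx, y1 = centre + dy)
    bgLine <- data.frame(cellId = cellId,
                         lineId = paste0("line", i), role = "background",
                         x0 = 1, y0 = 1, x1 = 1 + 2 * half, y1 = 1)
    rbind(cellLine, bgLine)
  }))

  list(image = img, mask = mask, lines = lines,
       groundTruth = list(expressionTrue = expressionTrue,
                          radiusPx = radiusPx, ringWidthPx = ringWidthPx,
                          background = background, imageMax = imageMax,
                          blurSdPx = blurSdPx, noiseSd = noiseSd,
                          centre = centre, seed = seed))
}

#' Read or write a grayscale cell image
#'
#' Thin wrappers around EBImage for 16-bit grayscale TIFF (or PNG) files.
#' Intensities are stored scaled to `[0, 1]` by `scale`; reading multiplies
#' the scale back.
#'
#' @param image numeric matrix of intensities (a.u.).
#' @param path file path; format follows the extension (.tif/.tiff/.png).
#' @param scale full-scale intensity mapped to 1.0 in the file.
#' @return `readCellImage` returns a numeric matrix; `writeCellImage`
#'   returns `path` invisibly.
#' @export
writeCellImage <- function(image, path, scale = 65535) {
  EBImage::writeImage(image / scale, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeCellImage
#' @export
readCellImage <- function(path, scale = 65535) {
  img <- EBImage::readImage(path)
  as.matrix(img) * scale
}
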