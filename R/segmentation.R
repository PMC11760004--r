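#' Read an RGB or grayscale cross-section image
#'
#' Reads a PNG, TIFF or JPEG image and returns an H x W x 3 integer array of
#' 8-bit intensities (row-major: first index is the image row).  Grayscale
#' inputs are replicated across the three channels; higher bit depths are
#' rescaled to 8-bit.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return integer array of dimension `c(H, W, 3)`, values in 0..255.
#' @export
read_rgb_image <- function(path) {
  px <- EBImage::imageData(EBImage::readImage(path))  # doubles in [0, 1]
  d <- dim(px)
  if (length(d) == 2L) {
    arr <- array(px, dim = c(d[1], d[2], 3))
  } else if (d[3] >= 3L) {
    arr <- px[, , 1:3, drop = FALSE]
  } else {
    arr <- array(px[, , 1L], dim = c(d[1], d[2], 3))
  }
  # EBImage stores x (width) first; transpose to row-major H x W
  out <- array(0L, dim = c(d[2], d[1], 3))
  for (ch in 1:3) out[, , ch] <- as.integer(round(t(arr[, , ch]) * 255))
  out[out < 0L] <- 0L
  out[out > 255L] <- 255L
  out
}

#' Convert an RGB image array to 8-bit luminance
#'
#' Applies the ITU-R 601 luma weights
#' `round(0.299 R + 0.587 G + 0.114 B)`, clipped to 0..255.
#'
#' @param img H x W x 3 array of 8-bit intensities (see [read_rgb_image()]),
#'   or an H x W matrix which is returned clipped unchanged.
#' @return integer H x W matrix of intensities in 0..255.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    g <- round(img)
  } else {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
    g <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    dim(g) <- dim(img)[1:2]             # keep matrix shape for 1-pixel edges
  }
  g <- pmin(pmax(g, 0), 255)
  dim(g) <- if (is.matrix(img)) dim(img) else dim(img)[1:2]
  storage.mode(g) <- "integer"
  g
}

#' Read a region-of-interest mask
#'
#' Accepts either a binary image (PNG/TIFF; nonzero = inside) of the same
#' dimensions as the paired cross-section image, or a plain-text polygon file
#' with one `x,y` vertex per line (0-based pixel coordinates, polygon closed
#' implicitly) which is rasterized by even-odd fill.
#'
#' @param path path to the mask image or polygon text file.
#' @param dim `c(H, W)` of the paired image; required for polygon input and
#'   used to validate image input.
#' @return logical H x W matrix, `TRUE` inside the ROI.
#' @export
read_roi_mask <- function(path, dim = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("txt", "csv", "poly")) {
    if (is.null(dim)) mf_stop("config", "polygon ROI requires image dimensions")
    v <- utils::read.csv(path, header = FALSE)
    polygon_to_mask(as.matrix(v), height = dim[1], width = dim[2])
  } else {
    m <- EBImage::readImage(path)
    px <- EBImage::imageData(m)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    roi <- t(px) > 0
    if (!is.null(dim) && !identical(base::dim(roi), as.integer(dim)))
      mf_stop("pairing", "ROI mask dimensions %dx%d do not match image %dx%d",
              nrow(roi), ncol(roi), dim[1], dim[2])
    roi
  }
}

#' Rasterize a polygon to a pixel mask by even-odd fill
#'
#' A pixel is inside when a ray from its center crosses the polygon boundary
#' an odd number of times (PNPOLY crossing rule).  Vertices are 0-based
#' `(x, y)` pixel-center coordinates; pixel `(r, c)` (1-based) has center
#' `(x, y) = (c - 1, r - 1)`.
#'
#' @param vertices n x 2 numeric matrix of `(x, y)` vertices.
#' @param height,width output mask dimensions.
#' @return logical `height` x `width` matrix.
#' @export
polygon_to_mask <- function(vertices, height, width) {
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])  # previous vertex
  mask <- matrix(FALSE, height, width)
  xs <- 0:(width - 1)
  for (r in seq_len(height)) {
    y <- r - 1
    inside <- rep(FALSE, width)
    for (e in seq_len(n)) {
      if ((vy[e] > y) != (jy[e] > y)) {
        xint <- (jx[e] - vx[e]) * (y - vy[e]) / (jy[e] - vy[e]) + vx[e]
        inside <- xor(inside, xs < xint)
      }
    }
    mask[r, ] <- inside
  }
  mask
}

#' Otsu threshold of ROI-restricted intensities
#'
#' Builds the 256-bin histogram from the pixels inside the ROI only (the
#' image background is excluded so it cannot bias the threshold) and returns
#' the integer threshold `t` in 0..254 that maximizes the between-class
#' variance of the two classes `{intensity <= t}` and `{intensity > t}`.
#' Ties are broken toward the smallest maximizing threshold so results are
#' reproducible.
#'
#' @param gray integer H x W matrix of intensities in 0..255.
#' @param roi logical H x W matrix (`TRUE` = inside the muscle region).
#' @param method thresholding algorithm; only `"otsu"` is implemented (hook
#'   for alternatives).
#' @return integer threshold in 0..254.
#' @export
otsu_threshold <- function(gray, roi = NULL, method = c("otsu")) {
  method <- match.arg(method)
  vals <- if (is.null(roi)) as.vector(gray) else gray[roi]
  if (length(vals) == 0L) mf_stop("degenerate_histogram", "empty ROI")
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    mf_stop("degenerate_histogram",
            "all ROI pixels share one intensity (%d)", which(counts > 0L) - 1L)
  counts <- as.numeric(counts)          # avoid integer overflow on big ROIs
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                  # pixels with intensity <= t
  s0 <- cumsum(counts * lev)
  stot <- s0[256L]
  # between-class variance at t = 0..254
  w0t <- w0[1:255]; w1t <- n - w0t
  mu0 <- ifelse(w0t > 0, s0[1:255] / w0t, 0)
  mu1 <- ifelse(w1t > 0, (stot - s0[1:255]) / w1t, 0)
  sigma_b <- ifelse(w0t > 0 & w1t > 0, w0t * w1t * (mu0 - mu1)^2, -Inf)
  as.integer(which.max(sigma_b) - 1L)   # which.max takes the first maximum
}

#' Binarize a grayscale image into a marbling mask
#'
#' Fat is the bright class: `fat(x) = roi(x) AND gray(x) > t`.  With
#' `fat_bright = FALSE` the dark class is taken instead (for inverted
#' imaging setups).
#'
#' @param gray integer H x W matrix in 0..255.
#' @param roi logical H x W ROI matrix.
#' @param t integer threshold in 0..254.
#' @param fat_bright take the bright class as fat (default `TRUE`).
#' @return a `marbling_mask`: list with `fat` (logical H x W matrix,
#'   guaranteed a subset of the ROI) and `threshold_used`.
#' @export
binarize <- function(gray, roi, t, fat_bright = TRUE) {
  stopifnot(t >= 0, t <= 254)
  fat <- if (fat_bright) (gray > t) else (gray <= t)
  fat <- fat & roi
  structure(list(fat = fat, threshold_used = as.integer(t)),
            class = "marbling_mask")
}

#' Segment marbling from an image and ROI
#'
#' Full segmentation stage: luminance conversion, ROI-restricted Otsu
#' threshold, binarization with fat as the bright class.
#'
#' @inheritParams binarize
#' @param img H x W x 3 array (or H x W matrix) of 8-bit intensities.
#' @return a `marbling_mask` (see [binarize()]).
#' @export
segment_marbling <- function(img, roi, fat_bright = TRUE) {
  gray <- to_grayscale(img)
  t <- otsu_threshold(gray, roi)
  binarize(gray, roi, t, fat_bright = fat_bright)
}

#' @export
print.marbling_mask <- function(x, ...) {
  cat(sprintf("marbling_mask: %d x %d, %d fat px, threshold %d\n",
              nrow(x$fat), ncol(x$fat), sum(x$fat), x$threshold_used))
  invisible(x)
}

# coerce marbling_mask or logical matrix to the fat matrix
as_fat_matrix <- function(mask) {
  if (inherits(mask, "marbling_mask")) mask$fat
  else if (is.logical(mask) && is.matrix(mask)) mask
  else mf_stop("config", "expected a marbling_mask or logical matrix")
}

#' Write a marbling mask as binary PNG with JSON sidecar
#'
#' The PNG encodes fat = 255, everything else 0; the sidecar
#' `<path>.json` records the Otsu threshold used.
#'
#' @param mask a `marbling_mask`.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  fat <- as_fat_matrix(mask)
  EBImage::writeImage(EBImage::Image(t(fat) * 1.0), path, type = "png")
  thr <- if (inherits(mask, "marbling_mask")) mask$threshold_used else NA
  jsonlite::write_json(list(threshold_used = thr, fat_px = sum(fat)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
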