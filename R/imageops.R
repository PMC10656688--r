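# Low-level grayscale image primitives shared by the phantom, segmentation
# and feature modules. Images are numeric matrices in [0,1], indexed
# (row, col), 1-based; row 1 is the skin (shallow) side.

#' Gaussian smoothing of a grayscale frame
#'
#' Separable Gaussian convolution with replicate padding. The kernel radius
#' is `ceiling(3 * sigma)`.
#'
#' @param img numeric matrix in `[0,1]`.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input.
#' @return smoothed matrix of the same dimensions.
#' @export
blur_gaussian <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  cpp_sep_convolve(img, k)
}

#' Otsu threshold of a grayscale frame
#'
#' Maximizes between-class variance on a 256-bin histogram of `[0,1]` data.
#'
#' @param img numeric matrix in `[0,1]`.
#' @return scalar threshold in `[0,1]`.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), nbins = 256L)
  p <- h / sum(h)
  mids <- (seq_len(256) - 0.5) / 256
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Binary morphology on logical matrices via the disk rank filter.
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  cpp_disk_filter(mask * 1.0, radius, FALSE) > 0.5
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  cpp_disk_filter(mask * 1.0, radius, TRUE) > 0.5
}

binary_open <- function(mask, radius) binary_dilate(binary_erode(mask, radius), radius)
binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

# Grey-scale white top-hat: img minus its morphological opening with a disk.
white_tophat <- function(img, radius) {
  opened <- cpp_disk_filter(cpp_disk_filter(img, radius, FALSE), radius, TRUE)
  img - opened
}

# Label 8-connected components; returns integer matrix (0 = background).
label_components <- function(mask) {
  cpp_label8(mask, 8L)
}

# Fill interior holes of a mask: background is labelled 4-connected and
# every background component that does not touch the image border is
# absorbed into the mask (bright calcific foci punch holes into a dark
# lesion mask, for example).
fill_holes <- function(mask) {
  lab <- cpp_label8(!mask, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Keep the largest 8-connected component of a logical mask (or NULL if empty).
largest_component <- function(mask) {
  lab <- cpp_label8(mask)
  n <- max(lab)
  if (n == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

# Ordered clockwise boundary of a single-component mask: n x 2 (row, col).
trace_contour <- function(mask) {
  cpp_trace_contour(mask)
}

# Perimeter estimate from an ordered digital contour using the
# Vossepoel-Smeulders step weights (0.948 isothetic, 1.340 diagonal),
# which keep the error for smooth convex shapes within about 1%.
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  d <- abs(nxt - contour)
  diag_step <- d[, 1] > 0 & d[, 2] > 0
  0.948 * sum(!diag_step) + 1.340 * sum(diag_step)
}

# Area (px count), convex-hull area and hull perimeter of a mask.
# Hull area uses the shoelace formula on pixel centres plus the usual
# half-perimeter + 1 correction so that solidity of convex digital shapes
# is close to 1.
hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(nrow(idx))
  h <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[h, , drop = FALSE]
  n <- nrow(pts)
  x <- pts[, 2]; y <- pts[, 1]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  area <- abs(sum(x * y2 - x2 * y)) / 2
  per <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  area + per / 2 + 1
}

# Bilinear interpolation of img at fractional (row, col) positions.
# Positions outside the image are clamped to the border.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i10 <- img[cbind(r0 + 1, c0)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

# Tight 1-based closed bounding box of a mask: c(row_min, col_min, row_max, col_max).
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
}
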