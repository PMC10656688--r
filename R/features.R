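# Per-frame BI-RADS lexicon extraction by morphological image processing.
# Each extractor maps (frame, mask) to one level of one lexicon category
# with the diagnostics that drove the call; all thresholds live in
# feature_config() so every decision is reproducible and tunable.

#' Feature-extraction configuration
#'
#' @param circularity_min shape gate: minimum `4*pi*A / P^2`.
#' @param solidity_min shape gate: minimum area / convex-hull-area ratio.
#' @param smoothness_max margin gate: maximum ratio of the raw contour
#'   perimeter to the perimeter of its 10-harmonic Fourier smoothing.
#' @param edge_gradient_min margin gate: minimum mean absolute intensity
#'   gradient (intensity/px) across the boundary normal in a 5-px band.
#' @param anechoic_max echo gate: maximum interior mean for anechoic.
#' @param cv_homog_max echo gate: maximum interior coefficient of variation
#'   (on the despeckled interior) for homogeneous.
#' @param posterior_delta posterior gate: band/flank mean ratio must leave
#'   `[1 - delta, 1 + delta]` to call enhancement or shadowing.
#' @param calc_z calcification gate: top-hat threshold in interior SDs.
#' @param calc_min_px minimum focus area (px) to count at all.
#' @param calc_coarse_px minimum focus area (px) to count as coarse.
#' @param despeckle_sigma Gaussian sigma (px) of the speckle-reduction
#'   smoothing used by the margin and echo extractors.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(circularity_min = 0.70, solidity_min = 0.90,
                           smoothness_max = 1.15, edge_gradient_min = 0.015,
                           anechoic_max = 0.08, cv_homog_max = 0.35,
                           posterior_delta = 0.15,
                           calc_z = 4.0, calc_min_px = 2, calc_coarse_px = 12,
                           despeckle_sigma = 2) {
  stopifnot(circularity_min > 0, circularity_min <= 1, solidity_min > 0,
            smoothness_max > 0, edge_gradient_min > 0, anechoic_max > 0,
            cv_homog_max > 0, posterior_delta > 0, calc_z > 0,
            calc_min_px >= 1, calc_coarse_px > calc_min_px)
  structure(list(circularity_min = circularity_min, solidity_min = solidity_min,
                 smoothness_max = smoothness_max,
                 edge_gradient_min = edge_gradient_min,
                 anechoic_max = anechoic_max, cv_homog_max = cv_homog_max,
                 posterior_delta = posterior_delta, calc_z = calc_z,
                 calc_min_px = calc_min_px, calc_coarse_px = calc_coarse_px,
                 despeckle_sigma = despeckle_sigma),
            class = "feature_config")
}

as_mask <- function(mask) {
  if (inherits(mask, "lesion_mask")) mask$mask else mask
}

feature_result <- function(level, diagnostics) {
  structure(list(level = level, diagnostics = diagnostics), class = "feature_result")
}

#' Shape: regular vs irregular
#'
#' Circularity `4*pi*A / P^2` (perimeter from the traced contour with
#' digitization-corrected step weights) and solidity (area over convex-hull
#' area). Regular requires both gates.
#'
#' @param mask logical matrix or [lesion_mask()]; must be nonempty.
#' @param config a [feature_config()].
#' @return `feature_result` with `level` and diagnostics
#'   `circularity`, `solidity`.
#' @export
extract_shape <- function(mask, config = feature_config()) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("extract_shape: empty mask")
  area <- sum(m)
  contour <- trace_contour(m)
  per <- contour_perimeter(contour)
  circ <- if (per > 0) 4 * pi * area / per^2 else 1
  sol <- area / hull_area(m)
  level <- if (circ >= config$circularity_min && sol >= config$solidity_min)
    "regular" else "irregular"
  feature_result(level, c(circularity = circ, solidity = sol))
}

#' Orientation: parallel vs not parallel
#'
#' Width and height are the bounding-box extents along the image axes
#' (rows are depth). Parallel ("wider than tall") wins ties.
#'
#' @inheritParams extract_shape
#' @return `feature_result` with diagnostics `width`, `height`.
#' @export
extract_orientation <- function(mask, config = feature_config()) {
  m <- as_mask(mask)
  bb <- mask_bbox(m)
  if (is.null(bb)) stop("extract_orientation: empty mask")
  height <- bb[3] - bb[1] + 1
  width <- bb[4] - bb[2] + 1
  feature_result(if (width >= height) "parallel" else "not_parallel",
                 c(width = width, height = height))
}

# Perimeter of the low-order Fourier smoothing of an ordered contour:
# keep harmonics |k| <= n_harmonics of the complex boundary signal.
fourier_smooth_perimeter <- function(contour, n_harmonics = 10) {
  n <- nrow(contour)
  if (n < 8) return(sum(Mod(diff(complex(real = contour[, 2], imaginary = contour[, 1])))))
  z <- complex(real = contour[, 2], imaginary = contour[, 1])
  Z <- stats::fft(z)
  keep <- rep(FALSE, n)
  k <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  keep[k <= n_harmonics] <- TRUE
  Z[!keep] <- 0
  zs <- stats::fft(Z, inverse = TRUE) / n
  dz <- c(diff(zs), zs[1] - zs[n])
  sum(Mod(dz))
}

#' Margin: circumscribed vs not circumscribed
#'
#' Two diagnostics: `smoothness`, the contour perimeter divided by the
#' perimeter of its 10-harmonic Fourier smoothing (spiculation and
#' microlobulation inflate it), and `mean_edge_gradient`, the mean absolute
#' intensity step across the boundary normal over a 5-px band of the
#' despeckled frame (an indistinct, blurred margin deflates it).
#' Circumscribed requires a smooth contour AND a sharp edge.
#'
#' @param frame numeric matrix in `[0,1]`.
#' @inheritParams extract_shape
#' @return `feature_result` with diagnostics `smoothness`,
#'   `mean_edge_gradient`.
#' @export
extract_margin <- function(frame, mask, config = feature_config()) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("extract_margin: empty mask")
  bb <- mask_bbox(m)
  if (bb[1] <= 2 || bb[2] <= 2 || bb[3] >= nrow(m) - 2 || bb[4] >= ncol(m) - 2)
    stop("extract_margin: mask touches the frame border; gradient band undefined")
  contour <- trace_contour(m)
  n <- nrow(contour)
  per_raw <- sum(Mod(diff(complex(real = c(contour[, 2], contour[1, 2]),
                                  imaginary = c(contour[, 1], contour[1, 1])))))
  per_smooth <- fourier_smooth_perimeter(contour, 10)
  smoothness <- if (per_smooth > 0) per_raw / per_smooth else 1

  s <- blur_gaussian(frame, config$despeckle_sigma)
  cen <- c(mean(contour[, 1]), mean(contour[, 2]))
  # outward normal approximated by the direction from the centroid;
  # sample the despeckled frame 2 px inside and 2 px outside the boundary
  dr <- contour[, 1] - cen[1]; dc <- contour[, 2] - cen[2]
  nrm <- sqrt(dr^2 + dc^2)
  ok <- nrm > 1e-9
  dr <- dr[ok] / nrm[ok]; dc <- dc[ok] / nrm[ok]
  pr <- contour[ok, 1]; pc <- contour[ok, 2]
  outer2 <- bilinear_sample(s, pr + 2 * dr, pc + 2 * dc)
  inner2 <- bilinear_sample(s, pr - 2 * dr, pc - 2 * dc)
  grad <- mean(abs(outer2 - inner2)) / 4
  level <- if (smoothness <= config$smoothness_max && grad >= config$edge_gradient_min)
    "circumscribed" else "not_circumscribed"
  feature_result(level, c(smoothness = smoothness, mean_edge_gradient = grad))
}

#' Echo pattern: anechoic, homogeneous, heterogeneous
#'
#' Computed on the interior eroded by 3 px to avoid boundary mixing, using
#' the despeckled frame: anechoic when the interior mean is at most
#' `anechoic_max`; otherwise homogeneous when the coefficient of variation
#' is at most `cv_homog_max`, else heterogeneous.
#'
#' @inheritParams extract_margin
#' @return `feature_result` with diagnostics `interior_mean`, `cv`.
#' @export
extract_echo <- function(frame, mask, config = feature_config()) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("extract_echo: empty mask")
  interior <- binary_erode(m, 3)
  if (sum(interior) < 9) interior <- binary_erode(m, 1)
  if (sum(interior) == 0) stop("extract_echo: interior empty after erosion")
  s <- blur_gaussian(frame, config$despeckle_sigma)
  v <- s[interior]
  mu <- mean(v)
  cv <- if (length(v) > 1) stats::sd(v) / max(mu, 1e-9) else 0
  level <- if (mu <= config$anechoic_max) "anechoic"
  else if (cv <= config$cv_homog_max) "homogeneous"
  else "heterogeneous"
  feature_result(level, c(interior_mean = mu, cv = cv))
}

#' Posterior acoustic features: none, enhancement, shadowing
#'
#' Compares the band directly beneath the lesion bounding box (height equal
#' to the lesion height, same width) with same-depth flank bands of the
#' same total width left and right of it. Enhancement when
#' `band/flank >= 1 + delta`, shadowing when `<= 1 - delta`, else none.
#'
#' @inheritParams extract_margin
#' @return `feature_result` with diagnostic `band_ratio`.
#' @export
extract_posterior <- function(frame, mask, config = feature_config()) {
  m <- as_mask(mask)
  bb <- mask_bbox(m)
  if (is.null(bb)) stop("extract_posterior: empty mask")
  h <- nrow(frame); w <- ncol(frame)
  les_h <- bb[3] - bb[1] + 1
  r0 <- bb[3] + 1; r1 <- bb[3] + les_h
  if (r1 > h) stop("extract_posterior: band extends past the image bottom")
  band <- frame[r0:r1, bb[2]:bb[4], drop = FALSE]
  half <- max(1, floor((bb[4] - bb[2] + 1) / 2))
  lf0 <- max(1, bb[2] - half); lf1 <- bb[2] - 1
  rf0 <- bb[4] + 1; rf1 <- min(w, bb[4] + half)
  flank <- c(if (lf1 >= lf0) frame[r0:r1, lf0:lf1],
             if (rf1 >= rf0) frame[r0:r1, rf0:rf1])
  if (length(flank) == 0) stop("extract_posterior: no flank pixels available")
  ratio <- mean(band) / mean(flank)
  level <- if (ratio >= 1 + config$posterior_delta) "enhancement"
  else if (ratio <= 1 - config$posterior_delta) "shadowing"
  else "none"
  feature_result(level, c(band_ratio = ratio))
}

#' Calcification: none, coarse, punctate
#'
#' Candidate focus pixels are interior pixels whose white-top-hat response
#' (7-px-radius disk, raw frame) exceeds the robust interior level by
#' `calc_z` robust SDs (median + `calc_z` * MAD — robust so that the foci
#' themselves cannot inflate the cut). Multiplicative speckle fragments a
#' focus, so candidate pixels are merged with a 1-px morphological closing
#' before connected-component analysis; each focus is then sized by its
#' closed-component interior pixel count. Foci below `calc_min_px` are
#' discarded; any focus of at least `calc_coarse_px` makes the call coarse,
#' any remaining focus makes it punctate, otherwise none.
#'
#' @inheritParams extract_margin
#' @return `feature_result` with diagnostics `n_foci`, `max_focus_px`.
#' @export
extract_calcification <- function(frame, mask, config = feature_config()) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("extract_calcification: empty mask")
  th <- white_tophat(frame, 7)
  # deep erosion: segmentation masks overshoot the lesion by a few pixels
  # (and a morphological closing can absorb bright inter-spicule tissue),
  # and those bright rim pixels would masquerade as foci, especially
  # against a near-anechoic interior
  interior <- binary_erode(m, 5)
  if (sum(interior) < 9) interior <- binary_erode(m, 2)
  if (sum(interior) < 9) interior <- m
  v <- th[interior]
  cut <- stats::median(v) + config$calc_z * stats::mad(v)
  cand <- th > cut & interior
  lab <- label_components(binary_close(cand, 1))
  nfoci <- max(lab)
  sizes <- if (nfoci > 0)
    vapply(seq_len(nfoci), function(k) sum(lab == k & interior), integer(1))
  else integer(0)
  sizes <- sizes[sizes >= config$calc_min_px]
  level <- if (length(sizes) == 0) "none"
  else if (max(sizes) >= config$calc_coarse_px) "coarse"
  else "punctate"
  feature_result(level, c(n_foci = length(sizes),
                          max_focus_px = if (length(sizes)) max(sizes) else 0))
}

#' Extract all six lexicon categories from one frame
#'
#' Aggregates the six extractors. When the posterior band does not fit in
#' the frame the posterior level falls back to `"none"` with a warning.
#'
#' @inheritParams extract_margin
#' @return object of class `frame_features`: named list of the six levels
#'   with a `diagnostics` attribute.
#' @export
extract_all <- function(frame, mask, config = feature_config()) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("extract_all: empty mask")
  sh <- extract_shape(m, config)
  or <- extract_orientation(m, config)
  mg <- tryCatch(extract_margin(frame, m, config), error = function(e) {
    warning("margin band unavailable; falling back to 'not_circumscribed': ",
            conditionMessage(e))
    feature_result("not_circumscribed", c(smoothness = NA, mean_edge_gradient = NA))
  })
  ec <- extract_echo(frame, m, config)
  po <- tryCatch(extract_posterior(frame, m, config), error = function(e) {
    warning("posterior band unavailable; falling back to 'none': ",
            conditionMessage(e))
    feature_result("none", c(band_ratio = NA))
  })
  ca <- extract_calcification(frame, m, config)
  res <- list(shape = sh$level, orientation = or$level, margin = mg$level,
              echo = ec$level, posterior = po$level, calcification = ca$level)
  attr(res, "diagnostics") <- list(shape = sh$diagnostics, orientation = or$diagnostics,
                                   margin = mg$diagnostics, echo = ec$diagnostics,
                                   posterior = po$diagnostics,
                                   calcification = ca$diagnostics)
  class(res) <- "frame_features"
  res
}
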