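# Lesion frame selection and segmentation. The runtime engine is a
# classical dark-object pipeline (breast lesions are hypoechoic against the
# parenchyma): Gaussian smoothing, Otsu thresholding of the dark class,
# morphological open/close, largest connected component, then area and
# contrast gates. The attention (SimAM) and detection-loss operations used
# by learned engines are provided as pure functions so an external learned
# engine can be validated against the same contracts.

#' Segmentation configuration
#'
#' @param smoothing_sigma Gaussian sigma (px) applied before thresholding.
#' @param threshold_method `"background_dark"` (default: robust background
#'   floor `median - 3 * MAD` of the smoothed frame — separates every
#'   hypoechoic structure from the speckle background, including multi-level
#'   heterogeneous interiors), `"otsu_dark"` (classic Otsu cut, keep the
#'   dark class; reliable only on clearly bimodal frames) or `"fixed"`
#'   (absolute cut at `fixed_threshold`).
#' @param fixed_threshold intensity cut used when `threshold_method = "fixed"`.
#' @param threshold_polarity `"dark"` keeps pixels below the cut (hypoechoic
#'   lesions); `"bright"` keeps pixels above it (hyperechoic lesions, only
#'   meaningful with the fixed method).
#' @param open_radius,close_radius disk radii (px) of the morphological
#'   open and close that remove speckle islands and seal small gaps.
#' @param min_area minimum component area in px^2.
#' @param min_contrast minimum background-minus-interior mean intensity
#'   (measured on the smoothed frame) for a detection to count.
#' @param simam_lambda regularizer of the SimAM energy.
#' @param focal_gamma,focal_alpha focal-loss focusing and balance parameters.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(smoothing_sigma = 2, threshold_method = "background_dark",
                       fixed_threshold = 0.25, threshold_polarity = "dark",
                       open_radius = 2, close_radius = 3,
                       min_area = 64, min_contrast = 0.08,
                       simam_lambda = 1e-4, focal_gamma = 2.0, focal_alpha = 0.25) {
  stopifnot(open_radius >= 0, close_radius >= 0, min_area >= 1,
            simam_lambda > 0,
            threshold_method %in% c("background_dark", "otsu_dark", "fixed"),
            threshold_polarity %in% c("dark", "bright"))
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 threshold_polarity = threshold_polarity,
                 open_radius = open_radius, close_radius = close_radius,
                 min_area = min_area, min_contrast = min_contrast,
                 simam_lambda = simam_lambda,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "seg_config")
}

#' Histogram equalization
#'
#' Classic 256-bin histogram equalization to `[0,1]`. The mapping is the
#' (shifted) empirical CDF, hence monotone: pixel ranks are preserved up to
#' ties. A constant frame is returned unchanged.
#'
#' @param frame numeric matrix in `[0,1]`.
#' @return equalized matrix in `[0,1]`.
#' @export
equalize <- function(frame) {
  v <- as.vector(frame)
  if (max(v) - min(v) < 1e-12) return(frame)
  bins <- pmin(pmax(floor(v * 256) + 1L, 1L), 256L)
  h <- tabulate(bins, nbins = 256L)
  cdf <- cumsum(h) / length(v)
  cdf_min <- min(cdf[cdf > 0])
  map <- (cdf - cdf_min) / (1 - cdf_min)
  map <- pmin(pmax(map, 0), 1)
  matrix(map[bins], nrow(frame), ncol(frame))
}

#' Lesion mask container
#'
#' @param mask logical matrix (the segmented support).
#' @return object of class `lesion_mask` with fields `mask`, `bbox`
#'   (tight 1-based closed box `c(row_min, col_min, row_max, col_max)`) and
#'   `area` (pixel count).
#' @export
lesion_mask <- function(mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("lesion_mask requires a nonempty mask")
  structure(list(mask = mask, bbox = bb, area = sum(mask)), class = "lesion_mask")
}

# Posterior acoustic shadowing is as dark as the lesion itself, so a dark
# component can be the lesion plus a shadow column hanging below it. A
# lesion tapers towards its bottom while the shadow band keeps the full
# lesion width, so a merged component shows a characteristic dip-then-rise
# in its row-width profile below the equator: the width falls below 85% of
# the equatorial width and then recovers by at least 30%. Shadow-free
# lesions taper monotonically and are left untouched. When the signature
# is present the component is cut at the dip row.
trim_posterior_shadow <- function(comp, profile_mask = NULL) {
  # the dip geometry is sharper on the strict (seed-level) mask, so the
  # hysteresis engine passes it separately; the cut applies to `comp`
  widths <- rowSums(if (is.null(profile_mask)) comp else profile_mask)
  nz <- which(widths > 0)
  if (length(nz) == 0) return(NULL)
  b_max <- nz[length(nz)]
  ws <- stats::runmed(widths, 5)
  # equator: first row near the maximal width, climbed to its local
  # maximum (the shadow band below can tie or slightly exceed the
  # equatorial width, so a global which.max could land inside the shadow)
  # climb from the top to the first local maximum: the lesion equator.
  # The shadow band deeper down can be wider than the (strict) lesion
  # width, so any global-maximum rule could land inside the shadow.
  rw <- nz[1]
  while (rw < b_max && ws[rw + 1] >= ws[rw]) rw <- rw + 1
  if (rw >= b_max) return(comp)
  # a lesion (even a spiculated one) tapers to a point at its bottom; a
  # shadow band is a column rectangle that ends abruptly wide
  bottom_w <- max(widths[max(nz[1], b_max - 3):b_max])
  if (bottom_w < 0.7 * ws[rw]) return(comp)
  # junction dip: a row below the equator that is narrow relative to the
  # equator AND followed further down by a substantial recovery (the
  # shadow band). Cut at the deepest such dip so that spiculation waists
  # higher up are left alone.
  rows_below <- (rw + 1):b_max
  suffix_max <- rev(cummax(rev(ws[rows_below])))
  eligible <- ws[rows_below] < 0.85 * ws[rw] &
    suffix_max >= 1.2 * pmax(1, ws[rows_below])
  if (!any(eligible)) return(comp)
  r_star <- max(rows_below[eligible])
  out <- comp
  if (r_star < nrow(comp)) out[(r_star + 1):nrow(comp), ] <- FALSE
  largest_component(out)
}

#' Segment one frame
#'
#' Gaussian smoothing, dark-object thresholding, morphological open then
#' close, largest 8-connected component, then the area and contrast gates.
#' Returns `NULL` (absent) when no component passes both gates: absence is
#' a value, not an error.
#'
#' @param frame numeric matrix in `[0,1]`.
#' @param config a [seg_config()].
#' @return a [lesion_mask()] or `NULL`.
#' @export
segment_frame <- function(frame, config = seg_config()) {
  s <- blur_gaussian(frame, config$smoothing_sigma)
  if (config$threshold_method == "background_dark") {
    # Hysteresis segmentation against the speckle background. Otsu is
    # reliable only on clearly bimodal frames; on near-unimodal frames its
    # cut drifts into the background mode, and on multi-level interiors it
    # splits inside the lesion. Instead: a strict robust floor
    # (median - 3 * MAD) finds seed regions that only genuine dark objects
    # undershoot; the seed component with the darkest mean (the lesion
    # core, never the lighter posterior shadow) is then grown at a
    # permissive cut (median - 2 * MAD) that recovers brighter lesion
    # portions (heterogeneous components, blurred margins).
    med <- stats::median(s); sdev <- stats::mad(s)
    strict <- binary_open(s < med - 3 * sdev, config$open_radius)
    lab <- label_components(strict)
    if (max(lab) == 0L) return(NULL)
    seed_means <- vapply(seq_len(max(lab)), function(k) mean(s[lab == k]), numeric(1))
    seed <- lab == which.min(seed_means)
    loose <- binary_close(binary_open(s < med - 2 * sdev, config$open_radius),
                          config$close_radius)
    lab2 <- label_components(loose | seed)
    comp <- lab2 == lab2[which(seed)[1]]
    strict_comp <- strict & comp
  } else {
    strict_comp <- NULL
    thr <- switch(config$threshold_method,
                  otsu_dark = otsu_threshold(s),
                  fixed = config$fixed_threshold)
    cand <- if (config$threshold_polarity == "dark") s < thr else s > thr
    cand <- binary_close(binary_open(cand, config$open_radius), config$close_radius)
    comp <- largest_component(cand)
    if (is.null(comp)) return(NULL)
  }
  if (config$threshold_polarity == "dark") {
    comp <- trim_posterior_shadow(comp, strict_comp)
    if (is.null(comp)) return(NULL)
  }
  # bright interior structures (calcific foci, echogenic debris) punch
  # holes into the dark mask; the lesion support is simply connected
  comp <- fill_holes(comp)
  if (sum(comp) < config$min_area) return(NULL)
  inside <- mean(s[comp])
  outside <- mean(s[!comp])
  contrast <- if (config$threshold_polarity == "dark") outside - inside else inside - outside
  if (contrast < config$min_contrast) return(NULL)
  lesion_mask(comp)
}

#' Segment every frame of a video
#'
#' Applies [segment_frame()] per frame, then a temporal consistency pass
#' that drops isolated single-frame detections flanked by absences (video
#' boundaries count as absences).
#'
#' @param video a [frame_sequence()].
#' @param config a [seg_config()].
#' @return list (one entry per frame) of [lesion_mask()] or `NULL`.
#' @export
segment_video <- function(video, config = seg_config()) {
  stopifnot(inherits(video, "frame_sequence"))
  res <- lapply(video$frames, segment_frame, config = config)
  n <- length(res)
  present <- !vapply(res, is.null, logical(1))
  drop <- vapply(seq_len(n), function(i) {
    if (!present[i]) return(FALSE)
    prev <- if (i > 1) present[i - 1] else FALSE
    nxt <- if (i < n) present[i + 1] else FALSE
    !prev && !nxt
  }, logical(1))
  res[drop] <- list(NULL)
  res
}

#' SimAM attention weighting
#'
#' Parameter-free attention: within each channel, every unit `t` gets the
#' closed-form minimal energy
#' `e_t = 4 * (sigma^2 + lambda) / ((t - mu)^2 + 2 * sigma^2 + 2 * lambda)`
#' where `mu` and `sigma^2` are the channel mean and variance computed over
#' the other units (excluding `t` itself). The attention map is
#' `sigmoid(1/e_t)` and the output is its Hadamard (elementwise) product
#' with the input, enhancing units that stand out from their channel.
#'
#' @param x 3-D array `(rows, cols, channels)`, or a matrix treated as one
#'   channel.
#' @param lambda positive regularizer.
#' @return array (or matrix) of the same shape: the weighted input. The
#'   attention weights are attached as attribute `"weights"`.
#' @export
simam_weights <- function(x, lambda = 1e-4) {
  stopifnot(lambda > 0)
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  out <- x
  wts <- x
  for (ch in seq_len(dim(x)[3])) {
    v <- x[, , ch]
    n <- length(v)
    if (n < 2) {
      w <- matrix(stats::plogis(0.5), nrow(v), ncol(v))
    } else {
      s <- sum(v); ss <- sum(v^2)
      mu <- (s - v) / (n - 1)
      var_ <- pmax(0, (ss - v^2) / (n - 1) - mu^2)
      e <- 4 * (var_ + lambda) / ((v - mu)^2 + 2 * var_ + 2 * lambda)
      w <- stats::plogis(1 / e)
    }
    wts[, , ch] <- w
    out[, , ch] <- v * w
  }
  if (was_matrix) { dim(out) <- dim(out)[1:2]; dim(wts) <- dim(wts)[1:2] }
  attr(out, "weights") <- wts
  out
}

clamp_prob <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    message("probabilities at 0/1 clamped to [1e-7, 1 - 1e-7]")
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  }
  p
}

#' Detection losses: binary cross-entropy, focal, and Complete-IoU
#'
#' `bce_loss(p, y)` is `-(y * log(p) + (1 - y) * log(1 - p))`.
#' `focal_loss(p, y, gamma, alpha)` is `-alpha_t * (1 - p_t)^gamma * log(p_t)`
#' with `p_t = p` when `y = 1` and `1 - p` otherwise (`alpha_t` analogous);
#' `gamma = 0, alpha = 0.5` reduces it to `0.5 * bce`.
#' `ciou_loss(boxA, boxB)` is `1 - IoU + rho2/c2 + alpha * v`, where `rho2`
#' is the squared distance between box centres, `c2` the squared diagonal of
#' the smallest enclosing box, and `v = (4/pi^2) * (atan(wA/hA) - atan(wB/hB))^2`
#' the aspect-ratio term with `alpha = v / (1 - IoU + v)`.
#' Boxes are numeric `(row0, col0, row1, col1)`, half-open.
#'
#' @param p predicted probabilities in `(0,1)` (values at 0/1 are clamped
#'   to `[1e-7, 1 - 1e-7]` with a note).
#' @param y labels in `{0,1}`.
#' @param gamma,alpha focal-loss parameters.
#' @param boxA,boxB numeric length-4 boxes.
#' @return numeric loss (vectorized over `p`, `y` for bce/focal).
#' @export
bce_loss <- function(p, y) {
  p <- clamp_prob(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname bce_loss
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  n <- max(length(p), length(y))
  p <- clamp_prob(rep_len(p, n))
  y <- rep_len(y, n)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

box_area <- function(b) max(0, b[3] - b[1]) * max(0, b[4] - b[2])

#' @rdname bce_loss
#' @export
ciou_loss <- function(boxA, boxB) {
  stopifnot(length(boxA) == 4, length(boxB) == 4,
            boxA[3] > boxA[1], boxA[4] > boxA[2],
            boxB[3] > boxB[1], boxB[4] > boxB[2])
  inter <- c(max(boxA[1], boxB[1]), max(boxA[2], boxB[2]),
             min(boxA[3], boxB[3]), min(boxA[4], boxB[4]))
  ia <- if (inter[3] > inter[1] && inter[4] > inter[2]) box_area(inter) else 0
  ua <- box_area(boxA) + box_area(boxB) - ia
  iou <- ia / ua
  cA <- c((boxA[1] + boxA[3]) / 2, (boxA[2] + boxA[4]) / 2)
  cB <- c((boxB[1] + boxB[3]) / 2, (boxB[2] + boxB[4]) / 2)
  rho2 <- sum((cA - cB)^2)
  enc <- c(min(boxA[1], boxB[1]), min(boxA[2], boxB[2]),
           max(boxA[3], boxB[3]), max(boxA[4], boxB[4]))
  c2 <- (enc[3] - enc[1])^2 + (enc[4] - enc[2])^2
  hA <- boxA[3] - boxA[1]; wA <- boxA[4] - boxA[2]
  hB <- boxB[3] - boxB[1]; wB <- boxB[4] - boxB[2]
  v <- (4 / pi^2) * (atan(wA / hA) - atan(wB / hB))^2
  alpha <- if (v == 0) 0 else v / ((1 - iou) + v)
  1 - iou + rho2 / c2 + alpha * v
}

#' Mask overlap metrics
#'
#' Dice `2|A∩B| / (|A| + |B|)` and IoU `|A∩B| / |A∪B|`. Two empty masks
#' compare as identical: both metrics are 1 by convention (needed for
#' blank-frame regression tests).
#'
#' @param maskA,maskB logical matrices of identical dimensions (or
#'   [lesion_mask()] objects).
#' @return named numeric `c(dice =, iou =)`.
#' @export
overlap_metrics <- function(maskA, maskB) {
  if (inherits(maskA, "lesion_mask")) maskA <- maskA$mask
  if (inherits(maskB, "lesion_mask")) maskB <- maskB$mask
  stopifnot(all(dim(maskA) == dim(maskB)))
  a <- sum(maskA); b <- sum(maskB); i <- sum(maskA & maskB)
  if (a + b == 0) return(c(dice = 1, iou = 1))
  u <- a + b - i
  c(dice = 2 * i / (a + b), iou = if (u > 0) i / u else 1)
}

#' Frame-level detection counts
#'
#' A predicted frame counts as a true positive when the prediction overlaps
#' the truth with IoU at or above `iou_cut`; a truly lesion-free frame with
#' an absent prediction counts as a true negative. A prediction on a lesion
#' frame with IoU below the cut counts as a miss (false negative), and a
#' prediction on a lesion-free frame as a false positive.
#'
#' @param predictions,truths lists of masks (`lesion_mask`, logical matrix,
#'   or `NULL` for absent) of equal length.
#' @param iou_cut IoU threshold in `(0,1)`.
#' @return named numeric with counts `tp, fp, fn, tn` and rates
#'   `precision, recall, specificity`.
#' @export
detection_counts <- function(predictions, truths, iou_cut = 0.5) {
  stopifnot(length(predictions) == length(truths), iou_cut > 0, iou_cut < 1)
  as_m <- function(x) if (inherits(x, "lesion_mask")) x$mask else x
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(predictions)) {
    p <- as_m(predictions[[i]]); t <- as_m(truths[[i]])
    p_here <- !is.null(p) && sum(p) > 0
    t_here <- !is.null(t) && sum(t) > 0
    if (t_here && p_here) {
      if (overlap_metrics(p, t)["iou"] >= iou_cut) tp <- tp + 1L else fn <- fn + 1L
    } else if (t_here && !p_here) fn <- fn + 1L
    else if (!t_here && p_here) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
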