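# Speckle phantom: synthetic linear-transducer sweep through a breast lesion.
# The transducer translates at constant speed, so the imaged cross-section
# appears, grows to the mid-sweep maximum, shrinks and disappears, with
# lesion-free frames at both ends of the cine loop. Ground-truth masks and
# the six lexicon labels are known exactly, which makes every downstream
# stage testable without clinical data.

LEXICON_LEVELS <- list(
  shape         = c("regular", "irregular"),
  orientation   = c("parallel", "not_parallel"),
  margin        = c("circumscribed", "not_circumscribed"),
  echo          = c("anechoic", "homogeneous", "heterogeneous"),
  posterior     = c("none", "enhancement", "shadowing"),
  calcification = c("none", "coarse", "punctate")
)

#' Phantom sweep specification
#'
#' Describes one synthetic sweep video: geometry of the lesion at mid-sweep,
#' the six BI-RADS lexicon levels it should express, and the speckle model.
#' Defaults describe a benign-looking solid nodule: oval, wider than tall,
#' sharp margin, homogeneous hypoechoic interior, no posterior change, no
#' calcification, on a 128 x 128 background of fully developed speckle.
#'
#' Coordinates are 1-based `(row, col)`; row 1 is the skin side, so depth
#' increases with the row index.
#'
#' @param image_height,image_width frame size in pixels.
#' @param n_frames number of frames in the sweep.
#' @param lesion_center `(row, col)` of the lesion centre.
#' @param max_radii `(vertical, horizontal)` semi-axes in pixels at mid-sweep.
#' @param shape_label `"regular"` or `"irregular"`.
#' @param spiculation `(count, amplitude_px)` radial cosine perturbation used
#'   when `shape_label == "irregular"`.
#' @param orientation_label `"parallel"` (wider than tall) or `"not_parallel"`;
#'   must agree with `max_radii`.
#' @param margin_label `"circumscribed"` or `"not_circumscribed"`.
#' @param edge_blur_sigma Gaussian sigma (px) applied to the lesion/background
#'   transition when the margin is not circumscribed.
#' @param interior_level mean interior intensity in `[0,1]`.
#' @param interior_pattern `"anechoic"`, `"homogeneous"` or `"heterogeneous"`.
#' @param posterior_label `"none"`, `"enhancement"` or `"shadowing"`.
#' @param posterior_gain multiplicative factor on the band beneath the lesion;
#'   must be > 1 for enhancement, < 1 for shadowing, 1 for none. `NULL` picks
#'   1, 1.5 or 0.5 from the label.
#' @param calcification_label `"none"`, `"coarse"` or `"punctate"`.
#' @param calc_foci list of `c(row, col, radius_px, intensity)` foci; `NULL`
#'   derives default foci from the label (one radius-3 focus for coarse,
#'   three radius-1 foci for punctate), placed around the lesion centre.
#' @param background_level mean background intensity.
#' @param speckle_shape gamma shape of the unit-mean multiplicative speckle.
#' @param seed integer seed for the speckle noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 128L, image_width = 128L,
                         n_frames = 24L,
                         lesion_center = c(48L, 64L),
                         max_radii = c(16L, 26L),
                         shape_label = "regular",
                         spiculation = c(12L, 6),
                         orientation_label = NULL,
                         margin_label = "circumscribed",
                         edge_blur_sigma = 8,
                         interior_level = 0.30,
                         interior_pattern = "homogeneous",
                         posterior_label = "none",
                         posterior_gain = NULL,
                         calcification_label = "none",
                         calc_foci = NULL,
                         background_level = 0.5,
                         speckle_shape = 4.0,
                         seed = 0L) {
  if (is.null(orientation_label)) {
    orientation_label <- if (max_radii[2] >= max_radii[1]) "parallel" else "not_parallel"
  }
  if (is.null(posterior_gain)) {
    posterior_gain <- switch(posterior_label, none = 1.0, enhancement = 1.5, shadowing = 0.5)
  }
  if (missing(interior_level)) {
    # anechoic: essentially echo-free; heterogeneous: keep both components
    # hypoechoic relative to the parenchyma (real mixed lesions keep an
    # overall hypoechoic envelope), so the +0.15 component stays dark.
    if (interior_pattern == "anechoic") interior_level <- 0.02
    if (interior_pattern == "heterogeneous") interior_level <- 0.22
  }
  if (is.null(calc_foci)) {
    cr <- lesion_center[1]; cc <- lesion_center[2]
    calc_foci <- switch(calcification_label,
      none = list(),
      coarse = list(c(cr, cc, 3, 0.95)),
      punctate = list(c(cr - 4, cc - 7, 1, 0.95),
                      c(cr + 3, cc + 6, 1, 0.95),
                      c(cr - 1, cc + 1, 1, 0.95)))
  }
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_frames = as.integer(n_frames),
    lesion_center = as.numeric(lesion_center), max_radii = as.numeric(max_radii),
    shape_label = shape_label, spiculation = as.numeric(spiculation),
    orientation_label = orientation_label,
    margin_label = margin_label, edge_blur_sigma = edge_blur_sigma,
    interior_level = interior_level, interior_pattern = interior_pattern,
    posterior_label = posterior_label, posterior_gain = posterior_gain,
    calcification_label = calcification_label, calc_foci = calc_foci,
    background_level = background_level, speckle_shape = speckle_shape,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with(spec, {
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (lesion_center[1] - max_radii[1] < 10 ||
        lesion_center[1] + max_radii[1] > image_height - 10 ||
        lesion_center[2] - max_radii[2] < 10 ||
        lesion_center[2] + max_radii[2] > image_width - 10)
      stop("max_radii must fit inside the image with a margin of at least 10 px")
    parallel <- max_radii[2] >= max_radii[1]
    if ((orientation_label == "parallel") != parallel)
      stop("orientation_label inconsistent with max_radii aspect")
    if (interior_pattern == "anechoic" && interior_level > 0.05)
      stop("anechoic interior requires interior_level <= 0.05")
    ok <- switch(posterior_label,
      none = posterior_gain == 1,
      enhancement = posterior_gain > 1,
      shadowing = posterior_gain < 1)
    if (!isTRUE(ok)) stop("posterior_gain inconsistent with posterior_label")
    if (!shape_label %in% LEXICON_LEVELS$shape) stop("bad shape_label")
    if (!orientation_label %in% LEXICON_LEVELS$orientation) stop("bad orientation_label")
    if (!margin_label %in% LEXICON_LEVELS$margin) stop("bad margin_label")
    if (!interior_pattern %in% LEXICON_LEVELS$echo) stop("bad interior_pattern")
    if (!posterior_label %in% LEXICON_LEVELS$posterior) stop("bad posterior_label")
    if (!calcification_label %in% LEXICON_LEVELS$calcification) stop("bad calcification_label")
    if (speckle_shape <= 0) stop("speckle_shape must be positive")
  })
  invisible(spec)
}

#' Ground-truth lexicon labels of a phantom spec
#'
#' @param spec a [phantom_spec()].
#' @return named character vector over the six lexicon categories.
#' @export
phantom_labels <- function(spec) {
  c(shape = spec$shape_label,
    orientation = spec$orientation_label,
    margin = spec$margin_label,
    echo = spec$interior_pattern,
    posterior = spec$posterior_label,
    calcification = spec$calcification_label)
}

#' Lesion radii at a given frame of the sweep
#'
#' The sweep is modelled as a constant-speed pass through an ellipsoid: the
#' cross-section radii scale by `sqrt(max(0, 1 - ((t - t_mid)/t_half)^2))`
#' with `t_mid = (n_frames - 1)/2` and `t_half = 0.4 * n_frames`, so the
#' lesion is absent at both ends of the cine loop ("until normal tissue
#' appears"), maximal at mid-sweep, and symmetric about it.
#'
#' @param spec a [phantom_spec()].
#' @param frame_index 0-based frame index in `[0, n_frames)`.
#' @return numeric `(vertical_radius, horizontal_radius)` in pixels.
#' @export
sweep_radius <- function(spec, frame_index) {
  stopifnot(frame_index >= 0, frame_index < spec$n_frames)
  t_mid <- (spec$n_frames - 1) / 2
  t_half <- 0.4 * spec$n_frames
  scale <- sqrt(max(0, 1 - ((frame_index - t_mid) / t_half)^2))
  spec$max_radii * scale
}

# Geometric lesion support at the given radii (no noise, no blur).
lesion_support <- function(spec, radii) {
  h <- spec$image_height; w <- spec$image_width
  if (min(radii) < 2) return(matrix(FALSE, h, w))
  cr <- spec$lesion_center[1]; cc <- spec$lesion_center[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  uy <- (rows - cr) / radii[1]
  ux <- (cols - cc) / radii[2]
  u <- sqrt(uy^2 + ux^2)
  if (spec$shape_label == "irregular") {
    theta <- atan2(uy, ux)
    amp_u <- spec$spiculation[2] / mean(spec$max_radii)
    u <= 1 + amp_u * cos(spec$spiculation[1] * theta)
  } else {
    u <= 1
  }
}

#' Render one phantom frame
#'
#' Composes the clean scene (background, lesion interior pattern, optional
#' margin blur, posterior band, calcific foci), multiplies it by unit-mean
#' gamma speckle, and clips to `[0,1]`. The returned mask is the unblurred
#' geometric lesion support.
#'
#' @param spec a [phantom_spec()].
#' @param frame_index 0-based frame index.
#' @param seed speckle seed for this frame; the default derives a distinct
#'   stream per frame from `spec$seed`.
#' @return list with `frame` (matrix in `[0,1]`) and `mask` (logical matrix).
#' @export
render_frame <- function(spec, frame_index, seed = NULL) {
  validate_phantom_spec(spec)
  radii <- sweep_radius(spec, frame_index)
  h <- spec$image_height; w <- spec$image_width
  mask <- lesion_support(spec, radii)
  cr <- spec$lesion_center[1]; cc <- spec$lesion_center[2]

  clean <- matrix(spec$background_level, h, w)
  if (any(mask)) {
    interior <- matrix(spec$interior_level, h, w)
    if (spec$interior_pattern == "heterogeneous") {
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      interior[cols < cc] <- spec$interior_level - 0.15
      interior[cols >= cc] <- spec$interior_level + 0.15
    }
    if (spec$margin_label == "not_circumscribed") {
      alpha <- blur_gaussian(mask * 1.0, spec$edge_blur_sigma)
      clean <- clean * (1 - alpha) + interior * alpha
    } else {
      clean[mask] <- interior[mask]
    }
    # posterior band: directly beneath the lesion bbox, height = vertical radius
    if (spec$posterior_gain != 1) {
      bb <- mask_bbox(mask)
      r0 <- bb[3] + 1L
      r1 <- min(h, bb[3] + max(1L, round(radii[1])))
      if (r0 <= r1) clean[r0:r1, bb[2]:bb[4]] <- clean[r0:r1, bb[2]:bb[4]] * spec$posterior_gain
    }
    # calcific foci, painted only where they fall inside the current support
    for (f in spec$calc_foci) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      disk <- (rows - f[1])^2 + (cols - f[2])^2 <= f[3]^2
      disk <- disk & mask
      clean[disk] <- f[4]
    }
  }

  if (is.null(seed)) seed <- (spec$seed * 10007L + frame_index * 271L) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  speckle <- matrix(stats::rgamma(h * w, shape = spec$speckle_shape,
                                  scale = 1 / spec$speckle_shape), h, w)
  frame <- pmin(pmax(clean * speckle, 0), 1)
  list(frame = frame, mask = mask)
}

#' Generate a phantom sweep video with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `video` (a [frame_sequence()]) and `truth`, a list with
#'   `masks` (per-frame logical matrices), `present` (per-frame flag: both
#'   radii at least 2 px), `labels` (the six lexicon levels) and `areas`
#'   (per-frame mask pixel counts).
#' @export
generate_video <- function(spec) {
  validate_phantom_spec(spec)
  out <- lapply(seq_len(spec$n_frames) - 1L, function(t) render_frame(spec, t))
  frames <- lapply(out, `[[`, "frame")
  masks <- lapply(out, `[[`, "mask")
  present <- vapply(seq_len(spec$n_frames) - 1L,
                    function(t) min(sweep_radius(spec, t)) >= 2, logical(1))
  list(video = frame_sequence(frames, source_id = sprintf("phantom_seed%d", spec$seed)),
       truth = list(masks = masks, present = present,
                    labels = phantom_labels(spec),
                    areas = vapply(masks, sum, numeric(1))))
}

#' Benign and malignant phantom archetypes
#'
#' `phantom_benign()` is the all-benign default nodule (oval, parallel,
#' circumscribed, homogeneous, no posterior change, no calcification).
#' `phantom_malignant()` expresses every suspicious level: irregular
#' spiculated shape, taller-than-wide, blurred margin, heterogeneous echo,
#' posterior shadowing and punctate calcification.
#'
#' @param seed speckle seed.
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
phantom_benign <- function(seed = 0L, ...) phantom_spec(seed = seed, ...)

#' @rdname phantom_benign
#' @export
phantom_malignant <- function(seed = 0L, ...) {
  # taller than wide; the image is deeper than the benign default so the
  # posterior evaluation band (height = lesion height) fits below the
  # tall spiculated outline
  # interior 0.18: markedly hypoechoic overall, as malignant solid lesions
  # are; the blurred margin mixes background into the interior, so the
  # two-level contrast must start low to survive as heterogeneous
  phantom_spec(image_height = 160L,
               max_radii = c(26L, 16L), shape_label = "irregular",
               margin_label = "not_circumscribed",
               interior_pattern = "heterogeneous",
               interior_level = 0.18,
               posterior_label = "shadowing",
               calcification_label = "punctate",
               seed = seed, ...)
}

#' Phantom expressing one lexicon level
#'
#' Returns the benign default spec modified so that the requested category
#' expresses the requested level, leaving the other five categories at their
#' benign defaults. Used by the factorial recovery battery.
#'
#' @param category one of `shape`, `orientation`, `margin`, `echo`,
#'   `posterior`, `calcification`.
#' @param level a level of that category (see `LEXICON_LEVELS`).
#' @param seed speckle seed.
#' @return a [phantom_spec()].
#' @export
phantom_for_level <- function(category, level, seed = 0L) {
  stopifnot(category %in% names(LEXICON_LEVELS),
            level %in% LEXICON_LEVELS[[category]])
  args <- list(seed = seed)
  if (category == "shape") args$shape_label <- level
  if (category == "orientation") {
    if (level == "not_parallel") args$max_radii <- c(26L, 16L)
  }
  if (category == "margin") args$margin_label <- level
  if (category == "echo") {
    args$interior_pattern <- level
    if (level == "anechoic") args$interior_level <- 0.02
  }
  if (category == "posterior") args$posterior_label <- level
  if (category == "calcification") args$calcification_label <- level
  do.call(phantom_spec, args)
}
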