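test_that("extract_shape separates smooth from spiculated outlines", {
  # a digital disk sits at the circularity optimum
  d <- extract_shape(disk_mask(30))
  expect_equal(d$level, "regular")
  expect_gte(d$diagnostics["circularity"], 0.95)
  expect_lte(d$diagnostics["circularity"], 1.02)
  expect_gte(d$diagnostics["solidity"], 0.95)

  # smooth 40 x 20 ellipse: Ramanujan perimeter gives circularity ~ 0.84
  e <- extract_shape(ellipse_mask(20, 40))
  expect_equal(e$level, "regular")
  expect_lt(abs(e$diagnostics["circularity"] - 0.84), 0.05)

  # disk with 8 spiculations of amplitude 10: circularity collapses
  sp <- extract_shape(ellipse_mask(30, 30, k = 8, amp = 10, pad = 16))
  expect_equal(sp$level, "irregular")
  expect_lt(sp$diagnostics["circularity"], 0.70)

  expect_error(extract_shape(matrix(FALSE, 5, 5)), "empty")
})

test_that("raising circularity_min never converts irregular to regular", {
  masks <- list(disk_mask(20), ellipse_mask(18, 30),
                ellipse_mask(24, 24, k = 10, amp = 6, pad = 14))
  for (m in masks) {
    prev <- "regular"
    for (cmin in seq(0.3, 1.0, by = 0.05)) {
      lev <- extract_shape(m, feature_config(circularity_min = cmin))$level
      if (prev == "irregular") expect_equal(lev, "irregular")
      prev <- lev
    }
  }
})

test_that("extract_orientation uses bbox extents with a parallel tie", {
  wide <- matrix(FALSE, 80, 100); wide[10:39, 10:69] <- TRUE   # 60 x 30
  tall <- matrix(FALSE, 100, 80); tall[10:69, 10:39] <- TRUE   # 30 x 60
  square <- matrix(FALSE, 50, 50); square[10:29, 10:29] <- TRUE
  expect_equal(extract_orientation(wide)$level, "parallel")
  expect_equal(extract_orientation(tall)$level, "not_parallel")
  expect_equal(extract_orientation(square)$level, "parallel")
})

test_that("extract_margin reads sharpness and contour smoothness", {
  cfg <- feature_config()
  # sharp smooth ellipse: circumscribed
  f <- render_frame(phantom_benign(seed = 1), 11)
  m1 <- extract_margin(f$frame, f$mask, cfg)
  expect_equal(m1$level, "circumscribed")
  expect_lte(m1$diagnostics["smoothness"], cfg$smoothness_max)
  expect_gte(m1$diagnostics["mean_edge_gradient"], cfg$edge_gradient_min)

  # spiculated but sharp: smoothness alone disqualifies
  spic <- phantom_spec(shape_label = "irregular", spiculation = c(16, 6), seed = 1)
  g <- render_frame(spic, 11)
  m2 <- extract_margin(g$frame, g$mask, cfg)
  expect_equal(m2$level, "not_circumscribed")
  expect_gt(m2$diagnostics["smoothness"], cfg$smoothness_max)

  # smooth but blurred (sigma 8): the gradient alone disqualifies
  blur <- phantom_spec(margin_label = "not_circumscribed", edge_blur_sigma = 8, seed = 1)
  h <- render_frame(blur, 11)
  m3 <- extract_margin(h$frame, h$mask, cfg)
  expect_equal(m3$level, "not_circumscribed")
  expect_lt(m3$diagnostics["mean_edge_gradient"], cfg$edge_gradient_min)

  # masks touching the border have no gradient band
  m <- matrix(TRUE, 10, 10)
  expect_error(extract_margin(matrix(0.5, 10, 10), m), "border")
})

test_that("extract_echo grades anechoic, homogeneous and heterogeneous", {
  cyst <- render_frame(phantom_spec(interior_pattern = "anechoic",
                                    interior_level = 0.02, seed = 2), 11)
  r1 <- extract_echo(cyst$frame, cyst$mask)
  expect_equal(r1$level, "anechoic")
  expect_lte(r1$diagnostics["interior_mean"], 0.08)

  # homogeneous at low noise (gamma shape 16, raw speckle cv = 0.25)
  hom <- render_frame(phantom_spec(speckle_shape = 16, seed = 2), 11)
  r2 <- extract_echo(hom$frame, hom$mask)
  expect_equal(r2$level, "homogeneous")

  # the spec'd two-level interior 0.15/0.45: structural cv ~ 0.5 > 0.35
  het <- render_frame(phantom_spec(interior_pattern = "heterogeneous",
                                   interior_level = 0.30, seed = 2), 11)
  r3 <- extract_echo(het$frame, het$mask)
  expect_equal(r3$level, "heterogeneous")
  expect_gt(r3$diagnostics["cv"], 0.35)
})

test_that("extract_posterior compares the band to its flanks", {
  # the evaluation band (height = lesion height) spans the rendered gain
  # region (height = vertical radius) plus normal tissue, so the measured
  # ratio is pulled towards 1 but must stay on the right side of the gate
  for (case in list(list("enhancement", 1.5), list("shadowing", 0.5),
                    list("none", 1.0))) {
    spec <- phantom_spec(posterior_label = case[[1]],
                         posterior_gain = if (case[[2]] == 1) NULL else case[[2]],
                         seed = 3)
    f <- render_frame(spec, 11)
    r <- extract_posterior(f$frame, f$mask)
    expect_equal(r$level, case[[1]])
    expect_lt(abs(r$diagnostics["band_ratio"] - 1), abs(case[[2]] - 1) + 0.05)
  }
  # band deeper than the image errors
  low <- matrix(FALSE, 40, 60); low[20:35, 20:40] <- TRUE
  expect_error(extract_posterior(matrix(0.5, 40, 60), low), "bottom")
})

test_that("extract_calcification grades foci by size", {
  f0 <- render_frame(phantom_benign(seed = 4), 11)
  expect_equal(extract_calcification(f0$frame, f0$mask)$level, "none")

  fc <- render_frame(phantom_for_level("calcification", "coarse", seed = 4), 11)
  rc <- extract_calcification(fc$frame, fc$mask)
  expect_equal(rc$level, "coarse")
  expect_gte(rc$diagnostics["max_focus_px"], 12)

  fp <- render_frame(phantom_for_level("calcification", "punctate", seed = 4), 11)
  rp <- extract_calcification(fp$frame, fp$mask)
  expect_equal(rp$level, "punctate")
  expect_lt(rp$diagnostics["max_focus_px"], 12)
})

test_that("extract_all reproduces the archetype lexicon end to end", {
  ben <- render_frame(phantom_benign(seed = 5), 11)
  expect_equal(unlist(unclass(extract_all(ben$frame, ben$mask))),
               c(shape = "regular", orientation = "parallel",
                 margin = "circumscribed", echo = "homogeneous",
                 posterior = "none", calcification = "none"))

  mal <- render_frame(phantom_malignant(seed = 5), 11)
  expect_equal(unlist(unclass(extract_all(mal$frame, mal$mask))),
               c(shape = "irregular", orientation = "not_parallel",
                 margin = "not_circumscribed", echo = "heterogeneous",
                 posterior = "shadowing", calcification = "punctate"))

  cyst <- render_frame(phantom_spec(interior_pattern = "anechoic",
                                    interior_level = 0.02,
                                    posterior_label = "enhancement", seed = 5), 11)
  res <- extract_all(cyst$frame, cyst$mask)
  expect_equal(res$echo, "anechoic")
  expect_equal(res$posterior, "enhancement")

  expect_error(extract_all(ben$frame, matrix(FALSE, 128, 128)), "empty")
})

test_that("labels depend only on content near the mask, not far-field speckle", {
  base <- unlist(unclass(extract_all(render_frame(phantom_benign(seed = 0), 11)$frame,
                                     render_frame(phantom_benign(seed = 0), 11)$mask)))
  for (s in 1:5) {
    f <- render_frame(phantom_benign(seed = s), 11)
    expect_equal(unlist(unclass(extract_all(f$frame, f$mask))), base)
  }
})
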