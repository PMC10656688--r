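test_that("equalize is monotone and fixes degenerate inputs", {
  expect_equal(equalize(matrix(0.4, 6, 6)), matrix(0.4, 6, 6))
  set.seed(1)
  f <- matrix(runif(64^2), 64, 64)
  e <- equalize(f)
  ord <- order(f)
  expect_true(all(diff(e[ord]) >= -1e-12))
  expect_gte(min(e), 0); expect_lte(max(e), 1)
  # exactly uniform histogram: the CDF is the identity up to one bin width
  u <- matrix(rep((0:255) / 255, 16), 64, 64)
  expect_lt(max(abs(equalize(u) - u)), 1 / 256 + 1e-9)
})

test_that("segment_frame finds phantom lesions accurately", {
  for (s in 0:2) {
    f <- render_frame(phantom_benign(seed = s), 11)
    m <- segment_frame(f$frame)
    expect_s3_class(m, "lesion_mask")
    expect_gte(overlap_metrics(m, f$mask)["dice"], 0.90)
    bb <- autobirads:::mask_bbox(m$mask)
    expect_identical(m$bbox, bb)
    expect_identical(m$area, sum(m$mask))
  }
})

test_that("segment_frame returns absent for speckle and tiny objects", {
  # pure speckle (lesion-free sweep end)
  for (s in 1:5) {
    f <- render_frame(phantom_benign(seed = 100 + s), 0)
    expect_null(segment_frame(f$frame))
  }
  # a lesion below min_area
  spec <- phantom_spec(max_radii = c(3, 4), lesion_center = c(48, 64),
                       n_frames = 24, seed = 1)
  f <- render_frame(spec, 11)
  expect_lt(sum(f$mask), 64)
  expect_null(segment_frame(f$frame))
})

test_that("segment_frame is translation-equivariant within a pixel", {
  base <- phantom_spec(lesion_center = c(48, 56), seed = 5)
  shifted <- phantom_spec(lesion_center = c(53, 63), seed = 5)
  m1 <- segment_frame(render_frame(base, 11)$frame)
  m2 <- segment_frame(render_frame(shifted, 11)$frame)
  expect_true(all(abs((m2$bbox - m1$bbox) - c(5, 7, 5, 7)) <= 1))
})

test_that("segment_video matches ground-truth flags at the sweep boundary", {
  gv <- generate_video(phantom_benign(seed = 6, n_frames = 30L))
  res <- segment_video(gv$video)
  detected <- !vapply(res, is.null, logical(1))
  expect_lte(sum(detected != gv$truth$present), 2)
  # determinism
  res2 <- segment_video(gv$video)
  expect_identical(lapply(res, function(m) if (is.null(m)) NULL else m$mask),
                   lapply(res2, function(m) if (is.null(m)) NULL else m$mask))
  # blank video
  blank <- frame_sequence(replicate(6, render_frame(phantom_benign(seed = 9), 0)$frame,
                                    simplify = FALSE))
  expect_true(all(vapply(segment_video(blank), is.null, logical(1))))
})

test_that("segment_video drops isolated single-frame detections", {
  gv <- generate_video(phantom_benign(seed = 3))
  lesion <- gv$video$frames[[12]]
  blank <- render_frame(phantom_benign(seed = 90), 0)$frame
  v <- frame_sequence(list(blank, lesion, blank, lesion, lesion, blank))
  res <- segment_video(v)
  expect_null(res[[2]])           # isolated detection removed
  expect_false(is.null(res[[4]])) # contiguous pair kept
  expect_false(is.null(res[[5]]))
})

test_that("simam_weights matches its closed form", {
  # constant channel: sigma2 = 0 and t = mu, so e = 2 and w = sigmoid(0.5)
  const <- matrix(0.7, 5, 5)
  out <- simam_weights(const, lambda = 1e-4)
  w <- attr(out, "weights")
  expect_equal(unique(as.vector(w)), stats::plogis(0.5), tolerance = 1e-12)
  expect_equal(out, const * stats::plogis(0.5),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a spike stands out from a zero background
  spike <- matrix(0, 7, 7); spike[4, 4] <- 1
  ws <- attr(simam_weights(spike, lambda = 1e-4), "weights")
  expect_gt(ws[4, 4], max(ws[-25]))
  # weights strictly inside (0,1)
  set.seed(2)
  x <- array(rnorm(4 * 6 * 3), dim = c(4, 6, 3))
  wa <- attr(simam_weights(x), "weights")
  expect_true(all(wa > 0 & wa < 1))
  # shift invariance is exact; scaling x by b with lambda scaled by b^2 too
  w1 <- attr(simam_weights(x[, , 1], lambda = 1e-3), "weights")
  w2 <- attr(simam_weights(x[, , 1] + 5, lambda = 1e-3), "weights")
  w3 <- attr(simam_weights(3 * x[, , 1], lambda = 9e-3), "weights")
  expect_equal(w1, w2, tolerance = 1e-9)
  expect_equal(w1, w3, tolerance = 1e-9)
})

test_that("detection losses match their closed forms", {
  p <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  for (y in c(0, 1)) {
    expect_equal(bce_loss(p, y), -(y * log(p) + (1 - y) * log(1 - p)))
    # focal with gamma = 0, alpha = 0.5 halves the BCE
    expect_equal(focal_loss(p, y, gamma = 0, alpha = 0.5), 0.5 * bce_loss(p, y))
  }
  expect_message(bce_loss(c(0, 1), 1), "clamped")
  # identical boxes: IoU 1, no centre offset, no aspect mismatch
  expect_equal(ciou_loss(c(0, 0, 10, 10), c(0, 0, 10, 10)), 0)
  # worked example: IoU 0, rho2 = 200, c2 = 800, equal aspect so v = 0
  expect_equal(ciou_loss(c(0, 0, 10, 10), c(10, 10, 20, 20)), 1.25)
  expect_error(ciou_loss(c(0, 0, 0, 10), c(0, 0, 10, 10)))
})

test_that("overlap metrics follow their definitions", {
  a <- matrix(FALSE, 10, 20); a[2:6, 2:11] <- TRUE
  expect_equal(unname(overlap_metrics(a, a)), c(1, 1))
  b <- matrix(FALSE, 10, 20); b[8:9, 15:18] <- TRUE
  expect_equal(unname(overlap_metrics(a, b)), c(0, 0))
  # |A| = |B| = 100, overlap 50
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
  B <- matrix(FALSE, 20, 20); B[1:10, 6:15] <- TRUE
  m <- overlap_metrics(A, B)
  expect_equal(unname(m["dice"]), 0.5)
  expect_equal(unname(m["iou"]), 1 / 3)
  # empty-vs-empty convention
  e <- matrix(FALSE, 4, 4)
  expect_equal(unname(overlap_metrics(e, e)), c(1, 1))
  # dice = 2 iou / (1 + iou) across random mask pairs
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(runif(100) < 0.4, 10, 10)
    y <- matrix(runif(100) < 0.4, 10, 10)
    mm <- overlap_metrics(x, y)
    expect_gte(mm["dice"] + 1e-12, mm["iou"])
    expect_equal(unname(mm["dice"]), unname(2 * mm["iou"] / (1 + mm["iou"])))
  }
})

test_that("detection_counts classifies frames by IoU and absence", {
  A <- matrix(FALSE, 10, 10); A[2:5, 2:5] <- TRUE
  half <- matrix(FALSE, 10, 10); half[2:5, 2] <- TRUE # IoU 0.25: a miss
  off <- matrix(FALSE, 10, 10); off[7:9, 7:9] <- TRUE
  none <- NULL
  preds <- list(A, half, off, A, none, none)
  truth <- list(A, A, A, none, A, none)
  res <- detection_counts(preds, truth, iou_cut = 0.5)
  expect_equal(unname(res[c("tp", "fp", "fn", "tn")]), c(1, 1, 3, 1))
  expect_equal(unname(res["precision"]), 0.5)
  expect_equal(unname(res["recall"]), 0.25)
  expect_equal(unname(res["specificity"]), 0.5)
})
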