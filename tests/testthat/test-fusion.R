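mk_feat <- function(shape = "regular", orientation = "parallel",
                    margin = "circumscribed", echo = "homogeneous",
                    posterior = "none", calcification = "none") {
  structure(list(shape = shape, orientation = orientation, margin = margin,
                 echo = echo, posterior = posterior,
                 calcification = calcification), class = "frame_features")
}

test_that("aggregate_profile counts level frequencies over lesion frames", {
  ident <- replicate(10, mk_feat(), simplify = FALSE)
  p <- aggregate_profile(ident)
  expect_equal(p$n_lesion_frames, 10)
  for (cat in names(p$proportions)) {
    expect_equal(sum(p$proportions[[cat]]), 1, tolerance = 1e-9)
    expect_equal(max(p$proportions[[cat]]), 1)
  }

  mixed <- c(replicate(6, mk_feat(shape = "irregular"), simplify = FALSE),
             replicate(4, mk_feat(), simplify = FALSE))
  p2 <- aggregate_profile(mixed)
  expect_equal(p2$proportions$shape, c(regular = 0.4, irregular = 0.6))

  # NULL entries (frames without a lesion) are excluded
  expect_equal(aggregate_profile(c(mixed, list(NULL)))$n_lesion_frames, 10)
  expect_error(aggregate_profile(list(NULL)), "zero lesion frames")
})

test_that("select_levels applies inclusive thresholds with malignant tie-breaks", {
  tab <- score_table()
  mk_prof <- function(n, ...) aggregate_profile(replicate(n, mk_feat(...), simplify = FALSE))

  # exactly at threshold: >= is inclusive, the suspicious level wins
  p <- aggregate_profile(c(replicate(5, mk_feat(shape = "irregular"), simplify = FALSE),
                           replicate(5, mk_feat(), simplify = FALSE)))
  expect_equal(unname(select_levels(p, tab)["shape"]), "irregular")

  # calcification threshold is 0.2: transient foci still count
  p2 <- aggregate_profile(c(replicate(1, mk_feat(calcification = "punctate"), simplify = FALSE),
                            replicate(3, mk_feat(), simplify = FALSE)))
  expect_equal(unname(select_levels(p2, tab)["calcification"]), "punctate")

  # below-threshold suspicious level falls back to the modal level
  p3 <- aggregate_profile(c(replicate(4, mk_feat(posterior = "enhancement"), simplify = FALSE),
                            replicate(6, mk_feat(), simplify = FALSE)))
  expect_equal(unname(select_levels(p3, tab)["posterior"]), "none")
})

test_that("score_and_classify maps scores through the rank table", {
  tab <- score_table()
  benign <- c(shape = "regular", orientation = "parallel",
              margin = "circumscribed", echo = "homogeneous",
              posterior = "none", calcification = "none")
  a <- score_and_classify(benign, tab)
  expect_equal(a$total_score, 0)
  expect_equal(a$category, "3")
  expect_false(a$malignant)

  suspicious <- c(shape = "irregular", orientation = "not_parallel",
                  margin = "not_circumscribed", echo = "heterogeneous",
                  posterior = "shadowing", calcification = "punctate")
  b <- score_and_classify(suspicious, tab)
  expect_equal(b$total_score, 11)
  expect_equal(b$category, "5")
  expect_true(b$malignant)

  cyst <- c(shape = "regular", orientation = "parallel",
            margin = "circumscribed", echo = "anechoic",
            posterior = "none", calcification = "none")
  d <- score_and_classify(cyst, tab)
  expect_equal(d$category, "2")
  expect_false(d$malignant)
  expect_true(d$override)
})

test_that("category rank is monotone in chosen-level weights", {
  tab <- score_table(simple_cyst_override = FALSE)
  rank_of <- function(lv) match(score_and_classify(lv, tab)$category,
                                c("2", "3", "4a", "4b", "4c", "5"))
  set.seed(11)
  levels_of <- autobirads:::LEXICON_LEVELS
  for (i in 1:50) {
    lv <- vapply(names(levels_of), function(cat) sample(levels_of[[cat]], 1),
                 character(1))
    base_rank <- rank_of(lv)
    base_mal <- score_and_classify(lv, tab)$malignant
    for (cat in names(levels_of)) {
      w <- tab$weights[[cat]]
      higher <- names(w)[w > w[[lv[[cat]]]]]
      for (h in higher) {
        lv2 <- lv; lv2[cat] <- h
        expect_gte(rank_of(lv2), base_rank)
        if (base_mal) expect_true(score_and_classify(lv2, tab)$malignant)
      }
    }
  }
})

test_that("the fused assessment is invariant to frame order and below-threshold noise", {
  set.seed(12)
  feats <- c(replicate(8, mk_feat(shape = "irregular", calcification = "punctate"),
                       simplify = FALSE),
             replicate(5, mk_feat(), simplify = FALSE))
  tab <- score_table()
  ref <- score_and_classify(select_levels(aggregate_profile(feats), tab), tab)
  for (i in 1:10) {
    sh <- sample(feats)
    a <- score_and_classify(select_levels(aggregate_profile(sh), tab), tab)
    expect_equal(a$category, ref$category)
    expect_equal(a$total_score, ref$total_score)
  }
  # swapping which frames carry a below-threshold minority level changes nothing
  f1 <- c(replicate(9, mk_feat(), simplify = FALSE),
          list(mk_feat(posterior = "enhancement")))
  f2 <- c(list(mk_feat(posterior = "shadowing")),
          replicate(9, mk_feat(), simplify = FALSE))
  a1 <- score_and_classify(select_levels(aggregate_profile(f1), tab), tab)
  a2 <- score_and_classify(select_levels(aggregate_profile(f2), tab), tab)
  expect_equal(a1$category, a2$category)
})

test_that("classify_video runs the full pipeline on phantoms", {
  ben <- classify_quiet(generate_video(phantom_benign(seed = 1))$video)
  expect_true(ben$category %in% c("2", "3"))
  expect_false(ben$malignant)
  expect_gte(ben$profile$n_lesion_frames, 10)

  mal <- classify_quiet(generate_video(phantom_malignant(seed = 1))$video)
  expect_true(mal$category %in% c("4c", "5"))
  expect_true(mal$malignant)

  blank <- frame_sequence(replicate(6, render_frame(phantom_benign(seed = 31), 0)$frame,
                                    simplify = FALSE))
  nl <- classify_video(blank)
  expect_true(nl$no_lesion)
  expect_true(is.na(nl$category))
})
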