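# Score fusion: per-frame lexicon labels are aggregated into per-category
# frame proportions over the lesion frames, a level is chosen per category
# by frame-proportion thresholds, the chosen levels are scored with
# per-level weights, and the total score is mapped through a rank-threshold
# table to a BI-RADS category (2-5) and a benign/malignant call.

#' Weighted rank-threshold score table
#'
#' Every number that drives the fused assessment lives here: per-level
#' weights, per-category frame-proportion thresholds, the rank thresholds
#' mapping total score to BI-RADS category, the malignancy cut, and the
#' simple-cyst override. Defaults are chosen so the canonical archetypes
#' land correctly: a simple cyst maps to category 2, an all-benign solid
#' nodule scores 0 (category 3), and an all-suspicious lesion scores 11
#' (category 5).
#'
#' @param weights named list: for each category, named numeric of per-level
#'   weights.
#' @param proportion_thresholds named numeric: per-category frame-proportion
#'   threshold. Calcification uses a lower threshold because transiently
#'   visible foci still count.
#' @param rank_min_scores named numeric: minimum total score of each
#'   category, strictly increasing in category order; a score below the
#'   first entry maps to category 2.
#' @param malignancy_cut first category called malignant.
#' @param simple_cyst_override when `TRUE`, an anechoic + circumscribed +
#'   regular + parallel lesion without calcification is category 2, benign,
#'   whatever its score.
#' @return object of class `score_table`.
#' @export
score_table <- function(
    weights = list(
      shape = c(regular = 0, irregular = 2),
      orientation = c(parallel = 0, not_parallel = 2),
      margin = c(circumscribed = 0, not_circumscribed = 2),
      echo = c(anechoic = -2, homogeneous = 0, heterogeneous = 1),
      posterior = c(none = 0, enhancement = 0, shadowing = 2),
      calcification = c(none = 0, coarse = 0, punctate = 2)),
    proportion_thresholds = c(shape = 0.5, orientation = 0.5, margin = 0.5,
                              echo = 0.5, posterior = 0.5, calcification = 0.2),
    rank_min_scores = c("3" = 0, "4a" = 1, "4b" = 3, "4c" = 5, "5" = 7),
    malignancy_cut = "4b",
    simple_cyst_override = TRUE) {
  stopifnot(setequal(names(weights), names(LEXICON_LEVELS)),
            setequal(names(proportion_thresholds), names(LEXICON_LEVELS)),
            all(names(rank_min_scores) %in% BIRADS_CATEGORIES),
            !is.unsorted(rank_min_scores, strictly = TRUE),
            malignancy_cut %in% BIRADS_CATEGORIES)
  for (cat in names(LEXICON_LEVELS)) {
    stopifnot(setequal(names(weights[[cat]]), LEXICON_LEVELS[[cat]]),
              all(is.finite(weights[[cat]])))
  }
  structure(list(weights = weights,
                 proportion_thresholds = proportion_thresholds,
                 rank_min_scores = rank_min_scores,
                 malignancy_cut = malignancy_cut,
                 simple_cyst_override = simple_cyst_override),
            class = "score_table")
}

#' Aggregate per-frame features into a frame-proportion profile
#'
#' Empirical level frequencies per lexicon category, computed over lesion
#' frames only (entries that are `NULL` — frames without a detected lesion —
#' are excluded before calling this).
#'
#' @param features list of `frame_features` (one per lesion frame).
#' @return object of class `feature_profile`: `proportions` (per category,
#'   named numeric over that category's levels, summing to 1) and
#'   `n_lesion_frames`.
#' @export
aggregate_profile <- function(features) {
  features <- Filter(Negate(is.null), features)
  n <- length(features)
  if (n == 0) stop("aggregate_profile: zero lesion frames")
  props <- lapply(names(LEXICON_LEVELS), function(cat) {
    levs <- LEXICON_LEVELS[[cat]]
    counts <- table(factor(vapply(features, function(f) f[[cat]], character(1)),
                           levels = levs))
    as.numeric(counts) / n -> p
    names(p) <- levs
    p
  })
  names(props) <- names(LEXICON_LEVELS)
  structure(list(proportions = props, n_lesion_frames = n),
            class = "feature_profile")
}

#' Choose one level per category from a profile
#'
#' Binary categories (shape, orientation, margin): the suspicious level is
#' chosen iff its frame proportion reaches the category threshold
#' (inclusive), else the benign level. Three-level categories: the
#' highest-weighted level whose proportion reaches its threshold wins; if
#' none does, the most frequent level wins, ties broken toward the higher
#' weight (malignant-leaning).
#'
#' @param profile a [aggregate_profile()] result.
#' @param table a [score_table()].
#' @return named character vector: chosen level per category.
#' @export
select_levels <- function(profile, table = score_table()) {
  stopifnot(inherits(profile, "feature_profile"))
  out <- character(0)
  for (cat in names(LEXICON_LEVELS)) {
    p <- profile$proportions[[cat]]
    w <- table$weights[[cat]][names(p)]
    thr <- table$proportion_thresholds[[cat]]
    if (length(p) == 2) {
      suspicious <- names(which.max(w))
      benign <- setdiff(names(p), suspicious)
      out[cat] <- if (p[suspicious] >= thr) suspicious else benign
    } else {
      # qualifying levels ranked by weight, then by frame proportion
      ord <- names(p)[order(-w, -p)]
      hit <- ord[vapply(ord, function(l) p[l] >= thr, logical(1))]
      if (length(hit) > 0) {
        out[cat] <- hit[1]
      } else {
        best <- p == max(p)
        cands <- names(p)[best]
        out[cat] <- cands[which.max(w[cands])]
      }
    }
  }
  out
}

category_rank <- function(category) match(category, BIRADS_CATEGORIES)

score_to_category <- function(total, table) {
  cuts <- table$rank_min_scores
  cat <- "2"
  for (k in names(cuts)) if (total >= cuts[[k]]) cat <- k
  cat
}

#' Score the chosen levels and assign the BI-RADS category
#'
#' Sums the per-level weights, maps the total through the rank thresholds,
#' and calls malignant iff the category reaches the malignancy cut. The
#' simple-cyst override (anechoic, circumscribed, regular, parallel, no
#' calcification) forces category 2 / benign and is flagged.
#'
#' @param levels named character vector: one level per category.
#' @param table a [score_table()].
#' @param profile optional [aggregate_profile()] result carried into the
#'   assessment for reporting.
#' @return object of class `assessment` with fields `category`, `malignant`,
#'   `total_score`, `levels`, `override`, `profile`.
#' @export
score_and_classify <- function(levels, table = score_table(), profile = NULL) {
  stopifnot(setequal(names(levels), names(LEXICON_LEVELS)))
  total <- sum(vapply(names(LEXICON_LEVELS),
                      function(cat) table$weights[[cat]][[levels[[cat]]]],
                      numeric(1)))
  override <- table$simple_cyst_override &&
    levels[["echo"]] == "anechoic" && levels[["margin"]] == "circumscribed" &&
    levels[["shape"]] == "regular" && levels[["orientation"]] == "parallel" &&
    levels[["calcification"]] == "none"
  category <- if (override) "2" else score_to_category(total, table)
  malignant <- if (override) FALSE else
    category_rank(category) >= category_rank(table$malignancy_cut)
  structure(list(category = category, malignant = malignant,
                 total_score = total, levels = levels,
                 override = override, profile = profile,
                 no_lesion = FALSE),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  if (isTRUE(x$no_lesion)) {
    cat("assessment: no lesion detected\n")
    return(invisible(x))
  }
  cat(sprintf("BI-RADS %s (%s), fused score %d%s\n", x$category,
              if (x$malignant) "malignant" else "benign",
              as.integer(x$total_score),
              if (isTRUE(x$override)) " [simple-cyst override]" else ""))
  cat("  levels:", paste(names(x$levels), unlist(x$levels), sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$profile))
    cat(sprintf("  lesion frames: %d\n", x$profile$n_lesion_frames))
  invisible(x)
}

#' Classify a whole sweep video
#'
#' Runs the full pipeline: [segment_video()], [extract_all()] on every
#' lesion frame, [aggregate_profile()], [select_levels()],
#' [score_and_classify()]. Deterministic for fixed inputs and
#' configuration. When no frame contains a detectable lesion the result is
#' an explicit no-lesion assessment (`no_lesion = TRUE`, category `NA`) —
#' distinct from BI-RADS 1, which this model never emits.
#'
#' @param video a [frame_sequence()].
#' @param seg a [seg_config()].
#' @param feat a [feature_config()].
#' @param table a [score_table()].
#' @return an `assessment`; also carries `per_frame` (per-lesion-frame
#'   labels) and `frame_indices` (1-based indices of the lesion frames).
#' @export
classify_video <- function(video, seg = seg_config(), feat = feature_config(),
                           table = score_table()) {
  masks <- segment_video(video, seg)
  keep <- which(!vapply(masks, is.null, logical(1)))
  if (length(keep) == 0) {
    return(structure(list(category = NA_character_, malignant = NA,
                          total_score = NA_integer_, levels = NULL,
                          override = FALSE, profile = NULL,
                          per_frame = list(), frame_indices = integer(0),
                          no_lesion = TRUE),
                     class = "assessment"))
  }
  feats <- lapply(keep, function(i) extract_all(video$frames[[i]], masks[[i]], feat))
  profile <- aggregate_profile(feats)
  levels <- select_levels(profile, table)
  out <- score_and_classify(levels, table, profile)
  out$per_frame <- lapply(feats, function(f) as.list(unclass(f)))
  out$frame_indices <- keep
  out
}
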