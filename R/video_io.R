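# Readers and writers: frame directories (PNG), mask directories, JSON
# assessment reports and CSV rating tables, plus the core sequence type.
# No video codec is available in this toolchain, so the cine-loop carrier
# is an ordered directory of zero-padded PNG frames; AVI/MP4 paths raise an
# informative error rather than a silent wrong answer.

#' Ordered frame sequence of one sweep video
#'
#' @param frames list of numeric matrices in `[0,1]`, all the same size.
#' @param source_id free-text identifier of the source video.
#' @param fps optional frame rate (frames/second).
#' @param pixel_spacing optional physical pixel size (mm/px).
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, source_id = "unknown", fps = NULL, pixel_spacing = NULL) {
  if (length(frames) < 1) stop("a frame_sequence needs at least one frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("frame intensities must lie in [0,1]")
  structure(list(frames = frames, source_id = source_id,
                 fps = fps, pixel_spacing = pixel_spacing),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence '%s': %d frames of %d x %d\n",
              x$source_id, length(x$frames), d[1], d[2]))
  invisible(x)
}

# Convert a readPNG result (matrix or array) to a grayscale matrix using
# Rec.601 luma weights; drops any alpha channel.
as_gray <- function(px) {
  if (is.matrix(px)) return(px)
  if (length(dim(px)) == 3) {
    ch <- dim(px)[3]
    if (ch >= 3) return(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    return(px[, , 1])
  }
  stop("unsupported PNG pixel layout")
}

#' Read a sweep video from a directory of PNG frames
#'
#' Frames are read in lexicographic filename order (use zero-padded names
#' such as `frame_0007.png`), converted to grayscale with Rec.601 luma
#' weights if stored as RGB, and returned in `[0,1]`.
#'
#' @param path directory containing `*.png` frames.
#' @param source_id identifier recorded in the sequence; defaults to `path`.
#' @return a [frame_sequence()].
#' @export
read_video <- function(path, source_id = path) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.(avi|mp4|mov)$", tolower(path)))
      stop("video containers (AVI/MP4) are not supported in this build; ",
           "export the cine loop to a directory of zero-padded PNG frames")
    stop("no such frame directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("frame directory contains no PNG frames: ", path)
  frames <- lapply(files, function(f) as_gray(png::readPNG(f)))
  frame_sequence(frames, source_id = source_id)
}

#' Write a frame sequence (or mask list) as 8-bit PNG files
#'
#' @param x a [frame_sequence()] or a list of logical/numeric matrices.
#' @param dir output directory, created if absent.
#' @param prefix filename prefix; files are `<prefix>_0000.png`, ...
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(x, dir, prefix = "frame") {
  frames <- if (inherits(x, "frame_sequence")) x$frames else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (is.logical(f)) f <- f * 1.0
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i - 1L))
    png::writePNG(pmin(pmax(f, 0), 1), paths[i])
  }
  invisible(paths)
}

#' Read binary masks from a directory of PNG files
#'
#' @param path directory of mask PNGs (lexicographic order).
#' @return list of logical matrices (pixel > 0.5).
#' @export
read_masks <- function(path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("mask directory contains no PNG files: ", path)
  lapply(files, function(f) as_gray(png::readPNG(f)) > 0.5)
}

BIRADS_CATEGORIES <- c("2", "3", "4a", "4b", "4c", "5")

#' Ordinal encoding of BI-RADS categories
#'
#' Maps `2, 3, 4a, 4b, 4c, 5` to `1..6` for ROC analysis.
#'
#' @param x character vector of category tokens.
#' @return integer vector in `1..6`.
#' @export
birads_ordinal <- function(x) {
  m <- match(as.character(x), BIRADS_CATEGORIES)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unknown BI-RADS category token '%s' (entry %d)", x[bad], bad))
  }
  m
}

#' Read a rating table for the agreement statistics
#'
#' CSV with header; required column `lesion_id`, optional `truth`
#' (`benign`/`malignant`), and any number of rater columns named
#' `rating_<rater>` whose values are BI-RADS tokens in
#' `{2, 3, 4a, 4b, 4c, 5}`. Feature-label columns are passed through.
#'
#' @param path CSV file.
#' @param require_truth error when the `truth` column is missing.
#' @return data.frame; each `rating_*` column gains an ordinal companion
#'   column `ord_<rater>` in `1..6`.
#' @export
read_ratings <- function(path, require_truth = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"lesion_id" %in% names(df)) stop("ratings CSV must have a lesion_id column")
  if (require_truth && !"truth" %in% names(df))
    stop("ratings CSV must have a truth column for performance statistics")
  if ("truth" %in% names(df)) {
    bad <- !df$truth %in% c("benign", "malignant")
    if (any(bad)) stop("truth must be 'benign' or 'malignant' (row ",
                       which(bad)[1], ")")
  }
  for (col in grep("^rating_", names(df), value = TRUE)) {
    v <- df[[col]]
    m <- match(v, BIRADS_CATEGORIES)
    if (anyNA(m) && any(nzchar(v[is.na(m)]))) {
      bad <- which(is.na(m) & nzchar(v))[1]
      stop(sprintf("unknown BI-RADS category token '%s' in column %s, row %d",
                   v[bad], col, bad))
    }
    df[[sub("^rating_", "ord_", col)]] <- m
  }
  df
}

#' Write an assessment report as JSON
#'
#' The report carries the BI-RADS category, the benign/malignant call, the
#' fused score, the six chosen levels, the per-category frame proportions,
#' the per-frame labels, the configuration hash and the seed, so a run can
#' be audited and reproduced.
#'
#' @param assessment an `assessment` object from [score_and_classify()] or
#'   [classify_video()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_report <- function(assessment, path) {
  payload <- list(
    birads = assessment$category,
    malignant = assessment$malignant,
    no_lesion = isTRUE(assessment$no_lesion),
    total_score = assessment$total_score,
    levels = as.list(assessment$levels),
    proportions = assessment$profile$proportions,
    n_lesion_frames = assessment$profile$n_lesion_frames,
    per_frame = assessment$per_frame,
    override = assessment$override,
    config_hash = assessment$config_hash,
    seed = assessment$seed,
    package_version = as.character(utils::packageVersion("autobirads")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a JSON assessment report
#'
#' @param path JSON file written by [write_report()].
#' @return list mirroring the report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
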