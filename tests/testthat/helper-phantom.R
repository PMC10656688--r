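# Shared fixtures and independent oracles.

# Tie-aware brute-force AUC: enumerate every positive x negative pair.
brute_auc <- function(ratings, truth) {
  pos <- ratings[truth == 1]
  neg <- ratings[truth == 0]
  total <- 0
  for (p in pos) for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# A filled disk mask of radius r centred in a (2r + 2*pad) square image.
disk_mask <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - c0)^2 + (cols - c0)^2 <= r^2
}

# Ellipse mask with semi-axes (rv vertical, rh horizontal), optionally with
# a radial cosine perturbation (count k, amplitude in px).
ellipse_mask <- function(rv, rh, k = 0, amp = 0, pad = 12) {
  nr <- 2 * (rv + pad) + 1
  nc <- 2 * (rh + pad) + 1
  cr <- rv + pad + 1
  cc <- rh + pad + 1
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  uy <- (rows - cr) / rv
  ux <- (cols - cc) / rh
  u <- sqrt(uy^2 + ux^2)
  if (k > 0 && amp > 0) {
    theta <- atan2(uy, ux)
    u <= 1 + (amp / mean(c(rv, rh))) * cos(k * theta)
  } else {
    u <= 1
  }
}

# Per-frame lexicon labels of a video, using the ground-truth masks.
labels_with_truth_masks <- function(gv, config = feature_config()) {
  idx <- which(gv$truth$present & vapply(gv$truth$masks, sum, numeric(1)) > 0)
  lapply(idx, function(i) extract_all(gv$video$frames[[i]], gv$truth$masks[[i]], config))
}

# Quiet end-to-end classification (margin/posterior fallbacks warn by design
# on onset/offset frames).
classify_quiet <- function(video, ...) {
  suppressWarnings(classify_video(video, ...))
}
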