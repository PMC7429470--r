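# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC by exhaustive pair counting, ties counted one half.
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Best Youden index by scanning every candidate threshold (all midpoints
# plus sentinels), assuming "higher score predicts positive".
scan_youden <- function(scores, positive) {
  su <- sort(unique(scores))
  thr <- c(-Inf, (su[-1] + su[-length(su)]) / 2, Inf)
  best <- -Inf
  for (t in thr) {
    sens <- mean(scores[positive] > t)
    spec <- mean(scores[!positive] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Best 3-slice window by checking every window explicitly.
scan_best_window <- function(counts) {
  best <- -1; start <- NA
  for (s in seq_len(length(counts) - 2)) {
    tot <- sum(counts[s:(s + 2)])
    if (tot > best) { best <- tot; start <- s }
  }
  start:(start + 2)
}

# A mask with prescribed per-slice in-mask areas on an n x n grid.
mask_from_areas <- function(areas, n = 4) {
  m <- array(FALSE, c(n, n, length(areas)))
  for (z in seq_along(areas)) {
    if (areas[z] > 0) m[, , z][seq_len(areas[z])] <- TRUE
  }
  m
}
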