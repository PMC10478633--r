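# Independent oracles and small utilities shared across the test files.

# Exhaustive MSSE stopping-rule scan, written as an explicit loop over every
# candidate stopping index; deliberately independent of the package's
# vectorized implementation.
msse_oracle <- function(residuals_sq, lambda = 3, k_min = 12L, p = 1L,
                        minimum_residual = 0) {
  r2 <- sort(pmax(residuals_sq, minimum_residual^2))
  n <- length(r2)
  k <- k_min
  while (k < n) {
    sigma2_k <- sum(r2[1:k]) / (k - p)
    if (r2[k + 1] > lambda^2 * sigma2_k) break
    k <- k + 1L
  }
  sigma <- sqrt(sum(r2[1:k]) / (k - p))
  list(sigma = sigma, k_inliers = k)
}

# Greedy one-to-one matching of detected peaks to planted peaks within
# `radius` pixels; returns precision and recall.
match_peaks <- function(peaks, truth, radius = 3) {
  if (nrow(peaks) == 0L) {
    return(list(precision = if (nrow(truth) == 0L) 1 else NA_real_,
                recall = if (nrow(truth) == 0L) 1 else 0,
                tp = 0L, fp = 0L, fn = nrow(truth)))
  }
  used <- logical(nrow(truth))
  tp <- 0L
  for (j in seq_len(nrow(peaks))) {
    d2 <- (peaks$centroid_row[j] - truth$row)^2 +
      (peaks$centroid_col[j] - truth$col)^2
    d2[used] <- Inf
    i <- which.min(d2)
    if (length(i) && d2[i] <= radius^2) {
      used[i] <- TRUE
      tp <- tp + 1L
    }
  }
  list(precision = tp / nrow(peaks), recall = tp / nrow(truth),
       tp = tp, fp = nrow(peaks) - tp, fn = sum(!used))
}

# Precision/recall of a predicted bad-pixel set against planted defects.
mask_pr <- function(mask, truth) {
  truth_bad <- rbind(truth$hot, truth$dead, truth$flicker)
  pred <- which(unclass(mask) > 0L, arr.ind = TRUE)
  tb <- paste(truth_bad[, 1L], truth_bad[, 2L])
  pb <- paste(pred[, 1L], pred[, 2L])
  list(precision = if (length(pb)) mean(pb %in% tb) else 1,
       recall = mean(tb %in% pb))
}
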