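# Shared fixtures, generated once per test run and cached.

pq_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = pq_test_cache)) {
    assign(key, force(expr), envir = pq_test_cache)
  }
  get(key, envir = pq_test_cache)
}

# Desk-scale phantom config used throughout the suite.
test_phantom_config <- function(seed = 1L, ...) {
  phantom_config(width_px = 256, height_px = 192, seed = seed, ...)
}

test_phantom <- function(seed = 1L, ...) {
  key <- paste0("ph_", seed, "_", paste(deparse(list(...)), collapse = ""))
  cached(key, generate_phantom(test_phantom_config(seed = seed, ...)))
}

# The canonical full-size phantom backing the packaged reference statistics.
canonical_phantom <- function() {
  cached("canonical", generate_phantom(phantom_config(seed = 20140723)))
}

# Per-class Dice between a predicted mask and ground truth.
dice_per_class <- function(mask, truth) {
  vapply(0:2, function(k) {
    denom <- sum(mask == k) + sum(truth == k)
    if (denom == 0) return(NA_real_)
    2 * sum(mask == k & truth == k) / denom
  }, 1)
}

# Match detections to ground-truth nuclei by nearest centroid.
match_nuclei <- function(detected, truth) {
  d2 <- outer(detected$centroid_row, truth$centroid_row, "-")^2 +
    outer(detected$centroid_col, truth$centroid_col, "-")^2
  nearest <- apply(d2, 1, which.min)
  list(
    nearest = nearest,
    dist = sqrt(d2[cbind(seq_len(nrow(detected)), nearest)]),
    true_class = truth$true_class[nearest]
  )
}
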