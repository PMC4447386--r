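# Shared fixtures and independent oracles, built in code.

# Independent per-pixel evaluation of the piecewise-linear warp. Scalar,
# branch-by-branch, no lookup table: the oracle the lut path is checked
# against.
oracle_warp <- function(image, orig_row, des_row) {
  m <- length(orig_row) - 2L
  L <- as.numeric(orig_row[2:(m + 1L)])
  Lp <- as.numeric(des_row[2:(m + 1L)])
  s <- (Lp[-1] - Lp[-m]) / (L[-1] - L[-m])
  f <- function(x) {
    if (x < L[1]) {
      xp <- Lp[1] - s[1] * (L[1] - x)
    } else if (x > L[m]) {
      xp <- Lp[m] + s[m - 1] * (x - L[m])
    } else {
      j <- min(max(which(L <= x)), m - 1L)
      xp <- Lp[j] + s[j] * (x - L[j])
    }
    floor(min(max(xp, 0), 255) + 0.5)
  }
  out <- vapply(as.numeric(image), f, numeric(1))
  matrix(as.integer(out), nrow(image), ncol(image))
}

# A random valid landmark-row pair: strictly increasing original integer
# landmarks, desired landmarks strictly increasing with gap >= 1.
random_row_pair <- function(m = 9L) {
  L <- sort(sample(5:250, m))
  while (any(diff(L) < 1)) L <- sort(sample(5:250, m))
  lo <- runif(1, 10, 80)
  hi <- runif(1, 180, 250)
  interior <- sort(runif(m - 2L, lo + 1, hi - 1))
  while (any(diff(c(lo, interior, hi)) < 1)) {
    interior <- sort(runif(m - 2L, lo + 1, hi - 1))
  }
  list(orig = c(0L, L, 255L), des = c(0, lo, interior, hi, 255))
}

random_image <- function(h = 32, w = 32) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# Histogram object from explicit per-gray-value counts (named by gray value).
hist_from_spec <- function(...) {
  spec <- c(...)
  counts <- integer(256)
  counts[as.integer(names(spec)) + 1L] <- spec
  img <- matrix(rep(0:255, counts), nrow = 1)
  compute_histogram(img)
}

# Small multi-modal test image: dark blob + mid blob on bright background.
blob_image <- function(h = 64, w = 64, bg = 230, dark = 80, mid = 170) {
  img <- matrix(bg, h, w)
  img[10:30, 10:30] <- dark
  img[40:55, 35:55] <- mid
  img
}
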