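# Landmark setup (Step 1): the dynamic range [L_1, L_m] of each histogram is
# found from the data, then the interior landmarks L_2..L_{m-1} are placed at
# equal steps of cumulative frequency so that together the row
# {L_0 = 0, L_1, ..., L_m, L_{m+1} = 255} delineates the histogram shape.

#' Detect the dynamic range of a histogram
#'
#' The lower bound `L1` is the darkest gray value where frequency appears
#' steadily: the smallest occupied `r` whose `k`-bin window carries at least
#' `k * eps` of the total mass. The windowed form tolerates the comb-like
#' histograms of contrast-stretched 8-bit images, where occupied bins
#' alternate with empty ones. The upper bound `Lm` is the bright-background
#' gray value: the mode of the top quartile of the histogram mass (the
#' brightest quarter of the pixels, which contains the background peak of a
#' slide-scanner micrograph wherever staining variation has shifted it)
#' when that peak carries at least `eps` mass, otherwise the brightest `r`
#' with `freq[r] >= eps`.
#'
#' @param hist A [compute_histogram()] result.
#' @param eps Frequency threshold, as a fraction of total mass. Default `1e-4`.
#' @param k Window length in bins for the steady-appearance rule. Default `3`.
#'
#' @return A list with elements `L1` and `Lm` (integer gray values,
#'   `L1 < Lm`).
#' @export
detect_dynamic_range <- function(hist, eps = 1e-4, k = 3L) {
  stopifnot(inherits(hist, "gray_histogram"))
  occupied <- which(hist$freq > 0)
  if (length(occupied) < 2L) {
    abort("Histogram is degenerate (fewer than two distinct gray values).",
          class = "histonorm_degenerate_histogram")
  }
  k <- as.integer(k)
  freq <- hist$freq
  # Windowed mass starting at each bin r (window truncated at 255).
  wsum <- vapply(seq_len(256L), function(a) {
    sum(freq[a:min(a + k - 1L, 256L)])
  }, numeric(1))
  cand <- which(freq > 0 & wsum >= k * eps)
  if (length(cand) == 0) cand <- occupied
  L1 <- cand[1] - 1L

  q75 <- which(hist$cumulative >= 0.75 - 1e-12)[1]
  top <- q75:256
  if (max(freq[top]) >= eps) {
    Lm <- top[which.max(freq[top])] - 1L
  } else {
    bright <- which(freq >= eps)
    if (length(bright) == 0) bright <- occupied
    Lm <- bright[length(bright)] - 1L
  }
  if (L1 >= Lm) {
    abort(sprintf("Dynamic-range detection failed: L1 = %d >= Lm = %d.",
                  L1, Lm),
          class = "histonorm_detection_failure")
  }
  list(L1 = as.integer(L1), Lm = as.integer(Lm))
}

#' Place interior landmarks by cumulative-frequency equipartition
#'
#' Divides \[`L1`, `Lm`\] into `m - 1` spans of equal cumulative mass:
#' interior landmark `j` (for `1 < j < m`) is the smallest gray value `r`
#' with `(T(r) - T(L1)) / (T(Lm) - T(L1)) >= (j - 1) / (m - 1)`. The
#' returned row is the full landmark vector `{0, L1, L2, ..., Lm, 255}`.
#'
#' @param hist A [compute_histogram()] result.
#' @param L1,Lm Dynamic-range bounds from [detect_dynamic_range()].
#' @param m Number of dynamic-range landmarks (>= 2). Default 9.
#'
#' @return Integer vector of length `m + 2`, non-decreasing.
#' @export
place_interior_landmarks <- function(hist, L1, Lm, m = 9L) {
  stopifnot(inherits(hist, "gray_histogram"))
  m <- as.integer(m)
  if (m < 2L) {
    abort("`m` must be at least 2.", class = "histonorm_parameter_error")
  }
  if (L1 >= Lm) {
    abort("`L1` must be below `Lm`.", class = "histonorm_parameter_error")
  }
  Tr <- hist$cumulative
  t0 <- Tr[L1 + 1L]
  t1 <- Tr[Lm + 1L]
  if (t1 <= t0) {
    abort("No cumulative mass between L1 and Lm.",
          class = "histonorm_detection_failure")
  }
  interior <- integer(0)
  if (m > 2L) {
    js <- 2:(m - 1L)
    targets <- (js - 1) / (m - 1)
    rel <- (Tr - t0) / (t1 - t0)
    interior <- vapply(targets, function(tg) {
      which(rel >= tg - 1e-12)[1] - 1L
    }, integer(1))
  }
  row <- c(0L, L1, interior, Lm, 255L)
  stopifnot(!is.unsorted(row))
  as.integer(row)
}

# Landmark rows for every image of a stack, via the thumbnail pathway the
# algorithm uses in Step 1. Degenerate images (constant, or failed range
# detection) get an NA row and are reported in `degenerate`.
stack_landmarks <- function(stack, m = 9L, thumbnail_factor = 8L,
                            eps = 1e-4, k = 3L) {
  N <- length(stack)
  rows <- matrix(NA_integer_, nrow = N, ncol = m + 2L)
  degenerate <- logical(N)
  for (i in seq_len(N)) {
    thumb <- make_thumbnail(stack$images[[i]], thumbnail_factor)
    h <- compute_histogram(thumb)
    res <- tryCatch({
      dr <- detect_dynamic_range(h, eps = eps, k = k)
      place_interior_landmarks(h, dr$L1, dr$Lm, m = m)
    }, histonorm_degenerate_histogram = function(e) NULL,
       histonorm_detection_failure = function(e) NULL)
    if (is.null(res)) degenerate[i] <- TRUE else rows[i, ] <- res
  }
  list(rows = rows, degenerate = degenerate)
}

landmark_colnames <- function(m) {
  c("L0", paste0("L", seq_len(m)), paste0("L", m + 1L))
}
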