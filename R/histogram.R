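#' Gray-value histogram of an image
#'
#' Computes the 256-bin frequency distribution \eqn{p_r(r)} of an 8-bit
#' image together with its cumulative form \eqn{T(r) = \sum_{x \le r} p_r(x)},
#' the discrete realization of the cumulative frequency integral. All
#' downstream landmark work consumes this object.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#'
#' @return An object of class `gray_histogram` with components `counts`
#'   (integer, length 256, bin `r` at position `r + 1`), `freq`
#'   (normalized, sums to 1) and `cumulative` (non-decreasing,
#'   `cumulative[256] == 1`).
#' @export
#'
#' @examples
#' h <- compute_histogram(matrix(c(0L, 0L, 255L, 255L), 2, 2))
#' h$cumulative[128]  # T(127) = 0.5
compute_histogram <- function(image) {
  check_image(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  n <- sum(counts)
  freq <- counts / n
  structure(
    list(counts = counts, freq = freq, cumulative = cumsum(freq)),
    class = "gray_histogram"
  )
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0) - 1L
  cat(sprintf("<gray_histogram> %d pixels, %d occupied bins in [%d, %d]\n",
              sum(x$counts), length(occ), min(occ), max(occ)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.gray_histogram <- function(x, ...) {
  tibble(gray = 0:255, count = x$counts, freq = x$freq,
         cumulative = x$cumulative)
}

# Histogram of already-tabulated counts (used for pushforward checks).
histogram_from_counts <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  n <- sum(counts)
  freq <- counts / n
  structure(list(counts = as.integer(counts), freq = freq,
                 cumulative = cumsum(freq)),
            class = "gray_histogram")
}
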