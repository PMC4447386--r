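#' Kullback-Leibler divergence between two gray-value distributions
#'
#' \eqn{KLD(P \| Q) = \sum_i P(i) \ln(P(i)/Q(i))}, with the convention
#' \eqn{0 \ln(0/q) = 0}. `P` is conventionally the original image's
#' histogram distribution and `Q` the processed one, so the statistic
#' measures how far processing has shifted the histogram. When some bin has
#' `P > 0` but `Q = 0` the raw divergence is infinite; in that case additive
#' smoothing `smooth_eps` is applied to every bin of both distributions
#' (then renormalized), keeping the statistic finite while leaving
#' conflict-free inputs untouched.
#'
#' @param p,q Numeric vectors of equal length, each summing to 1 within
#'   `1e-9` (e.g. the `freq` component of [compute_histogram()]).
#' @param smooth_eps Additive smoothing constant. Default `1e-8`.
#'
#' @return Non-negative scalar (natural-log units).
#' @export
#'
#' @examples
#' kld(c(0.5, 0.5), c(0.25, 0.75))  # 0.5*log(2) + 0.5*log(2/3)
kld <- function(p, q, smooth_eps = 1e-8) {
  if (length(p) != length(q)) {
    abort("`p` and `q` must have equal length.",
          class = "histonorm_parameter_error")
  }
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("`p` and `q` must each sum to 1.",
          class = "histonorm_normalization_error")
  }
  if (any(p > 0 & q == 0)) {
    p <- (p + smooth_eps) / (1 + length(p) * smooth_eps)
    q <- (q + smooth_eps) / (1 + length(q) * smooth_eps)
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Contrast per pixel
#'
#' The mean absolute gray-value difference between each pixel and its
#' neighbors in the 3x3 window: every pixel contributes the sum of
#' \eqn{|f(i,j) - f(m,n)|} over its existing 8-neighbors (border pixels use
#' truncated neighborhoods), and the grand total is divided by the pixel
#' count. A global contrast estimate: larger means stronger local contrast.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#'
#' @return Non-negative scalar.
#' @export
#'
#' @examples
#' cpp(matrix(c(0, 255), 1, 2))  # 255
cpp <- function(image) {
  check_image(image)
  d <- dim(image)
  nr <- d[1]; nc <- d[2]
  img <- matrix(as.numeric(image), nr, nc)
  total <- 0
  # Each unordered neighbor pair appears once per direction; summing the
  # four unique offsets twice counts both ordered contributions.
  if (nr > 1) total <- total + 2 * sum(abs(img[-1, , drop = FALSE] -
                                             img[-nr, , drop = FALSE]))
  if (nc > 1) total <- total + 2 * sum(abs(img[, -1, drop = FALSE] -
                                             img[, -nc, drop = FALSE]))
  if (nr > 1 && nc > 1) {
    total <- total + 2 * sum(abs(img[-1, -1] - img[-nr, -nc]))
    total <- total + 2 * sum(abs(img[-1, -nc] - img[-nr, -1]))
  }
  total / (nr * nc)
}

#' Stripe variance of a virtual reslice
#'
#' Brightness inconsistency between sections shows up as horizontal stripes
#' in an orthogonal reslice. This statistic is the variance, across the
#' section axis, of each section's mean intensity in the reslice; zero means
#' perfectly even brightness.
#'
#' @param reslice Matrix from [reslice_stack()] (rows = sections).
#'
#' @return Non-negative scalar.
#' @export
stripe_variance <- function(reslice) {
  if (!is.matrix(reslice) || nrow(reslice) < 2) {
    abort("`reslice` must be a matrix with at least two section rows.",
          class = "histonorm_parameter_error")
  }
  means <- rowMeans(reslice)
  stats::var(means) * (length(means) - 1) / length(means)
}

#' Per-image and block-averaged evaluation report
#'
#' For each section, the Kullback-Leibler divergence between the original
#' and processed histograms and the contrast per pixel of both images;
#' block means over consecutive index blocks summarize the stack the way
#' long serial-section studies tabulate them.
#'
#' @param original,processed [image_stack()]s of equal length.
#' @param block_size Number of sections per averaging block. Default 100.
#' @param smooth_eps Passed to [kld()].
#'
#' @return A list of two tibbles: `per_image` (columns `image`, `kld`,
#'   `cpp_before`, `cpp_after`) and `blocks` (columns `block`, `from`,
#'   `to`, `mean_kld`, `mean_cpp_before`, `mean_cpp_after`).
#' @export
metric_report <- function(original, processed, block_size = 100L,
                          smooth_eps = 1e-8) {
  stopifnot(inherits(original, "image_stack"),
            inherits(processed, "image_stack"))
  N <- length(original)
  if (length(processed) != N) {
    abort("Stacks differ in length.", class = "histonorm_parameter_error")
  }
  vals <- vapply(seq_len(N), function(i) {
    p <- compute_histogram(original$images[[i]])$freq
    q <- compute_histogram(processed$images[[i]])$freq
    c(kld(p, q, smooth_eps = smooth_eps),
      cpp(original$images[[i]]),
      cpp(processed$images[[i]]))
  }, numeric(3))
  per_image <- tibble(image = seq_len(N), kld = vals[1, ],
                      cpp_before = vals[2, ], cpp_after = vals[3, ])
  blk <- ceiling(seq_len(N) / block_size)
  blocks <- tibble(
    block = sort(unique(blk)),
    from = vapply(sort(unique(blk)), function(b) min(which(blk == b)), 1L),
    to = vapply(sort(unique(blk)), function(b) max(which(blk == b)), 1L),
    mean_kld = as.vector(tapply(per_image$kld, blk, mean)),
    mean_cpp_before = as.vector(tapply(per_image$cpp_before, blk, mean)),
    mean_cpp_after = as.vector(tapply(per_image$cpp_after, blk, mean))
  )
  list(per_image = per_image, blocks = blocks)
}
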