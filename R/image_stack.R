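#' Construct an image stack
#'
#' An `image_stack` is the ordered container for a series of same-size
#' single-channel 8-bit section images \eqn{I_1, \dots, I_N}. Each image is an
#' integer matrix with values in \[0, 255\]; `index` carries the 1-based
#' section numbers. RGB sections may keep their original color planes
#' alongside the intensity plane so that processed output can be recolored.
#'
#' @param images List of numeric matrices, all of identical dimensions, with
#'   values in \[0, 255\].
#' @param index Integer vector of section numbers, same length as `images`.
#'   Defaults to `seq_along(images)`.
#' @param color Optional list (same length) of `H x W x 3` arrays with values
#'   in \[0, 255\], or `NULL` entries for grayscale sections.
#'
#' @return An object of class `image_stack`.
#' @export
#'
#' @examples
#' imgs <- lapply(1:3, function(i) matrix(10L * i, 4, 4))
#' stk <- image_stack(imgs)
#' stk
image_stack <- function(images, index = seq_along(images), color = NULL) {
  if (!is.list(images) || length(images) == 0) {
    abort("`images` must be a non-empty list of matrices.",
          class = "histonorm_empty_input")
  }
  dims <- vapply(images, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf("Image %d has dimensions %dx%d; expected %dx%d.",
                  bad, dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]),
          class = "histonorm_dim_mismatch")
  }
  images <- lapply(images, function(im) as_gray8(check_image(im)))
  if (length(index) != length(images)) {
    abort("`index` must match the number of images.",
          class = "histonorm_parameter_error")
  }
  if (!is.null(color) && length(color) != length(images)) {
    abort("`color` must match the number of images.",
          class = "histonorm_parameter_error")
  }
  ord <- order(index)
  structure(
    list(
      images = images[ord],
      index = as.integer(index)[ord],
      color = if (!is.null(color)) color[ord]
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<image_stack> %d sections, %d x %d, 8-bit%s\n",
              length(x$images), d[1], d[2],
              if (!is.null(x$color)) ", with color planes" else ""))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$images)

stack_dim <- function(stack) dim(stack$images[[1]])

#' Block-subsample an image to a thumbnail
#'
#' Histograms for landmark detection are computed on thumbnails for speed.
#' Block subsampling (every `factor`-th pixel) is used rather than
#' interpolation so the thumbnail histogram is an unbiased subsample of the
#' full-resolution histogram.
#'
#' @param image Numeric matrix (8-bit gray values).
#' @param factor Positive integer subsampling factor; `1` is the identity.
#'
#' @return A `ceiling(H/factor) x ceiling(W/factor)` integer matrix.
#' @export
#'
#' @examples
#' make_thumbnail(matrix(0:15, 4, 4), 2)
make_thumbnail <- function(image, factor = 8L) {
  check_image(image)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != as.integer(factor)) {
    abort("`factor` must be a positive integer.",
          class = "histonorm_parameter_error")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(as_gray8(image))
  d <- dim(image)
  as_gray8(image[seq(1L, d[1], by = factor), seq(1L, d[2], by = factor),
                 drop = FALSE])
}

#' Extract a virtual section orthogonal to the stack
#'
#' Reslicing reveals inter-section brightness inconsistency as horizontal
#' stripes: the `xz` plane takes row `position` from every section and stacks
#' them over the section index (an `N x W` image); `yz` does the same with
#' column `position` (`N x H`).
#'
#' @param stack An [image_stack()].
#' @param plane `"xz"` or `"yz"`.
#' @param position Row (for `xz`) or column (for `yz`) index.
#'
#' @return An integer matrix with one row per section.
#' @export
reslice_stack <- function(stack, plane = c("xz", "yz"), position) {
  stopifnot(inherits(stack, "image_stack"))
  plane <- match.arg(plane)
  d <- stack_dim(stack)
  bound <- if (plane == "xz") d[1] else d[2]
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > bound) {
    abort(sprintf("`position` must be in [1, %d] for plane %s.", bound, plane),
          class = "histonorm_index_error")
  }
  position <- as.integer(position)
  rows <- if (plane == "xz") {
    lapply(stack$images, function(im) im[position, ])
  } else {
    lapply(stack$images, function(im) im[, position])
  }
  as_gray8(do.call(rbind, rows))
}
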