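#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero. base::round() rounds half to even, which would
# make lut values depend on parity; half-up keeps the warp reproducible
# across platforms and matches the fixed-point contract lut(L_j) = round(L'_j).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

clamp <- function(x, lo = 0, hi = 255) {
  pmin(pmax(x, lo), hi)
}

# Validate a single-channel 8-bit image matrix.
check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg), class = "histonorm_type_error")
  }
  if (length(image) == 0) {
    abort(sprintf("`%s` is empty.", arg), class = "histonorm_empty_input")
  }
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 255) {
    abort(sprintf("`%s` has values outside [0, 255].", arg),
          class = "histonorm_range_error")
  }
  invisible(image)
}

# Coerce an image matrix to integer storage (values already 0..255).
as_gray8 <- function(image) {
  storage.mode(image) <- "integer"
  image
}
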