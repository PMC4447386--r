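# Gray-value transformation (Step 2): a piecewise-linear warp carries each
# original span [L_j, L_{j+1}] onto the desired span [L'_j, L'_{j+1}] with
# scale factor s_j = (L'_{j+1} - L'_j) / (L_{j+1} - L_j). Outside the
# dynamic range the nearest interior scale factor is reused (s_1 below L_1,
# s_{m-1} above L_m) so dark and highlight detail is not crushed; results
# are clipped to [0, 255].

#' Build the piecewise-linear gray-value transform for one image
#'
#' For `x` in span `[L_j, L_{j+1}]` (dynamic-range ordinates `j = 1..m-1`):
#' `x' = L'_j + s_j * (x - L_j)`. Below `L_1`: `x' = L'_1 - s_1 * (L_1 - x)`;
#' above `L_m`: `x' = L'_m + s_{m-1} * (x - L_m)` — the only anchoring
#' consistent with continuity at the range ends. Results are clamped to
#' \[0, 255\] and rounded half-up into a 256-entry lookup table.
#'
#' @param original_row Length `m + 2` landmark row `{0, L_1, ..., L_m, 255}`;
#'   interior dynamic spans must have positive width.
#' @param desired_row Length `m + 2` desired row (numeric).
#'
#' @return An object of class `transform_map` with `lut` (integer, length
#'   256, `lut[x + 1]` maps gray value `x`) and `segments` (tibble of span
#'   endpoints and scale factors).
#' @export
#'
#' @examples
#' map <- build_transform(c(0, 100, 150, 255), c(0, 64, 228, 255))
#' map$lut[125 + 1]  # 146
build_transform <- function(original_row, desired_row) {
  m <- length(original_row) - 2L
  if (length(desired_row) != m + 2L) {
    abort("Landmark rows differ in length.",
          class = "histonorm_parameter_error")
  }
  L <- as.numeric(original_row[2:(m + 1L)])   # L_1..L_m
  Lp <- as.numeric(desired_row[2:(m + 1L)])   # L'_1..L'_m
  dw <- diff(L)
  if (any(dw <= 0)) {
    j <- which(dw <= 0)[1]
    abort(sprintf("Zero-width dynamic span between L_%d and L_%d.", j, j + 1L),
          class = "histonorm_degenerate_span")
  }
  s <- diff(Lp) / dw                          # s_1..s_{m-1}
  x <- 0:255
  xp <- numeric(256L)
  below <- x < L[1]
  above <- x > L[m]
  xp[below] <- Lp[1] - s[1] * (L[1] - x[below])
  xp[above] <- Lp[m] + s[m - 1] * (x[above] - L[m])
  inside <- !below & !above
  j <- findInterval(x[inside], L, rightmost.closed = TRUE)
  j <- pmin(j, m - 1L)
  xp[inside] <- Lp[j] + s[j] * (x[inside] - L[j])
  lut <- as.integer(round_half_up(clamp(xp)))
  structure(
    list(
      lut = lut,
      segments = tibble(
        j = seq_len(m - 1L),
        src_lo = L[-m], src_hi = L[-1],
        dst_lo = Lp[-m], dst_hi = Lp[-1],
        scale = s
      )
    ),
    class = "transform_map"
  )
}

#' @export
print.transform_map <- function(x, ...) {
  cat(sprintf("<transform_map> %d segments, lut range [%d, %d]\n",
              nrow(x$segments), min(x$lut), max(x$lut)))
  invisible(x)
}

#' Apply a gray-value transform to an image
#'
#' Pure lookup: `output[p] = lut[input[p]]`, so the output histogram is the
#' pushforward of the input histogram through the lut.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param map A [build_transform()] result.
#'
#' @return Integer matrix of the same dimensions.
#' @export
apply_transform <- function(image, map) {
  check_image(image)
  stopifnot(inherits(map, "transform_map"))
  out <- map$lut[as.integer(image) + 1L]
  dim(out) <- dim(image)
  as_gray8(out)
}

# Recolor an RGB plane after warping the intensity plane: each channel is
# scaled by the per-pixel ratio x'/x (pixels with x = 0 go to 0), clipped.
recolor_rgb <- function(color, gray_before, gray_after) {
  ratio <- ifelse(gray_before > 0, gray_after / gray_before, 0)
  out <- color
  for (ch in 1:3) out[, , ch] <- clamp(round_half_up(color[, , ch] * ratio))
  out
}
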