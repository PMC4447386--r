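# Comparison baselines: classic (global) histogram equalization, applied to
# each image independently, and exact equalization (classical histogram
# specification to one reference image of the stack).

#' Classic global histogram equalization
#'
#' `lut(r) = round(255 * T(r))` with `T` the image's own cumulative
#' histogram, applied per image. Deliberately includes the background, so
#' large background mass over-stretches the tissue band — the known
#' weakness of equalizing micrographs.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#'
#' @return A list: `image` (equalized integer matrix) and `map`
#'   (the [build_transform()]-style `transform_map` holding the lut).
#' @export
classic_equalization <- function(image) {
  h <- compute_histogram(image)
  lut <- as.integer(round_half_up(255 * h$cumulative))
  map <- structure(list(lut = lut, segments = tibble()),
                   class = "transform_map")
  list(image = apply_transform(image, map), map = map)
}

#' Histogram specification to a reference image
#'
#' Classical exact equalization for a stack: a reference section is chosen
#' (by default the middle one) and every other image's cumulative histogram
#' `T_i` is matched to the reference's via
#' `lut(r) = min{ s : T_ref(s) >= T_i(r) }`. The reference image passes
#' through unchanged.
#'
#' @param stack An [image_stack()].
#' @param reference_index Section position to use as reference; default the
#'   middle of the stack.
#'
#' @return A list: `stack` (processed [image_stack()]), `maps` (per-image
#'   `transform_map`), `reference_index`.
#' @export
exact_equalization <- function(stack, reference_index = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  N <- length(stack)
  reference_index <- reference_index %||% ((N + 1L) %/% 2L)
  if (reference_index < 1 || reference_index > N) {
    abort(sprintf("`reference_index` must be in [1, %d].", N),
          class = "histonorm_parameter_error")
  }
  T_ref <- compute_histogram(stack$images[[reference_index]])$cumulative
  maps <- vector("list", N)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    if (i == reference_index) {
      lut <- 0:255
    } else {
      T_i <- compute_histogram(stack$images[[i]])$cumulative
      # min s with T_ref(s) >= T_i(r); tolerance guards exact ties.
      lut <- vapply(T_i, function(t) {
        which(T_ref >= t - 1e-12)[1] - 1L
      }, integer(1))
    }
    maps[[i]] <- structure(list(lut = as.integer(lut), segments = tibble()),
                           class = "transform_map")
    out[[i]] <- apply_transform(stack$images[[i]], maps[[i]])
  }
  list(stack = image_stack(out, index = stack$index),
       maps = maps, reference_index = reference_index)
}

#' Enhance a stack by a chosen method
#'
#' One switch over the three methods so they can be compared side by side
#' with identical plumbing.
#'
#' @param stack An [image_stack()].
#' @param method `"shfa"`, `"classic"` or `"exact"`.
#' @param config An [shfa_config()] (used by `"shfa"`).
#' @param reference_index Reference section for `"exact"`.
#'
#' @return A list with at least `stack` (processed) and `maps`; for
#'   `"shfa"` the full `shfa_fit` is returned.
#' @export
enhance_stack <- function(stack, method = c("shfa", "classic", "exact"),
                          config = shfa_config(), reference_index = NULL) {
  method <- match.arg(method)
  switch(method,
    shfa = run_shfa(stack, config),
    classic = {
      res <- lapply(stack$images, classic_equalization)
      list(stack = image_stack(lapply(res, `[[`, "image"),
                               index = stack$index),
           maps = lapply(res, `[[`, "map"))
    },
    exact = exact_equalization(stack, reference_index)
  )
}
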