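#' Configuration for the sequential histogram fitting pipeline
#'
#' Defaults follow the reference configuration for toluidine-blue kidney
#' stacks: nine dynamic-range landmarks, cubic trajectory fits, desired
#' dynamic-range anchors at gray values 64 and 228, and histogram work on
#' factor-8 thumbnails.
#'
#' @param m Number of dynamic-range landmarks (>= 2).
#' @param degree Trajectory polynomial degree, 3 or 4.
#' @param anchors Desired gray values of the first and last dynamic-range
#'   landmarks, `c(low, high)`.
#' @param thumbnail_factor Block-subsampling factor for histogram
#'   computation; transforms are always applied at full resolution.
#' @param eps,k Dynamic-range detection thresholds, see
#'   [detect_dynamic_range()].
#'
#' @return A list of class `shfa_config`.
#' @export
shfa_config <- function(m = 9L, degree = 3L, anchors = c(64, 228),
                        thumbnail_factor = 8L, eps = 1e-4, k = 3L) {
  cfg <- list(m = as.integer(m), degree = as.integer(degree),
              anchors = as.numeric(anchors),
              thumbnail_factor = as.integer(thumbnail_factor),
              eps = eps, k = as.integer(k))
  class(cfg) <- "shfa_config"
  cfg
}

# Collapse duplicated source landmarks (possible when interior placement
# lands several quantiles on one gray value) so the warp stays well-defined.
dedupe_rows <- function(orig, des) {
  m <- length(orig) - 2L
  L <- orig[2:(m + 1L)]
  keep <- !duplicated(L)
  list(orig = c(orig[1], L[keep], orig[m + 2L]),
       des = c(des[1], des[2:(m + 1L)][keep], des[m + 2L]))
}

#' Run sequential histogram fitting on an image stack
#'
#' The full pipeline: per-image thumbnail histograms; dynamic-range
#' detection and cumulative-frequency landmark placement; polynomial
#' smoothing of each landmark trajectory across the stack; desired rows
#' anchored to the configured gray-value band; and a per-image
#' piecewise-linear warp applied at full resolution. Degenerate images
#' (constant, or with an undetectable dynamic range) are excluded from the
#' trajectory fits and warped against a fallback row spanning \[0, 255\];
#' a warning reports them.
#'
#' @param stack An [image_stack()].
#' @param config An [shfa_config()].
#'
#' @return An object of class `shfa_fit` with components `stack` (the
#'   processed [image_stack()]), `landmarks` (list of `original` and
#'   `desired` matrices), `curves`, `maps` (per-image `transform_map`),
#'   `degenerate` (logical) and `config`. Inspect with [tidy()],
#'   [glance()] or [ggplot2::autoplot()].
#' @export
run_shfa <- function(stack, config = shfa_config()) {
  stopifnot(inherits(stack, "image_stack"))
  N <- length(stack)
  if (N <= config$degree) {
    abort(sprintf("%d images cannot support a degree-%d trajectory fit.",
                  N, config$degree),
          class = "histonorm_insufficient_data")
  }
  lmk <- stack_landmarks(stack, m = config$m,
                        thumbnail_factor = config$thumbnail_factor,
                        eps = config$eps, k = config$k)
  if (any(lmk$degenerate)) {
    warn(sprintf("%d degenerate image(s) excluded from trajectory fitting: %s",
                 sum(lmk$degenerate),
                 paste(which(lmk$degenerate), collapse = ", ")))
  }
  curves <- withCallingHandlers(
    fit_landmark_curves(lmk$rows, degree = config$degree),
    histonorm_insufficient_data = function(e) {
      abort(sprintf("Trajectory fitting failed: %s", conditionMessage(e)),
            class = "histonorm_insufficient_data")
    })
  desired <- desired_landmarks(curves, N, anchors = config$anchors)
  fallback <- c(0L, round_half_up(seq(0, 255, length.out = config$m)), 255L)
  maps <- vector("list", N)
  out <- vector("list", N)
  color_out <- if (!is.null(stack$color)) vector("list", N)
  for (i in seq_len(N)) {
    orig_row <- if (lmk$degenerate[i]) fallback else lmk$rows[i, ]
    rows <- dedupe_rows(orig_row, desired[i, ])
    maps[[i]] <- build_transform(rows$orig, rows$des)
    out[[i]] <- apply_transform(stack$images[[i]], maps[[i]])
    if (!is.null(stack$color) && !is.null(stack$color[[i]])) {
      color_out[[i]] <- recolor_rgb(stack$color[[i]], stack$images[[i]],
                                    out[[i]])
    }
  }
  orig_mat <- lmk$rows
  colnames(orig_mat) <- landmark_colnames(config$m)
  structure(
    list(
      stack = image_stack(out, index = stack$index, color = color_out),
      landmarks = list(original = orig_mat, desired = desired),
      curves = curves,
      maps = maps,
      degenerate = lmk$degenerate,
      config = config
    ),
    class = "shfa_fit"
  )
}

#' @export
print.shfa_fit <- function(x, ...) {
  cat(sprintf(
    "<shfa_fit> %d sections, m = %d landmarks, degree-%d trajectories, anchors [%g, %g]\n",
    length(x$stack), x$config$m, x$config$degree,
    x$config$anchors[1], x$config$anchors[2]))
  if (any(x$degenerate)) {
    cat(sprintf("  %d degenerate section(s) warped via fallback row\n",
                sum(x$degenerate)))
  }
  invisible(x)
}

#' Tidy the landmark matrices of a fitted pipeline
#'
#' @param x An `shfa_fit`.
#' @param ... Unused.
#'
#' @return A tibble with one row per image and landmark ordinate: columns
#'   `image`, `ordinate` (0..m+1), `original` and `desired` gray values.
#' @exportS3Method generics::tidy
#' @export
tidy.shfa_fit <- function(x, ...) {
  m <- x$config$m
  N <- nrow(x$landmarks$original)
  tibble(
    image = rep(seq_len(N), times = m + 2L),
    ordinate = rep(0:(m + 1L), each = N),
    original = as.vector(x$landmarks$original),
    desired = as.vector(x$landmarks$desired)
  )
}

#' One-row summary of a fitted pipeline
#'
#' @param x An `shfa_fit`.
#' @param ... Unused.
#'
#' @return A tibble with the stack size, landmark count, degree, anchors and
#'   number of degenerate sections.
#' @exportS3Method generics::glance
#' @export
glance.shfa_fit <- function(x, ...) {
  tibble(
    n_images = length(x$stack),
    m = x$config$m,
    degree = x$config$degree,
    anchor_low = x$config$anchors[1],
    anchor_high = x$config$anchors[2],
    n_degenerate = sum(x$degenerate)
  )
}

#' Plot landmark trajectories before and after fitting
#'
#' Solid lines: detected landmark gray values per section. Dashed lines:
#' the desired (fitted, anchored) trajectories the warp targets.
#'
#' @param object An `shfa_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.shfa_fit <- function(object, ...) {
  d <- tidy.shfa_fit(object)
  d <- d[d$ordinate >= 1 & d$ordinate <= object$config$m, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$image,
                                  group = factor(.data$ordinate))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$original), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$desired), linetype = "dashed",
                       colour = "firebrick") +
    ggplot2::labs(x = "section index", y = "landmark gray value",
                  title = "Landmark trajectories (solid: detected, dashed: desired)") +
    ggplot2::ylim(0, 255) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
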