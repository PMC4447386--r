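# Trajectory smoothing (Step 1, continued): the gray values of landmark
# ordinate j across the stack, {L_1j, ..., L_Nj}, are fitted by a low-order
# polynomial in the section index. Because consecutive sections are microns
# apart, true landmark trajectories drift smoothly; the irregular
# staining-driven excursions are what the fit removes.

#' Fit polynomial landmark trajectories across the stack
#'
#' For each dynamic-range ordinate `j = 1..m`, fits a least-squares
#' polynomial of the given degree to the points `(i, L_ij)` over all images
#' with valid landmark rows. Cubic or quartic degrees balance speed and
#' accuracy for serial biological sections.
#'
#' @param landmarks `N x (m + 2)` matrix of landmark rows (columns
#'   `L0..L_{m+1}`), as produced by the landmark pipeline; rows with `NA`
#'   (degenerate images) are ignored.
#' @param degree Polynomial degree, 3 or 4.
#'
#' @return A list of `m` objects of class `landmark_curve`, each with
#'   `ordinate`, `coefficients` (intercept first) and `degree`.
#' @export
fit_landmark_curves <- function(landmarks, degree = 3L) {
  landmarks <- as.matrix(landmarks)
  degree <- as.integer(degree)
  if (!degree %in% c(3L, 4L)) {
    abort("`degree` must be 3 or 4.", class = "histonorm_parameter_error")
  }
  m <- ncol(landmarks) - 2L
  ok <- stats::complete.cases(landmarks)
  n_ok <- sum(ok)
  if (n_ok <= degree) {
    abort(sprintf(
      "Only %d usable images for a degree-%d fit; need more images or a lower degree.",
      n_ok, degree), class = "histonorm_insufficient_data")
  }
  i_ok <- which(ok)
  lapply(seq_len(m), function(j) {
    y <- landmarks[ok, j + 1L]
    fit <- stats::lm(y ~ stats::poly(i_ok, degree, raw = TRUE))
    structure(
      list(ordinate = j,
           coefficients = unname(stats::coef(fit)),
           degree = degree),
      class = "landmark_curve"
    )
  })
}

#' Evaluate a fitted landmark trajectory
#'
#' @param object A `landmark_curve`.
#' @param i Image indices at which to evaluate.
#' @param ... Unused.
#'
#' @return Fitted gray values, clamped to \[0, 255\].
#' @export
predict.landmark_curve <- function(object, i, ...) {
  co <- object$coefficients
  x <- outer(i, 0:object$degree, `^`)
  clamp(drop(x %*% co))
}

#' @export
print.landmark_curve <- function(x, ...) {
  cat(sprintf("<landmark_curve> ordinate %d, degree %d: %s\n",
              x$ordinate, x$degree,
              paste(signif(x$coefficients, 4), collapse = " ")))
  invisible(x)
}

#' Compute desired landmark rows from fitted trajectories
#'
#' The desired dynamic range is anchored at constant endpoints: `L'_i1 =
#' anchors[1]` and `L'_im = anchors[2]` for every image (defaults 64 and
#' 228), so the whole processed stack spans one designated gray-value band.
#' Interior ordinates take their fitted values `C_j(i)`, affinely remapped
#' from the fitted span `[C_1(i), C_m(i)]` onto the anchor span, then
#' repaired to be strictly increasing with a minimum gap of one gray level
#' (independent per-ordinate fits can cross). `L'_i0 = 0` and
#' `L'_i,m+1 = 255` close the row.
#'
#' @param curves List of `landmark_curve` objects from
#'   [fit_landmark_curves()].
#' @param N Number of images.
#' @param anchors Length-2 numeric, `0 <= anchors[1] < anchors[2] <= 255`.
#'
#' @return `N x (m + 2)` numeric matrix of desired landmark rows.
#' @export
desired_landmarks <- function(curves, N, anchors = c(64, 228)) {
  m <- length(curves)
  if (length(anchors) != 2L || anchors[1] >= anchors[2] ||
      anchors[1] < 0 || anchors[2] > 255) {
    abort("`anchors` must satisfy 0 <= low < high <= 255.",
          class = "histonorm_parameter_error")
  }
  lo <- anchors[1]; hi <- anchors[2]
  if (hi - lo < m - 1) {
    abort("Anchor span narrower than the number of landmarks.",
          class = "histonorm_parameter_error")
  }
  idx <- seq_len(N)
  fitted <- vapply(curves, function(cv) predict(cv, idx), numeric(N))
  fitted <- matrix(fitted, nrow = N)  # N x m
  out <- matrix(NA_real_, nrow = N, ncol = m + 2L)
  out[, 1] <- 0
  out[, m + 2L] <- 255
  for (i in idx) {
    f <- fitted[i, ]
    span <- f[m] - f[1]
    v <- numeric(m)
    v[1] <- lo
    v[m] <- hi
    if (m > 2) {
      v[2:(m - 1)] <- if (span > 0) {
        lo + (f[2:(m - 1)] - f[1]) / span * (hi - lo)
      } else {
        # Collapsed fitted span: fall back to even spacing.
        lo + (1:(m - 2)) / (m - 1) * (hi - lo)
      }
      # Monotonicity repair: forward sweep with unit gap, then backward
      # sweep from the fixed upper anchor.
      for (j in 2:(m - 1)) v[j] <- max(v[j], v[j - 1] + 1)
      for (j in (m - 1):2) v[j] <- min(v[j], v[j + 1] - 1)
    }
    out[i, 2:(m + 1L)] <- v
  }
  # Landmarks are gray values: round half-up. Unit gaps survive rounding
  # exactly, so rows stay strictly increasing over the dynamic range.
  out[, 2:(m + 1L)] <- round_half_up(out[, 2:(m + 1L)])
  colnames(out) <- landmark_colnames(m)
  out
}
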