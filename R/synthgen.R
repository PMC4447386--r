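# Synthetic serial-section stacks with known ground truth. The clean stack
# emulates resin-section micrographs: elliptical "tubule" profiles (dark
# tissue and mid-bright lumen components) over a bright background, with
# structure sizes drifting smoothly across sections as they would through a
# sectioned volume. The corruption emulates staining/illumination variation:
# an i.i.d. per-image affine intensity change (gain about mid-gray plus an
# offset), which degrades histograms without touching spatial structure.

#' Configuration for the synthetic stack generator
#'
#' @param n_sections Stack length `N` (>= 8). Default 120.
#' @param height,width Image size in pixels. Default 128 x 128.
#' @param n_tissue,n_lumen Number of dark tissue and mid-bright lumen
#'   ellipses. Defaults 12 and 4.
#' @param background Background gray value. Default 230.
#' @param tissue_range,lumen_range Gray-value ranges the per-structure
#'   values are drawn from. Defaults `c(65, 110)` and `c(165, 195)`.
#' @param radius_range Base ellipse semi-axis range in pixels. Default
#'   `c(6, 14)`.
#' @param drift Polynomial coefficients (intercept first, in `t = i/N`) of
#'   the structure-scale drift; structure radii at section `i` are the base
#'   radii times this polynomial, so component mixture weights drift
#'   smoothly. Default `c(0.8, 0.4, -0.3)`.
#' @param gain_range Uniform range of the per-image contrast gain `g_i`;
#'   must lie within \[0.3, 1.2\]. Default `c(0.5, 1.0)`.
#' @param offset_range Uniform range of the per-image brightness offset
#'   `b_i`; must lie within \[-60, 60\]. Default `c(-40, 10)`.
#' @param noise_sd Gaussian pixel-noise standard deviation added to the
#'   clean images. Default 3.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sections = 120L, height = 128L, width = 128L,
                         n_tissue = 12L, n_lumen = 4L, background = 230,
                         tissue_range = c(65, 110),
                         lumen_range = c(165, 195),
                         radius_range = c(6, 14),
                         drift = c(0.8, 0.4, -0.3),
                         gain_range = c(0.5, 1.0),
                         offset_range = c(-40, 10),
                         noise_sd = 3, seed = 1L) {
  if (n_sections < 8) {
    abort("`n_sections` must be at least 8.",
          class = "histonorm_parameter_error")
  }
  if (gain_range[1] > gain_range[2] || gain_range[1] < 0.3 ||
      gain_range[2] > 1.2) {
    abort("`gain_range` must be an increasing range within [0.3, 1.2].",
          class = "histonorm_parameter_error")
  }
  if (offset_range[1] > offset_range[2] || any(abs(offset_range) > 60)) {
    abort("`offset_range` must be an increasing range within [-60, 60].",
          class = "histonorm_parameter_error")
  }
  structure(
    list(n_sections = as.integer(n_sections), height = as.integer(height),
         width = as.integer(width), n_tissue = as.integer(n_tissue),
         n_lumen = as.integer(n_lumen), background = background,
         tissue_range = tissue_range, lumen_range = lumen_range,
         radius_range = radius_range, drift = drift,
         gain_range = gain_range, offset_range = offset_range,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

apply_corruption <- function(image, gain, offset) {
  as_gray8(clamp(round_half_up(gain * (image - 128) + 128 + offset)))
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Returns a clean stack (smooth structural drift only), a corrupted stack
#' (per-image affine brightness/contrast degradation of the clean one:
#' `clamp(g_i * (clean - 128) + 128 + b_i)`), the per-image truth `(g_i,
#' b_i)`, and the clean stack's landmark trajectories computed with the
#' landmark pipeline at full resolution.
#'
#' @param config A [synth_config()].
#' @param m Number of dynamic-range landmarks for the truth trajectories.
#'
#' @return A list with `clean`, `corrupted` ([image_stack()]s), `truth`
#'   (tibble: `image`, `gain`, `offset`) and `trajectories`
#'   (`N x (m + 2)` matrix).
#' @export
#'
#' @examples
#' s <- generate_stack(synth_config(n_sections = 10, height = 48, width = 48))
#' s$truth
generate_stack <- function(config = synth_config(), m = 9L) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  N <- config$n_sections
  H <- config$height; W <- config$width
  K <- config$n_tissue + config$n_lumen
  # Fixed structure geometry; values per structure; lumen drawn first so
  # tissue overwrites on overlap (nuclei inside tubule profiles).
  cx <- stats::runif(K, 0.1 * W, 0.9 * W)
  cy <- stats::runif(K, 0.1 * H, 0.9 * H)
  rx <- stats::runif(K, config$radius_range[1], config$radius_range[2])
  ry <- stats::runif(K, config$radius_range[1], config$radius_range[2])
  vals <- c(stats::runif(config$n_lumen, config$lumen_range[1],
                         config$lumen_range[2]),
            stats::runif(config$n_tissue, config$tissue_range[1],
                         config$tissue_range[2]))
  gains <- stats::runif(N, config$gain_range[1], config$gain_range[2])
  offsets <- stats::runif(N, config$offset_range[1], config$offset_range[2])

  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  tt <- seq_len(N) / N
  scale_t <- drop(outer(tt, seq_along(config$drift) - 1, `^`) %*% config$drift)

  clean <- vector("list", N)
  corrupted <- vector("list", N)
  for (i in seq_len(N)) {
    img <- matrix(config$background, H, W)
    sc <- max(scale_t[i], 0.05)
    for (kk in seq_len(K)) {
      mask <- ((X - cx[kk]) / (rx[kk] * sc))^2 +
        ((Y - cy[kk]) / (ry[kk] * sc))^2 <= 1
      img[mask] <- vals[kk]
    }
    if (config$noise_sd > 0) {
      img <- img + stats::rnorm(H * W, 0, config$noise_sd)
    }
    clean[[i]] <- as_gray8(clamp(round_half_up(img)))
    corrupted[[i]] <- apply_corruption(clean[[i]], gains[i], offsets[i])
  }
  clean_stack <- image_stack(clean)
  corrupted_stack <- image_stack(corrupted)
  traj <- stack_landmarks(clean_stack, m = m, thumbnail_factor = 1L)$rows
  colnames(traj) <- landmark_colnames(m)
  list(
    clean = clean_stack,
    corrupted = corrupted_stack,
    truth = tibble(image = seq_len(N), gain = gains, offset = offsets),
    trajectories = traj
  )
}
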