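# All file-format handling lives here: PNG and TIFF, one file per section or
# one multi-page TIFF. Pixel data are 8-bit; 16-bit inputs are rejected.

# ITU-R BT.601 luma, rounded to 8-bit.
rgb_to_luma <- function(arr) {
  as_gray8(round_half_up(0.299 * arr[, , 1] + 0.587 * arr[, , 2] +
                           0.114 * arr[, , 3]))
}

# Last integer token in a filename decides section order.
section_number <- function(paths) {
  base <- basename(paths)
  m <- regmatches(base, gregexpr("[0-9]+", base))
  num <- vapply(m, function(tok) {
    if (length(tok) == 0) NA_real_ else as.numeric(tok[length(tok)])
  }, numeric(1))
  if (anyNA(num)) {
    abort(sprintf("No numeric section token in filename(s): %s",
                  paste(base[is.na(num)], collapse = ", ")),
          class = "histonorm_parameter_error")
  }
  if (anyDuplicated(num)) {
    dup <- num[duplicated(num)][1]
    abort(sprintf("Duplicate section number %s among input files.",
                  format(dup)), class = "histonorm_parameter_error")
  }
  num
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (max(img) > 255) {
      abort(sprintf("%s is not an 8-bit image (max sample %d).",
                    basename(path), max(img)),
            class = "histonorm_bitdepth_error")
    }
  } else if (ext == "png") {
    info <- attr(png::readPNG(path, info = TRUE), "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      abort(sprintf("%s is not an 8-bit image (bit depth %d).",
                    basename(path), info$bit.depth),
            class = "histonorm_bitdepth_error")
    }
    img <- round_half_up(png::readPNG(path) * 255)
  } else {
    abort(sprintf("Unsupported image format: %s", basename(path)),
          class = "histonorm_parameter_error")
  }
  img
}

split_planes <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      arr <- img[, , 1:3, drop = FALSE]
      list(gray = rgb_to_luma(arr), color = array(as.numeric(arr), dim(arr)))
    } else {
      list(gray = as_gray8(img[, , 1]), color = NULL)  # gray+alpha etc.
    }
  } else {
    list(gray = as_gray8(img), color = NULL)
  }
}

#' Load an ordered image stack from disk
#'
#' Reads every file matching `pattern` under `path` (or all pages of a single
#' multi-page TIFF) and orders the sections by the last integer token in each
#' filename, so `s2` sorts before `s10`. RGB inputs are converted to an
#' intensity plane (BT.601 luma) for histogram work; the original color
#' planes are retained for recolored output.
#'
#' @param path Directory of section images, or path to one multi-page TIFF.
#' @param pattern Filename glob (default `"*"`) applied when `path` is a
#'   directory; only `.png`/`.tif`/`.tiff` files are considered.
#'
#' @return An [image_stack()].
#' @export
load_stack <- function(path, pattern = "*") {
  if (!file.exists(path)) {
    abort(sprintf("Path does not exist: %s", path),
          class = "histonorm_io_error")
  }
  if (!dir.exists(path)) {
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (max(unlist(lapply(pages, max))) > 255) {
      abort(sprintf("%s contains non-8-bit pages.", basename(path)),
            class = "histonorm_bitdepth_error")
    }
    planes <- lapply(pages, split_planes)
    return(image_stack(lapply(planes, `[[`, "gray"),
                       color = extract_color(planes)))
  }
  rx <- utils::glob2rx(pattern)
  files <- list.files(path, pattern = rx, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% c("png", "tif", "tiff")]
  if (length(files) == 0) {
    abort(sprintf("No image files matching '%s' under %s.", pattern, path),
          class = "histonorm_empty_input")
  }
  num <- section_number(files)
  files <- files[order(num)]
  planes <- lapply(files, function(f) split_planes(read_one_image(f)))
  grays <- lapply(planes, `[[`, "gray")
  dims <- vapply(grays, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0) {
    abort(sprintf("Image dimensions differ: %s is %dx%d, expected %dx%d.",
                  basename(files[bad[1]]), dims[1, bad[1]], dims[2, bad[1]],
                  dims[1, 1], dims[2, 1]),
          class = "histonorm_dim_mismatch")
  }
  image_stack(grays, color = extract_color(planes))
}

extract_color <- function(planes) {
  cols <- lapply(planes, `[[`, "color")
  if (all(vapply(cols, is.null, logical(1)))) NULL else cols
}

#' Write an image stack to disk
#'
#' One file per section, named `section_<i>.<ext>`, mirroring the input
#' layout. A round trip through [load_stack()] reproduces the pixel data
#' exactly. Stacks carrying color planes are written as RGB.
#'
#' @param stack An [image_stack()].
#' @param path Output directory (created if absent).
#' @param format `"png"` or `"tiff"`.
#'
#' @return Invisibly, the vector of files written.
#' @export
save_stack <- function(stack, path, format = c("png", "tiff")) {
  stopifnot(inherits(stack, "image_stack"))
  format <- match.arg(format)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory %s.", path),
                   class = "histonorm_io_error")
  }
  ext <- if (format == "png") "png" else "tif"
  width <- nchar(as.character(max(stack$index)))
  files <- file.path(path, sprintf(paste0("section_%0", width, "d.%s"),
                                   stack$index, ext))
  for (k in seq_along(stack$images)) {
    img <- if (!is.null(stack$color) && !is.null(stack$color[[k]])) {
      stack$color[[k]] / 255
    } else {
      stack$images[[k]] / 255
    }
    if (format == "png") {
      png::writePNG(img, files[k])
    } else {
      tiff::writeTIFF(img, files[k], bits.per.sample = 8L)
    }
  }
  invisible(files)
}
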