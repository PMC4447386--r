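test_that("stacks load in numeric filename order, not lexical", {
  dir <- withr::local_tempdir()
  vals <- c(s002 = 20L, s010 = 100L, s001 = 10L)
  for (nm in names(vals)) {
    png::writePNG(matrix(vals[[nm]], 4, 4) / 255, file.path(dir, paste0(nm, ".png")))
  }
  stk <- load_stack(dir)
  expect_s3_class(stk, "image_stack")
  expect_length(stk, 3)
  expect_equal(vapply(stk$images, function(im) im[1, 1], 1L), c(10L, 20L, 100L))
})

test_that("mixed dimensions and non-8-bit inputs are rejected by name", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "s1.png"))
  png::writePNG(matrix(0.5, 5, 4), file.path(dir, "s2.png"))
  expect_error(load_stack(dir), "s2", class = "histonorm_dim_mismatch")

  dir2 <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir2, "a1.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir2, "a2.tif"),
                  bits.per.sample = 16L)
  expect_error(load_stack(dir2), "a2", class = "histonorm_bitdepth_error")
})

test_that("empty matches and duplicate section numbers error", {
  dir <- withr::local_tempdir()
  expect_error(load_stack(dir, "*.png"), class = "histonorm_empty_input")
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "a1b.png"))
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "c1d.png"))
  expect_error(load_stack(dir), class = "histonorm_parameter_error")
})

test_that("save then load round-trips pixel data for png and tiff", {
  set.seed(7)
  stk <- image_stack(lapply(1:4, function(i) random_image(8, 6)))
  for (fmt in c("png", "tiff")) {
    dir <- withr::local_tempdir()
    save_stack(stk, dir, format = fmt)
    back <- load_stack(dir)
    expect_identical(back$images, stk$images)
  }
})

test_that("RGB inputs produce a luma plane and survive a color round trip", {
  dir <- withr::local_tempdir()
  arr <- array(runif(4 * 4 * 3), c(4, 4, 3))
  png::writePNG(arr, file.path(dir, "s1.png"))
  png::writePNG(arr, file.path(dir, "s2.png"))
  stk <- load_stack(dir)
  expect_false(is.null(stk$color))
  arr8 <- round(arr * 255)
  luma <- round(0.299 * arr8[, , 1] + 0.587 * arr8[, , 2] +
                  0.114 * arr8[, , 3])
  expect_equal(max(abs(stk$images[[1]] - luma)), 0)
  out <- withr::local_tempdir()
  save_stack(stk, out, format = "png")
  back <- load_stack(out)
  expect_equal(back$color, stk$color)
})

test_that("thumbnails block-subsample exactly", {
  img <- matrix(0:63, 8, 8)
  expect_identical(make_thumbnail(img, 1L), histonorm:::as_gray8(img))
  expect_identical(make_thumbnail(matrix(100L, 8, 8), 4L), matrix(100L, 2, 2))
  ramp <- matrix(0:15, 4, 4)
  expect_identical(make_thumbnail(ramp, 2L),
                   histonorm:::as_gray8(ramp[c(1, 3), c(1, 3)]))
  expect_error(make_thumbnail(img, 0), class = "histonorm_parameter_error")
})

test_that("reslicing assembles virtual sections row by row", {
  stk <- image_stack(lapply(c(10L, 20L, 30L), function(v) matrix(v, 4, 5)))
  rs <- reslice_stack(stk, "xz", 2)
  expect_equal(dim(rs), c(3, 5))
  expect_equal(rs[, 1], c(10L, 20L, 30L))
  expect_equal(apply(rs, 1, var), rep(0, 3))

  prof <- image_stack(lapply(1:6, function(i) matrix(i, 3, 3)))
  expect_equal(reslice_stack(prof, "yz", 2)[, 1], 1:6)

  single <- image_stack(list(matrix(0:11, 3, 4)))
  expect_equal(reslice_stack(single, "xz", 2), matrix(seq(1, 10, 3), 1))
  expect_error(reslice_stack(stk, "xz", 9), class = "histonorm_index_error")
})

test_that("degenerate stack construction is rejected", {
  expect_error(image_stack(list()), class = "histonorm_empty_input")
  expect_error(image_stack(list(matrix(300, 2, 2))),
               class = "histonorm_range_error")
})
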