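test_that("landmarks are fixed points and luts are monotone", {
  set.seed(3)
  for (rep in 1:50) {
    pr <- random_row_pair()
    map <- build_transform(pr$orig, pr$des)
    m <- length(pr$orig) - 2L
    expect_equal(map$lut[pr$orig[2:(m + 1)] + 1L],
                 as.integer(floor(pr$des[2:(m + 1)] + 0.5)))
    expect_false(is.unsorted(map$lut))
  }
})

test_that("equal rows give the identity transform on all 256 levels", {
  row <- c(0L, 40L, 80L, 120L, 160L, 200L, 255L)
  map <- build_transform(row, row)
  expect_identical(map$lut, 0:255)
})

test_that("the two-landmark hand example evaluates as stated", {
  map <- build_transform(c(0, 100, 150, 255), c(0, 64, 228, 255))
  expect_equal(map$segments$scale, 3.28)
  expect_equal(map$lut[125 + 1], 146L)
  expect_equal(map$lut[90 + 1], 31L)
  expect_equal(map$lut[160 + 1], 255L)
})

test_that("zero-width dynamic spans are rejected with the offending index", {
  expect_error(build_transform(c(0, 50, 50, 200, 255), c(0, 64, 100, 228, 255)),
               "L_1", class = "histonorm_degenerate_span")
})

test_that("apply_transform is a pure lookup with pushforward histogram", {
  img <- random_image(16, 16)
  ident <- build_transform(c(0, 1, 255, 255), c(0, 1, 255, 255))
  expect_equal(apply_transform(img, ident), histonorm:::as_gray8(img))

  zero_map <- ident
  zero_map$lut <- rep(0L, 256)
  expect_true(all(apply_transform(img, zero_map) == 0L))

  set.seed(9)
  pr <- random_row_pair()
  map <- build_transform(pr$orig, pr$des)
  out <- apply_transform(img, map)
  push <- integer(256)
  for (r in 0:255) {
    push[map$lut[r + 1] + 1L] <- push[map$lut[r + 1] + 1L] +
      sum(img == r)
  }
  expect_equal(tabulate(as.integer(out) + 1L, 256), push)
})

test_that("lut path agrees pixel-for-pixel with the per-pixel formula", {
  set.seed(21)
  for (rep in 1:10) {
    pr <- random_row_pair()
    img <- random_image(24, 24)
    map <- build_transform(pr$orig, pr$des)
    expect_identical(apply_transform(img, map),
                     oracle_warp(img, pr$orig, pr$des))
  }
})

test_that("the full pipeline enforces its preconditions and intermediates", {
  tiny <- image_stack(lapply(1:3, function(i) blob_image()))
  expect_error(run_shfa(tiny), class = "histonorm_insufficient_data")

  set.seed(5)
  imgs <- lapply(1:12, function(i) {
    im <- blob_image(dark = 70 + i, bg = 225 + round(i / 4))
    histonorm:::as_gray8(histonorm:::clamp(round(im + rnorm(length(im), 0, 2))))
  })
  stk <- image_stack(imgs)
  fit <- run_shfa(stk, shfa_config(thumbnail_factor = 2L))
  expect_s3_class(fit, "shfa_fit")
  expect_length(fit$maps, 12)
  expect_equal(dim(fit$landmarks$original), c(12, 11))
  expect_equal(dim(fit$landmarks$desired), c(12, 11))
  expect_length(fit$curves, 9)
  expect_false(any(fit$degenerate))
  # landmark fixed points survive orchestration
  for (i in c(1, 7, 12)) {
    rows <- histonorm:::dedupe_rows(fit$landmarks$original[i, ],
                                    fit$landmarks$desired[i, ])
    mm <- length(rows$orig) - 2L
    expect_equal(fit$maps[[i]]$lut[rows$orig[2:(mm + 1)] + 1L],
                 as.integer(floor(rows$des[2:(mm + 1)] + 0.5)))
  }
})

test_that("degenerate sections are warped via the fallback row with a warning", {
  set.seed(6)
  imgs <- lapply(1:10, function(i) {
    histonorm:::as_gray8(histonorm:::clamp(round(
      blob_image() + rnorm(64 * 64, 0, 2))))
  })
  imgs[[4]] <- matrix(128L, 64, 64)  # constant section
  stk <- image_stack(imgs)
  expect_warning(fit <- run_shfa(stk, shfa_config(thumbnail_factor = 2L)),
                 "degenerate")
  expect_true(fit$degenerate[4])
  expect_true(all(is.na(fit$landmarks$original[4, ])))
  expect_equal(dim(fit$stack$images[[4]]), c(64, 64))
})

test_that("broom-style accessors summarize the fit", {
  set.seed(8)
  imgs <- lapply(1:10, function(i) {
    histonorm:::as_gray8(histonorm:::clamp(round(
      blob_image() + rnorm(64 * 64, 0, 2))))
  })
  fit <- run_shfa(image_stack(imgs), shfa_config(thumbnail_factor = 2L))
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 10 * 11)
  expect_true(all(c("image", "ordinate", "original", "desired") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$n_images, 10)
  expect_equal(gl$anchor_high, 228)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
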