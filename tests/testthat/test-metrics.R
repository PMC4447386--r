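test_that("KLD matches hand evaluation and is zero on identical inputs", {
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_identical(kld(p, p), 0)
  expect_equal(kld(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  # asymmetry on a concrete pair
  a <- c(0.9, 0.1); b <- c(0.5, 0.5)
  expect_false(isTRUE(all.equal(kld(a, b), kld(b, a))))
  expect_error(kld(c(0.5, 0.4), c(0.5, 0.5)),
               class = "histonorm_normalization_error")
})

test_that("zero-bin conflicts are smoothed finitely, growing as eps shrinks", {
  p <- c(0.5, 0.5, 0)
  q <- c(1, 0, 0)
  v6 <- kld(p, q, smooth_eps = 1e-6)
  v8 <- kld(p, q, smooth_eps = 1e-8)
  expect_true(is.finite(v6) && is.finite(v8))
  expect_gt(v8, v6)
  expect_gte(v8, 0)
})

test_that("KLD is non-negative over random distribution pairs", {
  set.seed(13)
  for (rep in 1:25) {
    p <- runif(256); p <- p / sum(p)
    q <- runif(256); q <- q / sum(q)
    expect_gte(kld(p, q), 0)
  }
})

test_that("CPP matches brute-force neighborhood sums", {
  expect_identical(cpp(matrix(77, 5, 5)), 0)
  expect_equal(cpp(matrix(c(0, 255), 1, 2)), 255)
  spike <- matrix(0, 3, 3); spike[2, 2] <- 255
  expect_equal(cpp(spike), 4080 / 9)

  # brute force oracle on a random image
  set.seed(17)
  img <- random_image(7, 6)
  brute <- 0
  for (i in 1:7) for (j in 1:6) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 7 && jj >= 1 && jj <= 6) {
        brute <- brute + abs(img[i, j] - img[ii, jj])
      }
    }
  }
  expect_equal(cpp(img), brute / 42)
})

test_that("CPP is invariant to transposition and flips, linear in gain", {
  set.seed(19)
  img <- random_image(9, 9)
  expect_equal(cpp(t(img)), cpp(img))
  expect_equal(cpp(img[9:1, ]), cpp(img))
  expect_equal(cpp(img[, 9:1]), cpp(img))
  small <- matrix(sample(0:80, 36, TRUE), 6, 6)
  expect_equal(cpp(small * 3), 3 * cpp(small))
})

test_that("stripe variance quantifies inter-section brightness unevenness", {
  stk <- image_stack(lapply(rep(40L, 5), function(v) matrix(v, 4, 4)))
  expect_equal(stripe_variance(reslice_stack(stk, "xz", 1)), 0)

  alt <- image_stack(lapply(rep(c(100L, 120L), 3), function(v) matrix(v, 4, 4)))
  expect_equal(stripe_variance(reslice_stack(alt, "xz", 2)), 100)

  # rows sharing a common mean have zero stripe variance
  set.seed(23)
  rs <- t(replicate(6, {
    r <- rnorm(10); 100 + r - mean(r)
  }))
  expect_lt(stripe_variance(rs), 1e-20)
  expect_error(stripe_variance(matrix(1, 1, 4)),
               class = "histonorm_parameter_error")
})

test_that("metric reports tabulate per-image values and block means", {
  set.seed(29)
  orig <- image_stack(lapply(1:6, function(i) random_image(12, 12)))
  proc <- image_stack(lapply(orig$images, function(im) {
    histonorm:::as_gray8(histonorm:::clamp(im + 10L))
  }))
  rep_ <- metric_report(orig, proc, block_size = 3L)
  expect_equal(nrow(rep_$per_image), 6)
  expect_equal(nrow(rep_$blocks), 2)
  expect_equal(rep_$blocks$mean_kld[1], mean(rep_$per_image$kld[1:3]))
  expect_equal(rep_$blocks$mean_cpp_after[2],
               mean(rep_$per_image$cpp_after[4:6]))
  expect_true(all(rep_$per_image$kld >= 0))

  same <- metric_report(orig, orig, block_size = 100L)
  expect_true(all(same$per_image$kld == 0))
  expect_equal(same$per_image$cpp_before, same$per_image$cpp_after)
})
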