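# segment: maximum-entropy threshold, mask conversion, binary cleanup

test_that("max_entropy_threshold matches the exhaustive Kapur oracle", {
  # uniform histogram: criterion reduces to ln((t+1)(255-t)), max at 127
  h <- rep(4L, 256)
  expect_identical(max_entropy_threshold(h), oracle_max_entropy(h))
  expect_identical(max_entropy_threshold(h), 127L)
  # two-spike histogram: every t in [10,199] separates the spikes with the
  # same criterion value; the tie-break fixes the smallest, t = 10
  h2 <- integer(256); h2[10 + 1] <- 500L; h2[200 + 1] <- 300L
  t2 <- max_entropy_threshold(h2)
  expect_identical(t2, oracle_max_entropy(h2))
  expect_identical(t2, 10L)
  set.seed(17)
  for (rep in 1:30) {
    hh <- as.integer(rpois(256, exp(runif(256, 0, 6))))
    if (sum(hh > 0) < 2) next
    expect_identical(max_entropy_threshold(hh), oracle_max_entropy(hh))
  }
})

test_that("degenerate histograms are rejected", {
  h <- integer(256); h[40] <- 1000L
  expect_error(max_entropy_threshold(h), "degenerate")
  expect_error(max_entropy_threshold(rep(-1L, 256)), "non-negative")
  expect_error(max_entropy_threshold(1:10), "256")
})

test_that("intensity_histogram counts every pixel", {
  img <- matrix(c(0L, 0L, 255L, 17L), 2, 2)
  h <- intensity_histogram(img)
  expect_identical(sum(h), 4L)
  expect_identical(h[1], 2L)
  expect_identical(h[256], 1L)
  expect_identical(h[18], 1L)
})

test_that("apply_threshold follows the dark-foreground convention", {
  img <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  m <- apply_threshold(img, 127, dark_foreground = TRUE)
  expect_identical(m$pixels, matrix(c(1L, 0L, 1L, 0L), 2, 2))
  m2 <- apply_threshold(img, 127, dark_foreground = FALSE)
  expect_identical(m2$pixels, 1L - m$pixels)  # exact complement
  # empty mask permitted
  e <- apply_threshold(matrix(200L, 3, 3), 100, TRUE)
  expect_identical(sum(e$pixels), 0L)
})

test_that("binary_close bridges a 2-pixel gap and is extensive + idempotent", {
  m <- matrix(0L, 5, 10)
  m[3, c(2, 3, 4, 7, 8, 9)] <- 1L  # [1,1,1,0,0,1,1,1] embedded
  closed <- binary_close(binary_mask(m, 1), 1)
  expect_identical(max(astromorph:::cpp_label8(closed$pixels)), 1L)
  expect_true(all(closed$pixels[3, 2:9] == 1L))
  set.seed(23)
  for (rep in 1:30) {
    r <- matrix(rbinom(32 * 32, 1, runif(1, .1, .6)), 32, 32)
    cl <- binary_close(r, 1)
    expect_true(all(cl[r == 1] == 1L))               # extensive
    expect_identical(binary_close(cl, 1), cl)        # idempotent
  }
  em <- matrix(0L, 8, 8)
  expect_identical(binary_close(em, 2), em)
})

test_that("remove_outliers deletes isolated specks, matches the disk oracle", {
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  out <- remove_outliers(m, cleanup_params(2, 50, "bright"))
  expect_identical(out[6, 6], 0L)
  cst <- matrix(130, 7, 7)
  expect_true(all(remove_outliers(cst) == 130))
  # large solid square: interior and edges preserved
  sq <- matrix(0, 20, 20); sq[5:16, 5:16] <- 255
  out2 <- remove_outliers(sq, cleanup_params(2, 50, "bright"))
  expect_equal(unname(out2), unname(oracle_remove_outliers(sq, 2, 50)))
  expect_true(all(out2[7:14, 7:14] == 255))
  set.seed(29)
  for (rep in 1:3) {
    r <- matrix(sample(0:255, 18 * 18, TRUE), 18, 18)
    expect_equal(unname(remove_outliers(r, cleanup_params(2, 50, "bright"))),
                 unname(oracle_remove_outliers(r, 2, 50, bright = TRUE)))
    expect_equal(unname(remove_outliers(r, cleanup_params(2, 40, "dark"))),
                 unname(oracle_remove_outliers(r, 2, 40, bright = FALSE)))
    # never changes a pixel whose deviation is within the threshold
    expect_true(all(remove_outliers(r, cleanup_params(2, 300, "bright")) == r))
  }
})

test_that("remove_outliers on a binary mask works on its 0/255 display form", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  bm <- binary_mask(m, 1)
  out <- remove_outliers(bm, cleanup_params(2, 50, "bright"))
  expect_s3_class(out, "binary_mask")
  expect_identical(sum(out$pixels), 0L)
})

test_that("segment_image is exactly threshold -> despeckle -> close -> outliers", {
  g <- synth_generate(small_scene_spec(4))
  img <- g$image
  seg <- segment_image(img)
  t <- max_entropy_threshold(intensity_histogram(img))
  manual <- remove_outliers(
    binary_close(despeckle(apply_threshold(img, t, TRUE)), 1),
    cleanup_params())
  expect_identical(seg$threshold, t)
  expect_identical(seg$mask$pixels, manual$pixels)
})

test_that("cleanup_params enforces the printed defaults and bounds", {
  p <- cleanup_params()
  expect_equal(p$outlier_radius_px, 2)
  expect_equal(p$outlier_threshold, 50)
  expect_identical(p$outlier_polarity, "bright")
  expect_identical(p$close_iterations, 1L)
  expect_error(cleanup_params(outlier_radius_px = 0), "radius")
})
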