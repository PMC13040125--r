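# brute-force adaptive Wiener oracle: explicit window loops with symmetric
# padding, noise power = mean of local variances
bf_wiener <- function(px, kr = 3, kc = 3) {
  nr <- nrow(px); nc <- ncol(px)
  rr <- (kr - 1) / 2; cr <- (kc - 1) / 2
  mu <- matrix(0, nr, nc); sig2 <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (dr in -rr:rr) for (dc in -cr:cr) {
      vals <- c(vals, px[sym_idx(r + dr, nr), sym_idx(c + dc, nc)])
    }
    mu[r, c] <- mean(vals)
    sig2[r, c] <- mean(vals^2) - mean(vals)^2
  }
  nu <- mean(sig2)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    g <- if (max(sig2[r, c], nu) == 0) 0 else
      max(sig2[r, c] - nu, 0) / max(sig2[r, c], nu)
    out[r, c] <- mu[r, c] + g * (px[r, c] - mu[r, c])
  }
  out
}

sym_idx <- function(i, n) {
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

test_that("adaptive Wiener filter matches a window-by-window oracle", {
  set.seed(7)
  px <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
  got <- wiener_denoise(px)$pixels
  expect_equal(got, bf_wiener(px), tolerance = 1e-12, ignore_attr = TRUE)
  # and on a larger random image
  px2 <- matrix(rnorm(100), 10, 10)
  expect_equal(wiener_denoise(px2)$pixels, bf_wiener(px2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Wiener filter fixed points and smoothing property", {
  const <- matrix(5, 6, 6)
  expect_equal(wiener_denoise(const)$pixels, const, ignore_attr = TRUE)
  set.seed(3)
  noisy <- matrix(rnorm(25), 5, 5)
  out <- wiener_denoise(noisy)$pixels
  expect_lte(var(as.vector(out)), var(as.vector(noisy)))
  expect_true(all(is.finite(out)))
  expect_error(wiener_denoise(noisy, kernel = c(2, 2)),
               class = "usr_invalid_config")
})

test_that("zscore_roi standardizes within the ROI with sample SD", {
  px <- matrix(0, 3, 3)
  px[1, 1:3] <- c(2, 4, 6)
  m <- matrix(FALSE, 3, 3); m[1, 1:3] <- TRUE
  z <- zscore_roi(px, m)$pixels
  expect_equal(z[1, 1:3], c(-1, 0, 1))  # sample SD is 2
  set.seed(8)
  px2 <- matrix(runif(64, 10, 50), 8, 8)
  m2 <- matrix(runif(64) < 0.6, 8, 8); m2[1:2, 1:2] <- TRUE
  z2 <- zscore_roi(px2, m2)$pixels
  expect_equal(mean(z2[m2]), 0, tolerance = 1e-9)
  expect_equal(sd(z2[m2]), 1, tolerance = 1e-9)
  expect_error(zscore_roi(matrix(3, 4, 4), matrix(TRUE, 4, 4)),
               class = "usr_degenerate_roi")
})

test_that("discretize follows the fixed-bin-number edge conventions", {
  px <- matrix(c(0, 0.5, 1, 99), 2, 2)
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  d <- discretize(px, m, 2)
  expect_equal(d$levels[m], c(1L, 2L, 2L))  # top edge closed
  expect_equal(d$levels[!m], 0L)
  dc <- discretize(matrix(7, 3, 3), matrix(TRUE, 3, 3), 8)
  expect_true(all(dc$levels == 1L))
  set.seed(2)
  px3 <- matrix(rnorm(100), 10, 10)
  m3 <- matrix(runif(100) < 0.7, 10, 10); m3[1, 1] <- TRUE
  d3 <- discretize(px3, m3, 16)
  expect_true(all(d3$levels[m3] >= 1 & d3$levels[m3] <= 16))
  expect_error(discretize(px3, m3, 1), class = "usr_invalid_config")
})

test_that("z-score + fixed-bin discretization is affine invariant", {
  set.seed(11)
  px <- matrix(runif(144, 0, 200), 12, 12)
  m <- matrix(runif(144) < 0.7, 12, 12); m[3:5, 3:5] <- TRUE
  base <- discretize(zscore_roi(px, m), m, 12)$levels
  for (ab in list(c(3.7, 12), c(0.01, -5))) {
    tr <- discretize(zscore_roi(ab[1] * px + ab[2], m), m, 12)$levels
    expect_identical(tr, base)
  }
})

test_that("PNG reader rejects color and round-trips grayscale", {
  dir <- withr::local_tempdir()
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  p <- file.path(dir, "g.png")
  usradiomics:::write_grayscale_png(px, p)
  expect_equal(read_grayscale(p)$pixels, px, ignore_attr = TRUE)
  rgb_path <- file.path(dir, "c.png")
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  png::writePNG(arr, rgb_path)
  expect_error(read_grayscale(rgb_path), class = "usr_unsupported_format")
  expect_error(read_grayscale(file.path(dir, "nope.png")),
               class = "usr_io_error")
})

test_that("minimal DICOM reader honors rescale and rejects multi-frame", {
  dir <- withr::local_tempdir()
  px <- matrix(sample(0:255, 48, replace = TRUE), 6, 8)
  p <- file.path(dir, "a.dcm")
  write_dicom_image(px, p, pixel_spacing = 0.3)
  img <- read_dicom_image(p)
  expect_equal(img$pixels, px, ignore_attr = TRUE)
  expect_equal(img$pixel_spacing, 0.3)
  # read_grayscale sniffs DICOM content regardless of extension
  expect_equal(read_grayscale(p)$pixels, px, ignore_attr = TRUE)

  p2 <- file.path(dir, "b.dcm")
  write_dicom_image(px, p2, rescale_slope = 2, rescale_intercept = -10)
  expect_equal(read_dicom_image(p2)$pixels, px * 2 - 10, ignore_attr = TRUE)

  # hand-build a multi-frame file via the internal element writer
  de <- usradiomics:::dicom_element
  meta_body <- c(de(2L, 16L, "UI", usradiomics:::UID_EXPLICIT_LE))
  meta <- c(de(2L, 0L, "UL", usradiomics:::w32(length(meta_body))), meta_body)
  ds <- c(de(40L, 8L, "IS", "2"),
          de(40L, 16L, "US", usradiomics:::w16(2L)),
          de(40L, 17L, "US", usradiomics:::w16(2L)),
          de(32736L, 16L, "OB", as.raw(1:8)))
  p3 <- file.path(dir, "m.dcm")
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), p3)
  expect_error(read_dicom_image(p3), class = "usr_unsupported_format")
})
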