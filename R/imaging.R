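#' Grayscale image container
#'
#' Thin S3 wrapper around a numeric intensity matrix (row 1 at top), with
#' optional physical pixel spacing in millimetres.
#'
#' @param pixels numeric matrix of finite intensities.
#' @param pixel_spacing optional numeric, mm per pixel (isotropic).
#' @return object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, pixel_spacing = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    usr_stop("usr_invalid_spec", "image must have positive dimensions")
  if (!all(is.finite(pixels)))
    usr_stop("usr_invalid_spec", "image intensities must be finite")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing),
            class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image %d x %d, range [%.3g, %.3g]%s>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (!is.null(x$pixel_spacing))
                sprintf(", %.3g mm/px", x$pixel_spacing) else ""))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "grayscale_image")) x$pixels else as.matrix(x)
}

#' Binary region-of-interest mask
#'
#' @param mask logical (or coercible) matrix, same shape as its image.
#' @param require_nonempty error if no pixel is set (tumor ROIs must be
#'   nonempty; optional myometrium ROIs may be absent instead).
#' @return logical matrix of class `roi_mask`.
#' @export
roi_mask <- function(mask, require_nonempty = TRUE) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (require_nonempty && !any(mask))
    usr_stop("usr_degenerate_roi", "ROI mask is empty")
  structure(mask, class = c("roi_mask", "matrix"))
}

#' Read a grayscale image from PNG or DICOM
#'
#' PNG pixels are returned on the stored 8-bit (or 16-bit) integer scale.
#' DICOM pixels are returned as stored values with RescaleSlope/Intercept
#' applied; `pixel_spacing` is populated from PixelSpacing when present.
#' Multi-frame, color and compressed inputs are rejected.
#'
#' @param path file path ending in `.png`/`.dcm` (content is sniffed for
#'   DICOM regardless of extension).
#' @return a [grayscale_image()].
#' @export
read_grayscale <- function(path) {
  if (!file.exists(path))
    usr_stop("usr_io_error", paste("no such file:", path))
  if (is_dicom_file(path)) return(read_dicom_image(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] %in% c(2L, 4L)) a <- a[, , -dim(a)[3], drop = FALSE]
      if (length(dim(a)) == 3L && dim(a)[3] > 1L) {
        if (max(abs(a[, , 1] - a[, , 2])) > 0 ||
            max(abs(a[, , 1] - a[, , 3])) > 0)
          usr_stop("usr_unsupported_format",
                   "color PNG is not a grayscale ultrasound image")
      }
      a <- a[, , 1]
    }
    return(grayscale_image(round(a * 255)))
  }
  usr_stop("usr_unsupported_format", paste("unsupported image format:", path))
}

#' Read a binary mask from a 0/255 PNG
#'
#' @param path PNG path.
#' @param require_nonempty see [roi_mask()].
#' @return an `roi_mask`.
#' @export
read_mask <- function(path, require_nonempty = TRUE) {
  img <- read_grayscale(path)
  roi_mask(img$pixels > 127, require_nonempty = require_nonempty)
}

write_grayscale_png <- function(pixels, path) {
  pixels <- as_pixels(pixels)
  png::writePNG(pmin(pmax(pixels, 0), 255) / 255, path)
  invisible(path)
}

write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(as.matrix(mask), 1, 0), path)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param wiener_kernel integer (rows, cols) of the adaptive Wiener window;
#'   both odd, default `c(3, 3)`.
#' @param n_gray_levels number of discretization levels N_g (fixed-bin-number
#'   binning within the ROI), default 32.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(wiener_kernel = c(3L, 3L), n_gray_levels = 32L) {
  wiener_kernel <- as.integer(wiener_kernel)
  if (length(wiener_kernel) != 2L || any(wiener_kernel < 1L) ||
      any(wiener_kernel %% 2L == 0L))
    usr_stop("usr_invalid_config", "wiener_kernel dims must be odd and >= 1")
  if (n_gray_levels < 2L)
    usr_stop("usr_invalid_config", "n_gray_levels must be >= 2")
  structure(list(wiener_kernel = wiener_kernel,
                 n_gray_levels = as.integer(n_gray_levels)),
            class = "preprocess_config")
}

#' Adaptive Wiener speckle filter
#'
#' Classic locally adaptive Wiener denoiser: with local window mean \eqn{\mu}
#' and variance \eqn{\sigma^2}, and noise power \eqn{\nu} estimated as the
#' image-wide mean of the local variances, each pixel becomes
#' \deqn{\mu + \frac{\max(\sigma^2-\nu, 0)}{\max(\sigma^2, \nu)} (x-\mu).}
#' Borders are handled by symmetric padding. Constant images are fixed points.
#'
#' @param image a [grayscale_image()] or matrix.
#' @param kernel odd (rows, cols) window, default 3 x 3.
#' @return a [grayscale_image()].
#' @export
wiener_denoise <- function(image, kernel = c(3L, 3L)) {
  px <- as_pixels(image)
  kernel <- as.integer(kernel)
  if (any(kernel %% 2L == 0L) || any(kernel < 1L))
    usr_stop("usr_invalid_config", "Wiener kernel dims must be odd and >= 1")
  mu <- box_mean(px, kernel[1], kernel[2])
  m2 <- box_mean(px^2, kernel[1], kernel[2])
  sig2 <- pmax(m2 - mu^2, 0)
  nu <- mean(sig2)
  gain <- if (nu == 0) {
    matrix(0, nrow(px), ncol(px))
  } else {
    pmax(sig2 - nu, 0) / pmax(sig2, nu)
  }
  out <- mu + gain * (px - mu)
  grayscale_image(out, pixel_spacing = if (inherits(image, "grayscale_image"))
    image$pixel_spacing else NULL)
}

#' Within-ROI z-score normalization
#'
#' Standardizes the whole image by the mean and sample SD (n - 1 denominator)
#' of the intensities inside the ROI, so the ROI has mean 0 and SD 1 after.
#'
#' @param image image or matrix.
#' @param mask ROI mask.
#' @return a [grayscale_image()] of standardized intensities.
#' @export
zscore_roi <- function(image, mask) {
  px <- as_pixels(image)
  mask <- as.matrix(mask)
  if (!any(mask)) usr_stop("usr_degenerate_roi", "ROI mask is empty")
  v <- px[mask]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    usr_stop("usr_degenerate_roi", "ROI intensity SD is zero")
  grayscale_image((px - mean(v)) / s,
                  pixel_spacing = if (inherits(image, "grayscale_image"))
                    image$pixel_spacing else NULL)
}

#' Fixed-bin-number gray-level discretization within the ROI
#'
#' Maps in-ROI intensities to integer levels `1..n_gray` over the ROI range
#' with bin width `w = (max - min) / n_gray`; bin k covers
#' `[min + (k-1)w, min + kw)` and the top edge is closed. A constant ROI maps
#' to level 1. Outside-ROI pixels are level 0.
#'
#' @param image image or matrix (typically z-scored).
#' @param mask ROI mask.
#' @param n_gray number of gray levels (>= 2).
#' @return object of class `discretized_roi` with fields `levels`
#'   (integer matrix, 0 outside mask) and `n_gray`.
#' @export
discretize <- function(image, mask, n_gray = 32L) {
  if (n_gray < 2L) usr_stop("usr_invalid_config", "n_gray must be >= 2")
  px <- as_pixels(image)
  mask <- as.matrix(mask)
  if (!any(mask)) usr_stop("usr_degenerate_roi", "ROI mask is empty")
  v <- px[mask]
  lo <- min(v); hi <- max(v)
  lev <- matrix(0L, nrow(px), ncol(px))
  if (hi == lo) {
    lev[mask] <- 1L
  } else {
    k <- floor((v - lo) / (hi - lo) * n_gray) + 1L
    k[k > n_gray] <- as.integer(n_gray)  # close the top edge
    lev[mask] <- as.integer(k)
  }
  structure(list(levels = lev, n_gray = as.integer(n_gray)),
            class = "discretized_roi")
}
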