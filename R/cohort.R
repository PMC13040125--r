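# Synthetic lesion-imaging cohort generator.
#
# The generator emulates a case-control ultrasound study design: two classes
# of myometrial lesions with class-specific patient age distributions and
# class-specific lesion texture. The stated world follows the published
# cohort's descriptive statistics: 100 + 100 cases, ages 59 +/- 13 vs
# 45 +/- 9 years, sarcoma-like lesions heterogeneous with cystic areas and
# few shadows (non-uniform 95%, cysts 64%, shadows 21%), leiomyoma-like
# lesions more homogeneous with frequent shadowing (59% / 11% / 83%).
# Continuous effect sizes (heterogeneity amplitude, speckle grain) are
# calibration choices documented in the methods vignette.

#' Per-class lesion texture parameters
#'
#' @param speckle_grain_px Gaussian correlation length (pixels) of the
#'   multiplicative speckle grain.
#' @param heterogeneity_amp amplitude of the multiplicative low-frequency
#'   intensity field inside the lesion (0 = homogeneous echostructure).
#' @param cyst_rate expected number of anechoic cysts per lesion (Poisson).
#' @param shadow_prob probability of a vertical acoustic-shadow band.
#' @return named list of class `texture_params`.
#' @export
texture_params <- function(speckle_grain_px = 1.5, heterogeneity_amp = 0.2,
                           cyst_rate = 0.1, shadow_prob = 0.5) {
  if (speckle_grain_px <= 0)
    usr_stop("usr_invalid_spec", "speckle_grain_px must be > 0")
  if (heterogeneity_amp < 0 || cyst_rate < 0)
    usr_stop("usr_invalid_spec", "amplitudes and rates must be >= 0")
  if (shadow_prob < 0 || shadow_prob > 1)
    usr_stop("usr_invalid_spec", "shadow_prob must be in [0, 1]")
  structure(list(speckle_grain_px = speckle_grain_px,
                 heterogeneity_amp = heterogeneity_amp,
                 cyst_rate = cyst_rate, shadow_prob = shadow_prob),
            class = "texture_params")
}

#' Cohort specification for the synthetic generator
#'
#' Defaults encode the emulated study: 100 sarcomas and 100 leiomyomas, ages
#' 59 +/- 13 vs 45 +/- 9 years truncated at 18, a tumor-free myometrium ROI
#' for 32% of cases (the delta subanalysis subset), 0.2 mm/px so the 5-mm
#' cyst-exclusion diameter is 25 px. Class texture parameters follow the
#' reported lesion-appearance frequencies (shadows 21% vs 83%, cysts in 64%
#' vs 11% of lesions, non-uniform echostructure far more common in sarcomas).
#'
#' @param n_sarcoma,n_leiomyoma class sizes (>= 0).
#' @param image_height,image_width image dimensions in pixels.
#' @param age_mean_sarcoma,age_sd_sarcoma,age_mean_leiomyoma,age_sd_leiomyoma
#'   class-specific age distributions in years (normal, truncated at 18).
#' @param texture_sarcoma,texture_leiomyoma [texture_params()] per class.
#' @param myometrium_fraction fraction of cases per class given a tumor-free
#'   myometrium ROI.
#' @param pixel_spacing_mm physical scale, mm per pixel.
#' @param cyst_exclusion_mm cysts above this maximum diameter are excluded
#'   from the tumor ROI.
#' @param seed integer; the cohort is a pure function of (spec, seed).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sarcoma = 100L, n_leiomyoma = 100L,
                        image_height = 96L, image_width = 96L,
                        age_mean_sarcoma = 59, age_sd_sarcoma = 13,
                        age_mean_leiomyoma = 45, age_sd_leiomyoma = 9,
                        texture_sarcoma = texture_params(
                          speckle_grain_px = 1.2, heterogeneity_amp = 0.55,
                          cyst_rate = 1.0, shadow_prob = 0.21),
                        texture_leiomyoma = texture_params(
                          speckle_grain_px = 2.2, heterogeneity_amp = 0.15,
                          cyst_rate = 0.12, shadow_prob = 0.83),
                        myometrium_fraction = 0.32,
                        pixel_spacing_mm = 0.2, cyst_exclusion_mm = 5,
                        seed = 1L) {
  if (n_sarcoma < 0 || n_leiomyoma < 0)
    usr_stop("usr_invalid_spec", "class counts must be >= 0")
  if (image_height < 1 || image_width < 1)
    usr_stop("usr_invalid_spec", "image dimensions must be positive")
  if (age_sd_sarcoma <= 0 || age_sd_leiomyoma <= 0)
    usr_stop("usr_invalid_spec", "age SDs must be > 0")
  if (myometrium_fraction < 0 || myometrium_fraction > 1)
    usr_stop("usr_invalid_spec", "myometrium_fraction must be in [0, 1]")
  structure(list(
    n_sarcoma = as.integer(n_sarcoma), n_leiomyoma = as.integer(n_leiomyoma),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    age_mean_sarcoma = age_mean_sarcoma, age_sd_sarcoma = age_sd_sarcoma,
    age_mean_leiomyoma = age_mean_leiomyoma,
    age_sd_leiomyoma = age_sd_leiomyoma,
    texture_sarcoma = texture_sarcoma, texture_leiomyoma = texture_leiomyoma,
    myometrium_fraction = myometrium_fraction,
    pixel_spacing_mm = pixel_spacing_mm,
    cyst_exclusion_mm = cyst_exclusion_mm, seed = as.integer(seed)
  ), class = "cohort_spec")
}

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Synthesize one lesion image, tumor ROI and optional myometrium ROI
#'
#' The image is multiplicative speckle (gamma-distributed grain smoothed to
#' `speckle_grain_px`) over a class-specific echo field: a uniform lesion
#' base modulated by a low-frequency heterogeneity field, anechoic cyst
#' holes, and an optional vertical attenuation (shadow) band. Cysts wider
#' than the exclusion diameter are removed from the tumor ROI; smaller
#' cysts stay inside it. Consumes the current RNG state.
#'
#' @param params [texture_params()] for the lesion class.
#' @param height,width image dimensions (pixels).
#' @param pixel_spacing_mm physical scale.
#' @param cyst_exclusion_mm ROI cyst-exclusion diameter.
#' @param with_myometrium also delineate a tumor-free myometrium annulus.
#' @param keep_components retain the underlying field/speckle matrices in
#'   `truth` (used by generator tests).
#' @return list with `image`, `tumor_mask`, `myometrium_mask` (or NULL),
#'   and `truth` (the parameters used).
#' @export
synthesize_lesion <- function(params, height, width, pixel_spacing_mm = 0.2,
                              cyst_exclusion_mm = 5, with_myometrium = FALSE,
                              keep_components = FALSE) {
  h <- as.integer(height); w <- as.integer(width)
  if (h < 16L || w < 16L)
    usr_stop("usr_invalid_spec", "image too small to contain a lesion")
  # per-case biological variability: lesion appearance overlaps between
  # classes (most sarcomas but also many leiomyomas look non-uniform), so
  # grain and heterogeneity are lognormal draws around the class means
  grain <- params$speckle_grain_px * exp(rnorm(1, 0, 0.35))
  amp <- params$heterogeneity_amp * exp(rnorm(1, 0, 0.40))
  cy <- h / 2 + runif(1, -0.04, 0.04) * h
  cx <- w / 2 + runif(1, -0.04, 0.04) * w
  ry <- runif(1, 0.24, 0.34) * h
  rx <- runif(1, 0.26, 0.36) * w
  if (ry >= h / 2 || rx >= w / 2)
    usr_stop("usr_invalid_spec", "lesion larger than image")
  lesion <- ellipse_mask(h, w, cy, cx, ry, rx)

  base_bg <- 110; base_lesion <- 100
  field <- matrix(base_bg, h, w)
  het <- gaussian_blur(matrix(rnorm(h * w), h, w), sigma = h / 12)
  het <- (het - mean(het)) / sd(het)
  # fine-scale structural disruption (necrosis-like) rides on the same
  # amplitude: it decorrelates neighboring pixels, so heterogeneous lesions
  # show the higher co-occurrence entropy seen in malignant echotexture
  fine <- gaussian_blur(matrix(rnorm(h * w), h, w), sigma = 1.2)
  fine <- (fine - mean(fine)) / sd(fine)
  lesion_field <- base_lesion *
    pmax(1 + amp * het + 0.5 * amp * fine, 0.05)
  # mild background modulation so normal myometrium is not perfectly flat
  bg_field <- base_bg * pmax(1 + 0.08 * het, 0.05)
  field[!lesion] <- bg_field[!lesion]
  field[lesion] <- lesion_field[lesion]

  # anechoic cysts; large ones are carved out of the ROI
  excl_px <- cyst_exclusion_mm / pixel_spacing_mm
  n_cysts <- rpois(1, params$cyst_rate)
  tumor_mask <- lesion
  cysts <- list()
  if (n_cysts > 0) {
    for (i in seq_len(n_cysts)) {
      theta <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * 0.7
      ccy <- cy + rad * ry * sin(theta)
      ccx <- cx + rad * rx * cos(theta)
      diam <- runif(1, 6, min(40, 0.9 * min(ry, rx) * 2))
      disk <- ellipse_mask(h, w, ccy, ccx, diam / 2, diam / 2) & lesion
      field[disk] <- field[disk] * 0.06
      if (diam > excl_px) tumor_mask <- tumor_mask & !disk
      cysts[[i]] <- list(cy = ccy, cx = ccx, diam = diam,
                         excluded = diam > excl_px, pixels = disk)
    }
  }
  if (!any(tumor_mask)) tumor_mask <- lesion  # pathological carve-out guard

  shadow <- runif(1) < params$shadow_prob
  if (shadow) {
    bw <- runif(1, 0.2, 0.45) * 2 * rx
    bc <- cx + runif(1, -0.5, 0.5) * rx
    cols <- pmax(1, round(bc - bw / 2)):pmin(w, round(bc + bw / 2))
    top <- max(1, round(cy - 0.2 * ry))
    depth <- h - top
    atten <- seq(1, 0.3, length.out = depth + 1L)
    field[top:h, cols] <- field[top:h, cols] * atten
  }

  speckle <- matrix(rgamma(h * w, shape = 3, rate = 3), h, w)
  speckle <- gaussian_blur(speckle, grain)
  speckle <- speckle / mean(speckle)
  # 8-bit quantization, as stored by the ultrasound machine; PNG round-trips
  # are then lossless
  img <- round(pmin(pmax(field * speckle, 0), 255))

  myo <- NULL
  if (with_myometrium) {
    outer_m <- ellipse_mask(h, w, cy, cx, min(1.45 * ry, h / 2 - 1),
                            min(1.45 * rx, w / 2 - 1))
    inner_m <- ellipse_mask(h, w, cy, cx, 1.15 * ry, 1.15 * rx)
    ann <- outer_m & !inner_m & !tumor_mask
    if (any(ann)) myo <- roi_mask(ann)
  }
  truth <- params
  if (keep_components) {
    truth <- c(unclass(params),
               list(field = field, speckle = speckle, lesion = lesion,
                    shadow = shadow, cysts = cysts))
  }
  list(image = grayscale_image(img, pixel_spacing = pixel_spacing_mm),
       tumor_mask = roi_mask(tumor_mask), myometrium_mask = myo,
       truth = truth)
}

#' Generate a seeded synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of synthetic cases, each with `case_id`, `label`
#'   (`"sarcoma"`/`"leiomyoma"`), `age`, `image`, `tumor_mask`,
#'   `myometrium_mask` (possibly NULL) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "cohort"), {
    n <- spec$n_sarcoma + spec$n_leiomyoma
    labels <- rep(c("sarcoma", "leiomyoma"),
                  c(spec$n_sarcoma, spec$n_leiomyoma))
    ages <- c(
      rnorm_trunc_min(spec$n_sarcoma, spec$age_mean_sarcoma,
                      spec$age_sd_sarcoma, 18),
      rnorm_trunc_min(spec$n_leiomyoma, spec$age_mean_leiomyoma,
                      spec$age_sd_leiomyoma, 18)
    )
    myo_flags <- logical(n)
    for (lab in c("sarcoma", "leiomyoma")) {
      idx <- which(labels == lab)
      k <- round(spec$myometrium_fraction * length(idx))
      if (k > 0) myo_flags[sample(idx, k)] <- TRUE
    }
    lapply(seq_len(n), function(i) {
      params <- if (labels[i] == "sarcoma") spec$texture_sarcoma
                else spec$texture_leiomyoma
      les <- synthesize_lesion(
        params, spec$image_height, spec$image_width,
        pixel_spacing_mm = spec$pixel_spacing_mm,
        cyst_exclusion_mm = spec$cyst_exclusion_mm,
        with_myometrium = myo_flags[i]
      )
      list(case_id = sprintf("case_%04d", i), label = labels[i],
           age = ages[i], image = les$image, tumor_mask = les$tumor_mask,
           myometrium_mask = les$myometrium_mask, truth = les$truth)
    })
  })
}

#' Write a cohort to disk (PNG images + masks + CSV manifest)
#'
#' @param cases output of [generate_cohort()].
#' @param directory output directory (created if needed).
#' @param image_format `"png"` (default) or `"dicom"` for the images;
#'   masks are always 0/255 PNG.
#' @return path of the written manifest CSV, invisibly.
#' @export
write_cohort <- function(cases, directory, image_format = c("png", "dicom")) {
  image_format <- match.arg(image_format)
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0)
    usr_stop("usr_io_error", paste("cannot write to", directory))
  ext <- if (image_format == "png") ".png" else ".dcm"
  rows <- lapply(cases, function(cs) {
    ipath <- file.path(directory, paste0(cs$case_id, ext))
    if (image_format == "png") {
      write_grayscale_png(cs$image, ipath)
    } else {
      write_dicom_image(cs$image$pixels, ipath,
                        pixel_spacing = cs$image$pixel_spacing)
    }
    tpath <- file.path(directory, paste0(cs$case_id, "_tumor.png"))
    write_mask_png(cs$tumor_mask, tpath)
    mpath <- NA_character_
    if (!is.null(cs$myometrium_mask)) {
      mpath <- file.path(directory, paste0(cs$case_id, "_myo.png"))
      write_mask_png(cs$myometrium_mask, mpath)
    }
    data.frame(case_id = cs$case_id, label = cs$label, age = cs$age,
               image_path = ipath, tumor_mask_path = tpath,
               myometrium_mask_path = mpath, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a manifest CSV
#'
#' Reads the images and masks referenced by a [write_cohort()] manifest (or
#' any manifest with the same columns) back into the in-memory case format.
#'
#' @param manifest_path path to the manifest CSV.
#' @return list of cases as in [generate_cohort()] (without `truth`).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    usr_stop("usr_io_error", paste("no such manifest:", manifest_path))
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("case_id", "label", "age", "image_path", "tumor_mask_path")
  if (!all(need %in% names(man)))
    usr_stop("usr_io_error", "manifest is missing required columns")
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i) {
    ip <- resolve(man$image_path[i])
    tp <- resolve(man$tumor_mask_path[i])
    if (!file.exists(ip) || !file.exists(tp))
      usr_stop("usr_io_error",
               paste0("missing image or mask for case ", man$case_id[i]))
    myo <- NULL
    mp <- man$myometrium_mask_path[i]
    if (!is.null(mp) && !is.na(mp) && nzchar(mp)) {
      mp <- resolve(mp)
      if (!file.exists(mp))
        usr_stop("usr_io_error",
                 paste0("missing myometrium mask for case ", man$case_id[i]))
      myo <- read_mask(mp)
    }
    list(case_id = man$case_id[i], label = man$label[i], age = man$age[i],
         image = read_grayscale(ip), tumor_mask = read_mask(tp),
         myometrium_mask = myo)
  })
}
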