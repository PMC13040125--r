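# Radiomics feature families. The fixed 74-feature list is 17 first-order
# statistics computed on z-scored continuous intensities plus 57 textural
# features (25 co-occurrence, 16 run-length, 16 size-zone) computed on the
# 32-level fixed-bin discretization. Formulas follow the IBSI reference
# definitions; entropies use log base 2 with 0*log(0) = 0.

# four 2D directions: 0, 90, 45, 135 degrees
texture_offsets <- function(distance = 1L) {
  matrix(as.integer(distance * c(0, 1, 1, 1,   # drow
                                 1, 0, 1, -1)), # dcol
         ncol = 2L)
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order (histogram) statistics of in-ROI intensities
#'
#' Seventeen statistics of the continuous (z-scored) intensity sample:
#' mean, variance, SD, skewness, excess kurtosis (population moments),
#' median, minimum, maximum, 10th/90th percentiles, interquartile range,
#' range, mean absolute deviation, root mean square, energy, and histogram
#' entropy/uniformity over a fixed-bin-number histogram.
#'
#' @param values numeric vector of in-ROI intensities (>= 2 pixels).
#' @param n_bins histogram bins for entropy/uniformity (default 32).
#' @return named numeric vector of the 17 `F_stat.*` features.
#' @export
first_order_features <- function(values, n_bins = 32L) {
  if (length(values) < 2L)
    usr_stop("usr_degenerate_roi", "need at least 2 in-ROI pixels")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)   # population moments, IBSI convention
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  qs <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                 type = 7)
  lo <- min(values); hi <- max(values)
  if (hi > lo) {
    k <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    p <- tabulate(k, n_bins) / n
  } else {
    p <- c(1, rep(0, n_bins - 1L))
  }
  c(F_stat.mean = mu,
    F_stat.var = m2,
    F_stat.sd = sqrt(m2),
    F_stat.skew = if (m2 > 0) m3 / m2^1.5 else 0,
    F_stat.kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    F_stat.median = qs[3],
    F_stat.min = lo,
    F_stat.max = hi,
    F_stat.p10 = qs[1],
    F_stat.p90 = qs[5],
    F_stat.iqr = qs[4] - qs[2],
    F_stat.range = hi - lo,
    F_stat.mad = mean(abs(values - mu)),
    F_stat.rms = sqrt(mean(values^2)),
    F_stat.energy = sum(values^2),
    F_stat.entropy = -sum(xlog2(p)),
    F_stat.uniformity = sum(p^2))
}

#' Gray-level co-occurrence matrix
#'
#' Counts of in-ROI gray-level pairs at the given distance over the four 2D
#' directions (0/45/90/135 degrees), symmetrized (each pair counted in both
#' orders), pooled into a single matrix and normalized to sum 1.
#'
#' @param droi a `discretized_roi` from [discretize()].
#' @param distance pixel displacement, default 1.
#' @param offsets optional k x 2 matrix of (drow, dcol) displacements
#'   overriding the default four directions (used by tests).
#' @return normalized symmetric `n_gray x n_gray` matrix of class `glcm`.
#' @export
glcm <- function(droi, distance = 1L, offsets = NULL) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (is.null(offsets)) offsets <- texture_offsets(distance)
  storage.mode(offsets) <- "integer"
  P <- .glcm_counts(droi$levels, droi$n_gray, offsets)
  tot <- sum(P)
  if (tot == 0)
    usr_stop("usr_degenerate_roi", "no valid in-ROI pixel pair for GLCM")
  structure(P / tot, class = c("glcm", "matrix"))
}

#' Co-occurrence features from a normalized GLCM
#'
#' The 25-feature IBSI-consistent co-occurrence set, including joint entropy
#' \eqn{-\sum p \log_2 p}, inverse variance \eqn{\sum_{i \ne j} p_{ij}/(i-j)^2},
#' cluster shade \eqn{\sum (i+j-2\mu)^3 p_{ij}}, information correlation 2
#' \eqn{\sqrt{1-e^{-2(HXY2-HXY)}}} and angular second moment (energy).
#' Correlation-type features are returned as `NA` for single-gray-level ROIs.
#'
#' @param P normalized symmetric co-occurrence matrix.
#' @return named numeric vector of the 25 `F_cm.*` features.
#' @export
glcm_features <- function(P) {
  P <- unclass(as.matrix(P))
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)  # symmetric: px == py
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)

  dvals <- 0:(ng - 1)
  pd <- vapply(dvals, function(k) sum(P[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  ps <- vapply(svals, function(k) sum(P[(i + j) == k]), numeric(1))

  hxy <- -sum(xlog2(P))
  hx <- -sum(xlog2(px))
  pij_marg <- outer(px, px)
  hxy1 <- -sum(ifelse(pij_marg > 0, P * log2(pij_marg), 0))
  hxy2 <- -sum(xlog2(pij_marg))
  single <- sum(px > 0) <= 1L

  diff_avg <- sum(dvals * pd)
  sum_avg <- sum(svals * ps)
  c(F_cm.joint.max = max(P),
    F_cm.joint.avg = mu,
    F_cm.joint.var = sum((i - mu)^2 * P),
    F_cm.joint.entr = hxy,
    F_cm.diff.avg = diff_avg,
    F_cm.diff.var = sum((dvals - diff_avg)^2 * pd),
    F_cm.diff.entr = -sum(xlog2(pd)),
    F_cm.sum.avg = sum_avg,
    F_cm.sum.var = sum((svals - sum_avg)^2 * ps),
    F_cm.sum.entr = -sum(xlog2(ps)),
    F_cm.energy = sum(P^2),
    F_cm.contrast = sum((i - j)^2 * P),
    F_cm.dissimilarity = sum(abs(i - j) * P),
    F_cm.inv.diff = sum(P / (1 + abs(i - j))),
    F_cm.inv.diff.norm = sum(P / (1 + abs(i - j) / ng)),
    F_cm.inv.diff.mom = sum(P / (1 + (i - j)^2)),
    F_cm.inv.diff.mom.norm = sum(P / (1 + (i - j)^2 / ng^2)),
    F_cm.inv.var = sum(P[i != j] / (i - j)[i != j]^2),
    F_cm.corr = if (single || sig2 == 0) NA_real_ else
      (sum(i * j * P) - mu^2) / sig2,
    F_cm.auto.corr = sum(i * j * P),
    F_cm.clust.tend = sum((i + j - 2 * mu)^2 * P),
    F_cm.clust.shade = sum((i + j - 2 * mu)^3 * P),
    F_cm.clust.prom = sum((i + j - 2 * mu)^4 * P),
    F_cm.info.corr.1 = if (single || hx == 0) NA_real_ else
      (hxy - hxy1) / hx,
    F_cm.info.corr.2 = if (single) NA_real_ else
      sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)))
}

#' Gray-level run-length matrix
#'
#' Maximal same-level pixel runs collected over the four 2D directions and
#' pooled; runs are broken by the ROI mask.
#'
#' @param droi a `discretized_roi`.
#' @param offsets optional direction override (k x 2 matrix), as in [glcm()].
#' @return integer matrix (gray level x run length) of class `rlm`.
#' @export
rlm <- function(droi, offsets = NULL) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (!any(droi$levels > 0))
    usr_stop("usr_degenerate_roi", "empty ROI")
  if (is.null(offsets)) offsets <- texture_offsets(1L)
  storage.mode(offsets) <- "integer"
  R <- .rlm_counts(droi$levels, droi$n_gray, offsets)
  lmax <- max(1L, which(colSums(R) > 0))  # drop unreachable run lengths
  structure(R[, seq_len(lmax), drop = FALSE], class = c("rlm", "matrix"))
}

#' Run-length features
#'
#' The 16-feature run-length set, including long-run high-gray-level emphasis
#' \eqn{\sum R(g,l) l^2 g^2 / N_r} and gray-level non-uniformity
#' \eqn{\sum_g (\sum_l R(g,l))^2 / N_r}.
#'
#' @param R run-length count matrix from [rlm()].
#' @return named numeric vector of the 16 `F_rlm.*` features.
#' @export
rlm_features <- function(R) {
  R <- unclass(as.matrix(R))
  nr <- sum(R)
  if (nr == 0) usr_stop("usr_degenerate_roi", "no runs")
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  rg <- rowSums(R); rl <- colSums(R)
  np <- sum(l * R)
  gl <- seq_len(nrow(R)); ll <- seq_len(ncol(R))
  mug <- sum(g * R) / nr
  mul <- sum(l * R) / nr
  p <- R / nr
  c(F_rlm.sre = sum(rl / ll^2) / nr,
    F_rlm.lre = sum(rl * ll^2) / nr,
    F_rlm.lgre = sum(rg / gl^2) / nr,
    F_rlm.hgre = sum(rg * gl^2) / nr,
    F_rlm.srlge = sum(R / (g^2 * l^2)) / nr,
    F_rlm.srhge = sum(R * g^2 / l^2) / nr,
    F_rlm.lrlge = sum(R * l^2 / g^2) / nr,
    F_rlm.lrhge = sum(R * g^2 * l^2) / nr,
    F_rlm.glnu = sum(rg^2) / nr,
    F_rlm.glnu.norm = sum(rg^2) / nr^2,
    F_rlm.rlnu = sum(rl^2) / nr,
    F_rlm.rlnu.norm = sum(rl^2) / nr^2,
    F_rlm.r.perc = nr / np,
    F_rlm.gl.var = sum((g - mug)^2 * p),
    F_rlm.rl.var = sum((l - mul)^2 * p),
    F_rlm.rl.entr = -sum(xlog2(p)))
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal gray level within the ROI.
#'
#' @param droi a `discretized_roi`.
#' @return integer matrix (gray level x zone size) of class `szm`.
#' @export
szm <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (!any(droi$levels > 0))
    usr_stop("usr_degenerate_roi", "empty ROI")
  structure(.szm_counts(droi$levels, droi$n_gray),
            class = c("szm", "matrix"))
}

#' Size-zone features
#'
#' The 16-feature size-zone set, including large-zone emphasis
#' \eqn{\sum S(g,s) s^2 / N_z} and gray-level non-uniformity
#' \eqn{\sum_g (\sum_s S(g,s))^2 / N_z}.
#'
#' @param S size-zone count matrix from [szm()].
#' @return named numeric vector of the 16 `F_szm.*` features.
#' @export
szm_features <- function(S) {
  S <- unclass(as.matrix(S))
  nz <- sum(S)
  if (nz == 0) usr_stop("usr_degenerate_roi", "no zones")
  g <- matrix(seq_len(nrow(S)), nrow(S), ncol(S))
  s <- matrix(seq_len(ncol(S)), nrow(S), ncol(S), byrow = TRUE)
  sg <- rowSums(S); ss <- colSums(S)
  np <- sum(s * S)
  gl <- seq_len(nrow(S)); sl <- seq_len(ncol(S))
  mug <- sum(g * S) / nz
  mus <- sum(s * S) / nz
  p <- S / nz
  c(F_szm.sze = sum(ss / sl^2) / nz,
    F_szm.lze = sum(ss * sl^2) / nz,
    F_szm.lgze = sum(sg / gl^2) / nz,
    F_szm.hgze = sum(sg * gl^2) / nz,
    F_szm.szlge = sum(S / (g^2 * s^2)) / nz,
    F_szm.szhge = sum(S * g^2 / s^2) / nz,
    F_szm.lzlge = sum(S * s^2 / g^2) / nz,
    F_szm.lzhge = sum(S * g^2 * s^2) / nz,
    F_szm.glnu = sum(sg^2) / nz,
    F_szm.glnu.norm = sum(sg^2) / nz^2,
    F_szm.zsnu = sum(ss^2) / nz,
    F_szm.zsnu.norm = sum(ss^2) / nz^2,
    F_szm.z.perc = nz / np,
    F_szm.gl.var = sum((g - mug)^2 * p),
    F_szm.zs.var = sum((s - mus)^2 * p),
    F_szm.zs.entr = -sum(xlog2(p)))
}

#' The fixed 74-feature schema
#'
#' @return data.frame with columns `name` and `family` (17 first-order,
#'   25 co-occurrence, 16 run-length, 16 size-zone).
#' @export
feature_schema <- function() {
  tiny <- structure(list(levels = matrix(c(1L, 2L, 1L, 2L), 2), n_gray = 2L),
                    class = "discretized_roi")
  nm <- c(names(first_order_features(c(1, 2, 3))),
          names(glcm_features(glcm(tiny))),
          names(rlm_features(rlm(tiny))),
          names(szm_features(szm(tiny))))
  data.frame(name = nm,
             family = sub("\\..*$", "", sub("^F_", "", nm)),
             stringsAsFactors = FALSE)
}

#' Write the feature schema as JSON
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_schema <- function(path) {
  jsonlite::write_json(feature_schema(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract the full 74-feature radiomics vector for one image + ROI
#'
#' Runs the preprocessing chain (adaptive Wiener filter, within-ROI z-score)
#' and computes first-order features on the continuous standardized
#' intensities and matrix features on the fixed-bin discretization. A
#' degenerate ROI yields an all-`NA` vector with the cause attached as
#' attribute `"cause"` rather than an error.
#'
#' @param image [grayscale_image()] or matrix.
#' @param mask ROI mask.
#' @param config a [preprocess_config()].
#' @return named numeric vector of length 74.
#' @export
extract_all <- function(image, mask, config = preprocess_config()) {
  schema <- feature_schema()$name
  out <- tryCatch({
    filt <- wiener_denoise(image, config$wiener_kernel)
    z <- zscore_roi(filt, mask)
    droi <- discretize(z, mask, config$n_gray_levels)
    c(first_order_features(z$pixels[as.matrix(mask)],
                           n_bins = config$n_gray_levels),
      glcm_features(glcm(droi)),
      rlm_features(rlm(droi)),
      szm_features(szm(droi)))
  }, usr_degenerate_roi = function(e) {
    v <- setNames(rep(NA_real_, length(schema)), schema)
    attr(v, "cause") <- conditionMessage(e)
    v
  })
  stopifnot(identical(names(out), schema) || all(is.na(out)))
  out
}

#' Delta-radiomics ratios (tumor / tumor-free myometrium)
#'
#' Elementwise ratio of the tumor feature vector to the same-patient
#' myometrium feature vector; entries with zero or missing denominator are
#' returned as `NA` rather than infinite.
#'
#' @param tumor_fv,myometrium_fv named feature vectors sharing names.
#' @return named numeric vector of ratios over the shared names.
#' @export
delta_features <- function(tumor_fv, myometrium_fv) {
  shared <- intersect(names(tumor_fv), names(myometrium_fv))
  if (length(shared) == 0L)
    usr_stop("usr_schema_error", "feature vectors share no names")
  num <- tumor_fv[shared]
  den <- myometrium_fv[shared]
  out <- ifelse(is.na(den) | den == 0 | is.na(num), NA_real_, num / den)
  setNames(as.numeric(out), shared)
}

#' Build a cases-by-features table from a cohort
#'
#' @param cases list of cases from [generate_cohort()] or [read_cohort()].
#' @param config a [preprocess_config()].
#' @param roi `"tumor"` or `"myometrium"` (cases without a myometrium mask
#'   are skipped for the latter).
#' @return data.frame with `case_id`, `label`, `age` and the 74 features.
#' @export
feature_table <- function(cases, config = preprocess_config(),
                          roi = c("tumor", "myometrium")) {
  roi <- match.arg(roi)
  if (roi == "myometrium")
    cases <- Filter(function(cs) !is.null(cs$myometrium_mask), cases)
  rows <- lapply(cases, function(cs) {
    m <- if (roi == "tumor") cs$tumor_mask else cs$myometrium_mask
    fv <- extract_all(cs$image, m, config)
    cbind(data.frame(case_id = cs$case_id, label = cs$label, age = cs$age,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$case_id))
    usr_stop("usr_schema_error", "duplicate case_ids in cohort")
  tab
}

#' Delta-radiomics table for the myometrium subset
#'
#' @param cases cohort case list; only cases with a myometrium mask enter.
#' @param config a [preprocess_config()].
#' @return data.frame with `case_id`, `label`, `age` and per-feature
#'   tumor/myometrium ratios.
#' @export
delta_feature_table <- function(cases, config = preprocess_config()) {
  eligible <- Filter(function(cs) !is.null(cs$myometrium_mask), cases)
  if (length(eligible) == 0L)
    usr_stop("usr_invalid_input", "no cases with a myometrium ROI")
  rows <- lapply(eligible, function(cs) {
    tfv <- extract_all(cs$image, cs$tumor_mask, config)
    mfv <- extract_all(cs$image, cs$myometrium_mask, config)
    dv <- delta_features(tfv, mfv)
    cbind(data.frame(case_id = cs$case_id, label = cs$label, age = cs$age,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(dv), check.names = FALSE))
  })
  do.call(rbind, rows)
}

feature_columns <- function(tab) {
  setdiff(names(tab), c("case_id", "label", "age"))
}
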