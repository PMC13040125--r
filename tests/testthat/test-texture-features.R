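test_that("first-order features match hand computations", {
  fv <- first_order_features(c(1, 2, 2, 3))
  expect_equal(unname(fv["F_stat.rms"]), sqrt(18 / 4))
  expect_equal(unname(fv["F_stat.mean"]), 2)
  expect_equal(unname(fv["F_stat.energy"]), 18)
  expect_length(fv, 17)
  expect_true(all(startsWith(names(fv), "F_stat.")))

  const <- first_order_features(rep(4.2, 10))
  expect_equal(unname(const["F_stat.var"]), 0)
  expect_equal(unname(const["F_stat.entropy"]), 0)
  expect_equal(unname(const["F_stat.uniformity"]), 1)
  expect_error(first_order_features(numeric(1)),
               class = "usr_degenerate_roi")
})

test_that("GLCM construction: enumeration, symmetry, normalization", {
  d <- make_droi(matrix(c(1L, 1L, 2L, 2L), 2, 2))  # [[1,2],[1,2]] by row
  horiz <- matrix(c(0L, 1L), 1, 2)
  P <- glcm(d, offsets = horiz)
  expect_equal(P[1, 2], 0.5, ignore_attr = TRUE)
  expect_equal(P[2, 1], 0.5, ignore_attr = TRUE)
  expect_equal(P[1, 1] + P[2, 2], 0, ignore_attr = TRUE)

  for (s in 1:10) {
    d <- random_droi(s)
    P <- glcm(d)
    expect_equal(sum(P), 1, ignore_attr = TRUE)
    expect_equal(unclass(P), t(unclass(P)), ignore_attr = TRUE)
  }

  single <- make_droi(matrix(1L, 3, 3), ng = 4)
  Ps <- glcm(single)
  expect_equal(Ps[1, 1], 1, ignore_attr = TRUE)
  lone <- make_droi(matrix(c(1L, 0L, 0L, 0L), 2, 2), ng = 2)
  expect_error(glcm(lone), class = "usr_degenerate_roi")
})

test_that("GLCM features match direct formula evaluation", {
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  fv <- glcm_features(P)
  expect_equal(unname(fv["F_cm.joint.entr"]), 1)    # 1 bit
  expect_equal(unname(fv["F_cm.energy"]), 0.5)
  expect_equal(unname(fv["F_cm.inv.var"]), 1)

  point <- matrix(0, 3, 3); point[1, 1] <- 1
  fp <- glcm_features(point)
  expect_equal(unname(fp["F_cm.joint.entr"]), 0)
  expect_equal(unname(fp["F_cm.energy"]), 1)
  expect_equal(unname(fp["F_cm.clust.shade"]), 0)
  expect_true(is.na(fp["F_cm.info.corr.2"]))  # single-level guard
  expect_length(fv, 25)
})

test_that("run-length matrix and features match hand enumeration", {
  d <- make_droi(matrix(c(1L, 1L, 2L), 1, 3))
  horiz <- matrix(c(0L, 1L), 1, 2)
  R <- rlm(d, offsets = horiz)
  expect_equal(sum(R), 2, ignore_attr = TRUE)     # two runs
  expect_equal(R[1, 2], 1, ignore_attr = TRUE)    # (g=1, l=2)
  expect_equal(R[2, 1], 1, ignore_attr = TRUE)    # (g=2, l=1)
  fv <- rlm_features(R)
  expect_equal(unname(fv["F_rlm.glnu"]), 1)
  expect_equal(unname(fv["F_rlm.lrhge"]), 4)
  expect_length(fv, 16)

  const <- make_droi(matrix(2L, 3, 3), ng = 2)
  Rc <- rlm(const, offsets = horiz)
  expect_equal(Rc[2, 3], 3, ignore_attr = TRUE)   # one length-3 run per row

  # conservation per direction: sum(count * length) = in-mask pixels
  for (s in 1:10) {
    d <- random_droi(s + 100)
    Rr <- rlm(d, offsets = horiz)
    lens <- matrix(seq_len(ncol(Rr)), nrow(Rr), ncol(Rr), byrow = TRUE)
    expect_equal(sum(Rr * lens), sum(d$levels > 0), ignore_attr = TRUE)
  }
})

test_that("size-zone matrix and features match hand enumeration", {
  d <- make_droi(matrix(c(1L, 2L, 1L, 2L), 2, 2))  # [[1,1],[2,2]] rows
  S <- szm(d)
  expect_equal(sum(S), 2, ignore_attr = TRUE)
  fv <- szm_features(S)
  expect_equal(unname(fv["F_szm.lze"]), 4)
  expect_equal(unname(fv["F_szm.glnu"]), 1)
  expect_length(fv, 16)

  const <- make_droi(matrix(1L, 4, 5))
  expect_equal(unname(szm_features(szm(const))["F_szm.lze"]), 400)  # n^2

  for (s in 1:10) {
    d <- random_droi(s + 200)
    Ss <- szm(d)
    sizes <- matrix(seq_len(ncol(Ss)), nrow(Ss), ncol(Ss), byrow = TRUE)
    expect_equal(sum(Ss * sizes), sum(d$levels > 0), ignore_attr = TRUE)
  }
})

test_that("extract_all emits the fixed 74-name schema deterministically", {
  cs <- get_small_cohort()[[1]]
  fv1 <- extract_all(cs$image, cs$tumor_mask)
  fv2 <- extract_all(cs$image, cs$tumor_mask)
  expect_length(fv1, 74)
  expect_identical(fv1, fv2)
  expect_identical(names(fv1), feature_schema()$name)
  expect_equal(sum(startsWith(names(fv1), "F_stat.")), 17)
  expect_equal(sum(!startsWith(names(fv1), "F_stat.")), 57)
  named <- c("F_stat.rms", "F_cm.joint.entr", "F_cm.inv.var",
             "F_cm.clust.shade", "F_cm.info.corr.2", "F_cm.energy",
             "F_rlm.lrhge", "F_rlm.glnu", "F_szm.lze", "F_szm.glnu")
  expect_true(all(named %in% names(fv1)))

  # affine intensity rescaling leaves every feature except the first-order
  # location/scale statistics unchanged via z-score + fixed bins; texture
  # features must be identical
  resc <- grayscale_image(3 * cs$image$pixels + 7)
  fv3 <- extract_all(resc, cs$tumor_mask)
  tex <- names(fv1)[!startsWith(names(fv1), "F_stat.")]
  expect_equal(fv1[tex], fv3[tex], tolerance = 1e-9)

  # degenerate ROI: all-missing vector with a cause, not an error
  flat <- grayscale_image(matrix(9, 32, 32))
  fvna <- extract_all(flat, roi_mask(matrix(TRUE, 32, 32)))
  expect_true(all(is.na(fvna)))
  expect_match(attr(fvna, "cause"), "SD")
})

test_that("delta features are guarded ratios over shared names", {
  a <- c(F_stat.rms = 2, F_cm.energy = 2.0, F_rlm.glnu = 1)
  b <- c(F_stat.rms = 2, F_cm.energy = 0.5, F_rlm.glnu = 0)
  d <- delta_features(a, b)
  expect_equal(unname(d["F_stat.rms"]), 1)
  expect_equal(unname(d["F_cm.energy"]), 4)
  expect_true(is.na(d["F_rlm.glnu"]))   # zero denominator -> missing
  expect_identical(delta_features(a, a), setNames(rep(1, 3), names(a)))
  expect_error(delta_features(a, c(x = 1)), class = "usr_schema_error")
})

test_that("generator calibration: named features separate the classes", {
  # the calibration property is stated for the default lesion geometry,
  # so use default-size images here (60/60 cases)
  spec <- cohort_spec(n_sarcoma = 60, n_leiomyoma = 60,
                      myometrium_fraction = 0, seed = 23)
  tab <- feature_table(generate_cohort(spec))
  sarc <- tab$label == "sarcoma"
  expect_gt(median(tab$F_cm.joint.entr[sarc]),
            median(tab$F_cm.joint.entr[!sarc]))
  # heterogeneous sarcoma lesions fragment into more, less uniform zones:
  # normalized gray-level uniformity is lower
  expect_lt(median(tab$F_szm.glnu.norm[sarc]),
            median(tab$F_szm.glnu.norm[!sarc]))
  expect_lt(wmw_test(tab$F_cm.joint.entr[sarc], tab$F_cm.joint.entr[!sarc]),
            0.05)
})
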