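test_that("stratified split reproduces the study's 70:30 design", {
  tab <- data.frame(case_id = sprintf("c%03d", 1:200),
                    label = rep(c("sarcoma", "leiomyoma"), each = 100))
  sp <- stratified_split(tab, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 140)
  expect_equal(nrow(sp$validation), 60)
  expect_equal(unname(table(sp$train$label)), c(70L, 70L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$validation$label)), c(30L, 30L),
               ignore_attr = TRUE)
  expect_length(intersect(sp$train$case_id, sp$validation$case_id), 0)

  tab2 <- data.frame(label = rep(c("a", "b"), each = 10))
  sp2 <- stratified_split(tab2, 0.5, seed = 1)
  expect_equal(unname(table(sp2$train$label)), c(5L, 5L),
               ignore_attr = TRUE)
  expect_identical(stratified_split(tab, 0.7, seed = 4)$train$case_id,
                   sp$train$case_id)
  expect_error(stratified_split(data.frame(label = rep("a", 5)), 0.7),
               class = "usr_invalid_input")
})

test_that("AUC equals all-pairs counting on random instances", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(0:1, 5)), 0.5)
  set.seed(20)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    r <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(roc_auc(r, y), bf_auc(r, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "usr_undefined_auc")
})

test_that("Youden cutoff equals exhaustive search with the stated ties", {
  expect_equal(youden_cutoff(c(0.1, 0.2, 0.3, 0.6, 0.8),
                             c(0, 0, 0, 1, 1)), 0.6)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    r <- round(runif(n), 2)
    expect_equal(youden_cutoff(r, y), bf_youden(r, y))
  }
  # order invariance
  r <- c(0.3, 0.9, 0.2, 0.8, 0.1); y <- c(0, 1, 0, 1, 0)
  o <- sample(5)
  expect_equal(youden_cutoff(r, y), youden_cutoff(r[o], y[o]))
  # perfectly interleaved risks: J = 0 at the degenerate (lowest) cutoff
  ri <- c(0.1, 0.2, 0.3, 0.4); yi <- c(1, 0, 1, 0)
  sens <- mean(ri[yi == 1] >= youden_cutoff(ri, yi))
  spec <- mean(ri[yi == 0] < youden_cutoff(ri, yi))
  expect_equal(sens + spec - 1, 0)
})

test_that("classification metrics reproduce the printed CI arithmetic", {
  # 80/100 positives detected -> 0.80 (0.72-0.88)
  y <- rep(1, 100); r <- c(rep(1, 80), rep(0, 20))
  cm <- classification_metrics(c(r, rep(0, 100)), c(y, rep(0, 100)), 0.5)
  expect_equal(cm$sensitivity, 0.80)
  expect_equal(round(cm$sensitivity_ci, 2), c(0.72, 0.88))
  # 95/100 negatives correct -> 0.95 (0.91-0.99)
  cm2 <- classification_metrics(c(rep(1, 10), rep(1, 5), rep(0, 95)),
                                c(rep(1, 10), rep(0, 100)), 0.5)
  expect_equal(cm2$specificity, 0.95)
  expect_equal(round(cm2$specificity_ci, 2), c(0.91, 0.99))
  # 87/100 -> (0.80-0.94)
  cm3 <- classification_metrics(c(rep(1, 87), rep(0, 13), rep(0, 50)),
                                c(rep(1, 100), rep(0, 50)), 0.5)
  expect_equal(round(cm3$sensitivity_ci, 2), c(0.80, 0.94))
  # all 30 negatives correct -> specificity 1 (1-1)
  cm4 <- classification_metrics(c(rep(1, 30), rep(0, 30)),
                                rep(c(1, 0), each = 30), 0.5)
  expect_equal(cm4$specificity, 1)
  expect_equal(cm4$specificity_ci, c(1, 1))
})

test_that("subjective assessments encode with uncertain treated as malignant", {
  # Table-2-style counts: 73 malignant + 7 uncertain of 100 sarcomas
  calls <- encode_subjective(c(rep("malignant", 73), rep("uncertain", 7),
                               rep("benign", 20)))
  expect_equal(sum(calls), 80)
  expect_equal(encode_subjective("benign"), 0L)
  expect_equal(encode_subjective("uncertain"), 1L)
  expect_error(encode_subjective("weird"), class = "usr_invalid_input")
})

test_that("Cohen's kappa matches hand computations", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0))$kappa, 1)
  # 2x2 agreement table [[20,5],[5,20]]: p_o = 0.8, p_e = 0.5 -> 0.6
  a <- c(rep(1, 25), rep(0, 25))
  b <- c(rep(1, 20), rep(0, 5), rep(1, 5), rep(0, 20))
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.8)
  expect_equal(k$chance_agreement, 0.5)
  expect_equal(k$kappa, 0.6)
  expect_equal(cohens_kappa(rep(1, 30), rbinom(30, 1, 0.5))$kappa, 0)
  expect_error(cohens_kappa(1:3, 1:4), class = "usr_invalid_input")
})

test_that("calibration recovers truth on Bernoulli-consistent risks", {
  set.seed(33)
  r <- runif(2000, 0.02, 0.98)
  y <- rbinom(2000, 1, r)
  cal <- calibration(r, y, n_boot = 50, seed = 1)
  expect_lt(abs(cal$slope - 1), 0.15)
  expect_lt(abs(cal$intercept), 0.15)
  expect_equal(nrow(cal$curve), 50)
  expect_true(all(cal$curve$lo <= cal$curve$hi, na.rm = TRUE))

  # risks too moderate by construction: outcomes follow expit(2 logit(r))
  y2 <- rbinom(2000, 1, plogis(2 * qlogis(r)))
  cal2 <- calibration(r, y2, n_boot = 10, seed = 2)
  expect_gt(cal2$slope, 1)

  # near-perfect risks: flagged, no crash
  r3 <- ifelse(rep(0:1, each = 50) == 1, 0.999, 0.001)
  expect_warning(cal3 <- calibration(r3, rep(0:1, each = 50), n_boot = 5))
  expect_true(cal3$separation)
  expect_gt(cal3$slope, 1)
})

test_that("train_and_select applies the training-AUC winner rule", {
  set.seed(50)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = y * 4 + rnorm(n, sd = 0.1), f2 = rnorm(n))  # separable
  tm <- train_and_select(X, y, model_config(n_search_draws = 2, seed = 1))
  expect_equal(max(tm$family_reports$train_auc), 1)
  expect_equal(tm$family_reports$classifier,
               c("logistic", "rf", "svm", "gbt"))
  risks <- predict_risk(tm, X)
  expect_true(all(risks >= 0 & risks <= 1))

  # stub scorer forces an exact AUC tie: sensitivity must break it
  stub <- function(risks, labels) 0.9
  tm2 <- train_and_select(X, y, model_config(n_search_draws = 2, seed = 1),
                          auc_fn = stub)
  rep2 <- tm2$family_reports
  expect_equal(tm2$kind,
               rep2$classifier[which.max(rep2$train_sensitivity)])
})

test_that("label-permuted training data yields chance-level CV scores", {
  set.seed(60)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- sample(rep(0:1, each = n / 2))
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
    tm <- train_and_select(X, y, model_config(n_search_draws = 2, seed = s))
    tm$family_reports$cv_auc[tm$family_reports$classifier == tm$kind]
  }, numeric(1))
  expect_gt(mean(aucs >= 0.3 & aucs <= 0.7), 0.7)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("delta-model 3-fold CV detects planted signal, not noise", {
  make_delta <- function(seed, signal) {
    set.seed(seed)
    n <- 64
    y <- rep(c("sarcoma", "leiomyoma"), each = n / 2)
    data.frame(label = y,
               F_cm.energy = rnorm(n) + signal * (y == "sarcoma"),
               F_rlm.glnu = rnorm(n) + 0.8 * signal * (y == "sarcoma"),
               stringsAsFactors = FALSE)
  }
  res <- vapply(1:10, function(s) {
    cv <- crossvalidate_delta_model(make_delta(s, 1.5), folds = 3, seed = s)
    c(cv$auc$mean, cv$auc$sd)
  }, numeric(2))
  expect_true(all(res[1, ] > 0.5 + 2e-6))
  expect_gt(mean(res[1, ] > 0.5 + 2 * res[2, ]), 0.8)

  null_auc <- vapply(1:5, function(s) {
    crossvalidate_delta_model(make_delta(s + 50, 0), folds = 3,
                              seed = s)$auc$mean
  }, numeric(1))
  expect_true(all(null_auc >= 0.2 & null_auc <= 0.8))
  expect_lt(abs(mean(null_auc) - 0.5), 0.2)

  cv1 <- crossvalidate_delta_model(make_delta(1, 1.5), folds = 3, seed = 9)
  cv2 <- crossvalidate_delta_model(make_delta(1, 1.5), folds = 3, seed = 9)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_error(crossvalidate_delta_model(make_delta(1, 1)[1:4, ], folds = 3),
               class = "usr_invalid_input")
})

test_that("cohort summary reproduces pooled descriptive arithmetic", {
  set.seed(70)
  mk <- function(n, mean) {
    x <- rnorm(n, mean, 5)
    x - mean(x) + mean  # exact group mean
  }
  tab <- data.frame(label = rep(c("leiomyoma", "sarcoma"), each = 100),
                    age = c(mk(100, 45), mk(100, 59)),
                    postmenopausal = c(rep(c("no", "yes"), c(89, 11)),
                                       rep(c("no", "yes"), c(32, 68))),
                    stringsAsFactors = FALSE)
  s <- summarize_cohort(tab)
  age_row <- s[s$variable == "age", ]
  expect_equal(age_row$pooled_mean, 52)  # mean of 45 and 59 at equal n
  pm <- s[s$variable == "postmenopausal" & s$level == "yes", ]
  expect_equal(pm$pooled_mean, 39.5)     # (11 + 68) / 200
  expect_lt(age_row$p_value, 0.001)

  tab2 <- data.frame(label = rep(c("a", "b"), each = 20),
                     v = rep(rnorm(20), 2))
  s2 <- summarize_cohort(tab2)
  expect_equal(s2$p_value[s2$variable == "v"], 1, tolerance = 1e-9)
})
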