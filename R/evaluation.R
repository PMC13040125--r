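# Evaluation quantities: ROC/AUC with bootstrap CIs, Youden cutoff,
# classification metrics with normal-approximation CIs, Cohen's kappa,
# calibration intercept/slope/flexible curve, the delta-model 3-fold CV,
# subjective-assessment encoding and descriptive cohort summaries.

#' Stratified train/validation split
#'
#' Per-class training counts are `round(fraction * class size)`; the split
#' is disjoint, exhaustive and seeded.
#'
#' @param tab data.frame with a `label` column.
#' @param train_fraction default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `validation` data.frames.
#' @export
stratified_split <- function(tab, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    usr_stop("usr_invalid_config", "train_fraction must be in (0, 1)")
  y <- as_binary_labels(tab$label)
  if (length(unique(y)) < 2L)
    usr_stop("usr_invalid_input", "both classes must be present")
  train_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      k <- round(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx, k))
    }
  })
  list(train = tab[sort(train_idx), , drop = FALSE],
       validation = tab[setdiff(seq_len(nrow(tab)), train_idx), ,
                        drop = FALSE])
}

#' Area under the ROC curve (Mann-Whitney rank form)
#'
#' Ties between a positive and a negative risk count 1/2.
#'
#' @param risks predicted risks.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(risks, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    usr_stop("usr_undefined_auc", "AUC undefined with one class absent")
  r <- rank(risks)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap CI for the AUC
#'
#' Stratified case resampling (each class resampled separately), percentile
#' 2.5/97.5 interval, seeded.
#'
#' @param risks,labels as in [roc_auc()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)`.
#' @export
auc_bootstrap_ci <- function(risks, labels, n_boot = 2000L, seed = 1L) {
  y <- as_binary_labels(labels)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  stats <- with_seed(derive_seed(seed, "auc_boot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      roc_auc(risks[idx], y[idx])
    }, numeric(1))
  })
  unname(quantile(stats, c(0.025, 0.975)))
}

#' Youden-index risk cutoff
#'
#' Candidate cutoffs are the observed risks; the classification rule is
#' "malignant iff risk >= cutoff"; `J = sensitivity + specificity - 1` is
#' maximized, ties broken toward the smallest cutoff (highest sensitivity).
#'
#' @param risks training risks.
#' @param labels training labels.
#' @return the cutoff.
#' @export
youden_cutoff <- function(risks, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    usr_stop("usr_invalid_input", "both classes must be present")
  cands <- sort(unique(risks))
  j <- vapply(cands, function(ct) {
    sens <- mean(risks[y == 1L] >= ct)
    spec <- mean(risks[y == 0L] < ct)
    sens + spec - 1
  }, numeric(1))
  cands[which.max(j)]  # which.max returns the first (smallest) maximizer
}

normal_ci <- function(p, n) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Classification metrics at a fixed cutoff
#'
#' Confusion counts with the "risk >= cutoff => malignant" rule;
#' sensitivity, specificity and accuracy with normal-approximation 95% CIs
#' `p +/- 1.96 sqrt(p(1-p)/n)` clipped to `[0, 1]`.
#'
#' @param risks predicted risks (or binary calls).
#' @param labels true labels.
#' @param cutoff training-derived risk cutoff.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy` and `*_ci` bounds.
#' @export
classification_metrics <- function(risks, labels, cutoff) {
  y <- as_binary_labels(labels)
  call <- as.integer(risks >= cutoff)
  tp <- sum(call == 1L & y == 1L); fn <- sum(call == 0L & y == 1L)
  tn <- sum(call == 0L & y == 0L); fp <- sum(call == 1L & y == 0L)
  n1 <- tp + fn; n0 <- tn + fp; n <- n1 + n0
  sens <- if (n1 > 0) tp / n1 else NA_real_
  spec <- if (n0 > 0) tn / n0 else NA_real_
  acc <- (tp + tn) / n
  list(tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff,
       sensitivity = sens, sensitivity_ci = normal_ci(sens, n1),
       specificity = spec, specificity_ci = normal_ci(spec, n0),
       accuracy = acc, accuracy_ci = normal_ci(acc, n))
}

#' Full performance report for one model on one split
#'
#' @param risks predicted risks.
#' @param labels true labels.
#' @param cutoff training-derived Youden cutoff.
#' @param n_boot AUC bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list of class `performance_report`.
#' @export
performance_report <- function(risks, labels, cutoff, n_boot = 2000L,
                               seed = 1L) {
  auc <- roc_auc(risks, labels)
  ci <- auc_bootstrap_ci(risks, labels, n_boot = n_boot, seed = seed)
  cm <- classification_metrics(risks, labels, cutoff)
  y <- as_binary_labels(labels)
  jj <- cm$sensitivity + cm$specificity - 1
  structure(c(list(auc = auc, auc_ci = ci, youden_j = jj), cm),
            class = "performance_report")
}

#' Encode a subjective ultrasound assessment as a binary call
#'
#' `benign` is negative; `uncertain` and `malignant` are positive (uncertain
#' diagnoses are treated as malignant).
#'
#' @param assessment character vector in
#'   `c("benign", "uncertain", "malignant")`.
#' @return integer 0/1 calls.
#' @export
encode_subjective <- function(assessment) {
  assessment <- as.character(assessment)
  bad <- setdiff(unique(assessment), c("benign", "uncertain", "malignant"))
  if (length(bad))
    usr_stop("usr_invalid_input",
             paste("unknown assessment category:", paste(bad, collapse = ", ")))
  as.integer(assessment != "benign")
}

#' Cohen's kappa between two binary raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with marginal-product chance agreement.
#'
#' @param calls_a,calls_b equal-length binary call vectors.
#' @return list with `kappa`, `observed_agreement`, `chance_agreement`.
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    usr_stop("usr_invalid_input", "call vectors must have equal length")
  a <- as.integer(calls_a); b <- as.integer(calls_b)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  kap <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(kappa = kap, observed_agreement = po, chance_agreement = pe)
}

#' Calibration intercept, slope and flexible curve
#'
#' Slope: coefficient of a logistic regression of outcome on `logit(risk)`.
#' Intercept: intercept of the same regression with the slope fixed at 1
#' (offset form). Flexible curve: loess of outcome on risk with a
#' percentile bootstrap band.
#'
#' @param risks predicted risks (clamped to `[1e-6, 1 - 1e-6]`).
#' @param labels outcomes.
#' @param n_boot bootstrap replicates for the curve band (default 2000).
#' @param seed seed.
#' @param curve_points number of grid points for the flexible curve.
#' @return list of class `calibration_report`: `intercept`, `slope`,
#'   `curve` (data.frame: predicted, observed, lo, hi), `separation` flag.
#' @export
calibration <- function(risks, labels, n_boot = 2000L, seed = 1L,
                        curve_points = 50L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    usr_stop("usr_invalid_input", "both classes must be present")
  r <- pmin(pmax(risks, 1e-6), 1 - 1e-6)
  lr <- stats::qlogis(r)
  separation <- FALSE
  handler <- function(w) {
    if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
      separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  slope_fit <- withCallingHandlers(
    glm(y ~ lr, family = binomial()), warning = handler)
  int_fit <- withCallingHandlers(
    glm(y ~ offset(lr), family = binomial()), warning = handler)
  # risks that perfectly separate the outcomes leave the recalibration
  # slope unbounded without necessarily tripping a glm warning; flag them
  if (max(lr[y == 0L]) < min(lr[y == 1L])) separation <- TRUE
  if (separation) usr_warn("possible separation in calibration fit")

  grid <- seq(min(r), max(r), length.out = curve_points)
  fit_curve <- function(rr, yy) {
    # loess needs spread in the predictor; (near-)constant risks get a
    # flat curve at the observed event rate instead of a crash
    if (diff(range(rr)) < 1e-6 || length(unique(rr)) < 4L)
      return(rep(mean(yy), length(grid)))
    lo <- tryCatch(
      suppressWarnings(loess(yy ~ rr, degree = 2, family = "symmetric")),
      error = function(e) NULL)
    if (is.null(lo)) return(rep(NA_real_, length(grid)))
    predict(lo, newdata = data.frame(rr = grid))
  }
  obs <- suppressWarnings(fit_curve(r, y))
  band <- with_seed(derive_seed(seed, "calib_boot"), {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(length(r), replace = TRUE)
      suppressWarnings(tryCatch(fit_curve(r[idx], y[idx]),
                                error = function(e)
                                  rep(NA_real_, length(grid))))
    }, numeric(length(grid)))
    t(apply(reps, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  })
  structure(list(
    intercept = unname(coef(int_fit)[1]),
    slope = unname(coef(slope_fit)["lr"]),
    curve = data.frame(predicted = grid, observed = obs,
                       lo = band[, 1], hi = band[, 2]),
    separation = separation
  ), class = "calibration_report")
}

#' 3-fold cross-validation of the delta-radiomics model
#'
#' Stratified folds; within each fold's training part, a stepwise-AIC
#' logistic model over the table's feature columns plus the Youden cutoff
#' of its training risks; metrics computed on the held-out fold and
#' aggregated as mean +/- SD over folds.
#'
#' @param delta_tab delta-feature table (feature columns + `label`).
#' @param labels optional labels (defaults to `delta_tab$label`).
#' @param folds number of folds (default 3).
#' @param seed integer seed.
#' @return list of class `delta_cv_report` with `auc`, `accuracy`,
#'   `sensitivity`, `specificity` (each `mean` and `sd`), and `per_fold`.
#' @export
crossvalidate_delta_model <- function(delta_tab, labels = NULL, folds = 3L,
                                      seed = 1L) {
  y <- as_binary_labels(labels %||% delta_tab$label)
  if (min(table(y)) < folds)
    usr_stop("usr_invalid_input",
             "each class must have at least `folds` cases")
  feats <- feature_columns(delta_tab)
  feats <- setdiff(feats, "age")
  fold <- make_stratified_folds(y, folds, derive_seed(seed, "delta_cv"))
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    sm <- stepwise_aic_logistic(delta_tab[tr, , drop = FALSE], y[tr], feats)
    r_tr <- predict(sm, delta_tab[tr, , drop = FALSE])
    cut <- youden_cutoff(r_tr, y[tr])
    r_te <- predict(sm, delta_tab[!tr, , drop = FALSE])
    cm <- classification_metrics(r_te, y[!tr], cut)
    c(auc = roc_auc(r_te, y[!tr]), accuracy = cm$accuracy,
      sensitivity = cm$sensitivity, specificity = cm$specificity)
  })
  m <- do.call(rbind, per_fold)
  agg <- lapply(colnames(m), function(cn)
    list(mean = mean(m[, cn]), sd = sd(m[, cn])))
  names(agg) <- colnames(m)
  structure(c(agg, list(per_fold = as.data.frame(m))),
            class = "delta_cv_report")
}

#' Descriptive cohort summary with between-group tests
#'
#' Continuous variables: per-group and pooled mean +/- SD with an
#' equal-variance two-sample t-test. Categorical: counts (%) with a
#' continuity-corrected chi-square test, or Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param tab data.frame including a binary `label` column.
#' @return data.frame, one row per variable (categorical variables one row
#'   per level), with group summaries and p-values.
#' @export
summarize_cohort <- function(tab) {
  y <- as_binary_labels(tab$label)
  g1 <- y == 1L; g0 <- y == 0L
  vars <- setdiff(names(tab), c("label", "case_id"))
  rows <- list()
  for (v in vars) {
    x <- tab[[v]]
    if (is.numeric(x)) {
      p <- tryCatch(t.test(x[g1], x[g0], var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        pooled = sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
                         sd(x, na.rm = TRUE)),
        group0 = sprintf("%.1f ± %.1f", mean(x[g0], na.rm = TRUE),
                         sd(x[g0], na.rm = TRUE)),
        group1 = sprintf("%.1f ± %.1f", mean(x[g1], na.rm = TRUE),
                         sd(x[g1], na.rm = TRUE)),
        pooled_mean = mean(x, na.rm = TRUE), p_value = p,
        stringsAsFactors = FALSE)
    } else {
      x <- as.factor(x)
      ct <- table(x, factor(y, levels = c(0, 1)))
      exp_counts <- outer(rowSums(ct), colSums(ct)) / sum(ct)
      p <- tryCatch({
        if (any(exp_counts < 5)) fisher.test(ct)$p.value
        else chisq.test(ct, correct = TRUE)$p.value
      }, error = function(e) NA_real_)
      for (lev in levels(x)) {
        n_all <- sum(x == lev, na.rm = TRUE)
        n0 <- sum(x == lev & g0, na.rm = TRUE)
        n1 <- sum(x == lev & g1, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev,
          pooled = sprintf("%d (%.1f)", n_all, 100 * n_all / length(x)),
          group0 = sprintf("%d (%.1f)", n0, 100 * n0 / sum(g0)),
          group1 = sprintf("%d (%.1f)", n1, 100 * n1 / sum(g1)),
          pooled_mean = 100 * n_all / length(x), p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
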