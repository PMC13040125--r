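# Classifier families and randomized hyperparameter search. Four families
# mirror the study: logistic regression, random forest, RBF support vector
# machine and gradient-boosted trees. The tree ensembles are in-package
# (src/trees.cpp); the SVM is a squared-hinge primal fit with Platt-scaled
# risks. Every model exposes predict_risk() in [0, 1].

CLASSIFIER_KINDS <- c("logistic", "rf", "svm", "gbt")

#' Model configuration
#'
#' @param classifiers classifier families to search over.
#' @param n_search_draws randomized-search draws per family (default 50).
#' @param cv_folds cross-validation folds (default 5).
#' @param feature_scaling `"pooled"` scales features by mean/SD across all
#'   cases (faithful to the study's wording); `"train"` is the leakage-safe
#'   alternative using training-set statistics only.
#' @param seed integer seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(classifiers = CLASSIFIER_KINDS, n_search_draws = 50L,
                         cv_folds = 5L, feature_scaling = c("pooled", "train"),
                         seed = 1L) {
  feature_scaling <- match.arg(feature_scaling)
  classifiers <- match.arg(classifiers, CLASSIFIER_KINDS, several.ok = TRUE)
  if (cv_folds < 2L) usr_stop("usr_invalid_config", "cv_folds must be >= 2")
  if (n_search_draws < 1L)
    usr_stop("usr_invalid_config", "n_search_draws must be >= 1")
  structure(list(classifiers = classifiers,
                 n_search_draws = as.integer(n_search_draws),
                 cv_folds = as.integer(cv_folds),
                 feature_scaling = feature_scaling,
                 seed = as.integer(seed)),
            class = "model_config")
}

draw_hyper <- function(kind, p) {
  switch(kind,
    logistic = list(),
    rf = list(n_tree = sample(c(200L, 300L, 500L), 1),
              mtry = sample(seq_len(max(1L, p)), 1),
              min_node = sample(c(1L, 2L, 5L, 10L), 1),
              max_depth = sample(c(4L, 8L, 16L), 1)),
    svm = list(cost = 2^runif(1, -5, 7),
               gamma = 2^runif(1, -9, 1)),
    gbt = list(nrounds = sample(c(50L, 100L, 200L, 300L), 1),
               eta = runif(1, 0.05, 0.3),
               max_depth = sample(2:5, 1),
               min_child = sample(c(1L, 3L, 5L, 10L), 1),
               lambda = runif(1, 0, 2),
               subsample = runif(1, 0.6, 1))
  )
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  exp(-gamma * pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0))
}

fit_svm_rbf <- function(X, y, cost, gamma) {
  ypm <- ifelse(y == 1L, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  obj <- function(par) {
    a <- par[1:n]; b <- par[n + 1]
    f <- as.numeric(K %*% a) + b
    s <- pmax(0, 1 - ypm * f)
    0.5 * sum(a * (K %*% a)) + cost * sum(s^2)
  }
  grad <- function(par) {
    a <- par[1:n]; b <- par[n + 1]
    f <- as.numeric(K %*% a) + b
    s <- pmax(0, 1 - ypm * f)
    ga <- as.numeric(K %*% (a - 2 * cost * s * ypm))
    c(ga, -2 * cost * sum(s * ypm))
  }
  fit <- optim(rep(0, n + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  a <- fit$par[1:n]; b <- fit$par[n + 1]
  dec <- as.numeric(K %*% a) + b
  platt <- suppressWarnings(glm(y ~ dec, family = binomial()))
  list(alpha = a, b = b, X = X, gamma = gamma, platt = coef(platt))
}

predict_svm_rbf <- function(m, X) {
  dec <- as.numeric(rbf_kernel(X, m$X, m$gamma) %*% m$alpha) + m$b
  stats::plogis(m$platt[1] + m$platt[2] * dec)
}

fit_classifier <- function(kind, X, y, hyper, seed = 1L) {
  X <- as.matrix(X)
  fit <- switch(kind,
    logistic = {
      dat <- as.data.frame(X); dat$.y <- y
      suppressWarnings(glm(.y ~ ., family = binomial(), data = dat))
    },
    rf = .rf_train(X, as.integer(y), hyper$n_tree %||% 300L,
                   min(hyper$mtry %||% max(1L, floor(sqrt(ncol(X)))),
                       ncol(X)),
                   hyper$min_node %||% 2L, hyper$max_depth %||% 16L,
                   derive_seed(seed, "rf")),
    svm = fit_svm_rbf(X, y, hyper$cost %||% 1, hyper$gamma %||% 1 / ncol(X)),
    gbt = .gbt_train(X, as.integer(y), hyper$nrounds %||% 100L,
                     hyper$eta %||% 0.1, hyper$max_depth %||% 3L,
                     hyper$min_child %||% 3L, hyper$lambda %||% 1,
                     hyper$subsample %||% 1, derive_seed(seed, "gbt")),
    usr_stop("usr_invalid_config", paste("unknown classifier:", kind))
  )
  structure(list(kind = kind, fit = fit, hyper = hyper,
                 features = colnames(X)),
            class = "usr_model")
}

#' Predicted risk of malignancy
#'
#' @param model a fitted `usr_model` (or `trained_model`).
#' @param X matrix/data.frame of cases with the model's feature columns.
#' @return numeric risks in `[0, 1]`.
#' @export
predict_risk <- function(model, X) {
  if (inherits(model, "trained_model")) return(predict_risk_trained(model, X))
  X <- as.matrix(as.data.frame(X)[, model$features, drop = FALSE])
  r <- switch(model$kind,
    logistic = {
      dat <- as.data.frame(X)
      as.numeric(predict(model$fit, newdata = dat, type = "response"))
    },
    rf = as.numeric(.forest_predict(model$fit$trees, X)),
    svm = as.numeric(predict_svm_rbf(model$fit, X)),
    gbt = as.numeric(.gbt_predict(model$fit, X))
  )
  pmin(pmax(r, 0), 1)
}

make_stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

cv_auc <- function(kind, hyper, X, y, folds = 5L, seed = 1L) {
  for (attempt in 1:3) {
    fold <- make_stratified_folds(y, folds,
                                  derive_seed(seed, paste0("cv", attempt)))
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[fold != f])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 3L)
      usr_stop("usr_invalid_input",
               "degenerate single-class training fold after 3 re-seeds")
  }
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    m <- fit_classifier(kind, X[tr, , drop = FALSE], y[tr], hyper,
                        seed = derive_seed(seed, paste0("fold", f)))
    if (length(unique(y[!tr])) < 2L) return(NA_real_)
    roc_auc(predict_risk(m, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

tune_classifier <- function(kind, X, y, n_draws = 50L, folds = 5L,
                            seed = 1L) {
  if (kind == "logistic") n_draws <- 1L  # no tunable hyperparameters
  best <- NULL
  with_seed(derive_seed(seed, paste0("tune_", kind)), {
    for (d in seq_len(n_draws)) {
      hy <- draw_hyper(kind, ncol(X))
      sc <- cv_auc(kind, hy, X, y, folds,
                   seed = derive_seed(seed, paste0(kind, "_draw", d)))
      if (is.null(best) || sc > best$score) best <- list(hyper = hy,
                                                         score = sc)
    }
  })
  best
}

#' Train all classifier families and apply the model-choice rule
#'
#' For each family, a randomized hyperparameter search scored by k-fold
#' cross-validated AUC on the training set; each family is then refit on the
#' full training set. The winner is the family with the highest training-set
#' AUC; exact ties are broken by training sensitivity at the Youden cutoff.
#'
#' @param X training feature matrix (already scaled).
#' @param y binary labels (0/1 or labels coercible via the package rules).
#' @param config a [model_config()].
#' @param auc_fn AUC scorer used for the winner rule (injectable for tests).
#' @return object of class `trained_model`: the winning `usr_model` plus
#'   `family_reports` (per-family training AUC/sensitivity and CV score),
#'   `train_cutoff` (Youden cutoff of the winner on training risks).
#' @export
train_and_select <- function(X, y, config = model_config(),
                             auc_fn = roc_auc) {
  y <- as_binary_labels(y)
  X <- as.matrix(as.data.frame(X))
  fams <- lapply(config$classifiers, function(kind) {
    tuned <- tune_classifier(kind, X, y, config$n_search_draws,
                             config$cv_folds, seed = config$seed)
    model <- fit_classifier(kind, X, y, tuned$hyper, seed = config$seed)
    risks <- predict_risk(model, X)
    auc <- auc_fn(risks, y)
    cut <- youden_cutoff(risks, y)
    cm <- classification_metrics(risks, y, cut)
    list(kind = kind, model = model, cv_auc = tuned$score, train_auc = auc,
         train_sensitivity = cm$sensitivity, cutoff = cut)
  })
  aucs <- vapply(fams, `[[`, numeric(1), "train_auc")
  sens <- vapply(fams, `[[`, numeric(1), "train_sensitivity")
  best_auc <- max(aucs)
  tied <- which(aucs == best_auc)
  winner <- fams[[tied[which.max(sens[tied])]]]
  reports <- data.frame(
    classifier = vapply(fams, `[[`, character(1), "kind"),
    cv_auc = vapply(fams, `[[`, numeric(1), "cv_auc"),
    train_auc = aucs, train_sensitivity = sens,
    stringsAsFactors = FALSE)
  structure(list(model = winner$model, kind = winner$kind,
                 hyper = winner$model$hyper,
                 train_cutoff = winner$cutoff,
                 family_reports = reports),
            class = "trained_model")
}

predict_risk_trained <- function(tm, X) predict_risk(tm$model, X)

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s, training cutoff %.3f>\n", x$kind,
              x$train_cutoff))
  print(x$family_reports, row.names = FALSE)
  invisible(x)
}

#' Z-score feature scaling statistics
#'
#' @param tab feature table; statistics computed over `cols`.
#' @param cols columns to scale.
#' @return list of `center` and `scale` vectors (zero SDs become 1).
#' @export
scaling_stats <- function(tab, cols) {
  center <- vapply(cols, function(f) mean(tab[[f]], na.rm = TRUE), numeric(1))
  scl <- vapply(cols, function(f) sd(tab[[f]], na.rm = TRUE), numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = center, scale = scl)
}

apply_scaling <- function(tab, stats) {
  for (f in names(stats$center))
    tab[[f]] <- (tab[[f]] - stats$center[[f]]) / stats$scale[[f]]
  tab
}
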