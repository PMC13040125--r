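# Feature-selection procedure: degenerate-column removal, univariate
# Wilcoxon-Mann-Whitney testing with Benjamini-Hochberg FDR control, and
# iterative Spearman correlation pruning at |rho| > 0.6. The delta-radiomics
# branch adds Boruta (shadow-feature random forest) and stepwise-AIC
# logistic selection.

#' Selection configuration
#'
#' @param alpha FDR significance level (default 0.05).
#' @param corr_threshold absolute Spearman correlation bound (default 0.6).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, corr_threshold = 0.6) {
  if (alpha <= 0 || alpha >= 1)
    usr_stop("usr_invalid_config", "alpha must be in (0, 1)")
  if (corr_threshold <= 0 || corr_threshold >= 1)
    usr_stop("usr_invalid_config", "corr_threshold must be in (0, 1)")
  structure(list(alpha = alpha, corr_threshold = corr_threshold,
                 fdr_method = "benjamini-hochberg"),
            class = "selection_config")
}

#' Remove features carrying no usable information
#'
#' Drops feature columns that are missing for all cases or identically zero
#' for all cases. The rule is deliberately literal: a constant nonzero
#' column is kept.
#'
#' @param tab feature table (data.frame; non-feature columns `case_id`,
#'   `label`, `age` are preserved).
#' @return list with `table` (filtered) and `dropped` (named character
#'   vector of dropped columns, values giving the cause).
#' @export
drop_degenerate <- function(tab) {
  feats <- feature_columns(tab)
  cause <- character(0)
  for (f in feats) {
    v <- tab[[f]]
    if (all(is.na(v))) {
      cause[f] <- "all-missing"
    } else if (all(!is.na(v)) && all(v == 0)) {
      cause[f] <- "constant-zero"
    }
  }
  list(table = tab[, setdiff(names(tab), names(cause)), drop = FALSE],
       dropped = cause)
}

#' Two-sided Wilcoxon-Mann-Whitney test
#'
#' Exact enumeration of the rank-sum distribution when both groups have at
#' most 8 observations and there are no ties; otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b numeric observation vectors for the two groups.
#' @return two-sided p-value.
#' @export
wmw_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    usr_stop("usr_invalid_input", "both groups need >= 1 observation")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  wa <- sum(r[seq_len(na)])
  ties <- any(duplicated(pooled))
  if (na <= 8L && nb <= 8L && !ties) {
    sums <- combn(r, na, sum)
    p <- 2 * min(mean(sums <= wa), mean(sums >= wa))
    return(min(p, 1))
  }
  n <- na + nb
  mu <- na * (n + 1) / 2
  tie_tab <- table(pooled)
  sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (wa - mu - sign(wa - mu) * 0.5) / sqrt(sig2)
  min(2 * pnorm(-abs(z)), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_i = min over j with p_j >= p_i of (m * p_j / rank_j)`, capped
#' at 1; input order is preserved.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    usr_stop("usr_invalid_input", "p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m * p[o] / rank(p, ties.method = "max")[o]))
  adj[order(o)]
}

#' Iterative Spearman correlation pruning
#'
#' While any pair of features has absolute Spearman correlation above the
#' threshold: take the pair with the largest |rho| (ties broken
#' lexicographically by name), retain the member with the lower mean |rho|
#' against all currently remaining features, drop the other, and recompute.
#'
#' @param x data.frame or matrix of feature values (columns = features).
#' @param corr_threshold bound on |rho| (default 0.6).
#' @return list with `retained` (names, original order),
#'   `dropped_correlated` (data.frame: dropped, partner, rho),
#'   `correlation_matrix` (|rho| over the input features).
#' @export
spearman_decorrelate <- function(x, corr_threshold = 0.6) {
  x <- as.data.frame(x)
  nms <- names(x)
  if (length(nms) == 0L)
    return(list(retained = character(0),
                dropped_correlated = data.frame(dropped = character(0),
                                                partner = character(0),
                                                rho = numeric(0)),
                correlation_matrix = matrix(numeric(0), 0, 0)))
  cm_full <- abs(cor(x, method = "spearman", use = "pairwise.complete.obs"))
  cm_full[is.na(cm_full)] <- 0
  alive <- nms
  dropped <- data.frame(dropped = character(0), partner = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  repeat {
    if (length(alive) < 2L) break
    cm <- cm_full[alive, alive, drop = FALSE]
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= corr_threshold) break
    hits <- which(cm == mx, arr.ind = TRUE)
    pairs <- t(apply(hits, 1, function(rc) {
      sort(c(alive[rc[1]], alive[rc[2]]))
    }))
    pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs[[1]], pairs[[2]]), , drop = FALSE]
    f1 <- pairs[1, 1]; f2 <- pairs[1, 2]
    mean_abs <- function(f) mean(cm[f, setdiff(alive, f)])
    m1 <- mean_abs(f1); m2 <- mean_abs(f2)
    # retain the member with the lower mean correlation
    drop <- if (m1 < m2) f2 else if (m2 < m1) f1 else max(f1, f2)
    keepr <- setdiff(c(f1, f2), drop)
    dropped <- rbind(dropped,
                     data.frame(dropped = drop, partner = keepr, rho = mx,
                                stringsAsFactors = FALSE))
    alive <- setdiff(alive, drop)
  }
  list(retained = nms[nms %in% alive], dropped_correlated = dropped,
       correlation_matrix = cm_full)
}

#' Full univariate + FDR + decorrelation selection
#'
#' The training-set selection chain: degenerate-column removal, per-feature
#' two-sided Wilcoxon-Mann-Whitney tests, Benjamini-Hochberg adjustment,
#' retention of features with adjusted p below `alpha`, then iterative
#' Spearman pruning of the significant set. Returns an audit trail.
#'
#' @param tab feature table (training split).
#' @param labels binary labels, positive class `"sarcoma"` (or logical/0-1).
#' @param config a [selection_config()].
#' @return object of class `selection_result`: `retained`,
#'   `dropped_degenerate`, `dropped_correlated`, `univariate`
#'   (feature, raw_p, adjusted_p, significant), `correlation_matrix`.
#' @export
select_features <- function(tab, labels, config = selection_config()) {
  y <- as_binary_labels(labels)
  dd <- drop_degenerate(tab)
  feats <- feature_columns(dd$table)
  feats <- setdiff(feats, "age")  # age is a clinical variable, not a feature
  raw_p <- vapply(feats, function(f) {
    v <- dd$table[[f]]
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2L) return(1)
    wmw_test(v[ok & y == 1L], v[ok & y == 0L])
  }, numeric(1))
  adj_p <- benjamini_hochberg(raw_p)
  uni <- data.frame(feature = feats, raw_p = raw_p, adjusted_p = adj_p,
                    significant = adj_p < config$alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  sig <- feats[uni$significant]
  if (length(sig) == 0L) {
    usr_warn("no feature survived FDR selection")
    dec <- list(retained = character(0),
                dropped_correlated = data.frame(dropped = character(0),
                                                partner = character(0),
                                                rho = numeric(0)),
                correlation_matrix = matrix(numeric(0), 0, 0))
  } else {
    dec <- spearman_decorrelate(dd$table[, sig, drop = FALSE],
                                config$corr_threshold)
  }
  structure(list(retained = dec$retained,
                 dropped_degenerate = dd$dropped,
                 dropped_correlated = dec$dropped_correlated,
                 univariate = uni,
                 correlation_matrix = dec$correlation_matrix,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result: %d tested, %d significant after FDR, %d retained>\n",
    nrow(x$univariate), sum(x$univariate$significant), length(x$retained)))
  if (length(x$retained)) cat(" ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Write the selection audit trail as JSON
#'
#' @param sel a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_audit <- function(sel, path) {
  jsonlite::write_json(
    list(retained = sel$retained,
         dropped_degenerate = as.list(sel$dropped_degenerate),
         dropped_correlated = sel$dropped_correlated,
         univariate = sel$univariate,
         config = unclass(sel$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1)))
      usr_stop("usr_invalid_input", "numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) > 2L)
    usr_stop("usr_invalid_input", "labels must be binary")
  pos <- if ("sarcoma" %in% u) "sarcoma" else u[length(u)]
  as.integer(labels == pos)
}

#' Boruta all-relevant feature selection
#'
#' Each iteration appends a shuffled shadow copy of every still-undecided
#' feature, fits a random-forest importance ranking, and scores a hit for
#' real features whose importance beats the best shadow. Features are
#' confirmed or rejected by two-sided binomial tests on the hit counts at
#' `alpha` with Holm step-down correction; undecided features are tentative.
#'
#' @param x data.frame/matrix of features.
#' @param y binary labels.
#' @param max_iter maximum iterations (default 100).
#' @param alpha decision level (default 0.05).
#' @param n_tree forest size per iteration (default 500).
#' @param seed RNG seed.
#' @return object of class `boruta_result`: `confirmed`, `rejected`,
#'   `tentative` (disjoint, union = inputs), `n_iterations`, `hits`.
#' @export
boruta <- function(x, y, max_iter = 100L, alpha = 0.05, n_tree = 500L,
                   seed = 1L) {
  y <- as_binary_labels(y)
  if (min(table(y)) < 5L)
    usr_stop("usr_invalid_input", "need >= 5 cases per class")
  x <- as.data.frame(x)
  x[] <- lapply(x, function(v) {
    v[is.na(v)] <- median(v, na.rm = TRUE)
    v
  })
  feats <- names(x)
  p <- length(feats)
  confirmed <- rejected <- character(0)
  hits <- setNames(integer(p), feats)
  it <- 0L
  with_seed(derive_seed(seed, "boruta"), {
    while (it < max_iter) {
      it <- it + 1L
      active <- setdiff(feats, rejected)
      shadows <- as.data.frame(lapply(x[active], sample))
      names(shadows) <- paste0(".shadow.", active)
      X <- as.matrix(cbind(x[active], shadows))
      fit <- .rf_train(X, as.integer(y), as.integer(n_tree),
                       max(1L, floor(sqrt(ncol(X)))), 5L, 12L,
                       derive_seed(seed, paste0("boruta_iter", it)))
      imp <- setNames(fit$importance, colnames(X))
      best_shadow <- max(imp[names(shadows)])
      beat <- active[imp[active] > best_shadow]
      hits[beat] <- hits[beat] + 1L
      undecided <- setdiff(active, confirmed)
      if (length(undecided)) {
        p_conf <- 1 - pbinom(hits[undecided] - 1L, it, 0.5)
        p_rej <- pbinom(hits[undecided], it, 0.5)
        conf_new <- undecided[stats::p.adjust(p_conf, "holm") < alpha]
        rej_new <- undecided[stats::p.adjust(p_rej, "holm") < alpha]
        confirmed <- union(confirmed, conf_new)
        rejected <- union(rejected, setdiff(rej_new, conf_new))
      }
      if (length(setdiff(feats, union(confirmed, rejected))) == 0L) break
    }
  })
  tentative <- setdiff(feats, union(confirmed, rejected))
  structure(list(confirmed = feats[feats %in% confirmed],
                 rejected = feats[feats %in% rejected],
                 tentative = tentative, n_iterations = it, hits = hits),
            class = "boruta_result")
}

#' Bidirectional stepwise logistic regression by AIC
#'
#' Starts from the model containing all candidates and repeatedly applies
#' the single addition or deletion that lowers `AIC = 2k - 2 logL` the most,
#' stopping when no move improves it. Perfect separation is flagged, not
#' fatal.
#'
#' @param tab data.frame holding the candidate columns.
#' @param labels binary labels.
#' @param candidates character vector of candidate feature names.
#' @return object of class `stepwise_model`: `features`, `coefficients`,
#'   `intercept`, `aic`, `separated` flag and the fitted `glm`.
#' @export
stepwise_aic_logistic <- function(tab, labels, candidates) {
  y <- as_binary_labels(labels)
  dat <- as.data.frame(tab)[, candidates, drop = FALSE]
  names(dat) <- make.names(names(dat))
  key <- setNames(candidates, make.names(candidates))
  dat$.y <- y
  separated <- FALSE
  fml <- if (length(candidates) == 0L) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(names(key), collapse = " + ")))
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  final <- if (length(candidates) == 0L) fit else
    withCallingHandlers(
      step(fit, direction = "both", trace = 0,
           scope = list(lower = .y ~ 1, upper = fml)),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
  if (separated)
    usr_warn("possible separation in stepwise logistic fit")
  co <- coef(final)
  chosen <- setdiff(names(co), "(Intercept)")
  structure(list(features = unname(key[chosen]),
                 coefficients = setNames(co[chosen], unname(key[chosen])),
                 intercept = unname(co["(Intercept)"]),
                 aic = final$aic, separated = separated, model = final,
                 name_key = key),
            class = "stepwise_model")
}

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  names(nd) <- make.names(names(nd))
  as.numeric(predict(object$model, newdata = nd, type = "response"))
}
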