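make_table <- function(n = 40, feats) {
  tab <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                    label = rep(c("sarcoma", "leiomyoma"), length.out = n),
                    age = runif(n, 30, 70), stringsAsFactors = FALSE)
  for (nm in names(feats)) tab[[nm]] <- feats[[nm]]
  tab
}

test_that("drop_degenerate removes exactly the all-missing and all-zero", {
  set.seed(1)
  feats <- c(
    setNames(lapply(1:7, function(i) rnorm(40)), paste0("keep", 1:7)),
    list(miss1 = rep(NA_real_, 40), miss2 = rep(NA_real_, 40),
         zero1 = rep(0, 40)))
  tab <- make_table(40, feats)
  dd <- drop_degenerate(tab)
  expect_setequal(usradiomics:::feature_columns(dd$table),
                  paste0("keep", 1:7))
  expect_setequal(names(dd$dropped), c("miss1", "miss2", "zero1"))
  # literal rule: constant nonzero column is kept
  tab2 <- make_table(10, list(const5 = rep(5, 10)))
  expect_true("const5" %in% names(drop_degenerate(tab2)$table))
  expect_length(drop_degenerate(tab2)$dropped, 0)
})

test_that("WMW test: exact enumeration, symmetry, and agreement with the
           tie-corrected normal reference", {
  expect_equal(wmw_test(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2 / choose(6,3)
  expect_equal(wmw_test(c(4, 5, 6), c(1, 2, 3)), 0.1)  # label swap
  x <- c(5, 1, 9, 3)
  expect_gt(wmw_test(x, x), 0.9)  # identical groups, p ~ 1
  expect_error(wmw_test(numeric(0), 1:3), class = "usr_invalid_input")
  # large-sample path against stats::wilcox.test as an independent oracle
  set.seed(42)
  for (i in 1:20) {
    a <- sample(1:8, 30, replace = TRUE) + rnorm(30, sd = 0.01 * (i %% 2))
    b <- sample(2:9, 25, replace = TRUE) + rnorm(25, sd = 0.01 * (i %% 2))
    ref <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(wmw_test(a, b), ref, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg matches hand computation and brute force", {
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "usr_invalid_input")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    got <- benjamini_hochberg(p)
    expect_equal(got, bf_benjamini_hochberg(p), tolerance = 1e-12)
    expect_equal(got, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12) && all(got <= 1))
  }
})

test_that("Spearman pruning retains the member with lower mean correlation", {
  set.seed(5)
  n <- 400
  a <- rnorm(n)
  b <- a + rnorm(n, sd = 0.18)          # |rho(a,b)| ~ 0.95
  c_ <- 0.55 * b + rnorm(n, sd = 1)     # moderate with b, weak with a via b
  x <- data.frame(A = a, B = b, C = c_ - 0.5 * a)
  cm <- abs(cor(x, method = "spearman"))
  # construction sanity: (A,B) is the top pair and B is more redundant
  expect_gt(cm["A", "B"], 0.6)
  expect_gt(mean(cm["B", c("A", "C")]), mean(cm["A", c("B", "C")]))
  res <- spearman_decorrelate(x, 0.6)
  expect_identical(res$retained, c("A", "C"))
  expect_identical(res$dropped_correlated$dropped, "B")
  expect_identical(res$dropped_correlated$partner, "A")
})

test_that("Spearman pruning invariants: bound always honored, duplicates
           collapse, uncorrelated sets untouched", {
  set.seed(77)
  for (i in 1:10) {
    n <- 60; p <- 12
    x <- as.data.frame(matrix(rnorm(n * p), n))
    # inject correlated blocks
    x[[2]] <- x[[1]] + rnorm(n, sd = 0.1)
    x[[3]] <- -x[[1]] + rnorm(n, sd = 0.2)
    res <- spearman_decorrelate(x, 0.6)
    if (length(res$retained) > 1) {
      cm <- abs(cor(x[res$retained], method = "spearman"))
      diag(cm) <- 0
      expect_lte(max(cm), 0.6)
    }
  }
  x2 <- data.frame(u = rnorm(50))
  x2$v <- x2$u  # |rho| = 1 duplicate
  res2 <- spearman_decorrelate(x2, 0.6)
  expect_length(res2$retained, 1)
  x3 <- as.data.frame(matrix(rnorm(300), 100, 3))
  expect_length(spearman_decorrelate(x3, 0.99)$retained, 3)
})


test_that("select_features recovers planted signal and controls the null", {
  for (s in 1:5) {
    tab <- planted_table(s)
    sel <- select_features(tab, tab$label)
    sig <- sel$univariate$feature[sel$univariate$significant]
    # most planted features clear FDR; noise admissions stay at the level
    # FDR promises (a false-discovery fraction near alpha)
    expect_gte(sum(paste0("inf", 1:8) %in% sig), 4)
    expect_lte(sum(startsWith(sig, "noise")), 3)
    expect_gt(length(sel$retained), 0)
    expect_true(all(sel$retained %in% sig))
  }

  # global null (labels carry no signal): BH admits anything at all in only
  # ~alpha of runs, so discoveries are almost always zero
  n_sig <- vapply(1:10, function(s) {
    tab <- planted_table(s + 1000, shift = 0)
    suppressWarnings(sel <- select_features(tab, tab$label))
    sum(sel$univariate$significant)
  }, numeric(1))
  expect_gte(mean(n_sig <= 1), 0.9)
})

test_that("select_features is deterministic and audits every feature", {
  tab <- planted_table(3)
  s1 <- select_features(tab, tab$label)
  s2 <- select_features(tab, tab$label)
  expect_identical(s1[names(s1) != "config"], s2[names(s2) != "config"])
  expect_equal(nrow(s1$univariate), 58)
  expect_true(all(s1$univariate$adjusted_p >= s1$univariate$raw_p - 1e-12))
  aud <- withr::local_tempfile(fileext = ".json")
  write_selection_audit(s1, aud)
  back <- jsonlite::read_json(aud, simplifyVector = TRUE)
  expect_identical(back$retained, s1$retained)
})

test_that("Boruta confirms planted features and rejects noise", {
  confirmed_hit <- 0; null_clean <- 0
  for (s in 1:10) {
    set.seed(s * 17)
    n <- 100
    y <- rep(0:1, each = n / 2)
    x <- as.data.frame(matrix(rnorm(n * 20), n))
    names(x) <- paste0("noise", 1:20)
    x$signal <- y + rnorm(n, sd = 0.1)
    br <- boruta(x, y, max_iter = 20, n_tree = 100, seed = s)
    expect_setequal(c(br$confirmed, br$rejected, br$tentative), names(x))
    expect_length(intersect(br$confirmed, br$rejected), 0)
    if ("signal" %in% br$confirmed) confirmed_hit <- confirmed_hit + 1
    brn <- boruta(x[paste0("noise", 1:20)], y, max_iter = 12, n_tree = 80,
                  seed = s + 500)
    if (length(brn$confirmed) == 0) null_clean <- null_clean + 1
  }
  expect_gte(confirmed_hit, 9)
  expect_gte(null_clean, 9)
  expect_error(boruta(data.frame(a = rnorm(6)), rep(0:1, 3)),
               class = "usr_invalid_input")
})

test_that("stepwise AIC logistic drops noise and honors its guarantees", {
  dropped_noise <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    y <- rep(0:1, each = n / 2)
    tab <- data.frame(inf = y + rnorm(n, sd = 0.8), noise = rnorm(n))
    sm <- stepwise_aic_logistic(tab, y, c("inf", "noise"))
    full <- glm(y ~ inf + noise, family = binomial(), data = tab)
    expect_lte(sm$aic, full$aic + 1e-9)
    if (!"noise" %in% sm$features) dropped_noise <- dropped_noise + 1
  }
  expect_gte(dropped_noise, 18)

  y0 <- rep(0:1, each = 10)
  m0 <- stepwise_aic_logistic(data.frame(x = rnorm(20)), y0, character(0))
  ll0 <- sum(log(ifelse(y0 == 1, 0.5, 0.5)))
  expect_equal(m0$aic, 2 - 2 * ll0)
  expect_length(m0$features, 0)
})
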