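# Pipeline orchestration: simulate -> extract -> select -> train -> evaluate
# -> delta, seeded end to end, with machine-readable JSON reports.

#' Full pipeline run configuration
#'
#' Exactly one of `cohort` (a [cohort_spec()], simulated input) or
#' `manifest` (path to an on-disk cohort manifest) must be given. The global
#' `seed` fans out to every stochastic stage via [derive_seed()].
#'
#' @param cohort optional [cohort_spec()].
#' @param manifest optional manifest CSV path.
#' @param preprocess a [preprocess_config()].
#' @param selection a [selection_config()].
#' @param model a [model_config()].
#' @param train_fraction training fraction of the stratified split.
#' @param out_dir output directory for the report bundle (NULL = no files).
#' @param seed global integer seed.
#' @param run_delta also run the delta-radiomics subanalysis when
#'   myometrium ROIs are available.
#' @param verbose print stage progress to stderr.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, manifest = NULL,
                       preprocess = preprocess_config(),
                       selection = selection_config(),
                       model = model_config(),
                       train_fraction = 0.7, out_dir = NULL, seed = 1L,
                       run_delta = TRUE, verbose = FALSE) {
  if (is.null(cohort) == is.null(manifest))
    usr_stop("usr_invalid_config",
             "exactly one of `cohort` or `manifest` must be given")
  structure(list(cohort = cohort, manifest = manifest,
                 preprocess = preprocess, selection = selection,
                 model = model, train_fraction = train_fraction,
                 out_dir = out_dir, seed = as.integer(seed),
                 run_delta = run_delta, verbose = verbose),
            class = "run_config")
}

stage_msg <- function(config, stage, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %s", stage, paste0(...)))
}

# FNV-1a hash of a deparsed object; wall-clock never enters, so provenance
# hashes are reproducible.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", h)
}

variant_matrix <- function(tab, retained, variant) {
  cols <- switch(variant,
    radiomics = retained,
    `clinical-radiomics` = c(retained, "age"),
    `age-only` = "age",
    usr_stop("usr_invalid_config", paste("unknown variant:", variant)))
  as.matrix(tab[, cols, drop = FALSE])
}

#' Run the complete radiomics pipeline
#'
#' Generates (or loads) the cohort, extracts the 74-feature table, splits
#' 70:30 stratified by class, selects features on the training split only,
#' trains the four classifier families for the radiomics,
#' clinical-radiomics and age-only variants, applies the training-derived
#' Youden cutoff to the validation split, and computes performance and
#' calibration reports. With `run_delta`, the tumor/myometrium delta
#' subanalysis is run on the eligible subset.
#'
#' @param config a [run_config()].
#' @param n_boot bootstrap replicates for CIs (default 2000).
#' @return object of class `report_bundle`.
#' @export
run_full_pipeline <- function(config, n_boot = 2000L) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  stage_msg(config, "cohort", "loading cases")
  cases <- if (!is.null(config$cohort)) {
    spec <- config$cohort
    spec$seed <- derive_seed(seed, "pipeline_cohort")
    generate_cohort(spec)
  } else {
    read_cohort(config$manifest)
  }

  stage_msg(config, "extract", length(cases), " cases")
  tab <- feature_table(cases, config$preprocess)

  stage_msg(config, "split", "stratified 70:30")
  sp <- stratified_split(tab, config$train_fraction, seed = seed)

  stage_msg(config, "select", "training-split feature selection")
  sel <- select_features(sp$train, sp$train$label, config$selection)
  retained <- sel$retained
  if (length(retained) == 0L)
    usr_warn("empty retained feature set; variants degenerate to age only")

  scale_cols <- unique(c(retained, "age"))
  scale_src <- if (config$model$feature_scaling == "pooled") tab else sp$train
  sstats <- scaling_stats(scale_src, scale_cols)
  train_s <- apply_scaling(sp$train, sstats)
  val_s <- apply_scaling(sp$validation, sstats)

  y_tr <- as_binary_labels(train_s$label)
  y_va <- as_binary_labels(val_s$label)

  variants <- if (length(retained) > 0L)
    c("radiomics", "clinical-radiomics", "age-only") else "age-only"
  models <- list(); reports <- list(); calib <- list()
  for (v in variants) {
    stage_msg(config, "train", v)
    mc <- config$model
    mc$seed <- derive_seed(seed, paste0("train_", v))
    Xtr <- variant_matrix(train_s, retained, v)
    tm <- train_and_select(Xtr, y_tr, mc)
    r_tr <- predict_risk(tm, Xtr)
    cut <- tm$train_cutoff
    Xva <- variant_matrix(val_s, retained, v)
    r_va <- predict_risk(tm, Xva)
    reports[[v]] <- list(
      train = performance_report(r_tr, y_tr, cut, n_boot = n_boot,
                                 seed = derive_seed(seed, paste0("pr_tr_", v))),
      validation = performance_report(r_va, y_va, cut, n_boot = n_boot,
                                      seed = derive_seed(seed,
                                                         paste0("pr_va_", v))))
    calib[[v]] <- calibration(r_va, y_va, n_boot = n_boot,
                              seed = derive_seed(seed, paste0("cal_", v)))
    models[[v]] <- tm
    models[[v]]$validation_risks <- r_va
    models[[v]]$validation_calls <- as.integer(r_va >= cut)
  }

  delta <- NULL
  if (isTRUE(config$run_delta) &&
      any(vapply(cases, function(cs) !is.null(cs$myometrium_mask),
                 logical(1)))) {
    stage_msg(config, "delta", "tumor/myometrium subanalysis")
    delta <- tryCatch(
      run_delta_subanalysis(cases, preprocess = config$preprocess,
                            seed = seed),
      usr_error = function(e) {
        usr_warn(paste("delta subanalysis skipped:", conditionMessage(e)))
        NULL
      })
  }

  bundle <- structure(list(
    feature_table = tab, split = sp, selection = sel, models = models,
    reports = reports, calibration = calib, delta = delta,
    provenance = list(
      seed = seed,
      config_hash = config_hash(config[setdiff(names(config),
                                               c("out_dir", "verbose"))]),
      package_version = as.character(utils::packageVersion("usradiomics")),
      n_cases = nrow(tab))
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

report_to_list <- function(pr) {
  list(auc = pr$auc, auc_ci = pr$auc_ci, cutoff = pr$cutoff,
       youden_j = pr$youden_j,
       accuracy = pr$accuracy, accuracy_ci = pr$accuracy_ci,
       sensitivity = pr$sensitivity, sensitivity_ci = pr$sensitivity_ci,
       specificity = pr$specificity, specificity_ci = pr$specificity_ci,
       confusion = c(tp = pr$tp, fp = pr$fp, tn = pr$tn, fn = pr$fn))
}

#' Write a report bundle to disk
#'
#' Feature table as CSV, selection audit and per-variant performance,
#' calibration and delta reports as JSON. Files are written to a staging
#' directory and renamed into place so a crashed run never leaves a
#' plausible-looking partial bundle.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  staging <- paste0(out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  if (!dir.create(staging, recursive = TRUE, showWarnings = FALSE))
    usr_stop("usr_io_error", paste("cannot create", staging))
  write.csv(bundle$feature_table, file.path(staging, "features.csv"),
            row.names = FALSE)
  write_selection_audit(bundle$selection, file.path(staging,
                                                    "selection_audit.json"))
  perf <- lapply(bundle$reports, function(rp)
    list(train = report_to_list(rp$train),
         validation = report_to_list(rp$validation)))
  winners <- lapply(bundle$models, function(m)
    list(classifier = m$kind, train_cutoff = m$train_cutoff,
         family_reports = m$family_reports))
  jsonlite::write_json(list(performance = perf, winners = winners,
                            provenance = bundle$provenance),
                       file.path(staging, "performance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (v in names(bundle$calibration)) {
    cal <- bundle$calibration[[v]]
    jsonlite::write_json(list(intercept = cal$intercept, slope = cal$slope,
                              separation = cal$separation,
                              curve = cal$curve),
                         file.path(staging, paste0("calibration_",
                                                   gsub("[^a-z]", "_", v),
                                                   ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$delta)) {
    d <- bundle$delta
    jsonlite::write_json(
      list(n_eligible = d$n_eligible,
           selected = d$selected,
           cutoff = d$cutoff,
           cv = lapply(d$cv[c("auc", "accuracy", "sensitivity",
                              "specificity")], identity)),
      file.path(staging, "delta_report.json"), auto_unbox = TRUE,
      digits = NA)
  }
  unlink(out_dir, recursive = TRUE)
  if (!file.rename(staging, out_dir))
    usr_stop("usr_io_error", paste("cannot move bundle into", out_dir))
  invisible(out_dir)
}

#' Delta-radiomics subanalysis
#'
#' Filters to cases with a tumor-free myometrium ROI, computes per-feature
#' tumor/myometrium ratios, selects features by raw-p Wilcoxon-Mann-Whitney
#' (p < 0.05), Boruta confirmation and Spearman decorrelation, fits a
#' stepwise-AIC logistic model, and internally validates it with stratified
#' 3-fold cross-validation (metrics as mean +/- SD over folds).
#'
#' @param cases cohort case list.
#' @param preprocess a [preprocess_config()].
#' @param seed integer seed.
#' @param folds CV folds (default 3).
#' @param wmw_alpha univariate screen level (default 0.05, raw p).
#' @param boruta_n_tree,boruta_max_iter Boruta forest size and iteration cap.
#' @return list of class `delta_report`: `n_eligible`, `selected`, `model`
#'   (stepwise fit on all eligible cases), `cutoff` (Youden on the fitted
#'   risks), `cv` (the 3-fold report), `boruta`.
#' @export
run_delta_subanalysis <- function(cases, preprocess = preprocess_config(),
                                  seed = 1L, folds = 3L, wmw_alpha = 0.05,
                                  boruta_n_tree = 500L,
                                  boruta_max_iter = 100L) {
  eligible <- Filter(function(cs) !is.null(cs$myometrium_mask), cases)
  y_all <- vapply(eligible, function(cs) cs$label, character(1))
  n_pos <- sum(y_all == "sarcoma"); n_neg <- sum(y_all != "sarcoma")
  if (length(eligible) == 0L || min(n_pos, n_neg) < folds)
    usr_stop("usr_invalid_input", sprintf(
      "too few eligible cases for the delta subanalysis (%d sarcoma, %d leiomyoma, need >= %d per class)",
      n_pos, n_neg, folds))
  dtab <- delta_feature_table(eligible, preprocess)
  y <- as_binary_labels(dtab$label)

  dd <- drop_degenerate(dtab)
  feats <- setdiff(feature_columns(dd$table), "age")
  # keep only features observed for (nearly) all eligible cases
  feats <- feats[vapply(feats, function(f)
    mean(is.na(dd$table[[f]])) <= 0.2, logical(1))]
  raw_p <- vapply(feats, function(f) {
    v <- dd$table[[f]]; ok <- !is.na(v)
    if (length(unique(v[ok])) < 2L) return(1)
    wmw_test(v[ok & y == 1L], v[ok & y == 0L])
  }, numeric(1))
  screened <- feats[raw_p < wmw_alpha]
  if (length(screened) == 0L)
    usr_stop("usr_invalid_input", "no delta feature passes the WMW screen")

  br <- boruta(dd$table[, screened, drop = FALSE], y,
               max_iter = boruta_max_iter, n_tree = boruta_n_tree,
               seed = derive_seed(seed, "delta_boruta"))
  kept <- if (length(br$confirmed)) br$confirmed else screened
  dec <- spearman_decorrelate(dd$table[, kept, drop = FALSE], 0.6)
  cand <- dec$retained

  sm <- stepwise_aic_logistic(dd$table, y, cand)
  risks <- predict(sm, dd$table)
  cutoff <- youden_cutoff(risks, y)
  cvtab <- dd$table[, c(if (length(sm$features)) sm$features else cand,
                        "label"), drop = FALSE]
  cv <- crossvalidate_delta_model(cvtab, y, folds = folds,
                                  seed = derive_seed(seed, "delta_cv"))
  structure(list(n_eligible = length(eligible), screened = screened,
                 boruta = br, selected = sm$features, model = sm,
                 cutoff = cutoff, cv = cv),
            class = "delta_report")
}

# ---------------------------------------------------------------------------
# command-line interface

cli_usage <- function() {
  paste(
    "usage: usradiomics <command> [options]",
    "",
    "commands:",
    "  simulate  --out DIR [--seed N] [--n-sarcoma N] [--n-leiomyoma N]",
    "  extract   --manifest CSV --out CSV",
    "  select    --features CSV --out JSON [--alpha A] [--corr-threshold T]",
    "  run-all   --out DIR [--seed N] [--manifest CSV] [--draws N]",
    "  delta     --manifest CSV --out JSON [--seed N]",
    sep = "\n")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      usr_stop("usr_invalid_config", paste("unexpected argument:", a))
    key <- gsub("-", "_", substring(a, 3))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `extract`, `select`, `run-all` and `delta`
#' subcommands (see `exec/usradiomics`).
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
usradiomics_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat(cli_usage(), "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- cli_opts(args[-1])
  seed <- as.integer(opts$seed %||% "1")
  switch(cmd,
    simulate = {
      spec <- cohort_spec(
        n_sarcoma = as.integer(opts$n_sarcoma %||% "100"),
        n_leiomyoma = as.integer(opts$n_leiomyoma %||% "100"),
        seed = seed)
      man <- write_cohort(generate_cohort(spec), opts$out)
      message("wrote ", man)
    },
    extract = {
      cases <- read_cohort(opts$manifest)
      tab <- feature_table(cases)
      write.csv(tab, opts$out, row.names = FALSE)
      message("wrote ", opts$out)
    },
    select = {
      tab <- read.csv(opts$features, check.names = FALSE)
      sel <- select_features(tab, tab$label, selection_config(
        alpha = as.numeric(opts$alpha %||% "0.05"),
        corr_threshold = as.numeric(opts$corr_threshold %||% "0.6")))
      write_selection_audit(sel, opts$out)
      message("wrote ", opts$out)
    },
    `run-all` = {
      cfg <- run_config(
        cohort = if (is.null(opts$manifest)) cohort_spec(seed = seed),
        manifest = opts$manifest,
        model = model_config(
          n_search_draws = as.integer(opts$draws %||% "50")),
        out_dir = opts$out, seed = seed, verbose = TRUE)
      run_full_pipeline(cfg)
      message("bundle written to ", opts$out)
    },
    delta = {
      cases <- read_cohort(opts$manifest)
      rep <- run_delta_subanalysis(cases, seed = seed)
      jsonlite::write_json(
        list(n_eligible = rep$n_eligible, selected = rep$selected,
             cutoff = rep$cutoff,
             cv = rep$cv[c("auc", "accuracy", "sensitivity",
                           "specificity")]),
        opts$out, auto_unbox = TRUE, digits = NA)
      message("wrote ", opts$out)
    },
    {
      cat(cli_usage(), "\n")
      return(invisible(1L))
    })
  invisible(0L)
}
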