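#' Feature columns of a feature-set mode
#'
#' The three modeling modes partition the 31-feature dictionary: 6
#' time-related features, 25 eye-movement-related features, or both.
#' Age is included in every mode.
#'
#' @param mode `"combined"`, `"time_only"` or `"eye_only"`.
#' @return Character vector of feature column names (including `age`).
#' @export
feature_set_cols <- function(mode = c("combined", "time_only",
                                      "eye_only")) {
  mode <- match.arg(mode)
  dict <- ocat_feature_dictionary()
  feats <- switch(mode,
                  combined = dict$name,
                  time_only = dict$name[dict$category == "time"],
                  eye_only = dict$name[dict$category == "eye"])
  c(feats, "age")
}

#' Run the screening pipeline end to end
#'
#' Orchestrates the full workflow on a synthetic cohort: simulate -> QC
#' (tracking-ratio exclusion, spike correction) -> feature extraction ->
#' preprocessing (log transform, stratified split, SMOTE on training
#' only, train-fitted standardization) -> two-step feature selection ->
#' model training and bootstrapped evaluation, for every combination of
#' feature-set mode, balancing arm and model. All stage artifacts are
#' written to `out_dir` as plain-text files, and a manifest records the
#' configuration, seeds and artifact checksums so identical configs
#' reproduce identical runs.
#'
#' @param config A list (or YAML file path) with optional entries:
#'   `cohort` ([cohort_spec()] arguments), `qc_threshold`,
#'   `feature_sets`, `balancing` (subset of `c("smote", "original")`),
#'   `models` (subset of `c("LR", "KNN")`), `thresholds` (LR decision
#'   thresholds), `test_fraction`, `select` (logical; run feature
#'   selection), `bootstrap_B`, `seed`, `out_dir`.
#' @return Invisibly, a list with `model_reports` (data.frame),
#'   `pr_curves`, `selection`, `features`, `qc` and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(cohort = list(), qc_threshold = 0.80,
         feature_sets = c("combined", "time_only", "eye_only"),
         balancing = c("smote", "original"),
         models = c("LR", "KNN"), thresholds = c(0.45, 0.5),
         test_fraction = 0.2, select = TRUE, bootstrap_B = 1000,
         seed = 1, out_dir = tempfile("ocat_run_")),
    config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  spec <- stage("simulate", do.call(cohort_spec, cfg$cohort))
  cohort <- stage("simulate", generate_cohort(spec))
  utils::write.csv(cohort$metadata,
                   file.path(cfg$out_dir, "cohort_metadata.csv"),
                   row.names = FALSE)

  ext <- stage("extract",
               extract_cohort_features(cohort, cfg$qc_threshold))
  utils::write.csv(ext$qc, file.path(cfg$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(ext$features,
                   file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)

  lg <- stage("prep", log_transform(ext$features))
  split <- stage("prep", stratified_split(lg$table, cfg$test_fraction,
                                          seed = cfg$seed))
  imp <- stage("prep", impute_fit(split$train))
  split$train <- impute_apply(imp, split$train)
  split$test <- impute_apply(imp, split$test)
  manifest_counts <- list(
    excluded = sum(!ext$qc$included),
    train = as.list(split$counts$train),
    test = as.list(split$counts$test))

  # feature selection runs once, on the balanced training table when
  # the SMOTE arm is part of the run (matching the workflow order:
  # preprocessing incl. balancing, then selection, then models); both
  # balancing arms then compare models over the same feature list
  sel <- if (isTRUE(cfg$select)) {
    sel_train <- if ("smote" %in% cfg$balancing) {
      smote(split$train, seed = cfg$seed + 1)
    } else split$train
    stage("select", select_features(sel_train, seed = cfg$seed + 2))
  } else NULL

  reports <- list(); curves <- list()
  for (bal in cfg$balancing) {
    train <- split$train
    if (bal == "smote") train <- smote(train, seed = cfg$seed + 1)
    for (mode in cfg$feature_sets) {
      feats <- feature_set_cols(mode)
      if (!is.null(sel)) {
        feats <- union(intersect(sel$selected, feats), "age")
      }
      scaler <- standardize_fit(train, feats)
      tr <- standardize_apply(scaler, train)
      te <- standardize_apply(scaler, split$test)
      for (mdl in cfg$models) {
        model <- stage("train", switch(mdl,
          LR = train_lr(tr, feats),
          KNN = train_knn(tr, feats, seed = cfg$seed + 3)))
        p <- predict_prob(model, te)
        dts <- if (mdl == "LR") cfg$thresholds else 0.5
        for (dt in dts) {
          bm <- stage("evaluate",
                      bootstrap_metrics(te$label, p, dt,
                                        B = cfg$bootstrap_B,
                                        seed = cfg$seed + 4))
          hyper <- if (mdl == "LR") sprintf("DT = %.2f", dt)
                   else sprintf("Best k = %d", model$k)
          reports[[length(reports) + 1L]] <- cbind(
            data.frame(feature_set = mode, balancing = bal,
                       model = mdl, hyperparameter = hyper,
                       stringsAsFactors = FALSE),
            bm)
        }
        curves[[paste(mode, bal, mdl, sep = "_")]] <-
          cbind(data.frame(feature_set = mode, balancing = bal,
                           model = mdl),
                pr_curve(te$label, p))
      }
    }
  }
  model_reports <- do.call(rbind, reports)
  pr_curves <- do.call(rbind, curves)
  rownames(pr_curves) <- NULL
  utils::write.csv(model_reports,
                   file.path(cfg$out_dir, "model_reports.csv"),
                   row.names = FALSE)
  utils::write.csv(pr_curves, file.path(cfg$out_dir, "pr_curves.csv"),
                   row.names = FALSE)
  if (!is.null(sel)) {
    jsonlite::write_json(
      sel[c("groups", "retained", "selected")],
      file.path(cfg$out_dir, "selection_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  artifacts <- c("cohort_metadata.csv", "qc_report.csv", "features.csv",
                 "model_reports.csv", "pr_curves.csv")
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    counts = manifest_counts,
    hashes = as.list(tools::md5sum(file.path(cfg$out_dir, artifacts))))
  names(manifest$hashes) <- artifacts
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model_reports = model_reports, pr_curves = pr_curves,
                 selection = sel, features = ext$features,
                 qc = ext$qc, out_dir = cfg$out_dir))
}

#' Render a human-readable summary of a pipeline run
#'
#' Formats the model reports of a completed run as one table per
#' feature-set mode, metric cells printed as `mean [lo-hi]` to two
#' decimals, and writes `report.txt` into the run directory.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return The report text, invisibly; missing artifacts are listed and
#'   the rest rendered.
#' @export
render_report <- function(run_dir) {
  path <- file.path(run_dir, "model_reports.csv")
  if (!file.exists(path)) {
    warning("missing artifact: model_reports.csv; nothing to render")
    return(invisible(character(0)))
  }
  mr <- utils::read.csv(path, stringsAsFactors = FALSE)
  fmt <- function(m, lo, hi) sprintf("%.2f [%.2f-%.2f]", m, lo, hi)
  lines <- character(0)
  for (mode in unique(mr$feature_set)) {
    lines <- c(lines, sprintf("== Feature set: %s ==", mode))
    sub <- mr[mr$feature_set == mode, ]
    wide <- stats::reshape(
      transform(sub, cell = fmt(mean, lo, hi),
                row = paste0(model, "-", balancing, " (",
                             hyperparameter, ")"))[,
        c("row", "metric", "cell")],
      idvar = "row", timevar = "metric", direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    lines <- c(lines, utils::capture.output(print(wide,
                                                  row.names = FALSE)),
               "")
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
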