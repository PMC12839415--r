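#' Group mutually correlated features
#'
#' Builds the graph with an edge between two features whenever the
#' absolute Pearson correlation on the training rows exceeds the
#' threshold, and returns its connected components. Components (rather
#' than cliques) make the grouping deterministic and transitive: a chain
#' A-B, B-C lands in one group even when A-C is weaker. Constant features
#' get correlation 0 with a warning.
#'
#' @param train_features Numeric data.frame/matrix (training rows only).
#' @param r_threshold Absolute-correlation threshold (default 0.8,
#'   exceeded strictly).
#' @return A list of character vectors, one per group; singletons are
#'   their own group.
#' @export
correlation_groups <- function(train_features, r_threshold = 0.8) {
  X <- as.data.frame(train_features)
  stopifnot(nrow(X) >= 2)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0 | !is.finite(sds))) {
    warning("constant feature(s); correlations with them set to 0: ",
            paste(names(X)[sds == 0 | !is.finite(sds)], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0
  adj <- abs(r) > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(names(X), comp))
}

#' Retain the most important feature of each correlated group
#'
#' Fits one random-forest classifier (500 trees, fixed seed) on all
#' features and, within every multi-feature group, keeps the single
#' feature with the highest impurity (Gini) importance; singleton groups
#' pass through. Ties keep the feature that comes first in the supplied
#' column order.
#'
#' @param groups Output of [correlation_groups()].
#' @param train Training table with a `label` column.
#' @param label_col Name of the class column.
#' @param ntree Number of trees (default 500).
#' @param seed RNG seed for the forest.
#' @return Character vector of retained features, in original column
#'   order.
#' @export
rf_group_select <- function(groups, train, label_col = "label",
                            ntree = 500, seed = 1) {
  feats <- unlist(groups)
  y <- factor(train[[label_col]])
  if (nlevels(y) < 2) stop("training data has a single class")
  rf <- local_seed(seed, randomForest::randomForest(
    x = train[, feats, drop = FALSE], y = y, ntree = ntree))
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  kept <- vapply(groups, function(g) {
    if (length(g) == 1) return(g)
    g[which.max(imp[g])]   # which.max keeps the earlier feature on ties
  }, character(1))
  kept[order(match(kept, names(train)))]
}

#' Univariate decision-tree ROC-AUC filter
#'
#' Scores every feature with a single-feature, depth-limited decision
#' tree: in the default `"cv"` mode, mean ROC-AUC over stratified 5-fold
#' cross-validation on the training rows; in `"resubstitution"` mode, the
#' AUC of the tree refit on all training rows. Each tree is grown and
#' then cost-complexity pruned with the one-standard-error rule on
#' rpart's internal cross-validated error, so a feature that carries no
#' signal collapses to the root, predicts a constant and scores exactly
#' 0.5. Features whose score is at or below 0.5 — no better than chance
#' — are dropped.
#'
#' @param train Training table with a `label` column.
#' @param features Features to evaluate.
#' @param label_col Name of the class column.
#' @param positive Positive class (default `"PMCI"`).
#' @param folds Number of CV folds.
#' @param mode `"cv"` or `"resubstitution"`.
#' @param seed RNG seed for fold assignment.
#' @param maxdepth Tree depth limit.
#' @return A list with `selected` (features with AUC > 0.5) and `auc`
#'   (named vector of all scores).
#' @export
univariate_auc_filter <- function(train, features, label_col = "label",
                                  positive = "PMCI", folds = 5,
                                  mode = c("cv", "resubstitution"),
                                  seed = 1, maxdepth = 3) {
  mode <- match.arg(mode)
  y <- factor(train[[label_col]])
  lev <- levels(y)
  stopifnot(length(lev) == 2, positive %in% lev)
  neg <- setdiff(lev, positive)
  fold_id <- local_seed(seed, {
    id <- integer(length(y))
    for (cl in lev) {
      idx <- which(y == cl)
      id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    id
  })
  tree_auc <- function(fit_rows, score_rows, f, fit_seed) {
    df <- data.frame(y = y, x = train[[f]])
    fit <- local_seed(fit_seed, rpart::rpart(
      y ~ x, df[fit_rows, ], method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0.001,
                                     xval = 10)))
    cpt <- fit$cptable
    # the root (constant) classifier has relative error exactly 1 by
    # definition; its cross-validated estimate is replaced accordingly
    cpt[cpt[, "nsplit"] == 0, "xerror"] <- 1
    i_min <- which.min(cpt[, "xerror"])
    thr <- cpt[i_min, "xerror"] + cpt[i_min, "xstd"]
    best <- which(cpt[, "xerror"] <= thr)[1]
    fit <- rpart::prune(fit, cp = cpt[best, "CP"])
    p <- predict(fit, df[score_rows, ])[, positive]
    if (length(unique(p)) < 2 ||
        length(unique(y[score_rows])) < 2) return(0.5)
    as.numeric(pROC::auc(y[score_rows], p, levels = c(neg, positive),
                         direction = "<", quiet = TRUE))
  }
  auc <- vapply(features, function(f) {
    if (mode == "resubstitution") {
      all <- seq_along(y)
      tree_auc(all, all, f, seed)
    } else {
      mean(vapply(seq_len(folds), function(k) {
        tree_auc(which(fold_id != k), which(fold_id == k), f, seed + k)
      }, numeric(1)))
    }
  }, numeric(1))
  list(selected = features[auc > 0.5], auc = auc)
}

#' Two-step feature selection
#'
#' Runs the full selection used before modeling: correlation grouping
#' with random-forest importance within groups, then the univariate
#' decision-tree ROC-AUC filter. A pure function of the training split
#' and the seeds.
#'
#' @param train Training table with a `label` column.
#' @param features Candidate features; default: the 31 dictionary
#'   features present plus `age`.
#' @param label_col,positive,r_threshold,ntree,folds,mode,seed Settings
#'   passed to the two steps.
#' @return A `selection_report` list: `groups`, `retained`, `auc`,
#'   `selected`, `dropped` (with reasons) and `params`.
#' @export
select_features <- function(train, features = NULL, label_col = "label",
                            positive = "PMCI", r_threshold = 0.8,
                            ntree = 500, folds = 5, mode = "cv",
                            seed = 1) {
  if (is.null(features)) {
    features <- intersect(c(ocat_feature_dictionary()$name, "age"),
                          names(train))
  }
  groups <- correlation_groups(train[, features, drop = FALSE],
                               r_threshold)
  retained <- rf_group_select(groups, train, label_col, ntree, seed)
  flt <- univariate_auc_filter(train, retained, label_col, positive,
                               folds, mode, seed)
  dropped <- data.frame(
    feature = setdiff(features, flt$selected),
    stringsAsFactors = FALSE)
  dropped$reason <- ifelse(dropped$feature %in% retained,
                           "auc_at_or_below_0.5", "correlated_redundant")
  structure(
    list(groups = groups, retained = retained, auc = flt$auc,
         selected = flt$selected, dropped = dropped,
         params = list(r_threshold = r_threshold, ntree = ntree,
                       folds = folds, mode = mode, seed = seed)),
    class = "selection_report")
}
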