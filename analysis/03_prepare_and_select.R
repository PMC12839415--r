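#!/usr/bin/env Rscript

# Tabular preprocessing and two-step feature selection. Log-transform of
# the designated skewed features, stratified 80/20 split, SMOTE balancing
# of the training partition only, then — on the balanced training table,
# matching the workflow order — correlation grouping (|r| > 0.8) with
# random-forest importance followed by the univariate decision-tree
# ROC-AUC filter.

library(ocatscreen)

PREP_SEED <- 2027
dir.create("results", showWarnings = FALSE)
features <- read.csv("results/ocat_features.csv")
if (!nrow(features)) stop("run analysis/02_extract_features.R first")

lg <- log_transform(features)
cat("log-transformed features:", length(lg$features), "\n")
split <- stratified_split(lg$table, 0.2, seed = PREP_SEED)
imp <- impute_fit(split$train)
train0 <- impute_apply(imp, split$train)
test <- impute_apply(imp, split$test)
cat("split:\n"); print(split$counts)

manifest <- rbind(
  data.frame(id = split$train$id, split = "train"),
  data.frame(id = split$test$id, split = "test"))
write.csv(manifest, "results/split_manifest.csv", row.names = FALSE)

balanced <- smote(train0, seed = PREP_SEED + 1)
cat(sprintf("balanced training: %s\n",
            paste(names(table(balanced$label)), table(balanced$label),
                  collapse = " / ", sep = " = ")))
sel <- select_features(balanced, seed = PREP_SEED + 2)
cat(sprintf("groups > 1: %d | retained after RF step: %d | selected: %d\n",
            sum(lengths(sel$groups) > 1), length(sel$retained),
            length(sel$selected)))
cat("selected:", paste(sel$selected, collapse = ", "), "\n")
jsonlite::write_json(sel[c("groups", "retained", "selected", "auc")],
                     "results/selection_report.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/split_manifest.csv, results/selection_report.json\n")
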