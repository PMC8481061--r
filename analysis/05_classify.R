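#!/usr/bin/env Rscript
# Gender classification with SMOTE-balanced, stratified 10-fold
# cross-validated grid search: kNN (k = 7, Euclidean) and RBF-kernel SVM
# (C over 10^-4..10^4, sigma over 0.1..1.0), on each feature layout.
# Produces the six report tables (3 layouts x 2 classifiers) with
# row-percent confusion matrices, accuracies, ROC points and AUC.

suppressPackageStartupMessages(library(compen))
tables <- readRDS("results/analysis/feature_tables.rds")
seed <- 20260926L

rows <- list()
for (lay in names(tables)) {
  ft <- tables[[lay]]
  for (algo in c("knn", "svm")) {
    cfg <- classifier_config(algo, seed = seed)
    rep <- cross_validate_grid(ft$matrix, ft$labels, cfg)
    nm <- paste(tolower(lay), algo, sep = "_")
    jsonlite::write_json(
      list(layout = lay, algorithm = algo, accuracy = rep$accuracy,
           accuracy_pooled = rep$accuracy_pooled, auc = rep$auc,
           confusion_pct = rep$confusion_pct,
           fold_accuracies = rep$fold_accuracies,
           best_params = rep$best_params, roc_points = rep$roc_points),
      sprintf("results/analysis/report_%s.json", nm),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rows[[nm]] <- data.frame(
      layout = lay, algorithm = algo, accuracy_pct = rep$accuracy,
      auc = rep$auc,
      female_recall_pct = rep$confusion_pct["female", "female"],
      male_recall_pct = rep$confusion_pct["male", "male"])
    cat(sprintf("%-6s %-4s accuracy %5.1f%%  AUC %.3f  confusion diag %5.1f / %5.1f\n",
                lay, algo, rep$accuracy, rep$auc,
                rep$confusion_pct[1, 1], rep$confusion_pct[2, 2]))
  }
}
summary_df <- do.call(rbind, rows)
write.csv(summary_df, "results/analysis/classification_summary.csv",
          row.names = FALSE)
cat("\nFused CompEn features should match or beat either family alone;\n")
cat("see results/analysis/classification_summary.csv.\n")
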