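#!/usr/bin/env Rscript
# Multivariate pattern analysis per connection class: F-score ranking and
# linear SVM under LOOCV (selection, scaling and C search inside each
# fold), permutation-corrected performance, consensus features, and
# weighted regions.

library(richnet)

cohort <- read_cohort("results/cohort")
rich <- identify_rich_regions(cohort, 0.16, 0.15)
seed <- 17L
B <- 49L

dir.create("results/mvpa", recursive = TRUE, showWarnings = FALSE)
summary <- list()
for (cl in c("rich_club", "feeder", "local")) {
  fm <- class_feature_matrix(cohort, rich, cl, 0.16)
  nf <- min(30L, ncol(fm$x))
  cv <- loocv_linear_svm(fm$x, fm$labels, nf,
                         seed = richnet:::derive_seed(seed, 1))
  perf <- performance(cv$predictions, cv$decision_values, cv$labels)
  pt <- permutation_test(fm$x, fm$labels, nf, perf$accuracy, B = B,
                         seed = richnet:::derive_seed(seed, 2))
  cw <- consensus_and_weights(cv, fm$feature_edges)
  summary[[cl]] <- list(class = cl, n_candidate_features = ncol(fm$x),
                        n_features = nf, accuracy = perf$accuracy,
                        sensitivity = perf$sensitivity,
                        specificity = perf$specificity,
                        roc_auc = perf$roc_auc, permutation_p = pt$p,
                        consensus_edges = cw$consensus_features,
                        weighted_regions = cw$weighted_regions)
  write.csv(cw$consensus_features,
            sprintf("results/mvpa/consensus_%s.csv", cl), row.names = FALSE)
  write.csv(cw$region_weights,
            sprintf("results/mvpa/region_weights_%s.csv", cl),
            row.names = FALSE)
  cat(sprintf(
    "%-10s %3d features: acc %.2f sens %.2f spec %.2f AUC %.2f perm p %.3f; %d consensus, weighted regions: %s\n",
    cl, nf, perf$accuracy, perf$sensitivity, perf$specificity,
    perf$roc_auc, pt$p, nrow(cw$consensus_features),
    paste(cw$weighted_regions, collapse = " ")))
}
jsonlite::write_json(summary, "results/mvpa/performance.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
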