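#!/usr/bin/env Rscript
# Behavior correlation: Pearson correlation between the patients'
# speech-intelligibility scores and (a) the consensus features from the
# MVPA step, (b) the planted behavior-coupled connections as a positive
# control.

library(richnet)

cohort <- read_cohort("results/cohort")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
pat <- cohort$subjects$group == "patient"
scores <- cohort$subjects$behavior_score[pat]

edge_features <- function(edges) {
  x <- vapply(seq_len(nrow(edges)), function(r)
    vapply(cohort$matrices[pat], function(m) m[edges$i[r], edges$j[r]],
           numeric(1)), numeric(sum(pat)))
  colnames(x) <- paste0(edges$i, "_", edges$j)
  x
}

rows <- list()
for (cl in c("rich_club", "feeder", "local")) {
  cf <- tryCatch(read.csv(sprintf("results/mvpa/consensus_%s.csv", cl)),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(cf) || nrow(cf) == 0) next
  bc <- behavioral_correlation(edge_features(cf), scores)
  rows[[cl]] <- cbind(class = cl, bc, i = cf$i, j = cf$j)
}
res <- do.call(rbind, rows)
write.csv(res, "results/behavior_correlations.csv", row.names = FALSE)
sig <- res[res$p < 0.05, ]
cat("consensus features tested:", nrow(res),
    "; correlated with the score at p < 0.05:", nrow(sig), "\n")
if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)

ce <- truth$coupled_edges
bc_truth <- behavioral_correlation(edge_features(ce), scores)
cat("\nplanted couplings (target vs estimate):\n")
print(data.frame(edge = bc_truth$feature, target = ce$r,
                 estimate = round(bc_truth$r, 3),
                 p = signif(bc_truth$p, 3)), row.names = FALSE)
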