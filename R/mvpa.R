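#' F-score ranking of features
#'
#' Univariate discrimination score per feature,
#' \eqn{F = [(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2] /
#' [s^2_+ + s^2_-]}, with within-class sample variances (n-1 denominator);
#' larger F means better class separation. Features whose pooled
#' within-class variance is zero have an undefined score: they are flagged
#' and ranked after all scored features.
#'
#' @param x Subjects-by-features numeric matrix.
#' @param labels Group per subject (patient/control); patients are the
#'   positive class.
#' @return data.frame ordered by decreasing F: feature (column index),
#'   f, flagged.
#' @export
f_score_rank <- function(x, labels) {
  labels <- as.character(labels)
  pos <- labels == "patient"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  mu <- colMeans(x)
  mu_p <- colMeans(x[pos, , drop = FALSE])
  mu_n <- colMeans(x[!pos, , drop = FALSE])
  v_p <- apply(x[pos, , drop = FALSE], 2L, stats::var)
  v_n <- apply(x[!pos, , drop = FALSE], 2L, stats::var)
  den <- v_p + v_n
  f <- ifelse(den > 0, ((mu_p - mu)^2 + (mu_n - mu)^2) / den, NA_real_)
  flagged <- den == 0
  ord <- order(flagged, -ifelse(flagged, -Inf, f))
  data.frame(feature = ord, f = f[ord], flagged = flagged[ord])
}

standardize_by <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

# Stratified k-fold assignment (deterministic given the RNG state).
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Inner cross-validated choice of the SVM cost parameter C on the training
# fold only; ties go to the smaller C.
choose_cost <- function(x, labels, c_grid, inner_k = 5L) {
  if (length(c_grid) == 1L) return(c_grid)
  k <- min(inner_k, min(table(labels)))
  if (k < 2L) return(c_grid[1L])
  fold <- stratified_folds(labels, k)
  acc <- vapply(c_grid, function(cost) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L) next
      fit <- e1071::svm(x = x[tr, , drop = FALSE],
                        y = factor(labels[tr], c("control", "patient")),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / length(labels)
  }, numeric(1))
  c_grid[which.max(acc)]  # which.max returns the first = smallest C on ties
}

# Signed decision values and primal weight vector of a linear SVM,
# oriented so positive means "patient".
svm_decision <- function(fit, x_new) {
  dv <- attr(predict(fit, x_new, decision.values = TRUE),
             "decision.values")[, 1L]
  w <- drop(t(fit$coefs) %*% fit$SV)
  first <- fit$levels[fit$labels[1L]]
  if (first != "patient") {
    dv <- -dv
    w <- -w
  }
  list(dv = dv, w = w)
}

#' Leave-one-out cross-validated linear SVM with in-fold feature selection
#'
#' For each held-out subject: features are ranked by F-score on the
#' training fold ONLY, the top \code{n_features} are kept, the training
#' fold's mean/sd standardize both partitions, the SVM cost C is chosen by
#' inner stratified 5-fold cross-validation on the training fold, and a
#' linear SVM predicts the held-out subject. Keeping every step inside the
#' fold prevents information leaking from the test subject into selection
#' or scaling.
#'
#' @param x Subjects-by-features matrix (one connection class's edge
#'   weights); column names are feature ids.
#' @param labels patient/control per subject.
#' @param n_features Number of top-ranked features per fold.
#' @param c_grid Candidate SVM costs (default \code{c(0.01, 0.1, 1, 10,
#'   100)}); a length-1 grid skips the inner search.
#' @param inner_k Inner folds for the C search (default 5).
#' @param seed Seed for the inner-fold assignment.
#' @return List (class \code{loocv_svm}): predictions, decision_values
#'   (positive = patient), labels, fold_features (list of selected feature
#'   ids per fold), fold_weights (list of named SVM weight vectors),
#'   cost_chosen, n_features.
#' @export
loocv_linear_svm <- function(x, labels, n_features,
                             c_grid = c(0.01, 0.1, 1, 10, 100),
                             inner_k = 5L, seed = 1L) {
  labels <- as.character(labels)
  if (min(table(factor(labels, c("patient", "control")))) < 2L)
    stop("need >= 2 subjects per class")
  if (n_features > ncol(x)) stop("n_features exceeds available features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  ns <- nrow(x)
  pred <- character(ns)
  dv <- numeric(ns)
  fold_features <- fold_weights <- vector("list", ns)
  cost_chosen <- numeric(ns)
  for (i in seq_len(ns)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- labels[-i]
    rk <- f_score_rank(tr_x, tr_y)
    top <- rk$feature[seq_len(n_features)]
    ctr <- colMeans(tr_x[, top, drop = FALSE])
    scl <- apply(tr_x[, top, drop = FALSE], 2L, stats::sd)
    xs_tr <- standardize_by(tr_x[, top, drop = FALSE], ctr, scl)
    xs_te <- standardize_by(x[i, top, drop = FALSE], ctr, scl)
    set.seed(derive_seed(seed, i))
    cost <- choose_cost(xs_tr, tr_y, c_grid, inner_k)
    fit <- e1071::svm(x = xs_tr, y = factor(tr_y, c("control", "patient")),
                      kernel = "linear", cost = cost, scale = FALSE)
    dec <- svm_decision(fit, xs_te)
    dv[i] <- dec$dv
    pred[i] <- if (dec$dv > 0) "patient" else "control"
    fold_features[[i]] <- colnames(x)[top]
    wfull <- dec$w
    names(wfull) <- colnames(x)[top]
    fold_weights[[i]] <- wfull
    cost_chosen[i] <- cost
  }
  structure(list(predictions = pred, decision_values = dv, labels = labels,
                 fold_features = fold_features, fold_weights = fold_weights,
                 cost_chosen = cost_chosen, n_features = n_features,
                 c_grid = c_grid, seed = seed),
            class = "loocv_svm")
}

#' ROC area under the curve from decision values (rank statistic)
#'
#' Mann-Whitney concordance: the probability that a random patient's
#' decision value exceeds a random control's, ties counting one half.
#'
#' @param decision_values Signed scores, higher = more patient-like.
#' @param labels patient/control.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(decision_values, labels) {
  pos <- labels == "patient"
  n_p <- sum(pos); n_n <- sum(!pos)
  if (n_p == 0L || n_n == 0L) stop("need both classes for ROC")
  r <- rank(decision_values)
  (sum(r[pos]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
}

#' Classification performance summary
#'
#' Accuracy, sensitivity (patients = positive class), specificity, and
#' ROC-AUC from the cross-validated decision values.
#'
#' @param predictions Predicted labels.
#' @param decision_values Signed decision values (positive = patient).
#' @param labels True labels.
#' @return List (class \code{classifier_performance}): accuracy,
#'   sensitivity, specificity, roc_auc.
#' @export
performance <- function(predictions, decision_values, labels) {
  pos <- labels == "patient"
  if (!any(pos) || all(pos)) stop("need both classes in labels")
  list(accuracy = mean(predictions == labels),
       sensitivity = mean(predictions[pos] == "patient"),
       specificity = mean(predictions[!pos] == "control"),
       roc_auc = roc_auc(decision_values, labels))
}

#' Permutation test for LOOCV classification accuracy
#'
#' Repeats the FULL pipeline — F-score selection inside folds,
#' standardization, inner C search, LOOCV — on B random label
#' permutations, and returns \eqn{p = (1 + \#\{acc_{perm} \ge
#' acc_{obs}\}) / (B + 1)}, which is never zero and at least 1/(B+1).
#'
#' @param x,labels,n_features,c_grid,inner_k As in
#'   \code{\link{loocv_linear_svm}}.
#' @param observed_accuracy Accuracy of the unpermuted run.
#' @param B Number of permutations.
#' @param seed Master seed; permutation b uses a derived seed.
#' @return List: p, permuted_accuracies.
#' @export
permutation_test <- function(x, labels, n_features, observed_accuracy,
                             B = 100L, c_grid = c(0.01, 0.1, 1, 10, 100),
                             inner_k = 5L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  acc <- vapply(seq_len(B), function(b) {
    sb <- derive_seed(seed, b)
    set.seed(sb)
    perm <- sample(labels)
    cv <- loocv_linear_svm(x, perm, n_features, c_grid, inner_k,
                           seed = derive_seed(sb, 1L))
    mean(cv$predictions == perm)
  }, numeric(1))
  list(p = (1 + sum(acc >= observed_accuracy)) / (B + 1),
       permuted_accuracies = acc)
}

#' Consensus features and weighted regions
#'
#' Consensus features are the features selected in EVERY LOOCV fold. Each
#' gets the sign of its mean SVM weight across folds. A region's weight is
#' the sum of |mean weight| over its incident consensus features, and the
#' weighted regions are those whose region weight is at least one standard
#' deviation above the mean over all regions touched by consensus
#' features. Region weights are min-max normalized for reporting.
#'
#' @param cv A \code{loocv_svm} result.
#' @param feature_edges data.frame mapping feature ids to node pairs:
#'   columns feature, i, j.
#' @return List (class \code{consensus_report}): consensus_features
#'   (data.frame feature, i, j, mean_weight, sign), region_weights
#'   (data.frame node, weight, weight_normalized, is_weighted_region),
#'   weighted_regions (node ids), degenerate (TRUE when all region weights
#'   are equal so the threshold selects every touched node).
#' @export
consensus_and_weights <- function(cv, feature_edges) {
  consensus <- Reduce(intersect, cv$fold_features)
  if (length(consensus) == 0L)
    return(structure(list(consensus_features =
                            data.frame(feature = character(), i = integer(),
                                       j = integer(), mean_weight = numeric(),
                                       sign = numeric()),
                          region_weights = data.frame(node = integer(),
                                                      weight = numeric()),
                          weighted_regions = integer(0),
                          degenerate = FALSE),
                     class = "consensus_report"))
  mean_w <- vapply(consensus, function(f)
    mean(vapply(cv$fold_weights, function(w) w[[f]], numeric(1))),
    numeric(1))
  fe <- feature_edges[match(consensus, feature_edges$feature), , drop = FALSE]
  cf <- data.frame(feature = consensus, i = fe$i, j = fe$j,
                   mean_weight = unname(mean_w),
                   sign = sign(unname(mean_w)))
  touched <- sort(unique(c(cf$i, cf$j)))
  rw <- vapply(touched, function(nd)
    sum(abs(cf$mean_weight[cf$i == nd | cf$j == nd])), numeric(1))
  sd_rw <- stats::sd(rw)
  degenerate <- is.na(sd_rw) || sd_rw == 0
  thr <- mean(rw) + ifelse(degenerate, 0, sd_rw)
  is_wr <- rw >= thr
  span <- diff(range(rw))
  norm <- if (span > 0) (rw - min(rw)) / span else rep(1, length(rw))
  structure(list(consensus_features = cf,
                 region_weights = data.frame(node = touched, weight = rw,
                                             weight_normalized = norm,
                                             is_weighted_region = is_wr),
                 weighted_regions = touched[is_wr],
                 degenerate = degenerate),
            class = "consensus_report")
}

#' Select the feature count maximizing LOOCV accuracy
#'
#' Runs the full LOOCV pipeline for each candidate number of top-ranked
#' features and returns the count with the highest accuracy; ties go to
#' the smaller count. All candidates' results are retained.
#'
#' @param x,labels,c_grid,inner_k,seed As in
#'   \code{\link{loocv_linear_svm}}.
#' @param candidates Integer vector of feature counts.
#' @return List: best_n, accuracies (named by candidate), runs (list of
#'   \code{loocv_svm} objects).
#' @export
feature_count_search <- function(x, labels, candidates,
                                 c_grid = c(0.01, 0.1, 1, 10, 100),
                                 inner_k = 5L, seed = 1L) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  candidates <- sort(unique(as.integer(candidates)))
  runs <- lapply(candidates, function(nf)
    loocv_linear_svm(x, labels, nf, c_grid, inner_k, seed = seed))
  acc <- vapply(runs, function(cv) mean(cv$predictions == cv$labels),
                numeric(1))
  names(acc) <- candidates
  list(best_n = candidates[which.max(acc)], accuracies = acc, runs = runs)
}

#' Build the per-class feature matrix for MVPA
#'
#' Features are the connections of one class (rich-club, feeder or local)
#' that survive thresholding at the analysis density in every subject;
#' feature values are the subjects' edge weights.
#'
#' @param cohort A \code{cohort}.
#' @param rich_nodes Rich-club node ids.
#' @param class One of rich_club/feeder/local.
#' @param density Analysis density (default 0.16).
#' @return List: x (subjects x features, columns named "i_j"),
#'   labels, feature_edges (data.frame feature, i, j).
#' @export
class_feature_matrix <- function(cohort, rich_nodes,
                                 class = c("rich_club", "feeder", "local"),
                                 density = 0.16) {
  class <- match.arg(class)
  ns <- length(cohort$matrices)
  n <- cohort$n_nodes
  present <- matrix(0L, n, n)
  for (m in cohort$matrices) {
    g <- threshold_by_density(m, density)
    idx <- cbind(g$edges$i, g$edges$j)
    present[idx] <- present[idx] + 1L
  }
  sel <- which(present == ns, arr.ind = TRUE)
  cls <- edge_class_of(sel[, 1L], sel[, 2L], rich_nodes)
  sel <- sel[cls == class, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no common edges of class ", class)
  ord <- order(sel[, 1L], sel[, 2L])
  sel <- sel[ord, , drop = FALSE]
  ids <- paste0(sel[, 1L], "_", sel[, 2L])
  x <- t(vapply(cohort$matrices, function(m) m[sel], numeric(nrow(sel))))
  colnames(x) <- ids
  list(x = x, labels = cohort$subjects$group,
       feature_edges = data.frame(feature = ids, i = sel[, 1L],
                                  j = sel[, 2L]))
}
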