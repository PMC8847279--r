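#' Covariate-adjusted two-sample t-test
#'
#' Implements "corrected for age and sex" by residualization: the values
#' are regressed on the covariates (intercept + age + sex indicator) over
#' all subjects pooled, and an equal-variance two-sample t-test compares
#' the residuals between groups. The t statistic is signed
#' patient-minus-control. Constant covariates are dropped, so with
#' zero-variance covariates the result equals the plain two-sample t-test.
#'
#' @param values Numeric vector, one value per subject.
#' @param group Character/factor with levels patient/control.
#' @param age Numeric covariate.
#' @param sex Character covariate ("M"/"F").
#' @return List with t, p (two-sided), direction (sign of adjusted
#'   patient-minus-control difference).
#' @export
adjusted_two_sample_t <- function(values, group, age, sex) {
  group <- as.character(group)
  if (any(!group %in% c("patient", "control")))
    stop("group labels must be patient/control")
  if (min(table(group)) < 2L) stop("need >= 2 subjects per group")
  if (anyNA(values) || anyNA(age) || anyNA(sex))
    stop("values and covariates must be complete")
  if (stats::sd(values) == 0) stop("values are constant")
  covs <- list(age = age, sex = as.numeric(sex == "M"))
  covs <- covs[vapply(covs, function(v) stats::sd(v) > 0, logical(1))]
  res <- if (length(covs)) {
    stats::residuals(stats::lm(values ~ ., data = as.data.frame(covs)))
  } else {
    values - mean(values)
  }
  tt <- stats::t.test(res[group == "patient"], res[group == "control"],
                      var.equal = TRUE)
  t_stat <- unname(tt$statistic)
  list(t = t_stat, p = tt$p.value, direction = sign(t_stat))
}

#' Edge-wise covariate-adjusted group comparison
#'
#' Tests every connection for a group difference in weight, adjusted for
#' age and sex. Edges are eligible when retained at the analysis density
#' in at least \code{min_presence} of subjects (default: all of them), and
#' each eligible edge is labeled rich-club/feeder/local from the pooled
#' rich-node set. The default, following the convention in this literature, reports per-edge significance at
#' \code{alpha} uncorrected; set \code{correct = "fdr"} for
#' Benjamini-Hochberg instead.
#'
#' @param cohort A \code{cohort}.
#' @param rich_nodes Rich-club node ids (see
#'   \code{\link{identify_rich_regions}}).
#' @param density Analysis density (default 0.16).
#' @param alpha Per-edge significance threshold (default 0.001).
#' @param min_presence Minimum fraction of subjects in which an edge must
#'   survive thresholding to be testable (default 1 = all subjects).
#' @param correct \code{"none"} (default) or \code{"fdr"}.
#' @return data.frame: i, j, class, t, p, p_fdr, direction, significant;
#'   attribute \code{adjustment = "residualization"} records the
#'   covariate-correction scheme.
#' @export
edgewise_group_test <- function(cohort, rich_nodes, density = 0.16,
                                alpha = 0.001, min_presence = 1,
                                correct = c("none", "fdr")) {
  correct <- match.arg(correct)
  ns <- length(cohort$matrices)
  n <- cohort$n_nodes
  present <- matrix(0L, n, n)
  for (m in cohort$matrices) {
    g <- threshold_by_density(m, density)
    present[cbind(g$edges$i, g$edges$j)] <-
      present[cbind(g$edges$i, g$edges$j)] + 1L
  }
  sel <- which(present >= ceiling(min_presence * ns), arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("no testable edges at min_presence ", min_presence)
  sub <- cohort$subjects
  res <- lapply(seq_len(nrow(sel)), function(r) {
    i <- sel[r, 1L]; j <- sel[r, 2L]
    w <- vapply(cohort$matrices, function(m) m[i, j], numeric(1))
    at <- adjusted_two_sample_t(w, sub$group, sub$age, sub$sex)
    data.frame(i = i, j = j,
               class = edge_class_of(i, j, rich_nodes),
               t = at$t, p = at$p, direction = at$direction)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out$p_fdr <- stats::p.adjust(out$p, "fdr")
  out$significant <- if (correct == "fdr") out$p_fdr < alpha else out$p < alpha
  structure(out, adjustment = "residualization", alpha = alpha,
            density = density)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic without continuity correction, df = 1; used for the
#' sex distribution comparison between groups.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with chi2 and p.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Behavior-score correlation for patient features
#'
#' Pearson correlation (two-sided) between each feature (a connection
#' weight or a topological summary) and the behavioral score, computed in
#' patients only — the speech-intelligibility score is measured in the
#' patient group.
#'
#' @param features Numeric vector, or subjects-by-features matrix with
#'   column names as feature ids.
#' @param scores Behavioral scores, same length as rows of
#'   \code{features}.
#' @return data.frame: feature, r, p.
#' @export
behavioral_correlation <- function(features, scores) {
  if (is.null(dim(features)))
    features <- matrix(features, ncol = 1L,
                       dimnames = list(NULL, "feature"))
  if (nrow(features) != length(scores)) stop("features/scores length mismatch")
  if (length(scores) < 3L) stop("need >= 3 subjects with scores")
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  out <- lapply(seq_len(ncol(features)), function(c1) {
    v <- features[, c1]
    if (stats::sd(v) == 0) stop("feature ", colnames(features)[c1],
                                " has zero variance")
    ct <- stats::cor.test(v, scores, method = "pearson")
    data.frame(feature = colnames(features)[c1],
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
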