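#' Analysis configuration
#'
#' Bundles every tunable of the full pipeline. Defaults are desk-scale:
#' null ensembles of 100 networks and 100 label permutations keep a full
#' run in minutes on one CPU, while \code{full_scale = TRUE} restores
#' the literature-scale 5,000-network small-world ensemble, 1,000-network
#' rich-club ensemble, and 1,000 permutations.
#'
#' @param grid_start,grid_stop,grid_step Density grid (default
#'   0.05-0.50, step 0.01).
#' @param rich_density Density at which rich-club analysis, edge classes
#'   and MVPA features are computed (default 0.16).
#' @param rich_fraction Fraction of nodes in the rich club (default
#'   0.15).
#' @param sw_ensemble Null networks per density for gamma/lambda/sigma.
#' @param rc_ensemble Null networks for rich-club normalization.
#' @param alpha Per-edge significance threshold (default 0.001).
#' @param c_grid SVM cost grid.
#' @param n_features Top-ranked connections fed to the SVM per class
#'   (capped at the class's feature count); alternatively
#'   \code{feature_counts} gives candidates searched by LOOCV accuracy.
#' @param feature_counts Optional candidate counts for
#'   \code{\link{feature_count_search}}.
#' @param B Label permutations for the classifier permutation test.
#' @param k_range Rich-club degree range; NULL = 1 to the maximum degree
#'   observed at \code{rich_density}.
#' @param full_scale Restore literature-scale ensemble/permutation
#'   sizes.
#' @param seed Master seed for every stochastic stage.
#' @return List of class \code{analysis_config}.
#' @export
analysis_config <- function(grid_start = 0.05, grid_stop = 0.50,
                            grid_step = 0.01, rich_density = 0.16,
                            rich_fraction = 0.15, sw_ensemble = 100L,
                            rc_ensemble = 100L, alpha = 0.001,
                            c_grid = c(0.01, 0.1, 1, 10, 100),
                            n_features = 30L, feature_counts = NULL,
                            B = 100L, k_range = NULL,
                            full_scale = FALSE, seed = 1L) {
  if (full_scale) {
    sw_ensemble <- 5000L
    rc_ensemble <- 1000L
    B <- 1000L
  }
  structure(as.list(environment()), class = "analysis_config")
}

# All five small-world curves of one subject in a single pass: the null
# ensemble at each density is shared between gamma, lambda and sigma.
subject_smallworld_curves <- function(m, grid, ensemble_size, seed) {
  vals <- matrix(NA_real_, length(grid), 5L,
                 dimnames = list(NULL, c("cp", "lp", "gamma", "lambda",
                                         "sigma")))
  for (idx in seq_along(grid)) {
    res <- tryCatch({
      g <- threshold_by_density(m, grid[idx])
      ns <- ensemble_stats(g, size = ensemble_size,
                           seed = derive_seed(seed, idx),
                           metrics = c("cp", "lp"))
      sw <- small_world_metrics(g, ns)
      c(sw$cp, sw$lp, sw$gamma, sw$lambda_, sw$sigma)
    }, error = function(e) rep(NA_real_, 5L))
    vals[idx, ] <- res
  }
  vals
}

#' Run the full connectome analysis pipeline
#'
#' Executes the whole workflow on a cohort: small-world metric curves and
#' their AUCs per subject with covariate-adjusted group comparison;
#' rich-club identification, per-subject normalized rich-club profiles
#' with per-degree group tests; edge-class strengths and their group
#' tests; edge-wise group tests; per-class SVM MVPA with permutation
#' correction, consensus features and weighted regions; and behavior
#' correlation of consensus features in patients. Deterministic under a
#' fixed \code{config$seed}.
#'
#' @param cohort A \code{cohort} (at least 2 subjects per group).
#' @param config An \code{\link{analysis_config}}.
#' @param stages Character subset of
#'   \code{c("smallworld", "richclub", "edges", "mvpa", "behavior")};
#'   later stages may require earlier ones.
#' @return Nested report list (class \code{analysis_report}) embedding
#'   the fully resolved config.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              stages = c("smallworld", "richclub", "edges",
                                         "mvpa", "behavior")) {
  if (min(table(cohort$subjects$group)) < 2L)
    stop("validation: need at least 2 subjects per group before any stage")
  grid <- density_grid(config$grid_start, config$grid_stop,
                       config$grid_step)
  sub <- cohort$subjects
  report <- list(config = config, n_subjects = nrow(sub),
                 n_nodes = cohort$n_nodes)

  if ("smallworld" %in% stages) {
    aucs <- array(NA_real_, c(nrow(sub), 5L),
                  dimnames = list(sub$subject_id,
                                  c("cp", "lp", "gamma", "lambda", "sigma")))
    group_mean_curves <- 0
    for (s in seq_len(nrow(sub))) {
      cur <- subject_smallworld_curves(cohort$matrices[[s]], grid,
                                       config$sw_ensemble,
                                       derive_seed(config$seed, s))
      aucs[s, ] <- apply(cur, 2L, function(v)
        suppressWarnings(auc_trapezoid(grid, v)))
      group_mean_curves <- group_mean_curves + cur / nrow(sub)
    }
    sw_tests <- lapply(colnames(aucs), function(mt)
      c(list(metric = mt),
        adjusted_two_sample_t(aucs[, mt], sub$group, sub$age, sub$sex)))
    report$smallworld <- list(densities = grid, auc_per_subject = aucs,
                              mean_curves = group_mean_curves,
                              auc_group_tests =
                                do.call(rbind, lapply(sw_tests, as.data.frame)))
  }

  rich <- identify_rich_regions(cohort, config$rich_density,
                                config$rich_fraction)
  report$rich_nodes <- as.integer(rich)

  if ("richclub" %in% stages) {
    gs <- lapply(cohort$matrices, threshold_by_density, config$rich_density)
    k_range <- config$k_range
    if (is.null(k_range))
      k_range <- seq_len(max(vapply(gs, function(g)
        max(rowSums(g$weights > 0)), numeric(1))) - 1L)
    prof <- vector("list", nrow(sub))
    for (s in seq_len(nrow(sub))) {
      ens <- ensemble_stats(gs[[s]], size = config$rc_ensemble,
                            seed = derive_seed(config$seed, 10000L + s),
                            k_range = k_range, metrics = character())
      prof[[s]] <- rich_club_profile(cohort$matrices[[s]],
                                     config$rich_density, ens, k_range)
    }
    phi <- vapply(prof, function(p) p$phi, numeric(length(k_range)))
    phin <- vapply(prof, function(p) p$phi_norm, numeric(length(k_range)))
    per_k_test <- function(mat) {
      do.call(rbind, lapply(seq_along(k_range), function(ki) {
        v <- mat[ki, ]
        ok <- !is.na(v) & is.finite(v)
        if (sum(ok) < nrow(sub) || stats::sd(v[ok]) == 0)
          return(data.frame(k = k_range[ki], t = NA_real_, p = NA_real_,
                            direction = NA_real_))
        at <- adjusted_two_sample_t(v, sub$group, sub$age, sub$sex)
        data.frame(k = k_range[ki], t = at$t, p = at$p,
                   direction = at$direction)
      }))
    }
    report$richclub <- list(
      k_range = k_range,
      phi_mean = list(patient = rowMeans(phi[, sub$group == "patient",
                                             drop = FALSE], na.rm = TRUE),
                      control = rowMeans(phi[, sub$group == "control",
                                             drop = FALSE], na.rm = TRUE)),
      phi_norm_mean = list(patient = rowMeans(phin[, sub$group == "patient",
                                                   drop = FALSE], na.rm = TRUE),
                           control = rowMeans(phin[, sub$group == "control",
                                                   drop = FALSE], na.rm = TRUE)),
      phi_tests = per_k_test(phi), phi_norm_tests = per_k_test(phin))

    strengths <- t(vapply(gs, function(g) class_strengths(rich, g),
                          numeric(3)))
    rownames(strengths) <- sub$subject_id
    st_tests <- lapply(colnames(strengths), function(cl)
      c(list(class = cl),
        adjusted_two_sample_t(strengths[, cl], sub$group, sub$age,
                              sub$sex)))
    report$strengths <- list(per_subject = strengths,
                             group_tests =
                               do.call(rbind, lapply(st_tests, as.data.frame)))
  }

  if ("edges" %in% stages) {
    et <- edgewise_group_test(cohort, rich, config$rich_density,
                              config$alpha)
    report$edges <- list(tests = et,
                         n_significant = with(et, table(
                           factor(class[significant],
                                  c("rich_club", "feeder", "local")))))
  }

  if ("mvpa" %in% stages) {
    report$mvpa <- lapply(c(rich_club = "rich_club", feeder = "feeder",
                            local = "local"), function(cl) {
      fm <- tryCatch(class_feature_matrix(cohort, rich, cl,
                                          config$rich_density),
                     error = function(e) NULL)
      if (is.null(fm)) return(list(status = "not run"))
      if (!is.null(config$feature_counts)) {
        fs <- feature_count_search(fm$x, fm$labels,
                                   pmin(config$feature_counts, ncol(fm$x)),
                                   config$c_grid,
                                   seed = derive_seed(config$seed, 20000L))
        nf <- fs$best_n
      } else nf <- min(config$n_features, ncol(fm$x))
      cv <- loocv_linear_svm(fm$x, fm$labels, nf, config$c_grid,
                             seed = derive_seed(config$seed, 30000L))
      perf <- performance(cv$predictions, cv$decision_values, cv$labels)
      pt <- permutation_test(fm$x, fm$labels, nf, perf$accuracy,
                             B = config$B, c_grid = config$c_grid,
                             seed = derive_seed(config$seed, 40000L))
      cw <- consensus_and_weights(cv, fm$feature_edges)
      list(status = "run", class = cl, n_features = nf,
           n_candidate_features = ncol(fm$x),
           accuracy = perf$accuracy, sensitivity = perf$sensitivity,
           specificity = perf$specificity, roc_auc = perf$roc_auc,
           permutation_p = pt$p,
           consensus = cw,
           decision_values = cv$decision_values, labels = cv$labels)
    })
  }

  if ("behavior" %in% stages && !is.null(report$mvpa)) {
    pat <- sub$group == "patient"
    scores <- sub$behavior_score[pat]
    report$behavior <- lapply(report$mvpa, function(mv) {
      if (is.null(mv$consensus) ||
          nrow(mv$consensus$consensus_features) == 0L)
        return(NULL)
      cf <- mv$consensus$consensus_features
      feats <- vapply(seq_len(nrow(cf)), function(r)
        vapply(cohort$matrices[pat], function(m) m[cf$i[r], cf$j[r]],
               numeric(1)),
        numeric(sum(pat)))
      colnames(feats) <- cf$feature
      bc <- behavioral_correlation(feats, scores)
      cbind(bc, i = cf$i, j = cf$j)
    })
  }

  structure(report, class = "analysis_report")
}

#' Write a report bundle to disk
#'
#' \code{report.json} plus CSV side tables (small-world AUC tests,
#' edge-wise tests, per-class strengths) under \code{dir}.
#'
#' @param report An \code{analysis_report}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE, na = "null")
  if (!is.null(report$smallworld))
    utils::write.csv(report$smallworld$auc_group_tests,
                     file.path(dir, "smallworld_auc_tests.csv"),
                     row.names = FALSE)
  if (!is.null(report$edges))
    utils::write.csv(report$edges$tests,
                     file.path(dir, "edge_tests.csv"), row.names = FALSE)
  if (!is.null(report$strengths))
    utils::write.csv(data.frame(subject_id =
                                  rownames(report$strengths$per_subject),
                                report$strengths$per_subject),
                     file.path(dir, "class_strengths.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Human-readable summary of a report bundle
#'
#' @param report An \code{analysis_report}.
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
report_summary <- function(report) {
  lines <- c(sprintf("# Analysis summary (%d subjects, %d nodes)",
                     report$n_subjects, report$n_nodes))
  if (!is.null(report$smallworld)) {
    lines <- c(lines, "", "## Small-world AUC group tests",
               "metric | t | p")
    sw <- report$smallworld$auc_group_tests
    lines <- c(lines, sprintf("%s | %.3f | %.4g", sw$metric, sw$t, sw$p))
  }
  lines <- c(lines, "",
             sprintf("Rich-club regions (%d): %s",
                     length(report$rich_nodes),
                     paste(report$rich_nodes, collapse = " ")))
  if (!is.null(report$edges)) {
    ns <- report$edges$n_significant
    lines <- c(lines, "", "## Significant edges per class",
               sprintf("%s: %d", names(ns), as.integer(ns)))
  }
  lines <- c(lines, "", "## MVPA per connection class")
  if (is.null(report$mvpa)) {
    lines <- c(lines, "not run")
  } else {
    for (nm in names(report$mvpa)) {
      mv <- report$mvpa[[nm]]
      if (identical(mv$status, "not run")) {
        lines <- c(lines, sprintf("%s: not run", nm))
      } else {
        lines <- c(lines, sprintf(
          "%s: n_features=%d acc=%.3f sens=%.3f spec=%.3f auc=%.3f perm_p=%.4g",
          nm, mv$n_features, mv$accuracy, mv$sensitivity, mv$specificity,
          mv$roc_auc, mv$permutation_p))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
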