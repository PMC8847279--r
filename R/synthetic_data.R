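#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for cohorts with known ground truth: a
#' block-structured topology with a planted rich-club core (core-core
#' edges denser and stronger than feeder and peripheral ones), FA-like
#' Beta-distributed edge weights in (0, 1), subject-level weight noise,
#' group effects planted on designated edges, a behavior score linearly
#' coupled to designated patient edges, and age/sex covariates. Defaults
#' emulate the study conditions: two groups of 28 subjects, 90 regions,
#' a 15% rich core, ages 6-16 years, 21/7 males/females per group, and a
#' speech-intelligibility score with mean 91.6, sd 4.0, floored at the
#' 86-point rehabilitation threshold (full score 100).
#'
#' @param n_nodes Number of regions (default 90).
#' @param n_per_group Subjects per group (default 28).
#' @param rich_fraction Fraction of nodes in the planted core (default
#'   0.15).
#' @param core_density,feeder_density,periphery_density Edge probabilities
#'   for core-core, core-periphery and periphery-periphery pairs.
#' @param weight_shape1,weight_shape2 Beta parameters of baseline weights
#'   (Beta(5, 6): mean about 0.45, FA-plausible).
#' @param core_weight_boost,feeder_weight_boost Additive weight offsets
#'   making core-incident connections stronger, so the planted core also
#'   dominates after proportional thresholding.
#' @param subject_sd Subject-level Gaussian weight noise sd.
#' @param n_effect_feeder,n_effect_local Planted group-difference edges
#'   per class (patients higher), plus one planted lower-weight local edge
#'   mirroring a single decreased peripheral connection.
#' @param effect_size Standardized group effect d on planted edges.
#' @param n_coupled,coupling_r Behavior-coupled local edges and their
#'   target Pearson correlations (recycled to length \code{n_coupled}).
#' @param behavior_mean,behavior_sd,behavior_floor,behavior_ceiling Score
#'   distribution parameters.
#' @param age_min,age_max Uniform age range in years.
#' @param males_per_group Males per group (females make up the rest).
#' @param age_slope,sex_slope Optional confounding slopes adding
#'   covariate-driven signal to every edge (default 0).
#' @param seed Master seed.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_nodes = 90L, n_per_group = 28L,
                             rich_fraction = 0.15,
                             core_density = 0.90, feeder_density = 0.62,
                             periphery_density = 0.50,
                             weight_shape1 = 5, weight_shape2 = 6,
                             core_weight_boost = 0.18,
                             feeder_weight_boost = 0.08,
                             subject_sd = 0.05,
                             n_effect_feeder = 10L, n_effect_local = 10L,
                             effect_size = 1.5,
                             n_coupled = 3L,
                             coupling_r = c(0.45, 0.45, -0.44),
                             behavior_mean = 91.6, behavior_sd = 4.0,
                             behavior_floor = 86, behavior_ceiling = 100,
                             age_min = 6, age_max = 16,
                             males_per_group = 21L,
                             age_slope = 0, sex_slope = 0,
                             seed = 1L) {
  stopifnot(core_density > 0, core_density <= 1,
            feeder_density > 0, feeder_density <= 1,
            periphery_density > 0, periphery_density <= 1,
            core_density > periphery_density,
            rich_fraction > 0, rich_fraction < 1,
            is.finite(effect_size),
            males_per_group <= n_per_group)
  if (any(abs(coupling_r) >= 0.95))
    stop("infeasible coupling: |r| too large for the noise model")
  structure(as.list(environment()), class = "synthetic_config")
}

clip01 <- function(x) pmin(pmax(x, 0.001), 0.999)

#' Generate a synthetic cohort with planted ground truth
#'
#' Samples a cohort under a \code{\link{synthetic_config}}: one template
#' topology and baseline weight per edge (shared across subjects, as for
#' a population-template connectome), subject-level Gaussian weight
#' noise, planted patient-vs-control effects on designated feeder/local
#' edges, behavior scores coupled to designated local edges in patients,
#' and age/sex covariates. Effect and coupled edges are drawn from edges
#' strong enough to survive proportional thresholding at 16% density in
#' every subject.
#'
#' @param config A \code{synthetic_config}.
#' @return List: \code{cohort} (a \code{cohort}) and \code{truth} (list:
#'   rich_nodes, effect_edges data.frame (i, j, class, d), coupled_edges
#'   data.frame (i, j, r), config).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_nodes
  n_core <- floor(cf$rich_fraction * n)
  core <- sort(sample.int(n, n_core))
  is_core <- seq_len(n) %in% core

  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  n_core_end <- is_core[i] + is_core[j]
  p_edge <- c(cf$periphery_density, cf$feeder_density,
              cf$core_density)[n_core_end + 1L]
  present <- stats::runif(length(p_edge)) < p_edge
  boost <- c(0, cf$feeder_weight_boost, cf$core_weight_boost)[n_core_end + 1L]
  base <- ifelse(present,
                 clip01(stats::rbeta(length(p_edge), cf$weight_shape1,
                                     cf$weight_shape2) + boost),
                 0)

  cls <- c("local", "feeder", "rich_club")[n_core_end + 1L]

  pick <- function(pool, m) {
    if (length(pool) < m) stop("not enough edges to plant signal")
    if (m == 0L) return(integer(0))
    sample(pool, m)
  }
  avail <- which(present)
  fe <- pick(avail[cls[avail] == "feeder"], cf$n_effect_feeder)
  avail <- setdiff(avail, fe)
  le <- pick(avail[cls[avail] == "local"], cf$n_effect_local)
  avail <- setdiff(avail, le)
  neg <- pick(avail[cls[avail] == "local"], 1L)
  avail <- setdiff(avail, neg)
  cp <- pick(avail[cls[avail] == "local"], cf$n_coupled)
  r_target <- rep_len(cf$coupling_r, cf$n_coupled)

  # planted edges get strong baselines, comfortably above the 16%-density
  # cut, so subject noise cannot drop them out of any subject's graph and
  # every planted signal is testable on the common edge set
  planted <- c(fe, le, neg, cp)
  base[planted] <- stats::runif(length(planted), 0.72, 0.77)
  # the lower-in-patients edge keeps the same margin after its downward shift
  base[neg] <- base[neg] + cf$effect_size * cf$subject_sd

  effect_idx <- c(fe, le, neg)
  effect_d <- c(rep(cf$effect_size, length(fe) + length(le)),
                -cf$effect_size)

  n_sub <- 2L * cf$n_per_group
  group <- rep(c("patient", "control"), each = cf$n_per_group)
  sex <- unlist(lapply(1:2, function(g)
    sample(rep(c("M", "F"), c(cf$males_per_group,
                              cf$n_per_group - cf$males_per_group)))))
  age <- stats::runif(n_sub, cf$age_min, cf$age_max)
  u <- stats::rnorm(n_sub)  # latent behavior factor (used for patients)
  score <- pmin(pmax(cf$behavior_mean + cf$behavior_sd * u,
                     cf$behavior_floor), cf$behavior_ceiling)

  mats <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    dev <- stats::rnorm(length(base), 0, cf$subject_sd)
    w <- base + ifelse(present, dev, 0)
    if (group[s] == "patient") {
      w[effect_idx] <- w[effect_idx] + effect_d * cf$subject_sd
      # behavior coupling replaces the noise on coupled edges so that
      # corr(weight, latent score factor) targets r
      eps <- stats::rnorm(cf$n_coupled)
      w[cp] <- base[cp] +
        cf$subject_sd * (r_target * u[s] + sqrt(1 - r_target^2) * eps)
    }
    w <- w + cf$age_slope * (age[s] - mean(c(cf$age_min, cf$age_max))) +
      cf$sex_slope * (sex[s] == "M")
    w <- ifelse(present, clip01(w), 0)
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- w
    mats[[s]] <- m + t(m)
  }

  subjects <- data.frame(
    subject_id = sprintf("%s%02d", ifelse(group == "patient", "P", "C"),
                         unlist(lapply(1:2, function(g) 1:cf$n_per_group))),
    group = group, age = age, sex = sex,
    behavior_score = ifelse(group == "patient", score, NA_real_),
    matrix_file = NA_character_)

  truth <- list(
    rich_nodes = core,
    effect_edges = data.frame(i = i[effect_idx], j = j[effect_idx],
                              class = cls[effect_idx], d = effect_d),
    coupled_edges = data.frame(i = i[cp], j = j[cp], r = r_target),
    config = cf)
  list(cohort = new_cohort(subjects, mats), truth = truth)
}

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Ground-truth recovery metrics for a pipeline run
#'
#' Compares pipeline outputs against the generator's planted truth:
#' Jaccard overlap of the recovered and planted rich-node sets,
#' sensitivity and false-discovery rate of the detected group-difference
#' edges against the planted effect edges, and the bias of estimated
#' behavior correlations against their targets.
#'
#' @param truth Truth record from \code{\link{generate_cohort}}.
#' @param rich_nodes Recovered rich node ids (or NULL to skip).
#' @param significant_edges data.frame with columns i, j of edges called
#'   significant (or NULL).
#' @param estimated_r data.frame with columns i, j, r of estimated
#'   behavior correlations for the planted coupled edges (or NULL).
#' @return List of recovery metrics (NULL entries for skipped parts):
#'   rich_jaccard, effect_sensitivity, effect_fdr, coupling_bias
#'   (data.frame i, j, r_target, r_est, bias), coupling_max_abs_bias.
#' @export
truth_recovery_report <- function(truth, rich_nodes = NULL,
                                  significant_edges = NULL,
                                  estimated_r = NULL) {
  out <- list(rich_jaccard = NULL, effect_sensitivity = NULL,
              effect_fdr = NULL, coupling_bias = NULL,
              coupling_max_abs_bias = NULL)
  if (!is.null(rich_nodes))
    out$rich_jaccard <- jaccard(rich_nodes, truth$rich_nodes)
  if (!is.null(significant_edges)) {
    key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
    planted <- key(truth$effect_edges)
    called <- key(significant_edges)
    out$effect_sensitivity <- mean(planted %in% called)
    out$effect_fdr <- if (length(called)) mean(!called %in% planted) else 0
  }
  if (!is.null(estimated_r)) {
    ce <- truth$coupled_edges
    m <- match(paste(ce$i, ce$j),
               paste(pmin(estimated_r$i, estimated_r$j),
                     pmax(estimated_r$i, estimated_r$j)))
    if (anyNA(m)) stop("estimated_r is missing planted coupled edges")
    bias <- estimated_r$r[m] - ce$r
    out$coupling_bias <- data.frame(i = ce$i, j = ce$j, r_target = ce$r,
                                    r_est = estimated_r$r[m], bias = bias)
    out$coupling_max_abs_bias <- max(abs(bias))
  }
  out
}
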