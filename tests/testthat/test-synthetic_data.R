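test_that("default generator reproduces the study conditions deterministically", {
  res <- generate_cohort(synthetic_config(seed = 3))
  co <- res$cohort
  expect_equal(nrow(co$subjects), 56L)
  expect_equal(co$n_nodes, 90L)
  expect_equal(sum(co$subjects$group == "patient"), 28L)
  sex_tab <- table(co$subjects$sex[co$subjects$group == "patient"])
  expect_equal(as.vector(sex_tab[c("M", "F")]), c(21L, 7L))

  for (m in co$matrices[c(1, 30)]) {
    expect_true(isSymmetric(m))
    expect_equal(diag(m), rep(0, 90))
    expect_true(all(m >= 0 & m < 1))
  }
  expect_true(all(co$subjects$age >= 6 & co$subjects$age <= 16))

  scores <- co$subjects$behavior_score[co$subjects$group == "patient"]
  expect_true(all(scores >= 86 & scores <= 100))
  expect_true(all(is.na(co$subjects$behavior_score[
    co$subjects$group == "control"])))

  res2 <- generate_cohort(synthetic_config(seed = 3))
  expect_identical(res$cohort$matrices, res2$cohort$matrices)
  expect_identical(res$truth$effect_edges, res2$truth$effect_edges)
  expect_equal(nrow(res$truth$effect_edges), 21L)
  expect_true(all(res$truth$effect_edges$class %in% c("feeder", "local")))
})

test_that("behavior scores match the intended scale across seeds", {
  scores <- unlist(lapply(1:10, function(s) {
    co <- generate_cohort(small_config(seed = s))$cohort
    co$subjects$behavior_score[co$subjects$group == "patient"]
  }))
  expect_equal(mean(scores), 92.3, tolerance = 0.02)  # 91.6 shifted by the 86 floor
  expect_gt(stats::sd(scores), 2.5)
  expect_lt(stats::sd(scores), 4.5)
})

test_that("planted core nodes out-degree the periphery in every subject", {
  for (s in 1:10) {
    res <- generate_cohort(small_config(seed = 200 + s))
    core <- res$truth$rich_nodes
    for (m in res$cohort$matrices[c(1, 9)]) {
      g <- threshold_by_density(m, 0.16)
      deg <- rowSums(g$weights > 0)
      expect_gt(mean(deg[core]), mean(deg[-core]))
    }
  }
})

test_that("planted group effects match the configured effect size", {
  # across replicates, mean(patient - control) on effect edges ~ d * sd
  cf <- small_config(seed = 1)
  devs <- unlist(lapply(1:60, function(s) {
    res <- generate_cohort(small_config(seed = 400 + s))
    ee <- res$truth$effect_edges
    pos <- ee[ee$d > 0, ]
    grp <- res$cohort$subjects$group
    vapply(seq_len(nrow(pos)), function(r) {
      w <- vapply(res$cohort$matrices, function(m) m[pos$i[r], pos$j[r]],
                  numeric(1))
      mean(w[grp == "patient"]) - mean(w[grp == "control"])
    }, numeric(1))
  }))
  target <- cf$effect_size * cf$subject_sd
  se <- stats::sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs) - target), 2 * se + 0.002)
})

test_that("behavior coupling recovers the target correlation on average", {
  ests <- t(vapply(1:150, function(s) {
    res <- generate_cohort(small_config(seed = 700 + s))
    ce <- res$truth$coupled_edges
    pat <- res$cohort$subjects$group == "patient"
    scores <- res$cohort$subjects$behavior_score[pat]
    vapply(seq_len(nrow(ce)), function(r) {
      w <- vapply(res$cohort$matrices[pat], function(m) m[ce$i[r], ce$j[r]],
                  numeric(1))
      stats::cor(w, scores)
    }, numeric(1))
  }, numeric(2)))
  targets <- small_config(seed = 1)$coupling_r
  expect_lt(abs(mean(ests[, 1]) - targets[1]), 0.1)
  expect_lt(abs(mean(ests[, 2]) - targets[2]), 0.1)
})

test_that("truth recovery metrics behave at their extremes", {
  res <- generate_cohort(small_config(seed = 31))
  tr <- res$truth
  perfect <- truth_recovery_report(tr, rich_nodes = tr$rich_nodes,
                                   significant_edges = tr$effect_edges)
  expect_equal(perfect$rich_jaccard, 1)
  expect_equal(perfect$effect_sensitivity, 1)
  expect_equal(perfect$effect_fdr, 0)

  disjoint <- truth_recovery_report(
    tr, rich_nodes = setdiff(1:30, tr$rich_nodes),
    significant_edges = data.frame(i = 1, j = 2))
  expect_equal(disjoint$rich_jaccard, 0)
  expect_equal(disjoint$effect_sensitivity, 0)

  est <- tr$coupled_edges
  names(est)[3] <- "r"
  rec <- truth_recovery_report(tr, estimated_r = est)
  expect_equal(rec$coupling_max_abs_bias, 0)
})

test_that("with no planted effects the edge-wise false-positive rate is calibrated", {
  res <- generate_cohort(small_config(seed = 41, n_per_group = 14L,
                                      males_per_group = 10L,
                                      n_effect_feeder = 0L,
                                      n_effect_local = 0L,
                                      effect_size = 0))
  # the generator always plants one negative local edge; neutralize via d = 0
  expect_true(all(res$truth$effect_edges$d == 0))
  rich <- identify_rich_regions(res$cohort, 0.16, 0.15)
  et <- edgewise_group_test(res$cohort, rich, alpha = 0.05)
  expect_lt(mean(et$significant), 0.15)
})
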