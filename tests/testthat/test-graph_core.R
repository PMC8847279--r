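test_that("proportional thresholding keeps the k strongest edges", {
  # complete weighted 4-node graph: 6 edges, density 0.5 -> 3 strongest
  m <- mat_from_edges(4, c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4),
                      c(.9, .8, .7, .3, .2, .1))
  g <- threshold_by_density(m, 0.5)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sort(g$edges$w), c(.7, .8, .9))
  expect_equal(g$density, 0.5)

  g1 <- threshold_by_density(m, 1)
  expect_equal(nrow(g1$edges), 6L)
  expect_equal(g1$weights, m)

  expect_error(threshold_by_density(m, 0.01), "zero retained edges")
  expect_warning(threshold_by_density(mat_from_edges(6, 1, 2, .5), 0.9),
                 "keeping all")
})

test_that("ties at the density cut resolve by lexicographic (i, j) order", {
  # weights .9, .5, .5, .1 on distinct pairs; k = 2 cuts inside the .5 tie
  m <- mat_from_edges(5, c(1, 1, 2, 3), c(2, 3, 4, 4), c(.9, .5, .5, .1))
  k2 <- floor(0.2 * 10)  # = 2
  g <- threshold_by_density(m, 0.2)
  expect_equal(nrow(g$edges), k2)
  # the (1,3) .5 edge wins over (2,4) by smaller pair
  expect_equal(g$edges[, c("i", "j")],
               data.frame(i = c(1, 1), j = c(2, 3)))
  expect_identical(g, threshold_by_density(m, 0.2))
})

test_that("edge sets are nested along the density grid", {
  set.seed(21)
  for (rep in 1:5) {
    m <- random_weighted_matrix(12, p = 0.7)
    prev <- character(0)
    for (d in seq(0.1, 1, by = 0.15)) {
      # high grid densities may exceed the available edges; that path is
      # its own contract test elsewhere
      g <- suppressWarnings(threshold_by_density(m, d))
      cur <- paste(g$edges$i, g$edges$j)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("Onnela clustering matches hand values and brute force", {
  tri <- tg_full(mat_from_edges(3, c(1, 1, 2), c(2, 3, 3), 1))
  expect_equal(clustering_coefficient(tri), 1)

  star <- tg_full(mat_from_edges(4, c(1, 1, 1), c(2, 3, 4), 1))
  expect_equal(clustering_coefficient(star), 0)

  tri2 <- tg_full(mat_from_edges(3, c(1, 1, 2), c(2, 3, 3), c(1, 1, 0.125)))
  expect_equal(clustering_coefficient(tri2), 0.5)

  set.seed(31)
  for (rep in 1:10) {
    m <- random_weighted_matrix(sample(4:6, 1))
    if (all(m == 0)) next
    expect_equal(clustering_coefficient(tg_full(m)), brute_cp(m),
                 tolerance = 1e-12)
  }
})

test_that("characteristic path length uses 1/w distances and excludes disconnected pairs", {
  two <- tg_full(mat_from_edges(2, 1, 2, 0.5))
  expect_equal(as.numeric(characteristic_path_length(two)), 2)

  path3 <- tg_full(mat_from_edges(3, c(1, 2), c(2, 3), 1))
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)

  tri <- tg_full(mat_from_edges(3, c(1, 1, 2), c(2, 3, 3), 1))
  expect_equal(as.numeric(characteristic_path_length(tri)), 1)

  # isolated node: 2 of 3 pairs disconnected
  iso <- tg_full(mat_from_edges(3, 1, 2, 1))
  lp <- characteristic_path_length(iso)
  expect_equal(as.numeric(lp), 1)
  expect_equal(attr(lp, "n_disconnected_pairs"), 2L)

  set.seed(41)
  for (rep in 1:10) {
    m <- random_weighted_matrix(sample(4:6, 1))
    if (all(m == 0)) next
    expect_equal(as.numeric(characteristic_path_length(tg_full(m))),
                 brute_lp(m), tolerance = 1e-12)
  }
})

test_that("small-world normalization obeys the self-null identity and sigma = gamma/lambda", {
  set.seed(51)
  m <- random_weighted_matrix(10)
  g <- tg_full(m)
  self_null <- list(cp_mean = clustering_coefficient(g),
                    lp_mean = as.numeric(characteristic_path_length(g)))
  sw <- small_world_metrics(g, self_null)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda_, 1)
  expect_equal(sw$sigma, 1)
  expect_error(small_world_metrics(g, list(cp_mean = 0, lp_mean = 1)),
               "zero")

  ns <- ensemble_stats(threshold_by_density(m, 0.4), size = 10, seed = 3)
  sw2 <- small_world_metrics(threshold_by_density(m, 0.4), ns)
  expect_identical(sw2$sigma, sw2$gamma / sw2$lambda_)
})

test_that("trapezoid AUC matches hand-computed areas", {
  grid <- density_grid(0.05, 0.50, 0.01)
  expect_equal(auc_trapezoid(grid, rep(2, length(grid))), 0.45 * 2)
  lin <- seq(0, 1, length.out = length(grid))
  expect_equal(auc_trapezoid(grid, lin), 0.225)
  expect_warning(a1 <- auc_trapezoid(0.16, 3), "fewer than 2 points")
  expect_equal(a1, 0)
  expect_warning(auc_trapezoid(c(.1, .2, .3), c(1, NA, 1)), "missing")
})

test_that("metric_curve is deterministic under a fixed seed and records failures as missing", {
  set.seed(61)
  m <- random_weighted_matrix(20, p = 0.5)
  grid <- density_grid(0.1, 0.4, 0.1)
  c1 <- metric_curve(m, grid, "sigma", ensemble_size = 10, seed = 7)
  c2 <- metric_curve(m, grid, "sigma", ensemble_size = 10, seed = 7)
  expect_identical(c1$values, c2$values)
  expect_identical(c1$auc, c2$auc)
  expect_equal(length(c1$values), length(grid))

  cp_curve <- metric_curve(m, grid, "cp")
  g_manual <- vapply(grid, function(d)
    clustering_coefficient(threshold_by_density(m, d)), numeric(1))
  expect_equal(cp_curve$values, g_manual)
})
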