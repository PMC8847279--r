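#' Density grid for proportional thresholding
#'
#' The sequence of connection densities at which each subject's network is
#' thresholded; graph metrics are evaluated at every grid point and
#' summarized by the area under the resulting curve. The default range
#' 0.05 to 0.50 in steps of 0.01 is the standard sparse-to-dense sweep for
#' structural connectomes.
#'
#' @param start,stop,step Density fractions; \code{0 < start <= stop <= 1},
#'   \code{step > 0}.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(start = 0.05, stop = 0.50, step = 0.01) {
  if (!(start > 0 && start <= stop && stop <= 1 && step > 0))
    stop("need 0 < start <= stop <= 1 and step > 0")
  g <- seq(start, stop, by = step)
  # guard against seq() dropping the endpoint to fp error
  if (stop - g[length(g)] > step / 2) g <- c(g, stop)
  g
}

# Upper-triangle edge list of a symmetric matrix, ordered for thresholding:
# weight descending, ties by lexicographic (i, j) ascending so the retained
# edge set is deterministic and nested across densities.
edge_table <- function(m) {
  n <- nrow(m)
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  w <- m[ut]
  ord <- order(-w, ut[, 1L], ut[, 2L])
  data.frame(i = ut[ord, 1L], j = ut[ord, 2L], w = w[ord])
}

#' Proportional density thresholding
#'
#' Retains the \code{k = floor(density * n(n-1)/2)} strongest edges of a
#' weighted connectivity matrix so that every subject's graph has the same
#' number of edges at a given density. Retained edges keep their original
#' weights. Ties at the cut are broken by lexicographic (i, j) order
#' (smallest pair kept first), which makes edge sets nested across
#' densities.
#'
#' @param m Validated symmetric connectivity matrix.
#' @param density Target edge fraction in (0, 1].
#' @return A \code{thresholded_graph}: list with \code{weights} (dense
#'   symmetric matrix of retained edges), \code{edges} (data.frame i, j, w
#'   with i < j), \code{density_target} and \code{density} (achieved).
#' @export
threshold_by_density <- function(m, density) {
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  k <- floor(density * n_pairs)
  if (k < 1) stop("density ", density, " yields zero retained edges")
  et <- edge_table(m)
  if (nrow(et) < k) {
    # at density 1 "all nonzero edges" is the definition, not a shortfall
    if (density < 1)
      warning("only ", nrow(et), " nonzero edges available for k = ", k,
              "; keeping all")
    k <- nrow(et)
  }
  keep <- et[seq_len(k), , drop = FALSE]
  w <- matrix(0, n, n)
  w[cbind(keep$i, keep$j)] <- keep$w
  w <- w + t(w)
  structure(list(weights = w, edges = keep, n_nodes = n,
                 density_target = density, density = k / n_pairs),
            class = "thresholded_graph")
}

as_igraph <- function(g, weighted = TRUE) {
  if (weighted)
    igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  else
    igraph::graph_from_adjacency_matrix((g$weights > 0) + 0,
                                        mode = "undirected", diag = FALSE)
}

#' Network clustering coefficient (Cp, Onnela weighted variant)
#'
#' Per node, \eqn{C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h}
#' (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}} with weights normalized by
#' the network maximum, \eqn{\hat w = w / \max(w)}; nodes with degree < 2
#' contribute 0. Cp is the mean over all nodes and measures network
#' segregation.
#'
#' @param g A \code{thresholded_graph}.
#' @return Cp, a scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  n <- g$n_nodes
  if (n < 3) stop("clustering needs at least 3 nodes")
  if (nrow(g$edges) == 0L) stop("empty graph")
  w <- g$weights / max(g$weights)
  a <- (w > 0) + 0
  deg <- rowSums(a)
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)
  ci <- ifelse(deg >= 2, tri / (deg * pmax(deg - 1, 1)), 0)
  mean(ci)
}

#' Characteristic path length (Lp)
#'
#' Mean shortest path length over all connected node pairs, with edge
#' distance \code{1/weight} (stronger connections are shorter). Pairs in
#' different components are excluded from the mean; their count is attached
#' as attribute \code{n_disconnected_pairs}.
#'
#' @param g A \code{thresholded_graph}.
#' @return Lp (scalar, > 0), with attribute \code{n_disconnected_pairs}.
#' @export
characteristic_path_length <- function(g) {
  if (g$n_nodes < 2) stop("path length needs at least 2 nodes")
  ig <- as_igraph(g)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                         algorithm = "dijkstra")
  vals <- d[upper.tri(d)]
  fin <- is.finite(vals)
  if (!any(fin)) stop("no connected node pairs")
  structure(mean(vals[fin]), n_disconnected_pairs = sum(!fin))
}

#' Small-world metrics normalized by a null ensemble
#'
#' gamma = Cp / mean Cp of degree-preserving random networks,
#' lambda = Lp / mean Lp of the same ensemble, and small-worldness
#' sigma = gamma / lambda; sigma > 1 indicates small-world organization.
#'
#' @param g A \code{thresholded_graph}.
#' @param null_stats \code{\link{ensemble_stats}} of the same graph.
#' @return List with cp, lp, gamma, lambda, sigma.
#' @export
small_world_metrics <- function(g, null_stats) {
  cp <- clustering_coefficient(g)
  lp <- as.numeric(characteristic_path_length(g))
  if (!is.finite(null_stats$cp_mean) || null_stats$cp_mean == 0)
    stop("null ensemble Cp mean is zero or undefined")
  if (!is.finite(null_stats$lp_mean) || null_stats$lp_mean == 0)
    stop("null ensemble Lp mean is zero or undefined")
  gamma <- cp / null_stats$cp_mean
  lambda <- lp / null_stats$lp_mean
  list(cp = cp, lp = lp, gamma = gamma, lambda_ = lambda,
       sigma = gamma / lambda)
}

#' Trapezoidal area under a curve
#' @param x Ordered abscissae. @param y Values (NA allowed; dropped pairwise).
#' @return Scalar AUC over the span of non-missing points.
#' @export
auc_trapezoid <- function(x, y) {
  ok <- !is.na(y)
  if (any(!ok)) warning(sum(!ok), " missing values excluded from AUC")
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    warning("fewer than 2 points; AUC set to 0")
    return(0)
  }
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Graph metric as a function of density, with AUC
#'
#' Evaluates one metric (\code{"cp"}, \code{"lp"}, \code{"gamma"},
#' \code{"lambda"}, \code{"sigma"}) at every density of the grid. The
#' normalized metrics regenerate a degree-preserving null ensemble at each
#' density, with per-density seeds derived from \code{seed}. Densities
#' where the metric fails (for example no connected pairs) are recorded as
#' missing and excluded from the AUC with a warning.
#'
#' @param m Connectivity matrix.
#' @param grid Density vector from \code{\link{density_grid}}.
#' @param metric Metric name.
#' @param ensemble_size Null networks per density (normalized metrics only).
#' @param seed Master seed for the null ensembles.
#' @return A \code{metric_curve}: list(densities, values, auc, metric,
#'   ensemble_size, seed).
#' @export
metric_curve <- function(m, grid, metric = c("cp", "lp", "gamma", "lambda",
                                             "sigma"),
                         ensemble_size = 100L, seed = 1L) {
  metric <- match.arg(metric)
  needs_null <- metric %in% c("gamma", "lambda", "sigma")
  vals <- vapply(seq_along(grid), function(idx) {
    tryCatch({
      g <- threshold_by_density(m, grid[idx])
      if (needs_null) {
        ns <- ensemble_stats(g, size = ensemble_size,
                             seed = derive_seed(seed, idx),
                             metrics = c("cp", "lp"))
        sw <- small_world_metrics(g, ns)
        switch(metric, gamma = sw$gamma, lambda = sw$lambda_,
               sigma = sw$sigma)
      } else {
        switch(metric,
               cp = clustering_coefficient(g),
               lp = as.numeric(characteristic_path_length(g)))
      }
    }, error = function(e) {
      warning("density ", grid[idx], ": ", conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  structure(list(densities = grid, values = vals,
                 auc = auc_trapezoid(grid, vals),
                 metric = metric, ensemble_size = ensemble_size,
                 seed = seed),
            class = "metric_curve")
}

#' Export a metric curve as CSV plus sidecar JSON metadata
#' @param curve A \code{metric_curve}. @param path CSV path; the sidecar is
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_metric_curve <- function(curve, path) {
  utils::write.csv(data.frame(density = curve$densities,
                              value = curve$values),
                   path, row.names = FALSE)
  jsonlite::write_json(list(metric = curve$metric, auc = curve$auc,
                            ensemble_size = curve$ensemble_size,
                            seed = curve$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
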