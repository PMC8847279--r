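# Counter-based seed derivation: replicate r of a master seed gets an
# independent, reproducible stream regardless of execution order. Kept
# below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 +
                as.numeric(counter) * 1000003) %% 2147483647)
}

#' Degree-preserving randomization of a thresholded graph
#'
#' Randomizes topology by Maslov-Sneppen double-edge swaps (the standard
#' "comparable random network" construction), preserving every node's
#' degree exactly, then reassigns the original weight multiset onto the
#' rewired edges by random permutation, so total weight is conserved.
#'
#' @param g A \code{thresholded_graph}.
#' @param n_swaps_per_edge Swap attempts per edge (default 10).
#' @param seed Optional seed set before rewiring.
#' @return A randomized \code{thresholded_graph}.
#' @export
rewire_degree_preserving <- function(g, n_swaps_per_edge = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(g$edges)
  if (ne < 2L) {
    warning("graph too small to swap; returned unchanged")
    return(g)
  }
  ig <- as_igraph(g, weighted = FALSE)
  rg <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                  niter = n_swaps_per_edge * ne))
  el <- igraph::as_edgelist(rg, names = FALSE)
  i <- pmin(el[, 1L], el[, 2L])
  j <- pmax(el[, 1L], el[, 2L])
  w <- sample(g$edges$w)
  n <- g$n_nodes
  wm <- matrix(0, n, n)
  wm[cbind(i, j)] <- w
  wm <- wm + t(wm)
  ord <- order(-w, i, j)
  structure(list(weights = wm,
                 edges = data.frame(i = i[ord], j = j[ord], w = w[ord]),
                 n_nodes = n, density_target = g$density_target,
                 density = g$density),
            class = "thresholded_graph")
}

#' Null-ensemble statistics for small-world and rich-club normalization
#'
#' Generates \code{size} degree-preserving randomized copies of \code{g}
#' (per-replicate seeds derived from the master seed) and returns ensemble
#' means of the weighted clustering coefficient, characteristic path
#' length, and the rich-club coefficient Phi(k) for each degree k
#' requested. Phi is topological, so the weight permutation does not
#' affect \code{phi_rand_by_k}.
#'
#' @param g A \code{thresholded_graph}.
#' @param size Ensemble size (>= 1).
#' @param seed Master seed.
#' @param k_range Integer degrees at which to average Phi; NULL to skip.
#' @param metrics Which of \code{"cp"}, \code{"lp"} to compute (skipping
#'   unneeded metrics keeps rich-club-only ensembles fast).
#' @return List with size, seed, cp_mean, lp_mean, phi_rand_by_k (named
#'   vector, NA where fewer than 2 nodes exceed k in every replicate),
#'   density, and weight_null = "permuted" flagging the weighted-null
#'   construction used.
#' @export
ensemble_stats <- function(g, size, seed = 1L, k_range = NULL,
                           metrics = c("cp", "lp")) {
  if (size < 1L) stop("ensemble size must be >= 1")
  cp <- lp <- rep(NA_real_, size)
  phi <- if (!is.null(k_range))
    matrix(NA_real_, size, length(k_range),
           dimnames = list(NULL, k_range))
  for (r in seq_len(size)) {
    rg <- rewire_degree_preserving(g, seed = derive_seed(seed, r))
    if ("cp" %in% metrics) cp[r] <- clustering_coefficient(rg)
    if ("lp" %in% metrics)
      lp[r] <- as.numeric(characteristic_path_length(rg))
    if (!is.null(k_range))
      phi[r, ] <- vapply(k_range, function(k) rich_club_coefficient(rg, k),
                         numeric(1))
  }
  list(size = size, seed = seed,
       cp_mean = if ("cp" %in% metrics) mean(cp) else NA_real_,
       lp_mean = if ("lp" %in% metrics) mean(lp) else NA_real_,
       phi_rand_by_k = if (!is.null(k_range))
         colMeans(phi, na.rm = TRUE) else NULL,
       density = g$density_target,
       weight_null = "permuted")
}
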