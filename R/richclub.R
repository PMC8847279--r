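#' Rich-club coefficient Phi(k)
#'
#' Among the club of nodes with (binary) degree greater than k, the ratio
#' of existing to possible connections:
#' \eqn{\Phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))}, computed on the
#' binarized topology of the thresholded graph. Undefined (NA) when fewer
#' than two nodes exceed k.
#'
#' @param g A \code{thresholded_graph}.
#' @param k Degree threshold (>= 1).
#' @return Phi(k) in \[0, 1\], or NA when undefined.
#' @export
rich_club_coefficient <- function(g, k) {
  if (k < 1) stop("k must be >= 1")
  a <- (g$weights > 0) + 0
  deg <- rowSums(a)
  s <- which(deg > k)
  if (length(s) < 2L) return(NA_real_)
  e_s <- sum(a[s, s]) / 2
  2 * e_s / (length(s) * (length(s) - 1))
}

#' Rich-club profile with random-network normalization
#'
#' Phi(k), the ensemble mean Phi_rand(k) of degree-preserving random
#' networks, and the normalized coefficient
#' Phi_norm(k) = Phi(k) / Phi_rand(k) at each degree k, computed on the
#' matrix thresholded at a fixed density (16% is the conventional choice).
#' Phi_norm > 1 across a range of k indicates rich-club organization.
#'
#' @param m Connectivity matrix.
#' @param density Proportional threshold at which the graph and its null
#'   ensemble are evaluated.
#' @param ensemble \code{\link{ensemble_stats}} computed with the same
#'   density and a \code{k_range} covering \code{k_range} here.
#' @param k_range Integer degrees.
#' @return data.frame (class \code{rich_club_profile}) with columns k,
#'   phi, phi_rand, phi_norm.
#' @export
rich_club_profile <- function(m, density, ensemble, k_range) {
  if (!isTRUE(all.equal(ensemble$density, density)))
    stop("ensemble density ", ensemble$density,
         " does not match requested density ", density)
  if (is.null(ensemble$phi_rand_by_k) ||
      !all(as.character(k_range) %in% names(ensemble$phi_rand_by_k)))
    stop("ensemble lacks phi_rand for requested k_range")
  g <- threshold_by_density(m, density)
  phi <- vapply(k_range, function(k) rich_club_coefficient(g, k), numeric(1))
  phi_rand <- unname(ensemble$phi_rand_by_k[as.character(k_range)])
  phi_norm <- ifelse(!is.na(phi_rand) & phi_rand > 0, phi / phi_rand,
                     NA_real_)
  structure(data.frame(k = k_range, phi = phi, phi_rand = phi_rand,
                       phi_norm = phi_norm),
            class = c("rich_club_profile", "data.frame"),
            density = density)
}

#' Identify rich-club regions from a pooled cohort
#'
#' Each subject's matrix is thresholded at \code{density}; binary nodal
#' degree is averaged across ALL subjects (both groups pooled, so the
#' selection cannot favor either group), and the top
#' \code{floor(fraction_rich * n)} nodes by averaged degree are the
#' rich-club regions. Ties at the cut are broken by higher average
#' strength (sum of retained weights), then lower node id.
#'
#' @param cohort A \code{cohort}.
#' @param density Proportional threshold (default 0.16).
#' @param fraction_rich Fraction of nodes in the club (default 0.15; with
#'   90 regions that selects 13).
#' @return Integer vector of rich node ids (1-based), with attribute
#'   \code{mean_degree} (full per-node averaged degree, in node order).
#' @export
identify_rich_regions <- function(cohort, density = 0.16,
                                  fraction_rich = 0.15) {
  if (!(fraction_rich > 0 && fraction_rich < 1))
    stop("fraction_rich must be in (0, 1)")
  if (length(cohort$matrices) == 0L) stop("empty cohort")
  n <- cohort$n_nodes
  deg <- str <- matrix(0, length(cohort$matrices), n)
  for (s in seq_along(cohort$matrices)) {
    g <- threshold_by_density(cohort$matrices[[s]], density)
    deg[s, ] <- rowSums(g$weights > 0)
    str[s, ] <- rowSums(g$weights)
  }
  mean_deg <- colMeans(deg)
  mean_str <- colMeans(str)
  n_rich <- floor(fraction_rich * n)
  if (n_rich < 1) stop("fraction_rich selects zero nodes")
  ord <- order(-mean_deg, -mean_str, seq_len(n))
  rich <- sort(ord[seq_len(n_rich)])
  structure(rich, mean_degree = mean_deg)
}

#' Classify retained edges as rich-club / feeder / local
#'
#' Rich-club connections link two rich-club regions, feeder connections
#' link a rich-club region to a peripheral one, and local connections link
#' two peripheral regions. The labeling is exhaustive and mutually
#' exclusive.
#'
#' @param rich_nodes Integer vector of rich node ids.
#' @param g A \code{thresholded_graph}.
#' @return data.frame with columns i, j, w, class.
#' @export
classify_edges <- function(rich_nodes, g) {
  if (length(rich_nodes) == 0L) stop("rich set is empty")
  if (length(rich_nodes) >= g$n_nodes)
    stop("rich set must be a proper subset of nodes")
  e <- g$edges
  n_rich_end <- (e$i %in% rich_nodes) + (e$j %in% rich_nodes)
  e$class <- c("local", "feeder", "rich_club")[n_rich_end + 1L]
  e
}

edge_class_of <- function(i, j, rich_nodes) {
  c("local", "feeder", "rich_club")[(i %in% rich_nodes) +
                                      (j %in% rich_nodes) + 1L]
}

#' Connectivity strength per connection class
#'
#' Sum of retained edge weights within each class for one subject's
#' thresholded graph. The three strengths partition the total retained
#' weight exactly.
#'
#' @param rich_nodes Integer vector of rich node ids.
#' @param g A \code{thresholded_graph}.
#' @return Named numeric vector (rich_club, feeder, local).
#' @export
class_strengths <- function(rich_nodes, g) {
  e <- classify_edges(rich_nodes, g)
  out <- c(rich_club = 0, feeder = 0, local = 0)
  sums <- tapply(e$w, e$class, sum)
  out[names(sums)] <- sums
  out
}
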