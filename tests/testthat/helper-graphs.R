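# Small-graph constructors and brute-force oracles used across tests.

mat_from_edges <- function(n, i, j, w = 1) {
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- w
  m + t(m)
}

tg_full <- function(m) threshold_by_density(m, 1)

# random connected-ish weighted graph for property tests
random_weighted_matrix <- function(n, p = 0.6) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- ut[stats::runif(length(ut)) < p]
  m[on] <- stats::runif(length(on), 0.05, 1)
  m + t(m)
}

# Onnela weighted clustering by explicit triple loop
brute_cp <- function(m) {
  n <- nrow(m)
  w <- m / max(m)
  a <- m > 0
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# characteristic path length by Floyd-Warshall on 1/w distances
brute_lp <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[m > 0] <- 1 / m[m > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

# rich-club coefficient by direct enumeration
brute_phi <- function(m, k) {
  a <- m > 0
  deg <- rowSums(a)
  s <- which(deg > k)
  if (length(s) < 2) return(NA_real_)
  e <- 0
  for (x in s) for (y in s) if (x < y && a[x, y]) e <- e + 1
  2 * e / (length(s) * (length(s) - 1))
}

# ROC AUC by exhaustive pairwise concordance
brute_auc_roc <- function(dv, labels) {
  pos <- which(labels == "patient")
  neg <- which(labels == "control")
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (dv[p] > dv[q]) 1 else if (dv[p] == dv[q]) 0.5 else 0
  s / (length(pos) * length(neg))
}

# tiny synthetic cohorts for fast tests
small_config <- function(seed = 1L, n_per_group = 8L, males_per_group = 6L,
                         n_effect_feeder = 3L, n_effect_local = 3L,
                         n_coupled = 2L, coupling_r = c(0.5, -0.44), ...) {
  synthetic_config(n_nodes = 30L, n_per_group = n_per_group,
                   males_per_group = males_per_group,
                   n_effect_feeder = n_effect_feeder,
                   n_effect_local = n_effect_local,
                   n_coupled = n_coupled, coupling_r = coupling_r,
                   seed = seed, ...)
}

# well-separated two-class Gaussian feature matrix for SVM tests
gaussian_clouds <- function(n_per_class = 20L, n_features = 50L,
                            n_informative = 10L, d = 4, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  n_informative <- min(n_informative, n_features)
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  labels <- rep(c("patient", "control"), each = n_per_class)
  x[labels == "patient", seq_len(n_informative)] <-
    x[labels == "patient", seq_len(n_informative)] + d
  colnames(x) <- paste0("f", seq_len(n_features))
  list(x = x, labels = labels)
}
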