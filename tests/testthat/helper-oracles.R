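# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form and
# must stay independent of the package code paths they check.

# O(n^3) agglomerative complete linkage by exhaustive recomputation:
# returns the sorted merge heights and the partition at every k
brute_complete_linkage <- function(X) {
  X <- as.matrix(X)
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  partitions[[length(clusters)]] <- seq_len(nrow(X))
  cluster_dist <- function(a, b) {
    max(apply(X[a, , drop = FALSE], 1, function(p)
      apply(X[b, , drop = FALSE], 1, function(q) sqrt(sum((p - q)^2)))))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < bestd) { bestd <- d; best <- c(j, i) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    memb <- integer(nrow(X))
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# construct an n x p data matrix whose *sample* correlation matrix is
# exactly R (orthogonalise iid noise, then colour by chol(R))
exact_correlation_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, scale = FALSE)
  Z <- qr.Q(qr(Z)) * sqrt(n - 1)   # exactly uncorrelated, unit variance
  Z %*% chol(R)
}

# one-way MANOVA H and E matrices from first principles
manova_HE_oneway <- function(Y, g) {
  g <- factor(g)
  grand <- colMeans(Y)
  H <- matrix(0, ncol(Y), ncol(Y))
  E <- matrix(0, ncol(Y), ncol(Y))
  for (lv in levels(g)) {
    Yg <- Y[g == lv, , drop = FALSE]
    d <- colMeans(Yg) - grand
    H <- H + nrow(Yg) * tcrossprod(d)
    E <- E + crossprod(scale(Yg, scale = FALSE))
  }
  list(H = H, E = E)
}

# one-tailed Student-t quantile by numerical inversion of pt(), kept
# independent of qt()
t_quantile_inverted <- function(p, df) {
  stats::uniroot(function(x) stats::pt(x, df) - p,
                 interval = c(-50, 50), tol = 1e-10)$root
}

# pooled-covariance Gaussian classifier evaluated specimen by specimen
# (the discriminant-score argmax rule, re-derived independently of MASS)
argmax_classify <- function(X, g, prior = NULL) {
  g <- factor(g)
  k <- nlevels(g)
  n <- nrow(X)
  if (is.null(prior)) prior <- as.vector(table(g)) / n
  mus <- lapply(levels(g), function(lv) colMeans(X[g == lv, , drop = FALSE]))
  Sp <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(g))
    Sp <- Sp + crossprod(scale(X[g == lv, , drop = FALSE], scale = FALSE))
  Sp <- Sp / (n - k)
  Si <- solve(Sp)
  scores <- sapply(seq_len(k), function(j) {
    mu <- mus[[j]]
    as.vector(X %*% Si %*% mu) - 0.5 * drop(mu %*% Si %*% mu) +
      log(prior[j])
  })
  factor(levels(g)[max.col(scores)], levels = levels(g))
}

# small complete specimen table written to a temp CSV, for reader tests
write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

fixture_rows <- function() {
  data.frame(
    specimen_id = c("A1", "A2", "A3"),
    repository = "AMNH",
    subspecies = c("maynardi", "rileyi", "dominicae"),
    locale = c("Florida", "Barbuda", "Dominica"),
    sex = c("male", "female", "unknown"),
    collection_date = c("1901-05-02", "1920-11-30", ""),
    bill_length_mm = c(19.8, 22.1, 24.0),
    bill_width_mm = c(6.1, 6.9, 7.4),
    bill_depth_mm = c(7.0, 8.2, 9.1),
    color_chin = c(0, 2, 4),
    color_breast = c(1, 2, 5),
    color_belly = c(1, 3, 5),
    color_vent = c(2, 3, 5),
    stringsAsFactors = FALSE
  )
}
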