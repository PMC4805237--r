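test_that("PCA composite follows the correlation-matrix closed forms", {
  # three perfectly correlated traits: PC1 carries all the variance
  set.seed(1)
  z <- rnorm(40)
  X <- cbind(bill_length_mm = 3 * z + 20, bill_width_mm = 0.5 * z + 6,
             bill_depth_mm = z + 7)
  res <- pca_composite(X)
  expect_equal(res$prop_var[1], 1)

  # exact equicorrelation rho = 0.5: PC1 share is (1 + 2 rho) / 3
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  Xe <- exact_correlation_data(60, R, seed = 2)
  colnames(Xe) <- bill_traits()
  rese <- pca_composite(Xe)
  expect_equal(rese$prop_var[1], 2 / 3, tolerance = 1e-10)
  expect_equal(sum(rese$prop_var), 1)

  # orientation convention: composite correlates positively with depth
  expect_gt(rese$trait_correlations[["bill_depth_mm"]], 0)
  # loadings orthonormal
  expect_equal(crossprod(rese$loadings), diag(3), ignore_attr = TRUE)

  Xc <- X; Xc[, 2] <- 6
  expect_error(pca_composite(Xc), "constant")
})

test_that("PC1 share is at least 1/3 when all trait correlations are non-negative", {
  set.seed(3)
  for (i in 1:8) {
    repeat {
      A <- matrix(runif(9, 0, 1), 3)
      S <- crossprod(A) + diag(0.1, 3)
      R <- stats::cov2cor(S)
      if (all(R >= 0)) break
    }
    X <- exact_correlation_data(50, R, seed = i)
    colnames(X) <- bill_traits()
    expect_gte(pca_composite(X)$prop_var[1], 1 / 3)
  }
})

test_that("Pillai's trace matches the eigenvalue-form oracle and its bounds", {
  set.seed(5)
  # two-group bivariate fixture, one-way
  g <- rep(c("m", "f"), each = 12)
  Y <- cbind(a = rnorm(24) + (g == "m") * 0.8, b = rnorm(24))
  rec <- data.frame(sex = g, a = Y[, 1], b = Y[, 2])
  res <- pillai_manova(rec, response = c("a", "b"), covariate_name = NULL)

  HE <- manova_HE_oneway(Y, g)
  lam <- Re(eigen(HE$H %*% solve(HE$E))$values)
  expect_equal(res$pillai, sum(lam / (1 + lam)), tolerance = 1e-10)

  # agreement with the standard sequential implementation (one factor)
  sm <- summary(stats::manova(Y ~ g), test = "Pillai")$stats
  expect_equal(res$pillai, sm["g", "Pillai"], tolerance = 1e-10)
  expect_equal(res$approx_F, sm["g", "approx F"], tolerance = 1e-10)
  expect_equal(res$p, sm["g", "Pr(>F)"], tolerance = 1e-10)

  expect_gte(res$pillai, 0)
  expect_lte(res$pillai, min(2, 1))
})

test_that("Pillai's trace vanishes when adjusted sex means coincide", {
  # sexes differ only through subspecies composition; within every
  # subspecies the sex mean vectors are identical by construction
  base <- expand.grid(sex = c("male", "female"), subspecies = c("x", "y"),
                      rep = 1:4, stringsAsFactors = FALSE)
  base$a <- ifelse(base$subspecies == "x", 1, 5) + c(-1, 1, 2, -2)[base$rep]
  base$b <- ifelse(base$subspecies == "x", 2, 7) + c(-2, 1, -1, 2)[base$rep]
  res <- pillai_manova(base, response = c("a", "b"), factor_name = "sex",
                       covariate_name = "subspecies")
  expect_equal(res$pillai, 0, tolerance = 1e-10)
})

test_that("sex screen on synthetic specimens is non-significant", {
  tbl <- sample_specimens(build_config("clinal_step", seed = 21))
  res <- pillai_manova(tbl, bill_traits(), "sex", "subspecies")
  expect_gt(res$p, 0.001)
  expect_lt(res$pillai, 0.1)
})

test_that("Mahalanobis screen reduces to Euclidean geometry when it should", {
  # a specimen exactly at the centroid has distance zero
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1), c(0, 0, 0))
  colnames(X) <- bill_traits()
  scr <- mahalanobis_screen(X)
  expect_equal(min(scr$d2), 0)
  expect_equal(scr$specimen_id[1], "7")

  # exact identity covariance: squared distances equal squared Euclidean
  Xi <- exact_correlation_data(30, diag(3), seed = 4)
  colnames(Xi) <- bill_traits()
  scri <- mahalanobis_screen(Xi)
  eu <- rowSums(scale(Xi, scale = FALSE)^2)
  expect_equal(sort(scri$d2), sort(eu), tolerance = 1e-10)
  # plotting positions are the (i - 0.5)/n chi-square quantiles
  expect_equal(scri$chi2_quantile,
               qchisq((seq_len(30) - 0.5) / 30, df = 3))

  # a large multivariate-normal sample tracks the chi-square line
  set.seed(6)
  Xn <- MASS::mvrnorm(1000, rep(0, 3), diag(3))
  colnames(Xn) <- bill_traits()
  scrn <- mahalanobis_screen(Xn)
  slope <- coef(lm(d2 ~ chi2_quantile, data = scrn))[2]
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)

  Xs <- cbind(Xn[, 1], Xn[, 1], Xn[, 2])
  colnames(Xs) <- bill_traits()
  expect_error(mahalanobis_screen(Xs), "collinear")
})

test_that("complete linkage reproduces hand-worked and brute-force merges", {
  X <- matrix(c(0, 1, 10, 11, 30), ncol = 1)
  colnames(X) <- "bill_depth_mm"
  hc <- cluster_complete(X, traits = "bill_depth_mm")
  expect_equal(hc$height, c(1, 1, 11, 30))

  # duplicated points merge first at height zero
  X2 <- matrix(c(5, 5, 9), ncol = 1); colnames(X2) <- "bill_depth_mm"
  expect_equal(cluster_complete(X2, traits = "bill_depth_mm")$height[1], 0)

  # oracle equivalence for random sets, n <= 8
  set.seed(8)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    Xr <- matrix(rnorm(n * 3), n); colnames(Xr) <- bill_traits()
    hcr <- cluster_complete(Xr)
    oracle <- brute_complete_linkage(Xr)
    expect_equal(sort(hcr$height), sort(oracle$heights), tolerance = 1e-10)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(stats::cutree(hcr, k),
                                 oracle$partitions[[k]]))
    }
  }
})

test_that("merge heights are monotone and memberships ignore row order", {
  set.seed(9)
  X <- matrix(rnorm(60), 20); colnames(X) <- bill_traits()
  hc <- cluster_complete(X)
  expect_true(all(diff(hc$height) >= -1e-12))
  perm <- sample(20)
  hcp <- cluster_complete(X[perm, , drop = FALSE])
  for (k in c(2, 4, 6)) {
    expect_true(same_partition(stats::cutree(hc, k)[perm],
                               stats::cutree(hcp, k)))
  }
})

test_that("optimal k is found for constructed blob geometries", {
  set.seed(10)
  blob <- function(mu, n = 15) sweep(matrix(rnorm(n * 3, sd = 0.05), n), 2,
                                     mu, `+`)
  two <- rbind(blob(c(0, 0, 0)), blob(c(10, 0, 0)))
  colnames(two) <- bill_traits()
  hc2 <- cluster_complete(two)
  res2 <- optimal_k(hc2, two, k_range = 2:6)
  expect_equal(res2$k_best, 2)
  expect_true(all(res2$votes == 2))  # unanimous for well-separated blobs

  three <- rbind(blob(c(0, 0, 0)), blob(c(10, 0, 0)), blob(c(5, 5 * sqrt(3), 0)))
  colnames(three) <- bill_traits()
  hc3 <- cluster_complete(three)
  expect_equal(optimal_k(hc3, three, k_range = 2:6)$k_best, 3)
})

test_that("LDA matches the independent argmax classifier and its invariances", {
  set.seed(11)
  mus <- list(c(0, 0, 0), c(3, 0, 1), c(0, 3, 2))
  X <- do.call(rbind, lapply(mus, function(m)
    MASS::mvrnorm(20, m, diag(3) + 0.3)))
  colnames(X) <- bill_traits()
  g <- rep(c("p", "q", "r"), each = 20)
  rec <- data.frame(grp = g, X)
  names(rec)[2:4] <- bill_traits()
  fit <- lda_fit(rec, grouping = "grp")

  # confusion matrix equals per-specimen discriminant-score argmax
  pred <- argmax_classify(X, g)
  conf <- prop.table(table(actual = factor(g), predicted = pred), 1)
  expect_equal(unclass(fit$confusion), unclass(conf), ignore_attr = TRUE)

  # rows sum to one; between-group shares sum to one
  expect_equal(unname(rowSums(fit$confusion)), rep(1, 3))
  expect_equal(sum(fit$prop_between), 1)
  # orientation convention on the depth coefficient
  expect_true(all(fit$coefficients["bill_depth_mm", ] > 0))

  # classification invariant under any fixed invertible linear transform
  A <- matrix(c(2, 0.5, 0, -1, 1, 0.3, 0.2, 0, 1.5), 3, 3)
  Xt <- X %*% A
  colnames(Xt) <- bill_traits()
  rect <- data.frame(grp = g, Xt)
  names(rect)[2:4] <- bill_traits()
  fitt <- lda_fit(rect, grouping = "grp")
  expect_equal(unclass(fitt$confusion), unclass(fit$confusion),
               tolerance = 1e-10)

  # collinear group means: one axis carries all between-group variance
  Xc <- do.call(rbind, lapply(c(0, 4, 8), function(s)
    MASS::mvrnorm(15, c(s, 0, 0), diag(3))))
  colnames(Xc) <- bill_traits()
  recc <- data.frame(grp = rep(c("a", "b", "c"), each = 15), Xc)
  names(recc)[2:4] <- bill_traits()
  expect_gt(lda_fit(recc, grouping = "grp")$prop_between[1], 0.95)

  expect_warning(
    lda_fit(rec[c(1:20, 21:23, 41:60), ], grouping = "grp"),
    "specimens")
})

test_that("clinal-step synthetic data separates the Antillean extremes", {
  tbl <- sample_specimens(build_config("clinal_step", seed = 13))
  fit <- lda_fit(tbl, grouping = "region", group_levels = region_levels())
  conf <- fit$confusion
  # near-zero confusion between Lesser Antilles and the small-billed regions
  expect_lt(conf["lesser_antilles", "florida_bahamas"] +
              conf["lesser_antilles", "greater_antilles"], 0.05)
  expect_lt(conf["florida_bahamas", "lesser_antilles"] +
              conf["greater_antilles", "lesser_antilles"], 0.05)
  expect_gt(fit$prop_between[1], 0.8)
})

test_that("Spearman correlations handle ties, reversals, and constants", {
  rec <- data.frame(color_chin = c(1, 2, 3, 4), color_breast = c(4, 3, 2, 1),
                    color_belly = c(1, 2, 3, 4), color_vent = c(1, 2, 3, 4))
  rho <- rank_correlations(rec)
  expect_equal(rho["color_chin", "color_belly"], 1)
  expect_equal(rho["color_chin", "color_breast"], -1)
  expect_equal(diag(rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rho, t(rho), ignore_attr = TRUE)

  # tied ordinal fixture against the hand-computed average-rank formula
  x <- c(0, 1, 1, 2); y <- c(1, 1, 2, 2)
  rec2 <- data.frame(color_chin = x, color_breast = y,
                     color_belly = x, color_vent = y)
  rho2 <- rank_correlations(rec2)
  oracle <- stats::cor(rank(x), rank(y))  # average ranks, Pearson on ranks
  expect_equal(rho2["color_chin", "color_breast"], oracle)
  expect_equal(oracle, 3 / (sqrt(4.5) * 2))  # worked by hand

  rec3 <- rec
  rec3$color_vent <- 2
  expect_warning(rho3 <- rank_correlations(rec3), "color_vent")
  expect_equal(attr(rho3, "flagged"), "color_vent")
})
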