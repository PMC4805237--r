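## Multivariate toolkit: composite bill size (PCA), MANOVA sex screen,
## Mahalanobis outlier screen, complete-linkage clustering with multi-index
## optimal-k selection, discriminant classification, rank correlations.

# numeric trait matrix with specimen ids as rownames; refuses missing cells
trait_matrix <- function(records, traits) {
  if (is.matrix(records)) {
    X <- records[, traits, drop = FALSE]
  } else {
    bad <- setdiff(traits, names(records))
    if (length(bad) > 0L) stop("unknown trait column(s): ",
                               paste(bad, collapse = ", "))
    X <- as.matrix(as.data.frame(records)[, traits, drop = FALSE])
    if ("specimen_id" %in% names(records))
      rownames(X) <- records$specimen_id
  }
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("missing trait values; filter with complete_specimens() first")
  X
}

#' Composite bill size from principal components
#'
#' Eigen-decomposition of the correlation matrix of the bill traits
#' (standardised variables), with PC1 serving as the composite bill-size
#' score used by the diagnosability analysis. Axes are oriented so the
#' loading on bill depth (or on the first trait, if bill depth is not
#' among them) is positive, making the sign convention reproducible.
#'
#' @param records specimen data frame (complete cases) or numeric matrix.
#' @param traits trait columns; the three bill measurements by default.
#' @return list: `loadings` (unit-norm eigenvectors, traits x axes),
#'   `prop_var` (variance proportions, summing to 1), `scores`
#'   (specimens x axes), `composite` (the PC1 scores, named by specimen),
#'   `trait_correlations` (Pearson r of the composite with each raw
#'   trait), `sdev`.
#' @export
pca_composite <- function(records, traits = bill_traits()) {
  X <- trait_matrix(records, traits)
  if (nrow(X) < 3L) stop("need at least 3 specimens")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(traits[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  anchor <- if ("bill_depth_mm" %in% traits) "bill_depth_mm" else traits[1]
  flip <- ifelse(pc$rotation[anchor, ] < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  composite <- scores[, 1]
  names(composite) <- rownames(X)
  list(
    loadings = rot,
    prop_var = pc$sdev^2 / sum(pc$sdev^2),
    scores = scores,
    composite = composite,
    trait_correlations = drop(stats::cor(composite, X)),
    sdev = pc$sdev
  )
}

#' MANOVA screen for sexual dimorphism, adjusted for subspecies
#'
#' Fits the additive two-factor multivariate linear model and tests the
#' sex effect with Pillai's trace `V = tr[H (H + E)^-1]`, where `H` and
#' `E` are the hypothesis and error cross-product matrices. By default the
#' sex effect is adjusted for subspecies (Type II sums of squares, each
#' factor adjusted for the other); `type = "sequential"` fits sex after
#' the covariate in a sequential decomposition instead.
#'
#' @param records specimen data frame (complete cases for `response`).
#' @param response response trait columns (bill triple or color quadruple).
#' @param factor_name grouping factor under test (default `"sex"`).
#' @param covariate_name adjusting factor (default `"subspecies"`), or
#'   `NULL` for a one-way test.
#' @param type `"II"` or `"sequential"`.
#' @return list: `pillai`, `approx_F`, `df` (numerator, denominator), `p`,
#'   plus the `H` and `E` matrices.
#' @export
pillai_manova <- function(records, response = bill_traits(),
                          factor_name = "sex", covariate_name = "subspecies",
                          type = c("II", "sequential")) {
  type <- match.arg(type)
  Y <- trait_matrix(records, response)
  f <- factor(records[[factor_name]])
  if (nlevels(droplevels(f)) < 2L || any(table(droplevels(f)) < 2L))
    stop("factor '", factor_name,
         "' needs >= 2 levels with >= 2 specimens each")
  dat <- data.frame(.f = droplevels(f))
  form <- if (is.null(covariate_name)) Y ~ .f else Y ~ .g + .f
  if (!is.null(covariate_name)) dat$.g <- factor(records[[covariate_name]])

  mod <- stats::lm(form, data = dat)
  if (type == "II") {
    mnv <- car::Manova(mod, type = "II")
    H <- mnv$SSP[[".f"]]
    E <- mnv$SSPE
    df_h <- mnv$df[[".f"]]
    df_e <- mnv$error.df
  } else {
    mnv <- stats::manova(form, data = dat)
    ss <- summary(mnv)$SS
    H <- ss[[".f"]]
    E <- ss[["Residuals"]]
    df_h <- nlevels(dat$.f) - 1L
    df_e <- stats::df.residual(mnv)
  }
  ok <- tryCatch({ solve(H + E); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular error matrix; collinear responses among: ",
                paste(response, collapse = ", "))
  pillai_from_HE(H, E, df_h, df_e)
}

# Pillai's trace with the standard approximate-F transformation
pillai_from_HE <- function(H, E, df_h, df_e) {
  p <- ncol(E)
  V <- sum(diag(H %*% solve(H + E)))
  s <- min(p, df_h)
  m <- (abs(p - df_h) - 1) / 2
  n <- (df_e - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n + s + 1)
  Fstat <- ((2 * n + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  list(pillai = V, approx_F = Fstat, df = c(df1, df2),
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), H = H, E = E)
}

#' Mahalanobis outlier screen against chi-square quantiles
#'
#' Squared Mahalanobis distances of every specimen from the overall trait
#' centroid, paired with chi-square quantiles (df = number of traits) at
#' plotting positions `(i - 0.5) / n` so the table can be plotted as a
#' Q-Q screen. Returns an orderable table; no specimen is rejected
#' automatically.
#'
#' @inheritParams pca_composite
#' @return data frame sorted by ascending distance: `specimen_id`, `d2`
#'   (squared distance), `chi2_quantile`.
#' @export
mahalanobis_screen <- function(records, traits = bill_traits()) {
  X <- trait_matrix(records, traits)
  S <- stats::cov(X)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    cc <- stats::cor(X)
    pairs <- which(abs(cc) > 0.999 & row(cc) < col(cc), arr.ind = TRUE)
    stop("singular trait covariance; collinear traits: ",
         paste(apply(pairs, 1, function(ij)
           paste(traits[ij], collapse = "~")), collapse = ", "))
  }
  d2 <- stats::mahalanobis(X, colMeans(X), S)
  n <- length(d2)
  ord <- order(d2)
  data.frame(
    specimen_id = if (is.null(rownames(X))) as.character(ord) else
      rownames(X)[ord],
    d2 = d2[ord],
    chi2_quantile = stats::qchisq((seq_len(n) - 0.5) / n, df = ncol(X))
  )
}

#' Complete-linkage clustering of the raw bill traits
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' over the (unstandardised) trait columns. Merge heights are
#' non-decreasing; ties are resolved deterministically by the underlying
#' agglomeration order.
#'
#' @inheritParams pca_composite
#' @return an [stats::hclust] object with specimen ids as labels.
#' @export
cluster_complete <- function(records, traits = bill_traits()) {
  X <- trait_matrix(records, traits)
  if (nrow(X) < 2L) stop("need at least 2 specimens")
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "complete")
  hc$labels <- rownames(X)
  hc
}

#' Select the number of clusters by a three-index majority vote
#'
#' Cuts the dendrogram at each `k` and scores the partition with three
#' indices: Calinski-Harabasz pseudo-F (vote: argmax), mean silhouette
#' width (vote: argmax), and a Duda-Hart split test walked down the
#' hierarchy (vote: the smallest `k` whose next split is not supported at
#' the conventional `z = 3.20` critical value). The winning `k` is the
#' majority vote, ties resolved toward the smaller `k`.
#'
#' @param hc dendrogram from [cluster_complete()].
#' @param records,traits the data the dendrogram was built from.
#' @param k_range candidate cluster counts.
#' @return list: `k_best`, `votes` (named per index), `scores` (per-index
#'   values across `k_range`).
#' @export
optimal_k <- function(hc, records, traits = bill_traits(), k_range = 2:10) {
  X <- trait_matrix(records, traits)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0L) stop("k_range has no feasible values")
  D <- stats::dist(X)

  ch <- sil <- stats::setNames(rep(NA_real_, length(k_range)),
                               as.character(k_range))
  total_ss <- sum(scale(X, scale = FALSE)^2)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- stats::cutree(hc, k)
    ssw <- sum(vapply(split(seq_len(n), cl), function(idx)
      sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2), numeric(1)))
    ssb <- total_ss - ssw
    if (n - k > 0 && ssw > 0) {
      ch[i] <- (ssb / (k - 1)) / (ssw / (n - k))
    } else {
      message("optimal_k: Calinski-Harabasz skipped at k = ", k,
              " (degenerate partition)")
    }
    sil[i] <- mean(cluster::silhouette(cl, D)[, 3])
  }

  # Duda-Hart: at each k find the cluster split when moving to k + 1 and
  # test whether the within-SS drop is more than chance for a homogeneous
  # Gaussian cluster
  dh_vote <- max(k_range)
  p <- ncol(X)
  z <- 3.20
  for (k in k_range) {
    cl_k <- stats::cutree(hc, k)
    cl_k1 <- stats::cutree(hc, k + 1)
    split_parent <- unique(cl_k[ave(cl_k1, cl_k, FUN = function(v)
      length(unique(v))) > 1])
    if (length(split_parent) != 1L) next
    idx <- which(cl_k == split_parent)
    m <- length(idx)
    je1 <- sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
    je2 <- sum(vapply(split(idx, cl_k1[idx]), function(ii)
      sum(scale(X[ii, , drop = FALSE], scale = FALSE)^2), numeric(1)))
    ratio <- if (je1 > 0) je2 / je1 else 1
    crit <- 1 - 2 / (pi * p) -
      z * sqrt(2 * (1 - 8 / (pi^2 * p)) / (m * p))
    if (ratio >= crit) { dh_vote <- k; break }
  }

  votes <- c(
    calinski_harabasz = as.integer(names(which.max(ch))),
    silhouette = as.integer(names(which.max(sil))),
    duda_hart = dh_vote
  )
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k_best = min(winners), votes = votes,
       scores = list(calinski_harabasz = ch, silhouette = sil))
}

#' Linear discriminant classification of bill traits
#'
#' Canonical discriminant axes for a grouping factor (region or named
#' subspecies), with per-axis proportions of between-group variance,
#' specimen scores, and a classification matrix from resubstitution of
#' the training specimens (rows = actual group, columns = predicted,
#' row proportions). Priors are proportional to group sizes by default.
#' Axes are oriented so the coefficient on bill depth (or the first
#' trait) is positive; the sign of discriminant coefficients is otherwise
#' arbitrary.
#'
#' @param records specimen data frame (complete cases).
#' @param grouping grouping column name (`"region"` or `"subspecies"`).
#' @param traits trait columns.
#' @param prior `"proportional"` or `"equal"`.
#' @param cv if `TRUE`, the confusion matrix uses leave-one-out
#'   cross-validated predictions instead of resubstitution.
#' @param group_levels optional ordering of groups for the output matrix.
#' @return list: `coefficients` (traits x axes), `prop_between`
#'   (per-axis between-group variance shares, summing to 1), `scores`,
#'   `confusion` (row-stochastic matrix), `counts`, `prior`, `fit`.
#' @export
lda_fit <- function(records, grouping = "region", traits = bill_traits(),
                    prior = c("proportional", "equal"), cv = FALSE,
                    group_levels = NULL) {
  prior <- match.arg(prior)
  X <- trait_matrix(records, traits)
  g <- factor(records[[grouping]],
              levels = if (is.null(group_levels))
                unique(records[[grouping]]) else group_levels)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  sizes <- table(g)
  if (any(sizes <= ncol(X)))
    warning("group(s) with <= ", ncol(X), " specimens: ",
            paste(names(sizes)[sizes <= ncol(X)], collapse = ", "))
  pr <- if (prior == "proportional") as.vector(sizes) / length(g) else
    rep(1 / nlevels(g), nlevels(g))
  fit <- MASS::lda(X, grouping = g, prior = pr)
  anchor <- if ("bill_depth_mm" %in% traits) "bill_depth_mm" else traits[1]
  flip <- ifelse(fit$scaling[anchor, ] < 0, -1, 1)
  scaling <- sweep(fit$scaling, 2, flip, `*`)
  scores <- sweep(stats::predict(fit, X)$x, 2, flip, `*`)
  pred <- if (cv) {
    MASS::lda(X, grouping = g, prior = pr, CV = TRUE)$class
  } else {
    stats::predict(fit, X)$class
  }
  confusion <- prop.table(table(actual = g, predicted = pred), 1)
  list(
    coefficients = scaling,
    prop_between = fit$svd^2 / sum(fit$svd^2),
    scores = scores,
    confusion = confusion,
    counts = table(actual = g, predicted = pred),
    prior = stats::setNames(pr, levels(g)),
    fit = fit
  )
}

#' Spearman rank correlations among the color regions
#'
#' Symmetric matrix of Spearman's rho (average ranks for ties) among the
#' ordinal color-score columns. Constant columns yield undefined rho and
#' are flagged.
#'
#' @param records specimen data frame (complete color cases).
#' @param traits the four color columns by default.
#' @return correlation matrix with attribute `"flagged"` naming any
#'   constant columns.
#' @export
rank_correlations <- function(records, traits = color_traits()) {
  X <- trait_matrix(records, traits)
  if (nrow(X) < 3L) stop("need at least 3 specimens")
  constant <- traits[apply(X, 2, function(v) length(unique(v)) == 1L)]
  if (length(constant) > 0L)
    warning("constant color column(s), rho undefined: ",
            paste(constant, collapse = ", "))
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  diag(rho) <- 1
  attr(rho, "flagged") <- constant
  rho
}
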