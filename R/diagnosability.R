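## Pairwise subspecies diagnosability under the 75% rule: a Student-t
## quantile index for continuous traits (composite bill size), and an
## empirical range rule for ordinal color scores. This is the analysis's
## core statistic and is implemented here in full rather than wrapped.

#' Per-taxon sufficient statistics for the diagnosability index
#'
#' @param values numeric trait values (typically the PC1 composite
#'   bill-size scores).
#' @param labels taxon label per value (subspecies or region).
#' @param levels optional ordering of taxa for output.
#' @return data frame with one row per taxon: `taxon`, `n`, `mean`, `sd`
#'   (sample standard deviation, divisor n - 1).
#' @export
group_summaries <- function(values, labels, levels = NULL) {
  stopifnot(length(values) == length(labels))
  g <- factor(labels, levels = if (is.null(levels)) unique(labels) else levels)
  g <- droplevels(g)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    data.frame(taxon = lv, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  rownames(out) <- NULL
  out
}

#' Diagnosability index for an ordered pair of populations
#'
#' Implements the t-quantile diagnosability index behind the 75% rule: a
#' subspecies is valid when at least 75% of one population's distribution
#' of a character falls outside (nearly all of) the other population's.
#' For focal population f and reference population r,
#'
#' \deqn{D = |\bar{x}_f - \bar{x}_r|
#'   - t_{p_f, n_f - 1} s_f - t_{p_r, n_r - 1} s_r}
#'
#' with one-tailed Student-t quantiles and n - 1 degrees of freedom per
#' group. `D >= 0` means the focal population's inner 75% quantile
#' (toward the reference) lies beyond the reference population's outer
#' 99% bound. The index is asymmetric: swapping the pair swaps which
#' standard deviation receives which quantile multiplier, so the test
#' must pass in both directions for a pair to be reciprocally
#' diagnosable.
#'
#' @param focal,reference one-row data frames or lists with `n`, `mean`,
#'   `sd` (see [group_summaries()]).
#' @param p_focal quantile level for the focal population (0.75 under the
#'   75% rule).
#' @param p_reference quantile level bounding the reference population
#'   (0.99).
#' @return the index value (trait units).
#' @examples
#' a <- list(n = 30, mean = 0, sd = 1)
#' d_index(a, a)  # about -3.145: identical populations are far from
#'                # diagnosable
#' @export
d_index <- function(focal, reference, p_focal = 0.75, p_reference = 0.99) {
  for (g in list(focal, reference)) {
    if (g$n < 2) stop("group size must be >= 2 (t quantile undefined)")
    if (is.na(g$sd) || g$sd < 0) stop("invalid standard deviation")
  }
  if (p_focal <= 0.5 || p_focal >= 1 || p_reference <= 0.5 || p_reference >= 1)
    stop("quantile levels must lie in (0.5, 1)")
  abs(focal$mean - reference$mean) -
    stats::qt(p_focal, df = focal$n - 1) * focal$sd -
    stats::qt(p_reference, df = reference$n - 1) * reference$sd
}

#' Pairwise diagnosability matrix
#'
#' Computes the index for every ordered pair of taxa, flags each direction
#' against the threshold, and combines the directions into the symmetric
#' reciprocal-diagnosability matrix. By convention the row taxon is the
#' focal population; `orientation = "cols_focal"` transposes the roles.
#'
#' @param groups data frame from [group_summaries()].
#' @param p_focal,p_reference quantile levels, as [d_index()].
#' @param threshold flag value: `D >= threshold` counts as diagnosable in
#'   that direction (the rule's boundary case D = 0 counts).
#' @param orientation `"rows_focal"` (default) or `"cols_focal"`.
#' @return object of class `diagnosability_matrix`: list with `D` (index
#'   matrix, `NA` diagonal), `diagnosable` (directional flags),
#'   `reciprocal` (symmetric), `taxa`, `threshold`, `orientation`.
#' @export
d_matrix <- function(groups, p_focal = 0.75, p_reference = 0.99,
                     threshold = 0, orientation = c("rows_focal",
                                                    "cols_focal")) {
  orientation <- match.arg(orientation)
  if (nrow(groups) < 2L) stop("need >= 2 groups")
  if (anyDuplicated(groups$taxon))
    stop("duplicate taxon labels: ",
         paste(groups$taxon[duplicated(groups$taxon)], collapse = ", "))
  taxa <- groups$taxon
  k <- length(taxa)
  D <- matrix(NA_real_, k, k, dimnames = list(focal = taxa, reference = taxa))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    D[i, j] <- d_index(groups[i, ], groups[j, ], p_focal, p_reference)
  }
  if (orientation == "cols_focal") D <- t(D)
  diagnosable <- !is.na(D) & D >= threshold
  structure(list(
    D = D,
    diagnosable = diagnosable,
    reciprocal = diagnosable & t(diagnosable),
    taxa = taxa, threshold = threshold, orientation = orientation,
    p_focal = p_focal, p_reference = p_reference
  ), class = "diagnosability_matrix")
}

#' @export
print.diagnosability_matrix <- function(x, digits = 2, ...) {
  M <- matrix("-", nrow(x$D), ncol(x$D), dimnames = dimnames(x$D))
  off <- !is.na(x$D)
  M[off] <- sprintf(paste0("%.", digits, "f"), x$D[off])
  M[x$diagnosable] <- paste0(M[x$diagnosable], "*")
  cat("Pairwise diagnosability (", x$orientation,
      "; * marks D >= ", x$threshold, ")\n", sep = "")
  print(M, quote = FALSE)
  invisible(x)
}

#' Empirical 75% range rule for ordinal scores
#'
#' Applies the 75% rule directly to observed score distributions: the
#' fraction of focal scores strictly outside the closed range
#' `[min(reference), max(reference)]`. Counts are kept exact (a ratio of
#' integers) before any display rounding. Like the parametric index, the
#' rule is directional.
#'
#' @param focal_scores,reference_scores ordinal score vectors.
#' @param threshold diagnosable when the fraction reaches this value.
#' @return list: `fraction_outside`, `n_outside`, `n`, `diagnosable`.
#' @export
empirical_75 <- function(focal_scores, reference_scores, threshold = 0.75) {
  if (length(focal_scores) == 0L || length(reference_scores) == 0L)
    stop("score vectors must be non-empty")
  lo <- min(reference_scores)
  hi <- max(reference_scores)
  n_out <- sum(focal_scores < lo | focal_scores > hi)
  n <- length(focal_scores)
  list(fraction_outside = n_out / n, n_outside = n_out, n = n,
       diagnosable = n_out / n >= threshold)
}

#' Pairwise empirical-rule matrix for an ordinal trait
#'
#' @param scores ordinal scores.
#' @param labels taxon per score.
#' @param levels optional taxon ordering.
#' @inheritParams empirical_75
#' @return `diagnosability_matrix`-classed list where `D` holds the
#'   fraction of the row (focal) taxon's scores outside the column
#'   (reference) taxon's observed range.
#' @export
empirical_75_matrix <- function(scores, labels, levels = NULL,
                                threshold = 0.75) {
  g <- factor(labels, levels = if (is.null(levels)) unique(labels) else levels)
  g <- droplevels(g)
  taxa <- levels(g)
  k <- length(taxa)
  Fr <- matrix(NA_real_, k, k, dimnames = list(focal = taxa,
                                               reference = taxa))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    Fr[i, j] <- empirical_75(scores[g == taxa[i]], scores[g == taxa[j]],
                             threshold)$fraction_outside
  }
  diagnosable <- !is.na(Fr) & Fr >= threshold
  structure(list(
    D = Fr, diagnosable = diagnosable,
    reciprocal = diagnosable & t(diagnosable),
    taxa = taxa, threshold = threshold, orientation = "rows_focal"
  ), class = "diagnosability_matrix")
}

#' Reciprocal-diagnosability report
#'
#' Summarises a diagnosability matrix per taxon: which other taxa it is
#' reciprocally diagnosable from, and whether any taxon is reciprocally
#' diagnosable from all others (the criterion a valid subspecies would
#' have to meet).
#'
#' @param matrix a `diagnosability_matrix`.
#' @return list: `per_taxon` (named list of character vectors),
#'   `fully_diagnosable` (taxa reciprocally diagnosable from every other
#'   taxon), `any_fully_diagnosable`, `n_reciprocal_pairs`.
#' @export
reciprocal_report <- function(matrix) {
  stopifnot(inherits(matrix, "diagnosability_matrix"))
  R <- matrix$reciprocal
  taxa <- matrix$taxa
  per_taxon <- stats::setNames(lapply(seq_along(taxa), function(i)
    taxa[which(R[i, ])]), taxa)
  full <- taxa[vapply(seq_along(taxa), function(i)
    all(R[i, -i]), logical(1))]
  list(per_taxon = per_taxon,
       fully_diagnosable = full,
       any_fully_diagnosable = length(full) > 0L,
       n_reciprocal_pairs = sum(R[upper.tri(R)]))
}
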