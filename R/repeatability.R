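## Measurement repeatability (intraclass correlation) from repeated
## measurement sessions, by one-way ANOVA variance decomposition.

#' Repeatability of a trait from repeated measurement sessions
#'
#' Decomposes the variance of repeated measurements with specimen as the
#' single factor. With mean squares `MS_among` and `MS_within` from the
#' one-way ANOVA, the among-specimen variance component is
#' `s2_A = (MS_among - MS_within) / n0`, where
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)` for `a` specimens and `N` total
#' measurements (`n0` equals the session count for balanced designs), and
#' repeatability is `r = s2_A / (s2_A + MS_within)`.
#'
#' `r` can be negative when `MS_among <= MS_within`; it is returned
#' unclamped with a `"negative"` flag rather than truncated at zero. If
#' the data carry no variance at all, `r` is defined as 1 with a
#' `"degenerate"` flag.
#'
#' @param measurements long data frame with columns `specimen_id`,
#'   `trait`, `session`, `value` (as produced by [sample_repeats()]), or
#'   the list returned by [sample_repeats()] itself. Ordinal color scores
#'   are treated as numeric in the same decomposition.
#' @param trait which trait to analyse.
#' @return list with `r`, `ms_among`, `ms_within`, `n0`, `var_among`,
#'   `var_within`, `n_specimens`, `n_measurements`, `flags`.
#' @examples
#' m <- data.frame(specimen_id = rep(c("a", "b"), each = 2),
#'                 trait = "bill_length_mm", session = c(1, 2, 1, 2),
#'                 value = c(1, 2, 3, 4))
#' repeatability(m, "bill_length_mm")$r  # 0.778
#' @export
repeatability <- function(measurements, trait) {
  d <- repeat_trait_frame(measurements, trait)
  grp <- factor(d$specimen_id)
  a <- nlevels(grp)
  ni <- as.vector(table(grp))
  N <- length(d$value)
  if (a < 2L) stop("need at least 2 specimens with repeated sessions")
  if (any(ni < 2L))
    stop("every specimen needs >= 2 sessions; offenders: ",
         paste(levels(grp)[ni < 2L], collapse = ", "))
  if (any(!is.finite(d$value))) stop("non-finite measurement values")

  an <- stats::anova(stats::aov(value ~ grp, data = data.frame(value = d$value,
                                                               grp = grp)))
  ms_among <- an[["Mean Sq"]][1]
  ms_within <- an[["Mean Sq"]][2]
  n0 <- (N - sum(ni^2) / N) / (a - 1)

  flags <- character()
  if (ms_among == 0 && ms_within == 0) {
    r <- 1; s2a <- 0
    flags <- "degenerate"
  } else {
    s2a <- (ms_among - ms_within) / n0
    r <- s2a / (s2a + ms_within)
    if (r < 0) flags <- "negative"
  }
  list(r = r, ms_among = ms_among, ms_within = ms_within, n0 = n0,
       var_among = s2a, var_within = ms_within,
       n_specimens = a, n_measurements = N, flags = flags)
}

#' Differences between repeated measurements of a trait
#'
#' Absolute differences between a specimen's sessions (all pairwise
#' differences when a specimen has more than two), summarised as the
#' maximum and mean over all specimens, in the trait's units.
#'
#' @inheritParams repeatability
#' @return list with `max_abs_diff` and `mean_abs_diff`.
#' @export
repeat_differences <- function(measurements, trait) {
  d <- repeat_trait_frame(measurements, trait)
  diffs <- unlist(lapply(split(d$value, d$specimen_id), function(v) {
    if (length(v) < 2L) stop("every specimen needs >= 2 sessions")
    as.vector(stats::dist(v))
  }))
  list(max_abs_diff = max(diffs), mean_abs_diff = mean(diffs))
}

repeat_trait_frame <- function(measurements, trait) {
  if (is.list(measurements) && !is.data.frame(measurements) &&
      "measurements" %in% names(measurements)) {
    measurements <- measurements$measurements
  }
  stopifnot(is.data.frame(measurements),
            all(c("specimen_id", "trait", "session", "value") %in%
                  names(measurements)))
  d <- measurements[measurements$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no measurements for trait: ", trait)
  d
}

#' Repeatability summary across all traits present
#'
#' @inheritParams repeatability
#' @return data frame with one row per trait: `r`, variance components,
#'   and the repeat-difference summaries.
#' @export
repeatability_summary <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements) &&
      "measurements" %in% names(measurements)) {
    measurements <- measurements$measurements
  }
  traits <- unique(measurements$trait)
  do.call(rbind, lapply(traits, function(tr) {
    rep_ <- repeatability(measurements, tr)
    dif <- repeat_differences(measurements, tr)
    data.frame(trait = tr, r = rep_$r, ms_among = rep_$ms_among,
               ms_within = rep_$ms_within, n0 = rep_$n0,
               max_abs_diff = dif$max_abs_diff,
               mean_abs_diff = dif$mean_abs_diff,
               flags = paste(rep_$flags, collapse = ";"))
  }))
}
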