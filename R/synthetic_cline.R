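## Synthetic specimen worlds: clinal multivariate bill size across an ordered
## island arc, latent-Gaussian ordinal color with a unimodal darkness peak,
## and duplicate measurement sessions with a known target repeatability.

#' Build a configuration for the synthetic specimen generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: locales ordered geographically (Florida, then clockwise around
#' the Caribbean), per-locale multivariate-normal bill measurements whose
#' means follow a cline, ordinal plumage-color scores produced by
#' thresholding correlated latent Gaussians, sex labels independent of
#' phenotype, and session-level measurement error.
#'
#' Three presets are provided:
#' \describe{
#'   \item{`clinal_step`}{a logistic step cline in bill size centred between
#'     the Greater and Lesser Antilles, with phenotypically intermediate
#'     birds on Antigua/Barbuda and at the mainland locales; color darkness
#'     peaks at the Dominica/Guadeloupe locale; per-subspecies sample sizes
#'     follow the museum series (total 274).}
#'   \item{`flat_null`}{identical trait means everywhere — the null world in
#'     which no taxon should be diagnosable.}
#'   \item{`two_cluster`}{two well-separated mean vectors, for exercising
#'     cluster recovery.}
#' }
#'
#' @param preset one of `"clinal_step"`, `"flat_null"`, `"two_cluster"`.
#' @param ... named overrides for any configuration field (e.g. `seed`,
#'   `n_per_subspecies`, `within_locale_cov`, `cline_steepness`,
#'   `bill_amplitude`). The per-locale bill mean profile is recomputed from
#'   the cline unless `bill_mean_profile` itself is overridden.
#' @return object of class `cline_config`: a validated list. Key fields:
#'   `locales` (data frame: locale, subspecies, region, arc position,
#'   darkness level, n), `bill_baseline` and `bill_amplitude` (mm),
#'   `bill_mean_profile` (locales x 3, mm), `within_locale_cov` (mm^2),
#'   `color_thresholds`, `repeat_error_sd`, `score_error_sd`, `sex_ratio`,
#'   `seed`.
#' @examples
#' cfg <- build_config("clinal_step", seed = 42)
#' sum(cfg$locales$n)
#' @export
build_config <- function(preset = c("clinal_step", "flat_null", "two_cluster"),
                         ...) {
  preset <- match.arg(preset)
  overrides <- list(...)

  museum_series_n <- c(
    maynardi = 32L, caymanensis = 25L, nesiotes = 30L, teres = 27L,
    rileyi = 23L, dominicae = 27L, vincentis = 23L, grenadensis = 21L,
    minor = 8L, continentalis = 18L, palloris = 30L, abbotti = 10L
  )

  if (preset %in% c("clinal_step", "flat_null")) {
    sub <- c("maynardi", "caymanensis", "nesiotes", "teres", "rileyi",
             "dominicae", "vincentis", "grenadensis", "minor",
             "continentalis", "abbotti", "palloris")
    locales <- data.frame(
      locale = c("Florida and Bahamas", "Cayman Islands",
                 "Jamaica and Hispaniola", "Puerto Rico and Virgin Islands",
                 "Antigua and Barbuda", "Dominica and Guadeloupe",
                 "St. Lucia and St. Vincent", "Grenada",
                 "Northern South America", "Caribbean Middle America",
                 "Providencia and San Andres", "Pacific Middle America"),
      subspecies = sub,
      region = assign_region(sub),
      # arc position: 0 is the cline centre (Antigua/Barbuda); mainland
      # locales sit at 0 so the logistic puts them at the intermediate level
      arc_position = c(-4, -3.5, -3, -2.5, 0, 2.5, 3, 2, 0, 0, 0, 0),
      darkness = c(0.20, 0.25, 0.55, 0.60, 0.60, 0.90, 0.75, 0.30,
                   0.30, 0.65, 0.60, 0.25),
      n = unname(museum_series_n[sub]),
      stringsAsFactors = FALSE
    )
    cline_shape <- if (preset == "flat_null") "flat" else "logistic_step"
    if (preset == "flat_null") locales$darkness <- 0.5
  } else { # two_cluster
    locales <- data.frame(
      locale = c("cluster_a", "cluster_b"),
      subspecies = c("cluster_a", "cluster_b"),
      region = c("cluster_a", "cluster_b"),
      arc_position = c(-10, 10),
      darkness = c(0.5, 0.5),
      n = c(50L, 50L),
      stringsAsFactors = FALSE
    )
    cline_shape <- "logistic_step"
  }

  sds <- c(0.90, 0.45, 0.50)
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  cfg <- list(
    preset = preset,
    locales = locales,
    cline_shape = cline_shape,
    cline_steepness = 1,
    bill_baseline = c(bill_length_mm = 20.0, bill_width_mm = 6.0,
                      bill_depth_mm = 7.0),
    bill_amplitude = if (preset == "two_cluster")
      c(bill_length_mm = 5, bill_width_mm = 0, bill_depth_mm = 0)
    else c(bill_length_mm = 4.2, bill_width_mm = 1.4, bill_depth_mm = 2.0),
    within_locale_cov = diag(sds) %*% R %*% diag(sds),
    color_range = c(0L, 5L),
    color_thresholds = c(-1.5, -0.5, 0.5, 1.5, 2.5),
    darkness_latent_span = 4,    # latent mean = -1 + span * darkness level
    color_shared_sd = 0.85,      # individual effect shared by the 4 regions
    color_noise_sd = 0.55,       # region-specific latent component
    score_error_sd = 0.30,       # session-to-session scoring error (latent)
    repeat_error_sd = c(bill_length_mm = 0.45, bill_width_mm = 0.35,
                        bill_depth_mm = 0.30),
    sex_ratio = 0.5,
    date_missing_rate = 0.05,
    seed = 1L
  )
  recompute_profile <- !("bill_mean_profile" %in% names(overrides))
  for (nm in names(overrides)) {
    if (!nm %in% c(names(cfg), "bill_mean_profile", "n_per_subspecies"))
      stop("unknown configuration field: ", nm)
    cfg[[nm]] <- overrides[[nm]]
  }
  if ("n_per_subspecies" %in% names(overrides)) {
    np <- overrides$n_per_subspecies
    cfg$locales$n <- unname(np[cfg$locales$subspecies])
    cfg$n_per_subspecies <- NULL
  }
  if (recompute_profile) {
    lvl <- cline_level(cfg$locales$arc_position, cfg$cline_shape,
                       cfg$cline_steepness)
    cfg$bill_mean_profile <- outer(lvl, cfg$bill_amplitude) +
      matrix(cfg$bill_baseline, nrow(cfg$locales), 3, byrow = TRUE)
    colnames(cfg$bill_mean_profile) <- bill_traits()
    rownames(cfg$bill_mean_profile) <- cfg$locales$locale
  }
  validate_cline_config(cfg)
  class(cfg) <- "cline_config"
  cfg
}

# fraction of the cline amplitude expressed at each arc position
cline_level <- function(position, shape, steepness) {
  switch(shape,
         flat = rep(0.5, length(position)),
         linear = {
           rng <- range(position)
           if (diff(rng) == 0) rep(0.5, length(position))
           else (position - rng[1]) / diff(rng)
         },
         logistic_step = stats::plogis(steepness * position),
         stop("unknown cline shape: ", shape))
}

validate_cline_config <- function(cfg) {
  loc <- cfg$locales
  if (any(loc$n < 1L)) stop("per-locale sample sizes must be >= 1")
  S <- cfg$within_locale_cov
  if (!isTRUE(all.equal(S, t(S)))) stop("within_locale_cov must be symmetric")
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) stop("within_locale_cov must be positive definite")
  if (any(diff(cfg$color_thresholds) <= 0))
    stop("color_thresholds must be strictly increasing")
  if (nrow(cfg$bill_mean_profile) != nrow(loc) ||
      length(loc$darkness) != nrow(loc))
    stop("profile length must equal the number of locales")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  invisible(cfg)
}

# stage-specific substreams derived from the single global seed, so each
# sampling stage can be re-run independently yet reproducibly
derive_stage_seeds <- function(seed, n = 6L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample a synthetic specimen table
#'
#' Draws one table in the same schema as [read_specimens()] returns. Bill
#' triples come from locale-specific multivariate normals (plus one
#' session's measurement error, rounded to 0.1 mm as a caliper record
#' would be); the four color scores come from thresholded correlated
#' latent Gaussians (a shared individual darkness effect plus
#' region-specific components, plus scoring error); sex is assigned
#' independently of phenotype. Deterministic under a fixed `seed`.
#'
#' Ground truth (noise-free bill values and per-region color latents) is
#' attached as attributes `"true_bill"` and `"true_color_latent"` so
#' repeated measurement sessions ([sample_repeats()]) and recovery tests
#' can be generated against the same individuals.
#'
#' @param config a `cline_config` from [build_config()].
#' @return specimen data frame (canonical columns) with ground-truth
#'   attributes and the config attached as attribute `"config"`.
#' @export
sample_specimens <- function(config) {
  validate_cline_config(config)
  seeds <- derive_stage_seeds(config$seed)
  loc <- config$locales
  N <- sum(loc$n)

  set.seed(seeds[1]) # true bill values
  true_bill <- do.call(rbind, lapply(seq_len(nrow(loc)), function(i) {
    MASS::mvrnorm(loc$n[i], mu = config$bill_mean_profile[i, ],
                  Sigma = config$within_locale_cov)
  }))
  colnames(true_bill) <- bill_traits()

  set.seed(seeds[2]) # one measurement session for the main table
  measured <- true_bill
  for (tr in bill_traits()) {
    measured[, tr] <- round(true_bill[, tr] +
                              stats::rnorm(N, 0, config$repeat_error_sd[[tr]]),
                            1)
  }

  set.seed(seeds[3]) # color latents and one scoring session
  dark_mu <- -1 + config$darkness_latent_span * rep(loc$darkness, loc$n)
  shared <- dark_mu + stats::rnorm(N, 0, config$color_shared_sd)
  true_color_latent <- sapply(color_traits(), function(tr)
    shared + stats::rnorm(N, 0, config$color_noise_sd))
  scores <- apply(true_color_latent, 2, function(x)
    threshold_scores(x + stats::rnorm(N, 0, config$score_error_sd),
                     config$color_thresholds, config$color_range))

  set.seed(seeds[4]) # sex, dates, repositories: independent of phenotype
  sex <- ifelse(stats::runif(N) < config$sex_ratio, "male", "female")
  yr <- sample(1877:1986, N, replace = TRUE)
  mo <- sample(1:12, N, replace = TRUE)
  dy <- sample(1:28, N, replace = TRUE)
  dates <- sprintf("%04d-%02d-%02d", yr, mo, dy)
  dates[stats::runif(N) < config$date_missing_rate] <- ""
  repo <- sample(c("AMNH", "USNM", "FMNH", "MCZ"), N, replace = TRUE)

  out <- data.frame(
    specimen_id = sprintf("SYN-%04d", seq_len(N)),
    repository = repo,
    subspecies = rep(loc$subspecies, loc$n),
    region = rep(loc$region, loc$n),
    locale = rep(loc$locale, loc$n),
    sex = sex,
    collection_date = dates,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(measured), as.data.frame(scores))
  out$qc_flags <- ""
  rownames(out) <- NULL
  attr(out, "true_bill") <- true_bill
  attr(out, "true_color_latent") <- true_color_latent
  attr(out, "color_range") <- config$color_range
  attr(out, "config") <- config
  out
}

threshold_scores <- function(latent, thresholds, color_range) {
  s <- findInterval(latent, thresholds) + color_range[1]
  pmin(pmax(s, color_range[1]), color_range[2])
}

#' Generate repeated measurement sessions for a subset of specimens
#'
#' Picks `k` specimens at random and produces two fresh measurement
#' sessions per trait: true value plus independent session noise
#' (`repeat_error_sd` for the bill traits, `score_error_sd` on the latent
#' scale for the color scores, re-thresholded). Alongside the
#' measurements, the expected repeatability for each trait is emitted:
#' `r* = s2_between / (s2_between + error_sd^2)`, where `s2_between` is
#' the sample variance of the chosen specimens' true values (for color,
#' of their per-region latents — an approximation that ignores the
#' discretisation of scores).
#'
#' @param table a table from [sample_specimens()] (ground-truth attributes
#'   required).
#' @param k number of specimens to re-measure; the museum protocol used 17.
#' @param config generator configuration; defaults to the one attached to
#'   `table`.
#' @return list with `measurements` — long data frame (specimen_id, trait,
#'   session, value) — and `r_star`, a named vector of expected
#'   repeatabilities per trait.
#' @export
sample_repeats <- function(table, k = 17L, config = attr(table, "config")) {
  if (k <= 0L) stop("k must be positive")
  if (k > nrow(table)) stop("k exceeds the number of specimens")
  true_bill <- attr(table, "true_bill")
  true_col <- attr(table, "true_color_latent")
  if (is.null(true_bill) || is.null(config))
    stop("table lacks ground-truth attributes; use sample_specimens()")

  seeds <- derive_stage_seeds(config$seed)
  set.seed(seeds[5])
  idx <- sample.int(nrow(table), k)
  ids <- table$specimen_id[idx]

  rows <- list(); r_star <- c()
  for (tr in bill_traits()) {
    sd_e <- config$repeat_error_sd[[tr]]
    truth <- true_bill[idx, tr]
    for (s in 1:2) {
      val <- round(truth + stats::rnorm(k, 0, sd_e), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = ids, trait = tr, session = s, value = val)
    }
    r_star[tr] <- stats::var(truth) / (stats::var(truth) + sd_e^2)
  }
  for (tr in color_traits()) {
    sd_e <- config$score_error_sd
    truth <- true_col[idx, tr]
    for (s in 1:2) {
      val <- threshold_scores(truth + stats::rnorm(k, 0, sd_e),
                              config$color_thresholds, config$color_range)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = ids, trait = tr, session = s, value = as.numeric(val))
    }
    r_star[tr] <- stats::var(truth) / (stats::var(truth) + sd_e^2)
  }
  list(measurements = do.call(rbind, rows), r_star = r_star)
}
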