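#' cuckoomorph: morphometric diagnosability of clinal variation
#'
#' Tools to analyse geographic phenotypic variation in Mangrove Cuckoo
#' (*Coccyzus minor*) from a specimen measurement table: measurement
#' repeatability, a composite bill-size score, cluster and discriminant
#' structure across regions and named subspecies, and pairwise
#' diagnosability under the 75% rule. A synthetic generator
#' ([sample_specimens()]) emulates clinal island populations so the whole
#' pipeline can be validated against known ground truth.
#'
#' @keywords internal
"_PACKAGE"

## ---- taxon / region vocabulary -------------------------------------------

#' The twelve named subspecies and the six geographic regions
#'
#' The analysis covers the 12 named subspecies of Mangrove Cuckoo for which
#' museum series exist, grouped into six broad geographic regions. The
#' subspecies-to-region mapping is fixed by the taxa's published ranges:
#' *maynardi* (Florida, Bahamas); *caymanensis*, *nesiotes*, *teres*
#' (Greater Antilles, with *caymanensis* on the Cayman Islands grouped
#' here); *rileyi* (Antigua and Barbuda); *dominicae*, *vincentis*,
#' *grenadensis* (Lesser Antilles); *minor* (northern South America);
#' *continentalis*, *palloris*, *abbotti* (Middle America, with *abbotti*
#' on Providencia and San Andres grouped with the adjacent Caribbean
#' slope).
#'
#' @return `taxon_region_map()` returns a named character vector mapping
#'   each of the 12 subspecies names to one of the 6 region codes.
#'   `subspecies_levels()` and `region_levels()` return the canonical
#'   orderings (geographic order, Florida southward and clockwise around
#'   the Caribbean).
#' @examples
#' taxon_region_map()[["maynardi"]]
#' @export
taxon_region_map <- function() {
  c(
    maynardi      = "florida_bahamas",
    caymanensis   = "greater_antilles",
    nesiotes      = "greater_antilles",
    teres         = "greater_antilles",
    rileyi        = "antigua_barbuda",
    dominicae     = "lesser_antilles",
    vincentis     = "lesser_antilles",
    grenadensis   = "lesser_antilles",
    minor         = "south_america",
    continentalis = "middle_america",
    palloris      = "middle_america",
    abbotti       = "middle_america"
  )
}

#' @rdname taxon_region_map
#' @export
subspecies_levels <- function() names(taxon_region_map())

#' @rdname taxon_region_map
#' @export
region_levels <- function() {
  c("florida_bahamas", "greater_antilles", "antigua_barbuda",
    "lesser_antilles", "south_america", "middle_america")
}

#' Assign each specimen's subspecies to its geographic region
#'
#' Region is a deterministic function of the subspecies label; no
#' re-identification is attempted (sympatric taxa such as *nesiotes* and
#' *teres* keep their label as given).
#'
#' @param subspecies character vector of subspecies names.
#' @param map named character vector, as [taxon_region_map()].
#' @return character vector of region codes, same length as `subspecies`.
#' @export
assign_region <- function(subspecies, map = taxon_region_map()) {
  subspecies <- as.character(subspecies)
  unknown <- setdiff(unique(subspecies), names(map))
  if (length(unknown) > 0L) {
    stop("unknown subspecies: ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(map), collapse = ", "))
  }
  unname(map[subspecies])
}

## ---- schema ---------------------------------------------------------------

# canonical column set produced by read_specimens() and sample_specimens()
specimen_columns <- function() {
  c("specimen_id", "repository", "subspecies", "region", "locale", "sex",
    "collection_date", bill_traits(), color_traits(), "qc_flags")
}

#' Trait name helpers
#'
#' @return `bill_traits()`: the three bill measurement columns (mm);
#'   `color_traits()`: the four ordinal ventral color-score columns.
#' @export
bill_traits <- function() c("bill_length_mm", "bill_width_mm", "bill_depth_mm")

#' @rdname bill_traits
#' @export
color_traits <- function() c("color_chin", "color_breast", "color_belly",
                             "color_vent")

BILL_SANITY_CAP_MM <- 50

## ---- reading and writing --------------------------------------------------

#' Read a specimen measurement table from CSV
#'
#' Reads one row per museum specimen: identifiers, named subspecies,
#' collection locale, sex, collection date, three bill measurements (mm, to
#' 0.1 mm) and four ordinal ventral color scores (chin, breast, belly,
#' vent). Unparseable numeric cells become `NA` with a QC flag recorded in
#' `qc_flags`; rows are never dropped at read time (filtering is explicit,
#' see [complete_specimens()]). If the file has no `region` column it is
#' derived from `subspecies` via [assign_region()].
#'
#' @param path CSV file with a header row, UTF-8.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(bill_length_mm = "culmen")`. Unmapped canonical names are looked
#'   up directly.
#' @param color_range integer length-2, inclusive support of the ordinal
#'   color scale. The field notebook scale runs 0 (lightest, Methuen 4A2)
#'   to 5 (darkest, Methuen 5B5); the default reflects that.
#' @return data frame with the canonical columns (see Details); attribute
#'   `"color_range"` records the scale.
#' @export
read_specimens <- function(path, schema = NULL, color_range = c(0L, 5L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  if (nrow(raw) == 0L) stop("empty specimen table: ", path)

  required <- c("specimen_id", "subspecies", bill_traits(), color_traits())
  optional <- c("repository", "region", "locale", "sex", "collection_date",
                "qc_flags")
  resolve <- function(canon) {
    if (!is.null(schema) && canon %in% names(schema)) schema[[canon]] else canon
  }
  for (col in required) {
    if (!resolve(col) %in% names(raw)) {
      stop("required column missing from ", path, ": ", col,
           if (!is.null(schema) && col %in% names(schema))
             paste0(" (mapped to '", schema[[col]], "')") else "")
    }
  }

  n <- nrow(raw)
  out <- data.frame(matrix(nrow = n, ncol = 0L))
  for (col in c(required, optional)) {
    src <- resolve(col)
    out[[col]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  flags <- strsplit(ifelse(is.na(out$qc_flags), "", out$qc_flags), ";",
                    fixed = TRUE)

  parse_num <- function(col, values) {
    x <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(x) & !(is.na(values) | values == "" |
                                toupper(values) == "NA"))
    for (i in bad) flags[[i]] <<- c(flags[[i]], paste0("unparseable_", col))
    x
  }
  for (col in bill_traits()) {
    out[[col]] <- parse_num(col, out[[col]])
    oob <- which(!is.na(out[[col]]) &
                   (out[[col]] <= 0 | out[[col]] >= BILL_SANITY_CAP_MM))
    for (i in oob) flags[[i]] <- c(flags[[i]], paste0("out_of_range_", col))
  }
  for (col in color_traits()) {
    out[[col]] <- parse_num(col, out[[col]])
    oob <- which(!is.na(out[[col]]) &
                   (out[[col]] < color_range[1] | out[[col]] > color_range[2] |
                      out[[col]] != round(out[[col]])))
    for (i in oob) flags[[i]] <- c(flags[[i]], paste0("out_of_range_", col))
  }

  out$sex <- ifelse(tolower(out$sex) %in% c("male", "female"),
                    tolower(out$sex), "unknown")
  if (all(is.na(out$region) | out$region == "")) {
    out$region <- assign_region(out$subspecies)
  }
  out$qc_flags <- vapply(flags, function(f) paste(unique(f), collapse = ";"),
                         character(1))
  out <- out[specimen_columns()]
  attr(out, "color_range") <- as.integer(color_range)
  out
}

#' Write a specimen table to CSV
#'
#' Bill measurements are written to 0.1 mm so a write/read round trip is
#' field-identical at the recorded resolution.
#'
#' @param records specimen data frame.
#' @param path output CSV path.
#' @export
write_specimens <- function(records, path) {
  out <- records
  for (col in intersect(bill_traits(), names(out))) {
    out[[col]] <- sprintf("%.1f", out[[col]])
    out[[col]][out[[col]] == "NA"] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

## ---- filtering ------------------------------------------------------------

#' Complete-case filtering with an explicit drop report
#'
#' Missing values are never imputed; each analysis stage filters to the
#' complete cases for the traits it uses, and the reasons for every dropped
#' row are reported so sample sizes are auditable.
#'
#' @param records specimen data frame.
#' @param traits character vector of numeric/ordinal trait columns that
#'   must be present. `character(0)` keeps everything.
#' @return list with `records` (the kept rows), and `report`: a list with
#'   `n_in`, `n_kept`, and `dropped`, a data frame of specimen ids and the
#'   missing traits that excluded them.
#' @export
complete_specimens <- function(records, traits) {
  stopifnot(is.data.frame(records))
  bad <- setdiff(traits, names(records))
  if (length(bad) > 0L) stop("unknown trait column(s): ",
                             paste(bad, collapse = ", "))
  if (length(traits) == 0L) {
    keep <- rep(TRUE, nrow(records))
  } else {
    keep <- rowSums(is.na(as.data.frame(records[, traits, drop = FALSE]))) == 0L
  }
  dropped <- records[!keep, , drop = FALSE]
  reasons <- vapply(seq_len(nrow(dropped)), function(i) {
    miss <- traits[is.na(unlist(dropped[i, traits, drop = TRUE]))]
    paste("missing:", paste(miss, collapse = ","))
  }, character(1))
  report <- list(
    n_in = nrow(records),
    n_kept = sum(keep),
    dropped = data.frame(specimen_id = dropped$specimen_id,
                         reason = reasons)
  )
  if (report$n_kept == 0L) warning("no complete cases for traits: ",
                                   paste(traits, collapse = ", "))
  message(sprintf("complete_specimens: kept %d of %d rows (traits: %s)",
                  report$n_kept, report$n_in,
                  if (length(traits)) paste(traits, collapse = ", ")
                  else "<none>"))
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Tabulate specimen counts and collection-date ranges per subspecies
#'
#' @param records specimen data frame.
#' @return data frame with one row per subspecies present: `subspecies`,
#'   `region`, `n`, and the earliest/latest collection month where dates
#'   exist (`NA` where all dates are unknown).
#' @export
tabulate_collections <- function(records) {
  if (nrow(records) == 0L) {
    warning("empty specimen table")
    return(data.frame(subspecies = character(), region = character(),
                      n = integer(), first_month = integer(),
                      last_month = integer()))
  }
  sp <- factor(records$subspecies,
               levels = intersect(subspecies_levels(),
                                  unique(records$subspecies)))
  months <- suppressWarnings(
    as.integer(format(as.Date(records$collection_date), "%m")))
  agg <- lapply(split(seq_len(nrow(records)), sp), function(idx) {
    m <- months[idx]
    data.frame(
      n = length(idx),
      first_month = if (all(is.na(m))) NA_integer_ else min(m, na.rm = TRUE),
      last_month  = if (all(is.na(m))) NA_integer_ else max(m, na.rm = TRUE)
    )
  })
  region_of <- tapply(records$region, sp, function(r) r[1])
  out <- do.call(rbind, agg)
  out <- cbind(subspecies = names(agg),
               region = unname(region_of[names(agg)]), out)
  rownames(out) <- NULL
  out
}
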