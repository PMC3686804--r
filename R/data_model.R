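#' grebetrends: hierarchical Bayesian trends from winter count-circle surveys
#'
#' Estimates regional population trends and latitudinal range shifts of
#' wintering waterbirds from circle-based count surveys (Christmas Bird
#' Count style data).  The core model is an over-dispersed Poisson
#' regression on the log scale with region-specific intercepts and trends
#' drawn from a common distribution, a nonlinear survey-effort sub-model,
#' a binary boat-use covariate, and circle, year and observation-level
#' random effects, fitted by MCMC through JAGS.
#'
#' @importFrom stats rnorm rpois rbinom rlnorm runif quantile var sd
#'   weighted.mean dpois dnorm setNames update
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

SPECIES_LEVELS <- c("WEST", "CLARK", "UNID")

#' Construct a survey dataset
#'
#' Bundles count records with circle metadata and the analysis year span.
#' A (circle, year) combination with no records at all is a *missing
#' survey* and is treated as unobserved by the model; a recorded zero is
#' a real zero count.  The two are never conflated.
#'
#' @param records data frame with columns `circle_id`, `year`, `species`
#'   (one of `"WEST"`, `"CLARK"`, `"UNID"`), `count`, `effort_hours`,
#'   `boat_used` (0/1).  Counts may be fractional after species
#'   allocation; raw input counts must be non-negative.
#' @param circles data frame with columns `circle_id`, `latitude`,
#'   `longitude`, `coast_distance_km` (`NA` for landlocked circles) and
#'   optionally `region`.
#' @param year_range inclusive integer interval of the analysis period;
#'   defaults to the range of years present in `records`.
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(records, circles, year_range = NULL) {
  records <- as.data.frame(records)
  circles <- as.data.frame(circles)
  req_rec <- c("circle_id", "year", "species", "count", "effort_hours", "boat_used")
  req_cir <- c("circle_id", "latitude", "longitude", "coast_distance_km")
  miss <- setdiff(req_rec, names(records))
  if (length(miss) > 0)
    stop("records is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(req_cir, names(circles))
  if (length(miss) > 0)
    stop("circles is missing columns: ", paste(miss, collapse = ", "))
  if (!"region" %in% names(circles)) circles$region <- NA_character_

  records$circle_id <- as.character(records$circle_id)
  circles$circle_id <- as.character(circles$circle_id)
  records$species <- toupper(as.character(records$species))
  records$species[records$species == "UNIDENTIFIED"] <- "UNID"

  if (nrow(records) > 0) {
    bad <- !records$species %in% SPECIES_LEVELS
    if (any(bad))
      stop("unknown species code(s): ",
           paste(unique(records$species[bad]), collapse = ", "))
    if (any(!is.finite(records$count) | records$count < 0))
      stop("validation error: negative or non-finite count in row(s) ",
           paste(utils::head(which(!is.finite(records$count) | records$count < 0), 5),
                 collapse = ", "))
    if (any(!is.finite(records$effort_hours) | records$effort_hours <= 0))
      stop("validation error: effort_hours must be a known positive number ",
           "for every surveyed count (row(s) ",
           paste(utils::head(which(!is.finite(records$effort_hours) |
                                     records$effort_hours <= 0), 5),
                 collapse = ", "), ")")
    if (any(!records$boat_used %in% c(0, 1)))
      stop("validation error: boat_used must be 0 or 1")
    key <- paste(records$circle_id, records$year, records$species, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (circle, year, species) record(s): ",
           paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 5),
                 collapse = "; "))
  }

  if (anyDuplicated(circles$circle_id))
    stop("duplicate circle_id in circle metadata")
  if (any(!is.finite(circles$latitude) | abs(circles$latitude) > 90))
    stop("validation error: latitude must lie in [-90, 90]")
  cd <- circles$coast_distance_km
  if (any(!is.na(cd) & cd < 0))
    stop("validation error: coast_distance_km must be >= 0 when present")
  orphan <- setdiff(unique(records$circle_id), circles$circle_id)
  if (length(orphan) > 0)
    stop("records reference circles without metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  if (is.null(year_range)) {
    year_range <- if (nrow(records) > 0) range(records$year) else c(NA_integer_, NA_integer_)
  }
  year_range <- as.integer(year_range)
  if (!anyNA(year_range) && nrow(records) > 0 &&
      (min(records$year) < year_range[1] || max(records$year) > year_range[2]))
    stop("records contain years outside year_range")

  structure(list(records = records, circles = circles, year_range = year_range),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat("  circles: ", nrow(x$circles), "   records: ", nrow(x$records), "\n", sep = "")
  if (!anyNA(x$year_range))
    cat("  years:   ", x$year_range[1], "-", x$year_range[2], "\n", sep = "")
  nr <- sum(!is.na(x$circles$region))
  cat("  regions assigned: ", nr, "/", nrow(x$circles), "\n", sep = "")
  invisible(x)
}

#' Read a count-survey table from CSV
#'
#' Expects one row per circle x year x species with the circle metadata
#' repeated on each row.  Absent surveys are encoded by the absence of
#' rows for that circle-year, never by zeros.
#'
#' @param path path to a CSV file with columns `circle_id`, `latitude`,
#'   `longitude`, `coast_distance_km`, `year`, `species`, `count`,
#'   `effort_hours`, `boat_used` and optionally `region`.
#' @param year_range optional analysis year span; defaults to the years
#'   present in the file.
#' @return a [survey_dataset].
#' @export
read_count_table <- function(path, year_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         strip.white = TRUE)
  req <- c("circle_id", "latitude", "longitude", "coast_distance_km",
           "year", "species", "count", "effort_hours", "boat_used")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("input table is missing required column(s): ", paste(miss, collapse = ", "))

  num <- function(col, allow_na = FALSE) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    blank <- is.na(v) | v == "" | toupper(v) == "NA"
    bad <- which(is.na(out) & !blank)
    if (length(bad) > 0)
      stop("parse error: non-numeric value in column '", col, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (!allow_na && any(blank))
      stop("parse error: missing value in column '", col, "' at data row(s) ",
           paste(utils::head(which(blank), 5), collapse = ", "))
    out
  }

  records <- data.frame(
    circle_id = raw$circle_id,
    year = as.integer(num("year")),
    species = raw$species,
    count = num("count"),
    effort_hours = num("effort_hours"),
    boat_used = num("boat_used"),
    stringsAsFactors = FALSE
  )
  circles <- data.frame(
    circle_id = raw$circle_id,
    latitude = num("latitude"),
    longitude = num("longitude"),
    coast_distance_km = num("coast_distance_km", allow_na = TRUE),
    region = if ("region" %in% names(raw)) raw$region else NA_character_,
    stringsAsFactors = FALSE
  )
  circles <- circles[!duplicated(circles$circle_id), , drop = FALSE]
  circles$region[circles$region %in% c("", "NA")] <- NA_character_
  survey_dataset(records, circles, year_range = year_range)
}

#' Write a survey dataset to CSV
#'
#' Emits the same dialect accepted by [read_count_table()], with the
#' circle metadata repeated on every record row, so that a written
#' dataset round-trips to identical records.
#'
#' @param dataset a [survey_dataset]
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_count_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  out <- merge(dataset$records, dataset$circles, by = "circle_id", sort = FALSE)
  out <- out[, c("circle_id", "latitude", "longitude", "coast_distance_km",
                 "region", "year", "species", "count", "effort_hours", "boat_used")]
  out <- out[order(out$circle_id, out$year, match(out$species, SPECIES_LEVELS)), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default region assignment rules
#'
#' An ordered rule table splitting the Pacific winter range into eight
#' analysis regions by coast distance, latitude and longitude.  A circle
#' is *coastal* when its centre lies less than 50 km from the coast;
#' circles at exactly 50 km or farther (or with no coast distance at
#' all) are *interior*.  Latitude breaks follow the field's conventional
#' splits: 51 deg N separates the Alaska/north-coast region, 42 deg N
#' separates the Pacific-Northwest from California, and 36 deg N splits
#' the northern from the southern California coast.  The first matching
#' rule wins; the table is plain data and can be replaced wholesale.
#'
#' @return data frame with columns `region`, `coastal`, `lat_min`,
#'   `lat_max`, `lon_min`, `lon_max` (`NA` = unbounded; minima
#'   inclusive, maxima exclusive).
#' @export
default_region_rules <- function() {
  data.frame(
    region = c("Alaska/North BC", "Salish Sea", "Outer Washington/Oregon Coast",
               "Northern California Coast", "Southern California Coast",
               "Northern Interior", "Interior California/Nevada",
               "Southwestern Interior"),
    coastal = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    lat_min = c(51, 46.5, 42, 36, NA, 42, 35, NA),
    lat_max = c(NA, 51, 51, 42, 36, NA, 42, 42),
    lon_min = c(NA, -124, NA, NA, NA, NA, NA, -114),
    lon_max = c(NA, NA, -124, NA, NA, NA, -114, NA),
    stringsAsFactors = FALSE
  )
}

#' Assign circles to analysis regions
#'
#' Applies an ordered rule table ([default_region_rules()] by default) to
#' every circle: the coastal flag is `coast_distance_km < 50` (absent
#' distance counts as interior), then latitude/longitude bounds are
#' checked in rule order and the first match wins.
#'
#' @param x a [survey_dataset] or a circle metadata data frame
#' @param rules region rule table; see [default_region_rules()]
#' @param overwrite replace existing region labels? Default `FALSE`
#'   (only `NA` regions are filled in).
#' @return `x` with the `region` column populated.
#' @export
assign_region <- function(x, rules = default_region_rules(), overwrite = FALSE) {
  if (inherits(x, "survey_dataset")) {
    x$circles <- assign_region(x$circles, rules, overwrite)
    return(x)
  }
  circles <- as.data.frame(x)
  if (!"region" %in% names(circles)) circles$region <- NA_character_
  todo <- if (overwrite) rep(TRUE, nrow(circles)) else is.na(circles$region)
  if (!any(todo)) return(circles)
  coastal <- !is.na(circles$coast_distance_km) & circles$coast_distance_km < 50
  lab <- rep(NA_character_, nrow(circles))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    ok <- is.na(lab) & todo
    if (!is.na(r$coastal)) ok <- ok & (coastal == r$coastal)
    if (!is.na(r$lat_min)) ok <- ok & circles$latitude >= r$lat_min
    if (!is.na(r$lat_max)) ok <- ok & circles$latitude < r$lat_max
    if (!is.na(r$lon_min)) ok <- ok & circles$longitude >= r$lon_min
    if (!is.na(r$lon_max)) ok <- ok & circles$longitude < r$lon_max
    lab[ok] <- r$region
  }
  unmatched <- todo & is.na(lab)
  if (any(unmatched))
    stop("region assignment failed for circle(s): ",
         paste(utils::head(circles$circle_id[unmatched], 10), collapse = ", "))
  circles$region[todo] <- lab[todo]
  circles
}

#' Filter circles by total detections and survey coverage
#'
#' Retains circles on which at least `min_total` birds were recorded over
#' the whole period (all species categories pooled) and which were
#' surveyed in at least a fraction `min_coverage` of the years in the
#' analysis span.  With the defaults a circle surveyed in exactly half
#' the years is retained, and a circle with a lifetime total one below
#' the threshold is excluded.
#'
#' @param dataset a [survey_dataset]
#' @param min_total minimum lifetime total count (default 10)
#' @param min_coverage minimum surveyed fraction of the year span
#'   (default 0.5)
#' @return the filtered [survey_dataset]; excluded circles and their
#'   reasons are attached as `attr(, "exclusions")`.
#' @export
filter_circles <- function(dataset, min_total = 10, min_coverage = 0.5) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  n_years <- diff(dataset$year_range) + 1L
  tot <- tapply(rec$count, rec$circle_id, sum)
  cov <- tapply(rec$year, rec$circle_id, function(y) length(unique(y)))
  ids <- dataset$circles$circle_id
  tot <- ifelse(ids %in% names(tot), tot[ids], 0)
  cov <- ifelse(ids %in% names(cov), cov[ids], 0)
  keep <- tot >= min_total & cov >= min_coverage * n_years

  reason <- character(sum(!keep))
  low_tot <- tot[!keep] < min_total
  low_cov <- cov[!keep] < min_coverage * n_years
  reason[low_tot & !low_cov] <- "total below threshold"
  reason[!low_tot & low_cov] <- "insufficient survey coverage"
  reason[low_tot & low_cov] <- "total below threshold; insufficient survey coverage"
  exclusions <- data.frame(circle_id = ids[!keep],
                           total = as.numeric(tot[!keep]),
                           years_surveyed = as.integer(cov[!keep]),
                           reason = reason, stringsAsFactors = FALSE)

  if (!any(keep)) {
    cond <- structure(class = c("grebetrends_empty_filter", "error", "condition"),
                      list(message = paste0("no circles remain after filtering (",
                                            nrow(exclusions), " excluded)"),
                           call = sys.call(-1), exclusions = exclusions))
    stop(cond)
  }
  out <- dataset
  out$circles <- dataset$circles[keep, , drop = FALSE]
  rownames(out$circles) <- NULL
  out$records <- rec[rec$circle_id %in% ids[keep], , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Apportion genus-level counts to species
#'
#' Counts reported only to genus (`UNID`) are split between `WEST` and
#' `CLARK` in proportion to the birds identified to species on the same
#' count.  When a count identified no birds at all the fallback chain
#' is: (1) the pooled identified ratio for that circle's region in the
#' same year, (2) the region's all-years identified ratio, (3) leave the
#' count unallocated with a warning.  Allocation is fractional and
#' conserves the circle-year total exactly.
#'
#' @param dataset a [survey_dataset]; regions should be assigned if the
#'   fallback chain may be needed (an unassigned dataset pools over all
#'   circles instead).
#' @return a [survey_dataset] with `UNID` counts apportioned.
#' @export
allocate_unidentified <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0 || !any(rec$species == "UNID" & rec$count > 0)) {
    # drop zero-count UNID rows silently; nothing to apportion
    out <- dataset
    out$records <- rec[!(rec$species == "UNID"), , drop = FALSE]
    if (nrow(out$records) == nrow(rec)) out$records <- rec
    rownames(out$records) <- NULL
    return(out)
  }
  region_of <- setNames(dataset$circles$region, dataset$circles$circle_id)
  region_of[is.na(region_of)] <- "<all>"

  cy <- paste(rec$circle_id, rec$year, sep = "\r")
  wide <- data.frame(key = unique(cy), stringsAsFactors = FALSE)
  pick <- function(sp) {
    v <- setNames(rep(0, nrow(wide)), wide$key)
    sel <- rec$species == sp
    if (any(sel)) {
      s <- tapply(rec$count[sel], cy[sel], sum)
      v[names(s)] <- s
    }
    v
  }
  wide$west <- pick("WEST"); wide$clark <- pick("CLARK"); wide$unid <- pick("UNID")
  parts <- do.call(rbind, strsplit(wide$key, "\r", fixed = TRUE))
  wide$circle_id <- parts[, 1]
  wide$year <- as.integer(parts[, 2])
  wide$region <- unname(region_of[wide$circle_id])
  # survey covariates are shared by all species rows of a circle-year
  first <- !duplicated(cy)
  cov <- rec[first, c("effort_hours", "boat_used")]
  rownames(cov) <- cy[first]
  wide$effort_hours <- cov[wide$key, "effort_hours"]
  wide$boat_used <- cov[wide$key, "boat_used"]

  ident <- wide$west + wide$clark
  ry <- paste(wide$region, wide$year, sep = "\r")
  ry_w <- tapply(wide$west, ry, sum); ry_i <- tapply(ident, ry, sum)
  r_w <- tapply(wide$west, wide$region, sum); r_i <- tapply(ident, wide$region, sum)

  frac_west <- rep(NA_real_, nrow(wide))
  own <- ident > 0
  frac_west[own] <- wide$west[own] / ident[own]
  fb1 <- !own & ry_i[ry] > 0
  frac_west[fb1] <- (ry_w[ry] / ry_i[ry])[fb1]
  fb2 <- is.na(frac_west) & r_i[wide$region] > 0
  frac_west[fb2] <- (r_w[wide$region] / r_i[wide$region])[fb2]

  stuck <- is.na(frac_west) & wide$unid > 0
  if (any(stuck))
    warning(sum(stuck), " circle-year(s) had no identified birds anywhere in the ",
            "fallback chain; their counts remain unallocated")
  alloc <- !is.na(frac_west) & wide$unid > 0
  add_w <- ifelse(alloc, wide$unid * frac_west, 0)
  wide$west <- wide$west + add_w
  wide$clark <- wide$clark + ifelse(alloc, wide$unid - add_w, 0)
  wide$unid <- ifelse(alloc, 0, wide$unid)

  long <- rbind(
    data.frame(circle_id = wide$circle_id, year = wide$year, species = "WEST",
               count = wide$west, effort_hours = wide$effort_hours,
               boat_used = wide$boat_used, stringsAsFactors = FALSE),
    data.frame(circle_id = wide$circle_id, year = wide$year, species = "CLARK",
               count = wide$clark, effort_hours = wide$effort_hours,
               boat_used = wide$boat_used, stringsAsFactors = FALSE),
    data.frame(circle_id = wide$circle_id, year = wide$year, species = "UNID",
               count = wide$unid, effort_hours = wide$effort_hours,
               boat_used = wide$boat_used, stringsAsFactors = FALSE)
  )
  # keep a row when it carries count, or when it preserves an observed zero survey
  keep <- long$count > 0
  seen <- paste(long$circle_id, long$year, sep = "\r") %in%
    paste(long$circle_id, long$year, sep = "\r")[keep]
  keep <- keep | (long$species == "WEST" & !seen)
  long <- long[keep, , drop = FALSE]
  long <- long[order(long$circle_id, long$year, match(long$species, SPECIES_LEVELS)), ]
  rownames(long) <- NULL
  out <- dataset
  out$records <- long
  out
}

#' Summarize survey coverage by missing-year bins
#'
#' Tabulates circles by the number of years in the analysis span in
#' which they were not surveyed, using the bins 0, 1-5, 6-10, 11-18 and
#' more than 18 missing years.
#'
#' @param dataset a [survey_dataset]
#' @return data frame with columns `bin`, `n_circles`, `percent`.
#' @export
coverage_summary <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  bins <- c("0", "1-5", "6-10", "11-18", ">18")
  if (nrow(dataset$circles) == 0 || anyNA(dataset$year_range)) {
    return(data.frame(bin = bins, n_circles = 0L, percent = 0,
                      stringsAsFactors = FALSE))
  }
  n_years <- diff(dataset$year_range) + 1L
  surveyed <- tapply(dataset$records$year, dataset$records$circle_id,
                     function(y) length(unique(y)))
  ids <- dataset$circles$circle_id
  ns <- ifelse(ids %in% names(surveyed), surveyed[ids], 0L)
  missing <- n_years - ns
  cut_bin <- cut(missing, breaks = c(-0.5, 0.5, 5.5, 10.5, 18.5, Inf), labels = bins)
  n <- as.integer(table(cut_bin))
  data.frame(bin = bins, n_circles = n,
             percent = round(100 * n / length(ids), 1),
             stringsAsFactors = FALSE)
}
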