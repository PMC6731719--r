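#' Forest successional types
#'
#' The five-level closed classification of trap surroundings used
#' throughout the package, ordered along the successional gradient from
#' primary forest down to farmland.  Primary forest is the reference
#' level of every model.
#'
#' @return Character vector of the five forest-type labels.
#' @export
forest_types <- function() c("primary", "swamp", "disturbed", "clearcut", "farm")

DT_FMT <- "%Y-%m-%dT%H:%M"

parse_dt <- function(x, what, file = "") {
  out <- as.POSIXct(as.character(x), format = DT_FMT, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    mc_stop("mc_parse_error", "%s: unparseable %s at row %d: '%s'",
            file, what, bad[1], as.character(x)[bad[1]])
  out
}

fmt_dt <- function(x) format(x, DT_FMT, tz = "UTC")

#' Assemble a Malaise-trap dataset from its four component tables
#'
#' Bundles the trap-site, tree-transect, daily-weather and sample tables
#' into a single validated dataset object.  The species list is the set
#' of count columns of the sample table, in column order.
#'
#' @param sites Data frame with columns `trap_id`, `site_code`,
#'   `forest_type`, `orientation_deg`, `canopy_openness_pct` (the last
#'   two may be `NA`).
#' @param trees Data frame with columns `trap_id`, `transect_id`,
#'   `species_name`, `dbh_cm`, `distance_m`, `status`, `decay_level`.
#' @param weather Data frame with columns `date`, `rain_mm`, `tmin_c`,
#'   `tmax_c`.
#' @param samples Data frame with columns `sample_id`, `trap_id`,
#'   `start`, `end`, `usable`, followed by one non-negative integer
#'   count column per species.
#' @return An object of class `mt_dataset`: a list with elements
#'   `sites`, `trees`, `weather`, `samples` and `species`.
#' @export
new_dataset <- function(sites, trees, weather, samples) {
  species <- setdiff(names(samples),
                     c("sample_id", "trap_id", "start", "end", "usable"))
  d <- structure(list(sites = sites, trees = trees, weather = weather,
                      samples = samples, species = species),
                 class = "mt_dataset")
  validate_dataset(d)
  d
}

#' Validate a Malaise-trap dataset
#'
#' Checks the structural invariants of a dataset: unique trap and sample
#' identifiers, forest types drawn from the closed five-level set,
#' positive tree dimensions, decay level recorded exactly for dead
#' trees, unique contiguous weather dates, non-negative rainfall and
#' integer non-negative counts, positive sampling effort, and
#' referential integrity of every sample's and tree's trap.
#'
#' @param d An `mt_dataset`.
#' @return The dataset, invisibly; stops with a classed error otherwise.
#' @export
validate_dataset <- function(d) {
  s <- d$sites
  if (anyDuplicated(s$trap_id))
    mc_stop("mc_validation_error", "duplicate trap_id: %s",
            paste(unique(s$trap_id[duplicated(s$trap_id)]), collapse = ", "))
  bad <- setdiff(unique(s$forest_type), forest_types())
  if (length(bad))
    mc_stop("mc_validation_error", "unknown forest_type: %s",
            paste(bad, collapse = ", "))
  co <- s$canopy_openness_pct
  if (any(!is.na(co) & (co < 0 | co > 100)))
    mc_stop("mc_validation_error", "canopy_openness_pct outside [0,100]")

  tr <- d$trees
  if (nrow(tr)) {
    if (any(tr$dbh_cm <= 0) || any(tr$distance_m <= 0))
      mc_stop("mc_validation_error", "tree dbh_cm and distance_m must be > 0")
    if (!all(tr$status %in% c("alive", "dead")))
      mc_stop("mc_validation_error", "tree status must be alive/dead")
    dead <- tr$status == "dead"
    if (any(dead & !(tr$decay_level %in% 1:3)) ||
        any(!dead & !is.na(tr$decay_level)))
      mc_stop("mc_validation_error",
              "decay_level must be 1-3 for dead trees and empty for live ones")
    orphan <- setdiff(unique(tr$trap_id), s$trap_id)
    if (length(orphan))
      mc_stop("mc_validation_error", "tree rows reference unknown trap(s): %s",
              paste(orphan, collapse = ", "))
  }

  w <- d$weather
  if (anyDuplicated(w$date))
    mc_stop("mc_validation_error", "duplicate weather dates")
  if (any(w$rain_mm < 0))
    mc_stop("mc_validation_error", "negative rain_mm")
  if (nrow(w) > 1) {
    dd <- sort(w$date)
    if (any(diff(dd) != 1))
      mc_stop("mc_validation_error",
              "weather dates are not a single contiguous run (gap after %s)",
              format(dd[which(diff(dd) != 1)[1]]))
  }
  both <- !is.na(w$tmin_c) & !is.na(w$tmax_c)
  if (any(both & w$tmin_c > w$tmax_c))
    mc_stop("mc_validation_error", "tmin_c > tmax_c")

  sa <- d$samples
  if (nrow(sa)) {
    if (anyDuplicated(sa$sample_id))
      mc_stop("mc_validation_error", "duplicate sample_id")
    if (any(sa$end <= sa$start))
      mc_stop("mc_validation_error", "sample end must be after start (%s)",
              paste(sa$sample_id[sa$end <= sa$start], collapse = ", "))
    orphan <- setdiff(unique(sa$trap_id), s$trap_id)
    if (length(orphan))
      mc_stop("mc_validation_error",
              "sample rows reference unknown trap(s): %s",
              paste(orphan, collapse = ", "))
    for (sp in d$species) {
      v <- sa[[sp]]
      if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
        mc_stop("mc_validation_error",
                "counts for '%s' must be non-negative integers", sp)
    }
  }
  invisible(d)
}

req_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    mc_stop("mc_schema_error", "%s: missing column(s): %s",
            file, paste(missing, collapse = ", "))
}

num_col <- function(df, col, file) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
  if (length(bad))
    mc_stop("mc_parse_error", "%s: unparseable %s at row %d: '%s'",
            file, col, bad[1], df[[col]][bad[1]])
  v
}

#' Read a Malaise-trap dataset from its four CSV files
#'
#' @param paths Named list or character vector with elements `sites`,
#'   `trees`, `weather` and `samples` giving the file paths, or a single
#'   directory containing `sites.csv`, `trees.csv`, `weather.csv` and
#'   `samples.csv`.
#' @return A validated `mt_dataset`.
#' @export
read_dataset <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths))
    paths <- file.path(paths, c(sites = "sites.csv", trees = "trees.csv",
                                weather = "weather.csv",
                                samples = "samples.csv"))
  paths <- as.list(paths)
  if (is.null(names(paths)) || !all(c("sites","trees","weather","samples") %in% names(paths)))
    names(paths) <- c("sites", "trees", "weather", "samples")
  for (p in unlist(paths)) if (!file.exists(p))
    mc_stop("mc_io_error", "file not found: %s", p)

  rd <- function(p) read.csv(p, stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")

  s <- rd(paths$sites)
  req_cols(s, c("trap_id", "site_code", "forest_type",
                "orientation_deg", "canopy_openness_pct"), paths$sites)
  sites <- data.frame(trap_id = s$trap_id, site_code = s$site_code,
                      forest_type = s$forest_type,
                      orientation_deg = num_col(s, "orientation_deg", paths$sites),
                      canopy_openness_pct = num_col(s, "canopy_openness_pct", paths$sites),
                      stringsAsFactors = FALSE)

  t <- rd(paths$trees)
  req_cols(t, c("trap_id", "transect_id", "species_name", "dbh_cm",
                "distance_m", "status", "decay_level"), paths$trees)
  trees <- data.frame(trap_id = t$trap_id,
                      transect_id = as.integer(num_col(t, "transect_id", paths$trees)),
                      species_name = t$species_name,
                      dbh_cm = num_col(t, "dbh_cm", paths$trees),
                      distance_m = num_col(t, "distance_m", paths$trees),
                      status = t$status,
                      decay_level = as.integer(num_col(t, "decay_level", paths$trees)),
                      stringsAsFactors = FALSE)

  w <- rd(paths$weather)
  req_cols(w, c("date", "rain_mm", "tmin_c", "tmax_c"), paths$weather)
  wdate <- as.Date(w$date, format = "%Y-%m-%d")
  if (any(is.na(wdate) & !is.na(w$date)))
    mc_stop("mc_parse_error", "%s: unparseable date at row %d",
            paths$weather, which(is.na(wdate))[1])
  weather <- data.frame(date = wdate,
                        rain_mm = num_col(w, "rain_mm", paths$weather),
                        tmin_c = num_col(w, "tmin_c", paths$weather),
                        tmax_c = num_col(w, "tmax_c", paths$weather))

  sa <- rd(paths$samples)
  req_cols(sa, c("sample_id", "trap_id", "start", "end", "usable"),
           paths$samples)
  species <- setdiff(names(sa), c("sample_id", "trap_id", "start", "end", "usable"))
  samples <- data.frame(sample_id = sa$sample_id, trap_id = sa$trap_id,
                        start = parse_dt(sa$start, "start", paths$samples),
                        end = parse_dt(sa$end, "end", paths$samples),
                        usable = as.logical(toupper(sa$usable)),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (any(is.na(samples$usable)))
    mc_stop("mc_parse_error", "%s: unparseable usable flag", paths$samples)
  for (sp in species) {
    v <- num_col(sa, sp, paths$samples)
    if (any(is.na(v)))
      mc_stop("mc_parse_error", "%s: missing count for '%s'", paths$samples, sp)
    samples[[sp]] <- as.integer(v)
  }
  new_dataset(sites, trees, weather, samples)
}

#' Write a Malaise-trap dataset to four CSV files
#'
#' The inverse of [read_dataset()]: counts are written as one explicit
#' column per species (zeros included), datetimes at minute precision in
#' ISO-8601, and a second write of a re-read dataset is byte-identical.
#'
#' @param d An `mt_dataset`.
#' @param dir Output directory (created if missing).
#' @return The four file paths, invisibly.
#' @export
write_dataset <- function(d, dir) {
  validate_dataset(d)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c(sites = "sites.csv", trees = "trees.csv",
                            weather = "weather.csv", samples = "samples.csv"))
  names(paths) <- c("sites", "trees", "weather", "samples")
  wr <- function(x, p) {
    tryCatch(write.csv(x, p, row.names = FALSE, quote = FALSE, na = ""),
             error = function(e) mc_stop("mc_io_error", "cannot write %s: %s",
                                         p, conditionMessage(e)))
  }
  wr(d$sites, paths["sites"])
  wr(d$trees, paths["trees"])
  w <- d$weather
  w$date <- format(w$date, "%Y-%m-%d")
  wr(w, paths["weather"])
  sa <- d$samples
  sa$start <- fmt_dt(sa$start)
  sa$end <- fmt_dt(sa$end)
  sa$usable <- ifelse(sa$usable, "true", "false")
  wr(sa, paths["samples"])
  invisible(paths)
}

#' Sampling effort of each sample, in fractional trap days
#'
#' @param samples The `samples` table of an `mt_dataset`.
#' @return Numeric vector of effort in days.
#' @export
effort_days <- function(samples) {
  as.numeric(difftime(samples$end, samples$start, units = "days"))
}

#' Drop unusable and weather-uncovered samples
#'
#' Removes samples flagged not usable (e.g. trampled or partly eaten
#' samples that are unrepresentative of a normal catch) and, optionally,
#' samples whose collecting interval is not fully covered by the daily
#' weather record.  One log line is emitted per dropped sample; the
#' operation is idempotent.
#'
#' @param d An `mt_dataset`.
#' @param weather_required If `TRUE` (default), also drop samples whose
#'   interval includes a calendar day missing from the weather table.
#' @return The filtered `mt_dataset`.
#' @export
filter_samples <- function(d, weather_required = TRUE) {
  validate_dataset(d)
  sa <- d$samples
  keep <- sa$usable
  for (id in sa$sample_id[!keep])
    mc_log("filter_samples: dropping %s (flagged unusable)", id)
  if (weather_required && nrow(sa)) {
    # the weather table is a validated contiguous run, so coverage of
    # [start, end) reduces to a range check on first and last day
    wmin <- min(d$weather$date); wmax <- max(d$weather$date)
    first <- as.Date(sa$start, tz = "UTC")
    last <- pmax(first, as.Date(sa$end - 1, tz = "UTC"))
    covered <- first >= wmin & last <= wmax & nrow(d$weather) > 0
    for (i in which(keep & !covered))
      mc_log("filter_samples: dropping %s (no weather for %s)",
             sa$sample_id[i],
             format(if (first[i] < wmin) first[i] else last[i]))
    keep <- keep & covered
  }
  if (!any(keep)) warning("filter_samples: no samples retained")
  d$samples <- sa[keep, , drop = FALSE]
  rownames(d$samples) <- NULL
  attr(d, "n_dropped") <- sum(!keep)
  d
}

# calendar days whose [00:00, 24:00) window intersects [start, end)
sample_days <- function(start, end) {
  first <- as.Date(start, tz = "UTC")
  last <- as.Date(end - 1, tz = "UTC")   # end itself is exclusive
  seq(first, max(first, last), by = "day")
}
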