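#' Dead-wood score of one trap
#'
#' Quantifies the clearly decaying wood available around a trap from its
#' two tree transects.  Only dead trees at the highest decay level (3,
#' clearly decaying) contribute; each contributes its squared diameter
#' divided by its distance from the trap, so large logs close to the
#' trap dominate.  Diameter at breast height enters in metres, giving
#' scores of order 0.1-1 for well-provisioned forest traps.
#'
#' @param trees Tree records (rows of the `trees` table) for a single
#'   trap.
#' @param dbh_scale Divisor converting the recorded `dbh_cm` to the unit
#'   used in the score; the default 100 scores in m^2 m^-1.  Set to 1
#'   to keep dbh in centimetres.
#' @return Non-negative scalar score.
#' @export
deadwood_score <- function(trees, dbh_scale = 100) {
  if (nrow(trees) == 0) return(0)
  if (length(unique(trees$trap_id)) > 1)
    mc_stop("mc_validation_error", "deadwood_score: records from several traps")
  if (any(trees$distance_m <= 0))
    mc_stop("mc_validation_error", "deadwood_score: distance_m must be > 0")
  sel <- trees$status == "dead" & !is.na(trees$decay_level) &
    trees$decay_level == 3
  if (!any(sel)) return(0)
  sum((trees$dbh_cm[sel] / dbh_scale)^2 / trees$distance_m[sel])
}

#' Date covariate of a sample
#'
#' Days from a fixed reference instant to the midpoint of the collecting
#' interval; negative before the reference.
#'
#' @param start,end Sample start and end datetimes (POSIXct).
#' @param reference Reference datetime (POSIXct); the campaign default
#'   is 1 September 2014 00:00 UTC.
#' @return Signed decimal days.
#' @export
date_covariate <- function(start, end, reference) {
  if (any(end <= start))
    mc_stop("mc_validation_error", "date_covariate: end must be after start")
  mid <- start + as.numeric(difftime(end, start, units = "secs")) / 2
  as.numeric(difftime(mid, reference, units = "days"))
}

#' Rainfall covariate of a sample
#'
#' Unweighted mean of the daily rainfall over every calendar day whose
#' 24 h window intersects the collecting interval `[start, end)`.
#' Partial first and last days count fully.
#'
#' @param start,end Sample start and end datetimes (POSIXct).
#' @param weather The `weather` table of an `mt_dataset`.
#' @return Mean daily rainfall in mm per day.
#' @export
rain_covariate <- function(start, end, weather) {
  rain_covariate_vec(start, end, weather)
}

# vectorised core: the weather table is a contiguous daily run, so a
# sample's mean is a difference of cumulative sums
rain_covariate_vec <- function(starts, ends, weather) {
  o <- order(weather$date)
  wd <- weather$date[o]
  if (length(wd) > 1 && any(diff(as.integer(wd)) != 1L)) {
    # gappy table (not a validated dataset): per-day matching
    return(vapply(seq_along(starts), function(i) {
      days <- sample_days(starts[i], ends[i])
      idx <- match(as.character(days), as.character(wd))
      if (anyNA(idx))
        mc_stop("mc_coverage_error", "rain_covariate: no weather for %s",
                as.character(days)[which(is.na(idx))[1]])
      mean(weather$rain_mm[o][idx])
    }, numeric(1)))
  }
  cs <- cumsum(weather$rain_mm[o])
  first <- as.Date(starts, tz = "UTC")
  last <- pmax(first, as.Date(ends - 1, tz = "UTC"))
  fd <- as.integer(first - wd[1]) + 1L
  ld <- as.integer(last - wd[1]) + 1L
  bad <- which(fd < 1L | ld > length(wd))
  if (length(bad)) {
    b <- bad[1]
    miss <- if (fd[b] < 1L) first[b] else last[b]
    mc_stop("mc_coverage_error", "rain_covariate: no weather for %s",
            format(miss))
  }
  cs0 <- c(0, cs)
  (cs0[ld + 1L] - cs0[fd]) / (ld - fd + 1L)
}

#' Assemble the per-sample model design
#'
#' Builds one design row per retained sample: the effort offset (days),
#' the date, rainfall and dead-wood covariates, the forest type of the
#' trap, and the per-species count vector.  The dead-wood score is
#' computed once per trap and broadcast to its samples; traps with no
#' tree records at all get score 0 with a warning (in the field data the
#' farmland traps had no transect trees).
#'
#' @param d An `mt_dataset`, already passed through [filter_samples()]
#'   with `weather_required = TRUE`.
#' @param reference Reference datetime for the date covariate.
#' @param dbh_scale Passed to [deadwood_score()].
#' @return An object of class `mt_design` with elements `rows` (data
#'   frame: sample_id, trap_id, site_code, days, date, rain, deadwood,
#'   forest_type), `counts` (integer matrix samples x species),
#'   `species` and `reference`.
#' @export
assemble_design <- function(d, reference = as.POSIXct("2014-09-01 00:00:00", tz = "UTC"),
                            dbh_scale = 100) {
  validate_dataset(d)
  sa <- d$samples
  if (any(!sa$usable))
    mc_stop("mc_validation_error",
            "assemble_design: run filter_samples() first (unusable samples present)")
  score <- vapply(d$sites$trap_id, function(tp) {
    tr <- d$trees[d$trees$trap_id == tp, , drop = FALSE]
    if (nrow(tr) == 0 && tp %in% sa$trap_id) {
      warning(sprintf("trap %s has no tree records; dead-wood score set to 0", tp))
      return(0)
    }
    deadwood_score(tr, dbh_scale = dbh_scale)
  }, numeric(1))
  names(score) <- d$sites$trap_id

  si <- match(sa$trap_id, d$sites$trap_id)
  rows <- data.frame(
    sample_id = sa$sample_id,
    trap_id = sa$trap_id,
    site_code = d$sites$site_code[si],
    days = effort_days(sa),
    date = date_covariate(sa$start, sa$end, reference),
    rain = rain_covariate_vec(sa$start, sa$end, d$weather),
    deadwood = unname(score[sa$trap_id]),
    forest_type = factor(d$sites$forest_type[si], levels = forest_types()),
    stringsAsFactors = FALSE)
  counts <- as.matrix(sa[, d$species, drop = FALSE])
  rownames(counts) <- sa$sample_id
  storage.mode(counts) <- "integer"
  structure(list(rows = rows, counts = counts, species = d$species,
                 reference = reference),
            class = "mt_design")
}

# fixed model-matrix column order; primary forest is the all-zero
# reference so its coefficient is identically 0
design_colnames <- function() {
  c("intercept", "date", "rain", "deadwood", "swamp", "disturbed",
    "clearcut", "farm")
}

#' Model matrix of a design
#'
#' Fixed column order `intercept, date, rain, deadwood, swamp,
#' disturbed, clearcut, farm`; primary forest is the all-zero reference.
#'
#' @param design An `mt_design`.
#' @return Numeric matrix with one row per sample.
#' @export
design_matrix <- function(design) {
  r <- design$rows
  X <- cbind(intercept = 1, date = r$date, rain = r$rain,
             deadwood = r$deadwood,
             swamp = as.numeric(r$forest_type == "swamp"),
             disturbed = as.numeric(r$forest_type == "disturbed"),
             clearcut = as.numeric(r$forest_type == "clearcut"),
             farm = as.numeric(r$forest_type == "farm"))
  rownames(X) <- r$sample_id
  X
}

#' Write / read a design as CSV
#'
#' `design.csv` holds one row per sample with the covariates followed by
#' one count column per species; it is the exact input of the model
#' fitting stage.
#'
#' @param design An `mt_design`.
#' @param path Output CSV path.
#' @return `write_design`: the path, invisibly.  `read_design`: an
#'   `mt_design`.
#' @export
write_design <- function(design, path) {
  df <- design$rows
  df$date_reference <- fmt_dt(design$reference)
  df <- cbind(df, as.data.frame(design$counts, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("sample_id", "trap_id", "site_code", "days", "date", "rain",
             "deadwood", "forest_type", "date_reference")
  req_cols(df, fixed, path)
  species <- setdiff(names(df), fixed)
  counts <- as.matrix(df[, species, drop = FALSE])
  rownames(counts) <- df$sample_id
  storage.mode(counts) <- "integer"
  rows <- df[, c("sample_id", "trap_id", "site_code", "days", "date",
                 "rain", "deadwood", "forest_type")]
  rows$forest_type <- factor(rows$forest_type, levels = forest_types())
  structure(list(rows = rows, counts = counts, species = species,
                 reference = parse_dt(df$date_reference[1], "date_reference", path)),
            class = "mt_design")
}
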