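# Fixtures are built in code: a hand-sized toy dataset for the I/O and
# covariate contracts, and scaled-down scenarios for simulation-based
# checks.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# 3 traps in 2 sites, 2 species, 4 samples, three weeks of weather
toy_dataset <- function() {
  sites <- data.frame(
    trap_id = c("A1T1", "A1T2", "B1T1"),
    site_code = c("A1", "A1", "B1"),
    forest_type = c("primary", "primary", "farm"),
    orientation_deg = c(10, 200, NA),
    canopy_openness_pct = c(5, 8, 90),
    stringsAsFactors = FALSE)
  trees <- data.frame(
    trap_id = c("A1T1", "A1T1", "A1T2"),
    transect_id = c(1L, 2L, 1L),
    species_name = c("Celtis durandii", "Celtis durandii", "Markhamia lutea"),
    dbh_cm = c(80, 12, 40),
    distance_m = c(2, 5, 10),
    status = c("dead", "dead", "alive"),
    decay_level = c(3L, 2L, NA_integer_),
    stringsAsFactors = FALSE)
  weather <- data.frame(
    date = seq(as.Date("2014-09-01"), as.Date("2014-09-30"), by = "day"),
    rain_mm = rep(c(0, 4), 15),
    tmin_c = 15, tmax_c = 26)
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    trap_id = c("A1T1", "A1T2", "B1T1", "A1T1"),
    start = utc(c("2014-09-01", "2014-09-01", "2014-09-01", "2014-09-15")),
    end = utc(c("2014-09-15", "2014-09-15", "2014-09-15", "2014-09-29")),
    usable = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  samples[["sp one"]] <- c(3L, 0L, 0L, 1L)
  samples[["sp two"]] <- c(1L, 2L, 0L, 0L)
  new_dataset(sites, trees, weather, samples)
}

# the default campaign shrunk to one trap per site and ~5 services,
# for tests that only need a valid end-to-end dataset quickly
small_scenario <- function(seed = 1) {
  scen <- make_default_scenario(seed)
  scen$traps_per_site <- c(primary = 2, swamp = 1, disturbed = 1,
                           clearcut = 1, farm = 1)
  scen$campaign_end <- utc("2015-01-12 00:00:00")
  scen
}

# a tiny 3-site design with simulated counts for exact-enumeration work
tiny_design <- function(seed = 5, n_per_trap = 6, species = c("sp1", "sp2")) {
  set.seed(seed)
  sites <- c("S1", "S2", "S3")
  rows <- do.call(rbind, lapply(seq_along(sites), function(k) {
    data.frame(
      sample_id = sprintf("%s_%d", sites[k], seq_len(n_per_trap)),
      trap_id = paste0(sites[k], "T1"),
      site_code = sites[k],
      days = 14,
      date = seq(0, 70, length.out = n_per_trap),
      rain = round(runif(n_per_trap, 0, 8), 2),
      deadwood = c(0.3, 0.1, 0.02)[k],
      forest_type = factor(c("primary", "disturbed", "clearcut")[k],
                           levels = forest_types()),
      stringsAsFactors = FALSE)
  }))
  counts <- sapply(species, function(s) {
    mu <- rows$days * exp(-3.2 + 0.004 * rows$date - 0.05 * rows$rain +
                            1.5 * rows$deadwood)
    as.integer(rnbinom(nrow(rows), size = 1.5, mu = mu))
  })
  rownames(counts) <- rows$sample_id
  structure(list(rows = rows, counts = counts, species = species,
                 reference = utc("2014-09-01 00:00:00")),
            class = "mt_design")
}

# 3 primary + 3 disturbed sites with a configurable catch ratio
six_site_design <- function(seed, n_per_trap = 8, ratio = 1) {
  set.seed(seed)
  sites <- sprintf("S%d", 1:6)
  type <- rep(c("primary", "disturbed"), each = 3)
  rows <- do.call(rbind, lapply(1:6, function(k) {
    data.frame(
      sample_id = sprintf("%s_%d", sites[k], seq_len(n_per_trap)),
      trap_id = paste0(sites[k], "T1"),
      site_code = sites[k],
      days = 14,
      date = seq(0, 70, length.out = n_per_trap),
      rain = round(runif(n_per_trap, 0, 8), 2),
      deadwood = runif(1, 0.05, 0.3),
      forest_type = factor(type[k], levels = forest_types()),
      stringsAsFactors = FALSE)
  }))
  mu <- rows$days * exp(-2.2 + 0.004 * rows$date -
                          log(ratio) * (rows$forest_type == "disturbed"))
  counts <- cbind(sp1 = as.integer(rnbinom(nrow(rows), size = 2, mu = mu)),
                  sp2 = as.integer(rnbinom(nrow(rows), size = 2, mu = mu)))
  rownames(counts) <- rows$sample_id
  structure(list(rows = rows, counts = counts, species = c("sp1", "sp2"),
                 reference = utc("2014-09-01 00:00:00")),
            class = "mt_design")
}

# independent NB2 log-pmf by explicit lgamma arithmetic (oracle)
nb_logpmf_direct <- function(y, mu, th) {
  lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
    th * (log(th) - log(th + mu)) + y * (log(mu) - log(th + mu))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
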