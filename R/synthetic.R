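# Synthetic Malaise-trap campaigns with the statistical structure the
# analysis assumes: the log-linear catch model as generative mean, NB2
# noise, bimodal wet/dry rainfall, a successional dead-wood gradient and
# an optional shared log-normal site effect.

coef_names9 <- function() c("intercept", "date", "rain", "deadwood",
                            "primary", "swamp", "disturbed", "clearcut", "farm")

species_coef <- function(v) setNames(as.numeric(v), coef_names9())

#' Default synthetic campaign scenario
#'
#' The `kibale2014` scenario: 10 trap sites spread over the five forest
#' types, 34 traps serviced at approximately two-week intervals from
#' 8 September 2014 to 14 September 2015, two wet and two dry seasons,
#' and six wasp species whose catches follow the fitted catch model.
#' The four well-sampled species carry the published coefficient
#' vectors; the two rare species have intercepts calibrated so their
#' expected campaign totals are roughly 6 and 1 individuals.
#'
#' @param seed Integer seed stored in the scenario; all generators
#'   derive their randomness from it.
#' @return An object of class `mt_scenario`.
#' @export
make_default_scenario <- function(seed = 1) {
  sp <- list(
    `Epirhyssa ghesquierei` = list(
      coef = species_coef(c(-4.47, 0.00197, -0.0831, 3.57, 0, 0.250, -1.010, -0.627, -12.9)),
      theta = 1),
    `Epirhyssa johanna` = list(
      coef = species_coef(c(-10.44, 0.00400, -0.1000, 2.50, 0, 0.000, -0.500, 0.300, -12.0)),
      theta = 1),
    `Epirhyssa overlaeti` = list(
      coef = species_coef(c(-5.56, 0.00360, -0.0366, 4.42, 0, 0.0273, -1.300, -2.210, -12.3)),
      theta = 1),
    `Epirhyssa quagga` = list(
      coef = species_coef(c(-7.38, 0.00980, -0.1770, 3.820, 0, -0.4410, -0.646, -0.181, -10.8)),
      theta = 1),
    `Epirhyssa tombeaodiba` = list(
      coef = species_coef(c(-8.22, 0.00400, -0.2000, 3.00, 0, -0.300, -0.800, -0.800, -12.0)),
      theta = 1),
    `Epirhyssa uelensis` = list(
      coef = species_coef(c(-4.17, 0.00543, -0.3740, 2.31, 0, -1.040, -0.945, -0.999, -12.4)),
      theta = 1))
  scen <- structure(list(
    name = "kibale2014",
    seed = as.integer(seed),
    n_sites_per_type = c(primary = 2, swamp = 1, disturbed = 3,
                         clearcut = 3, farm = 1),
    traps_per_site = c(primary = 5, swamp = 4, disturbed = 3,
                       clearcut = 3, farm = 2),
    campaign_start = as.POSIXct("2014-09-08 00:00:00", tz = "UTC"),
    campaign_end = as.POSIXct("2015-09-14 00:00:00", tz = "UTC"),
    reference = as.POSIXct("2014-09-01 00:00:00", tz = "UTC"),
    service_interval_days = 14,
    service_jitter_days = 2,
    species_params = sp,
    weather_params = list(
      wet_windows = list(c("03-01", "05-31"), c("09-01", "11-30")),
      wet = list(p_wet = 0.60, shape = 0.9, scale = 13),
      dry = list(p_wet = 0.30, shape = 0.8, scale = 8)),
    deadwood_params = list(
      primary = c(meanlog = log(0.27), sdlog = 0.5),
      swamp = c(meanlog = log(0.20), sdlog = 0.5),
      disturbed = c(meanlog = log(0.15), sdlog = 0.5),
      clearcut = c(meanlog = log(0.08), sdlog = 0.5),
      farm = c(meanlog = -Inf, sdlog = 0)),
    site_effect_sd = 0.3,
    unusable_fraction = 0.022), class = "mt_scenario")
  validate_scenario(scen)
  scen
}

#' Validate a scenario
#'
#' @param scen An `mt_scenario`.
#' @return The scenario, invisibly; stops on an invariant breach.
#' @export
validate_scenario <- function(scen) {
  stopifnot(inherits(scen, "mt_scenario"))
  if (scen$campaign_end <= scen$campaign_start)
    mc_stop("mc_validation_error", "campaign_end must follow campaign_start")
  if (scen$service_interval_days <= 0 || scen$service_jitter_days < 0 ||
      scen$service_jitter_days >= scen$service_interval_days)
    mc_stop("mc_validation_error", "invalid service interval/jitter")
  if (scen$unusable_fraction < 0 || scen$unusable_fraction >= 1)
    mc_stop("mc_validation_error", "unusable_fraction outside [0,1)")
  if (scen$site_effect_sd < 0)
    mc_stop("mc_validation_error", "site_effect_sd must be >= 0")
  for (reg in c("wet", "dry")) {
    w <- scen$weather_params[[reg]]
    if (w$p_wet < 0 || w$p_wet > 1 || w$shape <= 0 || w$scale <= 0)
      mc_stop("mc_validation_error", "invalid %s-regime rain parameters", reg)
  }
  if (!setequal(names(scen$n_sites_per_type), forest_types()) ||
      any(scen$n_sites_per_type < 0) || any(scen$traps_per_site < 0))
    mc_stop("mc_validation_error", "invalid site/trap allocation")
  for (s in names(scen$species_params)) {
    p <- scen$species_params[[s]]
    if (p$theta <= 0)
      mc_stop("mc_validation_error", "theta must be > 0 for %s", s)
    if (!identical(names(p$coef), coef_names9()) || p$coef[["primary"]] != 0)
      mc_stop("mc_validation_error", "malformed coefficients for %s", s)
  }
  invisible(scen)
}

in_wet_window <- function(dates, windows) {
  md <- format(dates, "%m-%d")
  out <- rep(FALSE, length(md))
  for (w in windows) out <- out | (md >= w[1] & md <= w[2])
  out
}

#' Generate a daily weather series
#'
#' One row per calendar day of the campaign.  Rain is zero-inflated
#' gamma with separate wet- and dry-season regimes (wet seasons are
#' fixed month-day windows); temperatures are plausible fillers not
#' used by the catch model.
#'
#' @param scen An `mt_scenario`.
#' @param seed Seed; defaults to the scenario seed.
#' @return A `weather` data frame (date, rain_mm, tmin_c, tmax_c).
#' @export
generate_weather <- function(scen, seed = scen$seed) {
  validate_scenario(scen)
  dates <- seq(as.Date(scen$campaign_start), as.Date(scen$campaign_end),
               by = "day")
  wet <- in_wet_window(dates, scen$weather_params$wet_windows)
  with_seed(seed + 101L, {
    rain <- numeric(length(dates))
    for (reg in c("wet", "dry")) {
      idx <- if (reg == "wet") which(wet) else which(!wet)
      p <- scen$weather_params[[reg]]
      wet_day <- rbinom(length(idx), 1, p$p_wet) == 1
      rain[idx] <- ifelse(wet_day,
                          rgamma(length(idx), shape = p$shape, scale = p$scale),
                          0)
    }
    tmin <- round(rnorm(length(dates), 15, 1.5), 1)
    tmax <- pmax(round(rnorm(length(dates), 26, 2), 1), tmin + 1)
    data.frame(date = dates, rain_mm = round(rain, 2),
               tmin_c = tmin, tmax_c = tmax)
  })
}

#' Generate trap sites and tree transects
#'
#' Lays out the configured number of sites per forest type and traps
#' per site, then gives every non-farmland trap a tree list whose
#' clearly decaying (decay level 3) subset realises a log-normal draw
#' of the dead-wood score, plus live and lightly decayed distractor
#' trees.  Farmland traps have no transect trees at all.
#'
#' @param scen An `mt_scenario`.
#' @param seed Seed; defaults to the scenario seed.
#' @return List with `sites` and `trees` data frames and `trap_scores`,
#'   the realised per-trap dead-wood scores.
#' @export
generate_landscape <- function(scen, seed = scen$seed) {
  validate_scenario(scen)
  prefix <- c(primary = "P", swamp = "SW", disturbed = "D",
              clearcut = "C", farm = "F")
  canopy_mu <- c(primary = 8, swamp = 12, disturbed = 20, clearcut = 45,
                 farm = 85)
  tree_pool <- c("Fagara macrophylla", "Celtis durandii", "Funtumia latifolia",
                 "Markhamia lutea", "Strombosia scheffleri", "Uvariopsis congensis")
  with_seed(seed + 202L, {
    sites <- list(); trees <- list(); scores <- numeric(); k <- 0
    for (ty in forest_types()) {
      for (si in seq_len(scen$n_sites_per_type[[ty]])) {
        site_code <- paste0(prefix[[ty]], si)
        for (tj in seq_len(scen$traps_per_site[[ty]])) {
          k <- k + 1
          trap_id <- paste0(site_code, "T", tj)
          sites[[k]] <- data.frame(
            trap_id = trap_id, site_code = site_code, forest_type = ty,
            orientation_deg = 10 * sample.int(36, 1),
            canopy_openness_pct = round(min(100, max(0,
              rnorm(1, canopy_mu[[ty]], 5))), 1),
            stringsAsFactors = FALSE)
          dw <- scen$deadwood_params[[ty]]
          tr <- list()
          if (is.finite(dw[["meanlog"]])) {
            target <- rlnorm(1, dw[["meanlog"]], dw[["sdlog"]])
            npiece <- sample.int(3, 1)
            w <- runif(npiece); w <- w / sum(w)
            for (pc in seq_len(npiece)) {
              t_pc <- target * w[pc]
              # a piece this small cannot be realised by a >= 5 cm dbh
              # tree within the transect; its contribution is negligible
              if (t_pc < 1e-4) next
              d <- runif(1, min(max(1, 0.0025 / t_pc), 24.9), 25)
              dbh_m <- sqrt(t_pc * d)
              tr[[length(tr) + 1]] <- data.frame(
                trap_id = trap_id, transect_id = sample.int(2, 1),
                species_name = sample(tree_pool, 1),
                dbh_cm = round(100 * dbh_m, 1), distance_m = round(d, 1),
                status = "dead", decay_level = 3L, stringsAsFactors = FALSE)
            }
            n_live <- rpois(1, 12)
            if (n_live > 0) tr[[length(tr) + 1]] <- data.frame(
              trap_id = trap_id, transect_id = sample.int(2, n_live, replace = TRUE),
              species_name = sample(tree_pool, n_live, replace = TRUE),
              dbh_cm = round(pmax(5, rlnorm(n_live, log(15), 0.6)), 1),
              distance_m = round(runif(n_live, 1, 25), 1),
              status = "alive", decay_level = NA_integer_,
              stringsAsFactors = FALSE)
            n_light <- rpois(1, 2)
            if (n_light > 0) tr[[length(tr) + 1]] <- data.frame(
              trap_id = trap_id, transect_id = sample.int(2, n_light, replace = TRUE),
              species_name = sample(tree_pool, n_light, replace = TRUE),
              dbh_cm = round(pmax(5, rlnorm(n_light, log(12), 0.6)), 1),
              distance_m = round(runif(n_light, 1, 25), 1),
              status = "dead", decay_level = sample(1:2, n_light, replace = TRUE),
              stringsAsFactors = FALSE)
          }
          tr <- if (length(tr)) do.call(rbind, tr) else NULL
          if (!is.null(tr)) trees[[length(trees) + 1]] <- tr
          scores[trap_id] <- if (is.null(tr)) 0 else deadwood_score(tr)
        }
      }
    }
    sites <- do.call(rbind, sites)
    trees <- if (length(trees)) do.call(rbind, trees) else
      data.frame(trap_id = character(), transect_id = integer(),
                 species_name = character(), dbh_cm = numeric(),
                 distance_m = numeric(), status = character(),
                 decay_level = integer(), stringsAsFactors = FALSE)
    rownames(sites) <- rownames(trees) <- NULL
    list(sites = sites, trees = trees, trap_scores = scores)
  })
}

#' Generate the trap-service schedule
#'
#' Per trap, consecutive service intervals of the configured length
#' plus a uniform jitter span the campaign window; a configured
#' fraction of samples is flagged unusable.  Counts are left empty
#' (zero) for [simulate_counts()] to fill.
#'
#' @param scen An `mt_scenario`.
#' @param sites Trap-site table from [generate_landscape()].
#' @param seed Seed; defaults to the scenario seed.
#' @return A `samples` data frame without count columns.
#' @export
generate_campaign <- function(scen, sites, seed = scen$seed) {
  validate_scenario(scen)
  span <- as.numeric(difftime(scen$campaign_end, scen$campaign_start,
                              units = "days"))
  # enough candidate intervals per trap to overshoot the campaign end
  nmax <- ceiling(span / max(scen$service_interval_days -
                               scen$service_jitter_days, 0.5)) + 1L
  with_seed(seed + 303L, {
    out <- lapply(sites$trap_id, function(tp) {
      dur <- rep(scen$service_interval_days, nmax) +
        if (scen$service_jitter_days > 0)
          runif(nmax, -scen$service_jitter_days, scen$service_jitter_days)
        else 0
      dur_min <- round(dur * 86400 / 60) * 60          # minute precision
      ends <- scen$campaign_start + cumsum(dur_min)
      keep <- as.numeric(ends) <= as.numeric(scen$campaign_end) + 1e-6
      n <- sum(keep)
      if (n == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s_S%02d", tp, seq_len(n)),
        trap_id = tp,
        start = c(scen$campaign_start, ends[seq_len(n - 1)]),
        end = ends[seq_len(n)],
        usable = runif(n) >= scen$unusable_fraction,
        stringsAsFactors = FALSE)
    })
    samples <- do.call(rbind, out)
    rownames(samples) <- NULL
    samples
  })
}

# expected catch per sample row for one species (9-coefficient vector)
eta_for_species <- function(rows, coef9) {
  ft_eff <- coef9[forest_types()]
  coef9[["intercept"]] + coef9[["date"]] * rows$date +
    coef9[["rain"]] * rows$rain + coef9[["deadwood"]] * rows$deadwood +
    unname(ft_eff[as.character(rows$forest_type)])
}

#' Simulate counts into a design
#'
#' Draws NB2 counts for every design row and species: the mean is
#' `days * exp(eta + site_effect)` with `eta` the scenario's generating
#' linear predictor and, when `site_effect_sd > 0`, a shared normal
#' deviation per site and species on the log scale (the within-site
#' correlation that motivates site-level resampling).
#'
#' @param design An `mt_design` whose rows carry the covariates.
#' @param scen An `mt_scenario` whose species parameters to use.
#' @param seed Seed; defaults to the scenario seed.
#' @return The design with its `counts` matrix replaced by simulated
#'   counts (species = scenario species).
#' @export
simulate_counts <- function(design, scen, seed = scen$seed) {
  validate_scenario(scen)
  rows <- design$rows
  spn <- names(scen$species_params)
  sites <- sort(unique(rows$site_code))
  with_seed(seed + 404L, {
    eff <- matrix(if (scen$site_effect_sd > 0)
      rnorm(length(sites) * length(spn), 0, scen$site_effect_sd)
      else 0, length(sites), length(spn), dimnames = list(sites, spn))
    counts <- matrix(0L, nrow(rows), length(spn),
                     dimnames = list(rows$sample_id, spn))
    for (s in spn) {
      p <- scen$species_params[[s]]
      eta <- eta_for_species(rows, p$coef) + eff[rows$site_code, s]
      lmu <- eta + log(rows$days)
      if (any(lmu > 20))
        mc_stop("mc_validation_error",
                "simulate_counts: exp(eta) overflow at sample %s",
                rows$sample_id[which(lmu > 20)[1]])
      mu <- rows$days * exp(eta)
      counts[, s] <- as.integer(rnbinom(nrow(rows), size = p$theta, mu = mu))
    }
    design$counts <- counts
    design$species <- spn
    design
  })
}

#' Simulate a complete Malaise-trap campaign
#'
#' Runs weather, landscape, schedule and count generation in sequence
#' and returns a full `mt_dataset` ready for [filter_samples()] and
#' [assemble_design()].  Counts are simulated for every sample
#' (including the ones flagged unusable).
#'
#' @param scen An `mt_scenario`.
#' @param seed Seed; defaults to the scenario seed.
#' @return A validated `mt_dataset`.
#' @export
simulate_dataset <- function(scen, seed = scen$seed) {
  weather <- generate_weather(scen, seed)
  land <- generate_landscape(scen, seed)
  samples <- generate_campaign(scen, land$sites, seed)
  si <- match(samples$trap_id, land$sites$trap_id)
  rows <- data.frame(
    sample_id = samples$sample_id,
    trap_id = samples$trap_id,
    site_code = land$sites$site_code[si],
    days = effort_days(samples),
    date = date_covariate(samples$start, samples$end, scen$reference),
    rain = rain_covariate_vec(samples$start, samples$end, weather),
    deadwood = unname(land$trap_scores[samples$trap_id]),
    forest_type = factor(land$sites$forest_type[si], levels = forest_types()),
    stringsAsFactors = FALSE)
  des <- structure(list(rows = rows, counts = NULL,
                        species = names(scen$species_params),
                        reference = scen$reference), class = "mt_design")
  des <- simulate_counts(des, scen, seed)
  samples <- cbind(samples, as.data.frame(des$counts, check.names = FALSE))
  rownames(samples) <- NULL
  new_dataset(land$sites, land$trees, weather, samples)
}
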