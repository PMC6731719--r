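#' Fitting control parameters
#'
#' @param cap Box constraint on every coefficient (linear-predictor
#'   scale).  A level with no catches at all (complete separation, the
#'   field data's farmland) is pinned at `-cap` and flagged instead of
#'   diverging.
#' @param tol Relative log-likelihood convergence tolerance of the
#'   outer coefficient/dispersion alternation.
#' @param max_outer Maximum outer iterations.
#' @param resample_max_outer Iteration budget for warm-started refits
#'   inside the resampling tests.  Rarely-caught species resampled
#'   under the null can be quasi-separated, with maximum likelihood at
#'   a box corner approached arbitrarily slowly; those refits are
#'   stopped at this budget, counted into the null distribution at the
#'   capped solution, and tallied (the same budget applies to every
#'   resample, so the statistic is the same functional throughout).
#' @param low_n Species with fewer than this many individuals are
#'   fitted and pooled into multi-species statistics, but marked
#'   `low_n` in fits and reports.
#' @return A list of class `nb_control`.
#' @export
nb_control <- function(cap = 15, tol = 1e-8, max_outer = 200,
                       resample_max_outer = 25, low_n = 10) {
  stopifnot(cap > 0, tol > 0, max_outer >= 1, resample_max_outer >= 1)
  structure(list(cap = cap, tol = tol, max_outer = max_outer,
                 resample_max_outer = resample_max_outer, low_n = low_n),
            class = "nb_control")
}

#' Negative-binomial (NB2) log-likelihood
#'
#' Sum of log NB2 probabilities of the counts given means `mu` and
#' dispersion `theta` (variance `mu + mu^2/theta`; large `theta`
#' approaches the Poisson).
#'
#' @param counts Non-negative integer vector.
#' @param mu Positive mean vector (recycled).
#' @param theta Positive dispersion.
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(counts, mu, theta) {
  if (any(counts < 0) || any(counts != round(counts)))
    mc_stop("mc_validation_error", "nb_loglik: counts must be non-negative integers")
  stopifnot(all(mu > 0), theta > 0)
  sum(dnbinom(counts, size = theta, mu = mu, log = TRUE))
}

# shared low-level fit on an explicit design matrix; warm-startable
nb_fit <- function(X, y, offset, control = nb_control(),
                   beta_init = NULL, theta_init = NULL) {
  warm <- !is.null(beta_init) && !is.null(theta_init)
  if (is.null(beta_init)) {
    pf <- suppressWarnings(glm.fit(X, y, family = poisson(), offset = offset))
    beta_init <- pf$coefficients
    beta_init[!is.finite(beta_init)] <- 0
    beta_init <- pmin(pmax(beta_init, -control$cap), control$cap)
  }
  if (is.null(theta_init)) {
    mu0 <- mean(y)
    v0 <- var(y)
    theta_init <- if (is.finite(v0) && v0 > mu0 && mu0 > 0)
      max(0.1, min(100, mu0^2 / (v0 - mu0))) else 1
  }
  beta_init <- as.numeric(beta_init)
  beta_init[!is.finite(beta_init)] <- 0
  if (!is.finite(theta_init) || theta_init <= 0) theta_init <- 1
  res <- .nb_fit_core(X, as.numeric(y), offset, beta_init,
                      theta_init, control$cap, control$tol,
                      control$max_outer, warm)
  res$beta <- setNames(drop(res$beta), colnames(X))
  names(res$separated) <- colnames(X)
  res
}

# standard errors from the Fisher information of the coefficients at
# the fitted (beta, theta); separated coefficients get NA
nb_se <- function(X, offset, beta, theta, separated) {
  mu <- exp(pmin(offset + drop(X %*% beta), 700))
  w <- mu / (1 + mu / theta)
  info <- crossprod(X * sqrt(w))
  se <- rep(NA_real_, ncol(X))
  ok <- !separated
  cv <- try(solve(info[ok, ok, drop = FALSE]), silent = TRUE)
  if (!inherits(cv, "try-error")) se[ok] <- sqrt(pmax(diag(cv), 0))
  names(se) <- colnames(X)
  se
}

#' Fit one species' catch model
#'
#' Maximum-likelihood fit of the NB2 catch model: expected catch is
#' `days * exp(a1 + a2*date + a3*rain + a4*deadwood + a_foresttype)`
#' with `log(days)` entering as an offset.  Coefficients and dispersion
#' are maximised by alternating iteratively reweighted least squares for
#' the coefficients with a profile Newton update of `theta`, starting
#' from a Poisson fit.  Coefficients are constrained to `[-cap, cap]`;
#' a coefficient pinned at the cap with the score still pushing outward
#' is flagged as separated.
#'
#' @param design An `mt_design`.
#' @param species Species name (a column of the design's counts).
#' @param control An [nb_control()].
#' @param drop_terms Character vector of model terms to omit (for null
#'   models): any of `date`, `rain`, `deadwood`, `forest_type`.
#' @return An object of class `species_fit` with elements `species`,
#'   `coefficients` (named over the retained columns), `theta`,
#'   `loglik`, `converged`, `separated` (named logical), `se`, `n_obs`,
#'   `n_individuals` and `low_n`.
#' @export
fit_species <- function(design, species, control = nb_control(),
                        drop_terms = character()) {
  stopifnot(inherits(design, "mt_design"))
  if (!species %in% design$species)
    mc_stop("mc_validation_error", "unknown species '%s'", species)
  X <- design_matrix(design)
  X <- X[, term_columns(drop_terms, invert = TRUE), drop = FALSE]
  y <- design$counts[, species]
  off <- log(design$rows$days)
  res <- nb_fit(X, y, off, control)
  if (!res$converged)
    warning(sprintf("fit_species: %s did not converge in %d iterations",
                    species, control$max_outer))
  structure(list(species = species,
                 fitted = exp(pmin(off + drop(X %*% res$beta), 700)),
                 coefficients = res$beta,
                 theta = res$theta,
                 loglik = res$loglik,
                 converged = res$converged,
                 separated = res$separated,
                 se = nb_se(X, off, res$beta, res$theta, res$separated),
                 n_obs = length(y),
                 n_individuals = sum(y),
                 low_n = sum(y) < control$low_n,
                 cap = control$cap),
            class = "species_fit")
}

# columns of the model matrix belonging to each model term
term_columns <- function(terms, invert = FALSE) {
  map <- list(date = "date", rain = "rain", deadwood = "deadwood",
              forest_type = c("swamp", "disturbed", "clearcut", "farm"))
  bad <- setdiff(terms, names(map))
  if (length(bad))
    mc_stop("mc_validation_error", "unknown model term(s): %s",
            paste(bad, collapse = ", "))
  cols <- unlist(map[terms], use.names = FALSE)
  if (invert) setdiff(design_colnames(), cols) else cols
}

#' Fit every species in a design
#'
#' @inheritParams fit_species
#' @return Named list of [fit_species()] results, one per species.
#' @export
fit_all_species <- function(design, control = nb_control(),
                            drop_terms = character()) {
  fits <- lapply(design$species, fit_species, design = design,
                 control = control, drop_terms = drop_terms)
  names(fits) <- design$species
  fits
}

#' Likelihood-ratio statistic between nested fits
#'
#' `2 * (loglik_alt - loglik_null)`, clipped to zero (with a log line)
#' when a numerically negative value within tolerance arises.
#'
#' @param fit_alt,fit_null Fits of the alternative (full) and nested
#'   null model on the same observations.
#' @return Non-negative scalar.
#' @export
lr_statistic <- function(fit_alt, fit_null) {
  if (fit_alt$n_obs != fit_null$n_obs)
    mc_stop("mc_validation_error", "lr_statistic: fits on different row sets")
  lr <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (lr < 0) {
    if (lr < -1e-4)
      warning(sprintf("lr_statistic: negative LR %.3g clipped to 0", lr))
    else
      mc_log("lr_statistic: clipping %.3g to 0", lr)
    lr <- 0
  }
  lr
}

#' Predict the expected catch of a fitted species
#'
#' `days * exp(a1 + a2*date + a3*rain + a4*deadwood + a_foresttype)`;
#' linear in effort and log-linear in each covariate.  Arguments are
#' recycled to a common length.
#'
#' @param fit A `species_fit` (or any list with a full named
#'   `coefficients` vector).
#' @param date,rain,deadwood Covariate values.
#' @param forest_type Forest type label(s); see [forest_types()].
#' @param days Sampling effort in trap days.
#' @return Expected catch (individuals).
#' @export
predict_catch <- function(fit, date, rain, deadwood, forest_type, days) {
  b <- fit$coefficients
  if (!all(forest_type %in% forest_types()))
    mc_stop("mc_validation_error", "unknown forest type: %s",
            paste(setdiff(forest_type, forest_types()), collapse = ", "))
  ft_eff <- c(primary = 0, b[c("swamp", "disturbed", "clearcut", "farm")])
  names(ft_eff) <- forest_types()
  eta <- b[["intercept"]] + b[["date"]] * date + b[["rain"]] * rain +
    b[["deadwood"]] * deadwood + unname(ft_eff[forest_type])
  days * exp(eta)
}

#' @export
print.species_fit <- function(x, ...) {
  cat(sprintf("NB2 catch model for %s (n = %d individuals%s)\n", x$species,
              x$n_individuals, if (x$low_n) ", low-n" else ""))
  cat(sprintf("  theta = %.3g, loglik = %.3f, converged = %s\n",
              x$theta, x$loglik, x$converged))
  print(round(x$coefficients, 4))
  if (any(x$separated))
    cat("  separated:", paste(names(x$separated)[x$separated], collapse = ", "), "\n")
  invisible(x)
}

#' Write fitted species models to CSV (with a JSON mirror)
#'
#' @param fits Named list of `species_fit` objects.
#' @param path CSV path; a `.json` mirror is written alongside.
#' @return The CSV path, invisibly.
#' @export
write_fits <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    co <- as.list(f$coefficients)
    names(co) <- paste0("coef_", names(co))
    c(list(species = f$species), co,
      list(theta = f$theta, loglik = f$loglik, converged = f$converged,
           low_n = f$low_n,
           separated = paste(names(f$separated)[f$separated], collapse = ";")))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  slim <- lapply(fits, function(f) {
    f$fitted <- NULL
    f$coefficients <- as.list(f$coefficients)   # keep names in JSON
    f$separated <- as.list(f$separated)
    f$se <- as.list(f$se)
    unclass(f)
  })
  jsonlite::write_json(slim,
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
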