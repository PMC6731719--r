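# Significance machinery: species-wise likelihood ratios for one model
# term (or one forest-type pair), their sum over species, and p-values
# against a null distribution built by resampling trap sites.

block_factor <- function(design, blocks = c("site", "trap")) {
  blocks <- match.arg(blocks)
  f <- factor(if (blocks == "site") design$rows$site_code else design$rows$trap_id)
  if (nlevels(f) < 2)
    mc_stop("mc_validation_error", "resampling needs at least 2 blocks")
  f
}

# randomized probability-integral-transform residuals of a count matrix
# under fitted NB2 nulls: u ~ U(F(y-1), F(y)], uniform when the model
# holds.  Consumes runif(n * n_species).
pit_residuals <- function(counts, mu0, theta) {
  n <- nrow(counts); S <- ncol(counts)
  u <- matrix(0, n, S)
  for (s in seq_len(S)) {
    lo <- pnbinom(counts[, s] - 1, size = theta[s], mu = mu0[, s])
    hi <- pnbinom(counts[, s], size = theta[s], mu = mu0[, s])
    v <- runif(n)
    u[, s] <- lo + v * (hi - lo)
  }
  # clamp well inside (0,1): the inverse cdf must stay finite, and a
  # residual beyond the 1e-6 tail carries no information a B <= 999
  # resampling test can resolve, while its inversion through a row with
  # a heavier-tailed null fit can otherwise produce astronomical counts
  pmin(pmax(u, 1e-6), 1 - 1e-6)
}

# rebuild a count matrix from a block assignment: target block t takes
# the PIT residuals of donor block assignment[t] (rows recycled
# cyclically when sizes differ) and inverts them through the target
# rows' null fitted distributions
invert_assignment <- function(u, block_rows, assignment, mu0, theta) {
  n <- nrow(u); S <- ncol(u)
  donor_row <- integer(n)
  for (t in seq_along(block_rows)) {
    tgt <- block_rows[[t]]
    don <- block_rows[[assignment[t]]]
    donor_row[tgt] <- don[((seq_along(tgt) - 1L) %% length(don)) + 1L]
  }
  ystar <- matrix(0L, n, S, dimnames = dimnames(mu0))
  for (s in seq_len(S))
    ystar[, s] <- as.integer(pmin(qnbinom(u[donor_row, s], size = theta[s],
                                          mu = mu0[, s]),
                                  .Machine$integer.max - 1))
  ystar
}

# shared generator behind resample_null / term_test / pairwise tests.
# Must be called inside an established RNG state (set.seed done by the
# caller): draws the PIT matrix first, then one block assignment per
# resample, so the exact-enumeration oracle can reuse the same PIT
# matrix by seeding identically.
resample_engine <- function(counts, mu0, theta, bf, B,
                            scheme = c("residual", "parametric")) {
  scheme <- match.arg(scheme)
  # a quasi-separated null fit can extrapolate absurd means for a few
  # rows; no Malaise-trap sample holds 1e5 individuals, and uncapped
  # means would invert to counts beyond integer range
  mu0 <- pmin(mu0, 1e5)
  if (scheme == "parametric") {
    n <- nrow(counts); S <- ncol(counts)
    return(lapply(seq_len(B), function(b) {
      y <- matrix(0L, n, S, dimnames = dimnames(mu0))
      for (s in seq_len(S))
        y[, s] <- as.integer(rnbinom(n, size = theta[s], mu = mu0[, s]))
      y
    }))
  }
  block_rows <- split(seq_along(bf), bf)
  k <- length(block_rows)
  u <- pit_residuals(counts, mu0, theta)
  lapply(seq_len(B), function(b) {
    invert_assignment(u, block_rows, sample.int(k, k, replace = TRUE),
                      mu0, theta)
  })
}

#' Resample count matrices under fitted null models
#'
#' Builds `B` resampled count matrices preserving within-site
#' dependence.  The default `residual` scheme computes randomized
#' probability-integral-transform residuals under the supplied null
#' fits, resamples them as whole trap-site blocks with replacement, and
#' inverts them through each sample's null fitted distribution.  The
#' `parametric` alternative simulates counts independently from the
#' null fits.  Identical `seed`, scheme and inputs give identical
#' output.
#'
#' @param design An `mt_design`.
#' @param null_fits Named list of `species_fit` objects fitted under
#'   the null model, one per design species.
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param scheme `"residual"` (default) or `"parametric"`.
#' @param blocks Resampling block level: `"site"` (default, the trap
#'   site code) or `"trap"`.
#' @return List of `B` integer count matrices (samples x species).
#' @export
resample_null <- function(design, null_fits, B, seed = 1,
                          scheme = c("residual", "parametric"),
                          blocks = c("site", "trap")) {
  stopifnot(B >= 1)
  scheme <- match.arg(scheme)
  bf <- block_factor(design, match.arg(blocks))
  mu0 <- vapply(design$species, function(s) null_fits[[s]]$fitted,
                numeric(nrow(design$rows)))
  theta <- vapply(design$species, function(s) null_fits[[s]]$theta, numeric(1))
  with_seed(seed, resample_engine(design$counts, mu0, theta, bf, B, scheme))
}

# fit all species on an explicit (X, counts) pair, optionally warm
fit_matrix <- function(X, counts, off, control, warm = NULL) {
  S <- ncol(counts)
  fits <- vector("list", S)
  for (s in seq_len(S)) {
    fits[[s]] <- nb_fit(X, counts[, s], off, control,
                        beta_init = if (!is.null(warm)) warm[[s]]$beta,
                        theta_init = if (!is.null(warm)) warm[[s]]$theta)
  }
  names(fits) <- colnames(counts)
  fits
}

lr_vec <- function(full, null) {
  lr <- vapply(seq_along(full), function(s)
    2 * (full[[s]]$loglik - null[[s]]$loglik), numeric(1))
  pmax(lr, 0)
}

# common core of term_test / pairwise_forest_test: observed LRs plus a
# site-resampled null of the same statistics
lr_resampling_test <- function(design, X_full, X_null, term_label, B, seed,
                               scheme, blocks, control) {
  off <- log(design$rows$days)
  counts <- design$counts
  bf <- block_factor(design, blocks)
  full_obs <- fit_matrix(X_full, counts, off, control)
  null_obs <- fit_matrix(X_null, counts, off, control)
  obs_lr <- lr_vec(full_obs, null_obs)
  names(obs_lr) <- design$species
  obs_sum <- sum(obs_lr)

  mu0 <- vapply(seq_along(null_obs), function(s)
    exp(pmin(off + drop(X_null %*% null_obs[[s]]$beta), 700)),
    numeric(nrow(counts)))
  colnames(mu0) <- design$species
  theta0 <- vapply(null_obs, function(f) f$theta, numeric(1))

  rctrl <- control
  rctrl$max_outer <- control$resample_max_outer
  exceed <- numeric(length(obs_lr)); exceed_sum <- 0; n_bad <- 0L
  with_seed(seed, {
    mats <- resample_engine(counts, mu0, theta0, bf, B, scheme)
    for (b in seq_len(B)) {
      yb <- mats[[b]]
      fb <- fit_matrix(X_full, yb, off, rctrl, warm = full_obs)
      nb <- fit_matrix(X_null, yb, off, rctrl, warm = null_obs)
      n_bad <- n_bad + sum(!vapply(c(fb, nb), `[[`, logical(1), "converged"))
      lrb <- lr_vec(fb, nb)
      exceed <- exceed + (lrb >= obs_lr - 1e-12)
      exceed_sum <- exceed_sum + (sum(lrb) >= obs_sum - 1e-12)
    }
  })
  if (n_bad > 0)
    mc_log("%s: %d of %d resample fits stopped at the iteration cap",
           term_label, n_bad, 2L * B * length(obs_lr))
  structure(list(term = term_label,
                 per_species_lr = obs_lr,
                 sum_lr = obs_sum,
                 per_species_p = (1 + exceed) / (B + 1),
                 overall_p = (1 + exceed_sum) / (B + 1),
                 n_resamples = B, seed = seed, scheme = scheme,
                 blocks = blocks, n_nonconverged = n_bad,
                 full_fits = full_obs, null_fits = null_obs),
            class = "term_test")
}

#' Test one ecological variable by summed likelihood ratios
#'
#' Fits the full catch model and the model with `term` removed for
#' every species, computes the species-wise likelihood ratios and their
#' sum over species (the assemblage-level statistic), and compares each
#' to a null distribution obtained by resampling trap sites `B` times.
#' p-values use the add-one rule `(1 + exceedances) / (B + 1)` and are
#' never zero.  No multiple-testing adjustment is applied.
#'
#' @param design An `mt_design`.
#' @param term One of `date`, `rain`, `deadwood`, `forest_type` (the
#'   latter drops all four dummies jointly).
#' @param B Number of resamples (default 999).
#' @param seed Integer seed.
#' @param scheme,blocks Passed to the resampler; see [resample_null()].
#' @param control An [nb_control()].
#' @return A `term_test` object: per-species and summed LRs with their
#'   resampling p-values.
#' @export
term_test <- function(design, term, B = 999, seed = 1,
                      scheme = c("residual", "parametric"),
                      blocks = c("site", "trap"), control = nb_control()) {
  scheme <- match.arg(scheme); blocks <- match.arg(blocks)
  X_full <- design_matrix(design)
  X_null <- X_full[, term_columns(term, invert = TRUE), drop = FALSE]
  lr_resampling_test(design, X_full, X_null, term, B, seed, scheme, blocks,
                     control)
}

# model matrix with forest levels a and b merged into one level;
# primary (or the merged level containing it) is the reference
merged_forest_matrix <- function(design, type_a, type_b) {
  r <- design$rows
  ft <- as.character(r$forest_type)
  merged_label <- paste(sort(c(type_a, type_b)), collapse = "|")
  ft[ft %in% c(type_a, type_b)] <- merged_label
  lev <- unique(c(if ("primary" %in% c(type_a, type_b)) merged_label else "primary",
                  setdiff(forest_types(), c(type_a, type_b)), merged_label))
  f <- factor(ft, levels = lev)
  dummies <- vapply(lev[-1], function(l) as.numeric(f == l),
                    numeric(nrow(r)))
  cbind(intercept = 1, date = r$date, rain = r$rain, deadwood = r$deadwood,
        dummies)
}

#' Pairwise contrast of two forest types
#'
#' Null model: the full catch model with forest types `type_a` and
#' `type_b` merged into a single level; alternative: the full model.
#' Likelihood ratios and site-resampling p-values as in [term_test()].
#'
#' @param design An `mt_design`.
#' @param type_a,type_b Two distinct forest types present in the design.
#' @inheritParams term_test
#' @return A `term_test` object with term `pair:A|B`.
#' @export
pairwise_forest_test <- function(design, type_a, type_b, B = 999, seed = 1,
                                 scheme = c("residual", "parametric"),
                                 blocks = c("site", "trap"),
                                 control = nb_control()) {
  scheme <- match.arg(scheme); blocks <- match.arg(blocks)
  if (identical(type_a, type_b))
    mc_stop("mc_validation_error", "pairwise test needs two distinct types")
  for (ty in c(type_a, type_b)) {
    if (!ty %in% forest_types())
      mc_stop("mc_validation_error", "unknown forest type '%s'", ty)
    if (!any(design$rows$forest_type == ty))
      mc_stop("mc_validation_error", "forest type '%s' has no samples", ty)
  }
  X_full <- design_matrix(design)
  X_null <- merged_forest_matrix(design, type_a, type_b)
  lr_resampling_test(design, X_full, X_null,
                     paste0("pair:", type_a, "|", type_b),
                     B, seed, scheme, blocks, control)
}

#' Relative catches by forest type
#'
#' Catch of each species in each forest type relative to primary forest
#' (standardised to 1), holding date, rainfall and dead wood fixed:
#' `exp(a_type - a_primary)`.  A separated level -- one whose
#' coefficient is pinned at the cap, e.g. farmland with no catches at
#' all -- is not estimable; it is reported with the sentinel value 0
#' and flagged in the `separated` attribute, which carries the actual
#' meaning.
#'
#' @param fits Named list of full-model `species_fit` objects.
#' @return Data frame, species x forest types, with attribute
#'   `separated` (logical matrix of the same shape).
#' @export
relative_catch <- function(fits) {
  sp <- names(fits)
  tab <- matrix(1, length(sp), 5, dimnames = list(sp, forest_types()))
  sepm <- matrix(FALSE, length(sp), 5, dimnames = list(sp, forest_types()))
  for (s in sp) {
    b <- fits[[s]]$coefficients
    cap <- if (is.null(fits[[s]]$cap)) 15 else fits[[s]]$cap
    for (ty in forest_types()[-1]) {
      pinned <- isTRUE(fits[[s]]$separated[[ty]]) ||
        abs(b[[ty]]) >= cap - 1e-6
      if (pinned) {
        tab[s, ty] <- 0
        sepm[s, ty] <- TRUE
      } else tab[s, ty] <- exp(b[[ty]])
    }
  }
  out <- as.data.frame(tab)
  attr(out, "separated") <- sepm
  class(out) <- c("relative_catch", "data.frame")
  out
}

#' Exact enumeration of the site-resampling null (verification oracle)
#'
#' For tiny designs (at most 4 blocks) exhaustively enumerates every
#' block assignment of the residual resampling scheme (`k^k`
#' assignments for `k` blocks), computes the summed-LR statistic for
#' each, and returns the exact tail probability of the observed
#' statistic.  Seeding identically to [term_test()] reuses the same
#' PIT-residual matrix, so the Monte-Carlo p-value converges to this
#' exact value.
#'
#' @param design An `mt_design` with at most 4 blocks.
#' @param term Model term, as in [term_test()].
#' @param seed Integer seed (for the PIT residual draw).
#' @param blocks Block level, as in [resample_null()].
#' @param control An [nb_control()].
#' @return List with `p_exact`, `observed`, the enumerated `stats` and
#'   `n_assignments`.
#' @export
enumerate_null_exact <- function(design, term, seed = 1,
                                 blocks = c("site", "trap"),
                                 control = nb_control()) {
  bf <- block_factor(design, match.arg(blocks))
  k <- nlevels(bf)
  if (k > 4)
    mc_stop("mc_validation_error",
            "exact enumeration refused for %d blocks (max 4)", k)
  X_full <- design_matrix(design)
  X_null <- X_full[, term_columns(term, invert = TRUE), drop = FALSE]
  off <- log(design$rows$days)
  counts <- design$counts
  full_obs <- fit_matrix(X_full, counts, off, control)
  null_obs <- fit_matrix(X_null, counts, off, control)
  obs_sum <- sum(lr_vec(full_obs, null_obs))
  mu0 <- vapply(seq_along(null_obs), function(s)
    exp(pmin(off + drop(X_null %*% null_obs[[s]]$beta), 700)),
    numeric(nrow(counts)))
  mu0 <- pmin(mu0, 1e5)
  theta0 <- vapply(null_obs, function(f) f$theta, numeric(1))
  block_rows <- split(seq_along(bf), bf)
  u <- with_seed(seed, pit_residuals(counts, mu0, theta0))
  rctrl <- control
  rctrl$max_outer <- control$resample_max_outer
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), k)))
  stats <- apply(grid, 1, function(a) {
    yb <- invert_assignment(u, block_rows, a, mu0, theta0)
    fb <- fit_matrix(X_full, yb, off, rctrl, warm = full_obs)
    nb <- fit_matrix(X_null, yb, off, rctrl, warm = null_obs)
    sum(lr_vec(fb, nb))
  })
  list(p_exact = mean(stats >= obs_sum - 1e-12), observed = obs_sum,
       stats = stats, n_assignments = nrow(grid))
}

#' @export
print.term_test <- function(x, ...) {
  cat(sprintf("LR resampling test: %s (B = %d, scheme = %s, blocks = %s)\n",
              x$term, x$n_resamples, x$scheme, x$blocks))
  df <- data.frame(species = names(x$per_species_lr),
                   LR = round(x$per_species_lr, 3),
                   p = signif(x$per_species_p, 3))
  print(df, row.names = FALSE)
  cat(sprintf("  summed LR = %.3f, overall p = %.4g\n", x$sum_lr, x$overall_p))
  cat("  (p-values are not adjusted for multiple testing)\n")
  invisible(x)
}

#' Write test results to CSV
#'
#' One row per species per term plus an `overall` row for the summed
#' statistic.
#'
#' @param tests List of `term_test` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tests <- function(tests, path) {
  rows <- do.call(rbind, lapply(tests, function(tt) {
    rbind(data.frame(term = tt$term, species = names(tt$per_species_lr),
                     lr = unname(tt$per_species_lr),
                     p = unname(tt$per_species_p),
                     n_resamples = tt$n_resamples, seed = tt$seed,
                     scheme = tt$scheme, stringsAsFactors = FALSE),
          data.frame(term = tt$term, species = "overall", lr = tt$sum_lr,
                     p = tt$overall_p, n_resamples = tt$n_resamples,
                     seed = tt$seed, scheme = tt$scheme,
                     stringsAsFactors = FALSE))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
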