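test_that("nb_loglik matches closed forms and direct pmf summation", {
  # P(Y=0 | mu=1, theta=1) = theta/(theta+mu) = 1/2
  expect_equal(nb_loglik(0L, 1, 1), log(0.5), tolerance = 1e-12)

  # direct lgamma-arithmetic oracle on random fixtures
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    y <- rpois(n, 3)
    mu <- runif(n, 0.05, 20)
    th <- runif(1, 0.05, 50)
    expect_equal(nb_loglik(y, mu, th), sum(nb_logpmf_direct(y, mu, th)),
                 tolerance = 1e-8)
  }

  # Poisson limit at huge theta
  y <- c(0L, 1L, 3L, 7L); mu <- c(0.5, 1, 2.5, 6)
  expect_equal(nb_loglik(y, mu, 1e8), sum(dpois(y, mu, log = TRUE)),
               tolerance = 1e-4)

  # additivity over concatenation
  expect_equal(nb_loglik(c(y, y), c(mu, mu), 2),
               2 * nb_loglik(y, mu, 2), tolerance = 1e-12)

  expect_error(nb_loglik(c(0.5, 1), c(1, 1), 1), class = "mc_validation_error")
})

test_that("the intercept-only fit recovers the closed-form mean", {
  # all days 1, all counts k: NB mean MLE is the sample mean
  X <- matrix(1, 30, 1, dimnames = list(NULL, "intercept"))
  y <- rep(5, 30)
  f <- malaisecatch:::nb_fit(X, y, offset = rep(0, 30))
  expect_equal(unname(f$beta), log(5), tolerance = 1e-6)
})

test_that("fit_species recovers simulating parameters and matches a direct-search oracle", {
  set.seed(11)
  n <- 2000
  X <- cbind(intercept = 1, x = rnorm(n))
  beta_true <- c(0.5, 0.8); theta_true <- 1.5
  off <- log(runif(n, 5, 20))
  y <- rnbinom(n, size = theta_true, mu = exp(off + X %*% beta_true))
  f <- malaisecatch:::nb_fit(X, y, off)
  expect_true(f$converged)
  expect_equal(unname(f$beta), beta_true, tolerance = 0.1)
  expect_equal(f$theta, theta_true, tolerance = 0.25)

  # MLE dominance over the truth
  expect_gte(f$loglik + 1e-9,
             nb_loglik(y, exp(off + X %*% beta_true), theta_true))

  # independent derivative-free search lands on the same likelihood
  o <- optim(c(0, 0, 0), function(p)
    -nb_loglik(y, exp(pmin(off + X %*% p[1:2], 700)), exp(p[3])),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(f$loglik, -o$value, tolerance = 1e-3)
})

test_that("fit_species agrees with glm.nb on a clean design", {
  skip_if_not_installed("MASS")
  d <- simulate_dataset(make_default_scenario(8))
  des <- quiet(assemble_design(filter_samples(d)))
  # drop farm rows so no separated level clouds the comparison
  keep <- des$rows$forest_type != "farm"
  des$rows <- des$rows[keep, , drop = FALSE]
  des$counts <- des$counts[keep, , drop = FALSE]
  sp <- "Epirhyssa uelensis"
  f <- fit_species(des, sp)
  r <- des$rows
  r$y <- des$counts[, sp]
  m <- quiet(MASS::glm.nb(
    y ~ date + rain + deadwood + forest_type + offset(log(days)), data = r))
  ours <- f$coefficients[c("intercept", "date", "rain", "deadwood")]
  theirs <- coef(m)[c("(Intercept)", "date", "rain", "deadwood")]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-3)
  expect_equal(f$theta, m$theta, tolerance = 1e-2)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-4)
})

test_that("a forest level with no catches is flagged as separated at -cap", {
  d <- simulate_dataset(small_scenario(9))
  des <- quiet(assemble_design(filter_samples(d)))
  # farmland catches are structurally ~0 under the generating model
  sp <- "Epirhyssa uelensis"
  expect_equal(sum(des$counts[des$rows$forest_type == "farm", sp]), 0)
  f <- fit_species(des, sp)
  expect_true(f$separated[["farm"]])
  expect_equal(unname(f$coefficients[["farm"]]), -15)
  expect_true(is.na(f$se[["farm"]]))

  # all-zero counts pin the intercept instead
  des0 <- des
  des0$counts[, sp] <- 0L
  f0 <- fit_species(des0, sp)
  expect_true(f0$separated[["intercept"]])
  expect_equal(unname(f0$coefficients[["intercept"]]), -15)
})

test_that("likelihood ratios are nonnegative, zero on self, and grow with information", {
  d <- simulate_dataset(small_scenario(10))
  des <- quiet(assemble_design(filter_samples(d)))
  f <- fit_species(des, "Epirhyssa ghesquierei")
  expect_equal(lr_statistic(f, f), 0)

  # nesting: adding a column never decreases the likelihood
  for (seed in c(3, 14)) {
    des2 <- quiet(assemble_design(filter_samples(simulate_dataset(small_scenario(seed)))))
    for (tm in c("date", "rain", "deadwood")) {
      alt <- fit_species(des2, "Epirhyssa uelensis")
      null <- fit_species(des2, "Epirhyssa uelensis", drop_terms = tm)
      expect_gte(lr_statistic(alt, null), 0)
    }
  }

  # a strong simulated date effect: LR grows with n
  set.seed(21)
  lr_at_n <- sapply(c(100, 400, 1600), function(n) {
    x <- seq(0, 1, length.out = n)
    X <- cbind(intercept = 1, date = x)
    off <- rep(log(10), n)
    y <- rnbinom(n, size = 2, mu = exp(off - 1 + 1.2 * x))
    fa <- malaisecatch:::nb_fit(X, y, off)
    f0 <- malaisecatch:::nb_fit(X[, 1, drop = FALSE], y, off)
    2 * (fa$loglik - f0$loglik)
  })
  expect_true(all(diff(lr_at_n) > 0))
})

test_that("prediction is the exponential linear predictor times effort", {
  scen <- make_default_scenario()
  ov <- scen$species_params[["Epirhyssa overlaeti"]]
  fit <- list(coefficients = c(intercept = ov$coef[["intercept"]],
                               date = ov$coef[["date"]], rain = ov$coef[["rain"]],
                               deadwood = ov$coef[["deadwood"]],
                               swamp = ov$coef[["swamp"]],
                               disturbed = ov$coef[["disturbed"]],
                               clearcut = ov$coef[["clearcut"]],
                               farm = ov$coef[["farm"]]))
  # dead-wood effect at the highest-catch trap's score
  ratio <- predict_catch(fit, 100, 3, 0.27, "primary", 14) /
    predict_catch(fit, 100, 3, 0, "primary", 14)
  expect_equal(ratio, exp(4.42 * 0.27), tolerance = 1e-12)

  # zero effort predicts zero catch; doubling effort doubles it
  expect_equal(predict_catch(fit, 10, 1, 0.1, "swamp", 0), 0)
  expect_equal(predict_catch(fit, 10, 1, 0.1, "swamp", 28),
               2 * predict_catch(fit, 10, 1, 0.1, "swamp", 14))

  # baseline daily catch in primary forest from the intercept alone
  ue <- scen$species_params[["Epirhyssa uelensis"]]
  fit_ue <- list(coefficients = setNames(ue$coef[-5], names(fit$coefficients)))
  expect_equal(predict_catch(fit_ue, 0, 0, 0, "primary", 1), exp(-4.17),
               tolerance = 1e-12)

  expect_error(predict_catch(fit, 0, 0, 0, "meadow", 1),
               class = "mc_validation_error")
})

test_that("grid-plus-polish search confirms small-fixture likelihood optima", {
  set.seed(33)
  for (rep in 1:3) {
    n <- sample(15:30, 1)
    x <- runif(n)
    X <- cbind(intercept = 1, x = x)
    off <- rep(0, n)
    y <- rnbinom(n, size = 1, mu = exp(0.3 + 0.8 * x))
    f <- malaisecatch:::nb_fit(X, y, off)
    # coarse grid then Nelder-Mead polish, independent of the IRLS path
    grid <- expand.grid(b0 = seq(-2, 2, 0.5), b1 = seq(-2, 3, 0.5),
                        lt = seq(-2, 4, 1))
    gll <- apply(grid, 1, function(p)
      nb_loglik(y, exp(off + X %*% p[1:2]), exp(p[3])))
    best <- as.numeric(grid[which.max(gll), ])
    o <- optim(best, function(p)
      -nb_loglik(y, exp(pmin(off + X %*% p[1:2], 700)),
                 min(max(exp(p[3]), 1e-2), 1e4)),
      method = "Nelder-Mead", control = list(maxit = 4000, reltol = 1e-12))
    expect_equal(f$loglik, -o$value, tolerance = 1e-3)
  }
})
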