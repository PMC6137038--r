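test_that("interval labels follow the cause-of-death assignment rules", {
  expect_equal(assign_interval("KNP"), data.frame(lo = 0, hi = 0))
  expect_equal(assign_interval("KP"), data.frame(lo = 1, hi = 1))
  expect_equal(assign_interval("KP", conservative = TRUE),
               data.frame(lo = 0, hi = 1))
  expect_equal(assign_interval(c("Ukn", "Ind")),
               data.frame(lo = c(0, 0), hi = c(1, 1)))
  expect_error(assign_interval("boat"), "unknown cause")
})

test_that("number-weight residuals reproduce closed-form least squares", {
  # masses exactly proportional to counts: residuals vanish
  rec <- make_necropsy(c(1, 2, 3, 4), cod = rep("Ind", 4),
                       debris_mass_g = c(0.5, 1, 1.5, 2))
  expect_equal(unname(as.numeric(nw_residuals(rec))), rep(0, 4),
               tolerance = 1e-12)
  # 3-point fixture against the hand-computed OLS line
  rec3 <- make_necropsy(c(1, 2, 3), cod = rep("Ind", 3),
                        debris_mass_g = c(1, 2, 6))
  # slope 2.5, intercept -2 => fitted (0.5, 3, 5.5), residuals (0.5, -1, 0.5)
  expect_equal(unname(as.numeric(nw_residuals(rec3))), c(0.5, -1, 0.5),
               tolerance = 1e-10)
  # ineligible records get zero and a flag
  rec_mix <- make_necropsy(c(0, 1, 2, 3), cod = rep("Ukn", 4),
                           debris_mass_g = c(NA, 1, 2, 6))
  r <- nw_residuals(rec_mix)
  expect_identical(attr(r, "eligible"), c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(as.numeric(r)[1], 0)
  # unidentifiable slope
  expect_error(nw_residuals(make_necropsy(c(1, 0), cod = c("Ind", "Ukn"),
                                          debris_mass_g = c(1, NA))),
               "fewer than 3")
})

test_that("fractional logistic fit matches its closed forms and the GLM oracle", {
  # constant response 0.5 pins the intercept at logit(0.5) = 0
  f <- fit_fractional_logistic(matrix(1, 20, 1), rep(0.5, 20))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  # with binary responses it is the ordinary logistic MLE
  set.seed(14)
  for (i in 1:10) {
    x <- cbind(1, stats::rnorm(60), stats::runif(60))
    eta <- x %*% c(-0.5, 1, 0.8)
    y <- as.numeric(stats::runif(60) < stats::plogis(eta))
    ours <- fit_fractional_logistic(x, y)
    oracle <- stats::glm.fit(x, y, family = stats::binomial(),
                             control = list(epsilon = 1e-14, maxit = 200))
    expect_equal(unname(ours$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-8)
  }
  # rank-deficient design is an error
  expect_error(fit_fractional_logistic(cbind(1, 1:4, 2 * (1:4)),
                                       c(0, 0, 1, 1)),
               "rank deficient")
})

test_that("separated binary data are flagged and still near the likelihood supremum", {
  x <- cbind(1, 0:3)
  y <- c(0, 0, 1, 1)
  fit <- fit_fractional_logistic(x, y)
  expect_true(fit$separation)
  # grid search over a wide coefficient box cannot do meaningfully better
  grid <- expand.grid(b0 = seq(-60, 20, by = 2), b1 = seq(-10, 40, by = 1))
  ll <- mapply(function(b0, b1) {
    sum(stats::dbinom(y, 1, stats::plogis(b0 + b1 * (0:3)), log = TRUE))
  }, grid$b0, grid$b1)
  expect_gte(fit$log_likelihood, max(ll) - 1e-3)
  # the fitted curve separates the two groups
  expect_lt(fit$fitted[2], 0.01)
  expect_gt(fit$fitted[3], 0.99)
})

test_that("the fractional likelihood is linear in y (two-point expansion identity)", {
  set.seed(33)
  for (i in 1:5) {
    n <- 50
    x <- cbind(1, stats::rnorm(n))
    y <- stats::runif(n)
    direct <- fit_fractional_logistic(x, y)
    expanded <- fit_fractional_logistic(rbind(x, x), c(rep(1, n), rep(0, n)),
                                        weights = c(y, 1 - y))
    expect_equal(direct$coefficients, expanded$coefficients,
                 tolerance = 1e-8)
    expect_equal(direct$log_likelihood, expanded$log_likelihood,
                 tolerance = 1e-8)
  }
})

test_that("mc_fit with no interval records equals a single direct fit", {
  set.seed(5)
  rec <- make_necropsy(c(rep(0, 30), stats::rpois(30, 6) + 1),
                       cod = c(rep("KNP", 30), rep("KP", 30)))
  ens <- mc_fit(rec, "M3", n_reps = 25, seed = 2)
  expect_equal(ens$n_interval, 0L)
  # all replicates identical: zero-width envelope
  expect_equal(unname(ens$coefficient_envelope["lo", ]),
               unname(ens$coefficient_envelope["hi", ]), tolerance = 0)
  X <- turtledose:::build_dose_design(rec, dose_model_spec("M3"))$X
  y <- as.numeric(rec$cod == "KP")
  direct <- fit_fractional_logistic(X, y)
  expect_equal(ens$median_coefficients, direct$coefficients,
               tolerance = 1e-8)
})

test_that("a perfectly ordered cohort yields a positive slope in every replicate", {
  set.seed(6)
  rec <- make_necropsy(c(rep(0, 25), 10 + stats::rpois(25, 5),
                         stats::rpois(30, 1)),
                       cod = c(rep("KNP", 25), rep("KP", 25), rep("Ukn", 30)),
                       ccl_cm = stats::runif(80, 20, 80))
  ens <- mc_fit(rec, "M1", n_reps = 200, seed = 3)
  slopes <- ens$coefficients[, "debris_count"]
  expect_true(all(slopes[!is.na(slopes)] > 0))
})

test_that("ensembles are bit-reproducible given (records, spec, n_reps, seed)", {
  p <- generator_params(n_animals = 100, seed = 8)
  rec <- generate_necropsy_cohort(p)
  e1 <- mc_fit(rec, "M3", n_reps = 40, seed = 11)
  e2 <- mc_fit(rec, "M3", n_reps = 40, seed = 11)
  expect_identical(e1$median_coefficients, e2$median_coefficients)
  expect_identical(e1$coefficient_envelope, e2$coefficient_envelope)
  expect_identical(e1$aics, e2$aics)
  e3 <- mc_fit(rec, "M3", n_reps = 40, seed = 12)
  expect_false(identical(e1$median_coefficients, e3$median_coefficients))
})

test_that("the slope envelope narrows as interval-labelled records vanish", {
  # fixed informative records plus k unknown-cause records; in the
  # sparse-interval regime each extra [0,1] record adds draw sensitivity, so
  # the envelope widens with k (with many noise records the per-fit
  # averaging of draws takes over and the width falls again - see the
  # methods vignette)
  set.seed(77)
  fixed_counts <- c(stats::rpois(25, 2), stats::rpois(25, 5) + 1)
  fixed_ccl <- stats::runif(50, 20, 80)
  set.seed(5)
  noise_counts <- stats::rpois(6, 3)
  noise_ccl <- stats::runif(6, 20, 80)
  width_at <- function(k) {
    counts <- c(fixed_counts, noise_counts[seq_len(k)])
    cod <- c(rep("KNP", 25), rep("KP", 25), rep("Ukn", k))
    rec <- make_necropsy(counts, cod,
                         ccl_cm = c(fixed_ccl, noise_ccl[seq_len(k)]))
    ens <- mc_fit(rec, "M1", n_reps = 200, seed = 9)
    unname(diff(ens$coefficient_envelope[, "debris_count"]))
  }
  w <- c(width_at(6), width_at(2), width_at(0))
  expect_true(w[1] > w[2] && w[2] > w[3])
  expect_equal(w[3], 0)
})

test_that("mc model selection shares draws and respects labelling variants", {
  p <- generator_params(n_animals = 150, seed = 15)
  rec <- generate_necropsy_cohort(p)
  tab <- mc_model_selection(rec, list("M1", "M2", "M3"), n_reps = 30,
                            seed = 4)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$conservative == FALSE))
  expect_equal(min(tab$delta_aic), 0)
  # single candidate: one row, delta 0
  tab1 <- mc_model_selection(rec, list("M3"), n_reps = 10, seed = 4)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$delta_aic, 0)
  # all-binary labels: AIC constant across replicates
  rec_bin <- make_necropsy(c(rep(0, 20), stats::rpois(20, 5) + 1),
                           cod = c(rep("KNP", 20), rep("KP", 20)),
                           ccl_cm = stats::runif(40, 20, 80))
  ens_bin <- mc_fit(rec_bin, "M1", n_reps = 15, seed = 2)
  expect_equal(max(ens_bin$aics) - min(ens_bin$aics), 0)
})

test_that("records with debris but no recorded mass are excluded from M2 only", {
  rec <- make_necropsy(c(0, 1, 2, 3, 4, 5), cod = c("Ukn", "KNP", "Ind",
                                                    "KP", "Ukn", "KNP"),
                       ccl_cm = c(31, 38, 40, 47, 52, 49),
                       debris_mass_g = c(NA, 0.1, 0.2, 0.9, 0.3, 1.4))
  rec$debris_mass_g[2] <- NA  # debris present, mass unrecorded
  e2 <- mc_fit(rec, "M2", n_reps = 5, seed = 1)
  e1 <- mc_fit(rec, "M1", n_reps = 5, seed = 1)
  expect_equal(e2$n_excluded, 1L)
  expect_equal(e2$n_obs, 5L)
  expect_equal(e1$n_excluded, 0L)
  expect_equal(e1$n_obs, 6L)
})

test_that("the estimator is consistent for the generating curve when labels resolve", {
  # with causes fully resolved, the fractional fit targets the generating
  # conditional-on-death dose-response. Zero-load plastic deaths are
  # unrecognisable at necropsy (no debris to see), so labels at load 0 are
  # left-censored; consistency holds among debris-positive records, where
  # P(labelled KP | load) equals the generating curve exactly.
  p <- generator_params(n_animals = 40000, external_hazard = 0,
                        label_kp_given_plastic = 1,
                        label_knp_given_external = 1, seed = 6)
  rec <- generate_necropsy_cohort(p)
  rec <- rec[rec$debris_count >= 1 & rec$cod %in% c("KNP", "KP"), ,
             drop = FALSE]
  X <- turtledose:::build_dose_design(rec, dose_model_spec("M3"))$X
  fit <- fit_fractional_logistic(X, as.numeric(rec$cod == "KP"))
  expect_lt(abs(fit$coefficients["load_per_ccl"] - p$true_slope),
            3 * fit$std_errors["load_per_ccl"])
  expect_lt(abs(fit$coefficients["(Intercept)"] - p$true_intercept),
            3 * fit$std_errors["(Intercept)"])
})
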