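test_that("intercept-only NB fit maximises the likelihood (grid oracle)", {
  set.seed(1)
  records <- make_necropsy(c(0, 1, 1, 2, 3, 5, 8, 0),
                           cod = rep("Ukn", 8))
  fit <- fit_nb_glm(records, "0")
  # the NB mean MLE is the sample mean for any dispersion
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(mean(records$debris_count)), tolerance = 1e-6)
  # grid search over (log-mean, dispersion) cannot beat the fitted likelihood
  grid <- expand.grid(b0 = seq(0, 2, by = 0.01),
                      size = exp(seq(-3, 3, by = 0.05)))
  ll <- mapply(function(b0, size) {
    sum(stats::dnbinom(records$debris_count, size = size, mu = exp(b0),
                       log = TRUE))
  }, grid$b0, grid$size)
  expect_gte(fit$log_likelihood, max(ll) - 1e-6)
  # AIC identity with the dispersion parameter counted
  expect_equal(fit$aic, 2 * (length(fit$coefficients) + 1) -
                 2 * fit$log_likelihood)
})

test_that("an all-zero response is reported as degenerate, not an error", {
  records <- make_necropsy(rep(0, 12), cod = rep("Ukn", 12))
  fit <- fit_nb_glm(records, "0")
  expect_s3_class(fit, "count_model_fit")
  expect_true(!fit$converged || length(fit$separation_flags) > 0)
})

test_that("cause coefficients are null when generation ignores cause", {
  set.seed(71)
  # KP is excluded: its debris-count floor (a KP death requires debris)
  # truncates the count distribution and would break the null by design
  records <- sim_counts_by_cause(5000, mu_by_cause = c(Ukn = 2, KNP = 2,
                                                       Ind = 2),
                                 size = 0.5,
                                 cause_probs = c(Ukn = 1, KNP = 1, Ind = 1) / 3)
  fit <- fit_nb_glm(records, "C")
  cz <- grep("^cod", names(fit$coefficients), value = TRUE)
  expect_true(all(abs(fit$coefficients[cz]) <= 3 * fit$std_errors[cz]))
})

test_that("the NB fit approaches the Poisson GLM as dispersion grows", {
  set.seed(8)
  records <- sim_counts_by_cause(300, mu_by_cause = c(Ukn = 1, KNP = 2,
                                                      Ind = 3, KP = 5),
                                 size = 1e7)
  nb <- fit_nb_glm(records, "C", theta = 1e8)
  pois <- stats::glm(debris_count ~ cod,
                     data = turtledose:::prepare_count_data(records, "Ind",
                                                            "adult", "green"),
                     family = stats::poisson())
  expect_equal(unname(nb$coefficients), unname(stats::coef(pois)),
               tolerance = 1e-6)
})

test_that("separation from an all-zero factor level is flagged", {
  set.seed(4)
  counts <- c(rpois(30, 3) + 1, rep(0, 10))
  cod <- c(rep("KP", 30), rep("KNP", 10))
  fit <- fit_nb_glm(make_necropsy(counts, cod), "C")
  # the all-zero KNP cell drives its cell mean to -Inf; with KNP as the
  # reference the runaway shows in the intercept and the KP offset
  expect_gt(length(fit$separation_flags), 0)
  expect_true(all(fit$std_errors[fit$separation_flags] > 1e3))
})

test_that("overdispersion check is calibrated and detects a misfit family", {
  # under a correctly specified family the p-values are near-uniform
  set.seed(21)
  p_ok <- replicate(120, {
    rec <- make_necropsy(stats::rpois(150, 2), cod = rep("Ukn", 150))
    overdispersion_check(fit_nb_glm(rec, "0", theta = 1e8))$p_value
  })
  ks <- stats::ks.test(p_ok, "punif")
  expect_gt(ks$p.value, 0.01)
  # strongly over-dispersed data fitted in the Poisson limit are rejected
  set.seed(22)
  p_bad <- replicate(120, {
    rec <- make_necropsy(stats::rnbinom(150, size = 0.3, mu = 2),
                         cod = rep("Ukn", 150))
    overdispersion_check(fit_nb_glm(rec, "0", theta = 1e8))$p_value
  })
  expect_gte(mean(p_bad < 0.05), 0.9)
  # saturated fit has no residual degrees of freedom
  rec2 <- make_necropsy(c(1, 4), cod = c("Ukn", "KP"))
  expect_error(overdispersion_check(fit_nb_glm(rec2, "C", theta = 1)),
               "degrees of freedom")
})

test_that("AIC ranking is order-invariant with a parsimony tie-break", {
  set.seed(31)
  records <- sim_counts_by_cause(250, mu_by_cause = c(Ukn = 0.5, KNP = 0.6,
                                                      Ind = 2, KP = 6),
                                 size = 0.8)
  t1 <- select_by_aic(records, c("0", "C", "CA"))
  t2 <- select_by_aic(records, c("CA", "0", "C"))
  expect_identical(t1, t2)
  # duplicate specs give identical AICs and keep their relative order
  t3 <- select_by_aic(records, c("C", "C"))
  expect_equal(t3$aic[1], t3$aic[2])
  expect_identical(t3$delta_aic[2], 0)
})

test_that("AIC selection finds a strong cause effect and respects a null", {
  hits <- sapply(1:20, function(s) {
    set.seed(500 + s)
    rec <- sim_counts_by_cause(246, mu_by_cause = c(Ukn = 0.4, KNP = 0.5,
                                                    Ind = 2.5, KP = 10),
                               size = 0.8)
    tab <- select_by_aic(rec, c("0", "C"))
    tab$code[1] == "C" && tab$delta_aic[tab$code == "0"] >= 2
  })
  expect_gte(mean(hits), 0.9)
  nulls <- sapply(1:20, function(s) {
    set.seed(700 + s)
    rec <- sim_counts_by_cause(246, mu_by_cause = c(Ukn = 1, KNP = 1,
                                                    Ind = 1),
                               size = 0.8,
                               cause_probs = c(Ukn = 1, KNP = 1, Ind = 1) / 3)
    tab <- select_by_aic(rec, c("0", "C"))
    tab$delta_aic[tab$code == "0"] < 2
  })
  expect_gte(mean(nulls), 0.6)
})

test_that("contrast letters collapse under a null and split under strong effects", {
  set.seed(41)
  rec_null <- sim_counts_by_cause(800, mu_by_cause = c(Ukn = 2, KNP = 2,
                                                       Ind = 2),
                                  size = 1,
                                  cause_probs = c(Ukn = 1, KNP = 1, Ind = 1) / 3)
  ctr <- pairwise_cause_contrasts(fit_nb_glm(rec_null, "C"))
  expect_true(all(ctr$letters == ctr$letters[1]))
  rec_eff <- sim_counts_by_cause(800, mu_by_cause = c(Ukn = 0.3, KNP = 0.4,
                                                      Ind = 3, KP = 15),
                                 size = 0.8)
  ctr2 <- pairwise_cause_contrasts(fit_nb_glm(rec_eff, "C"))
  # KNP and KP must not share a letter under a 35x mean ratio
  shared <- intersect(strsplit(ctr2$letters["KNP"], "")[[1]],
                      strsplit(ctr2$letters["KP"], "")[[1]])
  expect_length(shared, 0)
  expect_equal(nrow(ctr2$contrasts), 6L)
})

test_that("contrasts do not depend on the reference-level coding", {
  set.seed(51)
  rec <- sim_counts_by_cause(400, mu_by_cause = c(Ukn = 0.5, KNP = 0.7,
                                                  Ind = 2, KP = 8),
                             size = 0.8)
  ctr_a <- pairwise_cause_contrasts(fit_nb_glm(rec, "C", cause_ref = "Ind"))
  ctr_b <- pairwise_cause_contrasts(fit_nb_glm(rec, "C", cause_ref = "KP"))
  key <- function(ctr) {
    d <- ctr$contrasts
    swap <- d$level_a > d$level_b
    est <- ifelse(swap, -d$estimate, d$estimate)
    o <- order(pmin(d$level_a, d$level_b), pmax(d$level_a, d$level_b))
    list(est = est[o], p = d$p_adjusted[o])
  }
  ka <- key(ctr_a)
  kb <- key(ctr_b)
  expect_equal(ka$est, kb$est, tolerance = 1e-6)
  expect_equal(ka$p, kb$p, tolerance = 1e-6)
  # the letter partition (which levels are grouped) is coding-invariant
  part <- function(ctr) unname(lapply(split(names(ctr$letters), ctr$letters),
                                      sort))
  expect_setequal(part(ctr_a), part(ctr_b))
})

test_that("a two-category fit yields a single unadjusted contrast", {
  set.seed(61)
  rec <- make_necropsy(c(stats::rpois(40, 1), stats::rpois(40, 4) + 1),
                       cod = c(rep("KNP", 40), rep("KP", 40)))
  ctr <- pairwise_cause_contrasts(fit_nb_glm(rec, "C"))
  expect_equal(nrow(ctr$contrasts), 1L)
  expect_equal(ctr$contrasts$p_adjusted, ctr$contrasts$p_value)
})

test_that("fitted coefficients recover known generating effects at n = 5000", {
  set.seed(81)
  mu <- c(Ukn = 0.5, KNP = 0.8, Ind = 2)
  rec <- sim_counts_by_cause(5000, mu_by_cause = mu, size = 0.7,
                             cause_probs = c(Ukn = 1, KNP = 1, Ind = 1) / 3)
  fit <- fit_nb_glm(rec, "C", cause_ref = "Ukn")
  truth <- log(mu[c("KNP", "Ind")] / mu["Ukn"])
  est <- fit$coefficients[paste0("cod", c("KNP", "Ind"))]
  se <- fit$std_errors[paste0("cod", c("KNP", "Ind"))]
  expect_true(all(abs(est - truth) <= 3 * se))
  expect_lt(abs(fit$dispersion - 0.7), 0.1)
})
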