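#' Candidate specifications for the debris-count model
#'
#' Short codes name the covariates of the negative binomial regression of
#' debris count: `0` intercept only, `C` cause of death, `A` age class, `S`
#' species, and `CA:S` cause + age class + their interaction + species. All
#' non-null models include an intercept.
#'
#' @param code one of "0", "C", "CA", "CS", "CAS", "CA:S".
#' @return a `count_model_spec` object carrying the code and model formula.
#' @export
count_model_spec <- function(code = c("0", "C", "CA", "CS", "CAS", "CA:S")) {
  code <- match.arg(code)
  rhs <- switch(code,
    "0" = "1",
    "C" = "cod",
    "CA" = "cod + age_class",
    "CS" = "cod + species",
    "CAS" = "cod + age_class + species",
    "CA:S" = "cod + age_class + cod:age_class + species"
  )
  structure(list(code = code,
                 formula = stats::as.formula(paste("debris_count ~", rhs))),
            class = "count_model_spec")
}

#' @export
print.count_model_spec <- function(x, ...) {
  cat(sprintf("Count model spec '%s': %s\n", x$code, deparse(x$formula)))
  invisible(x)
}

#' Fit a negative binomial GLM of debris count
#'
#' Maximum-likelihood negative binomial regression with log link, dispersion
#' (size) estimated jointly by alternating IRLS and profile ML. Subadults are
#' pooled with adults before fitting. Quasi-complete separation (a factor
#' level whose counts are all zero drives its coefficient to -Inf) is detected
#' as |coefficient| > 20 with standard error > 1000 and flagged rather than
#' treated as failure. AIC counts the dispersion parameter when it is
#' estimated.
#'
#' @param records necropsy records (see [generate_necropsy_cohort()]).
#' @param spec a [count_model_spec()] or a code string.
#' @param cause_ref,age_ref,species_ref reference levels; defaults: first
#'   alphabetical cause ("Ind"), adult, green.
#' @param theta optional fixed dispersion; when supplied the NB family with
#'   known size is used (large values approach the Poisson limit) and the
#'   dispersion is not counted as an estimated parameter.
#' @return a `count_model_fit` with coefficients, standard errors, covariance,
#'   dispersion, log-likelihood, AIC, convergence and separation flags.
#' @examples
#' cohort <- generate_necropsy_cohort(generator_params(n_animals = 200))
#' fit <- fit_nb_glm(cohort, "C")
#' fit$aic
#' @export
fit_nb_glm <- function(records, spec = "CAS",
                       cause_ref = sort(COD_LEVELS)[1],
                       age_ref = "adult", species_ref = "green",
                       theta = NULL) {
  if (is.character(spec)) spec <- count_model_spec(spec)
  if (nrow(records) == 0) stop("no records to fit")
  dat <- prepare_count_data(records, cause_ref, age_ref, species_ref)
  formula <- drop_single_level_terms(spec$formula, dat)

  converged <- TRUE
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      {
        if (is.null(theta)) {
          MASS::glm.nb(formula, data = dat,
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))
        } else {
          stats::glm(formula, data = dat,
                     family = MASS::negative.binomial(theta = theta),
                     control = stats::glm.control(epsilon = 1e-8, maxit = 100))
        }
      },
      error = function(e) e
    ),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  if (inherits(fit, "error")) {
    # Degenerate data (e.g. an all-zero response) breaks the dispersion
    # profile; fall back to the Poisson limit so the caller still gets
    # coefficients with separation flags instead of a crash.
    fit <- suppressWarnings(
      stats::glm(formula, data = dat, family = stats::poisson())
    )
    converged <- FALSE
    warn_msgs <- c(warn_msgs, "dispersion estimation failed; Poisson fallback")
  }
  if (any(grepl("iteration limit|did not converge|algorithm", warn_msgs,
                ignore.case = TRUE))) {
    converged <- FALSE
  }

  coefs <- stats::coef(fit)
  vcv <- stats::vcov(fit)
  # aliased coefficients are dropped from vcov; keep SEs name-aligned
  ses <- stats::setNames(rep(NA_real_, length(coefs)), names(coefs))
  shared <- intersect(names(coefs), colnames(vcv))
  ses[shared] <- sqrt(diag(vcv))[shared]
  ll <- as.numeric(stats::logLik(fit))
  disp <- if (!is.null(theta)) theta
          else if (!is.null(fit$theta)) fit$theta else NA_real_
  k <- fit$rank + if (is.null(theta) && !is.na(disp)) 1L else 0L
  aic <- 2 * k - 2 * ll
  sep <- names(coefs)[!is.na(coefs) & abs(coefs) > 20 &
                        !is.na(ses) & ses > 1e3]

  structure(
    list(spec = spec,
         coefficients = coefs,
         std_errors = ses,
         vcov = vcv,
         dispersion = disp,
         log_likelihood = ll,
         aic = aic,
         n_obs = nrow(dat),
         n_params = k,
         converged = converged && fit$converged,
         separation_flags = sep,
         fitted_values = stats::fitted(fit),
         response = dat$debris_count,
         cause_ref = levels(dat$cod)[1],
         cause_levels = levels(dat$cod),
         warnings = warn_msgs),
    class = "count_model_fit"
  )
}

# Remove model terms involving factors with fewer than two observed levels
# (and any interactions touching them); such terms are inestimable.
drop_single_level_terms <- function(formula, dat) {
  tl <- attr(stats::terms(formula), "term.labels")
  if (length(tl) == 0) return(formula)
  single <- names(dat)[vapply(dat, function(v) {
    (is.factor(v) || is.character(v)) && length(unique(as.character(v))) < 2
  }, logical(1))]
  keep <- tl[!vapply(tl, function(t) {
    any(strsplit(t, ":", fixed = TRUE)[[1]] %in% single)
  }, logical(1))]
  stats::reformulate(if (length(keep) == 0) "1" else keep,
                     response = "debris_count")
}

prepare_count_data <- function(records, cause_ref, age_ref, species_ref) {
  validate_necropsy_records(records)
  dat <- records
  dat$age_class <- aggregate_age_class(dat$age_class, ref = age_ref)
  dat$age_class <- droplevels(dat$age_class)
  cods <- sort(unique(dat$cod))
  if (!cause_ref %in% cods) cause_ref <- cods[1]
  dat$cod <- factor(dat$cod, levels = c(cause_ref, setdiff(cods, cause_ref)))
  sps <- sort(unique(dat$species))
  if (!species_ref %in% sps) species_ref <- sps[1]
  dat$species <- factor(dat$species,
                        levels = c(species_ref, setdiff(sps, species_ref)))
  dat
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("Negative binomial count model '%s' (n = %d)\n",
              x$spec$code, x$n_obs))
  cat(sprintf("  dispersion (size): %.4g   logLik: %.2f   AIC: %.1f\n",
              x$dispersion, x$log_likelihood, x$aic))
  if (!x$converged) cat("  NOTE: fit did not converge\n")
  if (length(x$separation_flags) > 0) {
    cat("  separation flagged for:",
        paste(x$separation_flags, collapse = ", "), "\n")
  }
  tab <- data.frame(estimate = x$coefficients, se = x$std_errors)
  print(round(tab, 4))
  invisible(x)
}

#' Pearson goodness-of-fit check for a count model
#'
#' Chi-square test of the Pearson statistic against the residual degrees of
#' freedom; a small p-value indicates residual over-dispersion not captured
#' by the fitted family.
#'
#' @param fit a `count_model_fit`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
overdispersion_check <- function(fit) {
  if (!inherits(fit, "count_model_fit")) stop("need a count_model_fit")
  mu <- fit$fitted_values
  y <- fit$response
  v <- if (is.finite(fit$dispersion)) mu + mu^2 / fit$dispersion else mu
  stat <- sum((y - mu)^2 / v)
  df <- fit$n_obs - length(fit$coefficients)
  if (df <= 0) stop("zero residual degrees of freedom; check is undefined")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Rank candidate count models by AIC
#'
#' Fits each candidate and returns a table sorted by AIC (ascending), ties
#' broken by fewer parameters. Differences of 2 or more AIC units from the
#' best model are flagged as significant. Non-converged fits are excluded
#' from the ranking and reported with `converged = FALSE`.
#'
#' @param records necropsy records.
#' @param specs character vector of codes or list of [count_model_spec()]s.
#' @param ... passed to [fit_nb_glm()].
#' @return data.frame with columns `code`, `aic`, `delta_aic`, `k`,
#'   `converged`, `significantly_worse`.
#' @export
select_by_aic <- function(records,
                          specs = c("0", "C", "CA", "CS", "CAS", "CA:S"),
                          ...) {
  if (length(specs) < 2) stop("need at least two candidate specifications")
  fits <- lapply(specs, function(s) fit_nb_glm(records, s, ...))
  tab <- data.frame(
    code = vapply(fits, function(f) f$spec$code, character(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ok <- tab[tab$converged, , drop = FALSE]
  bad <- tab[!tab$converged, , drop = FALSE]
  ok <- ok[order(ok$aic, ok$k, ok$code), , drop = FALSE]
  ok$delta_aic <- ok$aic - ok$aic[1]
  ok$significantly_worse <- ok$delta_aic >= 2
  if (nrow(bad) > 0) {
    bad$delta_aic <- NA_real_
    bad$significantly_worse <- NA
    ok <- rbind(ok, bad)
  }
  rownames(ok) <- NULL
  ok[, c("code", "aic", "delta_aic", "k", "converged", "significantly_worse")]
}

#' Pairwise contrasts among cause-of-death coefficients
#'
#' Wald z tests for all pairwise differences among the cause-of-death level
#' effects of a fitted count model, Holm-adjusted, with a compact letter
#' display (levels sharing a letter are not significantly different).
#'
#' @param fit a `count_model_fit` whose spec includes the cause term.
#' @param alpha significance level for the letter display.
#' @return a `cause_contrasts` object (see [letter_display()]).
#' @export
pairwise_cause_contrasts <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "count_model_fit")) stop("need a count_model_fit")
  if (!grepl("cod", deparse(fit$spec$formula))) {
    stop("model spec does not include the cause-of-death term")
  }
  cause_level_contrasts(fit$coefficients, fit$vcov, fit$cause_levels,
                        fit$cause_ref, alpha)
}

# Build level effects (reference = 0) from treatment-coded cause coefficients
# and run the shared contrast machinery.
cause_level_contrasts <- function(coefs, vcv, cause_levels, cause_ref, alpha) {
  k <- length(cause_levels)
  effects <- stats::setNames(numeric(k), cause_levels)
  V <- matrix(0, k, k, dimnames = list(cause_levels, cause_levels))
  for (lv in setdiff(cause_levels, cause_ref)) {
    nm <- paste0("cod", lv)
    if (!nm %in% names(coefs)) stop("cause coefficient missing: ", nm)
    effects[lv] <- coefs[nm]
  }
  other <- setdiff(cause_levels, cause_ref)
  nm <- paste0("cod", other)
  V[other, other] <- vcv[nm, nm]
  pairwise_wald_contrasts(effects, V, alpha = alpha)
}
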