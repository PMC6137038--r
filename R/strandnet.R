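#' Binary examination indicator
#'
#' Stranding-register necropsy reports vary widely in how thoroughly the
#' gastro-intestinal tract was examined (levels 0-3); for modelling, the
#' level is reduced to examined at all (level > 0) versus not (level 0).
#'
#' @param exam_level integer vector with values in 0..3.
#' @return logical vector, TRUE iff the level exceeds 0.
#' @examples
#' binarize_exam(c(0, 1, 3))
#' @export
binarize_exam <- function(exam_level) {
  if (any(!(exam_level %in% 0:3))) {
    stop("exam_level must be in 0..3")
  }
  exam_level > 0
}

#' Logistic presence/absence model for stranding records
#'
#' Maximum-likelihood binary logistic regression of the debris-present flag.
#' The cause-of-death term is cell-means coded (no intercept absorption) so
#' that all four cause coefficients are reported directly; their standard
#' errors then refer to cell log-odds. Species is excluded by default (low
#' representation of several species in typical registers). Separation is
#' flagged, not fatal.
#'
#' @param records StrandNet-style records (see
#'   [generate_strandnet_records()]).
#' @param terms subset of `c("cause", "adult", "exam")`; an empty set fits an
#'   intercept-only model.
#' @return a `presence_model_fit` with coefficients, standard errors,
#'   covariance, log-likelihood, AIC (2k - 2 logLik), convergence and
#'   separation flags.
#' @export
fit_presence_model <- function(records, terms = c("cause", "adult", "exam")) {
  validate_strandnet_records(records)
  if (nrow(records) == 0) stop("no records to fit")
  bad <- setdiff(terms, c("cause", "adult", "exam"))
  if (length(bad) > 0) stop("unknown terms: ", paste(bad, collapse = ", "))
  dat <- data.frame(
    y = records$debris_present,
    cod = factor(records$cod, levels = intersect(COD_LEVELS,
                                                 unique(records$cod))),
    adult = records$adult,
    exam_binary = binarize_exam(records$exam_level)
  )
  rhs <- character(0)
  if ("cause" %in% terms) rhs <- c("0", "cod")
  if ("adult" %in% terms) rhs <- c(rhs, "adult")
  if ("exam" %in% terms) rhs <- c(rhs, "exam_binary")
  if (length(rhs) == 0) rhs <- "1"
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))

  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  coefs <- stats::coef(fit)
  vcv <- stats::vcov(fit)
  ses <- sqrt(diag(vcv))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(coefs)
  sep_flags <- names(coefs)[abs(coefs) > 20 | ses > 1e3]
  if (any(grepl("fitted probabilities numerically 0 or 1", warn_msgs))) {
    sep_flags <- union(sep_flags, names(coefs)[abs(coefs) > 10])
  }
  structure(
    list(terms = terms,
         formula = form,
         coefficients = coefs,
         std_errors = ses,
         vcov = vcv,
         log_likelihood = ll,
         aic = 2 * k - 2 * ll,
         n_obs = nrow(dat),
         n_params = k,
         converged = fit$converged,
         separation_flags = sep_flags,
         cause_levels = levels(dat$cod),
         warnings = warn_msgs),
    class = "presence_model_fit"
  )
}

#' @export
print.presence_model_fit <- function(x, ...) {
  cat(sprintf("Debris presence/absence logistic model (n = %d)\n", x$n_obs))
  cat(sprintf("  terms: %s   AIC: %.1f\n",
              paste(x$terms, collapse = " + "), x$aic))
  if (length(x$separation_flags) > 0) {
    cat("  separation flagged for:",
        paste(x$separation_flags, collapse = ", "), "\n")
  }
  print(round(data.frame(estimate = x$coefficients, se = x$std_errors), 4))
  invisible(x)
}

#' Rank presence/absence models by AIC
#'
#' Fits each candidate term set (by default the power set of
#' {cause, adult, exam}, 8 models) and ranks by AIC with the same conventions
#' as [select_by_aic()].
#'
#' @param records StrandNet-style records.
#' @param candidates list of character vectors of terms; `character(0)` is
#'   the intercept-only model.
#' @return data.frame `terms`, `aic`, `delta_aic`, `k`, `converged`,
#'   `significantly_worse`.
#' @export
presence_model_selection <- function(records, candidates = NULL) {
  if (is.null(candidates)) {
    base <- c("cause", "adult", "exam")
    candidates <- list(character(0))
    for (m in 1:3) {
      cmb <- utils::combn(base, m, simplify = FALSE)
      candidates <- c(candidates, cmb)
    }
  }
  fits <- lapply(candidates, function(tt) fit_presence_model(records, tt))
  lab <- vapply(candidates, function(tt) {
    if (length(tt) == 0) "1" else paste(tt, collapse = "+")
  }, character(1))
  tab <- data.frame(
    terms = lab,
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ok <- tab[tab$converged, , drop = FALSE]
  bad <- tab[!tab$converged, , drop = FALSE]
  ok <- ok[order(ok$aic, ok$k), , drop = FALSE]
  ok$delta_aic <- ok$aic - ok$aic[1]
  ok$significantly_worse <- ok$delta_aic >= 2
  if (nrow(bad) > 0) {
    bad$delta_aic <- NA_real_
    bad$significantly_worse <- NA
    ok <- rbind(ok, bad)
  }
  rownames(ok) <- NULL
  ok[, c("terms", "aic", "delta_aic", "k", "converged", "significantly_worse")]
}

#' Pairwise comparisons among cause coefficients of a presence model
#'
#' All pairwise Wald z contrasts among the cell-means cause coefficients,
#' Holm-adjusted, with a compact letter display.
#'
#' @param fit a `presence_model_fit` including the cause term.
#' @param alpha significance level.
#' @return a `cause_contrasts` object.
#' @export
pairwise_cause_comparisons <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "presence_model_fit")) stop("need a presence_model_fit")
  if (!"cause" %in% fit$terms) stop("model does not include the cause term")
  lv <- fit$cause_levels
  nm <- paste0("cod", lv)
  effects <- stats::setNames(fit$coefficients[nm], lv)
  V <- fit$vcov[nm, nm, drop = FALSE]
  dimnames(V) <- list(lv, lv)
  pairwise_wald_contrasts(effects, V, alpha = alpha)
}
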