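#' Prediction context for dose-response curves
#'
#' The reference animal and load grid at which mortality curves are
#' evaluated. Defaults follow the reference analysis: the cohort's median
#' curved carapace length (43.5 cm), the most common age class (juvenile),
#' and loads from 0 to 250 items.
#'
#' @param ccl_cm curved carapace length in cm (> 0).
#' @param age_class age class of the reference animal.
#' @param load_grid strictly increasing non-negative loads (items).
#' @return a `prediction_context`.
#' @export
prediction_context <- function(ccl_cm = 43.5, age_class = "juvenile",
                               load_grid = 0:250) {
  if (length(ccl_cm) != 1 || !is.finite(ccl_cm) || ccl_cm <= 0) {
    .fail_field("ccl_cm", "must be a single positive length")
  }
  if (!age_class %in% AGE_CLASSES) {
    .fail_field("age_class", "must be one of the five age classes")
  }
  if (length(load_grid) < 1 || any(load_grid < 0) ||
      any(diff(load_grid) <= 0)) {
    .fail_field("load_grid", "must be strictly increasing and non-negative")
  }
  structure(list(ccl_cm = ccl_cm, age_class = age_class,
                 load_grid = load_grid),
            class = "prediction_context")
}

# Linear predictor at given loads for one coefficient vector.
# Handles the three dose-response designs by the terms present in the names:
# debris_count (+ ccl_cm, + nw_residual at 0) or load_per_ccl + age dummies.
dose_eta <- function(coefficients, context, load, age_ref = "adult") {
  cf <- coefficients
  eta <- rep(unname(cf["(Intercept)"]), length(load))
  if ("load_per_ccl" %in% names(cf)) {
    eta <- eta + cf["load_per_ccl"] * load / context$ccl_cm
  } else if ("debris_count" %in% names(cf)) {
    eta <- eta + cf["debris_count"] * load
  } else {
    stop("coefficients contain no load term (debris_count or load_per_ccl)")
  }
  if ("ccl_cm" %in% names(cf)) eta <- eta + cf["ccl_cm"] * context$ccl_cm
  # nw_residual enters at its centred value, 0
  age_terms <- grep("^age_class", names(cf), value = TRUE)
  if (length(age_terms) > 0) {
    ctx_age <- as.character(aggregate_age_class(context$age_class,
                                                ref = age_ref)[1])
    if (ctx_age != age_ref) {
      nm <- paste0("age_class", ctx_age)
      if (!nm %in% names(cf)) {
        stop("age class '", ctx_age,
             "' absent from the ensemble coefficients")
      }
      eta <- eta + cf[nm]
    }
  }
  unname(eta)
}

# Effective per-item slope of eta in load for one coefficient vector.
dose_slope_per_item <- function(coefficients, context) {
  if ("load_per_ccl" %in% names(coefficients)) {
    unname(coefficients["load_per_ccl"] / context$ccl_cm)
  } else {
    unname(coefficients["debris_count"])
  }
}

#' Mortality probability at a given plastic load
#'
#' Deterministic evaluation of the fitted logistic curve for a reference
#' animal: `plogis` of the linear predictor at the load.
#'
#' @param object an `mc_ensemble` (its median coefficients are used) or a
#'   named coefficient vector on the logit scale.
#' @param context a [prediction_context()].
#' @param load non-negative debris load (items); vectorised.
#' @param age_ref reference age-class level when `object` is a bare
#'   coefficient vector (ensembles carry their own).
#' @return probability vector.
#' @examples
#' cf <- c("(Intercept)" = -2, load_per_ccl = 4)
#' mortality_at_load(cf, prediction_context(ccl_cm = 40), load = 0)
#' @export
mortality_at_load <- function(object, context = prediction_context(),
                              load, age_ref = "adult") {
  if (any(load < 0)) stop("load must be non-negative")
  cf <- ensemble_coefficients(object)
  if (inherits(object, "mc_ensemble") && !is.null(object$age_ref)) {
    age_ref <- object$age_ref
  }
  stats::plogis(dose_eta(cf, context, load, age_ref = age_ref))
}

ensemble_coefficients <- function(object) {
  if (inherits(object, "mc_ensemble")) object$median_coefficients
  else if (is.numeric(object) && !is.null(names(object))) object
  else stop("need an mc_ensemble or a named coefficient vector")
}

#' Predict the mortality-vs-load curve with its uncertainty envelope
#'
#' Evaluates the dose-response curve over the context's load grid: the
#' central curve uses the ensemble's per-term median coefficients; the
#' envelope is the pointwise minimum and maximum over every successful
#' replicate's curve (widened, if ever necessary, to contain the median
#' curve, so the envelope-nesting invariant holds by construction).
#'
#' @param ensemble an `mc_ensemble`.
#' @param context a [prediction_context()].
#' @return a `dose_response_curve`: data.frame `load`, `p_median`, `p_lo`,
#'   `p_hi` with the context and spec in attributes.
#' @export
predict_curve <- function(ensemble, context = prediction_context()) {
  if (!inherits(ensemble, "mc_ensemble")) stop("need an mc_ensemble")
  age_ref <- if (is.null(ensemble$age_ref)) "adult" else ensemble$age_ref
  load <- context$load_grid
  p_med <- stats::plogis(dose_eta(ensemble$median_coefficients, context, load,
                                  age_ref = age_ref))
  ok <- which(!is.na(ensemble$aics))
  etas <- vapply(ok, function(r) {
    dose_eta(ensemble$coefficients[r, ], context, load, age_ref = age_ref)
  }, numeric(length(load)))
  etas <- matrix(etas, nrow = length(load))
  p_lo <- pmin(stats::plogis(apply(etas, 1, min)), p_med)
  p_hi <- pmax(stats::plogis(apply(etas, 1, max)), p_med)
  out <- data.frame(load = load, p_median = p_med, p_lo = p_lo, p_hi = p_hi)
  class(out) <- c("dose_response_curve", "data.frame")
  attr(out, "context") <- context
  attr(out, "spec") <- ensemble$spec
  out
}

#' @export
print.dose_response_curve <- function(x, ...) {
  ctx <- attr(x, "context")
  cat(sprintf("Dose-response curve (CCL %.1f cm, %s), %d grid points\n",
              ctx$ccl_cm, ctx$age_class, nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Invert the dose-response curve for a target mortality probability
#'
#' Solves `plogis(eta(load)) = p_target` for the load in closed form (the
#' linear predictor is linear in load). A target of exactly 1 is read as
#' "numerically certain death" and solved at `1 - tolerance`, since a
#' logistic curve never attains 1. The returned load is real-valued (callers
#' wanting whole items should round up); it is negative when the curve
#' already exceeds the target at load 0.
#'
#' @param object coefficient vector or `mc_ensemble`.
#' @param context a [prediction_context()].
#' @param p_target target probability in (0, 1\].
#' @param tolerance gap below 1 used when `p_target == 1`.
#' @param age_ref as in [mortality_at_load()].
#' @return real-valued load (items).
#' @examples
#' cf <- c("(Intercept)" = -2, debris_count = 0.2)
#' invert_for_probability(cf, prediction_context(), 0.5) # 10 items
#' @export
invert_for_probability <- function(object, context = prediction_context(),
                                   p_target, tolerance = 5e-3,
                                   age_ref = "adult") {
  if (length(p_target) != 1 || !is.finite(p_target) || p_target <= 0 ||
      p_target > 1) {
    stop("p_target must lie in (0, 1]")
  }
  if (p_target == 1) p_target <- 1 - tolerance
  cf <- ensemble_coefficients(object)
  if (inherits(object, "mc_ensemble") && !is.null(object$age_ref)) {
    age_ref <- object$age_ref
  }
  slope <- dose_slope_per_item(cf, context)
  if (!is.finite(slope) || slope <= 0) {
    stop("load coefficient is not positive; curve is not invertible upward")
  }
  eta0 <- dose_eta(cf, context, 0, age_ref = age_ref)
  (stats::qlogis(p_target) - eta0) / slope
}

#' Cohort-averaged 50%-mortality load
#'
#' The load at which the cohort-averaged predicted mortality - the mean over
#' the supplied records of the fitted curve evaluated at each animal's CCL
#' and age class - first reaches the target probability. Found by monotone
#' bisection; returns 0 when the average already meets the target at zero
#' load, and errors (reporting the attained maximum) if the target is never
#' reached on the search interval.
#'
#' @param ensemble an `mc_ensemble` (median coefficients are used).
#' @param records the cohort the ensemble was fitted to.
#' @param target target probability (default 0.5).
#' @param upper upper end of the bisection interval (items).
#' @param tol bisection tolerance on the load.
#' @return real-valued load (items).
#' @export
population_ed50 <- function(ensemble, records, target = 0.5, upper = 1e4,
                            tol = 1e-8) {
  cf <- ensemble_coefficients(ensemble)
  age_ref <- if (inherits(ensemble, "mc_ensemble") &&
                 !is.null(ensemble$age_ref)) ensemble$age_ref else "adult"
  # per-record intercepts and per-item slopes: eta_i(L) = eta0_i + s_i * L
  eta0 <- numeric(nrow(records))
  s <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    ctx <- prediction_context(ccl_cm = records$ccl_cm[i],
                              age_class = records$age_class[i], load_grid = 0)
    eta0[i] <- dose_eta(cf, ctx, 0, age_ref = age_ref)
    s[i] <- dose_slope_per_item(cf, ctx)
  }
  avg_p <- function(load) mean(stats::plogis(eta0 + s * load))
  if (avg_p(0) >= target) return(0)
  p_up <- avg_p(upper)
  if (p_up < target) {
    stop(sprintf("cohort-averaged mortality reaches only %.4f at load %g",
                 p_up, upper))
  }
  lo <- 0
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (avg_p(mid) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
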