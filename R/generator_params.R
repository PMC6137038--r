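#' Parameters for the synthetic necropsy-cohort generator
#'
#' Bundles and validates every knob of the synthetic-data model. The defaults
#' encode the composition of the necropsy cohort the analysis was designed
#' for: 246 animals with age-class counts 22/24/175/13/12 (hatchling through
#' adult), species counts 160/52/30/1/1/2 (green, hawksbill, loggerhead,
#' flatback, olive ridley, unidentified), curved carapace lengths spanning
#' roughly 4-116 cm with a pooled median near 43.5 cm, over-dispersed debris
#' counts, and a latent logistic mortality process in debris load per cm of
#' carapace.
#'
#' @param n_animals number of animals to generate.
#' @param age_class_weights probability vector over the five age classes
#'   (hatchling, post_hatchling, juvenile, subadult, adult).
#' @param species_weights probability vector over the six species categories
#'   (green, hawksbill, loggerhead, flatback, olive_ridley, unidentified).
#' @param ccl_mean_by_age,ccl_sd_by_age mean and sd (cm) of the truncated
#'   normal curved-carapace-length distribution, one entry per age class.
#' @param nb_mu_by_age_species 5 x 6 matrix of expected debris counts per age
#'   class (rows) and species (columns).
#' @param nb_dispersion negative binomial size parameter (> 0); smaller values
#'   give stronger over-dispersion.
#' @param mass_per_item_log_mean,mass_per_item_log_sd parameters of the
#'   lognormal per-item dry mass distribution (log grams).
#' @param true_intercept,true_slope generating logistic coefficients on the
#'   load-per-CCL scale (items per cm).
#' @param true_age_offsets named per-age-class shifts added to the logistic
#'   intercept.
#' @param external_hazard probability that an external (non-plastic) cause
#'   kills the animal first even when its plastic load would have been
#'   lethal; the probability that a recorded death was plastic-caused is
#'   `(1 - external_hazard) * plogis(intercept + offset + slope * load/ccl)`,
#'   so the latent logistic curve is itself the conditional-on-death
#'   dose-response.
#' @param label_kp_given_plastic probability that a plastic-caused death with
#'   debris present is definitively labelled KP (otherwise Ind).
#' @param label_knp_given_external probability that an externally caused death
#'   is definitively labelled KNP; otherwise the cause stays unresolved and
#'   the record is labelled Ind when substantial debris is present, Ukn when
#'   not.
#' @param ind_debris_threshold debris count (items) regarded as "substantial"
#'   when labelling an unresolved death indeterminate rather than unknown.
#' @param hatchling_zero_debris if TRUE (default) hatchlings receive a debris
#'   count of zero, as observed in the cohort emulated.
#' @param seed integer RNG seed used by the generators.
#' @return an object of class `generator_params` (a validated named list).
#' @examples
#' p <- generator_params(n_animals = 50, seed = 7)
#' cohort <- generate_necropsy_cohort(p)
#' @export
generator_params <- function(n_animals = 246,
                             age_class_weights = c(22, 24, 175, 13, 12) / 246,
                             species_weights = c(160, 52, 30, 1, 1, 2) / 246,
                             ccl_mean_by_age = c(hatchling = 5.5,
                                                 post_hatchling = 14,
                                                 juvenile = 45.3,
                                                 subadult = 72,
                                                 adult = 95),
                             ccl_sd_by_age = c(hatchling = 0.8,
                                               post_hatchling = 4,
                                               juvenile = 12,
                                               subadult = 10,
                                               adult = 10),
                             nb_mu_by_age_species = NULL,
                             nb_dispersion = 0.1,
                             mass_per_item_log_mean = log(0.02),
                             mass_per_item_log_sd = 1,
                             true_intercept = -1.4,
                             true_slope = 4.2,
                             true_age_offsets = c(hatchling = 0,
                                                  post_hatchling = 0,
                                                  juvenile = 0,
                                                  subadult = 0,
                                                  adult = 0),
                             external_hazard = 0.05,
                             label_kp_given_plastic = 0.7,
                             label_knp_given_external = 0.4,
                             ind_debris_threshold = 3L,
                             hatchling_zero_debris = TRUE,
                             seed = 1L) {
  if (is.null(nb_mu_by_age_species)) {
    base_mu <- c(hatchling = 0.3, post_hatchling = 15, juvenile = 2,
                 subadult = 1.2, adult = 1.3)
    sp_mult <- c(green = 1, hawksbill = 0.4, loggerhead = 0.8, flatback = 0.6,
                 olive_ridley = 0.6, unidentified = 0.6)
    nb_mu_by_age_species <- outer(base_mu, sp_mult)
  }
  # Normalise per-age vectors to the canonical age-class order.
  by_age <- function(x, field) {
    if (!is.null(names(x))) {
      if (!setequal(names(x), AGE_CLASSES)) {
        .fail_field(field, "names must be the five age classes")
      }
      x <- x[AGE_CLASSES]
    } else if (length(x) == 5) {
      names(x) <- AGE_CLASSES
    }
    x
  }
  params <- list(
    n_animals = n_animals,
    age_class_weights = stats::setNames(age_class_weights, AGE_CLASSES),
    species_weights = stats::setNames(species_weights, SPECIES_LEVELS),
    ccl_mean_by_age = by_age(ccl_mean_by_age, "ccl_mean_by_age"),
    ccl_sd_by_age = by_age(ccl_sd_by_age, "ccl_sd_by_age"),
    nb_mu_by_age_species = nb_mu_by_age_species,
    nb_dispersion = nb_dispersion,
    mass_per_item_log_mean = mass_per_item_log_mean,
    mass_per_item_log_sd = mass_per_item_log_sd,
    true_intercept = true_intercept,
    true_slope = true_slope,
    true_age_offsets = by_age(true_age_offsets, "true_age_offsets"),
    external_hazard = external_hazard,
    label_kp_given_plastic = label_kp_given_plastic,
    label_knp_given_external = label_knp_given_external,
    ind_debris_threshold = ind_debris_threshold,
    hatchling_zero_debris = hatchling_zero_debris,
    seed = seed
  )
  class(params) <- "generator_params"
  validate_generator_params(params)
  params
}

#' Validate generator parameters
#'
#' Checks every field of a [generator_params()] object and raises an error
#' naming the first offending field.
#'
#' @param params a `generator_params` object.
#' @return the validated object, invisibly.
#' @export
validate_generator_params <- function(params) {
  chk_prob_vec <- function(x, field, len) {
    if (length(x) != len || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
      .fail_field(field, sprintf("must be %d finite non-negative values", len))
    }
    if (abs(sum(x) - 1) > 1e-12) .fail_field(field, "must sum to 1")
  }
  chk_prob <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      .fail_field(field, "must be a single probability in [0,1]")
    }
  }
  n <- params$n_animals
  if (length(n) != 1 || !is.finite(n) || n < 0 || n != round(n)) {
    .fail_field("n_animals", "must be a single non-negative integer")
  }
  chk_prob_vec(params$age_class_weights, "age_class_weights", 5L)
  chk_prob_vec(params$species_weights, "species_weights", 6L)
  for (f in c("ccl_mean_by_age", "ccl_sd_by_age")) {
    x <- params[[f]]
    if (length(x) != 5 || anyNA(x) || any(!is.finite(x))) {
      .fail_field(f, "must be 5 finite values (one per age class)")
    }
  }
  if (any(params$ccl_mean_by_age <= 0)) {
    .fail_field("ccl_mean_by_age", "means must be positive")
  }
  if (any(params$ccl_sd_by_age < 0)) {
    .fail_field("ccl_sd_by_age", "standard deviations must be non-negative")
  }
  mu <- params$nb_mu_by_age_species
  if (!is.matrix(mu) || !all(dim(mu) == c(5, 6)) || anyNA(mu) ||
      any(!is.finite(mu)) || any(mu < 0)) {
    .fail_field("nb_mu_by_age_species",
                "must be a 5 x 6 matrix of finite non-negative means")
  }
  if (length(params$nb_dispersion) != 1 || !is.finite(params$nb_dispersion) ||
      params$nb_dispersion <= 0) {
    .fail_field("nb_dispersion", "must be a single positive value")
  }
  for (f in c("mass_per_item_log_mean", "mass_per_item_log_sd",
              "true_intercept", "true_slope")) {
    if (length(params[[f]]) != 1 || !is.finite(params[[f]])) {
      .fail_field(f, "must be a single finite value")
    }
  }
  if (params$mass_per_item_log_sd < 0) {
    .fail_field("mass_per_item_log_sd", "must be non-negative")
  }
  off <- params$true_age_offsets
  if (length(off) != 5 || anyNA(off) || any(!is.finite(off))) {
    .fail_field("true_age_offsets", "must be 5 finite values")
  }
  chk_prob(params$external_hazard, "external_hazard")
  chk_prob(params$label_kp_given_plastic, "label_kp_given_plastic")
  chk_prob(params$label_knp_given_external, "label_knp_given_external")
  thr <- params$ind_debris_threshold
  if (length(thr) != 1 || !is.finite(thr) || thr < 1 || thr != round(thr)) {
    .fail_field("ind_debris_threshold", "must be a positive integer")
  }
  if (!is.logical(params$hatchling_zero_debris) ||
      length(params$hatchling_zero_debris) != 1 ||
      is.na(params$hatchling_zero_debris)) {
    .fail_field("hatchling_zero_debris", "must be TRUE or FALSE")
  }
  s <- params$seed
  if (length(s) != 1 || !is.finite(s) || s != round(s)) {
    .fail_field("seed", "must be a single integer")
  }
  invisible(params)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n_animals: %d   seed: %d\n", x$n_animals, as.integer(x$seed)))
  cat(sprintf("  NB dispersion (size): %.3g\n", x$nb_dispersion))
  cat(sprintf("  logistic mortality: intercept %.3g, slope %.3g (per item/cm)\n",
              x$true_intercept, x$true_slope))
  cat(sprintf("  external hazard: %.3g\n", x$external_hazard))
  invisible(x)
}
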