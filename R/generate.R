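#' Generate a synthetic necropsy cohort
#'
#' Simulates one record per animal: age class and species are drawn from the
#' configured weights; curved carapace length (CCL) from a per-age-class
#' normal truncated to positive values; the debris count from a negative
#' binomial whose mean depends on age class and species; and the total debris
#' dry mass as a sum of independent lognormal per-item masses, floored at
#' 0.01 g when positive. Every record is a dead animal; the probability that
#' the death was caused by plastic is
#' `(1 - external_hazard) * plogis(intercept + age_offset + slope *
#' debris_count / ccl_cm)`, so the latent logistic curve is directly the
#' conditional-on-death dose-response the downstream analysis estimates,
#' discounted by the chance an external cause struck first even at a lethal
#' load. Plastic-caused deaths with debris present are
#' labelled KP with probability `label_kp_given_plastic`, otherwise Ind; a
#' plastic-caused death with no debris recovered cannot be recognised as such
#' and is labelled Ukn. External deaths are labelled KNP with probability
#' `label_knp_given_external`; when the cause stays unresolved the record is
#' labelled Ind if substantial debris (at least `ind_debris_threshold` items)
#' is present and Ukn otherwise, mirroring how the unknown and indeterminate
#' categories are defined at necropsy.
#'
#' @param params a [generator_params()] object.
#' @param seed optional seed overriding `params$seed`.
#' @return a `data.frame` with columns `animal_id`, `species`, `age_class`,
#'   `ccl_cm`, `cod`, `debris_count`, `debris_mass_g` (NA when no debris).
#' @examples
#' cohort <- generate_necropsy_cohort(generator_params(n_animals = 30))
#' table(cohort$cod)
#' @export
generate_necropsy_cohort <- function(params, seed = NULL) {
  validate_generator_params(params)
  set.seed(if (is.null(seed)) params$seed else seed)
  n <- params$n_animals
  if (n == 0) return(empty_necropsy_records())

  age <- sample(AGE_CLASSES, n, replace = TRUE, prob = params$age_class_weights)
  species <- sample(SPECIES_LEVELS, n, replace = TRUE,
                    prob = params$species_weights)

  ccl <- rtruncnorm_pos(n, params$ccl_mean_by_age[age], params$ccl_sd_by_age[age])

  mu <- params$nb_mu_by_age_species[cbind(match(age, AGE_CLASSES),
                                          match(species, SPECIES_LEVELS))]
  count <- stats::rnbinom(n, size = params$nb_dispersion, mu = mu)
  if (params$hatchling_zero_debris) count[age == "hatchling"] <- 0L

  mass <- vapply(count, function(k) {
    if (k == 0) return(NA_real_)
    max(sum(stats::rlnorm(k, params$mass_per_item_log_mean,
                          params$mass_per_item_log_sd)), 0.01)
  }, numeric(1))

  p_plastic <- stats::plogis(params$true_intercept +
                               params$true_age_offsets[age] +
                               params$true_slope * count / ccl)
  # every record is a death; the latent curve gives the probability that the
  # death was plastic-caused, discounted by the chance an external cause
  # struck first even at a lethal load
  plastic_death <- stats::runif(n) < (1 - params$external_hazard) * p_plastic

  cod <- label_cause(plastic_death, count, stats::runif(n), params)

  out <- data.frame(
    animal_id = sprintf("N%05d", seq_len(n)),
    species = species,
    age_class = age,
    ccl_cm = ccl,
    cod = cod,
    debris_count = as.integer(count),
    debris_mass_g = mass,
    stringsAsFactors = FALSE
  )
  validate_necropsy_records(out)
}

# Cause-of-death labelling. A plastic-caused death with debris present is
# definitively recognised (KP) with probability label_kp_given_plastic and
# otherwise recorded as indeterminate; with no debris recovered it cannot be
# recognised and falls into unknown. An external death is definitively
# attributed (KNP) with probability label_knp_given_external; otherwise the
# record is indeterminate when substantial debris (>= ind_debris_threshold
# items) is present and unknown when not -- unknowns carry at most low debris,
# indeterminates carry substantial debris, by definition of the categories.
label_cause <- function(plastic_death, count, u_label, params) {
  n <- length(plastic_death)
  cod <- character(n)
  sel <- plastic_death & count >= 1
  cod[sel] <- ifelse(u_label[sel] < params$label_kp_given_plastic, "KP", "Ind")
  cod[plastic_death & count == 0] <- "Ukn"
  ext <- !plastic_death
  cod[ext] <- ifelse(u_label[ext] < params$label_knp_given_external, "KNP",
                     ifelse(count[ext] >= params$ind_debris_threshold,
                            "Ind", "Ukn"))
  cod
}

# Normal truncated to (0, Inf) by resampling; sd may be 0 (degenerate).
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

empty_necropsy_records <- function() {
  data.frame(animal_id = character(0), species = character(0),
             age_class = character(0), ccl_cm = numeric(0),
             cod = character(0), debris_count = integer(0),
             debris_mass_g = numeric(0), stringsAsFactors = FALSE)
}

empty_strandnet_records <- function() {
  data.frame(record_id = character(0), debris_present = logical(0),
             exam_level = integer(0), adult = logical(0),
             cod = character(0), species = character(0),
             stringsAsFactors = FALSE)
}

#' Validate necropsy records
#'
#' Enforces the record invariants: positive CCL, non-negative counts, the
#' 0.01 g mass floor when debris is present, KP implying at least one debris
#' item, and valid enum values.
#'
#' @param records necropsy record `data.frame`.
#' @param line_offset added to the row number in error messages (use 1 for a
#'   file with a header row, so messages carry file line numbers).
#' @return the records, invisibly on validation, for chaining.
#' @export
validate_necropsy_records <- function(records, line_offset = 0L) {
  req <- c("animal_id", "species", "age_class", "ccl_cm", "cod",
           "debris_count", "debris_mass_g")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  row_fail <- function(rows, what) {
    stop(sprintf("invalid necropsy record (%s) at line %s", what,
                 paste(rows + line_offset, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(records$species %in% SPECIES_LEVELS))
  if (length(bad)) row_fail(bad, paste0("unparseable species '",
                                        records$species[bad[1]], "'"))
  bad <- which(!(records$age_class %in% AGE_CLASSES))
  if (length(bad)) row_fail(bad, paste0("unparseable age_class '",
                                        records$age_class[bad[1]], "'"))
  bad <- which(!(records$cod %in% COD_LEVELS))
  if (length(bad)) row_fail(bad, paste0("unparseable cod '",
                                        records$cod[bad[1]], "'"))
  bad <- which(!is.finite(records$ccl_cm) | records$ccl_cm <= 0)
  if (length(bad)) row_fail(bad, "ccl_cm must be > 0")
  bad <- which(is.na(records$debris_count) | records$debris_count < 0 |
                 records$debris_count != round(records$debris_count))
  if (length(bad)) row_fail(bad, "debris_count must be a non-negative integer")
  bad <- which(records$cod == "KP" & records$debris_count < 1)
  if (length(bad)) row_fail(bad, "cod KP requires debris_count >= 1")
  bad <- which(!is.na(records$debris_mass_g) & records$debris_count > 0 &
                 records$debris_mass_g < 0.01)
  if (length(bad)) row_fail(bad, "debris_mass_g below the 0.01 g floor")
  records
}

#' Validate stranding-register records
#'
#' @param records StrandNet-style record `data.frame`.
#' @param line_offset see [validate_necropsy_records()].
#' @return the records, invisibly on validation, for chaining.
#' @export
validate_strandnet_records <- function(records, line_offset = 0L) {
  req <- c("record_id", "debris_present", "exam_level", "adult", "cod",
           "species")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  row_fail <- function(rows, what) {
    stop(sprintf("invalid strandnet record (%s) at line %s", what,
                 paste(rows + line_offset, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(records$exam_level %in% 0:3))
  if (length(bad)) row_fail(bad, "exam_level must be in 0..3")
  bad <- which(!(records$cod %in% COD_LEVELS))
  if (length(bad)) row_fail(bad, paste0("unparseable cod '",
                                        records$cod[bad[1]], "'"))
  bad <- which(is.na(records$debris_present) | is.na(records$adult))
  if (length(bad)) row_fail(bad, "debris_present/adult must be TRUE or FALSE")
  bad <- which(!is.na(records$species) & !(records$species %in% SPECIES_LEVELS))
  if (length(bad)) row_fail(bad, paste0("unparseable species '",
                                        records$species[bad[1]], "'"))
  records
}

#' Generate synthetic stranding-register records
#'
#' Each record is backed by a latent animal drawn exactly as in
#' [generate_necropsy_cohort()]; its true debris presence is the dichotomised
#' debris count. The recorded presence flag is the truth filtered through an
#' examination-level detection probability: a record examined at level `l`
#' detects truly present debris with probability `detect_prob_by_level[l+1]`.
#' Records whose cause of death is KP are always recorded as debris-present
#' (a plastic-ingestion death implies the debris was seen). Age class is
#' reduced to a binary adult flag.
#'
#' @param params a [generator_params()] object (the latent-animal model).
#' @param n_records number of records to generate.
#' @param detect_prob_by_level 4 probabilities (levels 0-3), non-decreasing.
#' @param exam_level_weights sampling weights over examination levels 0-3;
#'   the default mirrors a register with 185/345/170/6 records at levels
#'   0/1/2/3.
#' @param seed optional seed overriding `params$seed`.
#' @return a `data.frame` with columns `record_id`, `debris_present`,
#'   `exam_level`, `adult`, `cod`, `species`, plus the latent truth in
#'   attribute `"true_presence"`.
#' @export
generate_strandnet_records <- function(params, n_records,
                                       detect_prob_by_level = c(0.1, 0.5, 0.8, 0.95),
                                       exam_level_weights = c(185, 345, 170, 6) / 706,
                                       seed = NULL) {
  validate_generator_params(params)
  if (length(detect_prob_by_level) != 4 || anyNA(detect_prob_by_level) ||
      any(detect_prob_by_level < 0) || any(detect_prob_by_level > 1)) {
    .fail_field("detect_prob_by_level", "must be 4 probabilities in [0,1]")
  }
  if (any(diff(detect_prob_by_level) < 0)) {
    .fail_field("detect_prob_by_level",
                "must be non-decreasing in examination level")
  }
  if (length(exam_level_weights) != 4 || any(exam_level_weights < 0) ||
      sum(exam_level_weights) <= 0) {
    .fail_field("exam_level_weights", "must be 4 non-negative weights")
  }
  if (length(n_records) != 1 || !is.finite(n_records) || n_records < 0 ||
      n_records != round(n_records)) {
    .fail_field("n_records", "must be a single non-negative integer")
  }
  set.seed(if (is.null(seed)) params$seed else seed)
  n <- n_records
  if (n == 0) return(empty_strandnet_records())

  age <- sample(AGE_CLASSES, n, replace = TRUE, prob = params$age_class_weights)
  species <- sample(SPECIES_LEVELS, n, replace = TRUE,
                    prob = params$species_weights)
  ccl <- rtruncnorm_pos(n, params$ccl_mean_by_age[age], params$ccl_sd_by_age[age])
  mu <- params$nb_mu_by_age_species[cbind(match(age, AGE_CLASSES),
                                          match(species, SPECIES_LEVELS))]
  count <- stats::rnbinom(n, size = params$nb_dispersion, mu = mu)
  if (params$hatchling_zero_debris) count[age == "hatchling"] <- 0L

  p_plastic <- stats::plogis(params$true_intercept +
                               params$true_age_offsets[age] +
                               params$true_slope * count / ccl)
  plastic_death <- stats::runif(n) < (1 - params$external_hazard) * p_plastic
  cod <- label_cause(plastic_death, count, stats::runif(n), params)

  exam_level <- sample(0:3, n, replace = TRUE, prob = exam_level_weights)
  true_presence <- count >= 1
  detected <- true_presence &
    (stats::runif(n) < detect_prob_by_level[exam_level + 1L])
  detected[cod == "KP"] <- TRUE

  out <- data.frame(
    record_id = sprintf("S%05d", seq_len(n)),
    debris_present = detected,
    exam_level = as.integer(exam_level),
    adult = age == "adult",
    cod = cod,
    species = species,
    stringsAsFactors = FALSE
  )
  attr(out, "true_presence") <- true_presence
  validate_strandnet_records(out)
}
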