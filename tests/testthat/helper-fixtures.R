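# Small programmatic fixtures shared across test files.

# Quick necropsy-record constructor with valid defaults.
make_necropsy <- function(debris_count,
                          cod,
                          ccl_cm = rep(40, length(debris_count)),
                          age_class = rep("juvenile", length(debris_count)),
                          species = rep("green", length(debris_count)),
                          debris_mass_g = ifelse(debris_count > 0,
                                                 pmax(0.02 * debris_count, 0.01),
                                                 NA_real_)) {
  data.frame(
    animal_id = sprintf("T%04d", seq_along(debris_count)),
    species = species,
    age_class = age_class,
    ccl_cm = ccl_cm,
    cod = cod,
    debris_count = as.integer(debris_count),
    debris_mass_g = debris_mass_g,
    stringsAsFactors = FALSE
  )
}

# Direct NB simulation of debris counts with cause assigned independently of
# the count model covariates; used as a generation-vs-fit oracle.
sim_counts_by_cause <- function(n, mu_by_cause, size,
                                cause_probs = c(Ukn = 0.45, KNP = 0.3,
                                                Ind = 0.15, KP = 0.1)) {
  cod <- sample(names(cause_probs), n, replace = TRUE, prob = cause_probs)
  counts <- stats::rnbinom(n, size = size, mu = mu_by_cause[cod])
  # a KP death requires debris; resample its count truncated to >= 1
  kp0 <- which(cod == "KP" & counts == 0)
  while (length(kp0) > 0) {
    counts[kp0] <- stats::rnbinom(length(kp0), size = size,
                                  mu = mu_by_cause["KP"])
    kp0 <- kp0[counts[kp0] == 0]
  }
  make_necropsy(counts, cod)
}

# Direct logistic simulation of stranding presence records: presence
# probability depends on cell-means cause effects, adult and exam terms.
sim_presence_by_cause <- function(n, b_cause, b_adult = -1, b_exam = 1,
                                  cause_probs = c(Ukn = 0.45, KNP = 0.3,
                                                  Ind = 0.15, KP = 0.1),
                                  p_adult = 0.2, p_exam = 0.7) {
  cod <- sample(names(cause_probs), n, replace = TRUE, prob = cause_probs)
  adult <- stats::runif(n) < p_adult
  exam_level <- ifelse(stats::runif(n) < p_exam,
                       sample(1:3, n, replace = TRUE), 0L)
  eta <- b_cause[cod] + b_adult * adult + b_exam * (exam_level > 0)
  data.frame(
    record_id = sprintf("R%04d", seq_len(n)),
    debris_present = stats::runif(n) < stats::plogis(eta),
    exam_level = as.integer(exam_level),
    adult = adult,
    cod = cod,
    species = "green",
    stringsAsFactors = FALSE
  )
}
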