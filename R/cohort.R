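# Virtual cohort construction and dataset simulation. The simulator replaces
# the mechanistic PBPK stage of the original study design with an empirical
# population model: covariate-adjusted log-normal individual parameters and
# combined residual error on the closed-form concentration profiles.

# Height lookup (cm) by age and gender; small race offsets for adults.
.base_height <- function(age, sex) {
  h <- ifelse(age <= 5, 110,
       ifelse(age <= 10, 140,
       ifelse(sex == "M",
              ifelse(age <= 20, 172, ifelse(age <= 30, 174, 169)),
              ifelse(age <= 20, 159, ifelse(age <= 30, 161, 155)))))
  h
}

.race_height_offset <- function(race, age) {
  ifelse(age < 18, 0,
         ifelse(race == "Japanese", -4, ifelse(race == "Chinese", -3, 1)))
}

#' Default sampling design
#'
#' The clinical sampling schedule: 14 time points over 0-12 h after a single
#' 600 ug inhaled dose (three successive 200 ug inhalations encoded as one
#' depot bolus at t = 0, their spacing being unreported).
#'
#' @param times Sampling times (h).
#' @param dose_amt Dose amount (ug).
#' @param dose_time Dose time (h).
#' @return A list of class `design_spec`.
#' @export
default_design <- function(times = c(0, 0.08, 0.17, 0.33, 0.50, 0.75, 1,
                                     1.5, 2, 4, 6, 8, 10, 12),
                           dose_amt = 600, dose_time = 0) {
  if (is.unsorted(times, strictly = TRUE)) stop("sampling times must be strictly increasing", call. = FALSE)
  if (dose_amt <= 0) stop("dose amount must be positive", call. = FALSE)
  structure(list(times = times, dose_amt = dose_amt, dose_time = dose_time),
            class = "design_spec")
}

#' Deterministic 32-subject virtual cohort
#'
#' Reproduces the margins of the virtual study population: 32 subjects,
#' 18 male / 14 female, 12 American Indian or Alaskan Native / 20 East Asian
#' (10 Japanese, 10 Chinese), ages drawn from the design set
#' \{5, 10, 20, 30, 65\} years with median 20.0, and BMI spanning the normal,
#' overweight and obese bands. Anthropometrics are deterministic package
#' constants approximating the published medians (the appendix table of
#' individual characteristics is not public).
#'
#' @return A tibble with columns `ID`, `AGE`, `SEX`, `RACE` (two-level),
#'   `SUBRACE`, `HT` (cm), `WT` (kg), `BMI` (kg/m^2).
#' @export
default_virtual_cohort <- function() {
  block6 <- function(age, bmis) {
    tibble::tibble(
      AGE = age,
      SEX = c("M", "M", "M", "F", "F", "F"),
      SUBRACE = c("AIAN", "Japanese", "Chinese", "AIAN", "Japanese", "Chinese"),
      bmi_target = bmis
    )
  }
  kids_bmi <- c(16.0, 16.5, 17.0, 16.2, 17.4, 18.0)
  adult_bmi6 <- c(20.5, 22.0, 26.5, 21.0, 28.0, 31.5)
  block20 <- tibble::tibble(
    AGE = 20,
    SEX = c("M", "M", "M", "M", "M", "M", "F", "F"),
    SUBRACE = c("AIAN", "AIAN", "Japanese", "Chinese", "AIAN", "Japanese",
                "AIAN", "Chinese"),
    bmi_target = c(20.0, 21.0, 21.3, 23.5, 25.5, 30.5, 21.5, 22.5)
  )
  cohort <- dplyr::bind_rows(
    block6(5, kids_bmi),
    block6(10, kids_bmi + 0.4),
    block20,
    block6(30, adult_bmi6),
    block6(65, adult_bmi6 + 0.5)
  )
  cohort <- cohort |>
    dplyr::mutate(
      ID = dplyr::row_number(),
      RACE = ifelse(.data$SUBRACE == "AIAN", "AmericanIndianAlaskanNative", "EastAsian"),
      HT = .base_height(.data$AGE, .data$SEX) +
        .race_height_offset(.data$SUBRACE, .data$AGE) +
        (dplyr::row_number() %% 3) - 1,
      WT = round(.data$bmi_target * (.data$HT / 100)^2, 1),
      BMI = round(.data$WT / (.data$HT / 100)^2, 1)
    ) |>
    dplyr::select("ID", "AGE", "SEX", "RACE", "SUBRACE", "HT", "WT", "BMI")
  tibble::as_tibble(cohort)
}

#' Default cohort composition rules
#'
#' Marginal composition used by [sample_cohort()]; defaults follow the
#' 32-subject virtual cohort margins.
#'
#' @param age_probs Named probabilities over the design ages.
#' @param female Probability of female gender.
#' @param race_probs Named probabilities over `AIAN`, `Japanese`, `Chinese`.
#' @param bmi_bands Adult probabilities of the normal / overweight / obese
#'   BMI bands.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(age_probs = c("5" = 6, "10" = 6, "20" = 8, "30" = 6, "65" = 6) / 32,
                        female = 14 / 32,
                        race_probs = c(AIAN = 12, Japanese = 10, Chinese = 10) / 32,
                        bmi_bands = c(normal = 0.6, overweight = 0.25, obese = 0.15)) {
  for (p in list(age_probs, race_probs, bmi_bands)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("composition proportions must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  if (female < 0 || female > 1) stop("female proportion must lie in [0, 1]", call. = FALSE)
  structure(list(age_probs = age_probs, female = female, race_probs = race_probs,
                 bmi_bands = bmi_bands), class = "cohort_spec")
}

# Per-subject random stream: fixed offsets off the master seed so that growing
# the cohort never reshuffles earlier subjects.
.subject_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i) + 7919 * as.numeric(salt)) %%
               2147483629)
}

#' Sample a random virtual cohort
#'
#' Draws subjects independently from the composition rules; reproducible for a
#' fixed seed, with per-subject streams so marginal frequencies converge to the
#' specification as `n` grows.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects (`>= 1`).
#' @param seed Integer master seed.
#' @return A cohort tibble (same columns as [default_virtual_cohort()]).
#' @export
sample_cohort <- function(spec = cohort_spec(), n, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  age <- numeric(n); sex <- character(n); sub <- character(n)
  ht <- numeric(n); bmi <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.subject_seed(seed, i))
    age[i] <- as.numeric(sample(names(spec$age_probs), 1, prob = spec$age_probs))
    sex[i] <- if (stats::runif(1) < spec$female) "F" else "M"
    sub[i] <- sample(names(spec$race_probs), 1, prob = spec$race_probs)
    ht[i] <- stats::rnorm(1, .base_height(age[i], sex[i]) +
                            .race_height_offset(sub[i], age[i]), 5)
    bmi[i] <- if (age[i] < 18) {
      stats::runif(1, 15, 19)
    } else {
      band <- sample(names(spec$bmi_bands), 1, prob = spec$bmi_bands)
      switch(band,
             normal = stats::runif(1, 18.5, 24.9),
             overweight = stats::runif(1, 25, 29.9),
             obese = stats::runif(1, 30, 35))
    }
  }
  wt <- round(bmi * (ht / 100)^2, 1)
  tibble::tibble(
    ID = seq_len(n), AGE = age, SEX = sex,
    RACE = ifelse(sub == "AIAN", "AmericanIndianAlaskanNative", "EastAsian"),
    SUBRACE = sub, HT = round(ht, 1), WT = wt,
    BMI = round(wt / (ht / 100)^2, 1))
}

#' Simulate an analysis-ready PK dataset
#'
#' For each subject, individual parameters are the covariate-adjusted typical
#' values times `exp(eta)` with `eta` drawn from the model's random-effect
#' covariance; observations are `y = f + (a + b f) * eps` with independent
#' standard-normal draws. Negative simulated concentrations are truncated at 0
#' and flagged (`TRUNC`). One dose record per subject at the design dose time.
#'
#' @param cohort Cohort tibble (see [default_virtual_cohort()]).
#' @param popmodel A [pop_model()].
#' @param design A [default_design()] specification.
#' @param seed Integer master seed; per-subject streams are derived by fixed
#'   offsets.
#' @return A `pk_dataset` tibble with NONMEM-style columns `ID`, `TIME`,
#'   `AMT`, `DV`, `EVID`, `MDV`, `TRUNC`, plus the cohort covariates, sorted by
#'   (`ID`, `TIME`) with the dose record first.
#' @export
simulate_dataset <- function(cohort, popmodel = default_pop_model(),
                             design = default_design(), seed = 1L) {
  en <- eta_names(popmodel)
  O <- omega_matrix(popmodel)
  R <- if (length(en)) chol(O) else NULL
  n <- nrow(cohort)
  eta <- matrix(0, n, length(en), dimnames = list(NULL, en))
  eps <- matrix(0, n, length(design$times))
  for (i in seq_len(n)) {
    set.seed(.subject_seed(seed, cohort$ID[i], salt = 1L))
    if (length(en)) eta[i, ] <- drop(stats::rnorm(length(en)) %*% R)
    eps[i, ] <- stats::rnorm(length(design$times))
  }
  th <- individual_parameters(popmodel, cohort, eta)
  f <- .conc_matrix(th[, .model_registry[[popmodel$model]]$pars, drop = FALSE],
                    design$times, design$dose_amt, design$dose_time, popmodel$model)
  y <- f + error_sd(popmodel, f) * eps
  trunc <- y < 0
  y[trunc] <- 0

  obs <- tibble::tibble(
    ID = rep(cohort$ID, each = length(design$times)),
    TIME = rep(design$times, n),
    AMT = 0, DV = as.vector(t(y)), EVID = 0L, MDV = 0L,
    TRUNC = as.vector(t(trunc))
  )
  dose <- tibble::tibble(ID = cohort$ID, TIME = design$dose_time,
                         AMT = design$dose_amt, DV = NA_real_,
                         EVID = 1L, MDV = 1L, TRUNC = FALSE)
  dat <- dplyr::bind_rows(dose, obs) |>
    dplyr::left_join(cohort, by = "ID") |>
    dplyr::arrange(.data$ID, .data$TIME, dplyr::desc(.data$EVID))
  attr(dat, "design") <- design
  attr(dat, "params") <- dplyr::bind_cols(tibble::tibble(ID = cohort$ID),
                                          tibble::as_tibble(th))
  class(dat) <- c("pk_dataset", class(tibble::tibble()))
  dat
}
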