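test_that("covariate-adjusted typical values follow the declared forms", {
  eff <- tibble::tibble(param = "Cl", covariate = "WT", type = "power",
                        beta = 0.75, ref_value = 70, level = NA_character_,
                        ref_level = NA_character_)
  expect_equal(typical_value(10, eff, list(WT = 140)), 10 * 2^0.75)
  expect_equal(10 * 2^0.75, 16.81793, tolerance = 1e-6)
  eff0 <- dplyr::mutate(eff, beta = 0)
  expect_equal(typical_value(10, eff0, list(WT = 140)), 10)
  expect_error(typical_value(10, eff, list(WT = -1)), "nonpositive")

  effc <- tibble::tibble(param = "ka", covariate = "SEX", type = "factor",
                         beta = -0.4, ref_value = NA, level = "F",
                         ref_level = "M")
  expect_equal(typical_value(2, effc, list(SEX = "M")), 2) # reference level
  expect_equal(typical_value(2, effc, list(SEX = "F")), 2 * exp(-0.4))
})

test_that("screening detects perfect association and stays calibrated under the null", {
  set.seed(51)
  covs <- data.frame(WT = runif(100, 40, 100), SEX = rep(c("M", "F"), 50))
  eta <- cbind(Cl = 0.01 * covs$WT - 0.7) # exact linear function of weight
  scr <- screen_covariates(eta, covs, candidates = c("WT", "SEX"))
  expect_lt(scr$p_value[scr$covariate == "WT"], 1e-10)
  expect_equal(scr$covariate[1], "WT") # sorted ascending by p

  # null calibration: p-values approximately uniform over replicates
  ps <- vapply(1:1000, function(r) {
    set.seed(1000 + r)
    e <- cbind(Cl = rnorm(60))
    screen_covariates(e, covs[1:60, , drop = FALSE], candidates = "WT")$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # constructed categorical null: identical values in both groups
  e2 <- cbind(Cl = rep(c(-1, 0, 1), 20))
  covs2 <- data.frame(SEX = rep(c("M", "F"), each = 30)[order(rep(1:30, 2))])
  e2 <- cbind(Cl = rep(c(-1, 0, 1), 20))
  covs2 <- data.frame(SEX = rep(c("M", "F"), 30))
  scr2 <- screen_covariates(e2, covs2, candidates = "SEX")
  expect_gt(scr2$p_value, 0.95)

  # constant covariates are excluded with a flag
  scr3 <- screen_covariates(cbind(Cl = rnorm(20)),
                            data.frame(RACE = rep("EastAsian", 20)),
                            candidates = "RACE")
  expect_true(is.na(scr3$p_value))
  expect_match(scr3$flag, "constant")
})

test_that("stepwise selection returns the base model for an empty candidate set", {
  pm <- onecmt_pm()
  dat <- simulate_dataset(sample_cohort(n = 20, seed = 61), pm, des13(), seed = 62)
  sel <- quiet(stepwise_select(
    dat, base_spec = onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
    candidates = tibble::tibble(parameter = character(), covariate = character()),
    settings = saem_settings(n_explore = 60, n_smooth = 30, seed = 63),
    n_is = 300))
  expect_equal(nrow(sel$trace), 0)
  expect_equal(nrow(sel$fit$spec$covariates), 0)
})

test_that("a duplicated covariate is never added on top of the original", {
  des <- default_design(times = c(0.08, 0.25, 0.5, 1, 1.5, 2, 3, 4))
  cov_tab <- tibble::tibble(param = "Cl", covariate = "WT", type = "power",
                            beta = 0.75, ref_value = 55, level = NA_character_,
                            ref_level = NA_character_)
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(ka = 0.2, Cl = 0.2), covariates = cov_tab,
                  error = c(a = 0.01, b = 0.1))
  coh <- sample_cohort(n = 100, seed = 71)
  coh$WT2 <- coh$WT # deterministic copy under another name
  dat <- simulate_dataset(coh, pm, des, seed = 72)
  sel <- quiet(stepwise_select(
    dat, base_spec = onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
    candidates = tibble::tibble(parameter = "Cl", covariate = c("WT", "WT2")),
    settings = saem_settings(n_explore = 80, n_smooth = 40, seed = 73),
    n_is = 500))
  eff <- sel$fit$spec$covariates
  expect_true("WT" %in% eff$covariate || "WT2" %in% eff$covariate)
  expect_false(all(c("WT", "WT2") %in% eff$covariate))
})

test_that("selection is invariant to candidate ordering", {
  des <- default_design(times = c(0.08, 0.25, 0.5, 1, 1.5, 2, 3, 4))
  cov_tab <- tibble::tibble(param = "Cl", covariate = "WT", type = "power",
                            beta = 0.75, ref_value = 55, level = NA_character_,
                            ref_level = NA_character_)
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(ka = 0.2, Cl = 0.2), covariates = cov_tab,
                  error = c(a = 0.01, b = 0.1))
  dat <- simulate_dataset(sample_cohort(n = 60, seed = 81), pm, des, seed = 82)
  cands <- tibble::tibble(parameter = "Cl", covariate = c("WT", "AGE", "SEX"))
  run <- function(cand_order) {
    sel <- quiet(stepwise_select(
      dat, base_spec = onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
      candidates = cand_order,
      settings = saem_settings(n_explore = 80, n_smooth = 40, seed = 83),
      n_is = 500))
    sort(paste(sel$fit$spec$covariates$param, sel$fit$spec$covariates$covariate))
  }
  expect_identical(run(cands), run(cands[c(3, 1, 2), ]))
})

test_that("confirmatory tests report Wald, normality and symmetry results", {
  # Wald arithmetic at the classic boundary
  expect_equal(2 * pnorm(-abs(1.96 / 1)), 0.04999579, tolerance = 1e-7)

  des <- default_design(times = c(0.08, 0.25, 0.5, 1, 1.5, 2, 3, 4))
  cov_tab <- tibble::tibble(param = "Cl", covariate = "WT", type = "power",
                            beta = 0.75, ref_value = 55, level = NA_character_,
                            ref_level = NA_character_)
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(ka = 0.2, Cl = 0.2), covariates = cov_tab,
                  error = c(a = 0.01, b = 0.1))
  dat <- simulate_dataset(sample_cohort(n = 60, seed = 91), pm, des, seed = 92)
  sp <- onecmt_spec(theta_init = c(ka = 1.5, Cl = 4),
                    covariates = dplyr::mutate(cov_tab, beta = 0))
  fit <- quiet(fit_saem(dat, sp, saem_settings(n_explore = 100, n_smooth = 50,
                                               seed = 93)))
  ct <- quiet(confirm_tests(fit))
  expect_equal(nrow(ct$wald), 1)
  expect_lt(ct$wald$p_value, 0.01) # the planted effect is confirmed
  expect_gt(ct$wald$beta, 0.4)
  expect_equal(nrow(ct$shapiro), 2)
  expect_true(all(ct$shapiro$p_value > 0 & ct$shapiro$p_value <= 1, na.rm = TRUE))
  expect_true(ct$symmetry$p_value > 0 && ct$symmetry$p_value <= 1)
})
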