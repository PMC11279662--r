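test_that("individual parameters apply log-normal random effects", {
  pm <- ident_pm()
  coh <- default_virtual_cohort()[1:4, ]
  th0 <- individual_parameters(pm, coh)
  expect_equal(unname(th0[1, ]), unname(pm$theta)) # eta = 0 -> typical values

  eta <- matrix(c(0.5, -0.3), 1, 2, dimnames = list(NULL, c("ka", "Cl")))
  th <- individual_parameters(pm, coh[1, ], eta)
  expect_equal(unname(th[1, "ka"]), pm$theta[["ka"]] * exp(0.5))
  expect_equal(unname(th[1, "Cl"]), pm$theta[["Cl"]] * exp(-0.3))

  # omega = 0 parameters never vary regardless of the simulator seed
  pm0 <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                   omega = c(Cl = 0.4), error = c(a = 0.01, b = 0.05))
  dat <- simulate_dataset(sample_cohort(n = 200, seed = 2), pm0,
                          default_design(times = c(1, 2)), seed = 3)
  ip <- attr(dat, "params")
  expect_true(all(ip$ka == 1.5) && all(ip$V1 == 10))
  expect_gt(sd(ip$Cl), 0)
  # Monte-Carlo mean of log theta_i near log theta_typ
  expect_lt(abs(mean(log(ip$Cl)) - log(4)), 3 * 0.4 / sqrt(200))
})

test_that("the conditional distribution matches a quadrature oracle", {
  pm <- pop_model(model = "1cmt", theta = c(ka = 2, Cl = 5, V1 = 20),
                  omega = c(Cl = 0.3), error = c(a = 0.02, b = 0.08))
  dat <- simulate_dataset(default_virtual_cohort()[1, ], pm, default_design(),
                          seed = 77)
  mc <- quiet(conditional_mcmc(pm, dat, n_samples = 4000, n_burn = 500, seed = 8))
  expect_true(mc$ok)

  fd <- salbupop:::.fit_data(dat)
  logpost <- function(e) {
    f <- predict_concentration(c(ka = 2, Cl = 5 * exp(e), V1 = 20), 600,
                               fd$times[[1]], model = "1cmt")$conc
    sum(dnorm(fd$y[[1]], f, 0.02 + 0.08 * f, log = TRUE)) +
      dnorm(e, 0, 0.3, log = TRUE)
  }
  gr <- seq(-1.2, 1.2, length.out = 2001)
  w <- exp(vapply(gr, logpost, numeric(1))); w <- w / sum(w)
  post_mean <- sum(gr * w)
  expect_lt(abs(mean(mc$samples[, "Cl"]) - post_mean), 0.02)
  expect_lt(abs(mc$mode - gr[which.max(w)]), 0.01)
})

test_that("conditional mass collapses as omega shrinks and EBEs recover eta", {
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(Cl = 1e-6), error = c(a = 0.05, b = 0.1))
  dat <- simulate_dataset(default_virtual_cohort()[1, ], pm, des13(), seed = 5)
  mc <- quiet(conditional_mcmc(pm, dat, n_samples = 500, n_burn = 200, seed = 6))
  expect_lt(sd(mc$samples[, "Cl"]), 1e-4)
  expect_lt(abs(mc$mode), 1e-4)

  # rich, nearly noise-free data at a known eta: the mode recovers it
  eta_true <- 0.25
  pm2 <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4 * exp(eta_true), V1 = 10),
                   error = c(a = 1e-15, b = 0))
  datr <- simulate_dataset(default_virtual_cohort()[1, ], pm2,
                           default_design(times = seq(0.25, 12, by = 0.25)), seed = 7)
  pm3 <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                   omega = c(Cl = 0.5), error = c(a = 1e-6, b = 1e-6))
  mc2 <- quiet(conditional_mcmc(pm3, datr, n_samples = 50, n_burn = 50, seed = 9))
  expect_lt(abs(mc2$mode - eta_true), 1e-4)
})

test_that("SAEM recovers parameters in the near-deterministic limit", {
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(ka = 1e-8, Cl = 1e-8), error = c(a = 1e-6, b = 0.02))
  dat <- simulate_dataset(sample_cohort(n = 20, seed = 5), pm, des13(), seed = 43)
  fit <- quiet(fit_saem(dat, onecmt_spec(),
                        settings = saem_settings(n_explore = 150, n_smooth = 100,
                                                 seed = 10)))
  expect_rel(fit$popmodel$theta[["ka"]], 1.5, 0.01)
  expect_rel(fit$popmodel$theta[["Cl"]], 4, 0.01)
  expect_rel(fit$error[["b"]], 0.02, 0.25)
})

test_that("SAEM estimates are invariant to dataset row order", {
  pm <- onecmt_pm()
  dat <- simulate_dataset(sample_cohort(n = 12, seed = 2), pm, des13(), seed = 3)
  st <- saem_settings(n_explore = 60, n_smooth = 30, seed = 4)
  sp <- onecmt_spec(theta_init = c(ka = 1.5, Cl = 4))
  f1 <- quiet(fit_saem(dat, sp, st))
  set.seed(99)
  shuffled <- dat[sample(nrow(dat)), ]
  f2 <- quiet(fit_saem(shuffled, sp, st))
  expect_equal(f1$popmodel$theta, f2$popmodel$theta, tolerance = 1e-12)
  expect_equal(f1$Omega, f2$Omega, tolerance = 1e-12)
})

test_that("the SAEM objective stabilizes in the smoothing phase", {
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  omega = c(ka = 0.2, Cl = 0.2), error = c(a = 1e-6, b = 0.02))
  dat <- simulate_dataset(sample_cohort(n = 8, seed = 5), pm, des13(), seed = 43)
  fit <- quiet(fit_saem(dat, onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
                        settings = saem_settings(n_explore = 120, n_smooth = 700,
                                                 step_power = 1, seed = 10)))
  expect_lt(diff(range(tail(fit$trace$m2ll_sa, 50))), 1)
})

test_that("the marginal likelihood collapses analytically without random effects", {
  pm <- pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
                  error = c(a = 0.02, b = 0.1))
  dat <- simulate_dataset(sample_cohort(n = 5, seed = 8), pm, des13(), seed = 9)
  m2 <- marginal_loglik(pm, dat, n_is = 10, seed = 1)
  obs <- dat[dat$EVID == 0, ]
  f <- rep(predict_concentration(pm$theta, 600, des13()$times, model = "1cmt")$conc, 5)
  # direct residual-density computation (per-subject f identical here)
  direct <- -2 * sum(dnorm(obs$DV, f, 0.02 + 0.1 * f, log = TRUE))
  expect_equal(as.numeric(m2), direct, tolerance = 1e-10)

  # duplicating one observation row shifts -2LL by its analytic per-point term
  extra <- obs[5, ]
  dat2 <- dplyr::arrange(dplyr::bind_rows(dat, extra), ID, TIME, dplyr::desc(EVID))
  m2b <- marginal_loglik(pm, dat2, n_is = 10, seed = 1)
  fi <- f[des13()$times == extra$TIME][1]
  expect_equal(as.numeric(m2b - m2),
               -2 * dnorm(extra$DV, fi, 0.02 + 0.1 * fi, log = TRUE),
               tolerance = 1e-10)
})

test_that("the importance-sampling likelihood is stable and scale-equivariant", {
  pm <- onecmt_pm(omega = c(ka = 0.15, Cl = 0.2))
  dat <- simulate_dataset(sample_cohort(n = 12, seed = 3), pm, des13(), seed = 4)
  m1 <- marginal_loglik(pm, dat, n_is = 5000, seed = 21)
  m2 <- marginal_loglik(pm, dat, n_is = 10000, seed = 22)
  expect_lt(abs(as.numeric(m1) - as.numeric(m2)), 0.5)

  # multiplying concentrations, dose and additive error by 10 shifts -2LL by
  # the measurement-scale Jacobian 2 n log(10)
  datx <- dat
  datx$DV <- datx$DV * 10
  datx$AMT <- datx$AMT * 10
  pmx <- pop_model(model = "1cmt", theta = pm$theta, omega = c(ka = 0.15, Cl = 0.2),
                   error = c(a = pm$error[["a"]] * 10, b = pm$error[["b"]]))
  mx <- marginal_loglik(pmx, datx, n_is = 5000, seed = 21)
  n_obs <- sum(dat$EVID == 0)
  expect_lt(abs(as.numeric(mx) - as.numeric(m1) - 2 * n_obs * log(10)), 1)

  # exact version in the no-random-effect collapse
  pm0 <- pop_model(model = "1cmt", theta = pm$theta, error = pm$error)
  pm0x <- pop_model(model = "1cmt", theta = pm$theta,
                    error = c(a = pm$error[["a"]] * 10, b = pm$error[["b"]]))
  d0 <- marginal_loglik(pm0, dat, n_is = 10, seed = 1)
  d0x <- marginal_loglik(pm0x, datx, n_is = 10, seed = 1)
  expect_equal(as.numeric(d0x - d0), 2 * n_obs * log(10), tolerance = 1e-8)
})

test_that("linearization standard errors are computable and calibrated", {
  # single-seed fit: RSE arithmetic and availability (the additive component
  # is kept large enough to be informed by the low late-time concentrations)
  pm <- onecmt_pm(omega = c(ka = 0.2, Cl = 0.2), error = c(a = 0.1, b = 0.05))
  dat <- simulate_dataset(sample_cohort(n = 32, seed = 13), pm, des13(), seed = 14)
  fit <- quiet(fit_saem(dat, onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
                        saem_settings(n_explore = 150, n_smooth = 100, seed = 15)))
  fit <- quiet(standard_errors(fit))
  expect_equal(fit$se$rse_pct, 100 * fit$se$se / abs(fit$se$estimate))
  expect_true(all(is.finite(fit$se$se[fit$se$term %in% c("ka", "Cl")])))
  expect_error(standard_errors(fit, method = "stochastic"))

  # replicate calibration: median linearization SE of Cl against the
  # empirical SD of the estimates (scaled-down replicate count)
  ests <- ses <- numeric(20)
  for (r in 1:20) {
    d <- simulate_dataset(sample_cohort(n = 32, seed = 100 + r), pm, des13(),
                          seed = 200 + r)
    f <- quiet(fit_saem(d, onecmt_spec(theta_init = c(ka = 1.5, Cl = 4)),
                        saem_settings(n_explore = 80, n_smooth = 40, seed = r)))
    f <- quiet(standard_errors(f))
    ests[r] <- f$popmodel$theta[["Cl"]]
    ses[r] <- f$se$se[f$se$term == "Cl"]
  }
  expect_gt(median(ses) / sd(ests), 0.5)
  expect_lt(median(ses) / sd(ests), 2)
})

test_that("residual error parameters are recovered within their uncertainty", {
  pm <- onecmt_pm(omega = c(ka = 0.15, Cl = 0.15), error = c(a = 0.1, b = 0.05))
  dat <- simulate_dataset(sample_cohort(n = 32, seed = 23), pm, des13(), seed = 24)
  sp <- onecmt_spec(theta_init = c(ka = 1.5, Cl = 4))
  fit <- quiet(fit_saem(dat, sp, saem_settings(n_explore = 250, n_smooth = 150,
                                               seed = 25)))
  fit <- quiet(standard_errors(fit))
  for (term in c("a", "b")) {
    est <- fit$se$estimate[fit$se$term == term]
    se <- fit$se$se[fit$se$term == term]
    expect_lt(abs(est - pm$error[[term]]), 3 * max(se, 0.1 * pm$error[[term]]))
  }
})
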