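test_that("micro constants follow the clearance parameterization", {
  k <- micro_constants(c(ka = 1, Cl = 10, V1 = 5, Q = 4, V2 = 2))
  expect_equal(unname(k), c(2, 0.8, 2))

  # zero intercompartmental flow is allowed as a limit
  k0 <- micro_constants(c(ka = 1, Cl = 10, V1 = 5, Q = 0, V2 = 2))
  expect_equal(unname(k0[c("k12", "k21")]), c(0, 0))

  # published-model values with the substituted central volume
  kr <- micro_constants(ref_params())
  expect_equal(unname(kr), c(24.33, 10.59, 10.59 / 0.0066), tolerance = 1e-12)
  expect_equal(unname(kr[["k21"]]), 1604.5455, tolerance = 1e-4)

  expect_error(micro_constants(c(ka = 1, Cl = -1, V1 = 5, Q = 4, V2 = 2)),
               "nonpositive")
  expect_error(structural_params(ka = 1, Cl = 0, V1 = 5, Q = 4, V2 = 2))
  expect_error(structural_params(ka = Inf, Cl = 1, V1 = 5, Q = 4, V2 = 2))
})

test_that("hybrid rates satisfy the sum/product identities", {
  # hand-solved quadratic for k10=2, k12=0.8, k21=2: lambda^2 - 4.8 lambda + 4
  p <- c(ka = 1, Cl = 10, V1 = 5, Q = 4, V2 = 2)
  hr <- hybrid_rates(p)
  expect_equal(unname(hr[["alpha"]]), (4.8 + sqrt(4.8^2 - 16)) / 2, tolerance = 1e-12)
  expect_equal(unname(hr[["beta"]]), (4.8 - sqrt(4.8^2 - 16)) / 2, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    th <- c(ka = 1, Cl = exp(runif(1, -2, 3)), V1 = exp(runif(1, -2, 3)),
            Q = exp(runif(1, -2, 3)), V2 = exp(runif(1, -2, 3)))
    k <- micro_constants(th); hr <- hybrid_rates(th)
    expect_equal(sum(hr), unname(k[["k10"]] + k[["k12"]] + k[["k21"]]),
                 tolerance = 1e-12)
    expect_equal(prod(hr), unname(k[["k10"]] * k[["k21"]]), tolerance = 1e-12)
    expect_true(hr[["alpha"]] >= hr[["beta"]] && hr[["beta"]] > 0)
  }

  # decoupled compartments: roots are exactly the micro constants
  hd <- hybrid_rates(c(ka = 1, Cl = 10, V1 = 5, Q = 0, V2 = 2))
  expect_equal(sort(unname(hd)), sort(c(2, 0)))
})

test_that("closed form matches the ODE oracle", {
  tt <- seq(0, 12, length.out = 50)
  check_one <- function(params, model) {
    cf <- predict_concentration(params, 600, tt, model = model)$conc
    od <- predict_concentration_ode(params, 600, tt, model = model,
                                    rtol = 1e-12, atol = 1e-14)$conc
    cmax <- max(od)
    meas <- od > 1e-6 * cmax # below this both solutions are numerically zero
    expect_lt(max(abs(cf - od)[meas] / od[meas]), 1e-8)
    expect_lt(max(abs(cf - od)), 1e-8 * cmax)
  }
  check_one(ref_params(), "2cmt")
  check_one(ident_pm()$theta, "2cmt")
  check_one(c(ka = 1.2, Cl = 5, V1 = 20), "1cmt")
  check_one(c(ka = 1.2, Cl = 5, V1 = 20, Q = 2, V2 = 40, Q2 = 0.5, V3 = 15), "3cmt")
  check_one(c(ka = 1.2, Cl = 5, V1 = 20, Q = 2, V2 = 40, tlag = 0.25), "2cmt_lag")

  set.seed(21)
  for (i in 1:20) {
    th <- c(ka = exp(runif(1, -1, 1.6)), Cl = exp(runif(1, 0, 3.4)),
            V1 = exp(runif(1, 0, 4)), Q = exp(runif(1, -0.7, 3)),
            V2 = exp(runif(1, 0, 4.6)))
    check_one(th, "2cmt")
  }
})

test_that("prediction is zero at the dose time and linear in dose", {
  tt <- c(0, 0.08, 0.5, 1, 4, 12)
  cf <- predict_concentration(ref_params(), 600, tt)
  expect_identical(cf$conc[1], 0)
  cf2 <- predict_concentration(ref_params(), 1200, tt)
  expect_equal(cf2$conc, 2 * cf$conc, tolerance = 1e-12)
  expect_error(predict_concentration(ref_params(), 600, c(-1, 2)), "time")
  expect_error(predict_concentration(ref_params(), 0, tt), "positive")
})

test_that("ODE form conserves mass", {
  tt <- seq(0, 12, length.out = 25)
  for (th in list(ref_params(), ident_pm()$theta)) {
    od <- predict_concentration_ode(th, 600, tt, rtol = 1e-11, atol = 1e-11)
    total <- od$a_depot + od$a_central + od$a_periph + od$a_elim
    expect_lt(max(abs(total - 600)), 1e-8 * 600)
  }
})

test_that("AUC to infinity equals dose over clearance", {
  for (th in list(ref_params(), ident_pm()$theta)) {
    f <- function(t) predict_concentration(th, 600, t)$conc
    auc <- integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 2000)$value
    expect_rel(auc, 600 / th[["Cl"]], 1e-6)
  }
})

test_that("the registry exposes the rival structures and lag variants", {
  expect_setequal(model_registry(),
                  c("1cmt", "2cmt", "3cmt", "1cmt_lag", "2cmt_lag", "3cmt_lag"))
  expect_equal(model_registry("3cmt")$pars,
               c("ka", "Cl", "V1", "Q", "V2", "Q2", "V3"))
  # lag shifts the profile without changing its shape
  th <- c(ka = 1.2, Cl = 5, V1 = 20, Q = 2, V2 = 40)
  tt <- seq(0.5, 6, by = 0.5)
  plain <- predict_concentration(th, 600, tt, model = "2cmt")$conc
  lagged <- predict_concentration(c(th, tlag = 0.5), 600, tt + 0.5,
                                  model = "2cmt_lag")$conc
  expect_equal(lagged, plain, tolerance = 1e-10)
})
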