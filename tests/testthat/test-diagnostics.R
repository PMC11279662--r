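test_that("individual weighted residuals vanish for noise-free data", {
  pm <- pop_model(model = "2cmt", theta = ident_pm()$theta,
                  error = c(a = 1e-12, b = 0))
  dat <- simulate_dataset(default_virtual_cohort()[1:5, ], pm, des13(), seed = 3)
  # evaluate at the generating model: IPRED == DV
  pm_eval <- pop_model(model = "2cmt", theta = ident_pm()$theta,
                       omega = c(Cl = 1e-6), error = c(a = 1e-6, b = 1e-6))
  fl <- quiet(evaluate_popmodel(pm_eval, dat, n_cond = 0))
  rt <- residual_table(fl, K_sim = 0)
  expect_lt(max(abs(rt$dv - rt$ipred)), 1e-5)
  expect_true(all(is.na(rt$npde)))
})

test_that("prediction distribution errors obey the clamped rank arithmetic", {
  pm <- ident_pm(omega = c(Cl = 0.2), error = c(a = 0.05, b = 0.1))
  dat <- simulate_dataset(default_virtual_cohort()[1:4, ], pm, des13(), seed = 5)
  fl <- quiet(evaluate_popmodel(pm, dat, n_cond = 0))
  rt <- residual_table(fl, K_sim = 2, seed = 6)
  allowed <- qnorm(c(0.25, 0.5, 0.75)) # K = 2 with midrank ties
  expect_true(all(vapply(rt$npde, function(z)
    any(abs(z - allowed) < 1e-12), logical(1))))
})

test_that("the outlier proportion matches its construction", {
  ip <- c(1, 2, 5, 10)
  err <- c(a = 0.1, b = 0.1)
  expect_equal(outlier_proportion(ip, ip, err), 0)
  g <- err["a"] + err["b"] * ip
  expect_equal(outlier_proportion(ip + 10 * g, ip, err), 1)
  # one of four displaced beyond the 90% band
  y <- ip; y[2] <- ip[2] + 2 * g[2]
  expect_equal(outlier_proportion(y, ip, err), 0.25)
})

test_that("information criteria implement the subject/observation penalties", {
  cen <- list(p_random = 4, p_fixed_only = 1)
  ic <- information_criteria(100, cen, 32, 448)
  expect_equal(ic[["AIC"]], 100 + 2 * 5)
  expect_equal(ic[["BIC"]], 100 + 5 * log(32))
  expect_equal(ic[["BICc"]], 100 + 4 * log(32) + 1 * log(448))
  # no observation-penalized parameters: BICc collapses to BIC
  cen0 <- list(p_random = 5, p_fixed_only = 0)
  ic0 <- information_criteria(100, cen0, 32, 448)
  expect_equal(ic0[["BICc"]], ic0[["BIC"]])
})

test_that("VPC percentiles degenerate correctly without variability", {
  pm <- pop_model(model = "2cmt", theta = ident_pm()$theta,
                  error = c(a = 1e-12, b = 0))
  dat <- simulate_dataset(default_virtual_cohort()[1:6, ], pm, des13(), seed = 7)
  pm_eval <- pop_model(model = "2cmt", theta = ident_pm()$theta,
                       omega = c(Cl = 1e-8), error = c(a = 1e-9, b = 1e-9))
  fl <- quiet(evaluate_popmodel(pm_eval, dat, n_cond = 0))
  vp <- vpc(fl, K_sim = 40, seed = 8)
  expect_lt(max(abs(vp$observed - vp$pi_med)), 1e-4)
  # band ordering within each bin
  wide <- tidyr::pivot_wider(vp[, c("bin_time", "prob", "observed")],
                             names_from = "prob", values_from = "observed")
  expect_true(all(wide$`0.1` <= wide$`0.5` & wide$`0.5` <= wide$`0.9`))
})

test_that("a misspecified structure violates the VPC bands more often", {
  pm <- ident_pm(omega = c(ka = 0.15, Cl = 0.2, V1 = 0.1, Q = 0.15, V2 = 0.15))
  dat <- simulate_dataset(sample_cohort(n = 40, seed = 9), pm, des13(), seed = 10)
  fl_true <- quiet(evaluate_popmodel(pm, dat, n_cond = 0))
  vp_true <- vpc(fl_true, K_sim = 120, seed = 11)
  fit1 <- quiet(fit_saem(dat, fit_spec(model = "1cmt", fixed = c(V1 = 10)),
                         saem_settings(n_explore = 120, n_smooth = 60, seed = 12)))
  vp_mis <- vpc(fit1, K_sim = 120, seed = 11)
  expect_gt(sum(vp_mis$outlier), sum(vp_true$outlier))
})

test_that("sparse bins are merged with a neighbor", {
  pm <- ident_pm(omega = c(Cl = 0.2))
  dat <- simulate_dataset(default_virtual_cohort()[1:6, ], pm, des13(), seed = 13)
  # give one subject an extra lonely time point
  extra <- dat[dat$EVID == 0 & dat$ID == 1, ][1, ]
  extra$TIME <- 0.6
  dat2 <- dplyr::arrange(dplyr::bind_rows(dat, extra), ID, TIME, dplyr::desc(EVID))
  class(dat2) <- class(dat)
  fl <- quiet(evaluate_popmodel(pm, dat2, n_cond = 0))
  vp <- vpc(fl, K_sim = 30, seed = 14)
  expect_false(0.6 %in% vp$bin_time)
  expect_match(attr(vp, "merged_bins"), "0.6", all = FALSE)
})

test_that("stratified summaries reduce to the pooled geometric summary", {
  dat <- simulate_dataset(sample_cohort(n = 30, seed = 15), default_pop_model(),
                          default_design(), seed = 16)
  ip <- attr(dat, "params")
  coh <- sample_cohort(n = 30, seed = 15)
  whole <- stratified_summary(ip[, c("ID", "Cl")], coh,
                              strata = list(all = function(d) rep("all", nrow(d))))
  pooled <- summarize_geometric(ip$Cl)
  expect_equal(whole$geo_mean, pooled[["geo_mean"]])
  expect_equal(whole$geo_sd, pooled[["geo_sd"]])

  # planted age effect: the young stratum has the higher clearance
  strat <- stratified_summary(ip[, c("ID", "Cl", "ka")], coh)
  young <- strat[strat$stratum_var == "age" & strat$stratum == "5-22" &
                   strat$parameter == "Cl", ]
  old <- strat[strat$stratum_var == "age" & strat$stratum == "23-65" &
                 strat$parameter == "Cl", ]
  expect_gt(young$geo_mean, old$geo_mean)

  # singleton stratum: geometric SD undefined, flagged
  s1 <- stratified_summary(ip[1, c("ID", "Cl")], coh[1, ],
                           strata = list(one = function(d) "only"))
  expect_true(is.na(s1$geo_sd))
  expect_match(s1$flag, "undefined")

  # empty declared level is reported with a flag
  s2 <- stratified_summary(ip[1:3, c("ID", "Cl")], coh[1:3, ],
                           strata = list(wt = function(d)
                             factor(rep("<=75 kg", nrow(d)),
                                    levels = c("<=75 kg", ">75 kg"))))
  expect_true(any(s2$flag == "empty stratum", na.rm = TRUE))
})
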