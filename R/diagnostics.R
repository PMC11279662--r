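# Model-evaluation surfaces: weighted residuals and NPDE, outlier proportion
# against the error-model prediction interval, visual predictive check, and
# information criteria.

# Symmetric inverse square root (eigen-based; permutation invariant).
.inv_sqrt <- function(V, ridge = 1e-8) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vals <- e$values
  flagged <- FALSE
  if (min(vals) < ridge * max(vals)) {
    vals <- vals + ridge * max(vals)
    flagged <- TRUE
  }
  W <- e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  attr(W, "ridged") <- flagged
  W
}

# Simulate replicate observation vectors for each subject under the fitted
# model. Returns list per subject: matrix [K x n_obs_i].
.simulate_replicates <- function(fit, K, seed) {
  fd <- fit$fd; spec <- fit$spec
  p <- length(spec$iiv)
  pars <- .model_registry[[spec$model]]$pars
  mu <- t(vapply(fit$dm$X, function(Xi) drop(Xi %*% fit$psi), numeric(p)))
  if (p == 1) mu <- matrix(mu, ncol = 1)
  R <- chol(fit$Omega)
  out <- lapply(seq_len(fd$n), function(i) matrix(NA_real_, K, length(fd$y[[i]])))
  set.seed(seed)
  th0 <- fit$popmodel$theta
  for (k in seq_len(K)) {
    eta <- matrix(stats::rnorm(fd$n * p), fd$n, p) %*% R
    th <- matrix(rep(th0, each = fd$n), fd$n, dimnames = list(NULL, names(th0)))
    th[, spec$iiv] <- exp(pmin(pmax(mu + eta, -30), 30))
    f <- .predict_all(fd, th[, pars, drop = FALSE], spec$model)
    for (i in seq_len(fd$n)) {
      g <- pmax(fit$error["a"] + fit$error["b"] * f[[i]], 1e-10)
      # same observation rule as the simulator: concentrations are physical
      # quantities, negative draws are truncated at 0
      out[[i]][k, ] <- pmax(f[[i]] + g * stats::rnorm(length(g)), 0)
    }
  }
  out
}

#' Residual table of a fitted model
#'
#' Per observation: `ipred` (conditional-mode prediction), `pred` (population
#' prediction), `iwres = (y - ipred)/g(ipred)`, simulation-based decorrelated
#' population residuals (`pwres`) and normalized prediction distribution
#' errors (`npde`). The decorrelation uses the symmetric matrix square root of
#' the per-subject simulated covariance (ridge-regularized, with a flag, when
#' singular); prediction distribution errors use a half-count continuity
#' correction and are clamped to `(1/(2K), 1 - 1/(2K))`.
#'
#' @param fit A `saem_fit`.
#' @param K_sim Simulation replicates (default 500). With `K_sim = 0` only
#'   `ipred`, `pred` (model prediction at zero random effects) and `iwres` are
#'   computed.
#' @param seed Integer seed for the simulation replicates.
#' @return A `salbu_residuals` tibble: `ID`, `time`, `dv`, `ipred`, `pred`,
#'   `iwres`, `pwres`, `npde`, `cov_ridged`.
#' @export
residual_table <- function(fit, K_sim = 500, seed = 1L) {
  fd <- fit$fd; spec <- fit$spec
  p <- length(spec$iiv)
  pars <- .model_registry[[spec$model]]$pars
  mu <- t(vapply(fit$dm$X, function(Xi) drop(Xi %*% fit$psi), numeric(p)))
  if (p == 1) mu <- matrix(mu, ncol = 1)
  th0 <- fit$popmodel$theta

  # individual predictions at the conditional modes
  th_i <- matrix(rep(th0, each = fd$n), fd$n, dimnames = list(NULL, names(th0)))
  th_i[, spec$iiv] <- exp(mu + fit$ebe)
  f_ind <- .predict_all(fd, th_i[, pars, drop = FALSE], spec$model)
  # population prediction at zero random effects
  th_p <- matrix(rep(th0, each = fd$n), fd$n, dimnames = list(NULL, names(th0)))
  th_p[, spec$iiv] <- exp(mu)
  f_pop0 <- .predict_all(fd, th_p[, pars, drop = FALSE], spec$model)

  rows <- vector("list", fd$n)
  sims <- if (K_sim > 0) .simulate_replicates(fit, K_sim, seed) else NULL
  for (i in seq_len(fd$n)) {
    y <- fd$y[[i]]
    ip <- f_ind[[i]]
    g <- pmax(fit$error["a"] + fit$error["b"] * ip, 1e-10)
    iwres <- (y - ip) / g
    if (is.null(sims)) {
      rows[[i]] <- tibble::tibble(ID = fd$ids[i], time = fd$times[[i]], dv = y,
                                  ipred = ip, pred = f_pop0[[i]], iwres = iwres,
                                  pwres = NA_real_, npde = NA_real_,
                                  cov_ridged = FALSE)
      next
    }
    S <- sims[[i]]
    mu_i <- colMeans(S)
    V <- stats::cov(S)
    W <- .inv_sqrt(V)
    ystar <- drop(W %*% (y - mu_i))
    pwres <- ystar
    Sstar <- t(W %*% (t(S) - mu_i))
    # midrank count of decorrelated simulations below the decorrelated
    # observation (ties, e.g. truncated zeros, count half)
    k <- rowSums(t(Sstar) < ystar) + 0.5 * rowSums(t(Sstar) == ystar)
    pde <- (k + 0.5) / K_sim
    pde <- pmin(pmax(pde, 1 / (2 * K_sim)), 1 - 1 / (2 * K_sim))
    rows[[i]] <- tibble::tibble(ID = fd$ids[i], time = fd$times[[i]], dv = y,
                                ipred = ip, pred = mu_i, iwres = iwres,
                                pwres = pwres, npde = stats::qnorm(pde),
                                cov_ridged = isTRUE(attr(W, "ridged")))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("salbu_residuals", class(out))
  out
}

#' Proportion of observations outside the error-model prediction interval
#'
#' Fraction of observations lying outside `ipred +- z * g(ipred)` where
#' `g(f) = a + b f` and `z` is the standard-normal quantile of
#' `(1 + level)/2` (default: 90% interval).
#'
#' @param observed,ipred Observation and individual-prediction vectors.
#' @param error Named vector `c(a = , b = )`.
#' @param level Interval level (default 0.90).
#' @return Fraction in `[0, 1]`.
#' @export
outlier_proportion <- function(observed, ipred, error, level = 0.90) {
  z <- stats::qnorm((1 + level) / 2)
  g <- pmax(error[["a"]] + error[["b"]] * ipred, 1e-10)
  mean(abs(observed - ipred) > z * g)
}

#' Visual predictive check
#'
#' Observed 10th/50th/90th percentiles per nominal-time bin against
#' simulation-based prediction intervals for each percentile (percentile of
#' per-replicate percentiles at the requested level). Bins with fewer than 3
#' observations are merged with their neighbor (recorded in the result).
#'
#' @param fit A `saem_fit`.
#' @param K_sim Number of replicate datasets (default 200).
#' @param seed Integer seed.
#' @param level Prediction-interval level (default 0.90).
#' @param probs Percentiles to track.
#' @return A `salbu_vpc` tibble: `bin_time`, `n_obs`, `prob`, `observed`,
#'   `pi_lo`, `pi_med`, `pi_hi`, `outlier`; attribute `merged_bins` logs
#'   merges.
#' @export
vpc <- function(fit, K_sim = 200, seed = 1L, level = 0.90,
                probs = c(0.1, 0.5, 0.9)) {
  fd <- fit$fd
  times_all <- unlist(fd$times)
  y_all <- unlist(fd$y)
  bins <- sort(unique(times_all))
  counts <- vapply(bins, function(b) sum(times_all == b), numeric(1))
  # merge sparse bins rightward (leftward for the last)
  bin_of <- stats::setNames(bins, as.character(bins))
  merged <- character()
  i <- 1
  while (i <= length(bins)) {
    b <- bins[i]
    n_b <- sum(counts[bin_of[as.character(bins)] == bin_of[as.character(b)]])
    if (n_b < 3 && length(bins) > 1) {
      tgt <- if (i < length(bins)) bins[i + 1] else bins[i - 1]
      merged <- c(merged, sprintf("%g->%g", b, tgt))
      bin_of[names(bin_of)[bin_of == b]] <- bin_of[as.character(tgt)]
    }
    i <- i + 1
  }
  grp <- bin_of[as.character(times_all)]
  sims <- .simulate_replicates(fit, K_sim, seed)
  simmat <- do.call(cbind, sims) # K x n_obs, columns in subject order
  stopifnot(ncol(simmat) == length(y_all))
  alpha <- (1 - level) / 2
  out <- list()
  for (b in unique(grp)) {
    sel <- grp == b
    obs_q <- stats::quantile(y_all[sel], probs, names = FALSE)
    rep_q <- apply(simmat[, sel, drop = FALSE], 1, stats::quantile,
                   probs = probs, names = FALSE)
    if (is.null(dim(rep_q))) rep_q <- matrix(rep_q, nrow = 1)
    for (j in seq_along(probs)) {
      qs <- stats::quantile(rep_q[j, ], c(alpha, 0.5, 1 - alpha), names = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        bin_time = as.numeric(b), n_obs = sum(sel), prob = probs[j],
        observed = obs_q[j], pi_lo = qs[1], pi_med = qs[2], pi_hi = qs[3],
        outlier = obs_q[j] < qs[1] | obs_q[j] > qs[3])
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$bin_time, .data$prob)
  attr(res, "merged_bins") <- merged
  attr(res, "level") <- level
  class(res) <- c("salbu_vpc", class(res))
  res
}

#' Information criteria for a mixed-effects fit
#'
#' `AIC = -2LL + 2p`; `BIC = -2LL + p log(N)`; the corrected
#' `BICc = -2LL + p_R log(N) + p_F log(n_obs)`, penalizing
#' random-effect-bearing parameters by the subject count and residual-error
#' parameters by the observation count.
#'
#' @param m2ll -2 log-likelihood.
#' @param census List with `p_random`, `p_fixed_only` (see
#'   [parameter_census()]).
#' @param n_subjects,n_obs Subject and observation counts.
#' @return Named vector `c(AIC, BIC, BICc)`.
#' @export
information_criteria <- function(m2ll, census, n_subjects, n_obs) {
  p <- census$p_random + census$p_fixed_only
  c(AIC = m2ll + 2 * p,
    BIC = m2ll + p * log(n_subjects),
    BICc = m2ll + census$p_random * log(n_subjects) +
      census$p_fixed_only * log(n_obs))
}

#' Individual parameter estimates of a fit
#'
#' Covariate-adjusted typical values times `exp(EBE)` per subject.
#'
#' @param fit A `saem_fit`.
#' @return Tibble: `ID` plus one column per structural parameter.
#' @export
individual_estimates <- function(fit) {
  spec <- fit$spec
  p <- length(spec$iiv)
  mu <- t(vapply(fit$dm$X, function(Xi) drop(Xi %*% fit$psi), numeric(p)))
  if (p == 1) mu <- matrix(mu, ncol = 1)
  th <- matrix(rep(fit$popmodel$theta, each = fit$fd$n), fit$fd$n,
               dimnames = list(NULL, names(fit$popmodel$theta)))
  th[, spec$iiv] <- exp(mu + fit$ebe)
  dplyr::bind_cols(tibble::tibble(ID = fit$fd$ids), tibble::as_tibble(th))
}

#' Stratified geometric summaries of individual parameters
#'
#' Geometric mean and geometric SD of each parameter within each stratum.
#' Default strata: age 5-22 vs 23-65 years, weight <= 75 vs > 75 kg, gender,
#' race. Strata of size 1 report an undefined geometric SD with a flag; empty
#' strata are omitted with a flag.
#'
#' @param params Tibble of per-subject parameters (e.g.
#'   [individual_estimates()]), `ID` column optional.
#' @param covariate_table Per-subject covariates, same row order.
#' @param strata Named list mapping stratum-variable names to functions of the
#'   covariate table returning a per-subject label; default as above.
#' @return Tibble: `stratum_var`, `stratum`, `parameter`, `n`, `geo_mean`,
#'   `geo_sd`, `flag`.
#' @export
stratified_summary <- function(params, covariate_table, strata = NULL) {
  if (is.null(strata)) {
    strata <- list(
      age = function(d) ifelse(d$AGE <= 22, "5-22", "23-65"),
      weight = function(d) ifelse(d$WT <= 75, "<=75 kg", ">75 kg"),
      gender = function(d) d$SEX,
      race = function(d) d$RACE
    )
  }
  pcols <- setdiff(names(params), "ID")
  out <- list()
  for (sv in names(strata)) {
    lab <- strata[[sv]](covariate_table)
    lvls <- if (is.factor(lab)) levels(lab) else unique(lab)
    for (lv in lvls) {
      sel <- lab == lv
      for (pc in pcols) {
        v <- params[[pc]][sel]
        n <- sum(sel)
        if (n == 0) {
          out[[length(out) + 1]] <- tibble::tibble(
            stratum_var = sv, stratum = lv, parameter = pc, n = 0L,
            geo_mean = NA_real_, geo_sd = NA_real_, flag = "empty stratum")
          next
        }
        gs <- summarize_geometric(v)
        out[[length(out) + 1]] <- tibble::tibble(
          stratum_var = sv, stratum = lv, parameter = pc, n = as.integer(n),
          geo_mean = gs[["geo_mean"]], geo_sd = gs[["geo_sd"]],
          flag = if (n == 1) "geometric SD undefined (n = 1)" else NA_character_)
      }
    }
  }
  dplyr::bind_rows(out)
}
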