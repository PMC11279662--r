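# Covariate screening (Pearson / one-way ANOVA on conditional random-effect
# samples), forward-backward stepwise selection against BICc, and confirmatory
# tests (Wald, Shapiro-Wilk, signed-rank symmetry).

#' Covariate-adjusted typical value for one subject
#'
#' Scalar convenience wrapper around the effect arithmetic: continuous effects
#' scale the typical value by `(cov/ref)^beta`, categorical ones by
#' `exp(beta)` off the reference level.
#'
#' @param theta_pop Population typical value (> 0).
#' @param effects Covariate-effect table (rows applying to this parameter):
#'   columns `type`, `beta`, `ref_value`, `level`, plus `covariate` naming the
#'   entry of `subject` to read.
#' @param subject Named list / one-row data frame of covariate values.
#' @return Adjusted typical value.
#' @export
typical_value <- function(theta_pop, effects, subject) {
  out <- theta_pop
  effects <- tibble::as_tibble(effects)
  for (i in seq_len(nrow(effects))) {
    x <- subject[[effects$covariate[i]]]
    if (effects$type[i] == "power") {
      if (x <= 0) stop("nonpositive continuous covariate", call. = FALSE)
      out <- out * (x / effects$ref_value[i])^effects$beta[i]
    } else {
      out <- out * exp(effects$beta[i] * as.numeric(x == effects$level[i]))
    }
  }
  out
}

#' Screen random-effect / covariate associations
#'
#' For every pair of a random effect and a candidate covariate, tests
#' association on per-subject conditional-distribution samples: Pearson's
#' correlation test for continuous covariates, one-way ANOVA for categorical
#' ones. With `L` conditional draws per subject the test is run per draw and
#' the median p-value is reported (less shrinkage-biased than testing the
#' modes). Pairs are returned sorted by ascending p-value.
#'
#' @param eta_samples Either a matrix of per-subject values (one draw, columns
#'   = random effects) or a list of such matrices (conditional draws).
#' @param covariate_table Data frame of per-subject covariates (same row order).
#' @param candidates Character vector of covariate columns to test; categorical
#'   vs continuous is decided by column type.
#' @return Tibble `parameter`, `covariate`, `test`, `p_value`, `flag`, sorted
#'   ascending by p; constant covariates are excluded with a flag.
#' @export
screen_covariates <- function(eta_samples, covariate_table,
                              candidates = c("AGE", "HT", "WT", "SEX", "RACE")) {
  if (!is.list(eta_samples)) eta_samples <- list(eta_samples)
  covariate_table <- as.data.frame(covariate_table)
  stopifnot(nrow(covariate_table) == nrow(eta_samples[[1]]))
  en <- colnames(eta_samples[[1]])
  res <- list()
  for (p in en) {
    for (cv in candidates) {
      x <- covariate_table[[cv]]
      if (is.null(x)) stop("missing covariate column: ", cv, call. = FALSE)
      categorical <- is.character(x) || is.factor(x) || is.logical(x)
      if (length(unique(x)) < 2) {
        res[[length(res) + 1]] <- tibble::tibble(
          parameter = p, covariate = cv, test = NA_character_,
          p_value = NA_real_, flag = "constant covariate")
        next
      }
      if (categorical && min(table(x)) < 2) {
        res[[length(res) + 1]] <- tibble::tibble(
          parameter = p, covariate = cv, test = NA_character_,
          p_value = NA_real_, flag = "level with < 2 subjects")
        next
      }
      ps <- vapply(eta_samples, function(m) {
        e <- m[, p]
        if (categorical) {
          stats::anova(stats::aov(e ~ factor(x)))[["Pr(>F)"]][1]
        } else {
          stats::cor.test(e, x)$p.value
        }
      }, numeric(1))
      res[[length(res) + 1]] <- tibble::tibble(
        parameter = p, covariate = cv,
        test = if (categorical) "anova" else "pearson",
        p_value = stats::median(ps), flag = NA_character_)
    }
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$p_value)
}

# Conditional eta draws of a fit as a list of per-subject matrices.
.cond_draws <- function(fit, L = 10) {
  ns <- length(fit$cond_eta)
  idx <- unique(round(seq(1, ns, length.out = min(L, ns))))
  fit$cond_eta[idx]
}

# Refit with one covariate effect added/removed; returns fit with -2LL/BICc.
# theta_init warm-starts the refit at the incumbent estimates (single mode).
.refit_with <- function(data, spec, cov_tab, settings, n_is, theta_init = NULL) {
  sp <- spec
  sp$covariates <- cov_tab
  if (!is.null(theta_init)) sp$theta_init <- theta_init
  f <- fit_saem(data, sp, settings)
  f <- loglik_importance(f, n_is = n_is, seed = settings$seed + 1L)
  g <- glance(f)
  list(fit = f, bicc = g$BICc)
}

# Candidate effect row for (parameter, covariate): power for numeric columns,
# factor contrasts against the most frequent level otherwise.
.candidate_effect <- function(param, covariate, covariate_table) {
  x <- covariate_table[[covariate]]
  if (is.numeric(x)) {
    tibble::tibble(param = param, covariate = covariate, type = "power",
                   beta = 0, ref_value = stats::median(x),
                   level = NA_character_, ref_level = NA_character_)
  } else {
    tb <- sort(table(x), decreasing = TRUE)
    ref <- names(tb)[1]
    tibble::tibble(param = param, covariate = covariate, type = "factor",
                   beta = 0, ref_value = NA_real_,
                   level = setdiff(names(tb), ref), ref_level = ref)
  }
}

#' Forward-backward stepwise covariate selection
#'
#' Forward phase: while any screened candidate has p below `alpha_add`, the
#' smallest-p candidate not yet attempted is added and kept only if the refit
#' lowers BICc. Backward phase: while any retained effect has Wald p above
#' `alpha_remove`, the highest-p effect not yet attempted is removed and the
#' removal kept only if it lowers BICc. The two phases iterate to a fixed
#' point (bounded revisits guard against cycling).
#'
#' @param data A `pk_dataset`.
#' @param base_spec A [fit_spec()] for the base (covariate-free) model.
#' @param candidates Tibble with columns `parameter`, `covariate` of candidate
#'   pairs, or character vector of covariate columns (crossed with all IIV
#'   parameters).
#' @param alpha_add,alpha_remove Inclusion / retention thresholds (default
#'   0.05).
#' @param settings [saem_settings()] used for every refit.
#' @param n_is Importance-sampling draws for each refit's likelihood.
#' @param max_steps Bound on total add/remove attempts.
#' @return List with `fit` (final `saem_fit`), `spec`, and `trace` (tibble log
#'   of every attempted step with p-value, BICc before/after and decision).
#' @export
stepwise_select <- function(data, base_spec = fit_spec(), candidates,
                            alpha_add = 0.05, alpha_remove = 0.05,
                            settings = saem_settings(n_explore = 150, n_smooth = 75),
                            n_is = 1000, max_steps = 40) {
  fd <- .fit_data(data)
  if (!is.data.frame(candidates)) {
    candidates <- tidyr::expand_grid(parameter = base_spec$iiv,
                                     covariate = candidates)
  }
  candidates <- tibble::as_tibble(candidates)
  cur <- .refit_with(data, base_spec, base_spec$covariates, settings, n_is)
  warm <- cur$fit$popmodel$theta[base_spec$iiv]
  trace <- list()
  included <- character() # "param:covariate" keys
  attempted_add <- character(); attempted_rm <- character()
  key <- function(p, cv) paste(p, cv, sep = ":")

  if (nrow(candidates) == 0) {
    return(list(fit = cur$fit, spec = base_spec,
                trace = tibble::tibble(step = integer(), action = character(),
                                       parameter = character(), covariate = character(),
                                       p_value = numeric(), bicc_before = numeric(),
                                       bicc_after = numeric(), accepted = logical())))
  }

  step <- 0
  repeat {
    changed <- FALSE
    # ---- forward ----
    repeat {
      scr <- screen_covariates(.cond_draws(cur$fit),
                               cur$fit$fd$subjects,
                               candidates = unique(candidates$covariate))
      scr <- dplyr::semi_join(scr,
                              dplyr::rename(candidates, parameter = "parameter"),
                              by = c("parameter", "covariate"))
      scr <- scr[!is.na(scr$p_value), , drop = FALSE]
      scr <- scr[!(key(scr$parameter, scr$covariate) %in% c(included, attempted_add)), ,
                 drop = FALSE]
      scr <- scr[scr$p_value < alpha_add, , drop = FALSE]
      if (!nrow(scr) || step >= max_steps) break
      cand <- scr[1, ]
      step <- step + 1
      attempted_add <- c(attempted_add, key(cand$parameter, cand$covariate))
      new_tab <- dplyr::bind_rows(cur$fit$spec$covariates,
                                  .candidate_effect(cand$parameter, cand$covariate,
                                                    fd$subjects))
      prop <- .refit_with(data, base_spec, new_tab, settings, n_is, warm)
      ok <- is.finite(prop$bicc) && prop$bicc < cur$bicc
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = step, action = "add", parameter = cand$parameter,
        covariate = cand$covariate, p_value = cand$p_value,
        bicc_before = cur$bicc, bicc_after = prop$bicc, accepted = ok)
      if (ok) {
        cur <- prop
        included <- c(included, key(cand$parameter, cand$covariate))
        attempted_rm <- character()
        changed <- TRUE
      }
    }
    # ---- backward ----
    repeat {
      if (!length(included) || step >= max_steps) break
      eff <- cur$fit$spec$covariates
      if (!nrow(eff)) break
      fit_se <- if (is.null(cur$fit$se)) standard_errors(cur$fit) else cur$fit
      cur$fit <- fit_se
      ct <- confirm_tests(fit_se)
      wald <- ct$wald
      wald$k <- key(wald$parameter, wald$covariate)
      wald <- wald[wald$k %in% included & !(wald$k %in% attempted_rm), , drop = FALSE]
      wald <- wald[order(-wald$p_value), , drop = FALSE]
      wald <- wald[!is.na(wald$p_value) & wald$p_value > alpha_remove, , drop = FALSE]
      if (!nrow(wald)) break
      cand <- wald[1, ]
      step <- step + 1
      attempted_rm <- c(attempted_rm, cand$k)
      new_tab <- eff[!(eff$param == cand$parameter & eff$covariate == cand$covariate), ,
                     drop = FALSE]
      prop <- .refit_with(data, base_spec, new_tab, settings, n_is, warm)
      ok <- is.finite(prop$bicc) && prop$bicc < cur$bicc
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = step, action = "remove", parameter = cand$parameter,
        covariate = cand$covariate, p_value = cand$p_value,
        bicc_before = cur$bicc, bicc_after = prop$bicc, accepted = ok)
      if (ok) {
        cur <- prop
        included <- setdiff(included, cand$k)
        attempted_add <- setdiff(attempted_add, cand$k)
        changed <- TRUE
      }
    }
    if (!changed || step >= max_steps) break
  }
  list(fit = cur$fit, spec = cur$fit$spec,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), action = character(),
                        parameter = character(), covariate = character(),
                        p_value = numeric(), bicc_before = numeric(),
                        bicc_after = numeric(), accepted = logical()))
}

#' Confirmatory tests of a fitted covariate model
#'
#' Wald tests (`p = 2 Phi(-|beta/SE|)`) for each covariate coefficient,
#' Shapiro-Wilk normality tests per random effect on the conditional modes,
#' and a Wilcoxon signed-rank symmetry-about-zero test on the individual
#' weighted residuals.
#'
#' @param fit A `saem_fit`; [standard_errors()] is run if needed (Wald is
#'   skipped with a flag for coefficients whose SE is undefined).
#' @return List of tibbles: `wald`, `shapiro`, `symmetry`.
#' @export
confirm_tests <- function(fit) {
  if (is.null(fit$se)) fit <- standard_errors(fit)
  spec <- fit$spec
  eff <- spec$covariates
  p <- length(spec$iiv)
  wald <- if (nrow(eff)) {
    se_beta <- fit$se$se[p + seq_len(nrow(eff))]
    beta <- fit$psi[p + seq_len(nrow(eff))]
    tibble::tibble(
      parameter = eff$param, covariate = eff$covariate,
      beta = unname(beta), se = se_beta,
      p_value = ifelse(is.na(se_beta), NA_real_,
                       2 * stats::pnorm(-abs(beta / se_beta))),
      flag = ifelse(is.na(se_beta), "SE undefined", NA_character_))
  } else {
    tibble::tibble(parameter = character(), covariate = character(),
                   beta = numeric(), se = numeric(), p_value = numeric(),
                   flag = character())
  }
  shapiro <- dplyr::bind_rows(lapply(seq_len(p), function(j) {
    e <- fit$ebe[, j]
    pv <- if (stats::sd(e) < 1e-12) NA_real_ else stats::shapiro.test(e)$p.value
    tibble::tibble(parameter = spec$iiv[j], p_value = pv)
  }))
  rt <- residual_table(fit, K_sim = 0)
  iw <- rt$iwres[is.finite(rt$iwres)]
  sym_p <- if (length(iw) >= 5 && stats::sd(iw) > 0) {
    suppressWarnings(stats::wilcox.test(iw, mu = 0)$p.value)
  } else NA_real_
  list(wald = wald, shapiro = shapiro,
       symmetry = tibble::tibble(statistic = "signed-rank about 0", p_value = sym_p))
}
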