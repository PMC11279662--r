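# Noncompartmental analysis: linear trapezoidal AUC (equal weighting),
# terminal-slope (lambda_z) selection by adjusted R-squared, per-subject
# metrics, and geometric summary statistics.

#' Linear trapezoidal AUC to the last sample
#'
#' Sum of linear trapezoids between consecutive points ("linear trapezoidal
#' linear", equal weighting).
#'
#' @param times Strictly increasing sampling times (h).
#' @param conc Nonnegative concentrations (ug/L).
#' @return AUC from the first to the last sample (ug*h/L).
#' @export
auc_trapezoid <- function(times, conc) {
  if (length(times) < 2) stop("at least 2 points are required", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Terminal elimination rate constant by adjusted-R-squared selection
#'
#' Fits ordinary least squares of log concentration on time for every candidate
#' terminal subset (the last k points, k = 3, ..., K, excluding the observed
#' Cmax point and zero concentrations) and keeps the subset maximizing adjusted
#' R-squared; when a larger subset comes within `tie_tol` of the best value the
#' larger subset is preferred (plateau rule, stabilizes the slope).
#' `lambda_z` is minus the selected slope.
#'
#' @param times,conc Concentration-time profile of one subject.
#' @param tie_tol Adjusted-R-squared plateau tolerance (default 1e-4).
#' @param max_points Upper bound on the candidate terminal-subset size (the
#'   last `max_points` samples; keeps dense profiles tractable).
#' @return A list of class `lambda_z_fit`: `lambda_z` (1/h), `adj_r2`,
#'   `n_points`, `intercept` (log scale), `t_half` (h), `ok` (logical; FALSE
#'   when no candidate has a negative slope or fewer than 3 usable points
#'   exist, in which case the numeric fields are `NA`).
#' @export
fit_lambda_z <- function(times, conc, tie_tol = 1e-4, max_points = 50) {
  stopifnot(length(times) == length(conc))
  imax <- which.max(conc)[1]
  keep <- seq_along(times) > imax & conc > 0
  tt <- times[keep]; cc <- conc[keep]
  fail <- list(lambda_z = NA_real_, adj_r2 = NA_real_, n_points = NA_integer_,
               intercept = NA_real_, t_half = NA_real_, ok = FALSE)
  class(fail) <- "lambda_z_fit"
  m <- length(tt)
  if (m < 3) return(fail)
  ly <- log(cc)
  best <- NULL
  for (k in 3:min(m, max_points)) {
    idx <- (m - k + 1):m
    x <- tt[idx]; y <- ly[idx]
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
    slope <- sxy / sxx
    if (!is.finite(slope) || slope >= 0) next
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
    ar2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || ar2 > best$adj_r2 + tie_tol ||
        (ar2 > best$adj_r2 - tie_tol && k > best$n_points)) {
      best <- list(lambda_z = -slope, adj_r2 = ar2, n_points = k,
                   intercept = mean(y) - slope * mean(x),
                   t_half = -log(2) / slope, ok = TRUE)
    }
  }
  if (is.null(best)) return(fail)
  class(best) <- "lambda_z_fit"
  best
}

#' Noncompartmental metrics for one subject
#'
#' Cmax and Tmax from the observed records (first occurrence on ties),
#' AUC0-last by linear trapezoids, AUC0-inf = AUC0-last + Clast/lambda_z using
#' the observed last positive concentration, and apparent clearance
#' Cl/F = dose / AUC0-inf. When the terminal fit fails, the extrapolated
#' quantities are `NA`.
#'
#' @param times,conc Observed profile (one subject).
#' @param dose Dose amount (ug).
#' @return One-row tibble: `cmax`, `tmax`, `auc_last`, `auc_inf`, `cl_f`,
#'   `lambda_z`, `t_half`, `lz_adj_r2`, `lz_n_points`, `lz_ok`.
#' @export
nca_subject <- function(times, conc, dose) {
  if (dose <= 0) stop("dose must be positive", call. = FALSE)
  imax <- which.max(conc)[1]
  auc_last <- auc_trapezoid(times, conc)
  lz <- fit_lambda_z(times, conc)
  pos <- which(conc > 0)
  clast <- if (length(pos)) conc[max(pos)] else NA_real_
  auc_inf <- if (lz$ok) auc_last + clast / lz$lambda_z else NA_real_
  tibble::tibble(
    cmax = conc[imax], tmax = times[imax],
    auc_last = auc_last, auc_inf = auc_inf,
    cl_f = if (lz$ok) dose / auc_inf else NA_real_,
    lambda_z = lz$lambda_z, t_half = lz$t_half,
    lz_adj_r2 = lz$adj_r2, lz_n_points = lz$n_points, lz_ok = lz$ok
  )
}

#' Noncompartmental analysis of a PK dataset
#'
#' Runs [nca_subject()] on every subject's observation records.
#'
#' @param data A `pk_dataset` tibble (see [simulate_dataset()] /
#'   [read_pkdataset()]).
#' @param dose Dose amount (ug); defaults to each subject's dose record.
#' @return A tibble with one row per subject (ID + NCA metrics).
#' @export
nca <- function(data, dose = NULL) {
  obs <- dplyr::filter(data, .data$EVID == 0)
  doses <- dplyr::filter(data, .data$EVID == 1) |>
    dplyr::select("ID", dose_amt = "AMT")
  obs |>
    dplyr::left_join(doses, by = "ID") |>
    dplyr::group_by(.data$ID) |>
    dplyr::group_modify(function(d, key) {
      nca_subject(d$TIME, d$DV, if (is.null(dose)) d$dose_amt[1] else dose)
    }) |>
    dplyr::ungroup()
}

#' Geometric mean and geometric SD
#'
#' `exp(mean(log x))` and `exp(sd(log x))` with the sample (n-1) standard
#' deviation.
#'
#' @param x Strictly positive values.
#' @return Named vector `c(geo_mean, geo_sd)`; `geo_sd` is `NA` for singletons.
#' @export
summarize_geometric <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no values to summarize", call. = FALSE)
  if (any(x <= 0)) stop("geometric summaries require positive values", call. = FALSE)
  c(geo_mean = exp(mean(log(x))),
    geo_sd = if (length(x) > 1) exp(stats::sd(log(x))) else NA_real_)
}
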