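# Structural kinetics: linear compartmental models with first-order absorption
# from an extravascular depot. Internal unit canon: amounts ug, volumes L,
# times h, concentrations ug/L.

#' Structural parameter set for the two-compartment model
#'
#' Builds and validates the structural parameter vector of the default
#' disposition model: first-order absorption (`ka`, 1/h) into a central
#' compartment of volume `V1` (L), linear elimination by clearance `Cl` (L/h),
#' and distribution to a peripheral compartment of volume `V2` (L) with
#' intercompartmental clearance `Q` (L/h). Bioavailability is absorbed into
#' the apparent parameters (Cl/F convention); no explicit F is carried.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param Cl Apparent clearance (L/h).
#' @param V1 Central volume of distribution (L).
#' @param Q Intercompartmental clearance (L/h).
#' @param V2 Peripheral volume of distribution (L).
#' @return A named numeric vector of class `structural_params`.
#' @examples
#' structural_params(ka = 3.71, Cl = 24.33, V1 = 1, Q = 10.59, V2 = 0.0066)
#' @export
structural_params <- function(ka, Cl, V1, Q, V2) {
  p <- c(ka = ka, Cl = Cl, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(p))) stop("structural parameters must be finite", call. = FALSE)
  if (any(p[c("ka", "Cl", "V1", "V2")] <= 0) || Q < 0) {
    stop("structural parameters must be strictly positive (Q may be 0 only as a limit)",
         call. = FALSE)
  }
  class(p) <- c("structural_params", "numeric")
  p
}

#' Micro rate constants of the two-compartment model
#'
#' Standard reparameterization of the clearance parameterization:
#' `k10 = Cl/V1`, `k12 = Q/V1`, `k21 = Q/V2`.
#'
#' @param params Named vector with `Cl`, `V1`, `Q`, `V2` (e.g. from
#'   [structural_params()]).
#' @return Named numeric vector `c(k10, k12, k21)` in 1/h.
#' @export
micro_constants <- function(params) {
  p <- unclass(params)
  if (any(!is.finite(p[c("Cl", "V1", "Q", "V2")]))) {
    stop("nonfinite structural parameter", call. = FALSE)
  }
  if (p[["Cl"]] <= 0 || p[["V1"]] <= 0 || p[["V2"]] <= 0 || p[["Q"]] < 0) {
    stop("nonpositive structural parameter", call. = FALSE)
  }
  c(k10 = p[["Cl"]] / p[["V1"]],
    k12 = p[["Q"]] / p[["V1"]],
    k21 = p[["Q"]] / p[["V2"]])
}

#' Hybrid (macro) rate constants of the two-compartment model
#'
#' The two disposition eigenvalues `alpha >= beta > 0`, the roots of
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`.
#'
#' @inheritParams micro_constants
#' @return Named numeric vector `c(alpha, beta)` in 1/h.
#' @export
hybrid_rates <- function(params) {
  k <- micro_constants(params)
  s <- k[["k10"]] + k[["k12"]] + k[["k21"]]
  p <- k[["k10"]] * k[["k21"]]
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- p / alpha  # numerically stable smaller root
  if (k[["k12"]] == 0) { # decoupled limit: roots are exactly {k10, k21}
    alpha <- max(k[["k10"]], k[["k21"]])
    beta <- min(k[["k10"]], k[["k21"]])
  }
  c(alpha = alpha, beta = beta)
}

# Registry of structural model tags. Each entry: parameter names (order used
# throughout), number of disposition compartments, lag flag.
.model_registry <- list(
  "1cmt"     = list(pars = c("ka", "Cl", "V1"), ncmt = 1L, lag = FALSE),
  "2cmt"     = list(pars = c("ka", "Cl", "V1", "Q", "V2"), ncmt = 2L, lag = FALSE),
  "3cmt"     = list(pars = c("ka", "Cl", "V1", "Q", "V2", "Q2", "V3"), ncmt = 3L, lag = FALSE),
  "1cmt_lag" = list(pars = c("ka", "Cl", "V1", "tlag"), ncmt = 1L, lag = TRUE),
  "2cmt_lag" = list(pars = c("ka", "Cl", "V1", "Q", "V2", "tlag"), ncmt = 2L, lag = TRUE),
  "3cmt_lag" = list(pars = c("ka", "Cl", "V1", "Q", "V2", "Q2", "V3", "tlag"), ncmt = 3L, lag = TRUE)
)

#' Structural model registry
#'
#' Names and parameterizations of the available structural models:
#' 1-, 2- and 3-compartment disposition, first-order absorption, linear
#' elimination, with optional absorption lag time (`*_lag` tags).
#'
#' @param tag Optional model tag; if missing, the available tags are returned.
#' @return Character vector of tags, or a list with `pars`, `ncmt`, `lag`.
#' @export
model_registry <- function(tag) {
  if (missing(tag)) return(names(.model_registry))
  entry <- .model_registry[[match.arg(tag, names(.model_registry))]]
  entry
}

# Relative perturbation applied to ka when it collides with a disposition
# eigenvalue; removable singularity of the poly-exponential solution.
.ka_tie_eps <- 1e-9

# Exponential-sum solution for central concentration after a single depot dose,
# vectorized over a parameter MATRIX (rows = subjects/draws, columns named as in
# the registry) and a common time grid. Works for 1/2/3 compartments via the
# eigenvalues of the (small) disposition matrix; for ncmt <= 2 these are closed
# form, for ncmt = 3 the cubic is solved per row.
#
# theta: numeric matrix; times: numeric vector (h, >= dose time); dose: list
# with time and amt. Returns matrix [nrow(theta) x length(times)] of ug/L.
.conc_matrix <- function(theta, times, dose_amt, dose_time = 0, tag = "2cmt") {
  entry <- .model_registry[[tag]]
  if (is.null(entry)) stop("unknown model tag: ", tag, call. = FALSE)
  if (any(times < dose_time)) stop("prediction times before dose time", call. = FALSE)
  if (dose_amt <= 0) stop("dose amount must be positive", call. = FALSE)
  theta <- as.matrix(theta)
  n <- nrow(theta)
  tt <- times - dose_time
  if (entry$lag) {
    # per-row lag: shift times; handled by evaluating at pmax(t - tlag, 0)
    tlag <- theta[, "tlag"]
  } else tlag <- rep(0, n)

  ka <- theta[, "ka"]
  V1 <- theta[, "V1"]
  k10 <- theta[, "Cl"] / V1

  nc <- entry$ncmt
  if (nc == 1L) {
    lam <- matrix(k10, n, 1)
    # residues of disposition unit-impulse response in concentration: 1/V1
    res <- matrix(1 / V1, n, 1)
  } else if (nc == 2L) {
    k12 <- theta[, "Q"] / V1
    k21 <- theta[, "Q"] / theta[, "V2"]
    s <- k10 + k12 + k21
    pr <- k10 * k21
    disc <- sqrt(pmax(s^2 - 4 * pr, 0))
    a <- (s + disc) / 2
    b <- pr / a
    deg <- (a - b) < 1e-9 * a  # coincident disposition eigenvalues: nudge apart
    deg[is.na(deg)] <- FALSE   # overflowing rows propagate NA concentrations
    a[deg] <- a[deg] * (1 + 1e-9)
    lam <- cbind(a, b)
    # unit-impulse central concentration: sum_j res_j exp(-lam_j t)
    res <- cbind((k21 - a) / (V1 * (b - a)), (k21 - b) / (V1 * (a - b)))
  } else {
    k12 <- theta[, "Q"] / V1
    k21 <- theta[, "Q"] / theta[, "V2"]
    k13 <- theta[, "Q2"] / V1
    k31 <- theta[, "Q2"] / theta[, "V3"]
    lam <- matrix(0, n, 3)
    res <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      # characteristic cubic of the 3-compartment disposition matrix
      a0 <- k10[i] * k21[i] * k31[i]
      a1 <- k10[i] * k31[i] + k21[i] * k31[i] + k21[i] * k13[i] +
        k10[i] * k21[i] + k31[i] * k12[i]
      a2 <- k10[i] + k12[i] + k13[i] + k21[i] + k31[i]
      if (!all(is.finite(c(a0, a1, a2)))) { # overflowing rate products
        lam[i, ] <- NA_real_; res[i, ] <- NA_real_
        next
      }
      rts <- sort(Re(polyroot(c(-a0, a1, -a2, 1))), decreasing = TRUE)
      rts <- pmax(rts, 1e-12)
      lam[i, ] <- rts
      res[i, ] <- vapply(seq_len(3), function(j) {
        lj <- rts[j]; others <- rts[-j]
        (k21[i] - lj) * (k31[i] - lj) /
          (V1[i] * prod(others - lj))
      }, numeric(1))
    }
  }

  # first-order input: convolution of ka*exp(-ka t) with impulse response;
  # term_j = res_j * ka/(ka - lam_j) * (exp(-lam_j t) - exp(-ka t))
  denom <- ka - lam
  tie <- abs(denom) < .ka_tie_eps * pmax(lam, ka)
  tie[is.na(tie)] <- FALSE # guarded rows propagate NA concentrations
  if (any(tie)) { # removable singularity: nudge ka
    ka <- ifelse(rowSums(tie) > 0, ka * (1 + .ka_tie_eps), ka)
    denom <- ka - lam
  }
  coefs <- res * (ka / denom) * dose_amt

  te <- outer(tlag, rep(1, length(tt)))
  tmat <- pmax(outer(rep(1, n), tt) - te, 0)
  out <- matrix(0, n, length(tt))
  for (j in seq_len(ncol(lam))) {
    out <- out + coefs[, j] * exp(-lam[, j] * tmat)
  }
  out <- out - rowSums(coefs) * exp(-ka * tmat)
  out[tmat == 0] <- 0
  pmax(out, 0)
}

#' Predict central-compartment concentrations
#'
#' Closed-form (poly-exponential) solution for the plasma concentration of the
#' selected structural model after a single extravascular dose into a depot at
#' `dose_time`, with first-order absorption of the full dose and linear
#' elimination. The prediction is linear in the dose amount and is exactly 0 at
#' the dose time.
#'
#' @param params Named parameter vector (see [model_registry()] for the names
#'   required by each `model`), e.g. from [structural_params()].
#' @param dose_amt Dose amount (ug).
#' @param times Numeric vector of times (h), all `>= dose_time`.
#' @param dose_time Time of administration (h), default 0.
#' @param model Structural model tag (default `"2cmt"`).
#' @return A tibble with columns `time` (h) and `conc` (ug/L).
#' @examples
#' p <- structural_params(ka = 3.71, Cl = 24.33, V1 = 1, Q = 10.59, V2 = 0.0066)
#' predict_concentration(p, dose_amt = 600, times = c(0, 0.08, 0.5, 1, 2))
#' @export
predict_concentration <- function(params, dose_amt, times, dose_time = 0,
                                  model = "2cmt") {
  entry <- .model_registry[[model]]
  if (is.null(entry)) stop("unknown model tag: ", model, call. = FALSE)
  if (any(times < dose_time)) stop("negative time relative to dose", call. = FALSE)
  need <- entry$pars
  if (!all(need %in% names(params))) {
    stop("missing parameters: ", paste(setdiff(need, names(params)), collapse = ", "),
         call. = FALSE)
  }
  th <- matrix(unclass(params)[need], nrow = 1, dimnames = list(NULL, need))
  cc <- .conc_matrix(th, times, dose_amt, dose_time, model)[1, ]
  tibble::tibble(time = times, conc = cc)
}

#' Predict concentrations by numerical ODE integration
#'
#' Integrates the depot/compartment mass-balance ODE system with
#' [deSolve::lsoda()] and returns central concentration plus all state amounts
#' (including cumulatively eliminated mass, so that total mass is conserved).
#' This is the ODE form of the same structural models as
#' [predict_concentration()]; the closed form is the production path.
#'
#' @inheritParams predict_concentration
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#' @return A tibble with `time`, `conc`, and amount columns `a_depot`,
#'   `a_central`, `a_periph` (and `a_periph2` for 3-compartment models),
#'   `a_elim`.
#' @export
predict_concentration_ode <- function(params, dose_amt, times, dose_time = 0,
                                      model = "2cmt", rtol = 1e-10, atol = 1e-10) {
  entry <- .model_registry[[model]]
  if (is.null(entry)) stop("unknown model tag: ", model, call. = FALSE)
  p <- as.list(unclass(params)[entry$pars])
  nc <- entry$ncmt
  tlag <- if (entry$lag) p$tlag else 0
  k10 <- p$Cl / p$V1
  k12 <- if (nc >= 2) p$Q / p$V1 else 0
  k21 <- if (nc >= 2) p$Q / p$V2 else 0
  k13 <- if (nc >= 3) p$Q2 / p$V1 else 0
  k31 <- if (nc >= 3) p$Q2 / p$V3 else 0
  deriv <- function(t, y, parms) {
    absorb <- if (t >= tlag) p$ka * y[1] else 0
    d1 <- -absorb
    d2 <- absorb - (k10 + k12 + k13) * y[2] + k21 * y[3] + k31 * y[4]
    d3 <- k12 * y[2] - k21 * y[3]
    d4 <- k13 * y[2] - k31 * y[4]
    d5 <- k10 * y[2]
    list(c(d1, d2, d3, d4, d5))
  }
  tt <- sort(unique(c(0, times - dose_time)))
  y0 <- c(dose_amt, 0, 0, 0, 0)
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL, rtol = rtol, atol = atol)
  idx <- match(times - dose_time, sol[, 1])
  out <- tibble::tibble(
    time = times,
    conc = pmax(sol[idx, 3] / p$V1, 0),
    a_depot = sol[idx, 2],
    a_central = sol[idx, 3],
    a_periph = sol[idx, 4],
    a_elim = sol[idx, 6]
  )
  if (nc >= 3) out$a_periph2 <- sol[idx, 5]
  out
}
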