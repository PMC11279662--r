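# Shared fixtures. All datasets are generated in code at test time.

# Published-model structural parameters (central volume substituted by 1 L).
ref_params <- function() {
  structural_params(ka = 3.71, Cl = 24.33, V1 = 1, Q = 10.59, V2 = 0.0066)
}

# Identifiable two-compartment model: both disposition phases visible on a
# 0-12 h schedule and concentrations well above the additive error floor.
ident_pm <- function(omega = c(ka = 0.2, Cl = 0.25, V1 = 0.15, Q = 0.2, V2 = 0.2),
                     error = c(a = 0.05, b = 0.10)) {
  pop_model(model = "2cmt",
            theta = c(ka = 1.5, Cl = 4, V1 = 10, Q = 3, V2 = 30),
            omega = omega, error = error)
}

# One-compartment fixture with the central volume fixed (the absorption /
# elimination flip-flop makes the free-V1 problem symmetric, so recovery-style
# checks pin V1).
onecmt_pm <- function(omega = c(ka = 0.2, Cl = 0.2), error = c(a = 0.01, b = 0.05)) {
  pop_model(model = "1cmt", theta = c(ka = 1.5, Cl = 4, V1 = 10),
            omega = omega, error = error)
}

onecmt_spec <- function(...) {
  fit_spec(model = "1cmt", fixed = c(V1 = 10), ...)
}

# Sampling schedule without the pre-dose time point (used where the
# zero-concentration row would only exercise the truncation rule).
des13 <- function() {
  default_design(times = c(0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4, 6, 8, 10, 12))
}

quiet <- function(expr) suppressWarnings(expr)

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
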