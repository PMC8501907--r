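# shared test helpers

expect_rel <- function(actual, expected, tol) {
  expect_true(
    all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-12)),
    label = sprintf("max rel err %.3g vs tol %.3g (actual %s, expected %s)",
                    max(abs(actual - expected) / pmax(abs(expected), 1e-12)),
                    tol, paste(signif(actual, 6), collapse = ","),
                    paste(signif(expected, 6), collapse = ","))
  )
}

est_of <- function(fit, term) {
  td <- tidy(fit)
  td$estimate[td$term == term]
}

se_of <- function(fit, term) {
  td <- tidy(fit)
  td$std.error[td$term == term]
}

# construct a variable-J record with a prescribed dCc/dA ratio: the larger
# root of r*(J - 4*aR)^2 = 12*Gamma_star*J (dCc/dA decreases in J there)
jf_for_dccda <- function(r, aR, Gamma_star) {
  B <- 8 * r * aR + 12 * Gamma_star
  (B + sqrt(B^2 - 64 * r^2 * aR^2)) / (2 * r)
}

# default-design true parameter sets, used by recovery loops
aq_truth <- list(A_sat = 25, phi_J = 0.05, theta_J = 0.85, R_d = 1.2)
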