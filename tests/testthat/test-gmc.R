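# variable-J mesophyll conductance and the dCc/dA reliability screen

test_that("the Harley relations evaluate as published", {
  d <- tibble::tibble(A_net = 10, C_i = 250, J_F = 100)
  fit <- fit_g_mc_variablej(d, Gamma_star = 40, R_light = 1)
  rec <- fit$extra$records
  expect_equal(rec$C_c, 40 * 188 / 56, tolerance = 1e-10)      # 134.2857
  expect_equal(rec$g_mc, 10 / (250 - 40 * 188 / 56),
               tolerance = 1e-10)                               # 0.086420
  expect_equal(rec$dCcdA, 12 * 40 * 100 / 56^2,
               tolerance = 1e-10)                               # 15.306
  expect_true(rec$reliable)
})

test_that("singular and non-physical records are excluded with reasons", {
  d <- tibble::tibble(A_net = c(10, 10), C_i = c(250, 100),
                      J_F = c(44, 100))
  fit <- fit_g_mc_variablej(d, Gamma_star = 40, R_light = 1)
  rec <- fit$extra$records
  expect_false(rec$valid[1]) # J_F = 4*(A+R): denominator collapse
  expect_match(rec$reason[1], "denominator")
  expect_false(rec$reliable[1])
  expect_false(rec$valid[2]) # C_c = 134.3 > C_i = 100
  expect_match(rec$reason[2], "non-physical")
})

test_that("exactly the records with dCcdA in [10, 50] enter the summary mean", {
  gs <- 40; R <- 1
  targets <- c(5, 9.99, 10, 15.3, 25, 49.99, 50, 50.01, 60)
  # aR chosen so that the boundary targets 10 and 50 come out as exact
  # floating-point values (J = 192 and 60 give 92160/9216 and 28800/576)
  A <- c(8, 9, 23, 11, 12, 13, 8, 15, 16)
  aR <- A + R
  J <- mapply(jf_for_dccda, targets, aR, MoreArgs = list(Gamma_star = gs))
  expect_identical(12 * gs * J[3] / (J[3] - 4 * aR[3])^2, 10)
  expect_identical(12 * gs * J[7] / (J[7] - 4 * aR[7])^2, 50)
  d <- tibble::tibble(
    A_net = c(A, 11), C_i = 2000,  # high C_i keeps every record physical
    J_F = c(J, 4 * (11 + R)))       # last record is exactly singular
  fit <- fit_g_mc_variablej(d, Gamma_star = gs, R_light = R)
  rec <- fit$extra$records
  expect_equal(rec$dCcdA[1:9], targets, tolerance = 1e-8)
  expect_equal(rec$reliable,
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                 FALSE))
  expect_false(rec$valid[10])
  expect_equal(fit$extra$g_mc_mean, mean(rec$g_mc[rec$reliable]))
  expect_equal(fit$stats$n_reliable, 5)
})

test_that("J_F can be computed from fluorescence with an explicit calibration", {
  d <- tibble::tibble(A_net = 10, C_i = 250, Q = 500, phi_PSII = 0.5)
  expect_error(fit_g_mc_variablej(d, Gamma_star = 40, R_light = 1),
               "calib")
  fit <- fit_g_mc_variablej(d, Gamma_star = 40, R_light = 1, calib = 0.4)
  expect_equal(fit$extra$records$J_F, 0.4 * 500 * 0.5)
})

test_that("the generator embeds a recoverable true g_mc", {
  d <- generate_synthetic_curve(curve_design("gmc_variablej", seed = 3))
  tp <- attr(d, "true_params")
  fit <- fit_g_mc_variablej(d, Gamma_star = tp$Gamma_star,
                            R_light = tp$R_light)
  rec <- fit$extra$records
  expect_rel(rec$g_mc[rec$valid], tp$g_mc, 1e-9)
})
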