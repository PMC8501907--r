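# FvCB CO2-response evaluation and A-Ci fitting

fvcb_p <- list(V_cmax = 100, J_max = 180, V_TPU = 12, R_d = 1.5,
               Gamma_star = 42, K_c = 404.9, K_o = 278.4, O = 210)

test_that("FvCB limitation rates honor their limits", {
  # at the compensation point both carboxylation-side rates vanish
  at_gs <- eval_fvcb_ci(fvcb_p, fvcb_p$Gamma_star)
  expect_equal(at_gs$A_c, 0)
  expect_equal(at_gs$A_j, 0)
  expect_equal(at_gs$A_mod, -fvcb_p$R_d)
  # high-CO2 asymptote of the RuBP-limited rate is J/4
  p <- modifyList(fvcb_p, list(V_TPU = Inf, V_cmax = 1e6))
  expect_equal(eval_fvcb_ci(p, 1e6)$A_mod, 180 / 4 - 1.5, tolerance = 1e-3)
  # hand-checked Rubisco-limited value: K_m chosen to make K_m total 1000-300
  p2 <- list(V_cmax = 100, J_max = 1e6, V_TPU = Inf, R_d = 0,
             Gamma_star = 42, K_c = 700, K_o = 1e12, O = 210)
  expect_equal(eval_fvcb_ci(p2, 300)$A_c, 100 * 258 / 1000)
  expect_error(eval_fvcb_ci(fvcb_p, -10), "positive")
})

test_that("the minimum rule and limitation labels are consistent", {
  ci <- seq(50, 1500, length.out = 300)
  md <- eval_fvcb_ci(fvcb_p, ci)
  expect_true(all(md$A_mod <= md$A_c - fvcb_p$R_d + 1e-12))
  expect_true(all(md$A_mod <= md$A_j - fvcb_p$R_d + 1e-12))
  expect_true(all(md$A_mod <= md$A_p - fvcb_p$R_d + 1e-12))
  # labels partition the axis into at most 3 contiguous runs
  runs <- rle(md$limitation)
  expect_lte(length(runs$values), 3)
})

test_that("noiseless A-Ci data are recovered within 1e-3 relative", {
  d <- generate_synthetic_curve(curve_design("aci", noise_sd = 0, seed = 2))
  truth <- attr(d, "true_params")
  fit <- fit_aci_response(d)
  expect_rel(est_of(fit, "V_cmax"), truth$V_cmax25, 1e-3)
  expect_rel(est_of(fit, "J_max"), truth$J_max25, 1e-3)
  expect_rel(est_of(fit, "V_TPU"), truth$V_TPU25, 1e-3)
  expect_rel(est_of(fit, "R_d"), truth$R_d25, 1e-3)
  expect_true(fit$extra$fit_TPU) # flattening heuristic saw the TPU plateau
})

test_that("a curve confined to the Rubisco branch flags J_max as unidentifiable", {
  p <- modifyList(fvcb_p, list(J_max = 500, V_TPU = Inf))
  ci <- seq(60, 260, length.out = 8)
  d <- tibble::tibble(C_i = ci, A_net = eval_fvcb_ci(p, ci)$A_mod,
                      T_leaf = 298.15)
  expect_warning(fit <- fit_aci_response(d, fit_TPU = FALSE),
                 "unidentifiable|standard error")
  expect_true(any(grepl("J_max", fit$stats$flags)) ||
                any(grepl("large_se", fit$stats$flags)))
})

test_that("NLS beats a coarse brute-force grid over (V_cmax, J, R_d)", {
  set.seed(9)
  d <- generate_synthetic_curve(
    curve_design("aci", true_params = list(V_TPU25 = Inf),
                 noise_sd = 0.5, seed = 9))
  fit <- fit_aci_response(d, fit_TPU = FALSE)
  kt <- photofit:::adjust_kinetics(tobacco_kinetics(), 298.15)
  K_m <- kt$K_c * (1 + kt$O / kt$K_o)
  grid <- expand.grid(V = seq(60, 140, length.out = 15),
                      J = seq(120, 240, length.out = 15),
                      R = seq(0, 4, length.out = 15))
  ssr_grid <- apply(grid, 1, function(p) {
    a <- pmin(p[1] * (d$C_i - kt$Gamma_star) / (d$C_i + K_m),
              p[2] * (d$C_i - kt$Gamma_star) / (4 * d$C_i + 8 * kt$Gamma_star))
    sum((d$A_net - (a - p[3]))^2)
  })
  expect_lte(fit$stats$ssr, min(ssr_grid))
})

test_that("fixed mesophyll conductance shifts the CO2 axis to the chloroplast", {
  # generate on the C_c basis, then present C_i = C_c + A/g_mc; fitting with
  # that same g_mc must recover the generating parameters
  g_mc <- 0.3
  p <- modifyList(fvcb_p, list(V_TPU = Inf))
  cc <- seq(50, 1200, length.out = 11)
  md <- eval_fvcb_ci(p, cc)
  d <- tibble::tibble(C_i = cc + md$A_mod / g_mc, A_net = md$A_mod,
                      T_leaf = 298.15)
  # at T_leaf = T_ref the 25 degC kinetics apply unscaled
  fit <- fit_aci_response(d, Gamma_star25 = 42, g_mc = g_mc,
                          fit_TPU = FALSE)
  expect_rel(fit$extra$kinetics_at_T$Gamma_star, 42, 1e-9)
  expect_rel(est_of(fit, "V_cmax"), 100, 1e-3)
  expect_rel(est_of(fit, "J_max"), 180, 1e-3)
})

test_that("the A-Ci plot overlays the limitation curves on the data", {
  d <- generate_synthetic_curve(curve_design("aci", seed = 5))
  gg <- autoplot(fit_aci_response(d))
  expect_s3_class(gg, "ggplot")
})
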