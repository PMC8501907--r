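# hydraulic vulnerability and pressure-volume curves

test_that("vulnerability model identities hold", {
  # the sigmoid passes through 50 % at psi = b
  expect_equal(eval_vuln("sigmoidal", list(a = 2, b = -2.5), -2.5), 50)
  # Weibull at tension b_w loses 1 - 1/e of conductivity
  expect_equal(eval_vuln("weibull", list(b_w = 2.7, c_w = 3), -2.7),
               100 * (1 - exp(-1)))
  # Weibull tension at 50 % equals b_w * log(2)^(1/c_w): numeric inversion
  p <- list(b_w = 2.2, c_w = 2.5)
  t50 <- uniroot(function(t) eval_vuln("weibull", p, -t) - 50,
                 c(0.01, 20), tol = 1e-12)$root
  expect_equal(t50, p$b_w * log(2)^(1 / p$c_w), tolerance = 1e-9)
})

test_that("noiseless sigmoidal data are recovered with derived thresholds", {
  d <- generate_synthetic_curve(curve_design("vuln", noise_sd = 0, seed = 1))
  fits <- fit_hydra_vuln_curve(d)
  sig <- fits$sigmoidal
  expect_rel(est_of(sig, "a"), 2, 1e-4)
  expect_rel(est_of(sig, "b"), -2.5, 1e-4)
  expect_equal(sig$extra$P_e, -1.5, tolerance = 1e-3)
  expect_equal(sig$extra$P_50, -2.5, tolerance = 1e-3)
  expect_equal(sig$extra$P_max, -3.5, tolerance = 1e-3)
  # tangent symmetry of the derived points around P_50
  expect_equal(sig$extra$P_e + sig$extra$P_max, 2 * sig$extra$P_50)
})

test_that("noiseless Weibull data are recovered", {
  d <- generate_synthetic_curve(
    curve_design("vuln", true_params = list(model = "weibull"),
                 noise_sd = 0, seed = 1))
  fit <- fit_hydra_vuln_curve(d, models = "weibull")$weibull
  expect_rel(est_of(fit, "b_w"), 2.7, 1e-4)
  expect_rel(est_of(fit, "c_w"), 3, 1e-4)
})

test_that("positive-tension input is auto-negated and bad input rejected", {
  d <- generate_synthetic_curve(curve_design("vuln", noise_sd = 0, seed = 1))
  d_pos <- dplyr::mutate(d, psi = -psi)
  expect_message(fits <- fit_hydra_vuln_curve(d_pos), "negating")
  expect_rel(est_of(fits$sigmoidal, "b"), -2.5, 1e-4)
  expect_error(
    fit_hydra_vuln_curve(tibble::tibble(psi = -(1:6), PLC = 40)),
    "identical")
  expect_error(
    fit_hydra_vuln_curve(tibble::tibble(psi = -(1:3),
                                        PLC = c(10, 50, 90))),
    "at least 5")
})

test_that("ideal PV data return the constructed osmotic and turgor parameters", {
  d <- generate_synthetic_curve(curve_design("pv", seed = 1))
  tp <- attr(d, "true_params")
  fit <- suppressWarnings(fit_pv_curve(d))
  expect_rel(est_of(fit, "pi_o"), tp$pi_o, 1e-3)
  expect_rel(est_of(fit, "RWC_TLP"), tp$RWC_TLP, 1e-3)
  # at the TLP psi equals the osmotic potential at that water content
  expect_rel(est_of(fit, "psi_TLP"), tp$pi_o * 100 / tp$RWC_TLP, 1e-3)
  expect_true(est_of(fit, "C_ft") > 0)
  expect_true(est_of(fit, "epsilon") > 0)
})

test_that("PV input order and degenerate thresholds are handled", {
  d <- generate_synthetic_curve(curve_design("pv", seed = 1))
  expect_error(fit_pv_curve(dplyr::arrange(d, RWC)), "decline")
  set.seed(8)
  noisy <- dplyr::mutate(d, psi = psi - abs(rnorm(dplyr::n(), 0, 0.01)))
  expect_warning(fit <- fit_pv_curve(noisy, r2_threshold = 1.0),
                 "best region")
  expect_true(is.finite(est_of(fit, "pi_o")))
})

test_that("mass-based input converts to relative water content", {
  d <- generate_synthetic_curve(curve_design("pv", seed = 1))
  dry <- 0.4; sat <- 1.4
  dm <- tibble::tibble(psi = d$psi, mass = dry + (sat - dry) * d$RWC / 100)
  fit <- suppressWarnings(fit_pv_curve(dm, dry_mass = dry, sat_mass = sat))
  expect_rel(est_of(fit, "pi_o"), -1.2, 1e-3)
  expect_error(fit_pv_curve(tibble::tibble(psi = -(1:8) / 4,
                                           mass = seq(1.4, 1, -0.05)[1:8])),
               "dry_mass")
})
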