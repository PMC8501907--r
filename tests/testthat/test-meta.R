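# batch fitting, compilation, sensitivity analysis

test_that("fit_many fits once per group and isolates failures", {
  d <- generate_synthetic_curve(curve_design("aq", n_curves = 4, seed = 7))
  fits <- fit_many(d, "curve_id", fit_aq_response)
  expect_equal(nrow(fits$groups), 4)
  expect_length(fits$failures, 0)

  # corrupt one group down to 2 points: it fails, the others succeed
  bad <- dplyr::bind_rows(
    dplyr::filter(d, curve_id != "curve_2"),
    dplyr::slice(dplyr::filter(d, curve_id == "curve_2"), 1:2))
  fits2 <- fit_many(bad, "curve_id", fit_aq_response)
  expect_equal(sum(fits2$groups$failed), 1)
  expect_match(fits2$failures$curve_2, "at least 6")
  expect_equal(sum(!fits2$groups$failed), 3)

  # a single group reproduces the direct call
  one <- dplyr::filter(d, curve_id == "curve_1")
  direct <- fit_aq_response(one)
  grouped <- fit_many(one, "curve_id", fit_aq_response)
  expect_equal(tidy(grouped$fits$curve_1), tidy(direct))

  expect_error(fit_many(d, "no_such_column", fit_aq_response), "absent")
})

test_that("compile_data extracts parameters, fitted values and graphs", {
  d <- generate_synthetic_curve(curve_design("aq", n_curves = 3, seed = 8))
  fits <- fit_many(d, "curve_id", fit_aq_response)
  params <- compile_data(fits, "parameters")
  expect_equal(nrow(params), 3 * 4) # 4 terms per curve
  expect_true(all(c("curve_id", "term", "estimate") %in% names(params)))
  fitted <- compile_data(fits, "fitted")
  expect_equal(nrow(fitted), nrow(d))
  graphs <- compile_data(fits, "graphs")
  expect_length(graphs, 3)
  expect_s3_class(graphs[[1]], "ggplot")
  expect_error(compile_data(fits, "bogus"), "parameters, fitted")
})

test_that("sensitivity grids have product size and record failures", {
  d <- generate_synthetic_curve(curve_design("aci", noise_sd = 0, seed = 3))
  grid <- suppressWarnings(analyze_sensitivity(
    d, fit_aci_response,
    factors = list(Gamma_star25 = seq(35, 55, length.out = 5),
                   g_mc = c(0.2, 0.35, 0.5, Inf)),
    fit_TPU = FALSE))
  expect_equal(nrow(grid), 20)
  expect_true(all(!grid$fit_failed))
  # the fitted V_cmax responds systematically to the assumed Gamma*:
  # overstating the compensation point drags the estimate down
  slice <- grid[grid$g_mc == Inf, ]
  slice <- slice[order(slice$Gamma_star25), ]
  expect_true(all(diff(slice$V_cmax) < 0))
  expect_gt(diff(range(slice$V_cmax)) / mean(slice$V_cmax), 0.01)
  expect_error(
    analyze_sensitivity(d, fit_aci_response,
                        factors = list(a = 1, b = 2, c = 3)),
    "1 or 2")
})

test_that("control coefficients and parameter effects follow their definitions", {
  ident <- function(data, p) p
  grid <- analyze_sensitivity(data.frame(x = 1), ident,
                              factors = list(p = c(0.5, 1, 1.1, 2)))
  out <- compute_sensitivity(grid, ref = list(p = 1))
  off <- !out$is_reference
  expect_equal(out$control_coefficient_p[off], rep(1, 3))
  expect_equal(out$parameter_effect[out$is_reference], 0)
  expect_true(is.na(out$control_coefficient_p[out$is_reference]))

  # constant output: zero effect everywhere
  const <- compute_sensitivity(
    analyze_sensitivity(data.frame(x = 1), function(data, p) 7,
                        factors = list(p = c(1, 2, 3))),
    ref = list(p = 2))
  expect_equal(const$parameter_effect, rep(0, 3))

  # quadratic output: finite-difference elasticity at p = 1.1 is 2.1
  sq <- compute_sensitivity(
    analyze_sensitivity(data.frame(x = 1), function(data, p) p^2,
                        factors = list(p = c(1, 1.1))),
    ref = list(p = 1))
  expect_equal(sq$control_coefficient_p[2], 2.1, tolerance = 1e-10)

  expect_error(compute_sensitivity(grid, ref = list(p = 0.7)),
               "not on the grid")
})

test_that("two-factor slices reproduce the one-factor run", {
  fn <- function(data, p, q) p^2 + 3 * q
  g2 <- compute_sensitivity(
    analyze_sensitivity(data.frame(x = 1), fn,
                        factors = list(p = c(1, 1.5, 2), q = c(2, 4))),
    ref = list(p = 1, q = 2))
  g1 <- compute_sensitivity(
    analyze_sensitivity(data.frame(x = 1), function(data, p) fn(data, p, 2),
                        factors = list(p = c(1, 1.5, 2))),
    ref = list(p = 1))
  slice <- g2[g2$q == 2, ]
  expect_equal(slice$parameter_effect, g1$parameter_effect)
  expect_equal(slice$control_coefficient_p, g1$control_coefficient_p)
  expect_equal(nrow(g2), 6)
})
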