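# FvCB forward simulation: parameter assembly and the C_c solver

test_that("make_parameters merges overrides and validates the vocabulary", {
  p <- make_parameters()
  expect_true(all(vapply(p$leaf, function(v) all(is.finite(v)), TRUE)))
  expect_true(all(vapply(p$env[c("C_air", "Q", "T_leaf", "O", "g_tc")],
                         is.finite, TRUE)))
  p2 <- make_parameters(list(V_cmax = 120))
  expect_equal(p2$leaf$V_cmax25, 120)
  changed <- setdiff(names(p$leaf), names(p2$leaf))
  expect_length(changed, 0)
  same <- setdiff(names(p$leaf), "V_cmax25")
  expect_equal(p$leaf[same], p2$leaf[same])
  expect_error(make_parameters(list(Vcmax = 120)), "V_cmax")
})

test_that("series conductance composition from stomatal component", {
  p <- make_parameters(list(g_sc = 0.3, g_mc = 0.6))
  expect_equal(p$env$g_tc, 1 / (1 / 0.3 + 1 / 0.6))
})

test_that("solver limits match closed forms", {
  # unlimited supply: C_c approaches C_air
  p <- make_parameters(list(g_tc = 1e6))
  sim <- solve_cc(p$leaf, p$env)
  expect_equal(sim$C_c, p$env$C_air, tolerance = 1e-3)
  # no photosynthetic capacity: pure respiration, C_c above ambient
  p0 <- make_parameters(list(V_cmax = 0, J_max = 0, V_TPU = Inf, Q = 0))
  sim0 <- solve_cc(p0$leaf, p0$env)
  R_d <- p0$leaf$R_d25
  expect_equal(sim0$A_net, -R_d, tolerance = 1e-8)
  expect_equal(sim0$C_c, p0$env$C_air + R_d / p0$env$g_tc,
               tolerance = 1e-6)
})

test_that("supply-demand residual is tiny and labels match the realized minimum", {
  set.seed(17)
  for (i in 1:100) {
    ov <- list(
      V_cmax = runif(1, 20, 150), J_max = runif(1, 40, 300),
      R_d = runif(1, 0.2, 3), g_mc = runif(1, 0.1, 1),
      C_air = runif(1, 150, 1000), Q = runif(1, 100, 2000),
      T_leaf = runif(1, 283, 313), g_tc = runif(1, 0.05, 0.5))
    p <- make_parameters(ov)
    sim <- solve_cc(p$leaf, p$env)
    expect_lt(abs(sim$residual), 1e-10)
    expect_equal(sim$limitation,
                 c("Ac", "Aj", "Ap")[which.min(c(sim$A_c, sim$A_j,
                                                 sim$A_p))])
    expect_true(sim$C_c > 0)
  }
})

test_that("assimilation is monotone and continuous in ambient CO2", {
  ca <- seq(100, 1200, by = 25)
  out <- simulate_photosynthesis(list(C_air = ca))
  expect_true(all(diff(out$A_net) > -1e-9))
  # jump bound from the supply line: |dA| <= g_tc * dC_air
  expect_true(all(abs(diff(out$A_net)) <= out$g_tc[1] * 25 + 1e-9))
})

test_that("simulation grids are Cartesian products with failure isolation", {
  out <- simulate_photosynthesis(list(C_air = c(200, 420, 800),
                                      Q = c(500, 1500)))
  expect_equal(nrow(out), 6)
  expect_true(all(!out$failed))
  # size-1 grid equals a direct solve
  one <- simulate_photosynthesis(list(C_air = 420))
  p <- make_parameters(list(C_air = 420))
  direct <- solve_cc(p$leaf, p$env)
  expect_equal(one$A_net, direct$A_net)
  expect_equal(one$C_c, direct$C_c)
  # a bad grid point is recorded, not fatal
  mixed <- simulate_photosynthesis(list(C_air = c(-5, 420)))
  expect_equal(nrow(mixed), 2)
  expect_true(mixed$failed[1] && !mixed$failed[2])
  expect_match(mixed$fail_message[1], "C_air")
})

test_that("a leaf-temperature plug-in overrides the environment value", {
  p <- make_parameters()
  hot <- solve_cc(p$leaf, p$env, t_leaf_fn = function(leaf, env) 308.15)
  expect_equal(hot$T_leaf, 308.15)
})
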