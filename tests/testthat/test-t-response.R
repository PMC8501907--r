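# temperature-response models: evaluation identities and fit recovery

test_that("exponential-family models return k_ref exactly at T_ref", {
  Tref <- 298.15
  cases <- list(
    list("arrhenius", list(k_ref = 100, E_a = 55000)),
    list("medlyn_peaked", list(k_ref = 100, E_a = 60000, H_d = 2e5,
                               dS = 650)),
    list("kruse", list(k_ref = 100, E_a_ref = 55000, dEa = -5e8)),
    list("mmrt", list(k_ref = 100, dH_act = 55000, dCp_act = -1500))
  )
  for (cs in cases) {
    expect_equal(eval_t_response(cs[[1]], cs[[2]], Tref), 100,
                 tolerance = 1e-12, label = cs[[1]])
  }
  # zero activation energy means a flat response
  expect_equal(
    eval_t_response("arrhenius", list(k_ref = 42, E_a = 0),
                    c(280, 300, 320)),
    rep(42, 3))
})

test_that("peaked-model numeric argmax matches the closed-form T_opt", {
  p <- list(k_ref = 1, E_a = 60000, H_d = 200000, dS = 650)
  grid <- seq(278, 328, by = 0.001)
  k <- eval_t_response("medlyn_peaked", p, grid)
  t_num <- grid[which.max(k)]
  t_closed <- t_opt_peaked(p$E_a, p$H_d, p$dS)
  expect_lt(abs(t_num - t_closed), 0.01)
  # unimodal when H_d > E_a: increasing then decreasing
  d <- diff(k)
  expect_equal(which(d < 0)[1] - 1, which.max(k) - 1)
  expect_true(all(d[seq_len(which.max(k) - 1)] > 0))
})

test_that("overflow regimes raise an informative error", {
  expect_error(
    eval_t_response("arrhenius", list(k_ref = 1, E_a = 1e9), 500),
    "non-finite")
})

test_that("noiseless Arrhenius data are recovered within 1e-4 relative", {
  Tk <- seq(278, 328, length.out = 11)
  d <- tibble::tibble(
    T_leaf = Tk,
    rate = eval_t_response("arrhenius", list(k_ref = 75, E_a = 55000), Tk))
  fit <- fit_t_response(d, models = "arrhenius")$arrhenius
  expect_rel(est_of(fit, "k_ref"), 75, 1e-4)
  expect_rel(est_of(fit, "E_a"), 55000, 1e-4)
})

test_that("quadratic fit reproduces the normal-equations solution to machine precision", {
  Tk <- seq(280, 320, length.out = 9)
  tc <- Tk - 273.15
  truth <- c(a = 2, b = 0.8, c = -0.01)
  d <- tibble::tibble(T_leaf = Tk,
                      rate = truth["a"] + truth["b"] * tc + truth["c"] * tc^2)
  fit <- fit_t_response(d, models = "quadratic")$quadratic
  # independent linear-in-parameters oracle via the normal equations
  X <- cbind(1, tc, tc^2)
  beta <- solve(t(X) %*% X, t(X) %*% d$rate)
  expect_equal(unname(est_of(fit, "a")), beta[1], tolerance = 1e-9)
  expect_equal(unname(est_of(fit, "b")), beta[2], tolerance = 1e-9)
  expect_equal(unname(est_of(fit, "c")), beta[3], tolerance = 1e-9)
})

test_that("kruse and mmrt round-trip their generating parameters", {
  Tk <- seq(278, 328, length.out = 11)
  pk <- list(k_ref = 60, E_a_ref = 52000, dEa = -6e8)
  dk <- tibble::tibble(T_leaf = Tk, rate = eval_t_response("kruse", pk, Tk))
  fk <- fit_t_response(dk, models = "kruse")$kruse
  expect_rel(est_of(fk, "k_ref"), pk$k_ref, 1e-3)
  expect_rel(est_of(fk, "E_a_ref"), pk$E_a_ref, 1e-3)
  expect_rel(est_of(fk, "dEa"), pk$dEa, 1e-3)

  pm <- list(k_ref = 80, dH_act = 60000, dCp_act = -2000)
  dm <- tibble::tibble(T_leaf = Tk, rate = eval_t_response("mmrt", pm, Tk))
  fm <- fit_t_response(dm, models = "mmrt")$mmrt
  expect_rel(est_of(fm, "k_ref"), pm$k_ref, 1e-3)
  expect_rel(est_of(fm, "dH_act"), pm$dH_act, 1e-3)
  expect_rel(est_of(fm, "dCp_act"), pm$dCp_act, 1e-3)
})

test_that("too few observations fail the model's precondition without blocking others", {
  d <- tibble::tibble(T_leaf = c(290, 300, 305, 310),
                      rate = c(10, 20, 26, 30))
  fits <- fit_t_response(d, models = c("arrhenius", "heskel"))
  expect_true(fits$arrhenius$stats$converged)   # 2 params, 4 >= 4 obs
  expect_true(fits$heskel$stats$failed)          # 3 params need >= 5
  expect_match(fits$heskel$stats$message, "at least 5")
})

test_that("AIC ordering of the polynomial models survives affine T rescaling", {
  set.seed(11)
  Tk <- seq(278, 328, length.out = 12)
  rate <- eval_t_response("heskel", list(a = 1.4, b = 0.12, c = -0.001),
                          Tk) + rnorm(12, 0, 0.5)
  rate <- pmax(rate, 0.1)
  d1 <- tibble::tibble(T_leaf = Tk, rate = rate)
  d2 <- tibble::tibble(T_leaf = 2 * (Tk - 300) + 300, rate = rate)
  g1 <- glance(fit_t_response(d1, models = c("heskel", "quadratic")))
  g2 <- glance(fit_t_response(d2, models = c("heskel", "quadratic")))
  expect_equal(order(g1$aic), order(g2$aic))
})

test_that("NLS beats a coarse brute-force grid (heskel)", {
  set.seed(21)
  Tk <- seq(280, 325, length.out = 12)
  truth <- list(a = 1.5, b = 0.1, c = -0.0008)
  d <- tibble::tibble(
    T_leaf = Tk,
    rate = eval_t_response("heskel", truth, Tk) + rnorm(12, 0, 0.4))
  d$rate <- pmax(d$rate, 0.05)
  fit <- fit_t_response(d, models = "heskel")$heskel
  grid <- expand.grid(a = seq(0.5, 2.5, length.out = 20),
                      b = seq(0.02, 0.2, length.out = 20),
                      c = seq(-0.002, 0, length.out = 20))
  tc <- d$T_leaf - 273.15
  ssr_grid <- apply(grid, 1, function(p) {
    sum((d$rate - exp(p[1] + p[2] * tc + p[3] * tc^2))^2)
  })
  expect_lte(fit$stats$ssr, min(ssr_grid))
})
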