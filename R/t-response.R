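# Temperature responses of biological rates.
#
# Seven models are available, spanning the forms in common ecophysiological
# use: simple Arrhenius, two peaked (deactivating) variants, the Heskel
# log-polynomial, a plain quadratic, the Kruse modified-Arrhenius and
# macromolecular rate theory (MMRT). All exponential-family models are
# anchored so that k(T_ref) = k_ref exactly.

#' Names of the available temperature-response models
#' @return character vector of model ids.
#' @export
t_response_models <- function() {
  c("arrhenius", "medlyn_peaked", "topt_peaked", "heskel", "quadratic",
    "kruse", "mmrt")
}

.t_response_npar <- c(
  arrhenius = 2, medlyn_peaked = 4, topt_peaked = 4, heskel = 3,
  quadratic = 3, kruse = 3, mmrt = 3
)

# raw model functions; p is a named list, T_leaf in Kelvin
.t_response_fn <- function(model) {
  switch(model,
    arrhenius = function(p, T_leaf) {
      p$k_ref * exp(p$E_a * (T_leaf - p$T_ref) / (p$T_ref * R_GAS * T_leaf))
    },
    medlyn_peaked = function(p, T_leaf) {
      kern <- p$k_ref *
        exp(p$E_a * (T_leaf - p$T_ref) / (p$T_ref * R_GAS * T_leaf))
      kern * (1 + exp((p$T_ref * p$dS - p$H_d) / (p$T_ref * R_GAS))) /
        (1 + exp((T_leaf * p$dS - p$H_d) / (T_leaf * R_GAS)))
    },
    topt_peaked = function(p, T_leaf) {
      num <- p$H_d * exp(p$E_a * (T_leaf - p$T_opt) /
                           (T_leaf * R_GAS * p$T_opt))
      den <- p$H_d - p$E_a * (1 - exp(p$H_d * (T_leaf - p$T_opt) /
                                        (T_leaf * R_GAS * p$T_opt)))
      p$k_opt * num / den
    },
    heskel = function(p, T_leaf) {
      tc <- T_leaf - T0_K
      exp(p$a + p$b * tc + p$c * tc^2)
    },
    quadratic = function(p, T_leaf) {
      tc <- T_leaf - T0_K
      p$a + p$b * tc + p$c * tc^2
    },
    kruse = function(p, T_leaf) {
      x <- (1 / p$T_ref - 1 / T_leaf) / R_GAS
      p$k_ref * exp(p$E_a_ref * x + (p$dEa / 2) * x^2)
    },
    mmrt = function(p, T_leaf) {
      # anchored at T_ref: the activation entropy is absorbed into k_ref
      lnk <- log(p$k_ref) +
        p$dH_act * (1 / (R_GAS * p$T_ref) - 1 / (R_GAS * T_leaf)) +
        p$dCp_act * (log(T_leaf / p$T_ref) / R_GAS -
                       (T_leaf - p$T_ref) / (R_GAS * T_leaf))
      exp(lnk)
    },
    abort(paste0("unknown temperature-response model: ", model))
  )
}

.t_response_terms <- function(model) {
  switch(model,
    arrhenius = c("k_ref", "E_a"),
    medlyn_peaked = c("k_ref", "E_a", "H_d", "dS"),
    topt_peaked = c("k_opt", "T_opt", "E_a", "H_d"),
    heskel = c("a", "b", "c"),
    quadratic = c("a", "b", "c"),
    kruse = c("k_ref", "E_a_ref", "dEa"),
    mmrt = c("k_ref", "dH_act", "dCp_act")
  )
}

#' Evaluate a temperature-response model
#'
#' @param model one of [t_response_models()].
#' @param params named list of parameters. Required fields by model:
#'   `arrhenius`: `k_ref`, `E_a`; `medlyn_peaked`: plus `H_d`, `dS`;
#'   `topt_peaked`: `k_opt`, `T_opt`, `E_a`, `H_d`; `heskel`/`quadratic`:
#'   `a`, `b`, `c` (on leaf temperature in degC); `kruse`: `k_ref`,
#'   `E_a_ref`, `dEa`; `mmrt`: `k_ref`, `dH_act`, `dCp_act`. Energies in
#'   J mol-1, entropies in J mol-1 K-1, temperatures in K. `T_ref` defaults
#'   to 298.15 K.
#' @param T_leaf leaf temperature(s), K (> 0).
#' @return rate(s) at `T_leaf`, in the units of `k_ref` (or of the
#'   polynomial coefficients).
#' @examples
#' eval_t_response("arrhenius", list(k_ref = 100, E_a = 55000), 308.15)
#' @export
eval_t_response <- function(model, params, T_leaf) {
  model <- match.arg(model, t_response_models())
  stopifnot(is.numeric(T_leaf))
  if (any(T_leaf <= 0)) abort("T_leaf must be positive (Kelvin)")
  p <- params
  if (is.null(p$T_ref)) p$T_ref <- 298.15
  need <- .t_response_terms(model)
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    abort(paste0("missing parameter(s) for ", model, ": ",
                 paste(miss, collapse = ", ")))
  }
  k <- .t_response_fn(model)(p, T_leaf)
  if (any(!is.finite(k))) {
    abort(paste0("non-finite rate from ", model,
                 " (exponential overflow); check E_a/H_d/dS magnitudes"))
  }
  k
}

#' Optimum temperature of the peaked (Medlyn) model
#'
#' Closed form of the temperature at which the deactivating Arrhenius model
#' peaks: `T_opt = H_d / (dS - R * log(E_a / (H_d - E_a)))`. Requires
#' `H_d > E_a`.
#'
#' @param E_a activation energy (J mol-1)
#' @param H_d deactivation energy (J mol-1)
#' @param dS entropy term (J mol-1 K-1)
#' @return optimum temperature, K.
#' @export
t_opt_peaked <- function(E_a, H_d, dS) {
  stopifnot(H_d > E_a)
  H_d / (dS - R_GAS * log(E_a / (H_d - E_a)))
}

# moment-based starting values per model; ln-linear models get exact lm starts
.t_response_start <- function(model, data, T_ref) {
  Tk <- data$T_leaf
  k <- data$rate
  kpos <- pmax(k, 1e-9)
  k_ref_guess <- {
    i <- which.min(abs(Tk - T_ref))
    max(k[i], 1e-6)
  }
  switch(model,
    arrhenius = {
      x <- (Tk - T_ref) / (T_ref * R_GAS * Tk)
      cf <- coef(lm(log(kpos) ~ x))
      list(k_ref = exp(cf[[1]]), E_a = cf[[2]])
    },
    medlyn_peaked = list(k_ref = k_ref_guess, E_a = 60000, H_d = 200000,
                         dS = 650),
    topt_peaked = list(k_opt = max(k), T_opt = Tk[which.max(k)],
                       E_a = 60000, H_d = 200000),
    heskel = {
      tc <- Tk - T0_K
      cf <- coef(lm(log(kpos) ~ tc + I(tc^2)))
      list(a = cf[[1]], b = cf[[2]], c = cf[[3]])
    },
    quadratic = {
      tc <- Tk - T0_K
      cf <- coef(lm(k ~ tc + I(tc^2)))
      list(a = cf[[1]], b = cf[[2]], c = cf[[3]])
    },
    kruse = {
      x <- (1 / T_ref - 1 / Tk) / R_GAS
      cf <- coef(lm(log(kpos / k_ref_guess) ~ 0 + x + I(x^2 / 2)))
      list(k_ref = k_ref_guess, E_a_ref = cf[[1]], dEa = cf[[2]])
    },
    mmrt = {
      x1 <- 1 / (R_GAS * T_ref) - 1 / (R_GAS * Tk)
      x2 <- log(Tk / T_ref) / R_GAS - (Tk - T_ref) / (R_GAS * Tk)
      cf <- coef(lm(log(kpos) ~ x1 + x2))
      list(k_ref = exp(cf[[1]]), dH_act = cf[[2]], dCp_act = cf[[3]])
    }
  )
}

# internal fitting scales: energies and entropy-like parameters are fitted
# on O(1-10) scale so numeric Jacobian columns are comparably sized
.t_response_scales <- function(model) {
  switch(model,
    arrhenius = c(k_ref = 1, E_a = 1e4),
    medlyn_peaked = c(k_ref = 1, E_a = 1e4, H_d = 1e5, dS = 1e2),
    topt_peaked = c(k_opt = 1, T_opt = 1e2, E_a = 1e4, H_d = 1e5),
    heskel = c(a = 1, b = 1, c = 1),
    quadratic = c(a = 1, b = 1, c = 1),
    kruse = c(k_ref = 1, E_a_ref = 1e4, dEa = 1e9),
    mmrt = c(k_ref = 1, dH_act = 1e4, dCp_act = 1e3)
  )
}

# physical-branch bounds (original units); the peaked forms have a mirror
# solution with negative energies that reproduces the same curve
.t_response_bounds <- function(model) {
  switch(model,
    arrhenius = list(lower = c(k_ref = 1e-9, E_a = -Inf)),
    medlyn_peaked = list(lower = c(k_ref = 1e-9, E_a = 1, H_d = 1,
                                   dS = 1e-3)),
    topt_peaked = list(lower = c(k_opt = 1e-9, T_opt = 200, E_a = 1,
                                 H_d = 1),
                       upper = c(k_opt = Inf, T_opt = 420, E_a = Inf,
                                 H_d = Inf)),
    kruse = list(lower = c(k_ref = 1e-9, E_a_ref = -Inf, dEa = -Inf)),
    mmrt = list(lower = c(k_ref = 1e-9, dH_act = -Inf, dCp_act = -Inf)),
    list()
  )
}

.t_response_start_grid <- function(model, data, T_ref, n = 3,
                                   max_starts = 60, shuffle_seed = NULL) {
  center <- .t_response_start(model, data, T_ref)
  grid <- make_start_grid(center, n = n, span = 3, max_starts = max_starts,
                          shuffle_seed = shuffle_seed)
  # always try the moment-based center first
  rbind(as.data.frame(center), grid)
}

#' Fit temperature-response models to rate data
#'
#' Fits each requested model to (`rate`, `T_leaf`) observations by nonlinear
#' least squares restarted over a grid of starting values, keeping the
#' lowest-SSR converged fit per model. A model that fails its precondition
#' or never converges yields a failed result without blocking the others.
#'
#' @param data data frame with columns `rate` and `T_leaf` (K).
#' @param models character vector of model ids (default: all seven).
#' @param T_ref reference temperature, K (default 298.15).
#' @param shuffle_seed optional seed for the start-order shuffle.
#' @return A named list of `photofit_fit` objects (class `photofit_fits`);
#'   `tidy()`/`glance()` bind across models.
#' @examples
#' d <- tibble::tibble(
#'   T_leaf = seq(278, 328, 5),
#'   rate = eval_t_response("arrhenius", list(k_ref = 75, E_a = 55000),
#'                          seq(278, 328, 5)))
#' fits <- fit_t_response(d, models = "arrhenius")
#' tidy(fits$arrhenius)
#' @export
fit_t_response <- function(data, models = t_response_models(),
                           T_ref = 298.15, shuffle_seed = NULL) {
  models <- match.arg(models, t_response_models(), several.ok = TRUE)
  data <- drop_missing(data, c("rate", "T_leaf"))
  out <- lapply(models, function(m) {
    npar <- .t_response_npar[[m]]
    if (nrow(data) < npar + 2) {
      return(failed_fit_result(
        paste0("t_response_", m),
        sprintf("need at least %d observations for %s (have %d)",
                npar + 2, m, nrow(data)), data = data))
    }
    fn <- .t_response_fn(m)
    terms <- .t_response_terms(m)
    scales <- .t_response_scales(m)
    form <- stats::as.formula(paste0(
      "rate ~ .t_pred('", m, "', ",
      paste0(terms, " * ", format(scales, scientific = FALSE),
             collapse = ", "),
      ", T_leaf, ", T_ref, ")"))
    grid <- .t_response_start_grid(m, data, T_ref,
                                   shuffle_seed = shuffle_seed)
    # on the internal scale all parameters are O(0.01-100); snap the odd
    # near-zero start away from 0 so finite-difference gradients stay alive
    grid[] <- Map(function(v, s) {
      v <- v / s
      ifelse(abs(v) < 1e-6, 1e-3, v)
    }, grid, scales[names(grid)])
    bnd <- .t_response_bounds(m)
    lo <- if (!is.null(bnd$lower)) bnd$lower[terms] / scales[terms]
    hi <- if (!is.null(bnd$upper)) bnd$upper[terms] / scales[terms]
    grid[] <- Map(function(v, l, h) pmin(pmax(v, l), h), grid,
                  as.list(lo %||% rep(-Inf, length(terms))),
                  as.list(hi %||% rep(Inf, length(terms))))
    fit <- fit_nls_multistart(form, data, grid, lower = lo, upper = hi)
    if (is.null(fit)) {
      return(failed_fit_result(
        paste0("t_response_", m), "no starting value converged",
        data = data,
        diagnostics = list(starts_tried = nrow(grid))))
    }
    coefs <- coef_table(fit)
    coefs$estimate <- coefs$estimate * scales[coefs$term]
    coefs$std.error <- coefs$std.error * scales[coefs$term]
    stats <- fit_stats(fit, nrow(data))
    stats$flags <- flag_large_se(coefs)
    est <- setNames(coefs$estimate, coefs$term)
    p <- c(as.list(est), list(T_ref = T_ref))
    fitted_vals <- fn(p, data$T_leaf)
    fitted_tb <- mutate(data, .fitted = fitted_vals,
                        .resid = .data$rate - fitted_vals)
    extra <- list(T_ref = T_ref)
    if (m == "medlyn_peaked" && est[["H_d"]] > est[["E_a"]]) {
      extra$T_opt <- t_opt_peaked(est[["E_a"]], est[["H_d"]], est[["dS"]])
    }
    vc <- tryCatch({
      S <- diag(scales[coefs$term], nrow = nrow(coefs))
      S %*% vcov(fit) %*% S  # back to the unscaled parameterization
    }, error = function(e) NULL)
    pb <- t_response_plot_builder(m, p, vc, fn)
    new_fit_result(paste0("t_response_", m), coefs, data = data,
                   fitted = fitted_tb, stats = stats, extra = extra,
                   fit = fit, plot_builder = pb)
  })
  names(out) <- models
  structure(out, class = "photofit_fits")
}

# predictor callable from an nls formula (arguments in .t_response_terms order)
.t_pred <- function(model, ...) {
  args <- list(...)
  nterm <- length(args) - 2L
  terms <- .t_response_terms(model)
  p <- setNames(args[seq_len(nterm)], terms)
  p$T_ref <- args[[nterm + 2L]]
  .t_response_fn(model)(p, args[[nterm + 1L]])
}

t_response_plot_builder <- function(model, p, vc, fn) {
  force(model); force(p); force(vc); force(fn)
  function(x) {
    grid <- tibble(T_leaf = seq(min(x$data$T_leaf), max(x$data$T_leaf),
                                length.out = 101))
    est <- setNames(x$coefs$estimate, x$coefs$term)
    pred_fn <- function(e, nd) {
      pp <- c(as.list(e), list(T_ref = p$T_ref))
      fn(pp, nd$T_leaf)
    }
    band <- predict_se_band(pred_fn, est, vc, grid)
    grid$fit <- band$fit
    grid$se <- band$se
    gg <- ggplot(x$data, aes(x = .data$T_leaf, y = .data$rate)) +
      labs(x = "T_leaf (K)", y = "rate", title = x$model) + theme_bw()
    if (all(is.finite(grid$se))) {
      gg <- gg + geom_ribbon(data = grid,
                             aes(y = .data$fit, ymin = .data$fit - .data$se,
                                 ymax = .data$fit + .data$se),
                             fill = "grey80")
    }
    gg + geom_line(data = grid, aes(y = .data$fit), colour = "blue") +
      geom_point()
  }
}

#' @export
print.photofit_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' @export
tidy.photofit_fits <- function(x, ...) {
  bind_rows(lapply(x, function(f) mutate(tidy(f), model = f$model,
                                         .before = 1)))
}

#' @export
glance.photofit_fits <- function(x, ...) {
  bind_rows(lapply(x, glance))
}

# drop rows with missing required drivers, with a logged count
drop_missing <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(paste0("required column(s) absent: ", paste(miss, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!keep)) {
    inform(sprintf("dropped %d row(s) with missing values in %s",
                   sum(!keep), paste(cols, collapse = "/")))
  }
  data[keep, , drop = FALSE]
}
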