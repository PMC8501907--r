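# Respiration in the light, by three regression methods: Kok (break in the
# low-light A-Q line), Yin (fluorescence-corrected Kok) and Walker-Ort
# (common intersection of low-C_i A-C_i lines across irradiances, which also
# yields C_i*, the apparent photocompensation point).

rlight_result <- function(method, R_light, coefs, data, fitted, stats,
                          extra = list(), fit = NULL, plot_builder = NULL) {
  extra$R_light <- R_light
  new_fit_result(paste0("r_light_", method), coefs, data = data,
                 fitted = fitted, stats = stats, extra = extra, fit = fit,
                 plot_builder = plot_builder)
}

ols_line_plot <- function(xvar, yvar) {
  function(x) {
    ggplot(x$data, aes(x = .data[[xvar]], y = .data[[yvar]])) +
      geom_point() +
      geom_line(data = x$fitted, aes(y = .data$.fitted), colour = "blue") +
      labs(title = x$model) + theme_bw()
  }
}

#' Light respiration by the Kok method
#'
#' Ordinary least squares of `A_net` on `Q` over the sub-inhibition
#' irradiance window; `R_light` is minus the intercept. The window defaults
#' to 40-100 umol m-2 s-1 and is configurable, since the method itself does
#' not prescribe one.
#'
#' @param data data frame with columns `A_net`, `Q`.
#' @param Q_bounds inclusive irradiance window, umol m-2 s-1.
#' @return A `photofit_fit` with terms `intercept` and `slope`;
#'   `$extra$R_light` holds the respiration estimate (positive magnitude;
#'   respiratory CO2 release).
#' @examples
#' d <- tibble::tibble(Q = c(40, 60, 80, 100), A_net = 0.04 * Q - 1)
#' fit_r_light_kok(d)$extra$R_light
#' @export
fit_r_light_kok <- function(data, Q_bounds = c(40, 100)) {
  data <- drop_missing(data, c("A_net", "Q"))
  d <- filter(data, .data$Q >= Q_bounds[1], .data$Q <= Q_bounds[2])
  if (nrow(d) < 3) {
    abort(sprintf("Kok method needs >= 3 observations with Q in [%g, %g] (have %d)",
                  Q_bounds[1], Q_bounds[2], nrow(d)))
  }
  fit <- lm(A_net ~ Q, data = d)
  coefs <- coef_table(fit)
  coefs$term <- c("intercept", "slope")
  stats <- fit_stats(fit, nrow(d))
  pred <- predict(fit)
  fitted_tb <- mutate(d, .fitted = pred, .resid = .data$A_net - pred)
  rlight_result("kok", -coef(fit)[[1]], coefs, d, fitted_tb, stats,
                extra = list(Q_bounds = Q_bounds), fit = fit,
                plot_builder = ols_line_plot("Q", "A_net"))
}

#' Light respiration by the Yin method
#'
#' As the Kok method, but regressing `A_net` on `Q * phi_PSII / 4`, which
#' corrects the Kok regression for the decline of PSII efficiency with
#' light; `R_light` is minus the intercept and the slope is the lumped
#' calibration factor.
#'
#' @param data data frame with columns `A_net`, `Q`, `phi_PSII`.
#' @param Q_bounds inclusive irradiance window, umol m-2 s-1.
#' @return A `photofit_fit`; `$extra$R_light` is the respiration estimate.
#' @export
fit_r_light_yin <- function(data, Q_bounds = c(40, 100)) {
  data <- drop_missing(data, c("A_net", "Q", "phi_PSII"))
  d <- filter(data, .data$Q >= Q_bounds[1], .data$Q <= Q_bounds[2])
  if (nrow(d) < 3) {
    abort(sprintf("Yin method needs >= 3 observations with Q in [%g, %g] (have %d)",
                  Q_bounds[1], Q_bounds[2], nrow(d)))
  }
  d <- mutate(d, x_yin = .data$Q * .data$phi_PSII / 4)
  if (stats::sd(d$x_yin) == 0) {
    abort("Q * phi_PSII / 4 is constant: degenerate regressor for the Yin method")
  }
  fit <- lm(A_net ~ x_yin, data = d)
  coefs <- coef_table(fit)
  coefs$term <- c("intercept", "calibration_slope")
  stats <- fit_stats(fit, nrow(d))
  pred <- predict(fit)
  fitted_tb <- mutate(d, .fitted = pred, .resid = .data$A_net - pred)
  rlight_result("yin", -coef(fit)[[1]], coefs, d, fitted_tb, stats,
                extra = list(Q_bounds = Q_bounds), fit = fit,
                plot_builder = ols_line_plot("x_yin", "A_net"))
}

#' Light respiration and C_i* by the Walker-Ort method
#'
#' Within a low-C_i window, fits one `A_net ~ C_i` line per irradiance
#' level; the lines of a Walker-Ort design intersect at
#' `(C_i*, -R_light)`. Regressing the per-level intercepts on the per-level
#' slopes (`intercept_i = -R_light - C_i* * slope_i`) recovers both the
#' apparent photocompensation point `C_i*` and `R_light`.
#'
#' @param data data frame with columns `A_net`, `C_i`, `Q`.
#' @param low_Ci_window inclusive C_i window (umol mol-1) for the per-level
#'   regressions.
#' @param min_levels minimum number of irradiance levels (default 3; with
#'   exactly 2 the intersection is solvable but its standard errors are not
#'   defined, and the result is flagged).
#' @return A `photofit_fit` with terms `R_light` and `C_i_star`;
#'   `$extra$lines` holds the per-irradiance slopes and intercepts.
#' @export
fit_r_light_walker_ort <- function(data, low_Ci_window = c(0, 300),
                                   min_levels = 3) {
  data <- drop_missing(data, c("A_net", "C_i", "Q"))
  d <- filter(data, .data$C_i >= low_Ci_window[1],
              .data$C_i <= low_Ci_window[2])
  levels <- split(d, d$Q)
  levels <- levels[vapply(levels, nrow, 1L) >= 3]
  if (length(levels) < 2) {
    abort("Walker-Ort method needs >= 2 irradiance levels with >= 3 low-C_i observations each")
  }
  flagged <- character(0)
  if (length(levels) < min_levels) {
    warn("only two irradiance levels: intersection solvable but standard errors undefined")
    flagged <- "two_levels_no_se"
  }
  lines <- bind_rows(lapply(levels, function(g) {
    cf <- coef(lm(A_net ~ C_i, data = g))
    tibble(Q = g$Q[1], intercept = cf[[1]], slope = cf[[2]], n = nrow(g))
  }))
  if (stats::sd(lines$slope) < 1e-12) {
    abort("per-irradiance slopes are indistinguishable (parallel lines): the intersection is undefined")
  }
  fit2 <- lm(intercept ~ slope, data = lines)
  cf <- coef(fit2)
  se <- tryCatch(summary(fit2)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  if (nrow(lines) == 2) se <- rep(NA_real_, 2)
  R_light <- -cf[[1]]
  C_i_star <- -cf[[2]]
  coefs <- tibble(term = c("R_light", "C_i_star"),
                  estimate = c(R_light, C_i_star),
                  std.error = unname(se))
  stats <- list(ssr = deviance(fit2), aic = AIC(fit2), bic = BIC(fit2),
                n = nrow(d), converged = TRUE, failed = FALSE,
                flags = flagged)
  pred <- predict(fit2)
  fitted_tb <- mutate(lines, .fitted = pred,
                      .resid = .data$intercept - pred)
  pb <- function(x) {
    ggplot(x$data, aes(x = .data$C_i, y = .data$A_net,
                       colour = factor(.data$Q))) +
      geom_point() +
      geom_point(data = tibble(C_i = x$coefs$estimate[2],
                               A_net = -x$coefs$estimate[1], Q = NA),
                 colour = "black", shape = 4, size = 3) +
      labs(colour = "Q", title = "Walker-Ort common intersection") +
      theme_bw()
  }
  rlight_result("walker_ort", R_light, coefs, d, fitted_tb, stats,
                extra = list(C_i_star = C_i_star, lines = lines,
                             low_Ci_window = low_Ci_window),
                fit = fit2, plot_builder = pb)
}
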