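# Photosynthetic light response: the non-rectangular hyperbola (Marshall &
# Biscoe form). Net assimilation rises with irradiance at initial slope
# phi_J (apparent quantum yield), bends with curvature theta_J and
# saturates at A_sat, offset by respiration R_d.

#' Evaluate the non-rectangular hyperbola light response
#'
#' `A_net = [phi_J*Q + A_sat - sqrt((phi_J*Q + A_sat)^2 -
#' 4*theta_J*phi_J*Q*A_sat)] / (2*theta_J) - R_d`. At `theta_J = 0` the
#' rectangular-hyperbola limit `phi_J*Q*A_sat / (phi_J*Q + A_sat) - R_d` is
#' used instead of dividing by zero.
#'
#' @param params named list: `A_sat` (umol m-2 s-1), `phi_J` (mol CO2 mol-1
#'   photons), `theta_J` (0-1), `R_d` (umol m-2 s-1).
#' @param Q PPFD (umol m-2 s-1, >= 0).
#' @return net assimilation (umol m-2 s-1).
#' @examples
#' eval_aq(list(A_sat = 25, phi_J = 0.05, theta_J = 0.85, R_d = 1.2), 500)
#' @export
eval_aq <- function(params, Q) {
  stopifnot(all(Q >= 0))
  with(params, {
    stopifnot(theta_J >= 0, theta_J <= 1)
    gross <- aq_gross(A_sat, phi_J, theta_J, Q)
    gross - R_d
  })
}

aq_gross <- function(A_sat, phi_J, theta_J, Q) {
  s <- phi_J * Q + A_sat
  if (all(theta_J == 0)) return(phi_J * Q * A_sat / pmax(s, .Machine$double.eps))
  disc <- pmax(s^2 - 4 * theta_J * phi_J * Q * A_sat, 0)
  (s - sqrt(disc)) / (2 * theta_J)
}

#' Fit a photosynthetic light-response curve
#'
#' Fits the non-rectangular hyperbola to (`A_net`, `Q`) observations by
#' multi-start nonlinear least squares, returning estimates of the
#' light-saturated assimilation rate, apparent quantum yield, curvature and
#' respiration with standard errors, fit statistics and a plot of data,
#' fitted curve and standard-error band.
#'
#' @param data data frame with columns `A_net` and `Q`.
#' @param shuffle_seed optional seed for the start-order shuffle.
#' @return A `photofit_fit` with terms `A_sat`, `phi_J`, `theta_J`, `R_d`.
#' @examples
#' q <- c(0, 25, 50, 75, 100, 125, 150, 375, 1500)
#' d <- tibble::tibble(Q = q,
#'   A_net = eval_aq(list(A_sat = 25, phi_J = 0.05, theta_J = 0.85,
#'                        R_d = 1.2), q))
#' tidy(fit_aq_response(d))
#' @export
fit_aq_response <- function(data, shuffle_seed = NULL) {
  data <- drop_missing(data, c("A_net", "Q"))
  if (nrow(data) < 6) {
    abort("fit_aq_response needs at least 6 observations spanning sub-saturating and saturating Q")
  }
  # moment starts: slope of the 3 dimmest points gives phi_J, plateau A_sat
  ord <- order(data$Q)
  lowQ <- data[head(ord, max(3, sum(data$Q < max(data$Q) / 4))), ]
  sl <- tryCatch(coef(lm(A_net ~ Q, data = lowQ))[[2]], error = function(e) 0.04)
  phi0 <- max(min(sl, 0.12), 0.01)
  A0 <- max(max(data$A_net) - min(0, min(data$A_net)), 1)
  R0 <- max(-min(data$A_net), 0.5)
  center <- list(A_sat = A0, phi_J = phi0, theta_J = 0.7, R_d = R0)
  grid <- rbind(as.data.frame(center),
                make_start_grid(center, n = 3, span = 3,
                                shuffle_seed = shuffle_seed))
  grid$theta_J <- pmin(grid$theta_J, 0.999)
  fit <- fit_nls_multistart(
    A_net ~ aq_gross(A_sat, phi_J, theta_J, Q) - R_d, data, grid,
    lower = c(A_sat = 1e-6, phi_J = 1e-6, theta_J = 1e-6, R_d = -50),
    upper = c(A_sat = Inf, phi_J = 1, theta_J = 1, R_d = Inf))
  if (is.null(fit)) {
    return(failed_fit_result("aq_response", "no starting value converged",
                             data = data))
  }
  coefs <- coef_table(fit)
  stats <- fit_stats(fit, nrow(data))
  stats$flags <- flag_large_se(coefs)
  est <- setNames(coefs$estimate, coefs$term)
  pred <- eval_aq(as.list(est), data$Q)
  fitted_tb <- mutate(data, .fitted = pred, .resid = .data$A_net - pred)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  pb <- function(x) {
    grid <- tibble(Q = seq(0, max(x$data$Q), length.out = 151))
    e <- setNames(x$coefs$estimate, x$coefs$term)
    band <- predict_se_band(function(e2, nd) eval_aq(as.list(e2), nd$Q),
                            e, vc, grid)
    grid$fit <- band$fit; grid$se <- band$se
    gg <- ggplot(x$data, aes(x = .data$Q, y = .data$A_net)) +
      labs(x = expression(Q~(mu*mol~m^-2~s^-1)),
           y = expression(A[net]~(mu*mol~m^-2~s^-1))) + theme_bw()
    if (all(is.finite(grid$se))) {
      gg <- gg + geom_ribbon(data = grid,
                             aes(y = .data$fit, ymin = .data$fit - .data$se,
                                 ymax = .data$fit + .data$se), fill = "grey80")
    }
    gg + geom_line(data = grid, aes(y = .data$fit), colour = "blue") +
      geom_point()
  }
  new_fit_result("aq_response", coefs, data = data, fitted = fitted_tb,
                 stats = stats, fit = fit, plot_builder = pb)
}
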