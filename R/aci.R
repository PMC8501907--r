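# CO2 response of net assimilation: the Farquhar-von Caemmerer-Berry (FvCB)
# C3 model. Demand for CO2 is the minimum of the Rubisco-limited (A_c),
# RuBP-regeneration-limited (A_j) and triose-phosphate-utilization-limited
# (A_p) rates, less day respiration R_d.

#' Evaluate the FvCB limitation rates at given CO2
#'
#' Computes `A_c = V_cmax*(C - Gamma_star)/(C + K_m)` with
#' `K_m = K_c*(1 + O/K_o)`, `A_j = J*(C - Gamma_star)/(4C + 8*Gamma_star)`,
#' `A_p = 3*V_TPU`, and `A_mod = min(A_c, A_j, A_p) - R_d`.
#'
#' @param params named list: `V_cmax`, `J_max` (electron transport rate J at
#'   the measurement irradiance), `V_TPU` (may be `Inf` for no TPU
#'   limitation), `R_d` (all umol m-2 s-1), `Gamma_star`, `K_c`
#'   (umol mol-1), `K_o`, `O` (mmol mol-1).
#' @param C_i intercellular (or chloroplastic) CO2 mole fraction,
#'   umol mol-1 (> 0).
#' @return A tibble with columns `C_i`, `A_c`, `A_j`, `A_p`, `A_mod`,
#'   `limitation` (one of `"Ac"`, `"Aj"`, `"Ap"`).
#' @examples
#' p <- list(V_cmax = 100, J_max = 180, V_TPU = 12, R_d = 1.5,
#'           Gamma_star = 42.75, K_c = 404.9, K_o = 278.4, O = 210)
#' eval_fvcb_ci(p, c(100, 300, 1200))
#' @export
eval_fvcb_ci <- function(params, C_i) {
  if (any(C_i <= 0)) abort("C_i must be positive")
  p <- params
  if (is.null(p$V_TPU)) p$V_TPU <- Inf
  K_m <- p$K_c * (1 + p$O / p$K_o)
  A_c <- p$V_cmax * (C_i - p$Gamma_star) / (C_i + K_m)
  A_j <- p$J_max * (C_i - p$Gamma_star) / (4 * C_i + 8 * p$Gamma_star)
  A_p <- rep(3 * p$V_TPU, length(C_i))
  gross <- pmin(A_c, A_j, A_p)
  lim <- c("Ac", "Aj", "Ap")[max.col(-cbind(A_c, A_j, A_p), "first")]
  tibble(C_i = C_i, A_c = A_c, A_j = A_j, A_p = A_p,
         A_mod = gross - p$R_d, limitation = lim)
}

# gross FvCB demand usable inside nls formulas
fvcb_gross <- function(V_cmax, J, V_TPU, C, Gamma_star, K_m) {
  A_c <- V_cmax * (C - Gamma_star) / (C + K_m)
  A_j <- J * (C - Gamma_star) / (4 * C + 8 * Gamma_star)
  pmin(A_c, A_j, 3 * V_TPU)
}

# temperature-adjust the kinetic constants from 25 degC to T_leaf
adjust_kinetics <- function(kin, T_leaf) {
  list(
    Gamma_star = arrhenius_scale(kin$Gamma_star25, kin$Ea_Gamma_star, T_leaf),
    K_c = arrhenius_scale(kin$K_c25, kin$Ea_K_c, T_leaf),
    K_o = arrhenius_scale(kin$K_o25, kin$Ea_K_o, T_leaf),
    O = kin$O
  )
}

#' Fit an A-Ci curve with the FvCB model
#'
#' Estimates `V_cmax`, `J_max` (J at the measurement irradiance), `R_d` and
#' optionally `V_TPU` by multi-start nonlinear least squares on
#' `A_net = min(A_c, A_j, A_p) - R_d`. Kinetic constants (Gamma*, K_c, K_o)
#' are temperature-adjusted to the curve's mean `T_leaf` (298.15 K when no
#' `T_leaf` column is present). With a finite mesophyll conductance `g_mc`
#' the CO2 axis is first converted to the chloroplastic value
#' `C_c = C_i - A_net/g_mc`.
#'
#' TPU limitation is fitted only when requested, or (by default) when the
#' high-CO2 end of the curve flattens (slope of the last three points below
#' `0.01` umol m-2 s-1 per umol mol-1).
#'
#' @param data data frame with columns `A_net`, `C_i` (and optionally
#'   `T_leaf`, `Q`).
#' @param kinetics kinetic constants at 25 degC with activation energies, as
#'   [tobacco_kinetics()].
#' @param Gamma_star25 override for the 25 degC CO2 compensation point
#'   (umol mol-1); defaults to the kinetics value. An assumed input, exposed
#'   for sensitivity analysis.
#' @param g_mc assumed mesophyll conductance (mol m-2 s-1); `Inf` (default)
#'   fits on the C_i basis.
#' @param fit_TPU `NULL` (auto-detect), `TRUE` or `FALSE`.
#' @param shuffle_seed optional seed for the start-order shuffle.
#' @return A `photofit_fit`; `$extra$modelled` holds the per-observation
#'   `A_c`/`A_j`/`A_p`/`A_mod` table, `$extra$kinetics_at_T` the adjusted
#'   constants. `autoplot()` overlays all limitation curves on the data.
#' @examples
#' p <- list(V_cmax = 100, J_max = 180, V_TPU = 12, R_d = 1.5,
#'           Gamma_star = 42.75, K_c = 404.9, K_o = 278.4, O = 210)
#' ci <- seq(50, 1500, length.out = 12)
#' d <- tibble::tibble(C_i = ci, A_net = eval_fvcb_ci(p, ci)$A_mod,
#'                     T_leaf = 298.15)
#' tidy(fit_aci_response(d))
#' @export
fit_aci_response <- function(data, kinetics = tobacco_kinetics(),
                             Gamma_star25 = NULL, g_mc = Inf,
                             fit_TPU = NULL, shuffle_seed = NULL) {
  data <- drop_missing(data, c("A_net", "C_i"))
  if (nrow(data) < 5) {
    abort("fit_aci_response needs at least 5 observations")
  }
  kin <- kinetics
  if (!is.null(Gamma_star25)) kin$Gamma_star25 <- Gamma_star25
  T_mean <- if ("T_leaf" %in% names(data)) mean(data$T_leaf) else 298.15
  kt <- adjust_kinetics(kin, T_mean)
  K_m <- kt$K_c * (1 + kt$O / kt$K_o)
  d <- tibble(A_net = data$A_net,
              C = data$C_i - data$A_net / g_mc)
  if (any(d$C <= kt$Gamma_star & d$A_net > 0)) {
    warn("some observations have CO2 below Gamma* with positive A_net; check g_mc")
  }
  ord <- order(d$C)
  d_s <- d[ord, ]
  # TPU auto-detection: flattening of the last three points
  if (is.null(fit_TPU)) {
    tail3 <- tail(d_s, 3)
    slope <- coef(lm(A_net ~ C, data = tail3))[[2]]
    fit_TPU <- is.finite(slope) && slope < 0.01 &&
      all(tail3$C > 2 * kt$Gamma_star)
  }
  # moment starts
  R0 <- 1
  low <- d_s[d_s$C < stats::quantile(d_s$C, 0.4), ]
  if (nrow(low) < 2) low <- head(d_s, 3)
  V0 <- stats::median((low$A_net + R0) * (low$C + K_m) /
                        pmax(low$C - kt$Gamma_star, 1))
  high <- tail(d_s, 3)
  J0 <- stats::median((high$A_net + R0) * (4 * high$C + 8 * kt$Gamma_star) /
                        pmax(high$C - kt$Gamma_star, 1))
  V0 <- max(V0, 5); J0 <- max(J0, 5)
  if (fit_TPU) {
    center <- list(V_cmax = V0, J = J0, V_TPU = (max(d$A_net) + R0) / 3,
                   R_d = R0)
    lower <- c(V_cmax = 1e-3, J = 1e-3, V_TPU = 1e-3, R_d = -10)
    form <- A_net ~ fvcb_gross(V_cmax, J, V_TPU, C, Gamma_star, K_m) - R_d
  } else {
    center <- list(V_cmax = V0, J = J0, R_d = R0)
    lower <- c(V_cmax = 1e-3, J = 1e-3, R_d = -10)
    form <- A_net ~ fvcb_gross(V_cmax, J, Inf, C, Gamma_star, K_m) - R_d
  }
  dd <- d
  dd$Gamma_star <- kt$Gamma_star
  dd$K_m <- K_m
  grid <- rbind(as.data.frame(center),
                make_start_grid(center, n = 3, span = 3,
                                shuffle_seed = shuffle_seed))
  fit <- fit_nls_multistart(form, dd, grid, lower = lower)
  if (is.null(fit)) {
    worst <- dd[which.max(abs(dd$A_net - mean(dd$A_net))), ]
    return(failed_fit_result(
      "aci_response", "no starting value converged", data = data,
      diagnostics = list(largest_residual_row = worst)))
  }
  coefs <- coef_table(fit)
  coefs$term[coefs$term == "J"] <- "J_max"
  stats <- fit_stats(fit, nrow(data))
  stats$flags <- flag_large_se(coefs)
  est <- setNames(coefs$estimate, coefs$term)
  p_hat <- list(V_cmax = est[["V_cmax"]], J_max = est[["J_max"]],
                V_TPU = if (fit_TPU) est[["V_TPU"]] else Inf,
                R_d = est[["R_d"]], Gamma_star = kt$Gamma_star,
                K_c = kt$K_c, K_o = kt$K_o, O = kt$O)
  modelled <- eval_fvcb_ci(p_hat, d$C)
  names(modelled)[names(modelled) == "C_i"] <- "C"
  modelled <- bind_cols(tibble(C_i = data$C_i, A_net = data$A_net), modelled)
  # identifiability probe: a parameter the data do not constrain can be
  # inflated without changing the SSR (the curve never leaves the other
  # limitation branches)
  ssr_of <- function(p) {
    sum((d$A_net - (fvcb_gross(p$V_cmax, p$J_max, p$V_TPU, d$C,
                               kt$Gamma_star, K_m) - p$R_d))^2)
  }
  ssr0 <- ssr_of(p_hat)
  tol_id <- max(1e-8, 1e-6 * ssr0)
  if (ssr_of(modifyList(p_hat, list(J_max = p_hat$J_max * 1.5))) - ssr0 <
        tol_id) {
    warn("the data never become RuBP-regeneration limited: J_max is unidentifiable from this curve")
    stats$flags <- c(stats$flags, "J_max_unidentifiable")
  }
  if (ssr_of(modifyList(p_hat, list(V_cmax = p_hat$V_cmax * 1.5))) - ssr0 <
        tol_id) {
    warn("the data never become Rubisco limited: V_cmax is unidentifiable from this curve")
    stats$flags <- c(stats$flags, "V_cmax_unidentifiable")
  }
  fitted_tb <- mutate(data, .fitted = modelled$A_mod,
                      .resid = .data$A_net - modelled$A_mod)
  pb <- function(x) {
    md <- x$extra$modelled
    grid_c <- seq(min(md$C), max(md$C), length.out = 151)
    curves <- eval_fvcb_ci(x$extra$params, grid_c)
    long <- tidyr::pivot_longer(
      curves, c("A_c", "A_j", "A_p"), names_to = "curve",
      values_to = "A")
    long$A <- long$A - x$extra$params$R_d
    long <- long[is.finite(long$A), ]
    ggplot(md, aes(x = .data$C, y = .data$A_net)) +
      geom_line(data = long, aes(x = .data$C_i, y = .data$A,
                                 colour = .data$curve)) +
      geom_line(data = curves, aes(x = .data$C_i, y = .data$A_mod),
                colour = "black", linewidth = 1) +
      geom_point(shape = 21, fill = "white") +
      scale_colour_manual(values = c(A_c = "blue", A_j = "orange",
                                     A_p = "red")) +
      labs(x = expression(C[i]~(mu*mol~mol^-1)),
           y = expression(A[net]~(mu*mol~m^-2~s^-1))) +
      theme_bw()
  }
  new_fit_result("aci_response", coefs, data = data, fitted = fitted_tb,
                 stats = stats,
                 extra = list(modelled = modelled, params = p_hat,
                              kinetics_at_T = kt, T_mean = T_mean,
                              fit_TPU = fit_TPU, g_mc = g_mc),
                 fit = fit, plot_builder = pb)
}
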