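# Mesophyll conductance by the variable J method (Harley et al. 1992):
# combine gas exchange with a fluorescence-based electron transport rate to
# back out the chloroplastic CO2 concentration per observation, and screen
# each estimate with the sensitivity ratio dCc/dA. Ratios between 10 and 50
# (inclusive) are deemed reliable and only those enter the summary mean.

#' Estimate mesophyll conductance by the variable J method
#'
#' Per observation:
#' `C_c = Gamma_star * (J_F + 8*(A_net + R_light)) / (J_F - 4*(A_net + R_light))`,
#' `g_mc = A_net / (C_i - C_c)`, and the reliability ratio
#' `dCcdA = 12 * Gamma_star * J_F / (J_F - 4*(A_net + R_light))^2`.
#' Records with `dCcdA` in `[10, 50]` (bounds inclusive) are flagged
#' reliable; the summary `g_mc` is the mean over reliable records only.
#'
#' The electron transport rate `J_F` is taken from a `J_F` column if
#' present; otherwise it is computed as
#' `calib * Q * phi_PSII`, where `calib` is the user-supplied product of
#' leaf absorptance and the PSII partitioning fraction (no default is
#' assumed).
#'
#' @param data data frame with columns `A_net`, `C_i`, and either `J_F` or
#'   both `Q` and `phi_PSII`.
#' @param Gamma_star chloroplastic CO2 compensation point (umol mol-1) at
#'   the measurement temperature.
#' @param R_light respiration in the light (umol m-2 s-1, positive
#'   magnitude), e.g. from [fit_r_light_yin()].
#' @param calib calibration factor for `J_F = calib * Q * phi_PSII`;
#'   required when no `J_F` column is present.
#' @param bounds inclusive reliability window on `dCcdA` (default
#'   `c(10, 50)`).
#' @return A `photofit_fit`: `$extra$records` is the per-observation table
#'   (`C_c`, `g_mc`, `dCcdA`, `reliable`, `valid`, `reason`),
#'   `$extra$g_mc_mean` the mean over reliable records, and `tidy()` reports
#'   that mean with the standard error of the reliable-record mean.
#'   `autoplot()` draws the reliability scatter of `g_mc` against `dCcdA`.
#' @examples
#' d <- tibble::tibble(A_net = 10, C_i = 250, J_F = 100)
#' fit_g_mc_variablej(d, Gamma_star = 40, R_light = 1)$extra$records
#' @export
fit_g_mc_variablej <- function(data, Gamma_star, R_light, calib = NULL,
                               bounds = c(10, 50)) {
  data <- drop_missing(data, c("A_net", "C_i"))
  if (!"J_F" %in% names(data)) {
    if (!all(c("Q", "phi_PSII") %in% names(data))) {
      abort("need a J_F column, or Q and phi_PSII columns plus `calib`")
    }
    if (is.null(calib)) {
      abort("no J_F column: supply `calib` (absorptance x PSII fraction) to compute J_F = calib * Q * phi_PSII")
    }
    data$J_F <- calib * data$Q * data$phi_PSII
  }
  stopifnot(R_light >= 0, Gamma_star > 0)
  aR <- data$A_net + R_light
  den <- data$J_F - 4 * aR
  valid <- den > 0
  reason <- ifelse(valid, NA_character_,
                   "J_F <= 4*(A_net + R_light): denominator collapse")
  C_c <- ifelse(valid, Gamma_star * (data$J_F + 8 * aR) / den, NA_real_)
  g_mc <- ifelse(valid, data$A_net / (data$C_i - C_c), NA_real_)
  nonphys <- valid & (data$C_i <= C_c)
  reason[nonphys] <- "C_i <= C_c: non-physical g_mc"
  dCcdA <- ifelse(valid, 12 * Gamma_star * data$J_F / den^2, NA_real_)
  reliable <- valid & !nonphys &
    dCcdA >= bounds[1] & dCcdA <= bounds[2]
  records <- mutate(data, C_c = C_c, g_mc = g_mc, dCcdA = dCcdA,
                    valid = valid & !nonphys, reliable = reliable,
                    reason = reason)
  g_rel <- records$g_mc[records$reliable]
  g_mean <- if (length(g_rel)) mean(g_rel) else NA_real_
  g_se <- if (length(g_rel) > 1) stats::sd(g_rel) / sqrt(length(g_rel)) else NA_real_
  coefs <- tibble(term = "g_mc_mean", estimate = g_mean, std.error = g_se)
  stats <- list(n = nrow(records), n_reliable = sum(records$reliable),
                n_invalid = sum(!records$valid), converged = TRUE,
                failed = FALSE)
  pb <- function(x) {
    rec <- filter(x$extra$records, .data$valid)
    ggplot(rec, aes(x = .data$dCcdA, y = .data$g_mc,
                    colour = .data$reliable)) +
      geom_point() +
      ggplot2::geom_vline(xintercept = x$extra$bounds, linetype = 2) +
      labs(x = expression(delta*C[c]/delta*A),
           y = expression(g[mc]~(mol~m^-2~s^-1))) +
      theme_bw()
  }
  new_fit_result("g_mc_variablej", coefs, data = data,
                 fitted = mutate(records, .fitted = g_mean,
                                 .resid = .data$g_mc - g_mean),
                 stats = stats,
                 extra = list(records = records, g_mc_mean = g_mean,
                              bounds = bounds, Gamma_star = Gamma_star,
                              R_light = R_light),
                 plot_builder = pb)
}
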