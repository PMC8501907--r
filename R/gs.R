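# Stomatal conductance models: Ball-Berry, Leuning and Medlyn. All three
# reduce to the residual conductance g0 at zero assimilation and scale
# stomatal opening with assimilation normalized by CO2 and a humidity
# signal (RH for Ball-Berry, VPD for Leuning and Medlyn).

#' Names of the available stomatal conductance models
#' @return character vector of model ids.
#' @export
gs_models <- function() c("ballberry", "leuning", "medlyn")

.gs_npar <- c(ballberry = 2, leuning = 2, medlyn = 2)

#' Evaluate a stomatal conductance model
#'
#' Forms: Ball-Berry `g_sw = g0 + g1 * A_net * RH / C_s`; Leuning
#' `g_sw = g0 + g1 * A_net / ((C_s - Gamma) * (1 + D/D0))`; Medlyn (explicit
#' approximate form) `g_sw = g0 + 1.6 * (1 + g1/sqrt(D)) * A_net / C_s`.
#'
#' @param model one of [gs_models()].
#' @param params named list: `g0` (mol m-2 s-1), `g1`; Leuning also `D0`
#'   (kPa) and `Gamma` (umol mol-1).
#' @param drivers data frame / list with `A_net`, `C_s` and `RH` (fraction,
#'   Ball-Berry) or `D` (kPa, Leuning/Medlyn).
#' @return stomatal conductance to water vapour, mol m-2 s-1.
#' @examples
#' eval_gs_model("ballberry", list(g0 = 0, g1 = 10),
#'               list(A_net = 10, RH = 0.5, C_s = 400))
#' @export
eval_gs_model <- function(model, params, drivers) {
  model <- match.arg(model, gs_models())
  p <- params
  d <- drivers
  stopifnot(all(d$C_s > 0))
  switch(model,
    ballberry = {
      stopifnot(all(d$RH >= 0 & d$RH <= 1))
      p$g0 + p$g1 * d$A_net * d$RH / d$C_s
    },
    leuning = {
      stopifnot(all(d$D > 0), p$D0 > 0)
      if (any(abs(d$C_s - p$Gamma) < 1e-9)) {
        abort("C_s equals Gamma in the Leuning model: singular denominator")
      }
      p$g0 + p$g1 * d$A_net / ((d$C_s - p$Gamma) * (1 + d$D / p$D0))
    },
    medlyn = {
      stopifnot(all(d$D > 0))
      p$g0 + 1.6 * (1 + p$g1 / sqrt(d$D)) * d$A_net / d$C_s
    }
  )
}

#' Fit stomatal conductance models
#'
#' Fits each requested model to observed `g_sw` by multi-start nonlinear
#' least squares (for these forms the surface is near-linear in `g0`, `g1`,
#' so moment-based starts converge quickly). Leuning's `Gamma` and `D0` are
#' fixed (supplied, not estimated) to preserve identifiability.
#'
#' @param data data frame with columns `g_sw`, `A_net`, `C_s`, plus `RH`
#'   (Ball-Berry) and/or `D` (Leuning, Medlyn).
#' @param models models to fit (default: every model whose drivers are
#'   present).
#' @param Gamma,D0 fixed Leuning constants (umol mol-1, kPa).
#' @param shuffle_seed optional seed for the start-order shuffle.
#' @return A named list of `photofit_fit` objects (class `photofit_fits`).
#' @export
fit_gs_models <- function(data, models = NULL, Gamma = 50, D0 = 1.5,
                          shuffle_seed = NULL) {
  data <- drop_missing(data, c("g_sw", "A_net", "C_s"))
  if (is.null(models)) {
    models <- c(if ("RH" %in% names(data)) "ballberry",
                if ("D" %in% names(data)) c("leuning", "medlyn"))
  }
  models <- match.arg(models, gs_models(), several.ok = TRUE)
  out <- lapply(models, function(m) {
    need <- c("g_sw", "A_net", "C_s", if (m == "ballberry") "RH" else "D")
    if (!all(need %in% names(data))) {
      return(failed_fit_result(
        paste0("gs_", m),
        paste0("missing driver column(s): ",
               paste(setdiff(need, names(data)), collapse = ", ")),
        data = data))
    }
    d <- drop_missing(data, need)
    if (nrow(d) < .gs_npar[[m]] + 2) {
      return(failed_fit_result(
        paste0("gs_", m),
        sprintf("need at least %d observations (have %d)",
                .gs_npar[[m]] + 2, nrow(d)), data = d))
    }
    if (all(abs(d$A_net) < 1e-12)) {
      warn(paste0("all A_net are zero: g1 is unidentifiable for ", m))
    }
    index <- switch(m,
      ballberry = d$A_net * d$RH / d$C_s,
      leuning = d$A_net / ((d$C_s - Gamma) * (1 + d$D / D0)),
      medlyn = 1.6 * d$A_net / d$C_s  # partial index; g1 enters via 1/sqrt(D)
    )
    g0_0 <- max(min(d$g_sw), 1e-4)
    g1_0 <- if (stats::sd(index) > 0) {
      max(abs(coef(lm(d$g_sw ~ index))[[2]]), 0.5)
    } else 5
    center <- list(g0 = g0_0, g1 = g1_0)
    grid <- rbind(as.data.frame(center),
                  make_start_grid(center, n = 4, span = 4,
                                  shuffle_seed = shuffle_seed))
    d2 <- d
    if (m == "leuning") { d2$Gamma <- Gamma; d2$D0 <- D0 }
    form <- switch(m,
      ballberry = g_sw ~ g0 + g1 * A_net * RH / C_s,
      leuning = g_sw ~ g0 + g1 * A_net / ((C_s - Gamma) * (1 + D / D0)),
      medlyn = g_sw ~ g0 + 1.6 * (1 + g1 / sqrt(D)) * A_net / C_s
    )
    fit <- fit_nls_multistart(form, d2, grid,
                              lower = c(g0 = 0, g1 = 0))
    if (is.null(fit)) {
      return(failed_fit_result(paste0("gs_", m),
                               "no starting value converged", data = d))
    }
    coefs <- coef_table(fit)
    stats <- fit_stats(fit, nrow(d))
    stats$flags <- flag_large_se(coefs)
    pred <- predict(fit)
    fitted_tb <- mutate(d, .fitted = pred, .resid = .data$g_sw - pred)
    pb <- function(x) {
      ggplot(x$fitted, aes(x = .data$.fitted, y = .data$g_sw)) +
        geom_abline(slope = 1, intercept = 0, linetype = 2) +
        geom_point() +
        labs(x = "fitted g_sw", y = "observed g_sw", title = x$model) +
        theme_bw()
    }
    extra <- list()
    if (m == "leuning") extra <- list(Gamma = Gamma, D0 = D0)
    new_fit_result(paste0("gs_", m), coefs, data = d, fitted = fitted_tb,
                   stats = stats, extra = extra, fit = fit,
                   plot_builder = pb)
  })
  names(out) <- models
  structure(out, class = "photofit_fits")
}
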