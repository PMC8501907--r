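# Xylem hydraulic vulnerability curves (sigmoidal and Weibull fits to PLC
# against water potential) and leaf pressure-volume curves (osmotic
# potential, turgor loss point and capacitance from psi vs relative water
# content).

# internal sign convention: water potential <= 0 MPa
normalize_psi <- function(psi) {
  if (mean(psi, na.rm = TRUE) > 0) {
    inform("water potentials supplied as positive tensions; negating to MPa <= 0")
    psi <- -psi
  }
  psi
}

#' Evaluate a hydraulic vulnerability model
#'
#' Sigmoidal: `PLC = 100 / (1 + exp(a * (psi - b)))` with `b` the water
#' potential at 50 % PLC. Weibull: `PLC = 100 * (1 - exp(-(tension/b_w)^c_w))`
#' with `tension = -psi`.
#'
#' @param model `"sigmoidal"` or `"weibull"`.
#' @param params named list: sigmoidal `a` (MPa-1, > 0), `b` (MPa);
#'   weibull `b_w` (MPa, > 0), `c_w` (> 0).
#' @param psi water potential, MPa (<= 0).
#' @return percent loss of conductivity (0-100).
#' @export
eval_vuln <- function(model, params, psi) {
  model <- match.arg(model, c("sigmoidal", "weibull"))
  p <- params
  switch(model,
    sigmoidal = 100 / (1 + exp(p$a * (psi - p$b))),
    weibull = 100 * (1 - exp(-(pmax(-psi, 0) / p$b_w)^p$c_w))
  )
}

#' Fit hydraulic vulnerability curves
#'
#' Fits both the sigmoidal and the Weibull model to (`psi`, `PLC`) data by
#' multi-start nonlinear least squares. Derived points for the sigmoidal
#' fit follow the tangent-line convention: air entry `P_e = b + 2/a`,
#' `P_50 = b`, hydraulic-failure threshold `P_max = b - 2/a`. For the
#' Weibull fit `P_50 = -b_w * log(2)^(1/c_w)`. Non-convergence of one model
#' does not block the other; `autoplot()` of either result overlays both.
#'
#' @param data data frame with columns `psi` (MPa; positive tensions are
#'   auto-negated with a notice) and `PLC` (0-100).
#' @param models subset of `c("sigmoidal", "weibull")`.
#' @param shuffle_seed optional seed for the start-order shuffle.
#' @return A named list of `photofit_fit` objects (class `photofit_fits`);
#'   derived water potentials sit in each fit's `$extra`.
#' @export
fit_hydra_vuln_curve <- function(data, models = c("sigmoidal", "weibull"),
                                 shuffle_seed = NULL) {
  data <- drop_missing(data, c("psi", "PLC"))
  if (nrow(data) < 5) abort("need at least 5 observations")
  if (any(data$PLC < 0 | data$PLC > 100)) abort("PLC outside [0, 100]")
  if (stats::sd(data$PLC) < 1e-12) {
    abort("all PLC values identical: no curve to fit")
  }
  data$psi <- normalize_psi(data$psi)
  # linearized starts
  frac <- pmin(pmax(data$PLC / 100, 1e-4), 1 - 1e-4)
  b0 <- data$psi[which.min(abs(data$PLC - 50))]
  a0 <- tryCatch(max(-coef(lm(log(1 / frac - 1) ~ data$psi))[[2]], 0.2),
                 error = function(e) 1)
  tension <- pmax(-data$psi, 1e-6)
  wcf <- tryCatch(coef(lm(log(-log(1 - frac)) ~ log(tension))),
                  error = function(e) c(0, 2))
  c0 <- max(wcf[[2]], 0.5)
  bw0 <- max(exp(-wcf[[1]] / c0), 0.1)
  fits <- list()
  for (m in models) {
    fits[[m]] <- tryCatch({
      if (m == "sigmoidal") {
        center <- list(a = a0, b = b0)
        grid <- rbind(as.data.frame(center),
                      make_start_grid(center, n = 5, span = 4,
                                      shuffle_seed = shuffle_seed))
        fit <- fit_nls_multistart(PLC ~ 100 / (1 + exp(a * (psi - b))),
                                  data, grid,
                                  lower = c(a = 1e-4, b = -Inf),
                                  upper = c(a = Inf, b = 0))
      } else {
        center <- list(b_w = bw0, c_w = c0)
        grid <- rbind(as.data.frame(center),
                      make_start_grid(center, n = 5, span = 4,
                                      shuffle_seed = shuffle_seed))
        fit <- fit_nls_multistart(
          PLC ~ 100 * (1 - exp(-(pmax(-psi, 1e-9) / b_w)^c_w)),
          data, grid, lower = c(b_w = 1e-4, c_w = 1e-3))
      }
      if (is.null(fit)) {
        failed_fit_result(paste0("vuln_", m), "no starting value converged",
                          data = data)
      } else {
        coefs <- coef_table(fit)
        stats <- fit_stats(fit, nrow(data))
        stats$flags <- flag_large_se(coefs)
        est <- setNames(coefs$estimate, coefs$term)
        extra <- if (m == "sigmoidal") {
          list(P_50 = est[["b"]], P_e = est[["b"]] + 2 / est[["a"]],
               P_max = est[["b"]] - 2 / est[["a"]])
        } else {
          list(P_50 = -est[["b_w"]] * log(2)^(1 / est[["c_w"]]))
        }
        pred <- predict(fit)
        fitted_tb <- mutate(data, .fitted = pred,
                            .resid = .data$PLC - pred)
        new_fit_result(paste0("vuln_", m), coefs, data = data,
                       fitted = fitted_tb, stats = stats, extra = extra,
                       fit = fit)
      }
    }, error = function(e) {
      failed_fit_result(paste0("vuln_", m), conditionMessage(e), data = data)
    })
  }
  out <- structure(fits, class = "photofit_fits")
  overlay <- function(x) {
    grid <- tibble(psi = seq(min(data$psi), max(data$psi),
                             length.out = 151))
    lines <- list()
    for (m in names(out)) {
      f <- out[[m]]
      if (isTRUE(f$stats$failed)) next
      est <- as.list(setNames(f$coefs$estimate, f$coefs$term))
      lines[[m]] <- tibble(psi = grid$psi,
                           PLC = eval_vuln(m, est, grid$psi), model = m)
    }
    ggplot(data, aes(x = .data$psi, y = .data$PLC)) +
      geom_line(data = bind_rows(lines),
                aes(colour = .data$model)) +
      geom_point() +
      labs(x = expression(Psi~(MPa)), y = "PLC (%)") + theme_bw()
  }
  for (m in names(out)) out[[m]]$plot_builder <- overlay
  out
}

#' Fit a leaf pressure-volume curve
#'
#' From paired water potential / water content observations (declining
#' relative water content down the rows, as a bench-dry PV curve is
#' measured), this: (i) finds the post-turgor-loss linear region of
#' `1/|psi|` against `100 - RWC` by growing the point set from the driest
#' end and keeping the largest set whose regression holds R^2 at or above
#' `r2_threshold`; (ii) extrapolates the line to full hydration to estimate
#' the osmotic potential at full turgor `pi_o = -1/intercept`; (iii) forms
#' turgor as `psi - pi(RWC)` and interpolates its first zero crossing for
#' the turgor loss point (`psi_TLP`, `RWC_TLP`); (iv) estimates the relative
#' capacitance at full turgor `C_ft` (slope of RWC fraction vs psi before
#' the TLP, MPa-1) and the bulk elastic modulus `epsilon` (slope of turgor
#' vs RWC fraction, MPa).
#'
#' @param data data frame with column `psi` (MPa) and either `RWC` (%) or
#'   `mass` (g).
#' @param dry_mass,sat_mass leaf dry and saturated mass (g), required when
#'   water content is given as `mass`:
#'   `RWC = 100 * (mass - dry_mass) / (sat_mass - dry_mass)`.
#' @param r2_threshold minimum R^2 for the linear region (default 0.995).
#'   When no region of >= 4 points reaches it, the best-R^2 region is used
#'   with a warning.
#' @return A `photofit_fit` with terms `pi_o`, `psi_TLP`, `RWC_TLP`, `C_ft`,
#'   `epsilon`; `$extra$linear_region` marks the points used.
#'   `autoplot()` draws the 1/|psi| transform with the fitted osmotic line;
#'   `$extra$plot_mass` holds the companion water-mass/psi figure.
#' @export
fit_pv_curve <- function(data, dry_mass = NULL, sat_mass = NULL,
                         r2_threshold = 0.995) {
  stopifnot(is.data.frame(data), "psi" %in% names(data))
  if (!"RWC" %in% names(data)) {
    if (!"mass" %in% names(data) || is.null(dry_mass) || is.null(sat_mass)) {
      abort("need an RWC column, or a mass column plus dry_mass and sat_mass")
    }
    data$RWC <- 100 * (data$mass - dry_mass) / (sat_mass - dry_mass)
  }
  data <- drop_missing(data, c("psi", "RWC"))
  if (nrow(data) < 8) abort("need at least 8 observations for a PV curve")
  if (any(diff(data$RWC) > 1e-9)) {
    abort("RWC must decline down the rows (bench-dry measurement order)")
  }
  data$psi <- normalize_psi(data$psi)
  if (any(data$psi >= 0)) {
    inform(sprintf(
      "dropping %d fully hydrated observation(s) with psi >= 0 (no 1/|psi| transform)",
      sum(data$psi >= 0)))
    data <- data[data$psi < 0, , drop = FALSE]
    if (nrow(data) < 8) abort("fewer than 8 observations with psi < 0")
  }
  x <- 100 - data$RWC
  y <- -1 / data$psi
  n <- nrow(data)
  # grow the linear set from the driest (largest-x) end
  r2 <- rep(NA_real_, n)
  for (m in 4:n) {
    idx <- (n - m + 1):n
    fit <- lm(y[idx] ~ x[idx])
    r2[m] <- summary(fit)$r.squared
  }
  ok <- which(r2 >= r2_threshold)
  if (length(ok)) {
    m_sel <- max(ok)
  } else {
    m_sel <- which.max(r2)
    warn(sprintf(
      "no linear region of >= 4 points reaches R^2 >= %g; using the best region (%d points, R^2 = %.4f)",
      r2_threshold, m_sel, r2[m_sel]))
  }
  idx <- (n - m_sel + 1):n
  osm_fit <- lm(y[idx] ~ x[idx])
  b0 <- coef(osm_fit)[[1]]
  b1 <- coef(osm_fit)[[2]]
  if (b0 <= 0) {
    abort("extrapolated 1/|psi| intercept is non-positive; no valid osmotic line (diagnostics: check for positive psi or mis-ordered rows)")
  }
  pi_o <- -1 / b0
  se_b0 <- tryCatch(summary(osm_fit)$coefficients[1, "Std. Error"],
                    error = function(e) NA_real_)
  se_pi_o <- se_b0 / b0^2 # delta method on -1/b0
  # osmotic potential along the curve and turgor
  pi_line <- -1 / (b0 + b1 * x)
  turgor <- data$psi - pi_line
  # first zero crossing of turgor moving from full hydration to dry
  nn <- nrow(data)
  cross <- which(turgor[-nn] > 0 & turgor[-1] <= 1e-12)[1]
  if (is.na(cross)) {
    abort("turgor never crosses zero: cannot locate the turgor loss point")
  }
  # locate the TLP by extending the pre-TLP turgor line to zero (turgor is
  # ~linear in water content near the loss point); fall back to sample
  # interpolation if the line is degenerate
  pre_pos <- which(turgor > 1e-12 & seq_along(turgor) <= cross)
  pre_pos <- tail(pre_pos, 4)
  x_tlp <- if (length(pre_pos) >= 2) {
    cf <- coef(lm(turgor[pre_pos] ~ x[pre_pos]))
    -cf[[1]] / cf[[2]]
  } else NA_real_
  if (!is.finite(x_tlp) || x_tlp < x[cross] || x_tlp > x[cross + 1]) {
    f <- turgor[cross] / (turgor[cross] - turgor[cross + 1])
    x_tlp <- x[cross] + f * (x[cross + 1] - x[cross])
  }
  RWC_TLP <- 100 - x_tlp
  psi_TLP <- -1 / (b0 + b1 * x_tlp)
  pre <- which(x <= x_tlp)
  if (length(pre) < 2) pre <- 1:2
  C_ft <- coef(lm(I(data$RWC[pre] / 100) ~ data$psi[pre]))[[2]]
  epsilon <- coef(lm(turgor[pre] ~ I(data$RWC[pre] / 100)))[[2]]
  coefs <- tibble(
    term = c("pi_o", "psi_TLP", "RWC_TLP", "C_ft", "epsilon"),
    estimate = c(pi_o, psi_TLP, RWC_TLP, C_ft, epsilon),
    std.error = c(se_pi_o, NA, NA, NA, NA))
  pred <- b0 + b1 * x
  fitted_tb <- mutate(data, .inv_psi = y, .fitted = pred,
                      .resid = y - pred)
  stats <- list(ssr = deviance(osm_fit), aic = AIC(osm_fit),
                bic = BIC(osm_fit), n = n, converged = TRUE, failed = FALSE,
                r2_linear = r2[m_sel], n_linear = m_sel)
  in_region <- seq_len(n) %in% idx
  pb <- function(fr) {
    d <- mutate(fr$fitted, x = 100 - .data$RWC,
                region = in_region)
    ggplot(d, aes(x = .data$x, y = .data$.inv_psi)) +
      geom_line(aes(y = .data$.fitted), colour = "grey50") +
      geom_point(aes(colour = .data$region)) +
      labs(x = "100 - RWC (%)", y = expression(1/abs(Psi)~(MPa^-1)),
           colour = "linear region") +
      theme_bw()
  }
  plot_mass <- ggplot(mutate(data, x = 100 - .data$RWC),
                      aes(x = .data$x, y = .data$psi)) +
    geom_point() + geom_line(colour = "grey50") +
    labs(x = "100 - RWC (%)", y = expression(Psi~(MPa))) + theme_bw()
  new_fit_result("pv_curve", coefs, data = data, fitted = fitted_tb,
                 stats = stats,
                 extra = list(linear_region = in_region,
                              osmotic_intercept = b0, osmotic_slope = b1,
                              turgor = turgor, plot_mass = plot_mass),
                 fit = osm_fit, plot_builder = pb)
}
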